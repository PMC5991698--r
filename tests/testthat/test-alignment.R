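test_that("score_shift evaluates the summed nearest-neighbour deviation", {
  expect_equal(score_shift(c(1.00, 2.00), c(1.10, 2.10), -0.10), 0)
  expect_equal(score_shift(c(1.00, 2.00), c(1.10, 2.10), 0), 0.20)
  # a query peak with no homologue behaves independently
  expect_equal(score_shift(1.00, c(1.00, 5.00), 0), 0)
  expect_error(score_shift(numeric(0), 1), "non-empty")
})

test_that("best_shift searches an inclusive grid and prefers no shift", {
  ref <- c(1.0, 2.0, 3.0)
  expect_equal(best_shift(ref, ref + 0.03, window = 0.05, step = 0.01), -0.03)
  expect_equal(best_shift(ref, ref, window = 0.05, step = 0.01), 0)
  # out-of-window drift still returns a bounded grid value
  sh <- best_shift(ref, ref + 0.20, window = 0.05, step = 0.01)
  expect_lte(abs(sh), 0.05)
})

test_that("select_reference minimises the median per-pair deviation", {
  # hand evaluation: A and B score median(0, 0.5)/2-peaks = 0.25, C scores 0.5;
  # A wins the A/B tie lexicographically
  d <- tiny_dataset()
  expect_equal(select_reference(d), "A")
  ident <- peak_dataset(list(Z = list(time = c(1, 2)),
                             Y = list(time = c(1, 2)),
                             X = list(time = c(1, 2))))
  expect_equal(select_reference(ident), "X")  # all score 0; lexicographic
  expect_error(select_reference(peak_dataset(list(A = list(time = 1)))),
               "at least 2")
})

test_that("full_align recovers injected drifts and conserves peaks", {
  sim <- simulate_peaks(sim_config(n_samples = 8, n_substances = 15,
                                   jitter_sd = 0, presence_prob = 1,
                                   n_unique_per_sample = 0, seed = 11))
  ref <- select_reference(sim$dataset)
  fa <- full_align(sim$dataset, ref, window = 0.1, step = 0.01)
  expect_equal(fa$shifts[[ref]], 0)
  rel_drift <- sim$truth$drift - sim$truth$drift[ref]
  expect_true(all(abs(fa$shifts + rel_drift) <= 0.005 + 1e-9))
  expect_equal(peak_counts(fa$dataset), peak_counts(sim$dataset))
  for (s in fa$dataset$sample_ids)
    expect_false(is.unsorted(fa$dataset$peaks[[s]]$time, strictly = TRUE))
  # identical samples need no shift
  ident <- peak_dataset(list(A = list(time = c(1, 2)),
                             B = list(time = c(1, 2))))
  expect_equal(unname(full_align(ident, "A")$shifts), c(0, 0))
  expect_error(full_align(ident, "Q"), "unknown reference")
})

test_that("partial alignment demotes cells per the two threshold rules", {
  # focal above mean + a: the focal cell moves down
  out <- partial_align(rm_of(matrix(c(2.00, 2.01, 2.05), nrow = 1)), 0.02)
  expect_equal(unname(out$rt), rbind(c(2.00, 2.01, 0), c(0, 0, 2.05)))
  # focal below mean - a: all previous cells move down
  out <- partial_align(rm_of(matrix(c(2.05, 2.05, 2.00), nrow = 1)), 0.02)
  expect_equal(unname(out$rt), rbind(c(0, 0, 2.00), c(2.05, 2.05, 0)))
  # all cells within a: unchanged
  rt <- matrix(c(2.00, 2.01, 2.02), nrow = 1)
  expect_equal(unname(partial_align(rm_of(rt), 0.02)$rt), rt)
  # equality with the threshold keeps the cell in place (strict inequalities)
  rt <- matrix(c(2.00, 2.02), nrow = 1)
  expect_equal(unname(partial_align(rm_of(rt), 0.02)$rt), rt)
  # measures travel with their retention times
  m <- retention_matrix(matrix(c(2.00, 2.01, 2.05), nrow = 1),
                        measures = list(area = matrix(c(5, 6, 7), nrow = 1)),
                        sample_ids = c("a", "b", "c"))
  out <- partial_align(m, 0.02)
  expect_equal(unname(out$measures$area), rbind(c(5, 6, 0), c(0, 0, 7)))
})

test_that("merge_rows merges complementary adjacent rows below b only", {
  out <- merge_rows(rm_of(rbind(c(2.00, 2.01, 0), c(0, 0, 2.03))), 0.08)
  expect_equal(unname(out$rt), rbind(c(2.00, 2.01, 2.03)))
  # a sample occupying both rows blocks the merge at any b
  conflicted <- rm_of(rbind(c(2.00, 2.01, 0), c(2.02, 0, 2.03)))
  expect_equal(nrow(merge_rows(conflicted, 10)$rt), 2)
  # strict inequality: b = 0 never merges
  out <- merge_rows(rm_of(rbind(c(2.00, 0), c(0, 2.00))), 0)
  expect_equal(nrow(out$rt), 2)
  # measures merge with their rows
  m <- retention_matrix(rbind(c(2.00, 0), c(0, 2.03)),
                        measures = list(area = rbind(c(5, 0), c(0, 7))),
                        sample_ids = c("a", "b"))
  expect_equal(unname(merge_rows(m, 0.08)$measures$area), rbind(c(5, 7)))
})

test_that("blank and singleton filters remove the documented rows", {
  rt <- rbind(c(1.0, 1.0, 1.0),
              c(2.0, 0.0, 2.0),
              c(0.0, 3.0, 0.0),
              c(4.0, 4.0, 0.0),
              c(5.0, 0.0, 0.0))
  m <- rm_of(rt, ids = c("S1", "S2", "BL"))
  rb <- remove_blanks(m, "BL")
  expect_equal(rb$removed, 2L)                    # rows 1 and 2 shared
  expect_equal(rb$matrix$sample_ids, c("S1", "S2"))
  expect_equal(nrow(rb$matrix$rt), 3)
  rs <- remove_singletons(rb$matrix)
  expect_equal(rs$removed, 2L)                    # rows "3.0" and "5.0"
  expect_equal(unname(rs$matrix$rt), rbind(c(4.0, 4.0)))
  expect_error(remove_blanks(m, "nope"), "unknown blank")
  # empty blank removes nothing; fully shared blank empties the matrix
  m2 <- rm_of(rbind(c(1, 0), c(2, 0)), ids = c("S1", "BL"))
  expect_equal(remove_blanks(m2, "BL")$removed, 0L)
  m3 <- rm_of(rbind(c(1, 1), c(2, 2)), ids = c("S1", "BL"))
  rb3 <- remove_blanks(m3, "BL")
  expect_equal(rb3$removed, 2L)
  expect_equal(nrow(rb3$matrix$rt), 0)
})

test_that("align_peaks pipeline conserves peaks and orders columns", {
  for (s in c(21, 22, 23)) {
    sim <- simulate_peaks(sim_config(n_samples = 8, n_substances = 12,
                                     rt_range = c(5, 15), seed = s))
    res <- align_peaks(sim$dataset)
    expect_equal(sum(res$matrix$rt != 0), sum(peak_counts(sim$dataset)))
    expect_equal(res$shifts[[res$reference]], 0)
    expect_true(all(abs(res$shifts) <= res$params$max_linear_shift + 1e-12))
    for (j in seq_len(ncol(res$matrix$rt))) {
      v <- res$matrix$rt[res$matrix$rt[, j] != 0, j]
      expect_false(is.unsorted(v, strictly = TRUE))
    }
    expect_true(all(rowSums(res$matrix$rt != 0) >= 1))
    means <- row_rt_means(res$matrix)
    expect_false(is.unsorted(means, strictly = TRUE))
  }
})

test_that("single-sample datasets pass through with one row per peak", {
  d <- peak_dataset(list(A = list(time = c(1.0, 1.5, 3.0))))
  res <- align_peaks(d)
  expect_equal(unname(res$matrix$rt), cbind(c(1.0, 1.5, 3.0)))
})

test_that("sample order only permutes the columns for a fixed reference", {
  sim <- simulate_peaks(sim_config(n_samples = 5, n_substances = 10,
                                   seed = 31))
  d <- sim$dataset
  perm <- rev(d$sample_ids)
  d2 <- peak_dataset(d$peaks[perm], rt_variable = d$rt_variable)
  params <- alignment_params(reference = d$sample_ids[1])
  r1 <- align_peaks(d, params)
  r2 <- align_peaks(d2, params)
  expect_equal(r2$matrix$rt[, d$sample_ids], r1$matrix$rt[, d$sample_ids])
})

test_that("alignment refuses invalid input and unknown samples", {
  dup_path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("S1\tS1", "time\ttime", "1.0\t1.2"), dup_path)
  expect_error(align_peaks(read_peak_list(dup_path)), "refuses")
  d <- tiny_dataset()
  expect_error(align_peaks(d, alignment_params(reference = "Q")),
               "unknown reference")
  expect_error(align_peaks(d, alignment_params(blanks = "Q")),
               "unknown blank")
})

test_that("threshold misconfiguration a >= b emits a warning", {
  expect_warning(alignment_params(max_diff_peak2mean = 0.08,
                                  min_diff_peak2peak = 0.08),
                 "min_diff_peak2peak")
  expect_silent(alignment_params(max_diff_peak2mean = 0.02,
                                 min_diff_peak2peak = 0.08))
})

test_that("partial alignment + merging agree with the oracle on random cases", {
  set.seed(99)
  grid <- seq(1.00, 1.30, by = 0.01)
  for (case in 1:200) {
    ncols <- sample(2:5, 1)
    cols <- lapply(seq_len(ncols), function(j)
      sort(sample(grid, sample(0:5, 1))))
    nmax <- max(1, max(lengths(cols)))
    rt <- vapply(cols, function(x) c(x, rep(0, nmax - length(x))),
                 numeric(nmax))
    rt <- matrix(rt, nrow = nmax)
    a <- sample(c(0.01, 0.02, 0.05), 1)
    b <- sample(c(0.02, 0.05, 0.1), 1)
    got <- partial_align(rm_of(rt), a)
    expect_equal(trim_rows(unname(got$rt)),
                 trim_rows(oracle_partial_align(rt, a)))
    merged <- merge_rows(got, b)
    expect_equal(unname(merged$rt), oracle_merge_rows(unname(got$rt), b))
    # conservation of each column's ordered peak values
    expect_equal(column_values(merged$rt), column_values(rt))
  }
})
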