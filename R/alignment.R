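#' Alignment parameters
#'
#' The tuning parameters of the three-step alignment. `max_linear_shift` is
#' the half-width (minutes) of the window searched for a systematic linear
#' drift of each sample against the reference; `max_diff_peak2mean` (the
#' partial-alignment threshold) is the allowed deviation of a focal peak's
#' retention time from the running mean of its row; `min_diff_peak2peak` (the
#' merge threshold) is the expected minimum difference in retention time
#' between distinct substances — adjacent rows closer than this are merged
#' when no sample occupies both. All three are in minutes.
#'
#' @param max_linear_shift shift window half-width, minutes.
#' @param max_diff_peak2mean partial-alignment threshold, minutes.
#' @param min_diff_peak2peak row-merge threshold, minutes.
#' @param shift_step grid interval of the linear-shift search, minutes.
#' @param reference sample id to align against, or `"auto"` to select the
#'   sample with the lowest median peak-deviation score.
#' @param blanks negative-control sample ids; substances shared with any
#'   blank are removed after alignment.
#' @param delete_single_peak if `TRUE`, substances present in a single sample
#'   are removed after alignment.
#' @return an `alignment_params` object.
#' @export
alignment_params <- function(max_diff_peak2mean = 0.02,
                             min_diff_peak2peak = 0.08,
                             max_linear_shift = 0.05,
                             shift_step = 0.01,
                             reference = "auto",
                             blanks = character(),
                             delete_single_peak = FALSE) {
  stopifnot(max_diff_peak2mean >= 0, min_diff_peak2peak >= 0,
            max_linear_shift >= 0, shift_step > 0)
  if (max_diff_peak2mean >= min_diff_peak2peak)
    warning("max_diff_peak2mean >= min_diff_peak2peak: split rows of one ",
            "substance cannot be merged back and error rates typically rise")
  structure(list(max_diff_peak2mean = max_diff_peak2mean,
                 min_diff_peak2peak = min_diff_peak2peak,
                 max_linear_shift = max_linear_shift,
                 shift_step = shift_step,
                 reference = reference,
                 blanks = as.character(blanks),
                 delete_single_peak = isTRUE(delete_single_peak)),
            class = "alignment_params")
}

#' Similarity score of a shifted query against a reference
#'
#' Sums, over all reference peaks, the deviation to the nearest query peak
#' after translating the query by `shift`. The score tends to zero as
#' homologous peaks line up, while peaks unique to either sample contribute
#' only their (roughly shift-independent) nearest-neighbour distance.
#'
#' @param ref_rts,query_rts retention times (minutes) of reference and query.
#' @param shift translation applied to the query, minutes.
#' @return non-negative score in minutes.
#' @export
score_shift <- function(ref_rts, query_rts, shift = 0) {
  if (!length(ref_rts) || !length(query_rts))
    stop("score_shift requires non-empty peak lists")
  q <- query_rts + shift
  sum(vapply(ref_rts, function(r) min(abs(r - q)), numeric(1)))
}

#' Best linear shift of a query against a reference
#'
#' Evaluates [score_shift()] on the inclusive grid
#' `seq(-window, window, by = step)` and returns the arg-min shift. Ties are
#' broken toward the smallest absolute shift, then toward the more negative
#' shift, so identical samples are a fixed point.
#'
#' @inheritParams score_shift
#' @param window half-width of the shift window, minutes.
#' @param step grid interval, minutes.
#' @return the selected shift in minutes.
#' @export
best_shift <- function(ref_rts, query_rts, window = 0.05, step = 0.01) {
  stopifnot(window >= 0, step > 0)
  grid <- seq(-window, window, by = step)
  if (grid[length(grid)] < window - 1e-12) grid <- c(grid, window)
  scores <- vapply(grid, function(s) score_shift(ref_rts, query_rts, s),
                   numeric(1))
  cand <- which(scores <= min(scores) + 1e-12)
  cand <- cand[order(abs(grid[cand]), grid[cand])]
  grid[cand[1]]
}

#' Automatic reference selection
#'
#' Scores every non-blank sample as a candidate reference: against each other
#' sample the average nearest-neighbour retention-time deviation of the
#' candidate's peaks is computed, and the candidate's score is the median of
#' these per-pair averages. The candidate with the lowest score wins; ties go
#' to the sample with more peaks, then to the lexicographically first id.
#'
#' @param dataset a `peak_dataset`.
#' @param blanks sample ids excluded from candidacy (they still serve as
#'   comparison samples).
#' @return the selected sample id.
#' @export
select_reference <- function(dataset, blanks = dataset$blanks) {
  rtv <- dataset$rt_variable
  n <- peak_counts(dataset)
  candidates <- setdiff(dataset$sample_ids[n > 0], blanks)
  if (length(candidates) < 2)
    stop("reference selection needs at least 2 non-blank samples with peaks")
  score_of <- function(cand) {
    ref <- dataset$peaks[[cand]][[rtv]]
    others <- setdiff(dataset$sample_ids[n > 0], cand)
    per_pair <- vapply(others, function(q) {
      qr <- dataset$peaks[[q]][[rtv]]
      mean(vapply(ref, function(r) min(abs(r - qr)), numeric(1)))
    }, numeric(1))
    stats::median(per_pair)
  }
  scores <- vapply(candidates, score_of, numeric(1))
  ord <- order(scores, -n[candidates], candidates)
  candidates[ord[1]]
}

#' Full alignment: correct systematic linear drift
#'
#' Translates every non-reference sample's retention times by the shift that
#' minimises the summed nearest-neighbour deviation against the reference
#' ([best_shift()]); abundance measures are untouched.
#'
#' @param dataset a `peak_dataset`.
#' @param reference sample id used as the fixed reference.
#' @param window,step see [best_shift()].
#' @return list with `dataset` (shifted `peak_dataset`) and `shifts` (named
#'   numeric, minutes; 0 for the reference).
#' @export
full_align <- function(dataset, reference, window = 0.05, step = 0.01) {
  if (!reference %in% dataset$sample_ids)
    stop("unknown reference sample: ", reference)
  rtv <- dataset$rt_variable
  ref_rts <- dataset$peaks[[reference]][[rtv]]
  shifts <- stats::setNames(numeric(length(dataset$sample_ids)),
                            dataset$sample_ids)
  peaks <- dataset$peaks
  for (s in dataset$sample_ids) {
    if (s == reference) next
    q <- peaks[[s]][[rtv]]
    if (!length(q) || !length(ref_rts)) next
    sh <- best_shift(ref_rts, q, window = window, step = step)
    shifts[s] <- sh
    peaks[[s]][[rtv]] <- q + sh
  }
  list(dataset = peak_dataset(peaks, rt_variable = rtv,
                              blanks = dataset$blanks, sort = FALSE),
       shifts = shifts)
}

# Move column j of every matrix in `mats` down one row starting at row r;
# grows the matrices by a zero row when the column's last row is occupied.
push_column_down <- function(mats, r, j) {
  n <- nrow(mats[[1]])
  if (mats[[1]][n, j] != 0) {
    mats <- lapply(mats, function(m) rbind(m, 0))
    n <- n + 1
  }
  for (i in seq_along(mats)) {
    col <- mats[[i]][, j]
    col[(r + 1):n] <- col[r:(n - 1)]
    col[r] <- 0
    mats[[i]][, j] <- col
  }
  mats
}

#' Partial alignment: sort individual peaks into substance rows
#'
#' Performs a single top-to-bottom pass over the matrix rows. Within a row,
#' cells are visited in sample order and each focal retention time is
#' compared with the mean of the previous non-zero cells of that row: if it
#' exceeds the mean by more than `a` the focal cell (with everything below it
#' in its column) is moved down one row; if it falls below the mean by more
#' than `a`, all previous non-zero cells (with everything below each, per
#' column) move down one row and the focal cell stays. New rows are appended
#' at the bottom as needed.
#'
#' @param mat a `retention_matrix` with individually sorted columns.
#' @param a the `max_diff_peak2mean` threshold in minutes.
#' @return the rearranged `retention_matrix`.
#' @export
partial_align <- function(mat, a) {
  stopifnot(a >= 0)
  mats <- c(list(mat$rt), mat$measures)
  n_col <- ncol(mat$rt)
  r <- 1
  while (r <= nrow(mats[[1]])) {
    run_sum <- 0
    run_n <- 0L
    m <- 1
    while (m <= n_col) {
      v <- mats[[1]][r, m]
      if (v != 0) {
        if (run_n > 0L) {
          mu <- run_sum / run_n
          if (v > mu + a) {
            mats <- push_column_down(mats, r, m)
          } else if (v < mu - a) {
            for (j in which(mats[[1]][r, seq_len(m - 1)] != 0))
              mats <- push_column_down(mats, r, j)
            run_sum <- v
            run_n <- 1L
          } else {
            run_sum <- run_sum + v
            run_n <- run_n + 1L
          }
        } else {
          run_sum <- v
          run_n <- 1L
        }
      }
      m <- m + 1
    }
    r <- r + 1
  }
  retention_matrix(mats[[1]], mats[-1], mat$sample_ids)
}

#' Merge adjacent rows holding one substance
#'
#' Homologous peaks split across two adjacent rows leave a complementary
#' pattern: no sample holds a peak in both rows. Such a pair is merged when
#' additionally the two row mean retention times differ by less than `b`.
#' Scans adjacent pairs top-to-bottom and repeats (with recomputed means)
#' until a full scan performs no merge; all-zero rows are deleted.
#'
#' @param mat a `retention_matrix`.
#' @param b the `min_diff_peak2peak` threshold in minutes.
#' @return the merged `retention_matrix`.
#' @export
merge_rows <- function(mat, b) {
  stopifnot(b >= 0)
  mat <- drop_empty_rows(mat)
  repeat {
    merged_any <- FALSE
    r <- 1
    while (r < nrow(mat$rt)) {
      top <- mat$rt[r, ]
      bot <- mat$rt[r + 1, ]
      no_conflict <- !any(top != 0 & bot != 0)
      mu_top <- mean(top[top != 0])
      mu_bot <- mean(bot[bot != 0])
      if (no_conflict && abs(mu_top - mu_bot) < b) {
        mat$rt[r, ] <- top + bot
        mat$rt <- mat$rt[-(r + 1), , drop = FALSE]
        mat$measures <- lapply(mat$measures, function(m) {
          m[r, ] <- m[r, ] + m[r + 1, ]
          m[-(r + 1), , drop = FALSE]
        })
        merged_any <- TRUE
      } else {
        r <- r + 1
      }
    }
    if (!merged_any) break
  }
  mat
}

#' Remove substances shared with negative controls
#'
#' Deletes every row with a peak in any blank column, then deletes the blank
#' columns themselves.
#'
#' @param mat a `retention_matrix`.
#' @param blanks blank sample ids (must exist among the columns).
#' @return list with `matrix` (filtered), `removed` (count) and `row_means`
#'   (mean retention times of the removed rows).
#' @export
remove_blanks <- function(mat, blanks) {
  unknown <- setdiff(blanks, mat$sample_ids)
  if (length(unknown))
    stop("unknown blank sample(s): ", paste(unknown, collapse = ", "))
  if (!length(blanks))
    return(list(matrix = mat, removed = 0L, row_means = numeric(0)))
  bcol <- mat$sample_ids %in% blanks
  shared <- rowSums(mat$rt[, bcol, drop = FALSE] != 0) > 0
  row_means <- row_rt_means(mat)[shared]
  keep_rows <- !shared
  out <- retention_matrix(
    mat$rt[keep_rows, !bcol, drop = FALSE],
    lapply(mat$measures, function(m) m[keep_rows, !bcol, drop = FALSE]),
    mat$sample_ids[!bcol])
  list(matrix = drop_empty_rows(out), removed = sum(shared),
       row_means = unname(row_means))
}

#' Remove single-sample substances
#'
#' Deletes rows present in exactly one sample; such substances carry no
#' information for similarity analyses.
#'
#' @param mat a `retention_matrix`.
#' @return list with `matrix`, `removed` and `row_means` as in
#'   [remove_blanks()].
#' @export
remove_singletons <- function(mat) {
  prev <- rowSums(mat$rt != 0)
  single <- prev == 1
  row_means <- row_rt_means(mat)[single]
  out <- retention_matrix(mat$rt[!single, , drop = FALSE],
                          lapply(mat$measures,
                                 function(m) m[!single, , drop = FALSE]),
                          mat$sample_ids)
  list(matrix = out, removed = sum(single), row_means = unname(row_means))
}

#' Align chromatogram peak lists
#'
#' Runs the full pipeline: reference selection (if `reference = "auto"`),
#' linear-shift full alignment, conversion to the retention-matrix working
#' format, partial alignment with threshold `max_diff_peak2mean`, merging of
#' adjacent complementary rows with threshold `min_diff_peak2peak`, removal
#' of substances shared with blanks, and removal of single-sample substances
#' if requested. Deterministic for fixed input and parameters.
#'
#' @param dataset a `peak_dataset` (or a path to a peak-list file, read via
#'   [read_peak_list()]). Must pass [check_input()] without errors.
#' @param params an [alignment_params()] object; alternatively pass
#'   individual parameters through `...`.
#' @param ... parameters forwarded to [alignment_params()] when `params` is
#'   not supplied.
#' @param rt_col_name,sep passed to [read_peak_list()] when `dataset` is a
#'   file path.
#' @return an `alignment_result` carrying the final `matrix`, the
#'   `input_snapshot`, the `reference` id, the applied `shifts`, filter logs,
#'   the `params` used and a step-by-step `log`.
#' @export
align_peaks <- function(dataset, params = NULL, ..., rt_col_name = "time",
                        sep = "\t") {
  if (is.character(dataset) && length(dataset) == 1)
    dataset <- read_peak_list(dataset, rt_col_name = rt_col_name, sep = sep)
  if (is.null(params)) params <- alignment_params(...)
  stopifnot(inherits(dataset, "peak_dataset"),
            inherits(params, "alignment_params"))
  if (length(params$blanks)) {
    dataset$blanks <- union(dataset$blanks, params$blanks)
    bad <- setdiff(dataset$blanks, dataset$sample_ids)
    if (length(bad)) stop("unknown blank sample(s): ", paste(bad, collapse = ", "))
  }
  report <- check_input(dataset)
  if (!report$ok)
    stop("input failed validation; alignment refuses to run. ",
         paste(report$issues$message[report$issues$severity == "error"],
               collapse = "; "))
  log <- list()
  note <- function(step, ...) log[[length(log) + 1]] <<-
    list(step = step, detail = sprintf(...))

  n_in <- peak_counts(dataset)
  multi_sample <- sum(peak_counts(dataset)[
    !dataset$sample_ids %in% dataset$blanks] > 0) >= 2

  reference <- params$reference
  if (identical(reference, "auto")) {
    if (multi_sample) {
      reference <- select_reference(dataset, blanks = dataset$blanks)
      note("select_reference", "automatically selected '%s'", reference)
    } else {
      reference <- dataset$sample_ids[which.max(n_in)]
      note("select_reference", "single eligible sample; reference '%s'",
           reference)
    }
  } else if (!reference %in% dataset$sample_ids) {
    stop("unknown reference sample: ", reference)
  } else {
    note("select_reference", "user-supplied reference '%s'", reference)
  }

  fa <- full_align(dataset, reference, window = params$max_linear_shift,
                   step = params$shift_step)
  note("full_align", "applied linear shifts in [%.3f, %.3f] min",
       min(fa$shifts), max(fa$shifts))

  mat <- to_matrix(fa$dataset)
  mat <- partial_align(mat, params$max_diff_peak2mean)
  note("partial_align", "%d rows after partial alignment", nrow(mat$rt))
  mat <- merge_rows(mat, params$min_diff_peak2peak)
  note("merge_rows", "%d rows after merging", nrow(mat$rt))

  stopifnot(sum(mat$rt != 0) == sum(n_in))  # conservation before filtering
  prefilter <- mat

  rb <- remove_blanks(mat, dataset$blanks)
  mat <- rb$matrix
  if (length(dataset$blanks))
    note("remove_blanks", "removed %d substance(s) shared with blanks %s",
         rb$removed, paste(dataset$blanks, collapse = ", "))
  rs <- list(matrix = mat, removed = 0L, row_means = numeric(0))
  if (params$delete_single_peak) {
    rs <- remove_singletons(mat)
    mat <- rs$matrix
    note("remove_singletons", "removed %d single-sample substance(s)",
         rs$removed)
  }

  structure(list(matrix = mat,
                 matrix_prefilter = prefilter,
                 input_snapshot = dataset,
                 reference = reference,
                 shifts = fa$shifts,
                 removed_blank_rows = list(count = rb$removed,
                                           row_means = rb$row_means),
                 removed_singleton_rows = list(count = rs$removed,
                                               row_means = rs$row_means),
                 params = params,
                 log = log),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  p <- x$params
  cat("Retention-time alignment summary\n")
  cat("--------------------------------\n")
  cat("Parameters (including unaltered defaults):\n")
  cat(sprintf("  max_diff_peak2mean = %g\n", p$max_diff_peak2mean))
  cat(sprintf("  min_diff_peak2peak = %g\n", p$min_diff_peak2peak))
  cat(sprintf("  max_linear_shift   = %g\n", p$max_linear_shift))
  cat(sprintf("  shift_step         = %g\n", p$shift_step))
  cat(sprintf("  reference          = %s\n", p$reference))
  cat(sprintf("  blanks             = %s\n",
              if (length(p$blanks)) paste(p$blanks, collapse = ", ") else "none"))
  cat(sprintf("  delete_single_peak = %s\n", p$delete_single_peak))
  cat(sprintf("Reference used: %s\n", x$reference))
  cat(sprintf("Samples: %d (input peaks: %d)\n",
              length(x$input_snapshot$sample_ids),
              sum(peak_counts(x$input_snapshot))))
  cat(sprintf("Applied shifts: %.3f to %.3f min\n",
              min(x$shifts), max(x$shifts)))
  cat(sprintf("Substances shared with blanks removed: %d\n",
              x$removed_blank_rows$count))
  cat(sprintf("Single-sample substances removed: %d\n",
              x$removed_singleton_rows$count))
  cat(sprintf("Aligned substances: %d\n", nrow(x$matrix$rt)))
  for (e in x$log) cat(sprintf("  - %s: %s\n", e$step, e$detail))
  invisible(x)
}

#' Write alignment output files
#'
#' Writes the aligned retention-time matrix and each abundance-measure matrix
#' as tab-delimited tables (one row per aligned substance, labelled by its
#' mean retention time, one column per sample), a plain-text run summary
#' reproducing the parameter set including unaltered defaults, and a
#' machine-readable JSON run log.
#'
#' @param result an `alignment_result`.
#' @param dir output directory (created if absent).
#' @param sep field separator for the tables.
#' @return named character vector of the files written, invisibly.
#' @export
write_aligned <- function(result, dir, sep = "\t") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat <- result$matrix
  files <- c()
  write_tab <- function(m, path) {
    df <- data.frame(mean_RT = row_rt_means(mat), m, check.names = FALSE)
    if (nrow(m) == 0) df <- df[0, , drop = FALSE]
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    path
  }
  files["rt"] <- write_tab(mat$rt, file.path(dir, "aligned_rt.txt"))
  for (v in names(mat$measures))
    files[v] <- write_tab(mat$measures[[v]],
                          file.path(dir, paste0("aligned_", v, ".txt")))
  summary_path <- file.path(dir, "summary.txt")
  writeLines(utils::capture.output(print(result)), summary_path)
  files["summary"] <- summary_path
  log_path <- file.path(dir, "run_log.json")
  jsonlite::write_json(
    list(reference = result$reference,
         shifts = as.list(result$shifts),
         params = unclass(result$params),
         removed_blank_rows = result$removed_blank_rows$count,
         removed_singleton_rows = result$removed_singleton_rows$count,
         n_substances = nrow(mat$rt),
         steps = result$log),
    log_path, auto_unbox = TRUE, digits = NA)
  files["log"] <- log_path
  invisible(files)
}
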