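#' Simulation configuration
#'
#' Parameters of the synthetic peak-list generator. A set of "true"
#' substances is placed on the retention-time axis with a minimum spacing;
#' every sample receives a systematic linear drift (uniform in
#' `[-drift_range, drift_range]`) plus independent Gaussian jitter per peak,
#' a Bernoulli presence/absence draw per substance, a number of
#' sample-exclusive peaks, and log-normal abundances. Blank samples contain
#' only a designated set of contaminant substances under the same noise
#' model.
#'
#' The defaults describe a typical medium-sized GC-FID study: 30 samples and
#' 40 substances spaced at least 0.15 min apart, per-peak jitter of
#' sd 0.005 min, per-sample drift within +/-0.04 min, 90% presence and 3
#' sample-unique peaks per sample.
#'
#' @param n_samples number of (non-blank) samples.
#' @param n_substances number of shared true substances.
#' @param rt_range retention-time interval (minutes) hosting the substances.
#' @param min_spacing minimum spacing between true substance retention times,
#'   also enforced between unique peaks and any other peak (minutes).
#' @param jitter_sd per-peak Gaussian retention-time noise, sd in minutes.
#' @param drift_range per-sample systematic shift drawn uniformly in
#'   `[-drift_range, drift_range]` minutes.
#' @param presence_prob probability that a substance appears in a sample.
#' @param n_unique_per_sample count of sample-exclusive peaks per sample.
#' @param n_blanks number of blank (negative-control) samples.
#' @param blank_contaminants number of true substances also injected into
#'   every blank.
#' @param abundance_logmean,abundance_logsd log-normal abundance parameters.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 30, n_substances = 40,
                       rt_range = c(5, 35), min_spacing = 0.15,
                       jitter_sd = 0.005, drift_range = 0.04,
                       presence_prob = 0.9, n_unique_per_sample = 3,
                       n_blanks = 0, blank_contaminants = 0,
                       abundance_logmean = 4, abundance_logsd = 1,
                       seed = 1L) {
  stopifnot(n_samples >= 1, n_substances >= 1, min_spacing > 0,
            length(rt_range) == 2, rt_range[1] < rt_range[2],
            jitter_sd >= 0, drift_range >= 0,
            presence_prob >= 0, presence_prob <= 1,
            n_unique_per_sample >= 0, n_blanks >= 0,
            blank_contaminants >= 0, blank_contaminants <= n_substances)
  if (diff(rt_range) < (n_substances - 1) * min_spacing)
    stop("rt_range is too narrow to host n_substances at min_spacing")
  structure(list(n_samples = n_samples, n_substances = n_substances,
                 rt_range = rt_range, min_spacing = min_spacing,
                 jitter_sd = jitter_sd, drift_range = drift_range,
                 presence_prob = presence_prob,
                 n_unique_per_sample = n_unique_per_sample,
                 n_blanks = n_blanks,
                 blank_contaminants = blank_contaminants,
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a key=value file
#'
#' @param path text file with one `key = value` pair per line; `rt_range` as
#'   two comma-separated numbers; `#` starts a comment.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    args[[key]] <- as.numeric(strsplit(val, ",")[[1]])
  }
  do.call(sim_config, args)
}

# Place `k` retention times uniformly in `rng` keeping >= spacing from
# everything in `avoid` and from each other.
place_away <- function(k, rng, spacing, avoid) {
  out <- numeric(0)
  for (i in seq_len(k)) {
    for (try in 1:1000) {
      x <- stats::runif(1, rng[1], rng[2])
      if (all(abs(x - c(avoid, out)) >= spacing)) break
      if (try == 1000)
        stop("infeasible spacing: could not place a unique peak")
    }
    out <- c(out, x)
  }
  out
}

#' Generate a synthetic peak-list dataset with ground truth
#'
#' Emits a multi-sample peak list (variables `time` and `area`) following the
#' noise model described in [sim_config()], together with a ground-truth
#' record mapping every generated peak to its true substance identity (or
#' `"unique"` for sample-exclusive peaks). A sample whose jittered peak order
#' differs from the true substance order is redrawn so that ground truth
#' remains well defined.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [peak_dataset()], blanks declared) and
#'   `truth` (list with `peaks`: data.frame sample/substance/rt/area,
#'   `drift`: named per-sample shifts, `true_rt`: named substance positions,
#'   `contaminants`: substance ids injected into blanks).
#' @export
simulate_peaks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sub <- config$n_substances
  u <- sort(stats::runif(n_sub, config$rt_range[1],
                         config$rt_range[2] - (n_sub - 1) * config$min_spacing))
  true_rt <- u + (seq_len(n_sub) - 1) * config$min_spacing
  sub_ids <- sprintf("sub%03d", seq_len(n_sub))
  names(true_rt) <- sub_ids
  contaminants <- if (config$blank_contaminants > 0)
    sort(sample(sub_ids, config$blank_contaminants)) else character(0)

  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
  blank_ids <- if (config$n_blanks > 0) sprintf("B%d", seq_len(config$n_blanks))
    else character(0)
  all_ids <- c(sample_ids, blank_ids)
  drift <- stats::setNames(
    stats::runif(length(all_ids), -config$drift_range, config$drift_range),
    all_ids)
  if (config$drift_range == 0) drift[] <- 0

  peaks <- list()
  truth_rows <- list()
  for (s in all_ids) {
    if (s %in% blank_ids) {
      base <- true_rt[contaminants]
      labels <- contaminants
    } else {
      present <- stats::runif(n_sub) < config$presence_prob
      uniq <- place_away(config$n_unique_per_sample, config$rt_range,
                         config$min_spacing, true_rt)
      base <- c(true_rt[present], uniq)
      labels <- c(sub_ids[present], rep("unique", length(uniq)))
    }
    ord <- order(base)
    base <- base[ord]
    labels <- labels[ord]
    n <- length(base)
    if (n > 0) {
      for (try in 1:100) {
        rts <- base + drift[s] + stats::rnorm(n, 0, config$jitter_sd)
        if (n == 1 || all(diff(rts) > 0)) break
        if (try == 100)
          stop("could not draw a sample preserving the substance order; ",
               "jitter_sd is too large relative to min_spacing")
      }
      area <- stats::rlnorm(n, config$abundance_logmean,
                            config$abundance_logsd)
    } else {
      rts <- numeric(0)
      area <- numeric(0)
    }
    peaks[[s]] <- list(time = unname(rts), area = area)
    if (n > 0)
      truth_rows[[s]] <- data.frame(sample = s, substance = labels,
                                    rt = unname(rts), area = area,
                                    stringsAsFactors = FALSE)
  }
  truth_peaks <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  dataset <- peak_dataset(peaks, rt_variable = "time", blanks = blank_ids)
  list(dataset = dataset,
       truth = list(peaks = truth_peaks, drift = drift, true_rt = true_rt,
                    contaminants = contaminants))
}

#' Known-substance map from simulator ground truth
#'
#' Restricts the ground-truth peak record to true substances (dropping
#' sample-unique peaks) in the format expected by [error_rate()].
#'
#' @param truth the `truth` element returned by [simulate_peaks()].
#' @return data.frame with columns `substance`, `sample`, `rt`.
#' @export
known_map <- function(truth) {
  k <- truth$peaks[truth$peaks$substance != "unique",
                   c("substance", "sample", "rt")]
  rownames(k) <- NULL
  k
}

#' Write a ground-truth file
#' @param truth the `truth` element of [simulate_peaks()].
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Alignment error rates over a parameter grid
#'
#' Simulates `n_reps` replicate datasets (replicate `r` uses `seed + r`) and
#' aligns each one under every combination of the partial-alignment threshold
#' `a` (`max_diff_peak2mean`) and the merge threshold `b`
#' (`min_diff_peak2peak`), recording the mean mode-row error rate per cell.
#' The reference sample is selected once per dataset so that cells differ
#' only in `a` and `b`.
#'
#' @param config a [sim_config()].
#' @param a_grid,b_grid threshold grids in minutes.
#' @param n_reps number of replicate datasets per cell.
#' @param window,step linear-shift search parameters.
#' @return data.frame with columns `a`, `b`, `mean_error`.
#' @export
parameter_sweep <- function(config, a_grid, b_grid, n_reps = 5,
                            window = 0.05, step = 0.01) {
  stopifnot(length(a_grid) > 0, length(b_grid) > 0, n_reps >= 1)
  sims <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    simulate_peaks(cfg)
  })
  refs <- vapply(sims, function(s) select_reference(s$dataset), character(1))
  grid <- expand.grid(a = a_grid, b = b_grid)
  grid$mean_error <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(n_reps), function(r) {
      params <- suppressWarnings(alignment_params(
        max_diff_peak2mean = grid$a[i], min_diff_peak2peak = grid$b[i],
        max_linear_shift = window, shift_step = step,
        reference = refs[r]))
      res <- align_peaks(sims[[r]]$dataset, params)
      error_rate(res, known_map(sims[[r]]$truth))$error_rate
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid
}
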