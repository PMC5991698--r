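#' Diagnostic summaries of an alignment
#'
#' Computes the quantities behind the standard diagnostic plots: per-sample
#' peak counts before and after alignment and filtering, the applied linear
#' shifts, the within-substance retention-time variation (max minus min over
#' the samples sharing a substance), the prevalence of each substance (number
#' of samples sharing it), and the signed deviation of every peak from its
#' substance's mean retention time (the heatmap matrix).
#'
#' @param result an `alignment_result`.
#' @return an `alignment_diagnostics` list with fields `peak_counts`
#'   (data.frame: sample, before, after), `shifts` (named numeric),
#'   `rt_variation` (per substance), `prevalence` (per substance) and
#'   `heatmap` (see [heatmap_matrix()]).
#' @export
align_diagnostics <- function(result) {
  before <- peak_counts(result$input_snapshot)
  mat <- result$matrix
  after <- stats::setNames(colSums(mat$rt != 0), mat$sample_ids)
  pc <- data.frame(sample = result$input_snapshot$sample_ids,
                   before = as.integer(before),
                   after = as.integer(after[result$input_snapshot$sample_ids]),
                   stringsAsFactors = FALSE)
  pc$after[is.na(pc$after)] <- 0L   # blank columns are dropped from the output
  rt <- mat$rt
  rt_var <- apply(rt, 1, function(r) {
    r <- r[r != 0]
    if (length(r)) max(r) - min(r) else NA_real_
  })
  structure(list(peak_counts = pc,
                 shifts = result$shifts,
                 rt_variation = unname(rt_var),
                 prevalence = unname(rowSums(rt != 0)),
                 heatmap = heatmap_matrix(result)),
            class = "alignment_diagnostics")
}

#' @export
print.alignment_diagnostics <- function(x, ...) {
  cat("alignment diagnostics\n")
  cat(sprintf("  peaks per sample: before %d-%d, after %d-%d\n",
              min(x$peak_counts$before), max(x$peak_counts$before),
              min(x$peak_counts$after), max(x$peak_counts$after)))
  cat(sprintf("  shifts: %.3f to %.3f min\n", min(x$shifts), max(x$shifts)))
  if (length(x$rt_variation))
    cat(sprintf("  substance rt variation: median %.4f min, max %.4f min\n",
                stats::median(x$rt_variation, na.rm = TRUE),
                max(x$rt_variation, na.rm = TRUE)))
  cat(sprintf("  prevalence: %s\n",
              paste(utils::head(sort(unique(x$prevalence))), collapse = ", ")))
  invisible(x)
}

#' Signed retention-time deviations for heatmap display
#'
#' For every present peak, the deviation of its retention time from the mean
#' retention time of its row; absences are `NA` (never 0, which is a legal
#' deviation). Rows whose deviations exceed a chosen threshold flag potential
#' misalignments.
#'
#' @param result an `alignment_result`.
#' @return numeric matrix (substances x samples) of signed deviations in
#'   minutes, `NA` where a sample lacks the substance.
#' @export
heatmap_matrix <- function(result) {
  rt <- result$matrix$rt
  means <- row_rt_means(result$matrix)
  dev <- sweep(rt, 1, means, "-")
  dev[rt == 0] <- NA
  dev
}

#' Plot alignment diagnostics
#'
#' Renders four base-graphics panels from the data computed by
#' [align_diagnostics()]: peak counts before/after, a histogram of applied
#' shifts, a histogram of within-substance retention-time variation, and the
#' distribution of substance prevalence.
#'
#' @param x an `alignment_diagnostics` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.alignment_diagnostics <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(t(as.matrix(x$peak_counts[, c("before", "after")])),
                    beside = TRUE, names.arg = x$peak_counts$sample,
                    las = 2, cex.names = 0.6, main = "Peaks per sample",
                    legend.text = c("before", "after"))
  graphics::hist(x$shifts, main = "Applied linear shifts",
                 xlab = "shift (min)")
  graphics::hist(x$rt_variation, main = "Retention time variation",
                 xlab = "max - min (min)")
  graphics::hist(x$prevalence, main = "Substances shared across samples",
                 xlab = "number of samples",
                 breaks = seq(0.5, max(x$prevalence) + 0.5, by = 1))
  invisible(x)
}
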