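#' Normalise aligned peak abundances
#'
#' Converts an abundance measure (for example peak area) to relative
#' concentrations per sample: each substance's value is expressed as a
#' percentage of the sample's total, so every non-empty sample row sums to
#' 100. The output is a samples-by-substances data frame, the community-matrix
#' orientation expected by downstream multivariate tools.
#'
#' @param result an `alignment_result`.
#' @param conc_col_name name of the abundance variable to normalise.
#' @param rt_digits decimals used to format the substance labels (mean
#'   retention times).
#' @return data.frame with one row per sample and one column per aligned
#'   substance; row names are the sample ids, column names the mean retention
#'   times.
#' @export
normalise_peaks <- function(result, conc_col_name, rt_digits = 2) {
  mat <- result$matrix
  if (!conc_col_name %in% names(mat$measures))
    stop(sprintf("unknown abundance variable '%s'; available: %s",
                 conc_col_name, paste(names(mat$measures), collapse = ", ")))
  m <- mat$measures[[conc_col_name]]
  if (any(m < 0)) stop("negative abundance values cannot be normalised")
  totals <- colSums(m)
  rel <- sweep(m, 2, ifelse(totals > 0, totals, 1), "/") * 100
  rel[, totals == 0] <- 0
  out <- as.data.frame(t(rel))
  colnames(out) <- formatC(row_rt_means(mat), format = "f", digits = rt_digits)
  rownames(out) <- mat$sample_ids
  out
}
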