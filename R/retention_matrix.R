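#' Retention matrices
#'
#' The working format of the aligner: a substances-by-samples matrix of
#' retention times in which each column holds one sample's peaks in ascending
#' order and 0 encodes the absence of a peak, together with parallel matrices
#' carrying each abundance variable at the same positions.
#'
#' @param rt numeric matrix of retention times (rows = putative substances,
#'   columns = samples), 0 = absent.
#' @param measures named list of numeric matrices with the same dimensions as
#'   `rt`, non-zero only where `rt` is non-zero.
#' @param sample_ids column identifiers.
#' @return an object of class `retention_matrix`.
#' @export
retention_matrix <- function(rt, measures = list(), sample_ids = colnames(rt)) {
  rt <- as.matrix(rt)
  if (is.null(sample_ids)) sample_ids <- paste0("V", seq_len(ncol(rt)))
  colnames(rt) <- sample_ids
  measures <- lapply(measures, function(m) {
    m <- as.matrix(m)
    stopifnot(all(dim(m) == dim(rt)))
    colnames(m) <- sample_ids
    m
  })
  structure(list(rt = rt, measures = measures, sample_ids = sample_ids),
            class = "retention_matrix")
}

#' @export
print.retention_matrix <- function(x, ...) {
  cat(sprintf("retention_matrix: %d putative substances x %d samples (%d peaks)\n",
              nrow(x$rt), ncol(x$rt), sum(x$rt != 0)))
  invisible(x)
}

#' @export
dim.retention_matrix <- function(x) dim(x$rt)

#' Convert a peak dataset to the initial retention matrix
#'
#' Each sample's peaks occupy the leading rows of its column in ascending
#' retention-time order, padded with 0 below; parallel matrices carry every
#' other variable at the same positions.
#'
#' @param dataset a `peak_dataset` that passes [check_input()] without
#'   errors.
#' @return a [retention_matrix()].
#' @export
to_matrix <- function(dataset) {
  rep_ <- check_input(dataset)
  if (!rep_$ok)
    stop("dataset fails validation; run check_input() for details")
  rtv <- dataset$rt_variable
  n <- peak_counts(dataset)
  nmax <- max(c(n, 1L))
  rt <- matrix(0, nrow = nmax, ncol = length(dataset$sample_ids))
  meas_names <- setdiff(dataset$variable_names, rtv)
  measures <- lapply(meas_names, function(v)
    matrix(0, nrow = nmax, ncol = length(dataset$sample_ids)))
  names(measures) <- meas_names
  for (k in seq_along(dataset$sample_ids)) {
    p <- dataset$peaks[[k]]
    if (n[k] == 0) next
    rt[seq_len(n[k]), k] <- p[[rtv]]
    for (v in meas_names) measures[[v]][seq_len(n[k]), k] <- p[[v]]
  }
  retention_matrix(rt, measures, dataset$sample_ids)
}

#' Row mean retention times over non-zero cells
#' @param mat a `retention_matrix` or numeric matrix (0 = absent).
#' @return numeric vector, `NaN` for all-zero rows.
#' @export
row_rt_means <- function(mat) {
  rt <- if (inherits(mat, "retention_matrix")) mat$rt else mat
  n <- rowSums(rt != 0)
  ifelse(n > 0, rowSums(rt) / n, NaN)
}

# Drop all-zero rows from a retention matrix.
drop_empty_rows <- function(mat) {
  keep <- rowSums(mat$rt != 0) > 0
  if (all(keep)) return(mat)
  if (!any(keep)) {
    empty <- matrix(0, nrow = 0, ncol = ncol(mat$rt))
    return(retention_matrix(empty, lapply(mat$measures, function(m) empty),
                            mat$sample_ids))
  }
  retention_matrix(mat$rt[keep, , drop = FALSE],
                   lapply(mat$measures, function(m) m[keep, , drop = FALSE]),
                   mat$sample_ids)
}
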