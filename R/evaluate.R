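#' Known-substance maps
#'
#' For datasets where a subset of substances has been identified externally
#' (for example by GC-MS), a known-substance map records every occurrence of
#' each known substance as a (sample, retention time) pair in the coordinates
#' of the input peak list. [error_rate()] and [retention_deviation()] use
#' these occurrences to score an alignment without requiring the aligner to
#' label rows.
#'
#' @param path tab-delimited file with columns `substance`, `sample`, `rt`.
#' @param sep field separator.
#' @return data.frame with columns `substance`, `sample`, `rt`.
#' @export
read_known_substances <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("substance", "sample", "rt")
  if (!all(need %in% names(df)))
    stop("known-substance file must have columns: ",
         paste(need, collapse = ", "))
  df$rt <- as.numeric(df$rt)
  if (anyDuplicated(df[c("sample", "rt")]))
    stop("each (sample, retention time) pair may belong to only one substance")
  df[need]
}

# Locate each occurrence in an alignment: returns the row index of every
# (sample, rt) pair after applying the per-sample shift, looking first in the
# final matrix, then in the pre-filter matrix ("filtered"), else "lost".
locate_occurrences <- function(result, known, tol = 1e-6) {
  find_row <- function(mat, sample, rt_shifted) {
    j <- match(sample, mat$sample_ids)
    if (is.na(j)) return(NA_integer_)
    hit <- which(abs(mat$rt[, j] - rt_shifted) < tol & mat$rt[, j] != 0)
    if (length(hit) == 1) hit else NA_integer_
  }
  shifts <- result$shifts
  rt_shifted <- known$rt + shifts[known$sample]
  row_final <- mapply(find_row, known$sample, rt_shifted,
                      MoreArgs = list(mat = result$matrix))
  row_pre <- mapply(find_row, known$sample, rt_shifted,
                    MoreArgs = list(mat = result$matrix_prefilter))
  status <- ifelse(!is.na(row_final), "aligned",
                   ifelse(!is.na(row_pre), "filtered", "lost"))
  if (any(status == "lost"))
    stop(sprintf("%d known occurrence(s) could not be located in the aligned matrix; check that the map uses input coordinates", sum(status == "lost")))
  data.frame(substance = known$substance, sample = known$sample,
             rt = known$rt, row = as.integer(row_final), status = status,
             stringsAsFactors = FALSE)
}

# Mode row per substance: the row holding most occurrences, earlier row on
# ties.
mode_row <- function(rows) {
  tab <- table(rows)
  as.integer(names(tab)[which.max(tab)])  # which.max takes the first maximum
}

#' Alignment error rate from known substances
#'
#' For every known substance the mode row is the aligned row containing the
#' largest number of its occurrences (ties broken toward the earlier row);
#' occurrences assigned to any other row count as misaligned. The error rate
#' is the ratio of misaligned occurrences to all located occurrences, pooled
#' over the known substances. Occurrences removed by the blank or singleton
#' filters are excluded from both numerator and denominator and reported
#' separately.
#'
#' @param result an `alignment_result`.
#' @param known a known-substance map: data.frame with columns `substance`,
#'   `sample`, `rt` (input coordinates; the applied shifts are added
#'   internally).
#' @return list with `error_rate` in `[0, 1]`, `misaligned`, `total`,
#'   `filtered` (occurrence counts) and `per_substance` (data.frame).
#' @export
error_rate <- function(result, known) {
  loc <- locate_occurrences(result, known)
  filt <- sum(loc$status == "filtered")
  loc <- loc[loc$status == "aligned", , drop = FALSE]
  per <- lapply(split(loc$row, loc$substance), function(rows) {
    mr <- mode_row(rows)
    c(n = length(rows), misaligned = sum(rows != mr), mode_row = mr)
  })
  per_df <- data.frame(substance = names(per),
                       do.call(rbind, per), row.names = NULL,
                       stringsAsFactors = FALSE)
  total <- sum(per_df$n)
  mis <- sum(per_df$misaligned)
  list(error_rate = if (total > 0) mis / total else 0,
       misaligned = mis, total = total, filtered = filt,
       per_substance = per_df)
}

#' Retention-time deviation of known substances
#'
#' Measures, for each known substance, the mean absolute offset (in rows) of
#' its occurrences from the substance's mode row, both in the final alignment
#' and in the initial unaligned matrix (each sample's peaks stacked in
#' retention order). Effective alignment should reduce this deviation to
#' zero.
#'
#' @inheritParams error_rate
#' @return data.frame with columns `substance`, `n`, `deviation_aligned`,
#'   `deviation_raw` and `change` (aligned minus raw).
#' @export
retention_deviation <- function(result, known) {
  loc <- locate_occurrences(result, known)
  loc <- loc[loc$status == "aligned", , drop = FALSE]

  raw <- to_matrix(result$input_snapshot)
  find_raw_row <- function(sample, rt) {
    j <- match(sample, raw$sample_ids)
    hit <- which(abs(raw$rt[, j] - rt) < 1e-9 & raw$rt[, j] != 0)
    if (length(hit) >= 1) hit[1] else NA_integer_
  }
  loc$row_raw <- mapply(find_raw_row, loc$sample, loc$rt)

  dev_of <- function(rows) {
    rows <- rows[!is.na(rows)]
    if (!length(rows)) return(NA_real_)
    mean(abs(rows - mode_row(rows)))
  }
  out <- lapply(split(loc, loc$substance), function(d)
    data.frame(substance = d$substance[1], n = nrow(d),
               deviation_aligned = dev_of(d$row),
               deviation_raw = dev_of(d$row_raw),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$change <- out$deviation_aligned - out$deviation_raw
  out
}
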