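#' Peak-list datasets
#'
#' A `peak_dataset` is an ordered collection of per-sample peak tables as
#' exported by GC-FID peak integration software: for every sample, one value
#' per peak for each recorded variable (at minimum a retention time in
#' minutes, typically also intensity measures such as peak area or height).
#'
#' @param peaks named list, one entry per sample; each entry is a list of
#'   equal-length numeric vectors, one per variable. Names of `peaks` are the
#'   sample identifiers; names of each inner list are the variable names.
#' @param rt_variable name of the retention-time variable (minutes).
#' @param blanks character vector of sample identifiers that are negative
#'   controls; must be a subset of the sample identifiers.
#' @param sort if `TRUE` (default) peaks within each sample are sorted by
#'   ascending retention time.
#'
#' @return An object of class `peak_dataset` with fields `sample_ids`,
#'   `variable_names`, `peaks`, `rt_variable` and `blanks`.
#' @export
peak_dataset <- function(peaks, rt_variable = "time", blanks = character(),
                         sort = TRUE) {
  if (!is.list(peaks) || is.null(names(peaks)))
    stop("'peaks' must be a named list of per-sample variable lists")
  sample_ids <- names(peaks)
  variable_names <- names(peaks[[1]])
  if (!rt_variable %in% variable_names)
    stop(sprintf("retention-time variable '%s' not found among variables: %s",
                 rt_variable, paste(variable_names, collapse = ", ")))
  peaks <- lapply(peaks, function(p) {
    lens <- lengths(p)
    if (length(unique(lens)) > 1)
      stop("all variables of one sample must have the same number of peaks")
    p <- lapply(p, as.numeric)
    if (sort && lens[[1]] > 0 && !anyNA(p[[rt_variable]])) {
      ord <- order(p[[rt_variable]])
      p <- lapply(p, `[`, ord)
    }
    p
  })
  bad <- setdiff(blanks, sample_ids)
  if (length(bad))
    stop("unknown blank sample(s): ", paste(bad, collapse = ", "))
  structure(list(sample_ids = sample_ids,
                 variable_names = variable_names,
                 peaks = peaks,
                 rt_variable = rt_variable,
                 blanks = as.character(blanks)),
            class = "peak_dataset")
}

#' @export
print.peak_dataset <- function(x, ...) {
  cat(sprintf("peak_dataset: %d samples, variables: %s (retention time: '%s')\n",
              length(x$sample_ids), paste(x$variable_names, collapse = ", "),
              x$rt_variable))
  n <- vapply(x$peaks, function(p) length(p[[x$rt_variable]]), integer(1))
  cat(sprintf("  peaks per sample: %d-%d (total %d)\n",
              min(n), max(n), sum(n)))
  if (length(x$blanks))
    cat("  blanks:", paste(x$blanks, collapse = ", "), "\n")
  invisible(x)
}

#' Number of peaks per sample
#' @param dataset a `peak_dataset`.
#' @return named integer vector.
#' @export
peak_counts <- function(dataset) {
  vapply(dataset$peaks, function(p) length(p[[dataset$rt_variable]]),
         integer(1))
}

#' Read a peak list file
#'
#' Reads the two-header-row tab-delimited peak-list dialect: the first row
#' holds the sample identifiers (one per sample block), the second row the
#' variable names, either repeated once per sample block or given a single
#' time and applied cyclically; the body holds per-sample column blocks of
#' peak values. Empty cells and zero retention times encode absent peaks and
#' are dropped, so samples may have different peak counts.
#'
#' @param path path to the text file.
#' @param rt_col_name name of the variable holding peak retention times.
#' @param sep field separator; tab by default.
#' @param blanks optional negative-control sample identifiers declared at
#'   call time.
#' @return a [peak_dataset()].
#' @export
read_peak_list <- function(path, rt_col_name = "time", sep = "\t",
                           blanks = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) stop("file must have two header rows and a body")
  split_row <- function(l) strsplit(l, sep, fixed = TRUE)[[1]]
  ids <- split_row(lines[1])
  sample_ids <- ids[nzchar(trimws(ids))]
  sample_ids <- trimws(sample_ids)
  vars_row <- trimws(split_row(lines[2]))
  vars_row <- vars_row[nzchar(vars_row)]
  n_samples <- length(sample_ids)
  if (n_samples < 1) stop("no sample identifiers found in the first row")
  if (length(vars_row) == 0) stop("no variable names found in the second row")
  if (length(vars_row) %% n_samples == 0 && length(vars_row) > n_samples ||
      (length(vars_row) == n_samples && n_samples > 1 &&
       length(unique(vars_row)) == 1)) {
    n_var <- length(vars_row) / n_samples
    variable_names <- vars_row[seq_len(n_var)]
    blocks <- matrix(vars_row, nrow = n_var)
    if (!all(apply(blocks, 2, identical, y = variable_names)))
      stop("variable names differ between sample blocks")
  } else {
    # single occurrence, applied cyclically to every block
    variable_names <- vars_row
    n_var <- length(variable_names)
  }
  if (!rt_col_name %in% variable_names)
    stop(sprintf("retention-time variable '%s' not found among variables: %s",
                 rt_col_name, paste(variable_names, collapse = ", ")))
  total_cols <- n_samples * n_var
  body <- lines[-(1:2)]
  cells <- lapply(body, function(l) {
    x <- split_row(l)
    length(x) <- total_cols      # pad short rows with NA
    trimws(x)
  })
  cells <- do.call(rbind, c(cells, list(matrix(character(0), 0, total_cols))))
  rt_idx <- match(rt_col_name, variable_names)
  peaks <- vector("list", n_samples)
  names(peaks) <- sample_ids
  for (k in seq_len(n_samples)) {
    block <- cells[, (k - 1) * n_var + seq_len(n_var), drop = FALSE]
    filled <- apply(block, 1, function(r) any(!is.na(r) & nzchar(r)))
    block <- block[seq_len(max(c(0, which(filled)))), , drop = FALSE]
    vals <- lapply(seq_len(n_var), function(j) {
      v <- block[, j]
      v[is.na(v) | !nzchar(v)] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(num)
      if (any(bad))
        stop(sprintf("non-numeric cell '%s' in sample '%s', variable '%s'",
                     v[bad][1], sample_ids[k], variable_names[j]))
      num
    })
    # rows where the retention time is empty or 0 encode absent peaks
    present <- !is.na(vals[[rt_idx]]) & vals[[rt_idx]] != 0
    vals <- lapply(vals, `[`, present)
    names(vals) <- variable_names
    peaks[[k]] <- vals
  }
  peak_dataset(peaks, rt_variable = rt_col_name, blanks = blanks,
               sort = !any(vapply(peaks, function(p) anyNA(unlist(p)),
                                  logical(1))))
}

#' Write a peak list file
#'
#' Inverse of [read_peak_list()]: writes the two-header-row dialect with the
#' variable names repeated once per sample block and trailing cells left
#' empty for samples with fewer peaks.
#'
#' @param dataset a `peak_dataset`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(dataset, path, sep = "\t") {
  n_var <- length(dataset$variable_names)
  n <- peak_counts(dataset)
  nmax <- if (length(n)) max(n) else 0L
  header1 <- unlist(lapply(dataset$sample_ids,
                           function(s) c(s, rep("", n_var - 1))))
  header2 <- rep(dataset$variable_names, length(dataset$sample_ids))
  body <- matrix("", nrow = nmax, ncol = n_var * length(dataset$sample_ids))
  for (k in seq_along(dataset$sample_ids)) {
    p <- dataset$peaks[[k]]
    for (j in seq_len(n_var)) {
      v <- p[[dataset$variable_names[j]]]
      if (length(v))
        body[seq_along(v), (k - 1) * n_var + j] <-
          format(v, trim = TRUE, scientific = FALSE, digits = 15)
    }
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header1, collapse = sep), con)
  writeLines(paste(header2, collapse = sep), con)
  if (nrow(body))
    writeLines(apply(body, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Validate a peak dataset
#'
#' Interrogates a dataset for typical formatting problems before alignment:
#' duplicated sample names and missing values are errors; sample names with
#' characters other than letters, digits and underscores, unsorted or
#' duplicated retention times, non-positive retention times and empty samples
#' are warnings. Alignment refuses to run while errors are present.
#'
#' @param dataset a `peak_dataset` (or a file path, which is read first with
#'   the remaining arguments passed to [read_peak_list()]).
#' @param ... passed to [read_peak_list()] when `dataset` is a path.
#' @return a `validation_report` with fields `ok` (TRUE iff no error-severity
#'   issue) and `issues` (data.frame with severity, code, message, location).
#' @export
check_input <- function(dataset, ...) {
  if (is.character(dataset) && length(dataset) == 1)
    dataset <- read_peak_list(dataset, ...)
  issues <- list()
  add <- function(severity, code, message, location = "") {
    issues[[length(issues) + 1]] <<-
      data.frame(severity = severity, code = code, message = message,
                 location = location, stringsAsFactors = FALSE)
  }
  dup <- unique(dataset$sample_ids[duplicated(dataset$sample_ids)])
  for (d in dup)
    add("error", "duplicate_sample", sprintf("duplicated sample name '%s'", d), d)
  bad_name <- dataset$sample_ids[!grepl("^[A-Za-z0-9_]+$", dataset$sample_ids)]
  for (s in bad_name)
    add("warning", "sample_name_characters",
        sprintf("sample name '%s' contains characters other than letters, digits and underscore", s),
        s)
  rtv <- dataset$rt_variable
  for (k in seq_along(dataset$sample_ids)) {
    s <- dataset$sample_ids[k]
    p <- dataset$peaks[[k]]
    rts <- p[[rtv]]
    if (length(rts) == 0) {
      add("warning", "empty_sample", sprintf("sample '%s' contains no peaks", s), s)
      next
    }
    n_na <- sum(vapply(p, function(v) sum(is.na(v)), integer(1)))
    if (n_na > 0)
      add("error", "missing_values",
          sprintf("sample '%s' has %d missing value(s)", s, n_na), s)
    rts_ok <- rts[!is.na(rts)]
    if (is.unsorted(rts_ok, strictly = FALSE))
      add("warning", "unsorted_rt",
          sprintf("retention times of sample '%s' are not sorted", s), s)
    if (anyDuplicated(rts_ok))
      add("warning", "duplicated_rt",
          sprintf("sample '%s' has duplicated retention times", s), s)
    if (any(rts_ok <= 0))
      add("warning", "nonpositive_rt",
          sprintf("sample '%s' has non-positive retention times", s), s)
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), code = character(0),
               message = character(0), location = character(0),
               stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$ok) "Input checks passed." else "Input checks FAILED.", "\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s: %s\n", x$issues$severity[i], x$issues$code[i],
                  x$issues$message[i]))
  } else cat("  no issues found\n")
  invisible(x)
}
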