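# Small in-code builders shared across tests.

# A 3-sample dataset with known structure: A and B share two substances,
# C has one peak between them.
tiny_dataset <- function() {
  peak_dataset(list(A = list(time = c(1.0, 2.0), area = c(10, 20)),
                    B = list(time = c(1.0, 2.0), area = c(5, 15)),
                    C = list(time = 1.5, area = 7)))
}

# Build a retention_matrix from a plain rt matrix (no measures).
rm_of <- function(rt, ids = paste0("s", seq_len(ncol(rt)))) {
  retention_matrix(as.matrix(rt), sample_ids = ids)
}

# Strip trailing all-zero rows so matrices from different construction paths
# compare equal.
trim_rows <- function(rt) {
  keep <- rowSums(rt != 0) > 0
  if (!any(keep)) return(rt[0, , drop = FALSE])
  rt[seq_len(max(which(keep))), , drop = FALSE]
}
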