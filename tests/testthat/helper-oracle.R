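# Independent list-based reimplementation of the partial-alignment and
# row-merging steps, used as an oracle. It recomputes the row mean from
# scratch at every focal cell (the package version tracks a running sum) and
# asserts the evaluation-time condition: every cell that stays in its row is
# within `a` of the mean of the previous non-zero cells at the moment it is
# evaluated.

oracle_push <- function(rows, r, j, ncols) {
  n <- length(rows)
  if (rows[[n]][j] != 0) {
    rows[[n + 1]] <- rep(0, ncols)
    n <- n + 1
  }
  for (i in n:(r + 1)) rows[[i]][j] <- rows[[i - 1]][j]
  rows[[r]][j] <- 0
  rows
}

oracle_partial_align <- function(rt, a) {
  ncols <- ncol(rt)
  rows <- lapply(seq_len(nrow(rt)), function(i) rt[i, ])
  r <- 1
  while (r <= length(rows)) {
    m <- 1
    while (m <= ncols) {
      v <- rows[[r]][m]
      if (v != 0 && m > 1) {
        prev <- rows[[r]][seq_len(m - 1)]
        prev <- prev[prev != 0]
        if (length(prev)) {
          mu <- mean(prev)
          if (v > mu + a) {
            rows <- oracle_push(rows, r, m, ncols)
          } else if (v < mu - a) {
            for (j in which(rows[[r]][seq_len(m - 1)] != 0))
              rows <- oracle_push(rows, r, j, ncols)
            stopifnot(rows[[r]][m] == v)
          } else {
            # evaluation-time condition for cells that stay (same comparison
            # form as the branch tests, to avoid spurious rounding in v - mu)
            stopifnot(v <= mu + a, v >= mu - a)
          }
        }
      }
      m <- m + 1
    }
    r <- r + 1
  }
  do.call(rbind, rows)
}

oracle_merge_rows <- function(rt, b) {
  rt <- rt[rowSums(rt != 0) > 0, , drop = FALSE]
  repeat {
    changed <- FALSE
    r <- 1
    while (r < nrow(rt)) {
      top <- rt[r, ]
      bot <- rt[r + 1, ]
      if (!any(top != 0 & bot != 0) &&
          abs(mean(top[top != 0]) - mean(bot[bot != 0])) < b) {
        rt[r, ] <- top + bot
        rt <- rt[-(r + 1), , drop = FALSE]
        changed <- TRUE
      } else r <- r + 1
    }
    if (!changed) break
  }
  rt
}

# Multiset of non-zero values per column, in top-to-bottom order.
column_values <- function(rt) {
  lapply(seq_len(ncol(rt)), function(j) unname(rt[rt[, j] != 0, j]))
}
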