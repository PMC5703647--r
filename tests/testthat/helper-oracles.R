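# Independent oracles shared across test files.

# exhaustive enumeration over all partial matchings (assignment oracle)
brute_assign <- function(A, B, cutoff) {
  n <- nrow(A); m <- nrow(B); c2 <- cutoff^2
  D <- outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2
  best <- list(cost = Inf, asgn = rep(NA_integer_, n))
  rec <- function(k, used, asgn, cost) {
    if (k > n) {
      if (cost < best$cost) best <<- list(cost = cost, asgn = asgn)
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j] && D[k, j] < c2) {
        used[j] <- TRUE; asgn[k] <- j
        rec(k + 1, used, asgn, cost + D[k, j])
        used[j] <- FALSE; asgn[k] <- NA_integer_
      }
    }
    rec(k + 1, used, asgn, cost + c2)
  }
  rec(1L, rep(FALSE, m), rep(NA_integer_, n), 0)
  best
}

assignment_cost <- function(A, B, asgn, cutoff) {
  tot <- 0
  for (i in seq_len(nrow(A))) {
    tot <- tot + if (is.na(asgn[i])) cutoff^2 else
      sum((A[i, ] - B[asgn[i], ])^2)
  }
  tot
}
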