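# Independent loop-based oracle for the cross-validated Mahalanobis
# dissimilarity: a literal transcription of the defining equations,
# deliberately written with explicit per-trial loops and no shared code with
# the package internals. arr_* are trials x channels x time arrays.
oracle_dissim <- function(arr_a, arr_b, symmetrize = TRUE) {
  nt <- dim(arr_a)[3]
  p <- dim(arr_a)[2]
  out <- numeric(nt)
  slice <- function(arr, t) {
    m <- arr[, , t]
    if (is.null(dim(m))) m <- matrix(m, ncol = p)
    m
  }
  for (t in seq_len(nt)) {
    x1 <- slice(arr_a, t); x2 <- slice(arr_b, t)
    n1 <- nrow(x1); n2 <- nrow(x2)
    cov_about_mean <- function(x) {
      mu <- colMeans(x)
      s <- matrix(0, p, p)
      for (i in seq_len(nrow(x))) s <- s + tcrossprod(x[i, ] - mu)
      s
    }
    pooled <- (cov_about_mean(x1) + cov_about_mean(x2)) / (n1 + n2 - 2)
    prec <- MASS::ginv(pooled)
    one_side <- function(xa, xb) {
      n <- nrow(xa)
      td2 <- colMeans(xb)
      d11 <- 0; d12 <- 0
      for (i in seq_len(n)) {
        td1 <- colMeans(xa[-i, , drop = FALSE])
        v1 <- td1 - xa[i, ]
        v2 <- td2 - xa[i, ]
        d11 <- d11 + sqrt(drop(t(v1) %*% prec %*% v1))
        d12 <- d12 + sqrt(drop(t(v2) %*% prec %*% v2))
      }
      (d12 - d11) / n
    }
    v <- one_side(x1, x2)
    if (symmetrize) v <- (v + one_side(x2, x1)) / 2
    out[t] <- v
  }
  out
}

# Wrap a trials x channels x time array as an epoch_set for the package path.
as_epochs <- function(arr, time = seq_len(dim(arr)[3]) - 1L,
                      day = "day1") {
  n <- dim(arr)[1]
  pursuitmvpa:::new_epoch_set(
    arr, sprintf("ch%02d", seq_len(dim(arr)[2])), time,
    data.frame(trial_id = sprintf("t%03d", seq_len(n)),
               day = rep(day, length.out = n), stringsAsFactors = FALSE))
}
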