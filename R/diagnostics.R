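#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic split R-hat: each chain is split in half, and the ratio of
#' pooled-to-within variance is computed over the resulting half-chains.
#' For this model, raw R-hat on the latent distances is expected to be
#' large even at convergence-in-topology, because the distance scale is not
#' identified across chains (chains may settle on proportional distance
#' matrices that imply the same tree).
#'
#' @param x matrix of draws, iterations x chains.
#' @return scalar R-hat (NA if degenerate).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(xs)
  nn <- nrow(xs)
  mu <- colMeans(xs)
  s2 <- apply(xs, 2, var)
  W <- mean(s2)
  B <- nn * var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains.
ess_basic <- function(x) {
  x <- as.matrix(x)
  total <- 0
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    n <- length(v)
    v <- v - mean(v)
    if (sd(v) == 0 || n < 8) { total <- total + n; next }
    ac <- stats::acf(v, lag.max = min(n - 2L, 200L), plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    ac <- ac / ac[1]
    # sum of adjacent pairs until the pair sum goes negative
    ssum <- 0
    k <- 2L
    while (k + 1L <= length(ac)) {
      pair <- ac[k] + ac[k + 1L]
      if (pair < 0) break
      ssum <- ssum + pair
      k <- k + 2L
    }
    total <- total + n / (1 + 2 * ssum)
  }
  total
}
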