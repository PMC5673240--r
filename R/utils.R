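# Internal helpers: named random substreams and small numeric utilities.

# Deterministic 32-bit substream seed from a base seed and a stream name.
# Each stochastic stage draws from its own named stream so that, e.g.,
# enlarging the gene panel does not perturb the ephys draws.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483563
  as.integer((as.numeric(seed) * 48271 + h * 69621 + 1) %% 2147483563)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# Spearman's rank correlation between each column of X (n x G) and a single
# vector y (length n), using average ranks. Zero-variance columns (or y)
# give NA. Vectorized: rank-transform, center, then one crossprod.
spearman_vector <- function(X, y) {
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  if (n < 3) return(rep(NA_real_, ncol(X)))
  rx <- apply(X, 2, rank)
  ry <- rank(y)
  rx <- sweep(rx, 2, colMeans(rx))
  ry <- ry - mean(ry)
  sx <- sqrt(colSums(rx^2))
  sy <- sqrt(sum(ry^2))
  out <- rep(NA_real_, ncol(X))
  good <- sx > 0 & sy > 0
  if (any(good)) {
    out[good] <- as.numeric(crossprod(rx[, good, drop = FALSE], ry)) /
      (sx[good] * sy)
  }
  # guard rounding just past +/-1
  pmin(pmax(out, -1), 1)
}

# Two-sided p-value for a Spearman correlation via the t approximation
# t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df. |r| = 1 maps to the
# smallest representable positive double.
spearman_p_from_r <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  at_one <- ok & abs(r) >= 1
  p[at_one] <- .Machine$double.xmin
  mid <- ok & !at_one
  if (any(mid)) {
    tt <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
    p[mid] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  p
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
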