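# Convergence diagnostics: rank-normalized split R-hat and bulk effective
# sample size (Geyer initial monotone sequence on rank-normalized split
# chains) -- the modern defaults for HMC output.

split_chain_matrix <- function(x) {
  # x: iterations x chains; returns floor(n/2) x (2*chains)
  n <- nrow(x)
  h <- floor(n / 2)
  if (h < 1L) return(x)
  do.call(cbind, lapply(seq_len(ncol(x)), function(cc)
    cbind(x[seq_len(h), cc], x[(n - h + 1L):n, cc])))
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  if (is.matrix(x)) matrix(z, nrow(x), ncol(x)) else z
}

rhat_basic <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  w <- mean(apply(m, 2L, stats::var))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split R-hat
#'
#' Maximum of the bulk (rank-normalized) and tail (folded, rank-normalized)
#' split R-hat; values near 1 indicate mixed chains.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return A scalar R-hat (NA for constant draws).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (all(x == x[1L])) return(NA_real_)
  sp <- split_chain_matrix(x)
  bulk <- rhat_basic(rank_normalize(sp))
  folded <- rhat_basic(rank_normalize(abs(sp - stats::median(sp))))
  max(bulk, folded, na.rm = TRUE)
}

autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m * n)
}

ess_basic <- function(m) {
  n <- nrow(m)
  nc <- ncol(m)
  if (n < 4L) return(NA_real_)
  acov <- apply(m, 2L, autocov_fft) * n / (n - 1)
  chain_var <- acov[1L, ]
  w <- mean(chain_var)
  if (!is.finite(w) || w == 0) return(NA_real_)
  var_plus <- w * (n - 1) / n + (if (nc > 1L) stats::var(colMeans(m)) else 0)
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  # Geyer initial positive + monotone sequence over pairs
  max_pairs <- floor((n - 1) / 2)
  tau <- 0
  prev <- Inf
  for (k in 0:(max_pairs - 1L)) {
    pair <- rho[2L * k + 1L] + rho[2L * k + 2L]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
  }
  tau <- max(2 * tau - 1, 1 / log10(n * nc + 10))
  min(nc * n / tau, nc * n * log10(nc * n))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains, using Geyer's initial monotone
#' positive sequence estimator of the autocorrelation time.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return A scalar ESS (NA for constant draws).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (all(x == x[1L])) return(NA_real_)
  ess_basic(rank_normalize(split_chain_matrix(x)))
}
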