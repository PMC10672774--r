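# Information criteria from the pointwise posterior log-likelihood:
# WAIC and PSIS-smoothed leave-one-out cross-validation (loo-ic), both on
# the deviance scale (-2 * elpd) with standard errors from the pointwise
# contributions.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_loglik <- function(log_lik) {
  if (!is.matrix(log_lik) || any(!is.finite(log_lik)))
    stop("`log_lik` must be a finite draws-by-observations matrix")
  log_lik
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` where `lppd` is the summed log pointwise
#' posterior predictive density and `p_waic` the summed posterior variance
#' of the pointwise log-likelihood.
#'
#' @param log_lik Matrix of pointwise log-likelihood, draws by observations
#'   (see [pointwise_loglik()]).
#' @return List of class `la_ic`: `estimate`, `se`, `p_eff`, `pointwise`
#'   (per-observation deviance-scale contributions).
#' @export
waic <- function(log_lik) {
  log_lik <- check_loglik(log_lik)
  S <- nrow(log_lik)
  lpd <- apply(log_lik, 2L, logsumexp) - log(S)
  p <- apply(log_lik, 2L, stats::var)
  pointwise <- -2 * (lpd - p)
  structure(
    list(estimate = sum(pointwise),
         se = sqrt(ncol(log_lik) * stats::var(pointwise)),
         p_eff = sum(p), pointwise = pointwise, criterion = "waic"),
    class = "la_ic")
}

# Generalized Pareto fit (Zhang & Stephens 2009 profile-posterior method,
# with the weakly-informative shape prior used for importance-ratio tails).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  ll <- n * (log(theta / k_of) + k_of - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(ll - ll[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k_zs <- -mean(log1p(-theta_hat * x))
  sigma <- k_zs / theta_hat
  k <- -k_zs  # shape xi in the standard orientation (xi > 0: heavy tail)
  # weakly informative prior pulls the shape toward 1/2
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(k * (-log1p(-p))) / k
}

# Pareto-smoothed importance weights for one observation.
# lr: log importance ratios (length S). Returns normalized log weights and
# the Pareto shape diagnostic.
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  if (M >= 5L && S >= 25L) {
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1L):S]
    cutoff <- lr[ord[S - M]]
    exc <- exp(lr[tail_ids]) - exp(cutoff)
    if (stats::sd(exc) > 0) {
      fit <- gpd_fit(exc[exc > 0])
      khat <- fit$k
      if (is.finite(khat)) {
        pp <- (seq_len(M) - 0.5) / M
        sm <- log(qgpd(pp, fit$k, fit$sigma) + exp(cutoff))
        # assign smoothed values in ascending order of the raw tail
        lr[tail_ids[order(lr[tail_ids])]] <- pmin(sm, 0)
      }
    }
  }
  list(lw = lr - logsumexp(lr), k = khat)
}

#' PSIS leave-one-out information criterion
#'
#' Pareto-smoothed importance-sampling estimate of leave-one-out expected
#' log predictive density, reported as `-2 * elpd_loo`. Pareto shape
#' diagnostics are returned per observation; values above 0.7 are flagged.
#'
#' @inheritParams waic
#' @return List of class `la_ic`: `estimate`, `se`, `p_eff`, `pointwise`,
#'   `pareto_k`.
#' @export
loo_ic <- function(log_lik) {
  log_lik <- check_loglik(log_lik)
  S <- nrow(log_lik)
  N <- ncol(log_lik)
  lpd <- apply(log_lik, 2L, logsumexp) - log(S)
  elpd <- numeric(N)
  k <- numeric(N)
  for (i in seq_len(N)) {
    ps <- psis_smooth(-log_lik[, i])
    elpd[i] <- logsumexp(ps$lw + log_lik[, i])
    k[i] <- ps$k
  }
  n_bad <- sum(is.finite(k) & k > 0.7)
  if (n_bad > 0L)
    warning(n_bad, " observation(s) with Pareto k > 0.7; loo estimate may be unstable",
            call. = FALSE)
  pointwise <- -2 * elpd
  structure(
    list(estimate = sum(pointwise), se = sqrt(N * stats::var(pointwise)),
         p_eff = sum(lpd - elpd), pointwise = pointwise, pareto_k = k,
         criterion = "looic"),
    class = "la_ic")
}

#' @export
print.la_ic <- function(x, ...) {
  cat(sprintf("%s: %.1f (SE %.1f), effective parameters %.1f\n",
              x$criterion, x$estimate, x$se, x$p_eff))
  invisible(x)
}

#' Information-criterion comparison of fitted model variants
#'
#' @param ... Named `la_fit` objects (e.g. `model1 = fit1, model2 = fit2`).
#' @return Data frame with one row per fit: `model`, `looic`, `looic_se`,
#'   `waic`, `waic_se`.
#' @export
compare_ic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], "la_fit"))
    fits <- fits[[1L]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  rows <- lapply(names(fits), function(nm) {
    ll <- pointwise_loglik(fits[[nm]])
    lo <- loo_ic(ll)
    wa <- waic(ll)
    data.frame(model = nm, looic = lo$estimate, looic_se = lo$se,
               waic = wa$estimate, waic_se = wa$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
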