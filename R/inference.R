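# Bayesian hierarchical model specification.
#
# Likelihood: Score ~ Binomial(n_stim, p), p = 1 - Phi((C(t) - mu[i,j]) / sigma[i,j]),
# C(t) = 100 - (1 - adr * V_adr) t.
# Hierarchy: mu[i,j] ~ Normal(mu0[i] (+ d[j] in variant 2), s_mu0[i]);
#            sigma[i,j] ~ LogNormal(log_sigma0[i], log_s_sigma0[i]).
# Priors: mu0 ~ Cauchy(50, 20); s_mu0 ~ HalfCauchy(0, 1); d ~ Normal(0, 20);
#         log_sigma0 ~ Normal(2.5, 1); adr ~ Uniform(0, 1);
#         log_s_sigma0 ~ Uniform(0, U) (the improper ">0" prior bounded at U).
#
# The sampler works on an unconstrained vector with a non-centered
# parameterization of the individual levels:
#   s_mu0 = exp(t_smu); log_s_sigma0 = U * logistic(t_lss); adr = logistic(t_adr)
#   mu[i,j] = mu0[i] + d[j] + s_mu0[i] * z_mu[i,j]
#   log sigma[i,j] = log_sigma0[i] + log_s_sigma0[i] * z_ls[i,j]
# lp_grad() returns the joint log-density on that space (including the
# change-of-variable Jacobians) together with its analytic gradient.

#' Prior specification for the hierarchical model
#'
#' Defaults follow the model's stated priors; the positive uniform prior on
#' `log_s_sigma0` is bounded above at `log_s_sigma0_upper` (a spread factor
#' of `exp(5)` amply covers plausible values).
#'
#' @param mu0_location,mu0_scale Cauchy prior on `mu0`.
#' @param s_mu0_scale Half-Cauchy scale on `s_mu0`.
#' @param log_sigma0_mean,log_sigma0_sd Normal prior on `log_sigma0`.
#' @param d_sd Normal prior SD on the per-animal offset `d` (variant 2).
#' @param log_s_sigma0_upper Upper bound of the uniform prior on `log_s_sigma0`.
#' @return A list of class `la_priors`.
#' @export
prior_spec <- function(mu0_location = 50, mu0_scale = 20, s_mu0_scale = 1,
                       log_sigma0_mean = 2.5, log_sigma0_sd = 1,
                       d_sd = 20, log_s_sigma0_upper = 5) {
  stopifnot(mu0_scale > 0, s_mu0_scale > 0, log_sigma0_sd > 0,
            d_sd > 0, log_s_sigma0_upper > 0)
  structure(
    list(mu0_location = mu0_location, mu0_scale = mu0_scale,
         s_mu0_scale = s_mu0_scale, log_sigma0_mean = log_sigma0_mean,
         log_sigma0_sd = log_sigma0_sd, d_sd = d_sd,
         log_s_sigma0_upper = log_s_sigma0_upper),
    class = "la_priors"
  )
}

#' Build the hierarchical model for a score dataset
#'
#' Prepares the data indices and the joint log-density (with analytic
#' gradient) for one hierarchy variant. Scores are fully observed; the
#' bench stopping rule truncates trajectories but needs no special-casing
#' in the likelihood.
#'
#' @param scores Long-format score table (`animal_id`, `arm`, `time_min`,
#'   `score`).
#' @param variant Hierarchy variant: 1 (no per-animal offset) or 2 (with
#'   offset `d`).
#' @param priors A [prior_spec()].
#' @param arms Named list mapping arm labels to [arm()] objects.
#' @param n_stim Stimuli per time point.
#' @param parameterization `"auto"` (default) parameterizes each
#'   animal-drug cell as centered when its trajectory pins down the probit
#'   transition (both score extremes observed, or several intermediate
#'   scores) and non-centered otherwise (e.g. all-zero bupivacaine
#'   trajectories, where only the individual prior identifies `mu`);
#'   `"centered"` / `"noncentered"` force one scheme. All choices induce
#'   the identical joint density and differ only in sampling geometry.
#' @return An object of class `la_model` (list of data, index maps and
#'   density closures) for [fit_hmc()].
#' @export
build_model <- function(scores, variant = 2L, priors = prior_spec(),
                        arms = study_arms(), n_stim = 6L,
                        parameterization = c("auto", "centered", "noncentered")) {
  scores <- validate_scores(scores, n_stim)
  variant <- check_model_variant(variant)
  parameterization <- match.arg(parameterization)
  stopifnot(inherits(priors, "la_priors"))

  unknown <- setdiff(unique(scores$arm), names(arms))
  if (length(unknown))
    stop("unknown arm label(s): ", paste(unknown, collapse = ", "))
  drug_of <- vapply(arms, function(a) a$drug, integer(1))
  vadr_of <- vapply(arms, function(a) a$v_adr, integer(1))

  animals <- sort(unique(scores$animal_id))
  J <- length(animals)
  K <- 4L * J
  arm_idx <- match(scores$arm, names(arms))
  j_obs <- match(scores$animal_id, animals)
  i_obs <- drug_of[arm_idx]
  v_obs <- as.numeric(vadr_of[arm_idx])
  k_obs <- (j_obs - 1L) * 4L + i_obs
  s_obs <- as.numeric(scores$score)
  f_obs <- n_stim - s_obs
  t_obs <- as.numeric(scores$time_min)
  const_ll <- sum(lchoose(n_stim, s_obs))
  i_cell <- rep(1:4, J)
  j_cell <- rep(seq_len(J), each = 4L)

  # per-cell parameterization flag (TRUE = centered)
  cflag <- switch(parameterization,
    centered = rep(TRUE, K),
    noncentered = rep(FALSE, K),
    auto = {
      lo_t <- tabulate(k_obs[s_obs <= 1], K)
      hi_t <- tabulate(k_obs[s_obs >= n_stim - 1], K)
      mid_t <- tabulate(k_obs[s_obs >= 1 & s_obs <= n_stim - 1], K)
      (lo_t > 0L & hi_t > 0L) | mid_t >= 3L
    })

  U <- priors$log_s_sigma0_upper
  ix <- list(mu0 = 1:4, t_smu = 5:8, ls0 = 9:12, t_lss = 13:16, t_adr = 17L)
  base <- 17L
  if (variant == 2L) {
    ix$d <- base + seq_len(J)
    base <- base + J
  }
  ix$z_mu <- base + seq_len(K)
  ix$z_ls <- base + K + seq_len(K)
  n_par <- base + 2L * K

  pm <- priors

  unpack <- function(theta) {
    d <- if (variant == 2L) theta[ix$d] else numeric(J)
    list(mu0 = theta[ix$mu0], t_smu = theta[ix$t_smu], smu = exp(theta[ix$t_smu]),
         ls0 = theta[ix$ls0], p_lss = stats::plogis(theta[ix$t_lss]),
         p_adr = stats::plogis(theta[ix$t_adr]), d = d,
         z_mu = theta[ix$z_mu], z_ls = theta[ix$z_ls])
  }

  lp_grad <- function(theta) {
    th <- unpack(theta)
    lss <- U * th$p_lss
    adr <- th$p_adr
    smu_cell <- th$smu[i_cell]
    lss_cell <- lss[i_cell]
    mu0_cell <- th$mu0[i_cell] + th$d[j_cell]
    ls0_cell <- th$ls0[i_cell]
    # per-cell centered (parameter = value) / non-centered (parameter = z)
    mu_c <- ifelse(cflag, th$z_mu, mu0_cell + smu_cell * th$z_mu)
    ls_c <- ifelse(cflag, th$z_ls, ls0_cell + lss_cell * th$z_ls)
    r_mu <- ifelse(cflag, (mu_c - mu0_cell) / smu_cell, th$z_mu)
    q_ls <- ifelse(cflag, (ls_c - ls0_cell) / lss_cell, th$z_ls)
    sig_c <- exp(ls_c)
    kern <- .score_ll_grad(s_obs, f_obs, t_obs, v_obs, k_obs,
                           mu_c, sig_c, adr, K)
    A_mu <- kern$A_mu
    A_ls <- kern$A_ls

    # hierarchy (up to additive constants), priors and Jacobians
    dm <- th$mu0 - pm$mu0_location
    lp <- kern$ll + const_ll +
      -0.5 * sum(r_mu^2) - 0.5 * sum(q_ls^2) -
      sum(log(smu_cell[cflag])) - sum(log(lss_cell[cflag])) +
      sum(stats::dcauchy(th$mu0, pm$mu0_location, pm$mu0_scale, log = TRUE)) +
      sum(log(2 / (pi * pm$s_mu0_scale)) -
            log1p((th$smu / pm$s_mu0_scale)^2) + th$t_smu) +
      sum(stats::dnorm(th$ls0, pm$log_sigma0_mean, pm$log_sigma0_sd, log = TRUE)) +
      sum(log(th$p_lss) + log1p(-th$p_lss)) +
      log(adr) + log1p(-adr) +
      (if (variant == 2L) sum(stats::dnorm(th$d, 0, pm$d_sd, log = TRUE)) else 0)

    g <- numeric(n_par)
    by_drug <- function(x) rowSums(matrix(x, nrow = 4L))
    by_animal <- function(x) colSums(matrix(x, nrow = 4L))
    r2 <- (th$smu / pm$s_mu0_scale)^2
    # "pull" terms feeding the hyperparameter gradients
    pull_mu <- ifelse(cflag, r_mu / smu_cell, A_mu)
    pull_ls <- ifelse(cflag, q_ls / lss_cell, A_ls)
    g[ix$z_mu] <- ifelse(cflag, A_mu - r_mu / smu_cell,
                         A_mu * smu_cell - r_mu)
    g[ix$z_ls] <- ifelse(cflag, A_ls - q_ls / lss_cell,
                         A_ls * lss_cell - q_ls)
    g[ix$mu0] <- by_drug(pull_mu) - 2 * dm / (pm$mu0_scale^2 + dm^2)
    g[ix$t_smu] <- by_drug(ifelse(cflag, r_mu^2 - 1, A_mu * r_mu * smu_cell)) +
      (-2 * r2 / (1 + r2) + 1)
    g[ix$ls0] <- by_drug(pull_ls) -
      (th$ls0 - pm$log_sigma0_mean) / pm$log_sigma0_sd^2
    g[ix$t_lss] <- by_drug(ifelse(cflag, (q_ls^2 - 1) / lss_cell,
                                  A_ls * q_ls)) *
      (U * th$p_lss * (1 - th$p_lss)) + (1 - 2 * th$p_lss)
    if (variant == 2L)
      g[ix$d] <- by_animal(pull_mu) - th$d / pm$d_sd^2
    g[ix$t_adr] <- kern$g_adr_raw * adr * (1 - adr) + (1 - 2 * adr)
    list(lp = lp, grad = g)
  }

  # Natural-scale joint log density (no change-of-variable Jacobians):
  # likelihood + hierarchy + priors, for oracle comparisons. `params` is a
  # list with mu0, s_mu0, log_sigma0, log_s_sigma0, adr, d (length J),
  # mu and sigma (4 x J matrices).
  log_density <- function(params) {
    mu_c <- as.numeric(params$mu)
    sig_c <- as.numeric(params$sigma)
    stopifnot(length(mu_c) == K, length(sig_c) == K)
    d <- if (variant == 2L) params$d else numeric(J)
    ll <- sum(.score_ll_pointwise(s_obs, f_obs, t_obs, v_obs, k_obs,
                                  mu_c, sig_c, params$adr)) + const_ll
    hier <- sum(stats::dnorm(mu_c, params$mu0[i_cell] + d[j_cell],
                             params$s_mu0[i_cell], log = TRUE)) +
      sum(stats::dlnorm(sig_c, params$log_sigma0[i_cell],
                        params$log_s_sigma0[i_cell], log = TRUE))
    pri <- sum(stats::dcauchy(params$mu0, pm$mu0_location, pm$mu0_scale, log = TRUE)) +
      sum(log(2 / (pi * pm$s_mu0_scale)) -
            log1p((params$s_mu0 / pm$s_mu0_scale)^2)) +
      sum(stats::dnorm(params$log_sigma0, pm$log_sigma0_mean,
                       pm$log_sigma0_sd, log = TRUE)) +
      sum(stats::dunif(params$log_s_sigma0, 0, U, log = TRUE)) +
      stats::dunif(params$adr, 0, 1, log = TRUE) +
      (if (variant == 2L) sum(stats::dnorm(params$d, 0, pm$d_sd, log = TRUE)) else 0)
    ll + hier + pri
  }

  # Map an unconstrained vector to the named natural parameters
  par_names <- c(
    paste0("mu0[", drug_names(), "]"),
    paste0("s_mu0[", drug_names(), "]"),
    paste0("log_sigma0[", drug_names(), "]"),
    paste0("log_s_sigma0[", drug_names(), "]"),
    "adr",
    if (variant == 2L) paste0("d[", animals, "]"),
    paste0("mu[", drug_names()[i_cell], ",", animals[j_cell], "]"),
    paste0("sigma[", drug_names()[i_cell], ",", animals[j_cell], "]")
  )

  transform <- function(theta) {
    th <- unpack(theta)
    lss <- U * th$p_lss
    mu_c <- ifelse(cflag, th$z_mu,
                   th$mu0[i_cell] + th$d[j_cell] + th$smu[i_cell] * th$z_mu)
    sig_c <- exp(ifelse(cflag, th$z_ls,
                        th$ls0[i_cell] + lss[i_cell] * th$z_ls))
    c(th$mu0, th$smu, th$ls0, lss, th$p_adr,
      if (variant == 2L) th$d, mu_c, sig_c)
  }

  # Pointwise log-likelihood for a matrix of natural draws (rows = draws,
  # columns named as par_names); returns draws x observations.
  log_lik <- function(draws) {
    adr_col <- match("adr", colnames(draws))
    mu_cols <- match(paste0("mu[", drug_names()[i_cell], ",", animals[j_cell], "]"),
                     colnames(draws))
    sig_cols <- match(paste0("sigma[", drug_names()[i_cell], ",", animals[j_cell], "]"),
                      colnames(draws))
    S <- nrow(draws)
    out <- matrix(NA_real_, S, length(s_obs))
    for (sdx in seq_len(S)) {
      out[sdx, ] <- .score_ll_pointwise(
        s_obs, f_obs, t_obs, v_obs, k_obs,
        draws[sdx, mu_cols], draws[sdx, sig_cols], draws[sdx, adr_col])
    }
    sweep(out, 2L, lchoose(s_obs + f_obs, s_obs), `+`)
  }

  # Crude data-driven warm start: per cell, place mu at the latent
  # concentration where the observed score trajectory crosses half-scale
  # (using a nominal adrenaline factor for v_adr = 1 observations), so
  # chains start inside the likelihood's typical set.
  mu_hat <- {
    adr0 <- 0.65
    est <- numeric(K)
    for (k in seq_len(K)) {
      sel <- which(k_obs == k)
      if (!length(sel)) {
        est[k] <- 50
        next
      }
      cc <- 100 - (1 - adr0 * v_obs[sel]) * t_obs[sel]
      o <- order(-cc)  # ascending effective time
      pr <- s_obs[sel][o] / n_stim
      cc <- cc[o]
      cross <- which(pr >= 0.5)
      est[k] <- if (!length(cross)) {
        min(cc) - 15  # never recovered: transition beyond observed range
      } else if (cross[1L] == 1L) {
        max(cc) + 10  # recovered from the start
      } else {
        mean(cc[c(cross[1L] - 1L, cross[1L])])
      }
    }
    est
  }
  mu0_hat <- vapply(1:4, function(i) stats::median(mu_hat[i_cell == i]),
                    numeric(1))
  smu_hat <- pmax(3, vapply(1:4, function(i)
    stats::mad(mu_hat[i_cell == i]), numeric(1)))

  init <- function() {
    theta <- numeric(n_par)
    theta[ix$mu0] <- mu0_hat + stats::rnorm(4L, 0, 2)
    theta[ix$t_smu] <- log(smu_hat) + stats::rnorm(4L, 0, 0.2)
    theta[ix$ls0] <- pm$log_sigma0_mean + stats::rnorm(4L, 0, 0.2)
    theta[ix$t_lss] <- stats::qlogis(min(0.9, 0.6 / U) + 0.05) +
      stats::rnorm(4L, 0, 0.3)
    theta[ix$t_adr] <- stats::qlogis(0.6) + stats::rnorm(1L, 0, 0.3)
    if (variant == 2L) theta[ix$d] <- stats::rnorm(J, 0, 1)
    theta[ix$z_mu] <- ifelse(cflag,
                             mu_hat + stats::rnorm(K, 0, 2),
                             stats::rnorm(K, 0, 0.2))
    theta[ix$z_ls] <- ifelse(cflag,
                             pm$log_sigma0_mean + stats::rnorm(K, 0, 0.2),
                             stats::rnorm(K, 0, 0.2))
    theta
  }

  init_sd <- {
    sd <- numeric(n_par)
    sd[ix$mu0] <- 5
    sd[ix$t_smu] <- 0.4
    sd[ix$ls0] <- 0.4
    sd[ix$t_lss] <- 0.6
    sd[ix$t_adr] <- 0.6
    if (variant == 2L) sd[ix$d] <- 5
    sd[ix$z_mu] <- ifelse(cflag, 8, 1)
    sd[ix$z_ls] <- ifelse(cflag, 0.5, 1)
    sd
  }

  structure(
    list(variant = variant, priors = priors, n_par = n_par, ix = ix,
         animals = animals, n_animals = J, n_cells = K, n_obs = length(s_obs),
         par_names = par_names, lp_grad = lp_grad, log_density = log_density,
         transform = transform, log_lik = log_lik, init = init,
         init_sd = init_sd, n_stim = n_stim,
         parameterization = parameterization, centered_cells = cflag,
         data = list(s = s_obs, t = t_obs, v = v_obs, k = k_obs,
                     i_cell = i_cell, j_cell = j_cell)),
    class = "la_model"
  )
}

#' @export
print.la_model <- function(x, ...) {
  cat(sprintf(
    "<hierarchical score model> variant %d, %d animals, %d observations, %d parameters\n",
    x$variant, x$n_animals, x$n_obs, x$n_par))
  invisible(x)
}
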