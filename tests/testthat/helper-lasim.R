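# Shared builders for small in-code fixtures.

# A tiny deterministic score table: two animals, two arms, short grid.
toy_scores <- function() {
  grid <- c(5, 10, 15, 20, 25)
  data.frame(
    animal_id = rep(1:2, each = 2L * length(grid)),
    arm = rep(rep(c("Pro", "Lid+Adr"), each = length(grid)), 2L),
    time_min = rep(grid, 4L),
    score = c(0L, 1L, 3L, 5L, 6L,
              0L, 0L, 1L, 2L, 4L,
              1L, 2L, 4L, 6L, 6L,
              0L, 1L, 1L, 3L, 5L),
    stringsAsFactors = FALSE
  )
}

# Random natural-scale parameter point for a model with J animals.
# Individual-level values are kept in a range where the plain
# double-precision brute-force likelihood (dbinom on 1 - pnorm) does not
# underflow; the package's log-tail evaluation remains finite further out.
random_natural_params <- function(J) {
  list(
    mu0 = stats::rnorm(4L, 50, 15),
    s_mu0 = stats::rlnorm(4L, 2, 0.4),
    log_sigma0 = stats::rnorm(4L, 2.4, 0.3),
    log_s_sigma0 = stats::runif(4L, 0.2, 1.5),
    adr = stats::runif(1L, 0.3, 0.9),
    d = stats::rnorm(J, 0, 8),
    mu = matrix(stats::runif(4L * J, 62, 98), 4L, J),
    sigma = matrix(pmax(6, stats::rlnorm(4L * J, 2.4, 0.25)), 4L, J)
  )
}

# Independent brute-force joint log density on the natural scale:
# binomial likelihood + hierarchy + priors, written from first principles
# (no shared code with the package internals).
brute_force_log_density <- function(scores, params, variant,
                                    d_sd = 20, lss_upper = 5, n_stim = 6L) {
  arms <- study_arms()
  total <- 0
  animals <- sort(unique(scores$animal_id))
  for (r in seq_len(nrow(scores))) {
    a <- arms[[scores$arm[r]]]
    j <- match(scores$animal_id[r], animals)
    conc <- 100 - (1 - params$adr * a$v_adr) * scores$time_min[r]
    p <- 1 - stats::pnorm((conc - params$mu[a$drug, j]) /
                            params$sigma[a$drug, j])
    total <- total + stats::dbinom(scores$score[r], n_stim, p, log = TRUE)
  }
  for (j in seq_along(animals)) {
    for (i in 1:4) {
      center <- params$mu0[i] + if (variant == 2L) params$d[j] else 0
      total <- total +
        stats::dnorm(params$mu[i, j], center, params$s_mu0[i], log = TRUE) +
        stats::dlnorm(params$sigma[i, j], params$log_sigma0[i],
                      params$log_s_sigma0[i], log = TRUE)
    }
  }
  total <- total +
    sum(stats::dcauchy(params$mu0, 50, 20, log = TRUE)) +
    sum(log(2) - log(pi) - log(1 + params$s_mu0^2)) +
    sum(stats::dnorm(params$log_sigma0, 2.5, 1, log = TRUE)) +
    sum(stats::dunif(params$log_s_sigma0, 0, lss_upper, log = TRUE)) +
    stats::dunif(params$adr, 0, 1, log = TRUE)
  if (variant == 2L)
    total <- total + sum(stats::dnorm(params$d, 0, d_sd, log = TRUE))
  total
}

quiet_fit <- function(...) {
  withCallingHandlers(
    fit_hmc(..., quiet = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
}
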