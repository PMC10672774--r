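test_that("joint log density matches a brute-force oracle at random points", {
  sc <- toy_scores()
  set.seed(8)
  for (variant in c(1L, 2L)) {
    m <- build_model(sc, variant = variant)
    for (rep in 1:5) {
      params <- random_natural_params(m$n_animals)
      expect_equal(m$log_density(params),
                   brute_force_log_density(sc, params, variant),
                   tolerance = 1e-8)
    }
  }
})

test_that("sampling-space density has an exact analytic gradient", {
  sc <- toy_scores()
  set.seed(9)
  for (variant in c(1L, 2L)) {
    for (param in c("auto", "noncentered", "centered")) {
      m <- build_model(sc, variant = variant, parameterization = param)
      th <- m$init()
      lg <- m$lp_grad(th)
      expect_true(is.finite(lg$lp))
      idx <- sample(m$n_par, min(20L, m$n_par))
      h <- 1e-5
      num <- vapply(idx, function(i) {
        tp <- th; tp[i] <- tp[i] + h
        tm <- th; tm[i] <- tm[i] - h
        (m$lp_grad(tp)$lp - m$lp_grad(tm)$lp) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(num - lg$grad[idx])), 1e-4)
    }
  }
})

test_that("sampling-space density differs from the natural one only by the
           fixed change-of-variable constant", {
  sc <- toy_scores()
  set.seed(10)
  m <- build_model(sc, variant = 2L, parameterization = "noncentered")
  offs <- vapply(1:4, function(r) {
    th <- m$init()
    nat <- m$transform(th)
    J <- m$n_animals; K <- m$n_cells
    params <- list(mu0 = nat[1:4], s_mu0 = nat[5:8],
                   log_sigma0 = nat[9:12], log_s_sigma0 = nat[13:16],
                   adr = nat[17], d = nat[17 + seq_len(J)],
                   mu = matrix(nat[17 + J + seq_len(K)], 4),
                   sigma = matrix(nat[17 + J + K + seq_len(K)], 4))
    # Jacobian of (exp, scaled-logit, logit, non-centered) transforms
    p_lss <- plogis(th[13:16]); p_adr <- plogis(th[17])
    jac <- sum(th[5:8]) + sum(log(5 * p_lss * (1 - p_lss))) +
      log(p_adr * (1 - p_adr)) +
      sum(log(exp(th[5:8])[m$data$i_cell])) +
      sum(log((5 * p_lss)[m$data$i_cell])) + sum(log(params$sigma))
    m$lp_grad(th)$lp - (m$log_density(params) + jac)
  }, numeric(1))
  # dropped normalization constants are theta-independent
  expect_lt(diff(range(offs)), 1e-8)
})

test_that("model construction enforces its contracts", {
  sc <- toy_scores()
  expect_error(build_model(transform(sc, arm = "Saline")), "unknown arm")
  expect_error(build_model(transform(sc, score = score + 3L)), "0..6")
  m1 <- build_model(sc, variant = 1L)
  m2 <- build_model(sc, variant = 2L)
  # variant 1 has no offset parameters
  expect_false(any(grepl("^d\\[", m1$par_names)))
  expect_equal(sum(grepl("^d\\[", m2$par_names)), m1$n_animals)
  expect_equal(m2$n_par - m1$n_par, m1$n_animals)
})

test_that("all-six scores drive the likelihood toward large mu (p -> 1)", {
  # p = 1 - Phi((C - mu)/sigma) rises as mu moves above the concentration
  # range: saturated scores favor an early transition
  grid <- c(5, 10, 15, 20)
  sat <- data.frame(animal_id = 1L, arm = "Pro", time_min = grid,
                    score = rep(6L, 4L))
  m <- build_model(sat, variant = 1L)
  set.seed(12)
  base <- random_natural_params(1L)
  ll_at <- function(mu_pro) {
    p <- base
    p$mu[1, 1] <- mu_pro
    nat <- c(p$mu0, p$s_mu0, p$log_sigma0, p$log_s_sigma0, p$adr,
             as.numeric(p$mu), as.numeric(p$sigma))
    sum(m$log_lik(matrix(nat, 1L, dimnames = list(NULL, m$par_names))))
  }
  expect_gt(ll_at(115), ll_at(60))
})

test_that("pointwise log-likelihood matches direct binomial evaluation", {
  sc <- toy_scores()
  m <- build_model(sc, variant = 2L)
  set.seed(11)
  params <- random_natural_params(m$n_animals)
  nat <- c(params$mu0, params$s_mu0, params$log_sigma0, params$log_s_sigma0,
           params$adr, params$d, as.numeric(params$mu), as.numeric(params$sigma))
  draws <- matrix(nat, 1L, dimnames = list(NULL, m$par_names))
  ll <- m$log_lik(draws)
  expect_equal(dim(ll), c(1L, nrow(sc)))
  arms <- study_arms()
  want <- vapply(seq_len(nrow(sc)), function(r) {
    a <- arms[[sc$arm[r]]]
    j <- sc$animal_id[r]
    conc <- 100 - (1 - params$adr * a$v_adr) * sc$time_min[r]
    p <- 1 - pnorm((conc - params$mu[a$drug, j]) / params$sigma[a$drug, j])
    dbinom(sc$score[r], 6L, p, log = TRUE)
  }, numeric(1))
  expect_equal(as.numeric(ll), want, tolerance = 1e-10)
})
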