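test_that("individual draws follow the stated hierarchy", {
  pop <- la_fixture("table5_param1")
  set.seed(1)
  n <- 10000L
  draws <- replicate(n, unlist(draw_individual(pop, model = 2)[c("d", "mu", "sigma")]))
  # law of large numbers on mu[Pro]: mean mu0 = 67.0, SD sqrt(s_mu0^2 + sd_d^2)
  se <- sqrt(pop$s_mu0[["Pro"]]^2 + pop$sd_d^2) / sqrt(n)
  expect_lt(abs(mean(draws["mu.Pro", ]) - 67.0), 3 * se)
  # lognormal median identity: median sigma[Pro] ~ exp(2.20) = 9.03
  expect_lt(abs(median(draws["sigma.Pro", ]) - exp(2.20)), 0.35)
  # offset: model 2 draws d with sd_d = 4
  expect_lt(abs(sd(draws["d", ]) - 4), 3 * 4 / sqrt(2 * (n - 1)) + 0.1)
  # model 1 fixes d at 0
  set.seed(2)
  expect_identical(draw_individual(pop, model = 1)$d, 0)
})

test_that("degenerate population distributions collapse to their means", {
  pop <- population_params(c(70, 60, 50, 30), rep(0, 4), rep(2.2, 4),
                           rep(0, 4), adr = 0.5, sd_d = 0)
  ind <- draw_individual(pop, model = 2)
  expect_equal(unname(ind$mu), c(70, 60, 50, 30))
  expect_equal(unname(ind$sigma), rep(exp(2.2), 4))
  expect_equal(ind$d, 0)
})

test_that("score trajectories saturate and match binomial moments", {
  grid <- default_grid(120)
  pop <- la_fixture("table5_param2")
  # mu far above the concentration range: p ~ 1, all-six trajectory;
  # mu far below: p ~ 0, all-zero trajectory
  ind <- structure(
    list(d = 0,
         mu = stats::setNames(c(1e5, 60, 50, -1e5), drug_names()),
         sigma = stats::setNames(rep(9, 4), drug_names())),
    class = "la_ind")
  set.seed(3)
  expect_true(all(simulate_scores(ind, arm("Pro"), pop$adr, grid) == 6))
  expect_true(all(simulate_scores(ind, arm("Bup"), pop$adr, grid) == 0))
  # empirical mean at fixed t ~ 6 p(t)
  t0 <- 50
  p0 <- reaction_probability(t0, 60, 9)
  reps <- replicate(4000, simulate_scores(ind, arm("Lid"), pop$adr, t0))
  expect_lt(abs(mean(reps) - 6 * p0), 3 * sqrt(6 * p0 * (1 - p0) / 4000))
})

test_that("cohorts are reproducible and share parameters across arms", {
  pop <- la_fixture("table5_param2")
  a <- simulate_cohort(pop, 5, seed = 42)
  b <- simulate_cohort(pop, 5, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 5L * 5L * length(default_grid(120)))
  ind <- attr(a, "individuals")
  expect_equal(nrow(ind), 5L)
  # Lid and Lid+Adr share (mu, sigma); only the slope factor differs, so
  # at matched times the Lid+Adr latent concentration is higher
  expect_true(all(c("mu_Lid", "sigma_Lid") %in% names(ind)))
  # scores table is valid long format
  expect_s3_class(a, "la_scores")
  expect_true(all(a$score %in% 0:6))
})

test_that("triple-six rule defines duration and censoring", {
  # event at the third consecutive six
  expect_equal(triple_six_time(c(50, 55, 60), c(6, 6, 6)),
               list(time = 60, event = TRUE))
  # broken run restarts the count
  tt <- seq(45, 80, 5)
  sc <- c(6, 6, 5, 6, 6, 6, 6, 6)
  expect_equal(triple_six_time(tt, sc)$time, 70)
  # no run: censored at the grid end
  expect_equal(triple_six_time(seq(5, 120, 5), rep(5, 24)),
               list(time = 120, event = FALSE))
  expect_error(triple_six_time(numeric(0), numeric(0)), "empty")
})

test_that("durations are extracted per animal-arm with censoring", {
  pop <- la_fixture("table5_param2")
  sc <- simulate_cohort(pop, 8, seed = 9)
  du <- duration_from_scores(sc, t_max = 120)
  expect_equal(nrow(du), 8L * 5L)
  expect_true(all(du$event %in% c(0L, 1L)))
  expect_true(all(du$time_min[du$event == 0L] == 120))
  # manual scan of one trajectory agrees
  one <- sc[sc$animal_id == 3 & sc$arm == "Pro", ]
  manual <- triple_six_time(one$time_min, one$score, t_max = 120)
  got <- du[du$animal_id == 3 & du$arm == "Pro", ]
  expect_equal(got$time_min, manual$time)
  expect_equal(got$event == 1L, manual$event)
})

test_that("cohort-level duration ordering matches the drug pharmacology", {
  # Pro subsides first, then Lid, Mep, Bup; Lid+Adr outlasts all
  pop <- la_fixture("table5_param1")
  hits <- 0L
  for (s in 1:5) {
    sc <- simulate_cohort(pop, 100, seed = 100 + s)
    du <- duration_from_scores(sc, t_max = 120)
    mean_dur <- tapply(du$time_min, du$arm, mean)
    ord <- mean_dur[c("Pro", "Lid", "Mep", "Bup", "Lid+Adr")]
    if (all(diff(ord) > 0)) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("trajectories fluctuate up and down when sigma is large", {
  pop <- la_fixture("table5_param1")
  sc <- simulate_cohort(pop, 100, seed = 7)
  non_monotone <- 0L
  key <- interaction(sc$animal_id, sc$arm)
  for (gr in split(sc, key)) {
    s <- gr$score[order(gr$time_min)]
    if (any(diff(s) < 0)) non_monotone <- non_monotone + 1L
  }
  expect_gte(non_monotone, 1L)
})
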