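test_that("latent concentration follows the anchored linear decay", {
  expect_equal(latent_concentration(0), 100)
  expect_equal(latent_concentration(100), 0)
  # adrenaline rescales the slope: evaluate at the published factor
  expect_equal(latent_concentration(100, adr_effect = 0.665), 66.5)
  expect_true(all(diff(latent_concentration(seq(0, 200, 5))) < 0))
  expect_error(latent_concentration(-1), ">= 0")
  expect_error(latent_concentration(10, adr_effect = 1), "\\[0, 1\\)")
  expect_error(latent_concentration(10, adr_effect = -0.1), "\\[0, 1\\)")
})

test_that("reaction probability is a probit in time with the stated anchors", {
  # p = 0.5 exactly at t = 100 - mu for any sigma
  for (sg in c(0.5, 9, 40)) {
    expect_equal(reaction_probability(100 - 67, mu = 67, sigma = sg), 0.5)
  }
  # one sigma-width later the probability is Phi(1)
  expect_equal(reaction_probability((100 - 67) + 9, mu = 67, sigma = 9),
               pnorm(1))
  # saturates toward 1 for large t while adr_effect < 1
  expect_gt(reaction_probability(1e4, mu = 67, sigma = 9, adr_effect = 0.9),
            1 - 1e-12)
  expect_error(reaction_probability(10, mu = 50, sigma = 0), "> 0")
})

test_that("probability curves are monotone and shift left with larger mu", {
  tt <- seq(5, 120, 5)
  for (mu in c(30, 67, 95)) {
    p <- reaction_probability(tt, mu, sigma = 11)
    expect_true(all(diff(p) >= 0))
  }
  # larger mu => higher probability at fixed t (earlier transition)
  expect_true(all(reaction_probability(tt, 70, 11) >
                    reaction_probability(tt, 50, 11)))
})

test_that("half-effect time inverts the concentration line", {
  expect_equal(half_effect_time(67), 33)
  expect_equal(half_effect_time(100), 0)
  expect_equal(half_effect_time(60.9, adr_effect = 0.665), 39.1 / 0.335)
  # identity: probability at the half-effect time is exactly 0.5
  grid <- expand.grid(mu = c(29.1, 50, 67, 75), sigma = c(2, 9, 12.2),
                      adr = c(0, 0.3, 0.665, 0.7))
  for (r in seq_len(nrow(grid))) {
    tstar <- half_effect_time(grid$mu[r], grid$adr[r])
    if (tstar >= 0)
      expect_equal(
        reaction_probability(tstar, grid$mu[r], grid$sigma[r], grid$adr[r]),
        0.5)
  }
  expect_error(half_effect_time(50, adr_effect = 1), "\\[0, 1\\)")
})

test_that("adrenaline acts as an exact time rescaling", {
  tt <- seq(0, 120, 2.5)
  for (a in c(0.3, 0.665, 0.7)) {
    expect_equal(reaction_probability(tt, 60, 11, adr_effect = a),
                 reaction_probability((1 - a) * tt, 60, 11, adr_effect = 0))
  }
})

test_that("score pmf is Binomial(6, p)", {
  expect_equal(unname(score_pmf(0)), c(1, rep(0, 6)))
  expect_equal(unname(score_pmf(1)), c(rep(0, 6), 1))
  expect_equal(score_pmf(0.5)[["3"]], 20 / 64)
  expect_equal(sum(score_pmf(0.37)), 1)
  expect_error(score_pmf(1.2), "\\[0, 1\\]")
  expect_error(score_pmf(c(0.2, 0.4)), "single")
})

test_that("arms map drugs and the adrenaline indicator", {
  a <- arm("Lid", 1)
  expect_equal(a$drug, 2L)
  expect_equal(a$v_adr, 1L)
  expect_equal(arm(4)$drug, 4L)
  expect_error(arm("Saline"), "unknown drug")
  expect_error(arm(5), "1..4")
  arms <- study_arms()
  expect_named(arms, c("Pro", "Lid", "Mep", "Bup", "Lid+Adr"))
  # Lid+Adr shares lidocaine's drug index
  expect_equal(arms[["Lid+Adr"]]$drug, arms[["Lid"]]$drug)
})
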