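test_that("bundled fixtures reproduce the published tables digit for digit", {
  m1 <- la_fixture("table1_model1")
  expect_equal(unname(m1$mu0), c(67.5, 61.0, 50.5, 29.3))
  expect_equal(unname(m1$s_mu0), c(19.5, 14.8, 14.5, 26.0))
  expect_equal(unname(m1$log_sigma0), c(2.19, 2.43, 2.41, 2.50))
  expect_equal(unname(m1$log_s_sigma0), c(0.79, 0.52, 0.65, 0.83))
  expect_equal(m1$adr, 0.663)
  expect_equal(m1$sd_d, 0)

  m2 <- la_fixture("table1_model2")
  expect_equal(m2$mu0[["Pro"]], 67.0)
  expect_equal(m2$s_mu0[["Lid"]], 5.1)
  expect_equal(m2$adr, 0.665)
  expect_equal(m2$sd_d, 13.0)
  # paired reporting: sigma0 = exp(log_sigma0) ~ 9.0 for procaine
  expect_equal(round(sigma0(m2)[["Pro"]], 1), 9.0)

  p1 <- la_fixture("table5_param1")
  expect_equal(p1$adr, 0.665)
  expect_equal(p1$sd_d, 4.0)
  expect_equal(unname(p1$mu0), unname(m2$mu0))  # estimates reused, d shrunk

  p2 <- la_fixture("table5_param2")
  expect_equal(unname(p2$mu0), c(75.0, 67.0, 43.0, 30.0))
  expect_equal(unname(p2$s_mu0), c(8.0, 5.0, 6.0, 10.0))
  expect_equal(unname(p2$log_s_sigma0), c(0.40, 0.40, 0.40, 0.50))
  expect_equal(p2$adr, 0.700)
  expect_equal(p2$sd_d, 4.0)

  expect_error(la_fixture("table9"), "available")
})

test_that("generate_study produces the full study layout", {
  pop <- la_fixture("table5_param2")
  sc <- generate_study(pop, n_animals = 51, seed = 2, truncate_at_stop = FALSE)
  expect_equal(length(unique(interaction(sc$animal_id, sc$arm))), 255L)
  expect_equal(nrow(sc), 255L * length(default_grid(100)))
  # zero contamination is identical to the plain cohort under one seed
  sc2 <- generate_study(pop, n_animals = 5, seed = 3, contamination = 0,
                        truncate_at_stop = FALSE)
  sc3 <- simulate_cohort(pop, 5, grid = default_grid(100), seed = 3)
  expect_equal(sc2$score, sc3$score)
})

test_that("stop-rule truncation ends trajectories at the third six", {
  pop <- la_fixture("table5_param2")
  sc <- generate_study(pop, n_animals = 20, seed = 4, truncate_at_stop = TRUE)
  for (gr in split(sc, interaction(sc$animal_id, sc$arm, drop = TRUE))) {
    s <- gr$score[order(gr$time_min)]
    runs <- rle(s == 6L)
    # no triple six strictly inside the kept trajectory
    if (any(s == 6L)) {
      inner <- which(runs$values & runs$lengths >= 3L)
      if (length(inner))
        expect_equal(sum(runs$lengths[seq_len(max(inner))]), length(s))
    }
  }
})

test_that("contaminated cells stay unrecovered", {
  pop <- la_fixture("table5_param2")
  sc <- generate_study(pop, n_animals = 30, seed = 5, contamination = 0.2,
                       truncate_at_stop = FALSE)
  du <- duration_from_scores(sc, t_max = 100)
  # with mu shifted ~150 low, ~20% of cells should censor; the clean
  # parameter-2 study has nearly none outside Lid+Adr
  clean <- generate_study(pop, n_animals = 30, seed = 5, contamination = 0,
                          truncate_at_stop = FALSE)
  du0 <- duration_from_scores(clean, t_max = 100)
  expect_gt(sum(du$event == 0), sum(du0$event == 0) + 10)
})

test_that("score CSV round-trips and rejects malformed input", {
  sc <- toy_scores()
  path <- tempfile(fileext = ".csv")
  write_scores(sc, path)
  back <- read_scores(path)
  expect_equal(as.data.frame(back), sc)

  bad <- sc
  bad$score[7] <- 7L
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_scores(path2), "row 7")

  noheader <- tempfile(fileext = ".csv")
  writeLines(c("1,Pro,5,0", "1,Pro,10,3"), noheader)
  expect_error(read_scores(noheader), "header")
  expect_error(read_scores(tempfile()), "not found")
})

test_that("duration CSV round-trips with 0/1 events", {
  du <- data.frame(animal_id = 1:3, arm = "Pro", time_min = c(30, 120, 55),
                   event = c(1L, 0L, 1L))
  path <- tempfile(fileext = ".csv")
  write_durations(du, path)
  expect_equal(as.data.frame(read_durations(path)), du)
  bad <- du
  bad$event[2] <- 2L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_durations(path), "row 2")
})

test_that("population parameter JSON round-trips", {
  pop <- la_fixture("table5_param1")
  path <- tempfile(fileext = ".json")
  write_params(pop, path)
  expect_equal(read_params(path), pop)
})
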