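# Forward simulation: draw individual parameters from the hierarchy,
# generate binomial score trajectories on the stimulation grid, and apply
# the triple-six stopping / censoring rule.

#' Draw one individual's parameters from the population distributions
#'
#' Model 2 draws a per-animal offset `d ~ Normal(0, sd_d)` shared by all
#' drugs, then `mu[i] ~ Normal(mu0[i] + d, s_mu0[i])`; Model 1 fixes
#' `d = 0`. In both variants `sigma[i] ~ LogNormal(log_sigma0[i],
#' log_s_sigma0[i])`. Uses R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param pop An `la_pop` parameter set.
#' @param model Hierarchy variant, 1 (no offset) or 2 (with offset).
#' @return An object of class `la_ind`: list with `d` (scalar) and named
#'   length-4 vectors `mu`, `sigma`.
#' @export
draw_individual <- function(pop, model = 2L) {
  stopifnot(inherits(pop, "la_pop"))
  model <- check_model_variant(model)
  d <- if (model == 2L) stats::rnorm(1L, 0, pop$sd_d) else 0
  mu <- stats::rnorm(4L, pop$mu0 + d, pop$s_mu0)
  sigma <- stats::rlnorm(4L, pop$log_sigma0, pop$log_s_sigma0)
  structure(
    list(d = d,
         mu = stats::setNames(mu, drug_names()),
         sigma = stats::setNames(sigma, drug_names())),
    class = "la_ind"
  )
}

check_model_variant <- function(model) {
  model <- as.integer(model)
  if (!model %in% c(1L, 2L)) stop("`model` must be 1 or 2")
  model
}

#' Simulate one score trajectory
#'
#' For each grid time, the score is an independent Binomial(`n_stim`, p(t))
#' draw with p from [reaction_probability()]; there is no serial dependence
#' between time points, so trajectories fluctuate up and down when sigma is
#' large.
#'
#' @param ind An `la_ind` from [draw_individual()].
#' @param arm An [arm()].
#' @param adr Population adrenaline factor (used only when `arm$v_adr == 1`).
#' @param grid Ascending, regularly spaced stimulation times in minutes.
#' @param n_stim Stimuli per time point.
#' @return Integer score vector along `grid`.
#' @export
simulate_scores <- function(ind, arm, adr, grid = default_grid(), n_stim = 6L) {
  stopifnot(inherits(ind, "la_ind"), inherits(arm, "la_arm"))
  check_grid(grid)
  p <- reaction_probability(grid, ind$mu[[arm$drug]], ind$sigma[[arm$drug]],
                            adr * arm$v_adr)
  stats::rbinom(length(grid), n_stim, p)
}

#' Stimulation grids
#'
#' Stimuli are applied every 5 minutes starting at t = 5. The simulation
#' protocol observes up to 120 min; bench-style raw data stop at 100 min.
#'
#' @param t_max Last stimulation time in minutes.
#' @param step Grid step in minutes.
#' @param t_min First stimulation time in minutes.
#' @return Numeric vector of times.
#' @export
default_grid <- function(t_max = 120, step = 5, t_min = 5) seq(t_min, t_max, by = step)

check_grid <- function(grid) {
  if (length(grid) < 1L || any(!is.finite(grid)))
    stop("`grid` must be a non-empty numeric vector")
  if (length(grid) > 1L) {
    d <- diff(grid)
    if (any(d <= 0)) stop("`grid` must be strictly increasing")
    if (max(d) - min(d) > 1e-8) stop("`grid` must be regularly spaced")
  }
  invisible(grid)
}

#' Simulate a cohort of individuals across study arms
#'
#' Each individual is drawn once with [draw_individual()] and then scored on
#' every arm, so arms of the same animal share the offset `d` and -- for Lid
#' versus Lid+Adr -- the identical `(mu, sigma)` pair; only the adrenaline
#' slope factor differs.
#'
#' @param pop An `la_pop` parameter set.
#' @param n Number of individuals.
#' @param arms Named list of [arm()]s; defaults to the five-arm study layout.
#' @param grid Stimulation grid (minutes).
#' @param model Hierarchy variant 1 or 2 (see [draw_individual()]).
#' @param seed Optional integer seed (calls `set.seed()`).
#' @param n_stim Stimuli per time point.
#' @return A long-format data frame of class `la_scores` with columns
#'   `animal_id`, `arm`, `time_min`, `score`, and an `"individuals"`
#'   attribute holding the drawn per-animal parameters.
#' @export
simulate_cohort <- function(pop, n, arms = study_arms(), grid = default_grid(),
                            model = 2L, seed = NULL, n_stim = 6L) {
  stopifnot(inherits(pop, "la_pop"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (length(arms) < 1L || is.null(names(arms)))
    stop("`arms` must be a named list of arm() objects")
  check_grid(grid)
  if (!is.null(seed)) set.seed(seed)

  n_arms <- length(arms)
  n_t <- length(grid)
  out <- vector("list", n * n_arms)
  ind_rows <- vector("list", n)
  for (j in seq_len(n)) {
    ind <- draw_individual(pop, model)
    ind_rows[[j]] <- data.frame(animal_id = j, d = ind$d,
                                t(ind$mu), t(ind$sigma))
    for (a in seq_len(n_arms)) {
      sc <- simulate_scores(ind, arms[[a]], pop$adr, grid, n_stim)
      out[[(j - 1L) * n_arms + a]] <- data.frame(
        animal_id = j, arm = names(arms)[a], time_min = grid, score = sc,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  inds <- do.call(rbind, ind_rows)
  names(inds) <- c("animal_id", "d",
                   paste0("mu_", drug_names()), paste0("sigma_", drug_names()))
  attr(res, "individuals") <- inds
  class(res) <- c("la_scores", "data.frame")
  res
}

#' Duration of anesthesia from a score trajectory
#'
#' Scans a single trajectory for the first run of three consecutive scores
#' of 6 and returns the time of the third six with `event = TRUE` (the
#' moment stimulation is stopped in the bench protocol). If no such run
#' occurs within the grid, the record is right-censored at `t_max` with
#' `event = FALSE`.
#'
#' @param time Ascending stimulation times.
#' @param score Integer scores 0..6, same length as `time`.
#' @param t_max Censoring time; defaults to the last grid time.
#' @return List with `time` and logical `event`.
#' @export
triple_six_time <- function(time, score, t_max = max(time)) {
  if (length(time) == 0L) stop("empty score trajectory")
  if (length(time) != length(score)) stop("`time` and `score` lengths differ")
  run <- 0L
  for (k in seq_along(score)) {
    run <- if (score[k] == 6L) run + 1L else 0L
    if (run == 3L) return(list(time = time[k], event = TRUE))
  }
  list(time = t_max, event = FALSE)
}

#' Durations for every animal-arm trajectory
#'
#' Applies [triple_six_time()] per `(animal_id, arm)` group of a long-format
#' score table.
#'
#' @param scores An `la_scores` data frame (columns `animal_id`, `arm`,
#'   `time_min`, `score`).
#' @param t_max Censoring time; defaults to the largest time in `scores`
#'   (for stop-truncated tables pass the design maximum explicitly).
#' @return Data frame of class `la_durations` with columns `animal_id`,
#'   `arm`, `time_min`, `event` (integer 0/1).
#' @export
duration_from_scores <- function(scores, t_max = NULL) {
  scores <- validate_scores(scores)
  if (is.null(t_max)) t_max <- max(scores$time_min)
  key <- interaction(scores$animal_id, scores$arm, drop = TRUE, lex.order = TRUE)
  pieces <- split(scores, key)
  rows <- lapply(pieces, function(gr) {
    gr <- gr[order(gr$time_min), , drop = FALSE]
    dur <- triple_six_time(gr$time_min, gr$score, t_max = t_max)
    data.frame(animal_id = gr$animal_id[1L], arm = gr$arm[1L],
               time_min = dur$time, event = as.integer(dur$event),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$animal_id, res$arm), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("la_durations", "data.frame")
  res
}

validate_scores <- function(scores, n_stim = 6L) {
  need <- c("animal_id", "arm", "time_min", "score")
  if (!is.data.frame(scores) || !all(need %in% names(scores)))
    stop("score table must have columns ", paste(need, collapse = ", "))
  if (nrow(scores) == 0L) stop("score table is empty")
  bad <- which(!is.finite(scores$score) | scores$score < 0 |
                 scores$score > n_stim | scores$score != round(scores$score))
  if (length(bad))
    stop("invalid score (must be an integer in 0..", n_stim, ") at row",
         if (length(bad) > 1L) "s " else " ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad_t <- which(!is.finite(scores$time_min) | scores$time_min < 0)
  if (length(bad_t))
    stop("invalid time_min at row", if (length(bad_t) > 1L) "s " else " ",
         paste(utils::head(bad_t, 5L), collapse = ", "))
  scores
}
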