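# Bundled parameter fixtures and practice-style study generation.

# Registry of published parameter sets. "table1_*" are the posterior-mean
# hyperparameter estimates under each hierarchy variant; "table5_*" are the
# simulation parameter sets (param 1 = estimates with the offset SD shrunk
# to 4; param 2 = hand-adjusted to match the bench medians).
fixture_registry <- function() {
  list(
    table1_model1 = population_params(
      mu0          = c(67.5, 61.0, 50.5, 29.3),
      s_mu0        = c(19.5, 14.8, 14.5, 26.0),
      log_sigma0   = c(2.19, 2.43, 2.41, 2.50),
      log_s_sigma0 = c(0.79, 0.52, 0.65, 0.83),
      adr = 0.663, sd_d = 0),
    table1_model2 = population_params(
      mu0          = c(67.0, 60.9, 50.0, 29.1),
      s_mu0        = c(15.7, 5.1, 12.0, 20.3),
      log_sigma0   = c(2.20, 2.42, 2.41, 2.50),
      log_s_sigma0 = c(0.78, 0.51, 0.65, 0.83),
      adr = 0.665, sd_d = 13.0),
    table5_param1 = population_params(
      mu0          = c(67.0, 60.9, 50.0, 29.1),
      s_mu0        = c(15.7, 5.1, 12.0, 20.3),
      log_sigma0   = c(2.20, 2.42, 2.41, 2.50),
      log_s_sigma0 = c(0.78, 0.51, 0.65, 0.83),
      adr = 0.665, sd_d = 4.0),
    table5_param2 = population_params(
      mu0          = c(75.0, 67.0, 43.0, 30.0),
      s_mu0        = c(8.0, 5.0, 6.0, 10.0),
      log_sigma0   = c(2.20, 2.40, 2.40, 2.50),
      log_s_sigma0 = c(0.40, 0.40, 0.40, 0.50),
      adr = 0.700, sd_d = 4.0)
  )
}

#' Bundled population parameter sets
#'
#' Returns one of the published parameter sets: the posterior-mean
#' hyperparameters of hierarchy variant 1 or 2 (`"table1_model1"`,
#' `"table1_model2"`), or the two simulation sets (`"table5_param1"`: the
#' variant-2 estimates with the offset SD reduced to 4; `"table5_param2"`:
#' the set adjusted by trial and error to reproduce the bench medians).
#'
#' @param name Fixture name.
#' @return An `la_pop` parameter set.
#' @export
#' @examples
#' la_fixture("table5_param1")$adr  # 0.665
la_fixture <- function(name) {
  reg <- fixture_registry()
  if (length(name) != 1L || !name %in% names(reg))
    stop("unknown fixture; available: ", paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Generate a practice-style synthetic study
#'
#' Simulates a full study with the structure the estimator assumes:
#' `n_animals` individuals scored on every arm over a regular grid. By
#' default trajectories are truncated after the third consecutive score of
#' 6, exactly as recorded on the bench sheet (the stopping rule depends only
#' on observed scores, so truncation does not bias the binomial likelihood).
#' A contamination fraction can shift some animal-arm `mu` values far below
#' the transition range, emulating technical failures where the measured
#' effect stays low throughout.
#'
#' @param pop An `la_pop` parameter set.
#' @param n_animals Number of animals (study design: 51).
#' @param arms Named list of [arm()]s (default: five-arm layout).
#' @param grid Stimulation grid; defaults to 5..100 min by 5 (bench-style).
#' @param model Hierarchy variant for the individual draws.
#' @param seed Optional integer seed.
#' @param truncate_at_stop Truncate each trajectory at the triple-six stop.
#' @param contamination Fraction of animal-arm cells rescored as failures.
#' @param contamination_shift Amount subtracted from `mu` in failed cells.
#' @return An `la_scores` data frame (see [simulate_cohort()]).
#' @export
generate_study <- function(pop, n_animals = 51L, arms = study_arms(),
                           grid = default_grid(t_max = 100), model = 2L,
                           seed = NULL, truncate_at_stop = TRUE,
                           contamination = 0, contamination_shift = 150) {
  if (contamination < 0 || contamination > 1)
    stop("`contamination` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  scores <- simulate_cohort(pop, n_animals, arms = arms, grid = grid,
                            model = model, seed = NULL)
  if (contamination > 0) {
    inds <- attr(scores, "individuals")
    cells <- expand.grid(animal_id = unique(scores$animal_id),
                         arm = names(arms), stringsAsFactors = FALSE)
    n_bad <- round(contamination * nrow(cells))
    if (n_bad > 0L) {
      bad <- cells[sample.int(nrow(cells), n_bad), , drop = FALSE]
      for (r in seq_len(n_bad)) {
        a <- arms[[bad$arm[r]]]
        j <- bad$animal_id[r]
        row <- inds[inds$animal_id == j, ]
        ind <- structure(
          list(d = row$d,
               mu = stats::setNames(as.numeric(row[paste0("mu_", drug_names())]),
                                    drug_names()),
               sigma = stats::setNames(as.numeric(row[paste0("sigma_", drug_names())]),
                                       drug_names())),
          class = "la_ind")
        ind$mu[a$drug] <- ind$mu[a$drug] - contamination_shift
        sel <- scores$animal_id == j & scores$arm == bad$arm[r]
        scores$score[sel] <- simulate_scores(ind, a, pop$adr, grid)
      }
    }
  }
  if (truncate_at_stop) {
    key <- interaction(scores$animal_id, scores$arm, drop = TRUE, lex.order = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(scores)), key), function(idx) {
      gr <- scores[idx, ]
      o <- order(gr$time_min)
      dur <- triple_six_time(gr$time_min[o], gr$score[o])
      if (dur$event) idx[o][gr$time_min[o] <= dur$time] else idx
    }), use.names = FALSE)
    keep <- sort(keep)
    inds <- attr(scores, "individuals")
    scores <- scores[keep, , drop = FALSE]
    rownames(scores) <- NULL
    attr(scores, "individuals") <- inds
    class(scores) <- c("la_scores", "data.frame")
  }
  scores
}

#' Read / write score tables in the shared CSV schema
#'
#' Long format with header `animal_id, arm, time_min, score`; validation
#' errors name the offending row numbers.
#'
#' @param path CSV file path.
#' @param scores An `la_scores`-compatible data frame.
#' @return `read_scores()` returns an `la_scores` data frame;
#'   `write_scores()` returns `path` invisibly.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  header <- utils::read.csv(path, nrows = 1L, header = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("animal_id", "arm", "time_min", "score")
  if (!all(need %in% as.character(unlist(header))))
    stop("score CSV must have header columns ", paste(need, collapse = ", "))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x <- validate_scores(x)
  class(x) <- c("la_scores", "data.frame")
  x
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  scores <- validate_scores(scores)
  utils::write.csv(
    scores[, c("animal_id", "arm", "time_min", "score")], path,
    row.names = FALSE)
  invisible(path)
}

#' Read / write duration records in the shared CSV schema
#'
#' Columns `animal_id, arm, time_min, event` with `event` in `{0, 1}`.
#'
#' @param path CSV file path.
#' @param durations An `la_durations`-compatible data frame.
#' @return `read_durations()` returns an `la_durations` data frame;
#'   `write_durations()` returns `path` invisibly.
#' @export
read_durations <- function(path) {
  if (!file.exists(path)) stop("duration file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "arm", "time_min", "event")
  if (!all(need %in% names(x)))
    stop("duration CSV must have columns ", paste(need, collapse = ", "))
  bad <- which(!x$event %in% c(0L, 1L))
  if (length(bad)) stop("`event` must be 0 or 1 at row",
                        if (length(bad) > 1L) "s " else " ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  class(x) <- c("la_durations", "data.frame")
  x
}

#' @rdname read_durations
#' @export
write_durations <- function(durations, path) {
  need <- c("animal_id", "arm", "time_min", "event")
  if (!all(need %in% names(durations)))
    stop("duration table must have columns ", paste(need, collapse = ", "))
  utils::write.csv(durations[, need], path, row.names = FALSE)
  invisible(path)
}
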