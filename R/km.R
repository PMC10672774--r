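# Kaplan-Meier product-limit estimation with right censoring.
#
# Greenwood variance on the log scale, log-transformed pointwise 95% CI,
# and Brookmeyer-Crowley inversion for the median CI -- the defaults of the
# standard survival toolchain, so results are directly comparable.

#' Kaplan-Meier estimate of the duration distribution
#'
#' @param time Positive event/censoring times.
#' @param event Event indicator: 1/TRUE = anesthesia subsided, 0/FALSE =
#'   right-censored at measurement end.
#' @param conf_level Confidence level for the pointwise CI (default 0.95).
#' @return An object of class `la_km`: data frame component `steps` with one
#'   row per distinct observed time (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `lower`, `upper`), plus `median` and `median_ci`
#'   (either may be `NA` when the curve never falls to 0.5, rendered as
#'   a dash when printed).
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) == 0L) stop("no duration records")
  if (length(time) != length(event)) stop("`time` and `event` lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("`time` must be positive")
  event <- as.integer(as.logical(event))

  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  at_risk <- n
  for (k in seq_along(ut)) {
    n_risk[k] <- at_risk
    n_event[k] <- sum(time == ut[k] & event == 1L)
    n_censor[k] <- sum(time == ut[k] & event == 0L)
    at_risk <- at_risk - n_event[k] - n_censor[k]
  }
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood variance of log S
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(gw)
  # the log-transformed CI is undefined where S reaches 0 (as in survfit)
  lower <- ifelse(surv > 0, exp(log(surv) - z * se_log), NA_real_)
  upper <- ifelse(surv > 0, pmin(1, exp(log(surv) + z * se_log)), NA_real_)

  first_leq <- function(s) {
    i <- which(!is.na(s) & s <= 0.5 + 1e-12)
    if (length(i)) ut[min(i)] else NA_real_
  }
  structure(
    list(
      steps = data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                         n_censor = n_censor, surv = surv,
                         lower = lower, upper = upper),
      n = n, events = sum(event),
      median = first_leq(surv),
      median_ci = c(lower = first_leq(lower), upper = first_leq(upper)),
      conf_level = conf_level
    ),
    class = "la_km"
  )
}

#' @export
print.la_km <- function(x, ...) {
  dash <- function(v) ifelse(is.na(v), "-", format(v))
  cat(sprintf("<Kaplan-Meier> n = %d, events = %d, median = %s [%s, %s]\n",
              x$n, x$events, dash(x$median),
              dash(x$median_ci[["lower"]]), dash(x$median_ci[["upper"]])))
  invisible(x)
}

#' Median duration report per drug and condition
#'
#' Lays out Kaplan-Meier medians with confidence intervals per arm within
#' one or more conditions (e.g. raw data versus a simulated cohort),
#' interleaving conditions within each arm.
#'
#' @param cohorts Named list of `la_durations` data frames (name = condition
#'   label), each with columns `animal_id`, `arm`, `time_min`, `event`.
#' @param conf_level Confidence level for the median CI.
#' @return Data frame with columns `arm`, `condition`, `n`, `events`,
#'   `median`, `ci_lower`, `ci_upper`; undefined quantities are `NA`.
#' @export
duration_report <- function(cohorts, conf_level = 0.95) {
  if (inherits(cohorts, "data.frame")) cohorts <- list(simulation = cohorts)
  if (length(cohorts) < 1L || is.null(names(cohorts)))
    stop("`cohorts` must be a named list of duration tables")
  arms_seen <- unique(unlist(lapply(cohorts, function(d) unique(d$arm))))
  canonical <- names(study_arms())
  arms_seen <- c(intersect(canonical, arms_seen), setdiff(arms_seen, canonical))
  rows <- list()
  for (a in arms_seen) {
    for (cond in names(cohorts)) {
      d <- cohorts[[cond]]
      d <- d[d$arm == a, , drop = FALSE]
      if (nrow(d) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          arm = a, condition = cond, n = 0L, events = 0L,
          median = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      km <- km_estimate(d$time_min, d$event, conf_level)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = a, condition = cond, n = km$n, events = km$events,
        median = km$median,
        ci_lower = km$median_ci[["lower"]], ci_upper = km$median_ci[["upper"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Export a Kaplan-Meier curve as a step function table
#'
#' @param km An `la_km` object.
#' @return Data frame `time`, `surv`, `n_risk`, `n_event`, `n_censor`,
#'   `lower`, `upper`, starting with the implicit (0, 1) point.
#' @export
km_steps <- function(km) {
  stopifnot(inherits(km, "la_km"))
  rbind(
    data.frame(time = 0, surv = 1, n_risk = km$n, n_event = 0L,
               n_censor = 0L, lower = 1, upper = 1),
    km$steps[, c("time", "surv", "n_risk", "n_event", "n_censor",
                 "lower", "upper")]
  )
}
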