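# Deterministic core of the probit-binomial effect model.
#
# A latent "log concentration" declines linearly in time from a fixed
# intercept of 100 with slope -1; co-injected adrenaline rescales the slope
# by (1 - adr). The probability of reacting to a needle stimulus is the
# upper tail of a Normal(mu, sigma) evaluated at the latent concentration,
# and the score at a time point is Binomial(n_stim, p).

#' Canonical drug labels
#'
#' Short labels for the four local anesthetic agents, in model index order:
#' procaine, lidocaine, mepivacaine, bupivacaine.
#'
#' @return Character vector of length 4.
#' @export
drug_names <- function() c("Pro", "Lid", "Mep", "Bup")

#' Latent concentration at time t
#'
#' The linear-in-time latent effect variable: `100 - (1 - adr_effect) * t`.
#' The intercept (100) and baseline slope (-1) are fixed identifiability
#' anchors, not free parameters. `adr_effect` is the product of the global
#' adrenaline slope-reduction factor and the arm's adrenaline indicator;
#' vasoconstriction slows washout, so the slope shrinks by `1 - adr_effect`.
#' Negative values are permitted for large t and simply drive the reaction
#' probability toward 1.
#'
#' @param t Time since injection in minutes, `>= 0`. Vectorized.
#' @param adr_effect Slope-reduction factor in `[0, 1)`.
#' @return Numeric vector of latent concentrations.
#' @export
#' @examples
#' latent_concentration(0)           # 100
#' latent_concentration(100)         # 0
#' latent_concentration(100, 0.665)  # 66.5
latent_concentration <- function(t, adr_effect = 0) {
  stopifnot(is.numeric(t), is.numeric(adr_effect))
  if (any(t < 0)) stop("`t` must be >= 0")
  check_adr_effect(adr_effect)
  100 - (1 - adr_effect) * t
}

check_adr_effect <- function(adr_effect) {
  if (any(!is.finite(adr_effect)) || any(adr_effect < 0) || any(adr_effect >= 1))
    stop("`adr_effect` must lie in [0, 1): a value >= 1 would freeze or reverse the decay")
  invisible(adr_effect)
}

#' Probability of reacting to a needle stimulus
#'
#' Upper-tail probability `1 - Phi((C(t) - mu) / sigma)` where `C(t)` is
#' [latent_concentration()]. Nondecreasing in t: as the anesthetic washes
#' out the latent concentration falls below the transition location `mu`
#' and sensation returns.
#'
#' @param t Time in minutes. Vectorized.
#' @param mu Transition location (latent-concentration units).
#' @param sigma Transition spread, `> 0`.
#' @param adr_effect Slope-reduction factor in `[0, 1)`.
#' @return Probabilities in `[0, 1]`.
#' @export
#' @examples
#' reaction_probability(100 - 67, mu = 67, sigma = 9)  # exactly 0.5
reaction_probability <- function(t, mu, sigma, adr_effect = 0) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("`sigma` must be > 0")
  conc <- latent_concentration(t, adr_effect)
  # 1 - pnorm((conc - mu)/sigma), written as the stable lower tail
  stats::pnorm((mu - conc) / sigma)
}

#' Time at which the reaction probability reaches one half
#'
#' Inverts the latent-concentration line at `C = mu`:
#' `(100 - mu) / (1 - adr_effect)`. Without adrenaline this reduces to
#' `100 - mu`, so a larger `mu` means an earlier transition and a shorter
#' anesthetic duration.
#'
#' @inheritParams reaction_probability
#' @return Time in minutes (may be negative when `mu > 100`).
#' @export
half_effect_time <- function(mu, adr_effect = 0) {
  check_adr_effect(adr_effect)
  (100 - mu) / (1 - adr_effect)
}

#' Probability mass function of the score
#'
#' Scores count reactions out of `n_stim` independent needle stimuli, so
#' the score at a fixed time is Binomial(`n_stim`, p).
#'
#' @param p Reaction probability, scalar in `[0, 1]`.
#' @param n_stim Number of stimuli per time point (study design: 6).
#' @return Numeric vector of length `n_stim + 1` with names `"0"`..`"n_stim"`.
#' @export
score_pmf <- function(p, n_stim = 6L) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]")
  n_stim <- as.integer(n_stim)
  stats::setNames(stats::dbinom(0:n_stim, n_stim, p), as.character(0:n_stim))
}

#' Construct a study arm
#'
#' An arm is a drug index 1..4 plus an adrenaline indicator. The bundled
#' study design uses five arms (Pro, Lid, Mep, Bup, Lid+Adr); Lid+Adr
#' shares lidocaine's drug parameters and only flips the indicator.
#'
#' @param drug Drug index 1..4 or one of [drug_names()].
#' @param v_adr Adrenaline indicator, 0 or 1.
#' @return An object of class `la_arm` with fields `drug` and `v_adr`.
#' @export
arm <- function(drug, v_adr = 0L) {
  if (is.character(drug)) {
    idx <- match(drug, drug_names())
    if (is.na(idx)) stop("unknown drug label: ", drug)
    drug <- idx
  }
  drug <- as.integer(drug)
  if (is.na(drug) || drug < 1L || drug > 4L)
    stop("`drug` must be an index in 1..4 or a label in drug_names()")
  v_adr <- as.integer(v_adr)
  if (!v_adr %in% c(0L, 1L)) stop("`v_adr` must be 0 or 1")
  structure(list(drug = drug, v_adr = v_adr), class = "la_arm")
}

#' The five-arm study layout
#'
#' @return Named list of [arm()] objects: Pro, Lid, Mep, Bup, Lid+Adr.
#' @export
study_arms <- function() {
  list(
    "Pro"     = arm(1L),
    "Lid"     = arm(2L),
    "Mep"     = arm(3L),
    "Bup"     = arm(4L),
    "Lid+Adr" = arm(2L, 1L)
  )
}

#' @export
print.la_arm <- function(x, ...) {
  cat(sprintf("<arm> drug %d (%s), adrenaline %s\n",
              x$drug, drug_names()[x$drug], ifelse(x$v_adr == 1L, "yes", "no")))
  invisible(x)
}
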