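# Population-level ("fixed effect") parameter sets.

#' Construct a population parameter set
#'
#' The hyperparameters of the hierarchical model: per drug, the mean and SD
#' of the Normal distribution of the individual transition location `mu`,
#' and the log-scale location and spread of the LogNormal distribution of
#' the individual transition width `sigma`; globally, the adrenaline
#' slope-reduction factor `adr` and the SD of the per-animal offset `d`.
#'
#' @param mu0 Length-4 numeric, per-drug mean of `mu` (Pro, Lid, Mep, Bup order).
#' @param s_mu0 Length-4 numeric `> 0`, per-drug SD of `mu`.
#' @param log_sigma0 Length-4 numeric, log-scale location of `sigma`.
#' @param log_s_sigma0 Length-4 numeric `> 0`, log-scale spread of `sigma`.
#' @param adr Adrenaline slope-reduction factor in `[0, 1]`.
#' @param sd_d SD of the per-animal offset `d` (`>= 0`; 0 disables offsets).
#' @return An object of class `la_pop`: a list with the above fields, each
#'   per-drug vector named by [drug_names()].
#' @export
#' @examples
#' pop <- la_fixture("table5_param2")
#' pop$mu0[["Pro"]]       # 75
#' sigma0(pop)[["Bup"]]   # exp(2.50)
population_params <- function(mu0, s_mu0, log_sigma0, log_s_sigma0, adr, sd_d = 0) {
  four <- function(x, nm) {
    if (length(x) != 4L || !is.numeric(x) || any(!is.finite(x)))
      stop("`", nm, "` must be numeric of length 4 (one value per drug)")
    stats::setNames(as.numeric(x), drug_names())
  }
  mu0 <- four(mu0, "mu0")
  s_mu0 <- four(s_mu0, "s_mu0")
  log_sigma0 <- four(log_sigma0, "log_sigma0")
  log_s_sigma0 <- four(log_s_sigma0, "log_s_sigma0")
  if (any(s_mu0 < 0)) stop("`s_mu0` must be >= 0")
  if (any(log_s_sigma0 < 0)) stop("`log_s_sigma0` must be >= 0")
  if (length(adr) != 1L || !is.finite(adr) || adr < 0 || adr > 1)
    stop("`adr` must be a single value in [0, 1]")
  if (length(sd_d) != 1L || !is.finite(sd_d) || sd_d < 0)
    stop("`sd_d` must be a single value >= 0")
  structure(
    list(mu0 = mu0, s_mu0 = s_mu0, log_sigma0 = log_sigma0,
         log_s_sigma0 = log_s_sigma0, adr = as.numeric(adr),
         sd_d = as.numeric(sd_d)),
    class = "la_pop"
  )
}

#' Natural-scale sigma0
#'
#' The LogNormal median of the individual transition width:
#' `exp(log_sigma0)`, the value reported next to the log-scale pair.
#'
#' @param pop An `la_pop` object.
#' @return Named length-4 numeric.
#' @export
sigma0 <- function(pop) {
  stopifnot(inherits(pop, "la_pop"))
  exp(pop$log_sigma0)
}

#' @export
print.la_pop <- function(x, ...) {
  cat("<population parameters>\n")
  s0 <- sigma0(x)
  for (i in seq_len(4L)) {
    cat(sprintf("  %-4s mu0 %6.1f (%.1f)   sigma0 %5.1f [%.2f, %.2f]\n",
                drug_names()[i], x$mu0[i], x$s_mu0[i], s0[i],
                x$log_sigma0[i], x$log_s_sigma0[i]))
  }
  cat(sprintf("  adrenaline %.3f   offset SD %.1f\n", x$adr, x$sd_d))
  invisible(x)
}

#' @export
as.data.frame.la_pop <- function(x, ...) {
  data.frame(
    drug = drug_names(),
    mu0 = unname(x$mu0), s_mu0 = unname(x$s_mu0),
    sigma0 = unname(exp(x$log_sigma0)),
    log_sigma0 = unname(x$log_sigma0), log_s_sigma0 = unname(x$log_s_sigma0),
    adr = x$adr, sd_d = x$sd_d
  )
}

#' Write / read a population parameter set as JSON
#'
#' @param pop An `la_pop` object.
#' @param path File path.
#' @return `read_params()` returns an `la_pop`; `write_params()` returns
#'   `path` invisibly.
#' @export
write_params <- function(pop, path) {
  stopifnot(inherits(pop, "la_pop"))
  jsonlite::write_json(unclass(pop), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  population_params(x$mu0, x$s_mu0, x$log_sigma0, x$log_s_sigma0, x$adr,
                    if (is.null(x$sd_d)) 0 else x$sd_d)
}
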