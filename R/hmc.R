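# Adaptive Hamiltonian Monte Carlo with dual-averaging step-size adaptation
# and diagonal mass-matrix estimation during warm-up. Generic: works on any
# target supplying `lp_grad(theta) -> list(lp, grad)`.

# One leapfrog trajectory; returns the proposal or a divergence flag.
leapfrog <- function(lp_grad, q, p, eps, L, inv_mass, cache) {
  g <- cache$grad
  p <- p + 0.5 * eps * g
  for (l in seq_len(L)) {
    q <- q + eps * inv_mass * p
    cache <- lp_grad(q)
    if (!is.finite(cache$lp) || any(!is.finite(cache$grad)))
      return(list(divergent = TRUE))
    p <- p + (if (l < L) eps else 0.5 * eps) * cache$grad
  }
  list(divergent = FALSE, q = q, p = p, cache = cache)
}

hamiltonian <- function(lp, p, inv_mass) -lp + 0.5 * sum(p^2 * inv_mass)

find_initial_stepsize <- function(lp_grad, q, inv_mass, eps = 0.1) {
  cache <- lp_grad(q)
  p <- stats::rnorm(length(q)) / sqrt(inv_mass)
  h0 <- hamiltonian(cache$lp, p, inv_mass)
  ratio_at <- function(eps) {
    step <- leapfrog(lp_grad, q, p, eps, 1L, inv_mass, cache)
    if (step$divergent) return(-Inf)
    h0 - hamiltonian(step$cache$lp, step$p, inv_mass)
  }
  a <- if (ratio_at(eps) > log(0.5)) 1 else -1
  for (it in seq_len(50L)) {
    eps_new <- eps * 2^a
    r <- ratio_at(eps_new)
    if ((a == 1 && r <= log(0.5)) || (a == -1 && r > log(0.5))) break
    eps <- eps_new
  }
  eps
}

# Run a single chain. Returns kept draws (matrix), kept log-posteriors and
# sampler diagnostics.
hmc_chain <- function(lp_grad, init, iter, warmup, thin,
                      target_accept = 0.9, inv_mass = NULL,
                      trajectory_length = 1.2, max_leapfrog = 48L) {
  q <- init
  n_par <- length(q)
  if (is.null(inv_mass)) inv_mass <- rep(1, n_par)
  cache <- lp_grad(q)
  if (!is.finite(cache$lp)) stop("initial point has non-finite log density")

  eps <- find_initial_stepsize(lp_grad, q, inv_mass)
  # dual averaging state (Hoffman & Gelman defaults)
  da <- list(mu = log(10 * eps), Hbar = 0, log_eps_bar = log(eps),
             gamma = 0.05, t0 = 10, kappa = 0.75, m = 0L)
  da_update <- function(da, alpha) {
    da$m <- da$m + 1L
    frac <- 1 / (da$m + da$t0)
    da$Hbar <- (1 - frac) * da$Hbar + frac * (target_accept - alpha)
    log_eps <- da$mu - sqrt(da$m) / da$gamma * da$Hbar
    eta <- da$m^(-da$kappa)
    da$log_eps_bar <- eta * log_eps + (1 - eta) * da$log_eps_bar
    da$eps <- exp(log_eps)
    da
  }

  # mass-matrix windows: re-estimate the diagonal metric twice during
  # warm-up, each time restarting step-size adaptation
  win_ends <- unique(pmax(2L, c(floor(0.5 * warmup), floor(0.9 * warmup))))
  win_lo <- max(1L, floor(0.15 * warmup))
  win_acc <- if (warmup > 1L) matrix(0, warmup, n_par)
  win_n <- 0L

  n_keep <- floor((iter - warmup) / thin)
  draws <- matrix(NA_real_, n_keep, n_par)
  lp_keep <- numeric(n_keep)
  kept <- 0L
  divergences <- 0L
  accept_sum <- 0

  for (it in seq_len(iter)) {
    p <- stats::rnorm(n_par) / sqrt(inv_mass)
    h0 <- hamiltonian(cache$lp, p, inv_mass)
    L_base <- max(1L, min(max_leapfrog, round(trajectory_length / eps)))
    L <- max(1L, as.integer(round(L_base * stats::runif(1, 0.5, 1))))
    step <- leapfrog(lp_grad, q, p, eps, L, inv_mass, cache)
    if (step$divergent) {
      alpha <- 0
      if (it > warmup) divergences <- divergences + 1L
    } else {
      dh <- h0 - hamiltonian(step$cache$lp, step$p, inv_mass)
      if (!is.finite(dh) || dh < -1000) {
        alpha <- 0
        if (it > warmup) divergences <- divergences + 1L
      } else {
        alpha <- min(1, exp(dh))
        if (log(stats::runif(1)) < dh) {
          q <- step$q
          cache <- step$cache
        }
      }
    }

    if (it <= warmup) {
      da <- da_update(da, alpha)
      eps <- da$eps
      if (warmup > 1L && it >= win_lo) {
        win_n <- win_n + 1L
        win_acc[win_n, ] <- q
      }
      if (it %in% win_ends && win_n > 10L) {
        v <- apply(win_acc[seq_len(win_n), , drop = FALSE], 2L, stats::var)
        # regularize toward the previous metric like Stan's windowed scheme
        v <- v * win_n / (win_n + 5) + inv_mass * 5 / (win_n + 5)
        inv_mass <- pmax(v, 1e-8)
        win_n <- 0L
        eps <- exp(da$log_eps_bar)
        da <- list(mu = log(10 * eps), Hbar = 0, log_eps_bar = log(eps),
                   gamma = 0.05, t0 = 10, kappa = 0.75, m = 0L)
      }
      if (it == warmup) eps <- exp(da$log_eps_bar)
    } else {
      accept_sum <- accept_sum + alpha
      if ((it - warmup) %% thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        draws[kept, ] <- q
        lp_keep[kept] <- cache$lp
      }
    }
  }

  list(draws = draws, lp = lp_keep, eps = eps, inv_mass = inv_mass,
       accept_rate = accept_sum / max(1L, iter - warmup),
       divergences = divergences)
}
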