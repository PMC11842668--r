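# Adaptive Hamiltonian Monte Carlo.
#
# A single-chain gradient-based sampler with the standard adaptation
# machinery: dual-averaging step-size tuning toward a target acceptance
# rate, windowed diagonal mass-matrix estimation during warmup, and
# uniformly jittered leapfrog trajectory lengths (which breaks the
# periodicity a fixed length can lock onto). Trajectories whose Hamiltonian
# error explodes are treated as divergent and rejected.

heuristic_eps <- function(lp_grad, theta, inv_mass, d) {
  eps <- 0.1
  p <- rnorm(d) / sqrt(inv_mass)
  cur <- lp_grad(theta)
  h0 <- -cur$lp + 0.5 * sum(inv_mass * p^2)
  ratio_at <- function(eps) {
    p1 <- p + 0.5 * eps * cur$grad
    th1 <- theta + eps * inv_mass * p1
    nx <- lp_grad(th1)
    if (!is.finite(nx$lp)) return(0)
    p1 <- p1 + 0.5 * eps * nx$grad
    h1 <- -nx$lp + 0.5 * sum(inv_mass * p1^2)
    exp(min(0, h0 - h1))
  }
  r <- ratio_at(eps)
  dir <- if (r > 0.5) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^dir
    r <- ratio_at(eps)
    if ((dir == 1 && r <= 0.5) || (dir == -1 && r > 0.5)) break
    if (eps > 10 || eps < 1e-7) break
  }
  min(max(eps, 1e-7), 10)
}

#' Adaptive Hamiltonian Monte Carlo sampler (single chain)
#'
#' The default sampler behind [sample_ps_posterior()]. Any function with
#' this signature returning a `n_draws` by `length(init)` matrix of
#' post-warmup draws qualifies as a sampler, so alternative MCMC schemes
#' can be plugged in.
#'
#' @param lp_grad function of the parameter vector returning
#'   `list(lp = , grad = )` — joint log-density and its gradient.
#' @param init numeric initial parameter vector (finite log-density).
#' @param n_warmup adaptation iterations (discarded).
#' @param n_draws retained post-warmup draws.
#' @param seed chain seed.
#' @param target_accept dual-averaging acceptance target, default 0.8.
#' @param int_time nominal trajectory integration time, default 2.5 (about
#'   pi/2 times the unit posterior scale the mass adaptation targets, with
#'   headroom for the wide directions of weakly identified coefficients).
#' @param max_leapfrog trajectory length cap, default 64.
#' @return matrix of draws with attributes `accept_rate` and `divergences`.
#' @export
hmc_chain <- function(lp_grad, init, n_warmup, n_draws, seed,
                      target_accept = 0.8, int_time = 2.5,
                      max_leapfrog = 64L) {
  set.seed(as.integer(seed))
  d <- length(init)
  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) abort("non-finite log-posterior at initial value")

  inv_mass <- rep(1, d)
  eps <- heuristic_eps(lp_grad, theta, inv_mass, d)
  # dual-averaging state (Hoffman-Gelman constants)
  da_init <- function(eps0) list(mu = log(10 * eps0), log_eps_bar = 0,
                                 h_bar = 0, m = 0)
  da <- da_init(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  w_end_fast <- max(1L, round(0.15 * n_warmup))
  w_end_collect <- max(w_end_fast + 2L, round(0.75 * n_warmup))
  collected <- matrix(NA_real_, w_end_collect - w_end_fast, d)

  draws <- matrix(NA_real_, n_draws, d)
  n_acc <- 0; n_div <- 0
  total <- n_warmup + n_draws

  for (it in seq_len(total)) {
    p0 <- rnorm(d) / sqrt(inv_mass)
    h0 <- -cur$lp + 0.5 * sum(inv_mass * p0^2)
    l_max <- max(1L, min(as.integer(max_leapfrog), ceiling(int_time / eps)))
    l_min <- max(1L, ceiling(l_max / 2))
    L <- if (l_max > l_min) sample(l_min:l_max, 1) else l_max

    th <- theta; pr <- p0; nx <- cur; ok <- TRUE
    for (s in seq_len(L)) {
      pr <- pr + 0.5 * eps * nx$grad
      th <- th + eps * inv_mass * pr
      nx <- lp_grad(th)
      if (!is.finite(nx$lp)) { ok <- FALSE; break }
      pr <- pr + 0.5 * eps * nx$grad
    }
    if (ok) {
      h1 <- -nx$lp + 0.5 * sum(inv_mass * pr^2)
      delta <- h0 - h1
      if (!is.finite(delta) || delta < -1000) { ok <- FALSE }
    }
    a <- if (ok) exp(min(0, delta)) else 0
    if (!ok) n_div <- n_div + 1
    if (ok && runif(1) < a) {
      theta <- th; cur <- nx
      if (it > n_warmup) n_acc <- n_acc + 1
    }

    if (it <= n_warmup) {
      # step-size adaptation
      da$m <- da$m + 1
      da$h_bar <- (1 - 1 / (da$m + t0)) * da$h_bar +
        (target_accept - a) / (da$m + t0)
      log_eps <- da$mu - sqrt(da$m) / gamma * da$h_bar
      eta <- da$m^(-kappa)
      da$log_eps_bar <- eta * log_eps + (1 - eta) * da$log_eps_bar
      eps <- exp(log_eps)
      # mass-matrix window
      if (it > w_end_fast && it <= w_end_collect)
        collected[it - w_end_fast, ] <- theta
      if (it == w_end_collect) {
        v <- apply(collected, 2, var)
        nc <- nrow(collected)
        inv_mass <- nc / (nc + 5) * v + 5 / (nc + 5) * 1e-3
        inv_mass[!is.finite(inv_mass) | inv_mass <= 0] <- 1e-3
        eps <- heuristic_eps(lp_grad, theta, inv_mass, d)
        da <- da_init(eps)
      }
      if (it == n_warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - n_warmup, ] <- theta
    }
  }
  structure(draws, accept_rate = n_acc / n_draws, divergences = n_div,
            step_size = eps)
}
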