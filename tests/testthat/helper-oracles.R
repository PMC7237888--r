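# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the full three-variable dimensional model is
# integrated directly, and matching is done by a naive double loop.

# Dimensional model: ds/dt = p - r*y*s; dy/dt = b*sum(x_i*g0*u_i*s) - alpha*y;
# dx_i/dt = x_i*(mu0*(u_i*s - s0) - a*(u_i/u_bar)^n). No QSS anywhere.
unscaled_oracle <- function(u, x0, up, n_hill, s_init, y_init, t_end,
                            n_steps = 400) {
  derivs <- function(t, state, parms) {
    s <- state[1]; y <- state[2]; x <- pmax(state[-(1:2)], 0)
    tot <- sum(x)
    u_bar <- if (tot > 0) sum(u * x) / tot else 1
    ds <- up$p - up$r * y * s
    dy <- up$b * sum(x * up$g0 * u * s) - up$alpha * y
    dx <- x * (up$mu0 * (u * s - up$s0) - up$a * (u / u_bar)^n_hill)
    list(c(ds, dy, dx))
  }
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::ode(y = c(s_init, y_init, x0), times = times, func = derivs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  list(times = times, s = sol[, 2], y = sol[, 3],
       x = sol[, -(1:3), drop = FALSE])
}

# Clone dynamics in dimensional time (rate mu0*s0 not rescaled away), signal
# slaved to its quasi-steady state. Used to check that time rescaling
# commutes with simulation.
dimensional_qss_oracle <- function(u, x0, mu0, s0, a, p_hat, n_hill, t_end,
                                   n_steps = 200) {
  derivs <- function(t, x, parms) {
    x <- pmax(x, 0)
    denom <- sum(u * x); tot <- sum(x)
    if (denom <= 1e-12 || tot <= 1e-12) return(list(rep(0, length(x))))
    s_rel <- p_hat / denom
    u_bar <- denom / tot
    list(x * (mu0 * s0 * (u * s_rel - 1) - a * (u / u_bar)^n_hill))
  }
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::ode(y = x0, times = times, func = derivs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  list(times = times, x = sol[, -1, drop = FALSE])
}

# Naive quadratic-time exact matcher.
brute_force_matches <- function(auto_seqs, public_seq_sets) {
  hits <- character(0)
  for (a in unique(auto_seqs)) {
    for (set in public_seq_sets) {
      found <- FALSE
      for (p in set) if (identical(a, p)) { found <- TRUE; break }
      if (found) { hits <- c(hits, a); break }
    }
  }
  hits
}

# Naive public-set builder: count subjects per sequence by looping.
brute_force_public <- function(tab, min_subjects) {
  seqs <- unique(tab$cdr3_aa)
  keep <- character(0)
  for (s in seqs) {
    n <- length(unique(tab$subject_id[tab$cdr3_aa == s]))
    if (n >= min_subjects) keep <- c(keep, s)
  }
  sort(keep)
}

expect_tolerant <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)), tol)
}
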