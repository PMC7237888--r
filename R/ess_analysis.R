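#' Invasion fitness of a rare missensing mutant
#'
#' Per-capita growth rate of a vanishingly rare clone with distortion `u`
#' introduced into a wild-type tissue at its steady state (`u_bar = 1`,
#' `s/s0 = 1 + gamma`):
#' \deqn{\lambda(u) = u (1+\gamma) - 1 - \gamma u^n.}
#' `lambda(u) > 0` means the mutant can expand. `lambda(1) = 0` always: the
#' wild type is neutral against itself.
#'
#' @param u Distortion(s), `> 0` (vectorized).
#' @param k A [killing_spec()].
#' @return Invasion fitness, same length as `u`.
#' @examples
#' invasion_fitness(2, killing_spec(0.25, 5)) # -6.5: surveillance removes it
#' invasion_fitness(2, killing_spec(0.01, 5)) # 0.70: mutant takeover
#' @export
invasion_fitness <- function(u, k) {
  stopifnot(inherits(k, "killing_spec"), is.numeric(u), all(is.finite(u)),
            all(u > 0))
  # algebraically equal to u*(1+gamma) - 1 - gamma*u^n; this grouping keeps
  # resident neutrality lambda(1) = 0 exact in floating point
  (u - 1) + k$gamma * (u - u^k$n)
}

#' Surveillance strength making killing an evolutionary stable strategy
#'
#' For power-law killing with cooperativity `n`, the unique strength at which
#' no missensing mutant (any `u`) has positive invasion fitness is
#' `gamma = 1/(n - 1)`. High observed T cell cooperativity (n = 3-5) thus
#' allows surveillance to work while killing well below the natural turnover
#' rate.
#'
#' @param n Hill cooperativity, `> 1`.
#' @return The ESS surveillance strength.
#' @examples
#' ess_gamma(5) # 0.25
#' @export
ess_gamma <- function(n) {
  stopifnot(is.numeric(n), all(is.finite(n)))
  if (any(n <= 1)) {
    stop(structure(
      class = c("ashm_no_ess", "error", "condition"),
      list(message = "no ESS exists for cooperativity n <= 1 (killing must be cooperative)",
           call = sys.call(-1))))
  }
  1 / (n - 1)
}

#' General function triple for the growth law
#'
#' Wraps arbitrary growth, secretion and killing functions for the general
#' (non-linearized) model `dx_i/dt = x_i (f(u_i s) - h(g(u_i s)/g_bar))`, for
#' use by [check_ess_conditions()]. `h` takes the relative antigen level
#' `z = g/g_bar` and must be non-negative and twice differentiable near
#' `z = 1`.
#'
#' @param f Growth function of the perceived signal.
#' @param g Secretion function of the perceived signal (positive).
#' @param h Killing function of relative antigen `z`.
#' @param s0 Natural removal-rate scale entering the first-order condition.
#' @param power_law_n If `h` is a declared power law `a * z^n`, its exponent;
#'   enables exact symbolic derivatives instead of finite differences.
#' @return An object of class `function_spec`.
#' @export
function_spec <- function(f = function(ps) ps - 1, g = function(ps) ps,
                          h, s0 = 1, power_law_n = NULL) {
  stopifnot(is.function(f), is.function(g), is.function(h),
            is.numeric(s0), length(s0) == 1L, s0 > 0)
  structure(list(f = f, g = g, h = h, s0 = s0, power_law_n = power_law_n),
            class = "function_spec")
}

# Central difference with one step of Richardson extrapolation.
richardson_deriv <- function(fn, x, order = 1, step = 1e-5) {
  d <- function(hh) {
    if (order == 1) (fn(x + hh) - fn(x - hh)) / (2 * hh)
    else (fn(x + hh) - 2 * fn(x) + fn(x - hh)) / hh^2
  }
  d1 <- d(step); d2 <- d(step / 2)
  (4 * d2 - d1) / 3
}

#' Check the ESS conditions on a killing function
#'
#' Evaluates the two conditions under which surveillance removes every
#' missensing mutant while the wild type remains at zero growth, assuming
#' proliferation and antigen secretion share a signaling pathway
#' (`f(us) = g(us) - s0`):
#' first order, `h'(1) = s0 + h(1)`; and curvature, `h''(1) > 0`.
#' Derivatives are exact for declared power laws, otherwise central
#' differences with Richardson refinement.
#'
#' @param fs A [function_spec()].
#' @param tol Tolerance on the first-order residual.
#' @param step Finite-difference step.
#' @return A list with `first_order_ok`, `curvature_ok`, the residual
#'   `h'(1) - s0 - h(1)`, and the derivative estimates `h1`, `hp1`, `hpp1`.
#' @examples
#' # power-law killing at the ESS strength for n = 5:
#' fs <- function_spec(h = function(z) 0.25 * z^5, s0 = 1, power_law_n = 5)
#' check_ess_conditions(fs)$first_order_ok # TRUE
#' @export
check_ess_conditions <- function(fs, tol = 1e-6, step = 1e-5) {
  stopifnot(inherits(fs, "function_spec"))
  h1 <- fs$h(1)
  if (!is.null(fs$power_law_n)) {
    n <- fs$power_law_n
    hp1 <- h1 * n
    hpp1 <- h1 * n * (n - 1)
  } else {
    hp1 <- richardson_deriv(fs$h, 1, order = 1, step = step)
    hpp1 <- richardson_deriv(fs$h, 1, order = 2, step = step)
  }
  if (!all(is.finite(c(h1, hp1, hpp1)))) {
    stop(structure(
      class = c("ashm_numderiv_error", "error", "condition"),
      list(message = "non-finite derivative estimate for killing function at z = 1",
           call = sys.call(-1))))
  }
  residual <- hp1 - fs$s0 - h1
  list(first_order_ok = abs(residual) <= tol,
       curvature_ok = hpp1 > 0,
       residual = residual,
       h1 = h1, hp1 = hp1, hpp1 = hpp1)
}

#' Brute-force scan for the most invasive mutant
#'
#' Grid-scans [invasion_fitness()] over distortions and polishes the argmax by
#' golden-section search. Surveillance is an evolutionary stable strategy iff
#' the global maximum sits at the wild type (`u = 1`) with fitness zero.
#'
#' @param k A [killing_spec()].
#' @param u_min,u_max Scan bounds, `0 < u_min < 1 < u_max`.
#' @param n_points Grid size, `>= 100`.
#' @param lambda_tol Tolerance on `|lambda(u_max)|` for the ESS flag.
#' @return A list of class `invasion_result`: `u_grid`, `lambda_values`,
#'   `u_max`, `lambda_max`, `ess_holds`.
#' @examples
#' max_invasion_u(killing_spec(ess_gamma(5), 5))$ess_holds # TRUE
#' @export
max_invasion_u <- function(k, u_min = 0.01, u_max = 10, n_points = 2000,
                           lambda_tol = 1e-9) {
  stopifnot(inherits(k, "killing_spec"),
            u_min > 0, u_min < 1, u_max > 1, n_points >= 100)
  u_grid <- exp(seq(log(u_min), log(u_max), length.out = n_points))
  lam <- invasion_fitness(u_grid, k)
  i <- which.max(lam)
  lo <- u_grid[max(1L, i - 1L)]
  hi <- u_grid[min(n_points, i + 1L)]
  opt <- stats::optimize(function(u) invasion_fitness(u, k),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  u_star <- opt$maximum
  lam_star <- opt$objective
  # lambda(1) = 0 exactly; prefer the wild type when the polished optimum is
  # not measurably better (golden section has O(tol) placement noise).
  if (lam_star <= lambda_tol) {
    u_star <- 1
    lam_star <- 0
  }
  grid_step <- max(diff(u_grid))
  structure(list(u_grid = u_grid, lambda_values = lam,
                 u_max = u_star, lambda_max = lam_star,
                 ess_holds = abs(u_star - 1) < grid_step &&
                   abs(lam_star) <= lambda_tol),
            class = "invasion_result")
}
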