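# Clone-competition dynamics under quasi-steady-state signal.
#
# dx_i/dt = x_i * (u_i * s_rel - 1 - gamma * (u_i/u_bar)^n),
# s_rel   = p_hat / sum(u_i x_i),  u_bar = sum(u_i x_i)/sum(x_i).
#
# The signal feedback sets an effective carrying capacity; killing is
# ratiometric, so a homogeneous tissue cannot be discriminated against.

.EXTINCTION_FLOOR <- 1e-9

clone_derivs <- function(t, x, parms) {
  x <- pmax(x, 0)
  u <- parms$u
  denom <- sum(u * x)
  tot <- sum(x)
  if (denom <= .TISSUE_FLOOR || tot <= .TISSUE_FLOOR) {
    return(list(rep(0, length(x))))
  }
  s_rel <- parms$p_hat / denom
  u_bar <- denom / tot
  dx <- x * (u * s_rel - 1 - parms$gamma * (u / u_bar)^parms$n)
  list(dx)
}

#' Simulate clone competition under surveillance
#'
#' Integrates the rescaled clone-competition equations with the signal slaved
#' to its quasi-steady state, using a stiff-capable adaptive integrator
#' (`deSolve::ode`, lsoda). Clones whose abundance falls below the extinction
#' floor (1e-9 in normalized units) are clamped to zero and labeled extinct;
#' the floor prevents negative overshoot from the steep killing term.
#'
#' @param clones0 Initial [clones()] table (at least one positive abundance).
#' @param params A [scaled_params()] object.
#' @param t_end End time in turnover units, `> 0`.
#' @param n_steps Number of stored output times.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @return An object of class `ashm_trajectory`: `times`, `abundances`
#'   (clones x times matrix), `s_rel`, `u_bar`, `outcome` (per clone,
#'   `"persists"` or `"extinct"`), and the input `clones0`/`params`.
#' @examples
#' sp <- scaled_params(killing_spec(0.25, 5))
#' tr <- simulate_clones(clones(u = c(1, 2, 0.5), x = c(1, 0.5, 0.5)), sp,
#'                       t_end = 50)
#' tr$outcome # mutants extinct, wild type persists
#' @export
simulate_clones <- function(clones0, params, t_end = 200, n_steps = 400,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(clones0, "clone_set"), inherits(params, "scaled_params"),
            is.numeric(t_end), t_end > 0)
  if (all(clones0$x <= 0)) stop("at least one clone must start with x > 0",
                                call. = FALSE)
  parms <- list(u = clones0$u, gamma = params$killing$gamma,
                n = params$killing$n, p_hat = params$p_hat)
  times <- seq(0, t_end, length.out = n_steps + 1)
  sol <- deSolve::ode(y = clones0$x, times = times, func = clone_derivs,
                      parms = parms, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(structure(
      class = c("ashm_integration_error", "error", "condition"),
      list(message = paste0("ODE integration failed (istate = ",
                            attr(sol, "istate")[1], ")"),
           call = sys.call(-1))))
  }
  ab <- t(unname(sol[, -1, drop = FALSE]))          # clones x times
  ab[ab < .EXTINCTION_FLOOR] <- 0
  denom <- colSums(clones0$u * ab)
  tot <- colSums(ab)
  s_rel <- ifelse(denom > .TISSUE_FLOOR, parms$p_hat / denom, NA_real_)
  u_bar <- ifelse(tot > .TISSUE_FLOOR, denom / tot, NA_real_)
  final <- ab[, ncol(ab)]
  outcome <- ifelse(final > 0, "persists", "extinct")
  structure(list(times = times, abundances = ab, s_rel = s_rel, u_bar = u_bar,
                 outcome = outcome, clones0 = clones0, params = params),
            class = "ashm_trajectory")
}

#' @export
print.ashm_trajectory <- function(x, ...) {
  cat(sprintf("<ashm_trajectory> %d clones over [0, %g] turnover times\n",
              nrow(x$abundances), max(x$times)))
  final <- x$abundances[, ncol(x$abundances)]
  for (i in seq_along(final)) {
    cat(sprintf("  u = %-5g x(0) = %-5g -> x(end) = %.4g [%s]\n",
                x$clones0$u[i], x$clones0$x[i], final[i], x$outcome[i]))
  }
  cat(sprintf("  s/s0(end) = %.4g\n", x$s_rel[length(x$s_rel)]))
  invisible(x)
}

#' Trajectory as a tidy tibble
#'
#' @param traj An `ashm_trajectory`.
#' @return A tibble with columns `time`, `clone`, `u`, `x`, `s_rel`, `u_bar`.
#' @export
trajectory_tbl <- function(traj) {
  stopifnot(inherits(traj, "ashm_trajectory"))
  nc <- nrow(traj$abundances)
  nt <- length(traj$times)
  tibble::tibble(
    time = rep(traj$times, each = nc),
    clone = rep(seq_len(nc), times = nt),
    u = rep(traj$clones0$u, times = nt),
    x = as.vector(traj$abundances),
    s_rel = rep(traj$s_rel, each = nc),
    u_bar = rep(traj$u_bar, each = nc))
}

#' Classify a parameter point into a disease regime
#'
#' Three mutually exclusive regimes of surveillance:
#' \describe{
#'   \item{autoimmune}{wild-type steady-state tissue falls below 50\% of the
#'     no-surveillance baseline; since `x*` scales as `(1+gamma)^-2`, this is
#'     the closed-form condition `(1+gamma)^2 > 2`, independent of `p_hat`.
#'     Takes precedence over invasion.}
#'   \item{mutant_expansion}{a single rare mutant with distortion `u_test` can
#'     invade the wild-type steady state (`lambda(u_test) > 0`).}
#'   \item{functional_surveillance}{neither: mutants are removed without
#'     sizable tissue loss.}
#' }
#'
#' @param params A [scaled_params()] object.
#' @param u_test Mutant distortion probed for invasion (default 2).
#' @return A list of class `regime_label`: `label`, `lambda_u_test`,
#'   `tissue_fraction` (wild-type steady state relative to `gamma = 0`).
#' @examples
#' classify_regime(scaled_params(killing_spec(0.25, 5)))$label
#' @export
classify_regime <- function(params, u_test = 2) {
  stopifnot(inherits(params, "scaled_params"), u_test > 0)
  g <- params$killing$gamma
  lam <- invasion_fitness(u_test, params$killing)
  frac <- 1 / (1 + g)^2
  label <- if ((1 + g)^2 > 2) "autoimmune"
           else if (lam > 0) "mutant_expansion"
           else "functional_surveillance"
  structure(list(label = label, lambda_u_test = lam, tissue_fraction = frac),
            class = "regime_label")
}

#' Regime map over a (gamma, n) grid
#'
#' @param gamma_grid,n_grid Positive numeric vectors.
#' @param u_test Probe distortion passed to [classify_regime()].
#' @return A tibble with columns `gamma`, `n`, `label`, `lambda_u_test`,
#'   `tissue_fraction` — one row per grid cell (CSV-exportable).
#' @examples
#' regime_map(c(0.01, 0.25, 2), c(2, 5))
#' @export
regime_map <- function(gamma_grid, n_grid, u_test = 2) {
  stopifnot(all(gamma_grid >= 0), all(n_grid >= 1))
  grid <- expand.grid(gamma = gamma_grid, n = n_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- classify_regime(
      scaled_params(killing_spec(grid$gamma[i], grid$n[i])), u_test = u_test)
    tibble::tibble(gamma = grid$gamma[i], n = grid$n[i], label = cl$label,
                   lambda_u_test = cl$lambda_u_test,
                   tissue_fraction = cl$tissue_fraction)
  })
  dplyr::bind_rows(res)
}

#' Gamma above which surveillance itself destroys the tissue
#'
#' The autoimmune boundary of the regime map: tissue loss exceeds 50% when
#' `(1+gamma)^2 > 2`, i.e. `gamma > sqrt(2) - 1`, independent of `n`.
#'
#' @return `sqrt(2) - 1`.
#' @export
autoimmune_boundary_gamma <- function() sqrt(2) - 1

# Right-hand side for a two-clone (wild type + mutant) system, open domain.
two_clone_rhs <- function(x, u, gamma, n, p_hat) {
  denom <- sum(u * x)
  tot <- sum(x)
  if (abs(denom) <= .TISSUE_FLOOR || abs(tot) <= .TISSUE_FLOOR) {
    return(c(0, 0))
  }
  s_rel <- p_hat / denom
  u_bar <- denom / tot
  x * (u * s_rel - 1 - gamma * (u / u_bar)^n)
}

#' Fixed points of the two-clone phase plane
#'
#' Finds non-negative fixed points of the wild-type vs mutant system by
#' Newton root-finding from a lattice of starting points (5x5 log-spaced over
#' `[1e-3, 3]^2` by default) plus the analytic boundary points (each clone
#' alone at `x = p_hat/(1+gamma)`), deduplicates within tolerance, and
#' classifies each by the eigenvalues of a numerically differentiated
#' Jacobian. The origin is always a (degenerate) fixed point: the
#' quasi-steady-state signal is undefined there.
#'
#' @param params A [scaled_params()] object.
#' @param u_mutant Mutant distortion (wild type `u = 1` is implied).
#' @param lattice_n Starts per axis.
#' @param lattice_range Range of the log-spaced lattice.
#' @param dedup_tol Distance below which two roots are merged.
#' @return A tibble with columns `x_wt`, `x_mut`, `stability`
#'   (`stable`/`saddle`/`unstable`/`degenerate`), `eig1`, `eig2`
#'   (real parts; NA for the origin).
#' @examples
#' phase_portrait(scaled_params(killing_spec(0.25, 5)), u_mutant = 2)
#' @export
phase_portrait <- function(params, u_mutant = 2, lattice_n = 5,
                           lattice_range = c(1e-3, 3), dedup_tol = 1e-6) {
  stopifnot(inherits(params, "scaled_params"), u_mutant > 0)
  g <- params$killing$gamma
  n <- params$killing$n
  p_hat <- params$p_hat
  u <- c(1, u_mutant)
  rhs <- function(x) two_clone_rhs(x, u, g, n, p_hat)

  # analytic single-clone boundary points: u * s_rel = 1 + g with
  # s_rel = p_hat/(u x) gives x = p_hat/(1+g) for either clone alone
  boundary <- list(c(p_hat / (1 + g), 0), c(0, p_hat / (1 + g)))

  starts <- exp(seq(log(lattice_range[1]), log(lattice_range[2]),
                    length.out = lattice_n))
  lattice <- expand.grid(x1 = starts, x2 = starts)
  roots <- boundary
  for (i in seq_len(nrow(lattice))) {
    x0 <- c(lattice$x1[i], lattice$x2[i])
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(rhs, x0, tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sol)) next
    xr <- sol$x
    if (any(!is.finite(xr)) || any(xr < -1e-8)) next
    if (max(abs(rhs(xr))) > 1e-8) next
    xr[abs(xr) < dedup_tol] <- 0
    roots <- c(roots, list(xr))
  }
  # deduplicate; the origin is reported separately as a degenerate point
  roots <- Filter(function(r) max(abs(r)) > dedup_tol, roots)
  uniq <- list()
  for (r in roots) {
    if (!any(vapply(uniq, function(q) max(abs(q - r)) < dedup_tol, logical(1)))) {
      uniq <- c(uniq, list(r))
    }
  }
  rows <- lapply(uniq, function(r) {
    J <- pracma::jacobian(rhs, r)
    ev <- eigen(J, only.values = TRUE)$values
    re <- sort(Re(ev))
    stab <- if (all(re < -1e-8)) "stable"
            else if (all(re > 1e-8)) "unstable"
            else if (re[1] < -1e-8 && re[2] > 1e-8) "saddle"
            else "marginal"
    tibble::tibble(x_wt = r[1], x_mut = r[2], stability = stab,
                   eig1 = re[1], eig2 = re[2])
  })
  out <- dplyr::bind_rows(rows)
  origin <- tibble::tibble(x_wt = 0, x_mut = 0, stability = "degenerate",
                           eig1 = NA_real_, eig2 = NA_real_)
  out <- dplyr::bind_rows(origin, out)
  out[order(out$x_wt, out$x_mut), ]
}
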