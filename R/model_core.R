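#' Killing specification for autoimmune surveillance
#'
#' Bundles the two parameters that define ratiometric immune killing of
#' secreting cells: the surveillance strength `gamma` (the removal rate that
#' surveillance inflicts on wild-type cells, in units of the tissue's natural
#' removal rate) and the Hill cooperativity `n` of the killing response to a
#' cell's antigen level relative to the tissue mean.
#'
#' @param gamma Surveillance strength, dimensionless, `>= 0`.
#' @param n Hill cooperativity of killing, dimensionless, `>= 1`.
#' @return An object of class `killing_spec`.
#' @examples
#' killing_spec(gamma = 0.25, n = 5)
#' @export
killing_spec <- function(gamma, n) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  structure(list(gamma = gamma, n = n), class = "killing_spec")
}

#' @export
print.killing_spec <- function(x, ...) {
  cat(sprintf("<killing_spec> gamma = %g, n = %g\n", x$gamma, x$n))
  invisible(x)
}

#' Unscaled (dimensional) model parameters
#'
#' Parameters of the dimensional tissue-feedback model: clones grow at rate
#' `mu0 * (u*s - s0)`, secrete hormone at gain `g0` (and scale `b`), the
#' signal is produced at rate `p` and removed at rate `r*y*s` by the hormone
#' `y`, which itself decays at rate `alpha`. Surveillance kills at scale `a`.
#' All fields must be strictly positive.
#'
#' @param mu0 Growth-rate gain per unit signal (1/time/signal).
#' @param s0 Zero-growth signal level (signal units).
#' @param g0 Secretion gain (hormone/time/signal).
#' @param a Killing-rate scale (1/time).
#' @param p Signal production rate (signal/time).
#' @param r Signal removal gain (1/(hormone * time)).
#' @param b Hormone secretion scale (hormone/(cell * time)).
#' @param alpha Hormone removal rate (1/time).
#' @return An object of class `unscaled_params`.
#' @examples
#' unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 0.25, p = 1, r = 1, b = 1, alpha = 1)
#' @export
unscaled_params <- function(mu0, s0, g0 = 1, a, p, r, b, alpha) {
  vals <- c(mu0 = mu0, s0 = s0, g0 = g0, a = a, p = p, r = r, b = b,
            alpha = alpha)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0)) {
    bad <- names(vals)[vals <= 0]
    stop("all parameters must be strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "unscaled_params")
}

#' Rescaled (dimensionless) model parameters
#'
#' The working parameterization of the model: time is measured in units of
#' tissue turnover (`t -> mu0*s0*t`), cell concentrations are normalized to
#' the wild-type steady state, and the signal production collapses into the
#' single dimensionless rate `p_hat = p*alpha/(b*r*s0^2)`.
#'
#' The default `p_hat = 1 + gamma` places the wild-type steady state at
#' normalized abundance `x* = 1`.
#'
#' @param killing A [killing_spec()].
#' @param p_hat Rescaled signal production, `> 0`. Default `1 + gamma`.
#' @return An object of class `scaled_params`.
#' @examples
#' scaled_params(killing_spec(0.25, 5))
#' @export
scaled_params <- function(killing, p_hat = 1 + killing$gamma) {
  stopifnot(inherits(killing, "killing_spec"),
            is.numeric(p_hat), length(p_hat) == 1L, is.finite(p_hat))
  if (p_hat <= 0) stop("`p_hat` must be > 0", call. = FALSE)
  structure(list(killing = killing, p_hat = p_hat), class = "scaled_params")
}

#' @export
print.scaled_params <- function(x, ...) {
  cat(sprintf("<scaled_params> gamma = %g, n = %g, p_hat = %g (time in turnover units)\n",
              x$killing$gamma, x$killing$n, x$p_hat))
  invisible(x)
}

# Upper validation bound on distortion u; catches config typos, not a model
# constraint.
.U_MAX_VALID <- 100

#' Clone population table
#'
#' A clone is a cell lineage with a fixed sensing distortion `u` (it perceives
#' `u * s` instead of the true signal `s`; `u = 1` is wild type) and a
#' normalized abundance `x` (wild-type steady-state concentration = 1).
#'
#' @param u Numeric vector of distortions, each in `(0, 100]`.
#' @param x Numeric vector of abundances, each `>= 0`, recycled against `u`.
#' @return A tibble of class `clone_set` with columns `u` and `x`.
#' @examples
#' clones(u = c(1, 2, 0.5), x = c(1, 0.5, 0.5))
#' @export
clones <- function(u, x = 1) {
  stopifnot(is.numeric(u), is.numeric(x))
  if (length(x) == 1L) x <- rep(x, length(u))
  if (length(u) != length(x)) stop("`u` and `x` lengths differ", call. = FALSE)
  if (any(!is.finite(u)) || any(u <= 0) || any(u > .U_MAX_VALID)) {
    stop("`u` must be finite and in (0, ", .U_MAX_VALID, "]", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and >= 0", call. = FALSE)
  }
  out <- tibble::tibble(u = as.numeric(u), x = as.numeric(x))
  class(out) <- c("clone_set", class(out))
  out
}

# Floor on total perceived-signal-weighted abundance below which the tissue is
# treated as collapsed (the quasi-steady-state signal would diverge).
.TISSUE_FLOOR <- 1e-12

stop_degenerate <- function() {
  stop(structure(
    class = c("ashm_degenerate_tissue", "error", "condition"),
    list(message = "degenerate tissue: total perceived abundance is (near) zero, signal diverges",
         call = sys.call(-1))))
}

#' Abundance-weighted mean distortion
#'
#' `u_bar = sum(u_i * x_i) / sum(x_i)` — the tissue-average distortion that
#' regulatory T cells normalize killing against.
#'
#' @param cl A [clones()] table.
#' @return Scalar mean distortion.
#' @examples
#' mean_distortion(clones(u = c(1, 2), x = c(3, 1))) # 1.25
#' @export
mean_distortion <- function(cl) {
  tot <- sum(cl$x)
  if (!is.finite(tot) || tot <= .TISSUE_FLOOR) stop_degenerate()
  sum(cl$u * cl$x) / tot
}

#' Quasi-steady-state relative signal
#'
#' With hormone and signal dynamics much faster than cell turnover, the
#' relative signal is slaved to the tissue: `s/s0 = p_hat / sum(u_i * x_i)`.
#'
#' @param cl A [clones()] table.
#' @param p_hat Rescaled production rate, `> 0`.
#' @return Scalar relative signal `s/s0`.
#' @examples
#' qss_signal(clones(u = 1, x = 1), p_hat = 1.25) # 1.25
#' @export
qss_signal <- function(cl, p_hat) {
  stopifnot(is.numeric(p_hat), length(p_hat) == 1L, p_hat > 0)
  denom <- sum(cl$u * cl$x)
  if (!is.finite(denom) || denom <= .TISSUE_FLOOR) stop_degenerate()
  p_hat / denom
}

#' Per-capita clone growth rate under surveillance
#'
#' The rescaled growth law for a clone with distortion `u` in a tissue with
#' relative signal `s_rel` and mean distortion `u_bar`:
#' `u * s_rel - 1 - gamma * (u / u_bar)^n`. The first term is perceived-signal
#' driven proliferation, `-1` is natural removal, and the last term is
#' cooperative immune killing of cells presenting more secretion antigen than
#' the tissue average (the `u_bar` normalization models Treg-mediated
#' tolerance).
#'
#' @param u Clone distortion, `> 0` (vectorized).
#' @param s_rel Relative signal `s/s0`, `> 0`.
#' @param u_bar Tissue-mean distortion, `> 0`.
#' @param k A [killing_spec()].
#' @return Per-capita growth rate in 1/turnover-time units.
#' @examples
#' k <- killing_spec(0.25, 5)
#' per_capita_growth(u = 1, s_rel = 1.25, u_bar = 1, k = k) # 0: wild-type set-point
#' per_capita_growth(u = 2, s_rel = 1.25, u_bar = 1, k = k) # -6.5
#' @export
per_capita_growth <- function(u, s_rel, u_bar, k) {
  stopifnot(inherits(k, "killing_spec"),
            is.numeric(u), all(u > 0),
            is.numeric(s_rel), length(s_rel) == 1L, s_rel > 0)
  if (!is.numeric(u_bar) || length(u_bar) != 1L || !is.finite(u_bar) ||
      u_bar <= 0) {
    stop_degenerate()
  }
  u * s_rel - 1 - k$gamma * (u / u_bar)^k$n
}

#' Closed-form wild-type steady state of the dimensional model
#'
#' For a tissue of wild-type cells only, the three-variable feedback model has
#' the set-points `s* = s0*(1+gamma)`, `x* = (p*alpha/(r*b)) / (s0^2*(1+gamma)^2)`
#' and `y* = (p/(r*s0)) / (1+gamma)`, with `gamma = a/(mu0*s0)`. Surveillance
#' strength therefore shifts both the signal set-point and the tissue size;
#' the signal set-point depends on `s0` and `gamma` only.
#'
#' @param up An [unscaled_params()] set.
#' @param k A [killing_spec()]; its `gamma` is ignored in favour of the value
#'   implied by `up` unless `use_spec_gamma = TRUE`.
#' @param use_spec_gamma If `TRUE`, take `gamma` from `k` rather than
#'   `a/(mu0*s0)`.
#' @return A list of class `steady_state` with `s_star`, `x_star`, `y_star`
#'   and the `gamma` used.
#' @examples
#' up <- unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 0.25, p = 1, r = 1,
#'                       b = 1, alpha = 1)
#' wild_type_steady_state(up, killing_spec(0.25, 5))$s_star # 1.25
#' @export
wild_type_steady_state <- function(up, k, use_spec_gamma = FALSE) {
  stopifnot(inherits(up, "unscaled_params"), inherits(k, "killing_spec"))
  gamma <- if (use_spec_gamma) k$gamma else up$a / (up$mu0 * up$s0)
  s_star <- up$s0 * (1 + gamma)
  x_star <- (up$p * up$alpha / (up$r * up$b)) / (up$s0^2 * (1 + gamma)^2)
  y_star <- (up$p / (up$r * up$s0)) / (1 + gamma)
  structure(list(s_star = s_star, x_star = x_star, y_star = y_star,
                 gamma = gamma),
            class = "steady_state")
}

#' Rescale dimensional parameters to turnover units
#'
#' Measures time in tissue-turnover units (`t -> mu0*s0*t`) and collapses the
#' signal/hormone parameters into `gamma = a/(mu0*s0)` and
#' `p_hat = p*alpha/(b*r*s0^2)`. Cell concentrations in the rescaled model are
#' normalized to the wild-type steady state.
#'
#' @param up An [unscaled_params()] set.
#' @param n Hill cooperativity for the resulting [killing_spec()].
#' @return A [scaled_params()] object; its `time_unit` attribute holds the
#'   turnover rate `mu0*s0` that converts rescaled times back to the original
#'   units.
#' @examples
#' up <- unscaled_params(mu0 = 1, s0 = 1, g0 = 1, a = 0.25, p = 1, r = 1,
#'                       b = 1, alpha = 1)
#' rescale(up, n = 5)
#' @export
rescale <- function(up, n) {
  stopifnot(inherits(up, "unscaled_params"))
  gamma <- up$a / (up$mu0 * up$s0)
  p_hat <- up$p * up$alpha / (up$b * up$r * up$s0^2)
  sp <- scaled_params(killing_spec(gamma, n), p_hat = p_hat)
  attr(sp, "time_unit") <- up$mu0 * up$s0
  sp
}
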