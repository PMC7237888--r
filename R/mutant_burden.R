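# Back-of-envelope calculators for how often activating (missensing)
# mutations arise during organ development, and for cross-organ comparisons of
# per-cell adenoma risk. All arithmetic is exact; a separate "presented" field
# carries the order-of-magnitude rounding used when quoting the numbers.

round_to_multiple <- function(x, m) m * round(x / m)

signif1 <- function(x) signif(x, 1)

#' Organ mutation input
#'
#' @param n_divisions Developmental cell divisions (e.g. ~1e10 for a 10 g
#'   thyroid of ~1e10 secreting cells).
#' @param mu_bp Mutation rate per basepair per division (~1e-9 in humans).
#' @param n_sites Number of distinct activating point mutations/sites
#'   (mutational target size), default 1.
#' @return A list of class `organ_mutation_input`.
#' @export
organ_mutation_input <- function(n_divisions, mu_bp, n_sites = 1) {
  stopifnot(is.numeric(n_divisions), n_divisions >= 0,
            is.numeric(mu_bp), mu_bp >= 0, mu_bp <= 1,
            is.numeric(n_sites), n_sites >= 0)
  structure(list(n_divisions = n_divisions, mu_bp = mu_bp, n_sites = n_sites),
            class = "organ_mutation_input")
}

#' Expected occurrences of any given point mutation during development
#'
#' `n_divisions * mu_bp`: with ~1e10 divisions and a mutation rate of
#' 1e-9/bp/division, any given point mutation arises about ten times by the
#' time the organ has developed.
#'
#' @param inp An [organ_mutation_input()].
#' @return List with `raw` (exact product) and `presented` (1 significant
#'   figure).
#' @examples
#' expected_occurrences_per_mutation(organ_mutation_input(1e10, 1e-9))$raw # 10
#' @export
expected_occurrences_per_mutation <- function(inp) {
  stopifnot(inherits(inp, "organ_mutation_input"))
  raw <- inp$n_divisions * inp$mu_bp
  list(raw = raw, presented = signif1(raw))
}

#' Expected number of hypersecreting founder clones
#'
#' `n_divisions * mu_bp * n_sites`: the per-mutation recurrence times the
#' activating target size. For the thyroid (1e10 divisions, 45 known
#' activating receptor sites) this is ~450 — hundreds of potential
#' hypersecreting nodules per individual, motivating a surveillance mechanism.
#'
#' @param inp An [organ_mutation_input()].
#' @return List with `raw` and `presented` (1 significant figure).
#' @examples
#' expected_founder_clones(organ_mutation_input(1e10, 1e-9, 45))$raw # 450
#' @export
expected_founder_clones <- function(inp) {
  stopifnot(inherits(inp, "organ_mutation_input"))
  raw <- inp$n_divisions * inp$mu_bp * inp$n_sites
  list(raw = raw, presented = signif1(raw))
}

#' Gland comparison input for per-cell adenoma risk
#'
#' @param mass_a,mass_b Gland masses in grams.
#' @param frac_a,frac_b Fraction of the gland's cells that are the relevant
#'   secreting type, in `(0, 1]`.
#' @param case_frac_a,case_frac_b Fraction of the clinical syndrome attributed
#'   to each gland, in `(0, 1]`, summing to at most 1.
#' @return A list of class `gland_comparison_input`.
#' @export
gland_comparison_input <- function(mass_a, frac_a, case_frac_a,
                                   mass_b, frac_b, case_frac_b) {
  vals <- c(mass_a = mass_a, frac_a = frac_a, case_frac_a = case_frac_a,
            mass_b = mass_b, frac_b = frac_b, case_frac_b = case_frac_b)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0)) stop("all comparison inputs must be > 0", call. = FALSE)
  if (any(c(frac_a, frac_b, case_frac_a, case_frac_b) > 1)) {
    stop("fractions must be <= 1", call. = FALSE)
  }
  if (case_frac_a + case_frac_b > 1 + 1e-12) {
    stop("case fractions must sum to <= 1", call. = FALSE)
  }
  structure(as.list(vals), class = "gland_comparison_input")
}

#' Per-cell adenoma risk ratio between two glands
#'
#' Assuming equal cell-mass density, gland B holds
#' `(mass_b*frac_b)/(mass_a*frac_a)` times more relevant cells than gland A,
#' so the per-cell risk ratio A:B is
#' `(case_frac_a/case_frac_b) * (mass_b*frac_b)/(mass_a*frac_a)`.
#' For pituitary corticotrophs (0.5 g, 15-20\%) vs adrenal cortisol-secreting
#' cells (10 g, 50\%) with an 80/20 split of Cushing cases, the adrenal has
#' ~50x more cells yet causes 4x fewer cases: a per-cell risk ratio of ~200-267,
#' presented as "about 250".
#'
#' Presentation rounding: nearest multiple of 50 when the ratio exceeds 100,
#' nearest multiple of 5 otherwise; the raw value is always kept.
#'
#' @param inp A [gland_comparison_input()].
#' @return List with `raw`, `presented`, `cell_ratio` (cells in B per cell in
#'   A, raw and presented) and `assumptions`.
#' @examples
#' inp <- gland_comparison_input(mass_a = 0.5, frac_a = 0.15, case_frac_a = 0.8,
#'                               mass_b = 10, frac_b = 0.5, case_frac_b = 0.2)
#' per_cell_risk_ratio(inp)$presented # 250
#' @export
per_cell_risk_ratio <- function(inp) {
  stopifnot(inherits(inp, "gland_comparison_input"))
  cell_ratio <- (inp$mass_b * inp$frac_b) / (inp$mass_a * inp$frac_a)
  raw <- (inp$case_frac_a / inp$case_frac_b) * cell_ratio
  present <- function(x) {
    if (x > 100) round_to_multiple(x, 50) else round_to_multiple(x, 5)
  }
  list(raw = raw,
       presented = present(raw),
       cell_ratio = list(raw = cell_ratio, presented = present(cell_ratio)),
       assumptions = "equal cell-mass density per gram across glands")
}
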