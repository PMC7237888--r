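competition <- function() gen_clone_population(preset = "competition")

test_that("wild type alone at its set-point is stationary", {
  sp <- scaled_params(killing_spec(0.25, 5))
  tr <- simulate_clones(clones(u = 1, x = 1), sp, t_end = 50)
  expect_lt(max(abs(tr$abundances - 1)), 1e-6)
  expect_lt(max(abs(tr$s_rel - 1.25)), 1e-6)
})

test_that("three-clone contest resolves by surveillance strength", {
  n <- 5
  # weak surveillance: hypersecretor takes over, signal hyporegulated
  tr_weak <- simulate_clones(competition(), scaled_params(killing_spec(0.01, n)),
                             t_end = 200)
  expect_identical(tr_weak$outcome, c("extinct", "persists", "extinct"))
  final_s <- tr_weak$s_rel[length(tr_weak$s_rel)]
  expect_lt(final_s, 1.01)                      # below the set-point 1+gamma
  expect_equal(final_s, 1.01 / 2, tolerance = 1e-3)  # (1+gamma)/2

  # ESS surveillance: both mutants eliminated, signal at its set-point
  tr_ess <- simulate_clones(competition(), scaled_params(killing_spec(0.25, n)),
                            t_end = 200)
  expect_identical(tr_ess$outcome, c("persists", "extinct", "extinct"))
  expect_equal(tr_ess$s_rel[length(tr_ess$s_rel)], 1.25, tolerance = 1e-3)

  # over-strong surveillance: hyposecretor dominates, tissue set-point < half
  tr_auto <- simulate_clones(competition(), scaled_params(killing_spec(2, n)),
                             t_end = 200)
  expect_identical(tr_auto$outcome, c("extinct", "extinct", "persists"))
  expect_lt(1 / (1 + 2)^2, 0.5)   # wild-type steady state vs gamma = 0
})

test_that("trajectories are non-negative and satisfy the QSS identity", {
  for (g in c(0.01, 0.25, 2)) {
    sp <- scaled_params(killing_spec(g, 5))
    tr <- simulate_clones(competition(), sp, t_end = 100)
    expect_gte(min(tr$abundances), 0)
    keep <- !is.na(tr$s_rel)
    denom <- colSums(tr$clones0$u * tr$abundances)[keep]
    expect_lt(max(abs(tr$s_rel[keep] * denom - sp$p_hat)), 1e-6)
  }
})

test_that("a homogeneous mutant tissue cannot be discriminated against", {
  # all-u=2 tissue: killing normalizes to u_bar = 2, signal settles at
  # (1+gamma)/2 (hyporegulation), not at the wild-type set-point
  g <- 0.25
  sp <- scaled_params(killing_spec(g, 5))
  tr <- simulate_clones(clones(u = 2, x = 0.7), sp, t_end = 200)
  expect_equal(tr$s_rel[length(tr$s_rel)], (1 + g) / 2, tolerance = 1e-6)
})

test_that("in the autoimmune regime the lowest-u clone persists and shrinks with gamma", {
  # fixed production p_hat across gamma so residual sizes are comparable
  residuals <- vapply(c(0.8, 1.5, 3), function(g) {
    tr <- simulate_clones(competition(),
                          scaled_params(killing_spec(g, 5), p_hat = 1),
                          t_end = 300)
    final <- tr$abundances[, ncol(tr$abundances)]
    expect_gt(final[3], max(final[1:2]))  # u = 0.5 dominates
    sum(final)
  }, numeric(1))
  expect_true(all(diff(residuals) < 0))
})

test_that("regime classification follows the invasion and tissue-loss criteria", {
  expect_identical(classify_regime(scaled_params(killing_spec(0.25, 5)))$label,
                   "functional_surveillance")
  expect_identical(classify_regime(scaled_params(killing_spec(0.01, 5)))$label,
                   "mutant_expansion")
  expect_identical(classify_regime(scaled_params(killing_spec(2, 5)))$label,
                   "autoimmune")
  # autoimmunity takes precedence even where invasion also holds
  expect_identical(classify_regime(scaled_params(killing_spec(2, 1.5)))$label,
                   "autoimmune")
  # the boundary is sqrt(2)-1, independent of n
  b <- autoimmune_boundary_gamma()
  for (n in c(2, 5, 9)) {
    expect_identical(
      classify_regime(scaled_params(killing_spec(b + 1e-9, n)))$label,
      "autoimmune")
    expect_false(
      classify_regime(scaled_params(killing_spec(b - 1e-9, n)))$label ==
        "autoimmune")
  }
})

test_that("regime map has no safe region without cooperativity and is safe at the ESS", {
  rm_tbl <- regime_map(gamma_grid = c(0.05, 0.2, 0.41, 0.6, 1, 2),
                       n_grid = c(1, 2, 4, 5, 8))
  # n = 1: every gamma is mutant expansion or autoimmune
  n1 <- rm_tbl[rm_tbl$n == 1, ]
  expect_true(all(n1$label %in% c("mutant_expansion", "autoimmune")))
  # gamma = 1/(n-1) is functional surveillance for n >= 4
  for (n in c(4, 5, 8)) {
    lab <- classify_regime(scaled_params(killing_spec(ess_gamma(n), n)))$label
    expect_identical(lab, "functional_surveillance")
  }
  # labels are mutually exclusive and exhaustive
  expect_true(all(rm_tbl$label %in%
    c("mutant_expansion", "functional_surveillance", "autoimmune")))
})

test_that("classification agrees with long-run simulation of a rare mutant", {
  grid <- expand.grid(gamma = c(0.05, 0.25, 0.41, 0.8, 2),
                      n = c(1.5, 3, 5, 7, 9))
  for (i in seq_len(nrow(grid))) {
    sp <- scaled_params(killing_spec(grid$gamma[i], grid$n[i]))
    lab <- classify_regime(sp)$label
    tr <- simulate_clones(clones(u = c(1, 2), x = c(1, 1e-3)), sp,
                          t_end = 400)
    mut_grew <- tr$outcome[2] == "persists" &&
      tr$abundances[2, ncol(tr$abundances)] > 1e-3
    if (lab == "mutant_expansion") {
      expect_true(mut_grew, label = sprintf(
        "mutant grows at gamma=%g n=%g", grid$gamma[i], grid$n[i]))
    } else if (lab == "functional_surveillance") {
      expect_false(mut_grew, label = sprintf(
        "mutant removed at gamma=%g n=%g", grid$gamma[i], grid$n[i]))
    } # autoimmune: invasion of u=2 may go either way; tissue criterion rules
  }
})

test_that("phase portrait finds bistability at the ESS and a saddle when weak", {
  sp <- scaled_params(killing_spec(0.25, 5))
  fp <- phase_portrait(sp, u_mutant = 2)
  wt_only <- fp[fp$x_mut == 0 & fp$x_wt > 0, ]
  mut_only <- fp[fp$x_wt == 0 & fp$x_mut > 0, ]
  expect_identical(wt_only$stability, "stable")
  expect_identical(mut_only$stability, "stable")
  expect_true(any(fp$stability == "saddle"))     # separatrix between them
  expect_equal(wt_only$x_wt, 1, tolerance = 1e-6)
  # origin flagged degenerate
  expect_identical(fp$stability[fp$x_wt == 0 & fp$x_mut == 0], "degenerate")
  # classification consistent with eigenvalue signs
  interior <- fp[!is.na(fp$eig1), ]
  expect_true(all((interior$stability == "stable") ==
                    (pmax(interior$eig1, interior$eig2) < 0)))

  # weak surveillance: wild-type-only point is a saddle (mutant invades)
  fp_weak <- phase_portrait(scaled_params(killing_spec(0.01, 5)), u_mutant = 2)
  wt_weak <- fp_weak[fp_weak$x_mut == 0 & fp_weak$x_wt > 0, ]
  expect_identical(wt_weak$stability, "saddle")
})
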