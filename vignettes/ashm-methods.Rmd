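---
title: "Methods: clonal dynamics and surveillance of hypersecreting mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal dynamics and surveillance of hypersecreting mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashm)
```

## The model

Endocrine tissue-size control is modeled as competition between cell clones
that differ only in how they perceive the regulating signal. Clone $i$ has a
sensing distortion $u_i > 0$ ($u_i = 1$ is wild type) and perceives $u_i s$
instead of the true signal $s$. Perceived signal drives both proliferation
and secretion, so a hypersensing clone both outgrows and outsecretes its
neighbours. Surveillance kills cells at a rate that is a steep (Hill,
cooperativity $n$) function of their secretion-pathway antigen *relative to
the tissue mean* — the normalization models regulatory T cells activated by
antigen sampled from the whole tissue. In rescaled units (time in tissue
turnovers, abundances normalized to the wild-type steady state):

$$\frac{dx_i}{dt} = x_i\!\left(u_i \frac{s}{s_0} - 1
  - \gamma\left(\frac{u_i}{\bar u}\right)^{\!n}\right),
\qquad \bar u = \frac{\sum_i u_i x_i}{\sum_i x_i},$$

with the signal slaved to its quasi-steady state,

$$\frac{s}{s_0} = \frac{\hat p}{\sum_i u_i x_i}.$$

$\gamma$ is the surveillance strength: the killing rate suffered by
wild-type cells in units of the tissue's natural removal rate. The signal
feedback provides the effective carrying capacity; the ratiometric killing
term is what distinguishes mutants — and only while the tissue is
heterogeneous. A homogeneous mutant tissue has $u_i = \bar u$ and is
indistinguishable from wild type, which is why surveillance is
frequency-dependent and cannot correct germline missensing.

The dimensional three-variable counterpart (signal produced at rate $p$ and
removed by the hormone, hormone secreted by the clones) has the wild-type
set-points
$s^* = s_0(1+\gamma)$, $x^* = (p\alpha/rb)/s_0^2(1+\gamma)^2$ and
$y^* = (p/rs_0)/(1+\gamma)$: surveillance raises the signal set-point and
shrinks the tissue. The signal set-point depends only on $s_0$ and $\gamma$
— a homeostatic property the test suite checks against direct integration of
the dimensional system.

**A note on the reduction.** The package treats the rescaled clone system
with the hyperbolic signal law $s/s_0 = \hat p / \sum u_i x_i$ as the model
definition. An exact quasi-steady-state elimination of the dimensional
signal/hormone pair instead yields a square-root law
$s/s_0 = (1+\gamma)/\sqrt{\sum u_i x_i}$; the two coincide at the wild-type
steady state, give identical invasion fitness (which is evaluated at that
steady state), the same ESS condition and the same regime boundaries, but
differ on finite transients and on the absolute abundance of
homogeneous-mutant steady states. All results reported by this package are
stated in the hyperbolic reduction; the dimensional model is used in the
tests only for steady-state and outcome-level cross-checks, and time
rescaling is verified within the reduced family.

## Evolutionary stability

A rare mutant in a wild-type tissue at steady state ($\bar u = 1$,
$s/s_0 = 1+\gamma$) grows at the invasion fitness

$$\lambda(u) = u(1+\gamma) - 1 - \gamma u^n,$$

implemented in a grouping that keeps $\lambda(1) = 0$ exact in floating
point. Surveillance is an evolutionary stable strategy when no $u$ has
$\lambda(u) > 0$; for power-law killing this pins the strength at
$\gamma = 1/(n-1)$, so observed T cell cooperativities of 3–5 allow
surveillance at a fraction of natural turnover. For a general killing
function $h$ of relative antigen $z$, the conditions are the first-order
balance $h'(1) = s_0 + h(1)$ and positive curvature $h''(1) > 0$;
`check_ess_conditions()` evaluates both, using exact derivatives for
declared power laws and central differences with one Richardson step
(default step $10^{-5}$) otherwise. For a power law $h = a z^n$ the
curvature is $a\,n(n-1)$, positive for any $n > 1$; the package therefore
reports curvature directly from $h''(1)$ and does not impose a stricter
cooperativity cutoff, while `max_invasion_u()` provides the brute-force
check (log-spaced grid, golden-section polish, ESS tolerance
$|\lambda| < 10^{-9}$ with the argmax within one grid step of $u = 1$).

## Regimes and numerics

`classify_regime()` applies two closed-form criteria: *autoimmune* when the
wild-type steady-state tissue falls below half the no-surveillance baseline
— since $x^* \propto (1+\gamma)^{-2}$ this is $(1+\gamma)^2 > 2$, i.e.
$\gamma > \sqrt 2 - 1 \approx 0.414$, independent of $n$ and of $\hat p$ —
and otherwise *mutant expansion* when $\lambda(u_\text{test}) > 0$ for the
probe distortion $u_\text{test} = 2$. Autoimmunity takes precedence when
both hold. The remaining region is functional surveillance: mutants removed
without sizable tissue loss.

Numerical choices, all config-exposed:

- Integration: `deSolve::ode` (lsoda, stiff-capable), relative tolerance
  $10^{-8}$, absolute $10^{-10}$ — the $u^n$ killing term is steep at
  $n = 5$.
- Extinction floor $10^{-9}$ in normalized units, with clamping to zero in
  stored output; this prevents negative overshoot and makes the
  extinct/persists label deterministic.
- Degenerate tissue: when $\sum u_i x_i$ falls below $10^{-12}$ the
  quasi-steady-state signal would diverge; the state is reported as
  collapsed (a typed error from `qss_signal()`/`mean_distortion()`, frozen
  derivatives inside the integrator, an explicit `degenerate` label for the
  origin in phase portraits).
- Fixed points: Newton/Broyden root-finding (`pracma::fsolve`) from a
  $5\times5$ log-spaced lattice over $[10^{-3}, 3]^2$ plus the analytic
  single-clone points $x = \hat p/(1+\gamma)$; roots deduplicated within
  $10^{-6}$ and classified by the eigenvalues of a numerically
  differentiated Jacobian (margin $10^{-8}$).
- Default $\hat p = 1 + \gamma$, which places the wild-type steady state at
  $x^* = 1$; $\hat p$ remains a free parameter. Distortions are validated
  into $(0, 100]$ to catch configuration typos; the model itself has no
  upper bound.
- Default scenario horizon 200 turnover times, which the scenario
  trajectories reach steady state well within; tests use 50–400 as
  appropriate to the slowest mode involved.

## Burden arithmetic and the cost proxy

The burden calculators are deliberately bare multiplication —
`divisions × rate` and `× activating sites` — with a separate presentation
field (1 significant figure for counts; risk ratios to the nearest 50 above
100, nearest 5 otherwise) so that quoted "about ten / about 50 / about 250"
style numbers never overwrite the raw values. The per-cell risk comparison
assumes equal cell-mass density across glands, recorded in the output. The
packaged comparison carries both printed endpoints of the corticotroph
fraction (15%–20%), which bracket the raw risk ratio at 267 and 200.

The cost proxy tabulates, per secreted factor, a physiological proxy
variable with its normal and acutely-lethal-low/high levels; long-term
morbidity is deliberately ignored. Fold-margins to each bound are mapped
into secretion space by the factor's direction of action (insulin *lowers*
glucose, so hypersecretion drives the proxy to its low bound), giving
$F_\text{hypo}$ and $F_\text{hyper}$ and the index
$C = \log_{10}(F_\text{hypo}/F_\text{hyper})$. The sign convention is the
one the classification actually uses: $C > 0$ means hypersecretion is the
nearer catastrophe, predicting that surveillance (and hence autoimmune
disease) is favoured. Log base 10 is a free choice; only sign and ordering
of $C$ are used. Stomach pH is handled on the log10 acid-concentration
scale (folds are $10^{|\Delta\text{pH}|}$), since ratios of a log quantity
are meaningless; its hypo-secretion bound uses the highest physiological pH
(7) as a conservative stand-in for an unknown lethal level. Calcium uses
the midpoint 1.2 mM of the normal range and the lower end (2.5 mM) of the
hypercalcemic-crisis range, which reproduces the tabulated folds. Blood
pressure uses systolic values (120/90/180 mmHg).

## TCR matching and the synthetic generator

Public repertoires are sets of CDR3β amino-acid sequences shared by at
least `min_subjects` distinct subjects; within-subject duplicates count
once, sequences are upper-cased and whitespace-stripped, and anything
outside the 20 standard one-letter codes is rejected at ingest with a
warning. Matching is character-exact — no V/J constraint, no edit-distance
neighbours — and no enrichment statistic is computed: the scientific
question is whether autoreactive receptors are present in healthy
repertoires at all, not whether they are over-represented.

The synthetic generator emulates the *structure* of per-subject repertoire
tables: a per-species public pool planted into at least
$\lceil \text{share} \times n_\text{subjects} \rceil$ subjects, a planted
cross-species core, unique private background sequences, and autoreactive
sequences copied verbatim from the pools. Because non-planted sequences are
collision-checked to be unique, recovered public-set sizes, core sizes and
match counts equal the planted counts exactly; the test suite verifies this
over 100 random specifications and against a brute-force pairwise matcher.
Sequences are random strings (length 8–20, optional CASS prefix) — the
generator makes no attempt at VDJ realism, germline convergence, or
realistic sharing distributions, so passing these tests demonstrates the
correctness of the set semantics, not performance on real sequencing data.
Real repertoires also carry abundance information and sequencing error,
both out of scope. The default unit-test scale (8–12 subjects, tens of
sequences each) keeps the suite fast; the acceptance script runs a larger
emulation (28 mice at a 25-of-28 sharing threshold, 60 humans, a
200-sequence pool with a 92-sequence planted core and 30 planted
autoreactive matches among 1000) sized to echo the shape of the real
analysis while remaining a few-second computation. Each generator is a pure
function of its specification and seed; one top-level seed fans out to
per-component substreams so adding a component never perturbs existing
outputs.

## Interfaces

Model parameters travel as flat YAML (`gamma`, `n`, optional `p_hat`,
`clones` as a list of `{u, x0}`); note that YAML 1.1 parses a bare `n` key
as a boolean, which the reader transparently maps back. Results are JSON
with a provenance block (package version, seed, config hash). The
command-line dispatcher `ashm_cli()` returns distinct exit codes for schema
violations (3), integration failures (4) and other errors (1), and writes
no partial outputs on failure. Plots are intentionally not part of the
canonical outputs; all artifacts are numeric CSV/JSON.

## Limitations

- No per-organ mechanistic models: organs enter only as parameter labels
  and physiological-range tables.
- The clone dynamics are deterministic; no birth–death stochasticity, no
  explicit T cell or Treg populations (their effect is the ratiometric
  normalization), and no adaptive-dynamics branching beyond single-mutant
  invasion.
- The cost proxy is an acute-lethality heuristic with no formal link to
  selection coefficients.
- The repertoire pipeline consumes filtered tables; raw-read processing,
  clonotype assembly and database clients are out of scope.
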