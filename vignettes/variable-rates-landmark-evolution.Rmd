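---
title: "Variable-rates evolution of landmark shape data: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-rates evolution of landmark shape data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphorates)
```

# The problem

Comparative morphometrics asks whether different clades — here, crown birds
versus the non-avian dinosaur groups they arose from — evolved a structure
(the skull) at different tempos, and which anatomical regions drove the
differences. The data are dense 3D landmark configurations, one per taxon,
partitioned into anatomical regions; the evolutionary model lives on a
time-calibrated phylogeny. morphorates implements the full chain:

1. **Generalized Procrustes analysis (GPA)** per region (or globally),
   removing position, scale, and orientation.
2. **Phylogenetic PCA** of the aligned coordinates, retaining the axes that
   carry 95% of cumulative variance.
3. A **variable-rates multivariate Brownian-motion (BM) model** over the
   retained scores, fitted by reversible-jump MCMC, giving every branch a
   posterior rate scalar.
4. Summaries: per-clade time-corrected mean scalars with rank-sum tests,
   the single-statistic multivariate rate `sigma_mult` with
   simulation-based significance, per-landmark rate and disparity maps, and
   sampling-artefact diagnostics.

A synthetic-data generator with known ground truth (true branch scalars,
true region rates) makes every stage testable end-to-end.

# Models and assumptions

## Brownian motion on a time tree

Under multivariate BM, the `N x q` trait matrix `Y` (taxa x traits) is
matrix-normal with among-taxon covariance `C` — the matrix of shared
root-to-tip path lengths in Myr — and among-trait covariance `R`:

$$\log L = -\tfrac12\left[q\,\ln|C(r)| + N\,\ln|R| +
  \mathrm{tr}\!\left(R^{-1}(Y-\mathbf{1}\hat a^\top)^\top C(r)^{-1}
  (Y-\mathbf{1}\hat a^\top)\right) + Nq\ln 2\pi\right]$$

with `a-hat` the generalized-least-squares root state, profiled out. The
variable-rates extension multiplies each branch `j`'s length by a scalar
`r_j >= 1` or `< 1`; `C(r)` is the covariance of the rescaled tree. Traits
are treated as correlated: `R` is a free symmetric positive-definite matrix
sampled along with the scalars.

`mn_loglik()` evaluates the dense formula above; the MCMC core evaluates an
algebraically identical pruning (independent-contrasts) form that costs
`O(N q)` per evaluation rather than `O(N^3)`. The two are cross-checked
against each other and against a brute-force Kronecker-product density in
the test suite. Because the trait covariance enters only through
`c' R^{-1} c` terms over contrasts, the sampler whitens the traits once per
`R` update and runs the pruning pass with an identity trait covariance.

Assumptions worth stating: shape evolves as a diffusion (no trends,
no Ornstein–Uhlenbeck pull, no early bursts); rate variation is captured by
branch-wise scalar multipliers; tips are observed without measurement
error; and the tree (topology and dates) is known.

## The reversible-jump sampler

The state is (set of scaled branches, their scalars, `R`). Moves:

* **birth** — add a uniformly chosen unscaled branch, drawing its scalar
  from the prior;
* **death** — drop a uniformly chosen scaled branch (scalar returns to 1);
* **perturb** — multiply a scalar by `exp(eps)`, `eps ~ Normal(0, 0.3^2)`;
* **covariance update** — random-walk on one element of the Cholesky
  factor of `R` (log scale on the diagonal).

Priors: the number of scaled branches is geometric with mean 2% of the
branch count (weakly favouring parsimony in rate shifts); scalar values are
log-Normal(0, 1); the Cholesky factor of `R` has weak normal priors centred
on an independent-contrasts estimate of the trait covariance — an
empirical-Bayes scaling that makes the sampler indifferent to the units of
the PC scores. Because the proposal for a new scalar is its prior, the
birth/death acceptance ratios collapse to the likelihood ratio times the
set-size prior ratio.

A global "background rate" multiplier is kept in the state description but
fixed at 1: with `R` free, a global multiplier is not separately
identifiable (doubling all `r_j` and halving `R` leaves the likelihood
unchanged — an invariance the tests assert). Downstream summaries therefore
only ever interpret scalars relative to each other.

Desk-scale defaults are 200,000 iterations, 10% burn-in, thinning 100.
Replicate runs (3 by default in the pipeline) are compared with the
Gelman–Rubin potential scale reduction factor
`PSRF = sqrt(((n-1)/n W + B/n)/W)` on the log-likelihood and on every
scalar, and the run with the highest mean post-burn-in log-likelihood is
retained (ties to the lowest index). Model comparison against single-rate
BM uses stepping-stone marginal likelihoods (16 rungs, powers spaced as
`(k/K)^{1/0.3}`), reported as `2 (ln ML_1 - ln ML_0)`; the harmonic-mean
estimator was deliberately avoided as unstable.

## Procrustes alignment

GPA centres each configuration, scales it to unit centroid size, and
iteratively rotates it onto the evolving consensus until the consensus
moves less than `1e-13` between iterations (maximum 500). Rotations come
from the SVD orthogonal-Procrustes solution with a determinant correction:
reflections are never allowed, since a mirrored skull is not a homologous
shape. Because the GPA fixed point is only defined up to a joint rotation,
the final configuration is pinned to the consensus' principal axes with a
fixed sign convention; this makes alignment idempotent and independent of
input orientation, which the tests verify to `1e-8`.

Specimens missing any region in the alignment scope are excluded from that
alignment only — each region keeps its maximal sample, which is how
incomplete fossils stay informative for the regions they do preserve.
Missing data are never imputed. Sliding of semilandmarks is out of scope:
inputs are treated as fixed points, as they are after upstream template
projection.

Two alignment scopes matter scientifically: *local* (each region aligned
alone, capturing pure shape) and *global* (several regions aligned jointly,
so that the relative position of, e.g., the jaw joint contributes to the
signal). Both are exposed in the pipeline configuration; restricting a
global alignment to one region does not equal the local alignment of that
region, and that contrast is itself informative.

## Phylogenetic PCA and the 95% rule

The evolutionary covariance `(N-1)^{-1} (X - 1 a')' C^{-1} (X - 1 a')` is
eigen-decomposed about the GLS mean; scores are projections of the centred
data. The retained dimension `q` is the smallest axis count whose
cumulative variance fraction reaches 0.95, with the boundary case counted
in (a cumulative fraction of exactly 0.95 retains that axis). `C` is
inverted via Cholesky; if its condition number exceeds `1e12` — routine
when fossils create near-zero terminal branches — a ridge of
`1e-8 * tr(C)/N` is added with a warning. The scores, not raw coordinates,
feed the MCMC; loadings are kept so rate results can be mapped back to
landmarks.

## Rate summaries

**Clade mean scalars.** For each posterior sample and clade, the mean of
`r_j` over the clade's branches, divided by a time correction — by default
the clade's summed branch lengths, with subtree height as an option (the
two differ only by a per-clade constant, so group rankings agree). Clade
branch sets exclude the stem branch by default, so the branch leading to
crown birds is treated separately from the crown radiation. A third option,
`scaling = "none"`, leaves the mean scalar uncorrected; it exists because
the time correction divides by a *deterministic per-clade constant*, which
places even null-identical groups at different locations — fine for the
descriptive Fig-2-style panels, wrong for a calibrated significance test.
Null-calibration checks therefore compare uncorrected distributions.

**A pseudo-replication caveat.** The rank-sum test compares two clades'
*posterior* distributions from a single analysis. Posterior spread is
uncertainty about one dataset, not replicate sampling noise, so a chance
data-driven difference between clades can be "confirmed" at arbitrarily
small p as chains lengthen. The stringent `p < 0.00005` flag mitigates but
does not remove this. Measured honestly on null simulations, the
cross-clade flag rate at that threshold is a few percent — far above the
nominal level — and this is a property of the protocol, not of the
implementation; the operation itself is exactly calibrated on exchangeable
inputs. Interpret the flags as descriptive strength-of-separation labels,
not as frequentist error rates.

**sigma_mult.** Tips are whitened by `C^{-1/2}` (symmetric eigen square
root, eigenvalue floor `1e-12` of the maximum) about the GLS mean; a
partition's rate is its total squared whitened deviation divided by
(contributing taxa x traits in the partition). Dividing by the trait count
makes rates comparable across partitions of unequal size — required for
per-landmark maps, where every landmark is its own 3-trait partition.
Significance for a group ratio comes from `nsim` draws (999 in reported
analyses) under single-rate BM at the pooled per-trait rate with
independent traits, with the `(count + 1)/(nsim + 1)` correction; the
max/min ratio statistic is scale-invariant, so the estimated pooled rate
cancels and the null is exact for independent traits. Trait correlations
are not preserved in the null draws — with strongly integrated traits the
test should be read as approximate.

**Disparity.** Procrustes variance is the mean squared aligned-frame
distance of a group's specimens to their own mean (the pooled grand mean is
available for the per-landmark maps, where one reference shape is wanted).
Pairwise group differences are tested by shuffling specimen labels;
per-landmark variances sum exactly to the full-configuration variance
before any landmark-count correction.

**Diagnostics.** Two post-hoc artefact checks: a Welch (unequal-variance)
two-sample t test on branch-length distributions between groups — densely
sampled extant clades have systematically shorter branches — and an OLS
regression of log posterior-mean branch rate on branch length, which should
explain essentially nothing if rate heterogeneity is biological rather
than a dating artefact.

# The synthetic-data generator

`sim_spec()` fixes the study conditions; `simulate_tree()` and
`simulate_landmarks()` realise them. The defaults emulate the sampling
design the analysis targets at test scale:

* **Taxa**: 40 extant birds (an ultrametric crown radiation, tips at 0 Ma),
  15 fossil non-avian theropods and 22 fossil non-theropod dinosaurs
  (77 tips). Fossil tip ages are uniform on 66–230 Ma (the Mesozoic range
  of the groups), fossil subtrees are dated with the minimum-branch-length
  method (`mbl = 1` Myr), the bird crown age is 70 Ma, and backbone stems
  are 10 Myr. Theropods are sister to birds.
* **Landmarks**: 96 points on a unit hemisphere (Fibonacci spiral) split
  into 8 contiguous azimuthal regions; a `full_scale` preset gives
  775 landmarks in 16 regions.
* **Evolution**: every coordinate is a BM trait; region `m`'s traits share
  base rate `sigma^2_m` (defaults log-spaced over a 4-fold range around
  `1e-4` shape-units^2/Myr, so that roughly 200 Myr of drift moves
  landmarks by an appreciable but not shape-destroying fraction of the
  template) and correlate within the region with `rho = 0.3` (regions
  behave as integrated modules). Clade rate scalars multiply branch
  variances inside tagged clades.
* **Incompleteness**: each fossil loses each region independently with
  probability 0.15; extant birds are complete.
* **Nuisance transforms**: unless `prealigned = TRUE`, every specimen is
  randomly rotated, translated, and scaled so that GPA is genuinely
  exercised.

What the generator does **not** emulate: mesh surfaces and semilandmark
sliding, retrodeformation error, non-BM dynamics (OU, early bursts),
correlated missingness (real fossils lose *adjacent* regions together),
measurement error, and intraspecific variation. Passing recovery tests on
these simulations therefore shows the estimator chain is correct under its
own model, not that real skulls satisfy that model.

# Numerical choices

* GPA convergence `1e-13` on the consensus; reflections excluded;
  principal-axes orientation pinning.
* `C^{-1}` by Cholesky with conditional ridge `1e-8 tr(C)/N`;
  `C^{-1/2}` by symmetric eigen-decomposition with eigenvalue floor.
* The retained-axis rule counts a cumulative fraction within `1e-12` of
  the cutoff as reaching it, so exact-boundary spectra are stable.
* Ties in replicate-run selection break to the lowest run index;
  degenerate (identical-constant) rank-sum inputs return `p = 1`;
  constant-rate regressions return slope 0, `R^2 = 0`, `p = 1` rather than
  relying on `lm`'s near-singular arithmetic.
* Wilcoxon tests use exact enumeration for small samples and the
  normal approximation with continuity correction for larger ones
  (the `stats::wilcox.test` switching rule at n = 50).
* All randomness flows from user-supplied integer seeds: chain `i` of an
  MCMC uses `seed + i - 1`; the generator is bit-reproducible given
  `sim_spec(seed = )`.

# Problem sizes used by the tests

The test and acceptance suites run the full chain at reduced,
stated scales chosen so the whole suite completes quickly while each
property is still sharply testable: 77 taxa x 96 landmarks for the
end-to-end study (10 replicate runs with 200k-iteration chains, 2 MCMC
replicates per region), 50-tip trees with q = 4 for scalar-recovery
checks (20 seeded simulations), and 300-replicate calibration studies for
the significance machinery. The likelihood, sigma_mult, and dating
contracts are verified against brute-force oracles on trees of 6 or fewer
tips, where exact dense computations are trivial.

# Known limitations

* The variable-rates model shares the non-identifiability of all
  rate-scalar formulations: only relative scalars are meaningful.
* Rank-sum comparisons of posterior distributions are descriptive, not
  calibrated tests (see the pseudo-replication caveat above).
* `sigma_mult` assumes single-rate BM when whitening; applying it to data
  that the variable-rates model fits better (the usual case) compresses
  rate contrasts toward 1, so its group ratios are conservative.
* The MBL dating rule returns the minimal consistent ages; real node ages
  are older with probability approaching 1, which compresses basal
  branches and can inflate their inferred scalars — exactly the artefact
  the branch-length diagnostics are there to flag.
* Absolute rate magnitudes depend on Procrustes units and the time scale;
  only relative comparisons travel across datasets.
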