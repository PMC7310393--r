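---
title: "Estimating across-country genetic correlations with rgacross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating across-country genetic correlations with rgacross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

International beef-cattle evaluations compare estimated breeding values
across countries. Because environments, management and national trait
definitions differ, the "same" trait recorded in two countries is treated
as two correlated traits, and the across-country genetic correlations
$r_g$ decide how much information flows between countries when
international breeding values are computed. Estimating those correlations
is hard for two reasons: genetic links between countries are scarce (they
come almost entirely from bulls with recorded offspring in more than one
country), and the multi-trait estimation problem is computationally
heavy, which in practice forces analysts to work with subsets of the
largest national dataset.

`rgacross` implements the full workflow at package scale: pedigree
handling and the inverse numerator relationship matrix, connectedness
measurement, national data edits and herd-level sub-setting strategies
for the dominant population, the multi-trait maternal-effects animal
model, Monte Carlo EM REML variance-component estimation with Monte Carlo
standard errors, and a synthetic multi-country data generator used to
validate all of it.

## The model

For populations $i = 1, \dots, P$ the record vector of population $i$ is

$$
\mathbf{y}_i = \mathbf{X}_i \mathbf{b}_i + \mathbf{C}_i \mathbf{r}_i +
\mathbf{Z}_i \mathbf{u}_i + \mathbf{W}_i \mathbf{m}_i +
\mathbf{P}_i \mathbf{pe}_i + \mathbf{e}_i ,
$$

with fixed national effects $\mathbf{b}_i$ (always including an overall
mean; by default the contemporary group and sex), an optional extra
random environmental effect $\mathbf{r}_i$ (e.g. a national herd-year
effect), direct genetic effects $\mathbf{u}_i$, maternal genetic effects
$\mathbf{m}_i$ attached to the record's dam, a maternal permanent
environmental effect $\mathbf{pe}_i$ per dam (omitted for populations
whose national model does not fit one), and residuals. The genetic
covariance assumption is

$$
\mathrm{var}\begin{bmatrix}\mathbf{u}_1\\\vdots\\\mathbf{u}_P\\
\mathbf{m}_1\\\vdots\\\mathbf{m}_P\end{bmatrix}
= \mathbf{G}_0 \otimes \mathbf{A},
$$

where $\mathbf{G}_0$ is the $2P \times 2P$ covariance matrix over
(direct, maternal) $\times$ population and $\mathbf{A}$ the numerator
relationship matrix. Permanent environmental and extra random effects
are uncorrelated across countries (each dam, and each record, belongs to
one country), and residual variances are population specific. The
across-country genetic correlations are
$r_{kl} = g_{kl} / \sqrt{g_{kk}\, g_{ll}}$ over the entries of
$\mathbf{G}_0$; they are reported in four blocks: direct-direct,
maternal-maternal, direct-maternal within-country, and direct-maternal
between-country.

## Connectedness measures

Connections between countries are quantified from phenotyped offspring
in the edited data:

* **GS** (genetic similarity) between two units is the proportion of
  their sired offspring that come from common bulls (sires with
  offspring in both units). It ranges from 0 to 1 and is also computed
  at herd level, against each foreign population, and through common
  maternal grand-sires (CMGS).
* **BOD** (balanced offspring distribution) of a sire is
  $1 - \sum_j |n_{ij} - \bar n_i| / (2 \sum_j n_{ij})$ over all $P$
  populations, zeros included; **AN_POP** $= P \cdot$ BOD rescales it to
  "how many populations this sire effectively connects".
* **HM**, the harmonic mean of a sire's progeny sizes in two units,
  summed over common bulls and foreign populations, scores a herd's
  connection strength while penalizing unbalanced progeny groups.

An undefined ratio (no sired offspring on either side) is reported as
missing, never as zero, and herd-level averages ignore missing pairs.

## Data edits and herd sub-setting

`apply_data_edits()` applies the national edits in order: contemporary
groups below the national minimum size, embryo-transfer records (when a
flag column is available), then records beyond three phenotypic standard
deviations of their population-sex cell, with the moments estimated on
the survivors of the first two filters in a single pass. Cells with
fewer than three survivors skip the outlier filter (the standard
deviation is not estimable there).

Four sub-setting strategies reduce the dominant population to a record
target while leaving all other populations whole: random herd groups
ranked on genetic similarity (`subset_random()`), herds ranked on
herd-level GS through common bulls (`subset_by_gs(ancestor = "cb")`) or
through the mean of the CB and CMGS coefficients (`ancestor = "tot"`),
and herds ranked on the harmonic-mean coefficient (`subset_by_hm()`).
Selection accumulates herds in rank order and stops when the cumulative
record count first reaches the target, so the realized size overshoots
by at most one herd; a top-fraction cutoff (e.g. the top 1% of herds) is
available as an alternative stopping rule. Ties are broken by record
count and then herd identifier, and selected herds whose similarity is
below 0.001 are flagged as disconnected. `finalize_subset()` re-prunes
the pedigree to the retained phenotyped animals and all their ancestors,
without a generation limit.

## Monte Carlo EM REML

Each REML round performs two steps. First, BLUP solutions are computed
for the real data by preconditioned conjugate gradient. Second, data are
simulated under the current parameter values over the same design
(fixed effects zero — BLUP solutions of simulated data are invariant to
them, which is asserted by a test), and solved against the same
coefficient matrix. The update for a genetic block entry is

$$
g_{kl} \leftarrow \frac{ \hat{\mathbf{u}}_k' \mathbf{A}^{-1}
\hat{\mathbf{u}}_l + \overline{\left( \mathbf{u}^{*\prime}_k
\mathbf{A}^{-1} \mathbf{u}^*_l - \hat{\mathbf{u}}^{*\prime}_k
\mathbf{A}^{-1} \hat{\mathbf{u}}^*_l \right)} }{q},
$$

where hats are BLUPs, stars simulated replicates, the bar averages over
the round's replicates, and $q$ is the pedigree size. The bracketed
correction is an unbiased Monte Carlo estimate of the prediction-error
trace $\mathrm{tr}(\mathbf{A}^{-1}\mathbf{C}_{kl})$ of exact EM REML;
`em_update_exact()` implements that dense-trace version and the test
suite verifies (i) that the Monte Carlo update matches it in expectation
and (ii) that exact-EM trajectories never decrease a densely evaluated
restricted likelihood. Permanent environmental, extra random and
residual variances update analogously with their level and record
counts. Scalar variances are floored at $10^{-6}$ of the phenotypic
variance so that a single noisy replicate cannot push them negative.

Convergence is monitored by regressing every component on the round
number over the last `slope_window` rounds (default 100) and
standardizing each slope by the component's window mean; the run stops
when the largest absolute standardized slope falls below
`vce_slope_tol` (default $10^{-9}$) or at `max_rounds`. The defaults —
at most 1000 PCG iterations per solve, PCG criterion $10^{-5}$, one
simulated dataset per round — mirror routine international-evaluation
practice, as do informed starting values: production analyses start
from the estimates currently in use, and the validation studies in this
package start from values of the right order of magnitude for the same
reason. With one simulated replicate per round the estimate sequence is
a stochastic process fluctuating around the EM path, so
`run_mcem_reml(report_window = k)` can report the mean of the last $k$
rounds instead of the last round; the default (`1`) reproduces the
plain last-round convention.

Heritabilities are a reporting convention in maternal-effects models:
the composition of the phenotypic-variance denominator (whether the
direct-maternal covariance, the permanent environmental variance and
the extra random variance enter) differs between evaluations, so
`heritabilities()` exposes each term as a flag instead of hard-coding
one formula.

If an intermediate update leaves the genetic matrix non-positive
semi-definite, it is projected back by clipping eigenvalues at
$10^{-8}$ of the largest — a numerical guard inside the iteration only.
Final reported matrices are never bent; their definiteness is checked
and reported by `genetic_correlations()`.

## Standard errors

`approximate_se()` runs one additional round at the final estimates with
`se_n_sim` simulated datasets (default 500) and an effectively unlimited
PCG iteration count. For each replicate it evaluates the complete-data
score at the final estimates; the score is a fixed linear map of the
replicate's conditional-expected sufficient statistics (BLUP quadratic
forms — the shared prediction-error constant cancels), so the empirical
covariance of the scores estimates the expected information matrix of
the restricted likelihood. Its inverse gives the sampling covariance of
the variance components, and the delta method on
$r = g_{kl}/\sqrt{g_{kk} g_{ll}}$ gives correlation standard errors.
The test suite validates the scores against finite-difference gradients
of a dense restricted likelihood (agreement to numerical precision) and
the standard errors against a finite-difference Hessian oracle averaged
over record replicates on a fixed design — averaging is needed because
a single realization's observed information at oracle-feasible sizes is
noisy and can be indefinite.

## The synthetic data generator

`simulation_config()` + `simulate_dataset()` emulate the structure of a
multi-country beef recording scheme: several populations of very
different sizes (the bundled `preset_interbeef_like()` uses eight
populations with record shares 87.1/4.1/2.9/2.8/1.1/1.0/0.7/0.3%, one of
which — the DEU analogue — lacks the maternal permanent environmental
effect, and the published national minimum contemporary-group sizes),
herds whose dams produce one calf per year over a configurable career,
replacement females recruited from the herd's own reared heifers (which
creates maternal grand-sire links), and a shared international sire pool
used with a herd-specific probability drawn around
`international_sire_fraction` (the lever that controls common-bull
counts and genetic similarity). Records are then generated by the
analysis model itself: population mean plus fixed contemporary-group
(herd-by-year) and sex effects plus genetic, permanent environmental
and residual effects, with genetic effects drawn by pedigree recursion
(parent average plus Mendelian sampling with inbreeding-adjusted
variance) under a true $2P \times 2P$ covariance matrix.

Default true parameters are chosen as realistic weaning-weight values on
the kg scale: direct genetic variance 120, maternal 60, maternal
permanent environmental 40, residual 350 (kg²), contemporary-group SD
10 kg, sex effect ±15 kg, direct correlations 0.8 and maternal 0.7
across countries, direct-maternal within-country −0.2. The generator
does **not** emulate selection response over generations, culling,
national pre-adjustment differences of the trait, or heterogeneous
residuals within population-sex cells. Passing the recovery tests on
these data therefore shows that the estimator finds the right optimum
when the model is true; it cannot show robustness to the model
misspecifications present in real national datasets.

## Numerical choices

* **Solver.** The mixed-model equations are solved by conjugate
  gradient with the convergence criterion used by production software:
  the square root of the ratio of squared norms of the solution change
  to the solution. The preconditioner is block-Jacobi over each
  animal's contiguous $2P \times 2P$ genetic block (plain Jacobi
  elsewhere): with across-country correlations near 0.8 the
  within-animal blocks are strongly coupled and plain Jacobi needed
  roughly four times as many iterations in our measurements.
* **Kronecker block.** $\mathbf{G}_0^{-1} \otimes \mathbf{A}^{-1}$ is
  never materialized during iteration; the solver applies it as
  $\mathrm{vec}(\mathbf{G}_0^{-1}\mathbf{X}\mathbf{A}^{-1})$ on the
  reshaped genetic segment, which costs a fraction of the explicit
  product's memory and time. An explicit assembly mode
  (`assemble_mme(explicit = TRUE)`) remains for dense reference
  computations.
* **Identifiability.** Fixed factors use reference-level (treatment)
  constraints, making solutions unique and directly comparable to dense
  reference solves; factors with a single observed level in a
  population are dropped to the intercept.
* **Equation ordering.** Fixed, extra random and permanent
  environmental equations come first, then genetic equations
  animal-major with the $2P$ within-animal block contiguous — the
  layout that makes both the factored Kronecker product and the block
  preconditioner cheap.
* **Reproducibility.** Every source of randomness flows from a single
  seed: per-round and per-replicate seeds are pre-drawn, logged in the
  fit object, and restore the caller's RNG state.

## Validation scale

The bundled validation studies run at desk scale: relationship-matrix
oracles on pedigrees up to 200 animals, exact-EM and solver oracles on
instances of 300-900 equations, standard-error oracles on a
single-population design with about 900 records and highly repeatable
dams, and a ten-replicate parameter-recovery study on three-population
data with about 2,000 records, strong international sire usage (60% of
matings from a shared pool of 30 sires) and 100 REML rounds per
replicate. These sizes were chosen so that the complete validation
suite runs in minutes on a laptop; the estimation code itself is sparse
throughout and has no small-data assumptions.

A caveat the recovery study makes explicit: at a few thousand records
the restricted likelihood is nearly flat in the across-country
correlations — the package's own expected-information computation puts
the sampling error of a direct correlation near 0.3 and of a maternal
correlation above 1 at that scale, consistent with the large standard
errors routinely reported for international beef evaluations even at
hundreds of thousands of records. Point recovery of across-country
correlations to tight tolerances is therefore not achievable at this
data size for any estimator; the recovery study checks estimator
behaviour (movement from the start toward the truth, coverage by the
reported standard errors, positive-definite reported matrices), and the
estimator's correctness rests on the exact-EM, likelihood-ascent and
score oracles above.

## Known limitations

* Unknown-parent groups (genetic groups) are not implemented; unknown
  parents are treated as unrelated founders.
* One record per animal per population; no repeated measures.
* No genomic information; relationship structure is pedigree-based
  only.
* The residual variance is homogeneous within population (no
  population-sex heterogeneity).
* Bending of non-positive-definite matrices is deliberately absent;
  definiteness is reported, not enforced, on final results.
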