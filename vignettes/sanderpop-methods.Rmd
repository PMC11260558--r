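---
title: "Models and methods in sanderpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sanderpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sanderpop` analyses hybridization and population divergence in a
two-species riverine fish system (native sauger, introduced walleye). This
vignette is the package's own account of the models it implements, the
choices made where the underlying procedures were open, and what the
synthetic-data tests do and do not establish.

## Ancestry model

Each individual is summarised by the admixture proportion $q$ (fraction of
its genome derived from walleye) and the interspecific ancestry $Q$ (the
fraction of loci carrying one allele copy from each species). The pair
$(q, Q)$ separates hybrid categories that $q$ alone confounds: an F1 and
an F2 both have $q \approx 0.5$, but the F1 has $Q \approx 1$ and the F2
$Q \approx 0.5$.

The estimator treats the per-locus ancestry state
$z \in \{AA, AB, BB\}$ as latent. Given parental alternate-allele
frequencies $p_A, p_B$ at a locus, genotype likelihoods are Hardy-Weinberg
draws: binomial$(2, p_A)$ under $AA$, binomial$(2, p_B)$ under $BB$, and
under $AB$ one Bernoulli draw from each pool. An EM algorithm maximises
the likelihood over genome-wide state proportions
$(\pi_{AA}, \pi_{AB}, \pi_{BB})$, and
$q = \pi_{BB} + \pi_{AB}/2$, $Q = \pi_{AB}$.

Design choices:

* **Fixed parental frequencies.** Panel frequencies are estimated once
  from the reference individuals (additive smoothing, pseudocount 0.5 per
  allele) and held fixed during the EM, so admixed query individuals
  cannot drift the panels. A hierarchical Bayesian admixture model would
  re-estimate cluster frequencies jointly and propagate genotype
  uncertainty; the EM targets the same $(q, Q)$ estimands with smaller
  machinery, at the cost of ignoring panel-frequency uncertainty. Locus
  bootstrap intervals (`bootstrap_qQ()`) quantify the sampling variance
  that remains.
* **Convergence** when the log-likelihood gain drops below $10^{-8}$ or at
  500 iterations. The log-likelihood is non-decreasing by construction and
  asserted so in the tests.
* **Classification thresholds** follow the field's convention: $q < 0.1$
  and $q > 0.9$ for the parentals, F1 as $0.4 \le q \le 0.6,\ Q > 0.8$,
  F2 as $0.4 \le q \le 0.6,\ 0.4 \le Q \le 0.6$, backcrosses as
  $|Q - 2q| \le 0.1$ (sauger side) and $1.9 \le Q + 2q \le 2.1$ (walleye
  side). The sources that use these rules do not state whether interval
  ends are open; closed intervals are adopted everywhere, with the pure
  cutoffs strict as written. The sub-rules can overlap at region corners;
  they are applied in the fixed order F1, F2, BC, and a hybrid matching
  none of them is reported as `hybrid_unassigned` rather than forced into
  a class.

## Sex-linked locus screen

Reduced-representation data in this system carry a block of
sex-differentiated loci that would masquerade as population structure.
The screen is a discriminant analysis of principal components: PCA of the
mean-imputed, centred genotype matrix; a linear discriminant on the
retained PC scores with sex as the grouping variable; per-locus loadings
as the squared back-projection of the discriminant axis, normalised to sum
to one. Retained PCs default to the smallest number explaining 90% of
variance, capped at a third of the sample size — the usual guard against
overfitting the discriminant; the source analyses do not state their
choice. Loci at or above the 0.99 loading quantile are flagged. A
randomization threshold (default: 95th percentile of the maximum loading
over 100 label permutations, with the PCA computed once and reused) gives
a significance reference; the quantile rule decides removal, and both are
reported, since how the original analyses combined them is not stated.

## Population statistics

* **F_ST** uses the Reich-Patterson unbiased allele-count estimator; per
  locus, with $\hat h = a(n-a)/(n(n-1))$,
  $\hat N = (a_1/n_1 - a_2/n_2)^2 - \hat h_1/n_1 - \hat h_2/n_2$ and
  $\hat D = \hat N + \hat h_1 + \hat h_2$, combined as
  $\sum \hat N / \sum \hat D$. Significance against zero comes from a
  percentile bootstrap over loci (default $B = 1000$; the procedure's
  sources do not state their replicate count).
* **Diversity.** $\theta_W$ and $\pi$ are per-site estimates and therefore
  need a total-site denominator (variant plus invariant); a SNP-only
  matrix cannot supply it, so `total_sites` is a required input rather
  than a silently assumed constant. Observed heterozygosity is computed
  per individual and averaged; expected heterozygosity ($2p(1-p)$
  averaged over variant loci) is reported alongside because the two are
  easily conflated in study reports.
* **Isolation by distance** linearises divergence as $F_{ST}/(1-F_{ST})$
  and tests the association with river distance by a one-sided Mantel
  permutation test, $p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(B + 1)$ with
  999 permutations by default (matching the granularity of p = .001
  reported in this literature); for small systems all $n!$ permutations
  can be enumerated exactly. River distances are shortest paths on an
  edge-list network with sites splitting their edges; this replaces
  GIS-specific tooling with a plain, testable graph computation.

## Divergence-time model

The two-population history is an ancestral population of $N_{ref}$
diploids splitting into isolated daughters of relative sizes
$\nu_1, \nu_2$ with the constraint $\nu_1 + \nu_2 \le 1$ (the daughters
cannot outnumber the ancestor — appropriate when a dam partitions an
existing population), evolving for $T$ units of $2 N_{ref}$ generations;
the nesting model adds asymmetric migration $m_{12}, m_{21}$ (scaled as
$2 N_{ref} m$).

**Expected spectra.** Instead of a diffusion solver, expected joint SFS
come from a discrete Wright-Fisher computation on a frequency grid
(default grid population 100 diploids):

* Ancestral standing variation has density $\theta/x$; its joint founding
  mass onto the two daughter grids is integrated in closed form,
  $C(K_1, j_1) C(K_2, j_2)\,B(j_1 + j_2,\ K_1 + K_2 - j_1 - j_2 + 1)$,
  so the ancestral frequency is never discretised.
* Each daughter frequency then evolves by a binomial transition matrix of
  its grid size for $T \cdot 2N_{ref}$ generations (matrix powers by
  binary exponentiation; the post-split mutation influx, rate
  $\theta\nu_k/2$ per generation entering as grid singletons, accumulates
  through the same recursion). The migration model propagates the full
  joint distribution generation by generation with migration mixing.
* Samples are binomial draws from grid frequencies; folding is applied
  last. The spectrum is made continuous in $(\nu_1, \nu_2, T)$ by linear
  interpolation between the bracketing integer grid sizes and generation
  counts — without this the likelihood surface is piecewise-constant and
  derivative-free optimisers stall on the plateaus.
* The leading $O(1/\text{grid})$ discretisation error (visible mostly in
  singleton cells) can be removed by Richardson extrapolation over two
  grid sizes (`extrapolate = TRUE`); the test suite checks the
  extrapolated backend against an independent stochastic coalescent
  backend (average branch lengths over simulated structured genealogies)
  cell by cell within Monte Carlo error.

**Fitting.** The Poisson composite log-likelihood over unmasked SFS cells
has its scale $\theta$ profiled analytically
($\hat\theta = \sum \text{obs} / \sum M$). COBYLA (derivative-free,
honouring the size constraint) runs from random restarts on
log-transformed size/time parameters; 26 restarts by default, mirroring
replicated-fitting practice, with restarts ending more than 10
log-likelihood units below the best flagged as local optima. Warm starts
can be supplied; fitting the migration model warm-started from the
no-migration optimum guarantees the nested fit is never spuriously
out-optimised. Since each SNP is treated as an independent site, the
composite likelihood is an actual likelihood here, and the
likelihood-ratio test $D = 2(LL_c - LL_s)$ against $\chi^2_2$ at
$\alpha = 0.05$ is approximately calibrated (conservative, because the
migration rates sit on their boundary under the null); the type-I rate is
measured in the acceptance suite over 100 parametric no-migration
replicates. A clearly negative $D$ (beyond a 0.05 numerical tolerance) is
flagged as an optimiser failure rather than silently clamped.

**Real time.** $N_{ref} = \hat\theta/(4\mu L)$ with $L$ the effective
sequence length (total sites scaled by the SNP retention fraction, since
missing-data filtering removes invariant sites in proportion);
$T_{gen} = 2 T N_{ref}$ and years $= 3\,T_{gen}$ (3-year generation time,
typical for sauger). Because no sauger mutation-rate estimate exists, the
scaling is computed for a panel of rates: human $2.5\times10^{-8}$,
cichlid $3.5\times10^{-9}$, Atlantic herring $2\times10^{-9}$, and an
average fish rate $5.97\times10^{-9}$. Parameter uncertainty uses a 1-Mb
block bootstrap of the SFS with refitting (percentile intervals), which
respects linkage within blocks.

## What the synthetic data emulate — and what they do not

The generator produces: two parental gene pools diverged under a
Balding-Nichols model around shared ancestral frequencies (differentiation
parameter $d$, with a tunable fraction of diagnostic loci, default 0.05 —
the study system's true parental frequency divergence is unreported, so
$d$ is chosen for testability, with $d = 0.3$ as the package's standard
test condition); pure, F1, F2 and backcross genotypes with recorded true
$(q, Q)$; missing-completely-at-random genotype masking (the emulated
datasets report only marginal missingness, ~20% per locus); a planted
sex-differentiated block on one chromosome; a coalescent population split
with one conditioned SNP per locus; and a forward stepping-stone river.
Coordinates are synthetic (ten 5-Mb chromosomes by default) so 1-Mb block
bootstrapping is exercisable.

Passing tests on these data show that the estimators recover the
quantities they claim under the stated models. They do not show
robustness to what the generator omits: linkage and linked selection,
locus-specific introgression, genotyping error and allele dropout,
non-random missingness correlated with divergence, reference-panel
contamination, or more than two source populations.

## Problem sizes and numerical settings

The shipped tests use 5,000-locus panels for ancestry recovery (50
replicates), 8,000 loci with an 80-locus planted block for the sex screen,
spectra on 20+20 or 8+8 haplotypes with grid populations 15-100 for the
demographic checks, and 100 parametric replicates for the LRT and F_ST
calibrations — sizes at which every behaviour under test is already
asymptotic while the whole suite stays desk-scale. EM tolerance is
$10^{-8}$; COBYLA uses `xtol_rel` $10^{-7}$ with 120-400 evaluation caps;
Wright-Fisher transition matrices abort if row mass leaks beyond
$10^{-6}$. Degenerate inputs are flagged, not guessed at: monomorphic
F_ST returns NaN, individuals with no informative loci are marked invalid,
and an F_ST of 1 is excluded from isolation-by-distance with a warning.

## Known limitations

* The EM ancestry estimator conditions on called genotypes; with very
  high missingness or extremely similar parental pools its variance grows
  and the backcross regions of the $(q, Q)$ triangle blur first.
* The migration backend propagates the joint grid distribution and is
  deliberately coarse; it is meant for nested-model comparison, not for
  precise migration-rate estimation.
* Individual-missingness removal defaults to 0.8 but is exposed as a
  configuration override (0.7 is a plausible alternative in this
  literature, which is not internally consistent on the value).
* The pipeline's command surface is R functions plus `run_pipeline()`
  with a plain-text config; there is no separate shell executable, as the
  package is meant to be driven from R.
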