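---
title: "Cryptic mtDNA mutations and mitochondrial age: models and methods"
author: "mitocrypt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic mtDNA mutations and mitochondrial age: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocrypt)
```

## The problem

A post-mitotic cell carries hundreds to thousands of mitochondrial DNA
(mtDNA) molecules that are continually replicated and degraded even though
the cell itself never divides. Replication errors seed new mutations, and
random turnover lets a mutation's *heteroplasmy* — the fraction of the
cell's mtDNA molecules that carry it — drift between loss and fixation
(homoplasmy). Mutations born inside a single cell are, with overwhelming
probability, unique to that cell: they are **cryptic**. Pooling reads
across cells (a bulk experiment) dilutes a cryptic mutation by the number
of cells sampled, so cryptic variation is essentially invisible in bulk;
it only becomes measurable when variants are called per cell from
single-cell sequencing.

`mitocrypt` implements the full chain from per-cell base counts to
population-genetic inference:

1. quality control and heteroplasmy calling (`qc_filter()`,
   `call_variants()`),
2. classification into cryptic / shared / common variants
   (`classify_variants()`),
3. construction of the **cryptic site frequency spectrum** (cSFS,
   `build_csfs()`) and its summary statistics,
4. a forward Moran-model simulator of the sub-cellular mtDNA population
   (`simulate_cell()`, `ensemble_csfs()`),
5. a coalescent-based Bayesian fit of a donor's *mitochondrial age* `W`
   and scaled mutation rate `Theta` (`mito_fit()`), with lifetime
   prediction curves (`predict()`).

A synthetic-data generator (`cohort_config()`, `generate_cohort()`,
`render_base_counts()`) provides cohorts with known ground truth so every
stage is testable without any sequencing download.

## Heteroplasmy calling and classification

For a qualified position (strictly more than `min_depth = 200` reads) the
heteroplasmy of base $i$ is its read fraction,

$$h_i = \frac{N_i}{\sum_{j\in\{A,C,G,T\}} N_j},$$

with one row per non-reference base (two mutations at one site are
legitimate and kept as separate rows). Reads are assumed pre-filtered for
base quality and unique alignment to the mitochondrial genome (NUMT
exclusion); those are upstream alignment concerns, which keeps the core
testable on plain base-count tables. Cells are retained when at least
`min_positions = 200` positions qualify and the log10 qualified-position
count lies within `sigma_mult = 3` standard deviations of the cohort
mean — a log-normal outlier rule whose exact band width the calling
literature leaves open; we fix mean ± 3 SD and expose it as a parameter.

Classification applies, in this order:

1. **site exclusion**: variants at sites qualified in fewer than
   `min_cells_per_site = 10` retained cells of the donor are dropped
   (systematically under-covered sites);
2. **common rule**: substitutions occurring (above the 5% cryptic floor)
   in more than `common_donor_count = 3` donors are labelled *common* and
   excluded from statistics — these are overwhelmingly RNA edits or
   shared polymorphisms;
3. **cryptic rule**: a variant is *cryptic* when its (site, alt) occurs
   above the `cryptic_floor = 0.05` in exactly one cell of the donor;
   otherwise it is *shared*;
4. **report floor**: only variants with `h` strictly above
   `report_floor = 0.10` are kept (0.05 is appropriate for sparse,
   low-coverage data). All floor comparisons are strict: a value exactly
   at a floor is excluded.

The ordering site QC → common exclusion → cryptic test → report floor is
a package decision (the interaction is not fully pinned down by the
method descriptions this design follows); it is fixed here and covered by
tests, and "occurrence" for both the cryptic and common rules means a
call above the cryptic floor, so that isolated error reads cannot break a
variant's crypticity.

## The cSFS and its statistics

A donor's cSFS collects the heteroplasmies of all retained cryptic
mutations of all cells and bins them: equal-width bins on
`(floor, homoplasmy_cut)` plus a terminal bin for `h >= homoplasmy_cut`
(default 0.95). The terminal bin extends the classical site frequency
spectrum with a homoplasmic class: homoplasmic mutations can no longer be
lost by drift, so they accumulate without bound while the segregating
part of the spectrum equilibrates. Bin widths are a display/likelihood
choice (20 equal bins by default), not a scientific claim.

Statistics on the cSFS:

* **mutation load** $\mu^{t\%} = \sum_j h_j\,H(h_j - t)$ per cell, with a
  strict threshold (equality contributes nothing) and synonymous
  mutations excluded by default;
* **rank-biserial correlation difference** `rbc_difference()`: over all
  cross pairs, the fraction where the first spectrum's value is strictly
  larger minus the fraction where the second's is, a probability-scale
  effect size in $[-1, 1]$; ties count to neither side. Between an older
  and a younger donor we always orient the comparison older-minus-younger
  and report the signed value;
* **Mann–Whitney U** spectrum shifts through `stats::wilcox.test()`
  (exact for small tie-free samples, normal approximation with tie
  correction otherwise), with Bonferroni adjustment over comparison
  families (`compare_sfs_groups()`);
* **dN/dS-style Fisher test** `dnds_test()`: variants cross-classified by
  pathology class and by heteroplasmy above/below a floor, two-sided
  exact Fisher on the 2×2 table; the non-synonymous/synonymous ratio is
  normalized by opportunity counts from the annotation table's
  substitution universe rather than a codon model — the test is a ratio
  test, not an evolutionary rate model;
* **pseudobulk spectrum** `pseudobulk_spectrum()`: the read-weighted
  pooled heteroplasmy of each variant across retained cells, quantifying
  how much of the single-cell mutational landscape falls below a bulk
  detectability cut (0.5% by default);
* **homoplasmy rate** `homoplasmy_rate()`: per cell, cryptic mutations at
  `h >=` 0.95 divided by the number of qualified positions — normalizing
  by bases observed makes cells with different coverage comparable.

## The Moran model

Within one cell the mtDNA population is a fixed-size Moran process: `N`
molecules; at waiting times $t \sim \mathrm{Exp}(N\ln 2 / t_{1/2})$ one
molecule (uniform) replicates and one molecule (uniform, with
replacement — the same molecule can replicate and then die) is destroyed,
keeping the population at `N`. Each replication adds
$m \sim \mathrm{Binomial}(L, \nu)$ never-seen-before mutations to the
daughter (infinite sites, no back mutation); new mutations are assigned
to the daughter strand only. The population starts mutation-free, so the
spectrum is *out of equilibrium* over a lifetime.

Defaults: `N = 1000` copies, genome length `L = 16569`,
`nu = 4.6e-8` per base per replication (the package's own inference on
synthetic data recovers this value, and it matches literature estimates
of POLG error rates), and `t_half = 0.07` years (~26 days, within the
measured range of mammalian mtDNA turnover). The simulator treats all
four as free parameters; the inference below works in scaled time and
never needs `t_half`.

**Implementation.** Under neutrality, each mutation's copy count is
marginally an unbiased birth–death walk on $\{0,\dots,N\}$: per event it
moves $\pm 1$ each with probability $p(1-p)$, $p = k/N$. The engine
(`src/moran.cpp`) therefore simulates mutations independently with
geometric event-skipping — exact for every marginal quantity (the SFS,
fixation probabilities, threshold crossing) and orders of magnitude
faster than per-molecule bookkeeping. The per-molecule implementation
with full linkage (`simulate_cell_genomes()`) is retained and the test
suite checks the two agree at small `N`, alongside exact small-`N`
Markov-chain enumerations, the $1/N$ fixation probability, the
stationary $1/i$ neutral spectrum, and the neutral molecular clock: the
long-run fixed-mutation flux $\nu L \ln 2 / t_{1/2}$ per year.

**Timescales.** Any ordered pair of lineages coalesces with probability
$2/N^2$ per event, giving a mean pairwise coalescence time of
$N t_{1/2} / (2\ln 2)$ years — proportional to copy number times
half-life — and an expected whole-population fixation time
$T_{\mathrm{fix}} = 2(1 - 1/N)$ pairwise times. `mitocrypt` measures
time in units of $T_{\mathrm{fix}}$: the **mitochondrial age**
$W = \mathrm{age} / T_{\mathrm{fix}}$. The constant is calibrated
empirically by `pair_coalescence_oracle()` rather than assumed; the
analytic value is exposed alongside the simulation estimate and the two
agree within Monte-Carlo error.

## The coalescent expectation and the likelihood

In scaled time the normalized cryptic spectrum is independent of `N`
(the Kingman coalescent describes a broad class of forward models, the
Moran model among them), so expectations are computed once at a modest
reference copy number (`N_ref = 50`) and reused for any donor.
`expected_csfs()` has two backends, which must and do agree:

* `"matrix"` (default): deterministic propagation of the forward
  Kolmogorov equations of the marginal birth–death chain with unit
  mutation influx — an exact expectation, no Monte-Carlo noise;
* `"simulation"`: a seed-fixed forward Moran ensemble, the ground-truth
  oracle.

The reference-`N` computation discretizes heteroplasmy to multiples of
$1/N_{\mathrm{ref}}$ while real cells (thousands of copies) are
quasi-continuous, so both backends map a copy count $i$ to the interval
$((i-\tfrac12)/N, (i+\tfrac12)/N)$ — deterministic spreading in the
matrix backend, uniform dequantization in the ensemble. Without this the
detection floor slices the discrete grid differently at different
reference `N` and the scaled-time invariance degrades visibly; with it,
spectra at `N_ref` 30 and 100 agree to a total-variation distance below
0.01.

The likelihood of a donor's observed cryptic heteroplasmies
($m$ values from $n$ cells, all above the floor) combines

* a multinomial term for the binned spectrum shape, which depends on `W`
  only, and
* a Poisson term for the total count with mean
  $n \cdot L\,\Theta\, c(W)$, linear in $\Theta = N\nu$ (mutations are
  independent under the infinite-sites assumption, so counts are
  Poisson).

This construction is the package's own: the likelihood conditions on
`h > floor` exactly as the calling pipeline does, and any
misspecification is bounded by the backend-equivalence tests against the
forward simulation. The homoplasmic bin sits inside the same multinomial
by default (`homoplasmic = "joint"`); a `"separate"` mode models it as
its own Poisson accumulation term instead, for users who prefer to keep
the unbounded component out of the shape.

## The Bayesian fit

`mito_fit()` evaluates the posterior on a dense grid: the model table's
native `W` grid (step 0.025) crossed with 121 points of
$\log_{10}\Theta$. Priors are uniform on `W` over `[0, 3]` and
log-uniform on `Theta` over `[1e-7, 1e-2]` — weakly informative ranges
chosen to bracket plausible lifetimes and published mutation-rate
estimates by orders of magnitude on each side; both are configurable.
A dense grid was chosen over MCMC because the posterior is
two-dimensional and cheap to evaluate against the cached model table;
it is exactly reproducible, free of convergence diagnostics, and ties in
the posterior maximum are broken toward smaller `W` deterministically.
The object returns the MAP, central 95% credible intervals from the
marginal grid posteriors, seeded posterior samples, and a log-evidence
proxy; `summary()` converts $\Theta$ to a per-base rate via
$\nu = \Theta/N$ under an assumed copy number.

With no data and a deliberately narrow `Theta` prior the likelihood is
flat and the posterior reproduces the prior — checked in the tests as a
Bayes-identity sanity.

`predict()` converts chronological ages to `W` through an assumed
`(N, t_half)` and returns (a) the expected homoplasmic count per cell
with its first and second derivatives — the speed and acceleration of
mitochondrial ageing, computed from a smoothing spline because the
expectation is tabulated on a discrete scaled-time grid and raw finite
differences of the interpolant carry grid-scale noise — and (b) the
fraction of cells expected to carry at least one mutation above each
heteroplasmy threshold, $1 - e^{-\lambda}$ under the Poisson count
model. On human-scale parameters the homoplasmy curve is convex early
and asymptotically linear (the neutral clock), the acceleration has a
single interior peak in mid-life, and the threshold-crossing curves are
sigmoidal — the qualitative signature of multi-timescale mtDNA ageing.

## The synthetic cohort generator

`generate_cohort()` emulates what the calling pipeline sees in a
multi-donor single-cell study:

* **cryptic truth**: each cell's mutations are an independent Moran
  realization of length equal to the donor's age, so true cryptic
  heteroplasmies carry genuine coalescent structure; cryptic sites are
  drawn without replacement within a donor and never collide with
  planted sites;
* **shared variants** (developmental or clonal): drawn once per donor at
  a uniform donor-level frequency and binomially down-sampled into each
  cell — a stand-in, since shared-variant dynamics are not modelled,
  only classified;
* **common variants**: planted across more than three donors when the
  cohort is large enough, to exercise the common rule;
* **rendering**: per-(cell, site) depth is negative-binomial with a
  log-normal site multiplier shared across cells (transcript-coverage
  unevenness), alternate reads are binomial at the true frequency, and
  each read is miscalled with probability `error_rate`, uniformly onto
  the other three bases — the simplest symmetric error model, adequate
  for testing the 5–10% calling floors. Only mutated sites plus a fixed
  background set are rendered; the rest of the genome is unobserved.

What the generator does *not* emulate: alignment artifacts, NUMT
contamination, UMI chemistry, strand bias, non-uniform error spectra, or
cell-type coverage structure. Passing tests on synthetic cohorts
therefore validates the statistical machinery — calling arithmetic,
classification logic, spectrum construction, inference — not robustness
to upstream artifacts, which must be handled at alignment time.

Default cohort shape (eight donors spanning one month to 54 years, some
hundreds of cells each, mean depth 2000, error rate $5\times10^{-4}$)
mirrors a deep full-length scRNA-seq pancreas-style study. All
randomness derives from one master seed.

## Numerical choices and problem sizes

* Floors and thresholds are strict inequalities throughout; homoplasmy
  is operationalized as `h >= 0.95` (configurable).
* The model table uses `N_ref = 50`, `W` step 0.025, and is cached per
  `(N_ref, floor, cut, bins, w_max)`.
* Grid-posterior MAP ties break toward smaller `W`; credible intervals
  interpolate the discrete marginal CDF linearly.
* Empty spectra are explicit, flagged objects (`empty = TRUE`), never
  silent zeros; `W = 0` likewise returns a flagged "no mutations" point
  mass rather than a degenerate histogram.
* Validation experiments run at deliberately modest sizes chosen for
  tight-but-fast Monte-Carlo error: 2×10⁴ fixation trials at `N = 20`,
  1500-cell ensembles for the molecular clock, 10⁴-cell ensembles for
  backend equivalence, 20 synthetic donors of 400–500 cells for
  parameter recovery, and six-donor cohorts of 50 cells for the
  end-to-end pipeline quantities. These sizes reproduce every property
  the package claims; users wanting tighter error bars can raise the
  ensemble sizes linearly in runtime.

## Worked example

```{r example, eval = FALSE}
library(mitocrypt)

# a synthetic donor: 400 cells, mitochondrial age 0.6, Theta = 4.6e-5
h <- simulate_donor(W = 0.6, theta = 4.6e-5, n_cells = 400, seed = 7)
fit <- mito_fit(h, n_cells = 400, seed = 1)
summary(fit, N = 1000)

# lifetime predictions under 1000 copies and a 26-day half-life
pr <- predict(fit, ages = 0:100, thresholds = c(0.6, 0.95, 1.0),
              N = 1000, t_half = 0.07)
subset(pr$fractions, age == 80)
```

## Known limitations

* Selection is not modelled: the cryptic regime is treated as neutral,
  which is the package's scientific premise for mutations that have
  escaped early selective filtering; `dnds_test()` exists precisely to
  check that premise on data.
* Cell division and turnover are out of scope (post-mitotic assumption);
  so are indels, phasing, and copy-number dynamics.
* The fit is per-donor; hierarchical multi-donor pooling is not
  implemented.
* `W` is identified in scaled time only; converting it to years requires
  an external assumption about `N` and `t_half`, exactly as the theory
  dictates.
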