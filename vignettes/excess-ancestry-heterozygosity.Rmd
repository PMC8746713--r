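---
title: "Detecting environment-dependent hybrid incompatibility from excess ancestry heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting environment-dependent hybrid incompatibility from excess ancestry heterozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exhet)
```

## The statistic and why it works

When two diverged populations are crossed, their F2 (and later) hybrids
segregate ancestry at every locus that differed between the founders. If
alleles of opposite ancestry interact poorly at different loci — a
Dobzhansky–Muller incompatibility — then hybrids carrying both ancestries
*heterozygously* retain one working combination at every interacting pair,
whereas hybrids homozygous for opposite ancestries at interacting loci
express the incompatibility. Selection against incompatibilities therefore
leaves a genome-wide fingerprint: survivors are more heterozygous for
ancestry than segregation alone predicts.

The statistic is computed per recombinant individual over its genotyped
diagnostic loci:

- hybrid index $h$: the frequency of side-B ancestry alleles
  ($h = \sum_i d_i / 2L$ for dosages $d_i \in \{0,1,2\}$ over $L$ loci);
- observed ancestry heterozygosity $p_{AB}$: the fraction of loci with
  $d_i = 1$;
- expected heterozygosity $2 p_A p_B = 2h(1-h)$, computed from the
  *individual's own* genome-wide ancestry frequencies, so that drift in
  ancestry proportions (which depresses heterozygosity below 0.5) is not
  mistaken for selection;
- excess ancestry heterozygosity $p_{AB} - 2h(1-h)$.

The same quantities are computed per locus across individuals
(`summarize_loci()`); both views of the matrix answer the same question and
agree in expectation.

The key design is the *environmental contrast*. Intrinsic incompatibilities
act everywhere; ecological (extrinsic) incompatibilities — mismatched trait
combinations that fail against an ecological background — act only where
that background exists. Comparing crosses raised in aquaria with the same
cross types raised in semi-natural ponds isolates the environment-dependent
component: excess heterozygosity elevated in ponds but absent in aquaria
indicates selection on ecological mismatch rather than intrinsic genetics,
heterosis, or genotyping artifacts.

## Marker filtering

Ancestry is only defined where it can be read unambiguously.
`select_diagnostic_markers()` keeps a marker when

1. the side-A and side-B founders share no alleles (unions across all
   same-side founders for multi-founder designs — the strictest reading
   that guarantees polarizability),
2. every genotyped F1 carries exactly one allele from each side (F1s are
   obligate ancestry heterozygotes, so this doubles as a genotyping-quality
   control; the panel reports the F1 validation rate), and
3. the marker is not on the sex chromosome (label `"19"` by default,
   matching the threespine stickleback karyotype), where segregation is
   confounded with sex.

GBS calls at depth $\le$ 20 are treated as missing before the rules are
evaluated (the strict reading of "more than 20x"). After polarization,
individuals with fewer than 20 genotyped loci and loci with fewer than 20
genotyped recombinants are dropped; the two rules are iterated to a fixed
point so the result does not depend on their order. F0 and F1 rows are
controls, not data: they are never counted toward the locus threshold and
never summarized.

The optional small-sample correction multiplies the expected heterozygosity
by $2N/(2N-1)$ ($N$ = loci for individual summaries, individuals for locus
summaries). Uncorrected, $2h(1-h)$ is biased low by $\mathrm{Var}(h) \cdot 2
= 1/(4L)$ under neutrality, so neutral cohorts show a small positive mean
excess (0.0025 at 100 loci); the correction removes exactly this bias. The
default is `correction = "none"`, matching the main analysis convention,
and the bias is immaterial wherever $L \gtrsim 100$ or wherever it cancels
(it is common to both environments, so it never contaminates the contrast).

## The environment model

`fit_environment_model()` fits, by REML,

$$\text{excess}_i = \beta_0 + \beta_E\,\text{pond}_i +
\beta_C\,\text{cross}_i + \beta_{EC}\,(\text{pond} \times \text{cross})_i +
\beta_L\,\text{lake}_i + u_{\text{source}(i)} + \varepsilon_i$$

with a random intercept per data source. Lake of origin is a contrast that
only exists within benthic × limnetic crosses; it enters as a treatment
dummy and is dropped when inestimable. The quantity of interest is the
per-cross pond − lab contrast, a linear combination of fixed effects
reported with Wald $z$ and two-sided $P$ (the scale of inference the study
design calls for; no small-sample denominator-degree correction is
applied). When the random-intercept variance is estimated at the boundary —
common with few data sources — the fit degrades to the fixed-effects model
and says so in `note`; group means come from `emmeans` either way.

Secondary analyses distinguish competing explanations:

- `hybrid_index_deviation_correlation()`: under within-locus heterosis the
  benefit of heterozygosity is background-independent, predicting no
  relation between $|h - 0.5|$ and excess; under between-locus
  incompatibility the benefit dilutes as the genome becomes parent-like,
  predicting a negative Spearman correlation.
  `bootstrap_correlation_difference()` tests whether two such correlations
  differ, resampling individuals within group with the $(k+1)/(B+1)$
  continuity convention so $P$ is never exactly zero.
- `compare_group_means()` covers the inbred-vs-outbred, F2-vs-F3,
  among-study homogeneity, and a-priori phenotype-group comparisons as
  one-way fixed-effects contrasts.
- `within_family_size_regression()` tests for hybrid vigor expressed as
  growth, standardizing standard length within family to remove shared
  family environments.
- `single_marker_resampling()` re-estimates the environment main effect
  with one random marker per chromosome per dataset, checking that the
  conclusion does not hinge on marker density or linkage. With one marker
  per chromosome at most ~20 loci remain, so the ≥20-loci filter is not
  reapplied inside replicates (it would discard every fish); the full-data
  reference is computed on filtered matrices.

## What the generator emulates — and what it does not

`sim_bundle_config()` + `generate_study_bundle()` produce the full
structure the analyses need: multiple datasets per environment, both cross
types, Paxton/Priest lakes, microsatellite / SNP-array / GBS platforms
(lab datasets default to microsatellites and pond datasets to SNP arrays,
the platform split typical of such compilations), F2 and optionally F3
generations, platform-appropriate allele tokens (fragment-size-like
integers vs nucleotides), per-call negative-binomial GBS depth (mean 60,
dispersion 5, putting a realistic minority of calls under the 20x rule),
missingness, and the conservative genotyping-error model.

Deliberate simplifications, and their consequences for what passing tests
can show:

- **No linkage.** Dosages are i.i.d. 1:2:1 per marker. The excess statistic
  and its null expectation are linkage-free, so calibration results
  transfer; but the *variance* of genome-wide summaries in real data, where
  tens of markers share a chromosome, is larger than in simulation.
  Chromosome labels exist so grouped analyses (per-chromosome means,
  single-marker resampling) have groups.
- **Equal family sizes.** Natural F1 mating in ponds produces unequal
  families; the generator uses equal sizes (the family-size distribution is
  not stated for the emulated studies, and none of the statistics weight by
  family).
- **F3s** are bred by random union of one recombination-free gamete per
  marker from two randomly chosen surviving F2 parents — adequate because
  F2 and F3 cohorts are analyzed together and compared only for their
  means.
- **Viability selection** removes individuals, never edits genotypes, with
  survival probability proportional to fitness, scaled so the fittest
  cohort member survives with probability one. Only the survivor
  *composition* matters to every statistic; the scaling choice sets cohort
  sizes without touching composition. Selected cohorts are sampled
  post-mortality: birth batches are simulated until the configured number
  of genotyped fish is reached, as a field study genotypes the fish it
  recaptures.
- **No sequence-level reads, no mutation within pedigrees, no null
  alleles.** The F1-heterozygosity filter exists precisely to catch such
  artifacts in real data; in simulation it is exercised by injected
  genotyping error instead.

## Selection architectures

Three fitness models span the mechanisms that can elevate survivor
heterozygosity (`selection_spec()`):

- `heterozygote_advantage`: $w = (1-s)^{n_{hom}}$ over $k$ designated loci.
  $n_{hom}$ is counted over the designated loci themselves, not capped at
  $k$ globally: a global cap is inert whenever $k$ is small relative to the
  locus count (essentially every F2 carries at least $k$ homozygous loci,
  equalizing all fitnesses), and an inert architecture could never generate
  excess heterozygosity at any $s$.
- `pairwise_dmi`: $w = (1-s)^{n_{pairs}}$ over designated locus pairs
  homozygous for opposite ancestries — the classical two-locus
  incompatibility.
- `fgm_mismatch`: $w = \exp(-s\,\sigma_{scale}\,d_\perp^2)$, polygenic
  selection against perpendicular phenotypic deviation from the
  inter-parent axis under an additive geometric trait model over the loci.

`selection_strength_required()` inverts any of these by bisection: the $s$
at which survivors of a neutral cohort show a target mean excess (0.03 by
default, tolerance 0.002). Common random numbers — the same cohorts and
survival draws across $s$ — make the survivor mean monotone in $s$ so the
bisection is well behaved. Comparing $s^\*$ across architectures makes the
point that the selection strength consistent with a given excess varies by
orders of magnitude with the assumed architecture; notably, the
`fgm_mismatch` response *saturates* with many small-effect loci (the
mismatch axis constrains roughly one linear combination of dosages, so the
attainable excess shrinks like $1/L$), and reaching 3% requires an
architecture of few, larger-effect loci.

The genotyping-error analysis (`genotyping_error_threshold()`) asks the
converse robustness question: how bad would genotyping have to be to fake
the signal? Under the conservative model every error converts a true
homozygote into a called heterozygote — the direction that inflates the
statistic — so the simulated threshold is a lower bound on the error any
benign error model would need. Analytically the mean excess grows as
$e/2 + (1-e)/(4L)$; the simulation scans a grid over $[0, 0.10]$ with 20
replicate 500 × 100 cohorts per rate.

## The geometric model

The `fgm_*` functions reproduce the mechanistic link between
heterozygosity and mismatch. A derived population adapts to a displaced
optimum by an origin–fixation walk: mutations with i.i.d.
$\mathcal{N}(0, \alpha^2)$ trait effects ($\alpha = 0.15$) arise one at a
time in a monomorphic population, each fixing with the diffusion
probability $\pi = (1 - e^{-2Nsp})/(1 - e^{-2Ns})$ at $N = 1000$,
$p = 1/N$, where $s = w_{mut}/w_{wt} - 1$ and
$w = \exp(-\sigma\,\lVert z - o\rVert^2)$ with $\sigma = 10$. The 1,000
proposals of the default configuration suffice for the walk to reach the
optimum ($[1,1]$ for two traits; for ten traits only trait 1 is under
divergent selection). F2 hybrids against the unmutated ancestor then
segregate the fixed loci 0.25/0.5/0.25 with free recombination and strictly
additive phenotypes.

The emergent pattern — verified by the test suite rather than asserted —
is a negative rank correlation between a hybrid's excess heterozygosity
and its mismatch (perpendicular distance from the axis through the two
*realized* parent phenotypes: the walk ends near, not on, the optimum, so
the idealized axis would misstate the geometry). A fully heterozygous
hybrid is the additive midpoint and has mismatch exactly zero; the
implementation computes the distance in residual-vector form because the
Pythagorean form $\sqrt{|u|^2 - \text{proj}^2}$ surrenders that exactness
to floating-point cancellation. For $m > 2$ traits the distance over the
non-selected traits is also reported; the walk's non-selected optimum
components are zero for *all* non-selected traits (indices $2..m$).

Numerical notes: $\pi$ is evaluated in a log-stable form (the naive
expression overflows for strongly deleterious proposals), clamped to
$[0,1]$, and routed to its continuous limit $\pi = p$ when $|2Ns| <
10^{-8}$; fixation of deleterious proposals is possible, as it should be —
the walk asserts only that accepted proposals have systematically higher
$s$ than rejected ones.

## Reproducibility and problem sizes

Every stochastic operation takes a seed, and repeated operations derive
per-index sub-seeds by integer mixing (`mix_seed()`), so a bundle, a walk,
a bootstrap, or a full pipeline run is byte-reproducible from its
configuration. Pipeline outputs are stamped with a hash of the scientific
configuration (excluding the output directory and log level, which must
not change results), so tables from different configurations cannot be
mixed silently.

The test suite works at deliberately modest scales chosen to keep the full
run around a minute while leaving Monte Carlo error well inside the
asserted tolerances: null-calibration sweeps use 100 bundles of 4 × 80
fish on 28 diagnostic loci; the grand-mean check uses one 2,000-fish
dataset on 100 loci; error-threshold cohorts are 500 × 100 with 20
replicates per rate; fixation probabilities are checked against an
independent forward Wright–Fisher oracle (a diploid population of 100,
whose 200 gene copies with per-copy advantage $s/2$ realize the $2Ns$
diffusion scaling) at $10^5$ runs per selection coefficient.

## Limitations

- The contrast identifies environment-*dependent* selection on ancestry
  heterozygosity; it cannot by itself localize incompatibility loci or
  distinguish many-weak from few-strong architectures (the
  selection-strength analysis quantifies exactly this unidentifiability).
- Individual-level excess at few loci carries the $1/(4L)$ neutral bias
  discussed above; analyses of datasets with tens of loci should prefer
  `correction = "small_sample"` or locus-level summaries.
- The mixed model treats individuals as exchangeable within data source;
  family structure inside datasets is not modeled (families are available
  in the summaries for grouping-based checks).
- VCF import handles biallelic SNPs with GT (and optional DP) only —
  multiallelic records are masked, not split.
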