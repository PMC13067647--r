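---
title: "Half-sib recombination maps: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-sib recombination maps: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmapr)
```

## The problem

Artificial-insemination livestock populations consist of large paternal
half-sib families: one sire, many progeny, each progeny from a different
dam. Every progeny genotype carries one sire gamete, so a family of `n`
progeny is a sample of `n` sire meioses. Comparing the transmitted sire
homolog along the chromosome reveals crossovers, and pooling crossover
frequencies over families gives per-interval recombination rates whose
accumulation is a sex-specific genetic map in Morgan units. The same
decoded transmissions yield two parental phenotypes of recombination
activity — the mean autosomal crossover count and the intra-chromosomal
allelic shuffling — which can then be analysed with genomic mixed models
(GBLUP, GWAS) like any other quantitative trait.

`hsmapr` implements this whole chain: a simulator with known truth, three
estimator families for the maps, map quality and comparison tools, the two
recombination traits, and the quantitative-genetic layer.

## The simulator and what it emulates

`sim_half_sib_population()` generates `N` paternal half-sib families of
exactly `n` progeny on a marker map from `sim_physical_map()`.

* **Founders** are in linkage equilibrium: one allele frequency per marker
  drawn from a MAF law (default Uniform(0.05, 0.5)), alleles i.i.d. across
  founders and markers. Real populations carry LD; founder LD mainly helps
  population-scale phasing methods, which are outside the estimators
  compared here, so linkage-equilibrium founders are sufficient for
  validating family-based estimators. This is a deliberate simplification
  relative to a full coalescent or forward simulation.
* **Meiosis** (`sim_meiosis()`) places a crossover in marker interval `j`
  independently with probability equal to the interval's recombination
  rate (no interference), starting from a fair-coin homolog. Map lengths
  are sums of interval rates in Morgan; no Haldane or Kosambi transform is
  applied anywhere, because coordinates are defined as accumulated
  adjacent-marker rates. Rates are capped at 0.5. Chromosome boundaries
  assort independently and are never recorded as crossovers. An
  interference model is intentionally not the default: the validation
  design uses interference-free meiosis so that expected crossover counts
  equal map lengths exactly.
* **Mating**: the first `N` founders are sires; dams are drawn with
  replacement from a pool of the remaining founders (capped at
  `2 N n / 3`), so most dams have few progeny, as in field pedigrees.
* **Missingness** (`mask_genotypes()`) masks genotype entries of parents
  and progeny uniformly at random, or in marker-range blocks to emulate
  chip-design (systematic) missingness. The pre-mask matrix is retained
  separately; truth bookkeeping (crossover intervals, start homologs,
  parental haplotypes) is never masked.

What passing tests on these data do **not** show: behaviour under founder
LD, genotyping error (the simulator has none, so Mendelian checks are
exact), systematic rather than random missingness at scale, or crossover
interference. The desk-scale study design is a single 1 Morgan chromosome
with 1,500 evenly spaced markers (a 50K-panel density on a large bovine
autosome); family-number and family-size grids follow the population
structures relevant to cattle breeding (`N` in 10–500, `n` in 50–1,000).

## The three estimator families

All three are re-implementations of method *families*, not ports of the
reference tools, and all start from the same family-based phasing:

**Windowed deterministic phasing** (`phase_families()`). Sire
heterozygosity is established from opposing-homozygote progeny (or, for
the HMM pipeline, from the sire's own genotype where observed). Homozygous
progeny reveal the transmitted sire allele; consecutive heterozygous loci
are oriented by a majority vote over a sliding window of 30 heterozygous
loci, chaining strand groups into two full-length haplotypes defined up to
a global swap per chromosome. Ties vote "no flip". The deterministic and
likelihood estimators use progeny genotypes only and require families of
at least 30 progeny; both follow the reduction used in practice.

**Deterministic rate estimation** (`deterministic_rates()`). Each
progeny's origin calls at consecutive discriminating markers are compared;
a switch is spread evenly over the marker intervals its gap spans, and
rates are switch mass divided by the number of decoded meioses. The
genome-wide map length therefore equals the mean number of *detected*
switches per meiosis: crossovers whose flanking evidence is lost
(chromosome ends, long gaps) deflate the estimate, which is why this
estimator tends to come out slightly below 1 on accuracy and why random
missingness costs it a little length. A caveat found during validation:
because the window vote pools up to 29 previous loci, this phasing is far
more robust to 50% random missingness than the reference block heuristic,
so the degradation reported for the original tool (tens of percent) shrinks
to well under 5% here. The direction is preserved; the magnitude is not.

**Pairwise two-locus likelihood** (`pairwise_adjacent_rates()`). For each
within-chromosome adjacent marker pair and each family with a sire
heterozygous (and phased) at both markers, progeny two-locus genotype
counts enter a mixture likelihood: the paternal gamete is one of four
haplotypes with probabilities `(1-θ)/2` (parental) or `θ/2` (recombinant),
and the maternal gamete carries one of the four haplotypes with
frequencies that are estimated *jointly* with `θ` by EM. Estimating the
maternal haplotype frequencies rather than plugging in marginal allele
frequencies matters: with a finite dam pool the maternal side carries
incidental two-locus dependence, and a fixed-frequency independence model
pushes that dependence into `θ` (we measured about +11% map length at
`N = 50`, `n = 1000` before making the change). When every progeny's
paternal gamete is directly classifiable the MLE collapses to the
recombinant fraction `k/n`. The estimator needs a lot of data per pair —
with few families or small families the per-pair MLE is wildly variable
and the accumulated map length explodes; this mirrors the reference
method's documented need for `N ≥ 50` and large `n`.

**Transmission HMM with EM rate updates** (`estimate_map(method =
"hmm")`). Each meiosis is a 2-state hidden Markov chain over markers
(which sire homolog is transmitted), with transition probability `r_j`
between adjacent markers and emissions from the progeny genotype given the
transmitted sire allele and the other parent's contribution — the dam's
genotype where available, population allele frequencies otherwise; missing
genotypes emit 1 in both states, and residual conflicts are neutralised
and counted rather than crashing the chain. Forward–backward runs jointly
over all meioses; the EM update of `r_j` is the posterior-expected switch
count divided by the number of meioses, clamped to `[1e-6, 0.5]` (the
floor keeps the chain ergodic), iterated until the largest rate change is
below `1e-4` or 20 iterations. Initial rates are `1e-3` per interval.
Posterior decoding (not Viterbi) defines the path; exact-0.5 ties inherit
the previous state to avoid fabricated switches.

### Confidence filtering (two-run scheme)

After a first full run, each marker gets a confidence score: the
posterior-weighted fraction of its origin calls that do not form an
isolated blip — a run of at most one informative call flanked on both
sides by the other state within a 5-informative-marker window, i.e. an
implied immediate double crossover, the signature of a misplaced or
corrupted marker. Runs touching a chromosome end are consistent (a genuine
terminal crossover looks like that). Markers scoring below 0.986, markers
never informative, and individuals with more than 58 detected crossovers
are removed, and decoding/EM runs once more for the final estimates. The
0.986 and 58 cut-offs are treated as given constants of the workflow; both
are arguments of `estimate_map()`. On clean simulated data the filter
removes (almost) nothing and the second run reproduces the first; a
planted permuted marker is reliably caught and excluded.

### Maternal meioses

Dams in these designs have 1–2 progeny, so dam phase cannot be estimated
from progeny. Female maps are supported through `phase_source = "truth"`
(supplied parental haplotypes, the semi-real design); estimated female
maps from field data would require population-scale phasing, which is out
of scope.

## Map quality and comparison

`map_accuracy()` is the ratio of estimated to true total map length
(`acc = d̂_q / d_q`); `map_mse()` the mean squared coordinate error.
Accuracy is measured against the *designed* map length; with only 500
meioses the realised crossover count fluctuates by ±4–5%, which bounds how
tightly any estimator can sit at 1 in a single repetition.
`map_pca()` (centred, unscaled — all entries share Morgan units) and
`map_hclust()` (average-linkage on Euclidean distances of coordinate
vectors over shared markers; linkage configurable since the convention is
not fixed) compare maps across populations and sexes. Undefined-rate
intervals enter maps as 0 with a warning, biasing accuracy down rather
than leaving it undefined.

## Recombination traits

`parent_traits()` combines, per parent, the mean genome-wide crossover
count over its decoded meioses (`nco`) and intra-chromosomal allelic
shuffling: `r̄ = (1/n_i) Σ_j Σ_k 2 p (1-p) L_k²`, where `p` is the
fraction of chromosome `k`'s physical span transmitted from the parent's
first homolog (segment breakpoints at crossover midpoints, the midpoint
being the centre of the interval between the nearest informative flanking
markers) and `L_k` the chromosome's share of the total physical span.
Physical (bp) proportions are used, consistent with midpoint placement;
`L_k` uses marker spans because assembly lengths are not an input. The
statistic is invariant to homolog labelling (`2p(1-p)` is symmetric) and
bounded by `0.5 Σ L_k²`. Shuffling is z-scored for the mixed-model
analyses, as customary.

## Quantitative-genetic layer

* `build_grm()`: VanRaden method-1 GRM with observed allele frequencies,
  per-marker mean imputation (for the GRM only), monomorphic markers
  excluded. `filter_missingness()` applies the 20%/20%
  individual-then-marker missingness filter first.
* `fit_weighted_gblup()`: `y = 1μ + u + e`, `u ~ N(0, K σ_g²)`,
  `e ~ N(0, D σ_e²)`, `D = diag(1/n_i)`. REML profiles the variance ratio
  on the eigendecomposition of the weight-transformed GRM (a grid plus
  golden-ratio refinement on `log λ`, boundary λ = 0 always evaluated), so
  each fit is one eigendecomposition plus cheap 1-D optimisation.
  Indefinite GRMs get a logged ridge.
* `rlrt_genomic_variance()`: the boundary-corrected restricted LRT with
  the 50:50 mixture of a point mass at zero and χ²₁.
* `fit_bivariate_gblup()`: the cross-sex model with `u ~ N(0, Σ ⊗ G)`
  restricted to observed parents and sex as fixed effect. The restricted
  likelihood is maximised directly over (log σ_s², log σ_d², atanh ρ,
  log σ_e²) with a 100-iteration cap and explicit non-convergence
  reporting. A classical EM on the augmented 2n-dimensional effect was
  considered and rejected: per iteration it needs an O((2n)³) solve plus
  trace terms, which is strictly slower than direct maximisation of a
  4-parameter restricted likelihood at the sample sizes involved, with no
  accuracy benefit.
* `gwas_scan()`: single-SNP generalised least squares with the polygenic
  covariance fixed at the null REML fit (the P3D shortcut), `T = m̂/SE`,
  `P = 2[1-Φ(|T|)]`, Benjamini–Hochberg adjustment, strong/suggestive
  flags at 1e-5/1e-4. Exact per-SNP REML sits behind `per_snp_reml =
  TRUE`; it is not the default because the null-fit approximation is
  standard, calibrated (type-I error checked in the tests) and orders of
  magnitude faster. Individuals missing a SNP's genotype are excluded for
  that SNP; monomorphic SNPs are skipped. `region_variance()` reports
  `σ_x² = Σ 2 f (1-f) m̂²` and `signal_regions()` groups ≥3
  strong/suggestive hits; `annotate_signals()` looks up genes within
  ±500 kb from a user-supplied table.
* `anova_sex_breed()`: weighted least squares with sex × breed fixed
  effects, global F tests, LS-means and Tukey-adjusted pairwise contrasts
  (via `emmeans`).

## Numerical choices and degenerate inputs

Tie-breaks: phasing votes tie to "no flip"; posterior ties inherit the
previous state. Zero-likelihood emissions (Mendelian conflicts surviving
QC) are neutralised and counted. Intervals with no informative meioses get
rate 0 with a warning. The EM floor (`1e-6`), ridge (`1e-8` relative) and
clamps are stated above. `benjamini_hochberg()` delegates to the standard
step-up implementation. Problem sizes in the test-suite and the
reproduction script — a 1 M chromosome with 1,500 markers, `N` up to 50
and `n` up to 1,000, 3–10 repetitions per claim — were chosen as the
smallest sizes at which the reported qualitative contrasts are resolvable
above simulation noise.

## Known limitations

* Founders carry no LD and no genotyping error; QC code paths for
  Mendelian errors are exercised only by constructed fixtures.
* Female maps require supplied parental phase.
* The deterministic estimator's robustness to random missingness is
  *better* than the reference tool it emulates (see above); comparisons of
  absolute degradation magnitudes with published figures should keep that
  in mind.
* The likelihood estimator is reliable only with many large families;
  at `N = 10` its accumulated map length can overshoot severely rather
  than undershoot as published for the reference tool — the instability is
  reproduced, its sign is not guaranteed.
* Binary PLINK, imputation, liftover and multi-generation pedigrees are
  out of scope.
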