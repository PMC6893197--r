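---
title: "Methods: mixed-model modifier screens with modscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model modifier screens with modscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

modscreen implements the statistics of a natural-variation modifier
screen across a panel of inbred, sequenced strains: a quantitative
phenotype measured in every strain is mapped by per-variant linear
mixed models, associated variants are rolled up to genes and gene
sets, and knockdown follow-ups are tested against shared controls.
This vignette is the package's account of those methods: the models
and their assumptions, the parameters that matter, what the synthetic
panel generator does and does not emulate, and the numerical and
design choices behind the implementation.

## The phenotype model

Each strain `i` of the panel is measured on `n_i` individuals (by
design 10–15 females; eye area in pixels in the motivating
application). Strain summaries (`summarize_strains()`) reduce those to
per-strain mean, median and SD; the mean is the mapping phenotype,
because a strain mean is the natural estimate of the strain's genetic
value and the panel design keeps `n_i` roughly constant. A one-way
fixed-effects ANOVA on the individual measurements
(`strain_effect_anova()`) answers the threshold question — does
genetic background move the phenotype at all — before any mapping is
attempted. Cross-model comparisons use Pearson correlation of strain
summaries joined exactly on strain id (`correlate_strain_means()`),
two-sided, with a `statistic` switch between means (the mapping
phenotype) and medians (robust for range-style displays). The package
ships the published per-strain extremes of the two apoptosis models it
was built around (`published_eye_size_extremes()`); the cross-model
ranges derived from them (`eye_size_ranges()`: 8 927 px for the
*reaper* model, 7 293 px for the *p53* model) are recomputed, not
stored.

## The association model

For each variant the phenotype vector of strain means `y` follows

    y = α + x β + u + ε,   u ~ MVN(0, λ τ⁻¹ K),   ε ~ MVN(0, τ⁻¹ I)

where `x` is the genotype vector (0/2 coding: the panel is homozygous,
so an allele substitution changes two copies), `β` the effect in
phenotype units per allele copy, `K` the marker-based centered
relatedness matrix, `λ` the polygenic-to-residual variance ratio and
`τ⁻¹` the residual variance. `K` (`compute_grm()`) is the average over
variants of the outer products of mean-centered genotype columns,
missing calls imputed to the variant mean; it is a Gram matrix, hence
symmetric and positive semidefinite by construction, and monomorphic
variants contribute exactly zero.

Assumptions worth stating: strain means are Gaussian around the
genetic value (reasonable with ≥10 replicates); relatedness acts
through a single variance component with covariance proportional to
`K`; effects are additive per variant with no covariates (the
motivating design measured one sex and established that body size
needs no correction); and residual variances are equal across strains,
which is only approximately true when replicate counts vary between 10
and 15 — the consequences are quantified below.

### Fitting

`fit_lmm_variant()` eigendecomposes `K = U D Uᵀ` once per scan
(cached and shared by `run_gwas()`). Rotating `y`, the intercept and
`x` by `Uᵀ` whitens the covariance to `diag(λ dᵢ + 1)/τ`, so a
candidate `λ` reduces the fit to weighted least squares with weights
`1/(λ dᵢ + 1)` and `τ` profiles out analytically. The profiled
log-likelihood is maximized over `log₁₀ λ ∈ [−5, 5]` with a 21-point
grid followed by Brent refinement (tolerance 1e-6) in the best
bracket; `λ = 0` is always evaluated as a boundary candidate, so the
fit degrades gracefully to ordinary least squares when the polygenic
component is absent (and reproduces OLS exactly when `λ` is fixed at
0). Significance is the Wald statistic `(β̂/se)²` against χ²₁, the
conventional large-panel reference; REML is available behind
`method = "REML"`. No variant-level multiple-testing correction is
applied — panel-scale screens are not powered for genome-wide
significance, and candidates are taken below the conventional
suggestive cutoff `p < 1e-4` for downstream enrichment and functional
follow-up.

Numerical notes: eigenvalues of `K` are clamped at zero when round-off
makes them slightly negative (a matrix more indefinite than
`−1e-8·trace` is rejected); the residual sum of squares is floored at
1e-300 before taking logs; constant genotype vectors are a
degenerate-variant error, and variants that become constant after the
phenotype join are dropped with a warning. Because the profile
likelihood is often nearly flat in `λ`, quantities that are invariant
in exact arithmetic (e.g. under 0↔2 coding flips, or joint line
permutations) agree to roughly four significant digits rather than to
machine precision; the tests encode that expectation.

Calibration, measured by the package's own suite: on null panels of
200 lines × 2000 variants the fraction of `p < 0.05` is ≈ 0.055
(λ_GC ≈ 1.00–1.06). The mild excess over 0.05 traces to per-variant
`λ` optimization and to the heteroskedasticity of strain means with
10–15 replicates, and sits well within the tolerance the acceptance
checks allow. `qq_diagnostics()` reports the full QQ curve and
`λ_GC = median(χ²)/0.4549`, the standard genomic-control summary.

### Variant filters

`filter_variants()` keeps biallelic variants with sample MAF ≥ 0.05
(computed over non-missing calls, boundary inclusive) and missing
fraction ≤ 0.20. The MAF floor matches standard panel practice — below
it, a variant is carried by fewer than ~10 strains and single-variant
tests are uninformative. Heterozygous calls in input VCFs are treated
as missing by default (`het_policy = "missing"`) because residual
heterozygosity in inbred panels is genotyping noise at the strain
level; `het_policy = "error"` makes them fatal.

## Variant-to-gene assignment

A variant belongs to a gene if it lies in the gene body or within 1 kb
of it, boundary inclusive: "±1 kb" is read as a closed interval, so a
variant exactly 1000 bp from a gene span is assigned and one at
1001 bp is not. When several genes are in range the variant goes to
the gene with the highest-priority feature context — exon > UTR >
intron > upstream/downstream — reflecting the prior that coding and
UTR variants are likelier to be functional than intronic or flanking
ones. Two deliberate interpretations: a base inside an annotated UTR
is classified UTR even though UTRs are exonic subregions (so UTR and
coding counts stay disjoint), and upstream/downstream form a single
flank tier because there is no a priori reason to rank promoters over
terminators at this resolution. Ties at equal priority resolve to the
nearer gene body, then to the lexicographically smaller gene id, so
assignment is a pure function of the annotation with no input-order
dependence. Strand decides which flank is "upstream" (the
high-coordinate side on the minus strand). Variants with no gene
within 1 kb are INTERGENIC and excluded from gene-level analyses.
Synonymous/nonsynonymous annotation is out of scope — it needs
transcript and codon models, not intervals.

## Gene-set enrichment

`rank_genes()` scores each gene by `−log₁₀` of the minimum Wald p over
its assigned variants. A minimum is used rather than a mean or a count
because single-variant candidates are real (a gene supported by one
`p = 1e-6` variant should outrank one with ten `p = 0.1` variants);
score ties break lexicographically so ranks are reproducible.
`enrichment_score()` walks the ranked list accumulating
`|score|^w / Σ_hits |score|^w` at member genes and `−1/(N − N_H)` at
non-members; the enrichment score is the running sum's maximum
excursion from zero, signed. Weight `w = 1` (default) is the standard
score-weighted statistic; `w = 0` reduces exactly to the classical
two-sample KS statistic on ranks, which is what the test suite checks
it against (plus an independent implementation from the fgsea
package at `w = 1`).

Significance comes from a gene-label permutation null: `N_H` labels
resampled without replacement per permutation, 1000 permutations by
default, with the add-one convention
`p = (1 + #[ES* ≥ ES]) / (1 + n_perm)` on the same-sign tail so p is
never zero. Gene-label permutation (rather than phenotype permutation)
is the honest null available at this stage of the pipeline — only
summary statistics reach it, and re-running the scan inside the
permutation loop would be prohibitive. NES divides ES by the mean
same-sign permuted ES and is reported but not filtered on.
Benjamini–Hochberg corrects across sets. The reporting filter keeps
sets with ES strictly positive (negative or zero ES means unenriched),
strictly more than 3 member genes (pathways seen through multiple
genes, not one), and adjusted p strictly below 0.05. One arithmetic
consequence worth knowing: with 50 sets and 1000 permutations, the
smallest attainable adjusted p for a top set is 50/1001 ≈ 0.04995, so
the permutation count cannot be reduced below 1000 without emptying
the filtered output.

## Knockdown validation

`dunnett_test()` implements Dunnett's many-to-one design: each
knockdown group against the shared control with pooled-variance t
statistics. The family-wise two-sided adjusted p for comparison `j` is
`P(maxᵢ |Tᵢ| ≥ |t_j|)` under the joint null, where the `Tᵢ` share the
control group and are therefore correlated with
`ρᵢⱼ = λᵢλⱼ, λᵢ = sqrt((1/n₀)/(1/nᵢ + 1/n₀))` — the general unbalanced
form (validation groups realistically run 9–15 animals). The joint
tail is evaluated by seeded Monte Carlo on the multivariate t via its
factor representation (one shared control normal, one shared χ²
denominator), 200 000 draws by default, giving Monte-Carlo error well
under 0.002; the test suite pins the k = 1 case to the pooled t-test
and the balanced k = 3 case to direct numerical integration of the
trivariate t (ρ = 0.5). Tests are two-sided because both directions
are biologically meaningful: a knockdown that shrinks the eye further
enhances degeneration, one that enlarges it suppresses.

## The synthetic panel generator

The generator exists so every downstream stage can be tested against
known ground truth. What it emulates, with the defaults chosen once
for realism at the scale of the motivating screen:

* **Panel structure** — 200 fully homozygous lines (0/2 genotypes,
  never heterozygous), 5000 biallelic variants with ancestral MAF
  uniform on [0.05, 0.5], 2% missing calls.
* **Relatedness** — 20 blocks of ~10 lines; each block draws an
  ancestral allele per variant and lines copy their block's allele,
  except that with probability 0.25 a call is redrawn independently
  from the ancestral frequency. The redraw construction keeps marginal
  allele frequencies unbiased (the mean realized MAF stays within 0.01
  of the ancestral midpoint) while giving within-block genotype
  correlation of (1 − 0.25)² ≈ 0.56, enough to make `K` decidedly
  non-trivial.
* **Phenotypes** — per-line genetic value `g = Σ xβ + u` with
  `u ~ MVN(0, λ τ⁻¹ K_s)`, then 10–15 individuals per line at
  `baseline + g + N(0, replicate_sd²)`. Defaults: baseline 14 000 px
  (inside the published strain range of the motivating screens),
  replicate SD 400 px (the published per-strain SDs are hundreds of
  px), `λ = 1`, `τ⁻¹ = 12 800 px²`. The residual variance default is
  `replicate_sd²` divided by the mean replicate count, so the `τ⁻¹`
  handed to the generator coincides with the residual variance the
  line-mean LMM actually sees and `λ` keeps its meaning as the
  variance ratio.
* **`K_s` rescaling** — the polygenic draw uses `K` rescaled to unit
  mean diagonal. The raw centered GRM of such a panel has mean
  diagonal ≈ 0.73 (it equals the average genotype variance, ~4f(1−f)
  for MAF f), and without the rescaling `λ` would silently shrink by
  that factor; with it, `λ = 1` produces panels whose fitted `λ̂`
  centers on 1 and whose line-mean variance follows
  `τ⁻¹(λ + 1/n̄)`, both of which the suite verifies by Monte Carlo.
* **Causal structure** — 20 causal variants, all within ±1 kb of genes
  of one planted set, effects ±300 px per allele with random signs.
  300 px is a deliberately strong but not absurd modifier effect: it
  gives individual causal variants Wald p around 1e-4–1e-6 at n = 200,
  so single-variant candidate lists are partially recovered and the
  planted set is recovered through enrichment in essentially every
  run.
* **Annotation substrate** — 300 genes on a 3 Mb chromosome, 1–4
  exons each, optional terminal UTRs, with two built-in edge cases
  (a gene pair under 2 kb apart, one intergenic gap over 4 kb) so the
  assignment logic is always exercised at its boundaries.
* **Validation experiments** — `simulate_rnai_experiment()` draws one
  control and k knockdown groups at configurable shifts, mirroring an
  11–15 animal RNAi follow-up.

What it does **not** emulate: real linkage-disequilibrium decay,
inversions, segregating symbionts, genotyping error structure,
non-Gaussian phenotype tails, shared-environment block effects, or any
image-level noise. Passing tests on these panels therefore demonstrate
the statistics are implemented correctly and calibrated under the
stated model — not that the model captures every property of a real
panel.

Every generator function threads an explicit integer seed (phenotype
simulation offsets it so genotype and phenotype draws never reuse the
same stream), and identical configurations are bit-identical across
runs.

## Problem sizes used by the checks

The packaged checks run at deliberately modest sizes: null calibration
on three panels of 200 × 2000, λ-recovery on 50 panels of 200 × 500
(40 variants fitted each), planted-pathway recovery on twenty
200 × 5000 screens with 1000-permutation GSEA, family-wise error on
2000 simulated null Dunnett families of 3 × 12 animals, and format
round-trips on hundreds of random fixtures. These sizes put every
Monte-Carlo tolerance comfortably above its standard error while
keeping a full run of suite plus acceptance script under a few minutes
on one CPU.

## Known limitations

* Per-variant `λ` maximization makes the scan mildly anticonservative
  (~0.055 at nominal 0.05 with 200 lines); EMMAX-style null-model `λ`
  reuse would trade that for conservatism but is not what the
  motivating analyses ran.
* The Wald χ²₁ reference ignores the small-sample t correction; at
  n = 200 this contributes ≈ 0.0013 of the excess above.
* Gene-label permutation treats gene scores as exchangeable, ignoring
  correlation between physically adjacent genes that share variants;
  with ±1 kb windows on a 300-gene substrate the sharing is small, and
  the measured null p distribution is uniform, but denser gene models
  would need a rotation or circular-shift null.
* The heterozygote policy discards rather than models residual
  heterozygosity; for panels with appreciable heterozygosity a
  dosage model would be more appropriate.
* `read_genotypes()` loads the full matrix into memory — panels of
  ~200 lines by a few million variants fit comfortably, but this is
  not a biobank-scale tool.
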