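---
title: "Post-GWAS inference from summary statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-GWAS inference from summary statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumgwas)
```

# Scope and data model

`sumgwas` implements the inference stages that follow a genome-wide
association meta-analysis of a quantitative trait — the worked context is
fasting proinsulin, an intermediate phenotype for beta-cell function whose
signals help separate type 2 diabetes mechanisms. The unit of data
throughout is a per-variant summary record: marker, chromosome, position,
effect/non-effect allele, effect-allele frequency, beta, SE, p, sample
size, plus study-level QC columns (imputation quality, HWE p, call rate).
All functions take tibbles of such records (or an `ld_panel`, below) and
return tibbles, so stages compose with the pipe.

Individual-level genotypes appear in exactly one role: as LD reference
panels. An `ld_panel` wraps a dosage matrix with variant metadata and
answers allele-frequency, correlation and proxy queries. Real panels can
be wrapped with `as_ld_panel()`; simulated ones come from
`simulate_ld_panel()`.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth without any external download.

**LD panels.** Haplotypes are simulated with a Gaussian copula per block:
a latent AR(1) Gaussian with adjacent-variant correlation `decay` is
thresholded at `qnorm(maf)`; two independent haplotypes sum to a dosage.
Within a block, latent correlation decays exponentially with index
distance; across blocks it is exactly zero in the generating process (and
O(1/sqrt(n)) empirically). The thresholding attenuates genotype
correlation below the latent value, so tests that need a specific
realised r² (proxy grouping, locus merging, HEIDI linkage) either build
dosage columns directly or select variant pairs by their empirical r².
A panel stores its generation spec, and `regenerate_panel()` draws fresh,
independent cohorts from the same population — the sampling model behind
fixed-effects meta-analysis.

**Traits.** `simulate_phenotype()` is the additive model
`y = Σ β_j g_j + covariate effects + N(0, noise_sd²)`. Cohort analysts'
two-step covariate adjustment is reproduced exactly:
residualise on covariates, rank-based inverse-normal transform (Blom
offset `(r − 3/8)/(n + 1/4)`, ties sharing the average rank), residualise
again. The double residualisation removes trait–covariate correlation
reintroduced by the non-linear transform; it matters for type-I error at
low-frequency variants. Note one consequence for simulation design: the
transform standardises the trait, so planted per-allele effects are
attenuated by the total trait SD, and power calculations must use the
standardised effect.

**Summary statistics.** Per-variant OLS of the adjusted residuals on
dosage, vectorised; monomorphic variants are emitted with missing
estimates and a flag. The imputation-quality, HWE and call-rate columns
are drawn independently of the genotypes: they exist to exercise QC
logic, not to model imputation. Population structure is represented by
generic covariates rather than principal components, since the pipeline
only ever consumes residualised traits.

**Annotations.** `simulate_annotations()` scatters background intervals
to a target coverage `c` and then tops up coverage at designated target
variants so they overlap at rate `min(1, fold·c)`; `fold = 1` reduces to
the background. The realised merged background coverage is recorded as an
attribute.

**What the generator does not emulate:** realistic human LD maps,
imputation error, relatedness/mixed-model association, X-chromosome
dosage, cohort-specific assay heterogeneity (cohorts differ only in size
and noise scale). Passing tests therefore demonstrate correctness of the
statistical machinery under its stated assumptions, not robustness to
every artefact of real cohort data.

# Meta-analysis

Per-study QC applies, in a fixed precedence order (MAC, MAF, call rate,
HWE, imputation quality, SE), the thresholds MAC < 3, MAF < 0.005, call
rate < 0.95, HWE p < 1e-5, info < 0.3, SE > 10; the exclusion log records
the first failing rule per variant so audits are deterministic. The SE
rule is strictly "greater than", so SE = 10 survives.

Genomic control uses `λ = median(z²)/0.4549364`; the constant is the
median of the χ²₁ distribution (`qchisq(0.5, 1)`), hard-coded to seven
significant digits for cross-platform reproducibility. Correction only
ever inflates: when λ ≤ 1 the statistics are untouched but λ is still
reported (standard METAL behaviour). The double-GC design applies this
per study and then again to the pooled statistics; the meta-level λ is
computed on the pooled z-scores *after* per-study correction. Two
numerical facts worth knowing: the median-based λ on 10,000 variants has
Monte-Carlo SD ≈ 0.023 (calibration checks therefore average over
replicates), and with small cohorts the t-distributed z-scores inflate λ
slightly (≈ +0.5% at n = 400), which disappears by n ≈ 1,000–2,000.

Inverse-variance pooling is the textbook fixed-effects estimator;
effect-allele frequency is pooled as the sample-size-weighted mean (the
natural "average frequency in the meta-analysis" when no weighting rule
is stated). Allele harmonisation matches records to a reference
orientation allowing strand flips; swapped records flip beta and EAF;
palindromic (A/T, C/G) variants are dropped when MAF > 0.4 and otherwise
read as same-strand, preferring a same-orientation match over a
strand-flip interpretation when both fit.

Loci are defined greedily: significant variants are ranked by p (ties
broken by smaller SE then marker id, making the output independent of row
order), each new lead claims ± 500 kb, and loci whose leads show
r² > 0.4 in the reference panel are merged into one extended region led
by the smallest-p lead. A significant variant within 500 kb of a stronger
lead is a member of that locus, never a lead itself; the merge rule
exists for leads 0.5–1 Mb apart whose windows chain through LD.

Variance explained per variant is `2β²f(1−f)` on the standardised trait
scale; summing over independent leads gives the total. For the published
*STARD10* lead (β = 0.26, EAF = 0.19) this evaluates to 0.0208, i.e.
2.1% after percent rounding — the quantity `scripts/acceptance.R`
recomputes.

# Conditional signals

The approximate joint model is assembled from summary statistics by the
standard normal-equations construction: `X'X` is approximated by panel
dosage covariances scaled by per-variant sample size
(`W_jk = r_jk sqrt(v_j v_k) sqrt((n_j−1)(n_k−1))`), `X'y_j` by
`v_j (n_j−1) b_j`, and the phenotypic variance by the median across
window variants of the per-variant implied value
`v_j((n_j−1)se_j² + b_j²)`. The median is robust to the variants in LD
with strong signals, whose implied variance is inflated by their `b²`
term. When the panel *is* the generating sample these equations reproduce
multiple-regression OLS exactly — the basis of the oracle test — and with
an external panel they degrade gracefully with LD accuracy.

Forward selection seeds with the smallest-p variant, scores every
remaining candidate by its conditional estimate given the selected set
(computed jointly for all candidates via the Schur complement), skips
candidates whose multiple-regression r² on the selected set (a pure LD
quantity from the panel correlation matrix) exceeds 0.8, and stops at
convergence or three signals. The three-signal cap reflects the
instability of summary-statistics conditioning with external panels at
deeply significant loci. Two conditional summaries are reported per
signal: the joint-fit coefficient (`bJ`) and the estimate obtained by
fixing the other signals at their joint estimates (`bC`); for a
single-signal locus the conditional columns are defined as the marginal
ones (conditioning on nothing). Numerical guards: a singular system drops
the most recent candidate and continues; Schur complements below
`1e-10 · W_jj` are treated as collinear.

Signals from different reference panels are then reconciled by a
consensus rule: signals are grouped by the proxy relation (r² > 0.8 in a
designated LD source, by default the first panel supplied), groups
supported by at least two panels are accepted, and the representative is
the member with the smallest conditional p. Finally a MAF-consistency
screen drops signals whose meta-analysis MAF differs from the panel MAF
by more than 0.05 (absolute, config-exposed; the published exemplar is a
0.12-vs-<0.01 discrepancy) in a strict majority of the panels containing
the variant, or that no panel contains at all.

# Fine-mapping

Per-variant evidence is `ln BF = 0.5 z²` — the prior-variance constant of
the Wakefield ABF cancels under normalisation, so this minimal form gives
identical posteriors. Posteriors are normalised in the log domain
(`logsumexp`), making windows with z in the hundreds safe. The 99%
credible set is the smallest prefix of the (posterior-descending,
marker-ascending) ordering reaching 0.99; the deterministic tie-break
means exactly-uniform posteriors over 100 variants yield a set of 99.

For multi-signal loci the scored quantities are conditional estimates
given the locus's other accepted signals, computed from the same normal
equations with the other signals' joint effects fixed. The extended
credible set is the union of the Bayesian set and every panel variant
with r² ≥ 0.8 with the lead inside the ± 500 kb window — the boundary is
treated as inclusive (config-exposed), and the window restriction is a
package choice. Extension members that were never scored (variants absent
from the meta-analysis, e.g. unimputed indels) carry an absent posterior
rather than zero, because zero would misstate evidence that was never
evaluated.

# Colocalization

`coloc_pair()` is the exact five-hypothesis enumeration over per-variant
Wakefield ABFs with priors p1 = p2 = 1e-4, p12 = 1e-5, computed in the
log domain; the test suite holds it to within 1e-10 of a brute-force
O(n²) summation over all variant assignments. The Wakefield prior SD
defaults to 0.15 for quantitative traits (0.2 is conventional for
case-control log-odds; both are config-exposed).

The multi-trait engine makes the single-causal-configuration assumption
per trait and models three families of hypotheses: any subset of traits
associated (each at its own variant), all traits associated at distinct
variants, and all traits sharing one variant (prior
`prior1 · prior2^(m−1)`, defaults 1e-4 and 0.98). Partial sharing —
a proper subset of traits colocalizing while others are associated
elsewhere — is *not* modelled directly; it is reached instead through
divisive clustering: if the full set fails the regional (all associated)
or alignment (shared variant, given association) thresholds, the trait
whose removal most improves the PPFC is peeled off and the remainder
re-evaluated. PPFC is the product of the regional and alignment
statistics. This is a deliberately transparent simplification of the
published multi-trait branch-and-bound machinery; its behaviour is
validated by cross-method concordance with the pairwise engine on
two-trait problems and by truth recovery on planted three-trait scenarios.

Sensitivity scores rerun an engine over a grid and report the passing
fraction: for the pairwise engine, 100 values of p12 log-uniform in
[1e-8, 1e-4] (the scale on which this prior is naturally varied, with the
default 1e-5 inside); for the multi-trait engine, regional and alignment
thresholds 0.6–0.9 crossed with prior2 in {0.98, 0.985, 0.99, 0.995}
(64 runs). The composite decision rule — colocalized iff posterior > 0.6
and (sensitivity > 0.4 or lead-pair r² > 0.8) — is implemented with all
three comparisons strict, and a missing lead-pair r² is treated as 0 with
a message.

Direction-of-effect classification follows a two-tier rule: if T2D or
fasting glucose associates at p < 1e-4, their sign (on the primary
trait's effect allele) is the consensus; otherwise two or more companion
outcomes sharing a sign at p < 0.01 set it; conflicting qualifying signs
yield `unclassified` with a conflict flag.

# Annotation enrichment

For each index variant, the signal (index or any r² > 0.8 proxy) either
overlaps the track or not; matched controls estimate the per-index null
overlap rate. Matching bins are LD-proxy-count {0, 1–4, 5–9, 10–24, ≥25},
MAF deciles, and distance-to-nearest-gene quartiles (bins computed on the
panel pool); controls are drawn without replacement from the index's
cell, excluding the index and its own proxies, and cells smaller than
`n_controls` are relaxed to neighbouring bins with a warning. The default
of 500 controls per index stabilises each rate to about ± 0.02.

The test is exact rather than approximate: observed overlap count
referred to the upper tail of the Poisson-binomial distribution with the
per-index control rates, evaluated by dynamic programming (instances are
tens of leads, so exactness is free and testable against Monte-Carlo).
One honest property of exact discrete tails: with few indexes the
p-value distribution is conservative (its atoms have mass ~1/sd of the
count), so the suite's uniformity checks run at 100 indexes per
replicate, where discreteness is negligible; fold estimates are unbiased
at any scale. When the expected overlap is zero but the observed is not,
the p-value is floored at `1/(n_controls + 1)` and the fold flagged
infinite.

# SMR and HEIDI

SMR uses the top cis-eQTL variant as an instrument:
`b_xy = b_zy/b_zx` is the trait change per unit expression, with
`T = z²_zy z²_zx/(z²_zy + z²_zx)` referred to χ²₁ and the delta-method
standard error. The experiment-wide threshold defaults to 0.0029 (the
published 0.05/17) but is recomputed as `0.05/n_tests` when the number of
tested genes is supplied.

HEIDI asks whether the `b_xy` implied by the cis-SNPs around the top
eQTL are mutually consistent. Eligible SNPs have eQTL χ² ≥ 10
(p < 1.6e-3) and r² with the top SNP in [0.05, 0.9] — avoiding both
near-collinearity and irrelevance — capped at the 20 strongest. The
statistic Σ z_d² (differences from the top SNP's ratio, standardised by
the delta-method covariance assembled from panel LD) is referred to an
eigenvalue-weighted sum of χ²₁ evaluated by Imhof's
characteristic-function inversion, which is effectively exact at m ≤ 20
and is itself tested against Monte-Carlo.

Calibration: on exactly multivariate-normal summary statistics with
known LD the test's type-I error is nominal. In genotype-level
simulations calibration depends on LD accuracy — with a small reference
panel (thousands of samples) relative to the analysed cohorts the test
becomes mildly anticonservative, a known property of HEIDI with external
panels. The package's calibration experiments therefore use a
10,000-sample reference panel (the scale of the large genotype panels
used for conditional analysis) and a well-powered expression study;
users applying HEIDI with small panels should expect some inflation, and
the heterogeneity flag (p < 0.0029 by default) is deliberately far from
the nominal 0.05.

# Pipeline and problem sizes

`run_pipeline()` sequences simulate → QC → per-study GC → meta + post-meta
GC → filters → loci → per-panel conditional selection → consensus → MAF
screen → (conditional) credible sets + LD extension → pairwise
colocalization with sensitivity and decision → direction classification →
annotation enrichment → SMR/HEIDI, and writes TSV/JSON outputs plus a
manifest recording the seed, a configuration hash and every threshold.
Reruns with the same configuration are identical; all randomness derives
from the single configuration seed.

The bundled demo scenario uses 16 cohorts of 600 (total N = 9,600), six
60-variant LD blocks spaced 2.2 Mb apart, two loci (one with two
conditionally distinct causal variants, one shared with a companion
trait), three reference panels of 1,000/900/800, a 420-sample expression
study, and an 8-fold-enriched annotation track. Planted effect sizes
(0.20, 0.13, 0.17) were set from the power formula
`z = β·sqrt(2f(1−f)N)/σ` to give z ≥ 6.3 at the worst-case planted MAF of
0.15 — i.e. > 99.9% power — so recovery failures indicate defects, not
sampling accidents. Test and calibration simulations elsewhere use
windows of 30–100 variants and cohorts of 600–10,000, sizes chosen so the
Monte-Carlo error of each check is small relative to its acceptance band.

# Known limitations

- The LD simulator's post-threshold attenuation means planted latent
  correlations are not realised r²; tests needing exact r² construct it.
- The multi-trait colocalization engine omits partial-sharing
  configurations (reached only via divisive clustering) and, like its
  published counterparts, assumes one causal configuration per trait;
  violations surface through the sensitivity score rather than the point
  posterior.
- Conditional analysis with external panels inherits the usual
  reference-panel sensitivity; the consensus and MAF-consistency screens
  are mitigations, not cures.
- HEIDI is mildly anticonservative when panel LD is noisy (above).
- The enrichment p-value is conservative at small index counts, as any
  exact discrete tail is.
- BMI-adjusted and unadjusted analyses are two configurations of the same
  pipeline (`mode` is recorded in the manifest); the union of their
  significant loci is a reporting step, not a statistical one.
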