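---
title: "Cell-type-resolved RNA editing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved RNA editing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscape)
```

# The measurement model

A-to-I editing is observed as A>G mismatches in stranded RNA-seq. The unit
of data is a pileup row: per position, per sample, the counts of A, C, G
and T among reads covering the position. For a site on the `+` transcript
strand the edited count is the G count; minus-strand sites appear as T>C on
the reference and the counting layer complements. The editing level is the
edited-read fraction, `edited / coverage`, a binomial proportion whose
sampling noise at coverage `c` and rate `p` has standard deviation
`sqrt(p(1-p)/c)` — at the default coverage of 50 and typical rates this is
0.04–0.07, which sets the scale for every downstream power calculation.

A site is *called* in a sample only with coverage ≥ 10 reads, ≥ 3 edited
reads and an editing ratio ≥ 5%. These thresholds are applied per sample;
a site then enters the per-cell-type catalog only if ≥ 8 of the 9 donors of
that cell type call it. Candidate positions are additionally screened, in a
fixed order, against: multi-allelism (two or more alternate alleles each
with ≥ 3 reads and ≥ 1% of pooled coverage — a definition chosen to be
robust to singleton sequencing errors), blacklist and homopolymer
intervals, common genomic variation (SNPs with minor allele frequency
above 0.05), and proximity to splice sites (≤ 5 bp, where mis-mapped
junction reads mimic editing). The cascade is order-faithful: a site
removed by rule *j* is never re-counted under a later rule, so the removal
counts in a `FilterReport` always sum to input minus retained.

Two reading choices deserve note. The coverage/edited thresholds are
applied inclusively (≥ 10, ≥ 3): where the operational description of the
quantification uses "at least", the headline summary elsewhere says
"> 10 / > 3"; the inclusive form is the one the quantification actually
implements. And the 5% ratio is evaluated per sample rather than on pooled
counts, consistent with the per-sample detection rule; a config switch
(`min_ratio` on pooled counts is a one-line change in `call_denovo`) would
express the alternative but the per-sample default is the one tested.

## Zero classes and missingness

For sites detected in exactly one cell type, the other two cell types are
re-queried on pooled counts: `covered-unedited` (coverage ≥ 10, edited < 3
— the cell type measurably does not edit) versus `insufficient-coverage`
(no power to decide). Pooling the samples of the evaluating cell type is a
deliberate simplification: the distinction being made is about the cell
type, not any one library, and pooled counts give it maximal sensitivity.
Remaining missing values inside a cell type's data frame are imputed by the
per-site median of that cell type's observed values, which leaves every
per-site group median unchanged — the invariant the tests assert.

# Global editing indices

The **Alu editing index** is a ratio of sums, not a mean of ratios:
`AEI = Σ G / Σ coverage` over all adenosines in Alu elements, strand-aware.
It is therefore invariant to permuting positions and to uniform coverage
scaling, and is dominated by well-covered positions — which is the point:
it is a global activity measure robust to per-site noise.

**Hyper-editing** defeats ordinary alignment because a read with many of
its adenosines converted no longer matches the reference. The detector
erases the signal by transformation: the plus-strand pass converts A→G in
both reads and genome; the minus-strand pass aligns the reverse-complement
of the read against a T→C genome. Alignment uses exact k-mer seeding
(k = 16, three seed offsets) with ungapped verification at ≤ 5% transformed
mismatches, and must be unique — ambiguous placements are discarded and
counted. This stands in for the BWA-based aligner of the published
hyper-editing pipeline; on the ≤ 10 Mb synthetic genomes this package
targets, the contract that matters (unique transformed alignment) is
identical. After restoring original sequences, a read is hyper-edited if it
carries ≥ 5 A>G sites, A>G accounts for ≥ 60% of its mismatches, and ≤ 90%
of its bases mismatch. We read the middle threshold as a share of
*mismatches*, the quantity the adopted upstream pipeline thresholds on: a
share-of-adenosines reading would reject, by binomial fluctuation, about
half of all reads whose adenosines are edited with probability 0.6 — i.e.
it would make typical hyper-edited reads undetectable by design.

Sites from hyper-edited reads are clustered per strand (gap ≤ 100 bp, ≥ 3
sites), each cluster's span is extended by its mean inter-site distance on
both ends, and overlapping clusters are merged; the merge is idempotent.
The normalized signal is sites per million mapped bases,
`n / MM × 10⁶`. Mapped-base counts are taken from sample metadata, which
the generator provides directly.

Motif profiles around edited adenosines use ±4 bp of sequence context on
the site strand, a pseudocount of 1 per cell, and log2 enrichment against
genome-wide adenosine contexts capped at ±8 so that empty cells yield
finite, plottable values.

# Cell-type statistics

**Differential editing** fits, per site, `editing ~ cell type + age + PMI`
across the 9 + 9 samples of a contrast. Donors recur across cell types, so
observations are not independent. Rather than a per-site mixed model (noisy
at n = 18), one consensus intra-donor correlation is estimated and shared
across sites, and each site is refit by GLS under compound symmetry — the
same statistical target as limma's `duplicateCorrelation`, implemented
directly. The naive estimator (correlating OLS residual pairs) is biased
downward because residuals inherit hat-matrix structure; the package
instead matches the observed mean within-donor residual product to its
expectation under compound symmetry and solves the resulting linear
equation for ρ. On null simulations this estimator centres on 0 (and
recovers ρ = 0.5 when planted), and the resulting p-values pass
Kolmogorov–Smirnov uniformity — the property the acceptance suite asserts.
A fixed-effect donor term (`donor = "fixed"`) is the fallback. The change
in editing is reported as a difference of proportions on the 0–1 scale;
Cohen's *d* uses the degrees-of-freedom-pooled SD; significance is BH FDR
< 0.05 across the sites of the contrast. Sites with zero residual variance
are flagged degenerate with p = 1 instead of erroring: constant sites are
data, not exceptions.

**Specificity labels** partition the catalog. `specific:<ct>` requires
detection in exactly one cell type plus recorded zero-class evidence for
the other two; `enriched:<ct>` requires detection in ≥ 2 cell types and at
least one winning contrast at FDR < 0.05 (any one contrast suffices — the
conservative alternative of requiring both is a stricter filter a caller
can apply on the returned evidence strings); everything else detected in
≥ 2 cell types is `shared`.

**Variance partitioning** treats cell type and donor as random grouping
effects and age, pH, PMI and ADAR1/2/3 expression as fixed covariates in a
per-site mixed model; each covariate contributes the variance of its fitted
term, random effects their variance component, and fractions sum to 1 with
the residual. This scheme shrinks grouping-factor fractions properly under
the null (a sequential-ANOVA decomposition would not: its expected
cell-type share under pure noise equals its degrees-of-freedom share,
~8%), and is invariant to affine rescaling of covariates. The estimator is
validated purely by simulation recovery — the published per-factor
percentages are data-bound quantities this artifact does not claim to
reproduce. A site fit perfectly by one grouping factor (zero residual) is
assigned fraction 1 directly rather than pushed through a singular mixed
fit. The eight factors default to the six named above plus PMI and ADAR3;
both lists are arguments.

**Overlap statistics** come in two forms. Set overlap uses a one-sided
(over-representation) Fisher exact test with the sample odds ratio
`ad/bc`, capped at 10⁶ when a margin is empty. Region overlap uses
permutation: query regions are redrawn uniformly per chromosome with
identical lengths and per-chromosome counts, `p = (1 + #{perm ≥ obs}) /
(n_perm + 1)`, with a z-score from the permutation moments.

# Pseudo-bulk validation

Nuclei are assigned to pools by deterministic marker logic (RBFOX3 × SOX6
splits the neurons; SOX10, GFAP, CLDN5 and a microglia marker classify the
rest; first matching rule wins; marker presence is any nonzero count, with
a configurable minimum). Pool re-quantification is supervised measurement,
so only the coverage threshold (default 10, sweepable 3–20) gates a value —
no edited-read minimum is imposed on a site that is merely being
re-measured. The validation rule is read **relatively**:
`|pool median − FANS median| ≤ 0.5 × FANS median`. The absolute reading
(± 0.5 in level units) is available but not the default, because with
editing levels mostly below 0.5 it would validate nearly everything. A
FANS median of exactly 0 makes the relative rule degenerate; such sites
validate only at pool median 0 and are flagged rather than silently
decided. The 3′-bias test bins sites into high (top coverage quintile),
medium (quintiles 2–4) and low (bottom quintile) coverage and compares TSS
distances of validated versus non-validated sites with two-sided
Mann–Whitney tests; comparisons with < 2 sites in a group are skipped with
a note.

# Bulk deconvolution and edQTLs

Counts are filtered to genes with ≥ 1 CPM in ≥ 50% of samples (inclusive)
and log2(CPM + 1)-transformed. NNLS solves `min ‖S f − b‖, f ≥ 0` per
sample over the genes shared with the signature (≥ 10 required), via the
standard active-set solver (`pracma::lsqnonneg`); excitatory and inhibitory
estimates are summed into one neuronal fraction before normalizing to 1.
Detection saturation retains sites detected in ≥ t·n samples over a
threshold grid; the 90%-vs-10% fold enrichment is a **share ratio**
(category share among sites detected in ≥ 90% of samples over its share
among sites detected in ≥ 10%), with label-permutation significance; a
count-ratio definition is a switch, since the figure being emulated does
not state the algebra.

cis-edQTL mapping regresses editing on genotype dosage plus sex, age, RIN
and death type (unordered categorical, dummy-coded) for every SNP–site
pair within 1 Mb, with BH FDR across all pairs of all chromosomes jointly.
Monomorphic SNPs are skipped and reported. Before mapping, sites detected
in < 50% of donors are dropped and the rest are completed by k-nearest
predictive mean matching (regress the incomplete site on its 5
most-correlated complete sites, then copy the observed value of one of the
k = 5 donors with the nearest predictions); k and the masked-value
validation protocol are artifact choices — the source method is named but
not parameterized. Max-edQTLs take the minimum-p pair per site, with ties
broken by larger |β|, then smaller |distance|, then SNP id.

# The synthetic study design

The generator encodes the generative assumptions the analysis tests, under
the study's own design: 3 cell types × 9 donors, per-site coverage
Poisson(50), uniform base miscalls at ε = 0.001 (the simplest error model
that exercises the 5% ratio filter), editing rates Beta(2, 3) truncated
below at 0.05 (an edited site whose rate is below the ratio filter is not
a detectable site under any method), enrichment differences δ = 0.2,
genotypes at Hardy–Weinberg proportions with MAF in [0.05, 0.5], additive
effects β = 0.08 clipped to [0, 1], pseudo-bulk coverage scaling linearly
with pool size and decaying toward the TSS as `exp(−bias · d)` with `d`
the fractional distance from the 3′ end.

Ground-truth sites are placed at "clean" adenosines — outside blacklist
and homopolymer intervals, > 5 bp from splice sites, off common SNPs —
because the truth models genuine editing, which the filter cascade is
designed to *retain*; recovery rates are meaningful only under that
convention. Hyper-edited reads are drawn from non-overlapping windows so
that planted clusters remain individually recoverable.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: alignment and mapping artifacts
(reads are never actually aligned), position- and cycle-dependent
sequencing error, overdispersion of editing levels beyond binomial
sampling, linkage disequilibrium between SNPs, doublets and ambient RNA in
single-nucleus data, and the empirical distribution of editing levels per
class (the Beta defaults are configurable, not claims about the data).

# Numerical choices and problem sizes

All coordinates are 1-based closed (pileup/VCF convention); BED I/O
converts at the boundary. Each simulation function takes a seed and is
byte-reproducible; the acceptance script derives independent sub-seeds
from one master seed. The test suite and `scripts/acceptance.R` run on
desk-scale problems chosen to make the statistical assertions sharp but
cheap: 200 kb–600 kb genomes, 300–1,000 sites, 9 donors per cell type, 150
donors for edQTL recovery, 5,000 independent null pairs for type-I
calibration, 1,000 label permutations, 200 repeated runs for p-value
uniformity checks. Tolerances follow the statistic: exact identities are
asserted to machine precision or 10⁻⁸–10⁻¹⁰ (NNLS, normal equations),
stochastic recoveries to 3 standard errors of their sampling distribution,
and calibration fractions to 2 binomial standard errors.

# Known limitations

The transformed aligner is exact-seed and ungapped: it is adequate for the
synthetic genomes it targets, not a replacement for BWA on a human genome
with repeats at scale. The compound-symmetry GLS shares one correlation
across sites; strongly site-specific donor effects are only approximated.
Variance partitioning at n = 27 has limited resolution for small
components. The permutation overlap test's p-values are discrete with
granularity 1/(n_perm + 1) and conservative under heavy ties. PMM
imputation assumes the missing mechanism is ignorable given correlated
sites; informative missingness (e.g. coverage-driven) is exactly what the
detection-fraction filter is there to limit.
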