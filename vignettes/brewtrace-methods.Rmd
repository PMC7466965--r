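---
title: "brewtrace: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brewtrace: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

brewtrace characterizes a polyploid yeast isolate against a reference
genome: ploidy, relatedness to known strains, the age of its split from its
closest relatives, copy-number and structural variation, and a growth-rate
phenotype. This vignette is the package's own account of the underlying
models: what is assumed, which knobs matter, what the synthetic-data
generators do and do not emulate, and where the procedures have known
limits. Every empirical statement here is computed by the package's test
suite or acceptance script; nothing is quoted from elsewhere.

## Coordinates and containers

All interval arithmetic is 0-based half-open. VCF (1-based) is converted at
the boundary; BED and bedGraph already match the internal convention and
pass through untouched. Genotypes live in a `VariantTable`: a sites ×
strains matrix of canonical sorted allele-index strings (`"0/0/1/1"`), a
fixed per-strain ploidy inferred from genotype arity (mixed arity within a
strain is an error naming strain and site), per-site annotations (`QD`,
`MQ`, rank-sum statistics, a `SYN` synonymous flag), and per-genotype
quality/depth. Indels and multiallelic sites are retained but flagged;
every population-genetic statistic excludes them.

Haplotype projection (`project_genotypes`) assigns unphased alleles to
haplotype copies in sorted order. This is a convention, not an inference:
every downstream statistic in the package is allele-count based, so phase
is irrelevant; the projection exists to emit per-haplotype FASTA for
external alignment-based tools. Missing or masked genotypes project as `N`.

## Ploidy inference

DNA content: a Gaussian kernel density (Silverman's rule-of-thumb
bandwidth; the original bandwidth is not recoverable, so the R default is
the documented choice) over per-cell fluorescence; the two highest local
maxima are the G1 and G2 populations, G1 being the lower (G2 cells carry
twice the DNA). Local maxima below 1% of the density maximum are ignored —
kernel tails produce numeric wiggles that are not peaks. Ploidy is the
ratio of sample to haploid-control G1 peaks, rounded.

Allele-frequency spectrum: alternate-allele read fractions of heterozygous
sites are histogrammed in bins of width 0.05 *centered on grid multiples*,
so a peak at 0.25 falls in the middle of a bin rather than on an edge
(edge-aligned bins would split a binomial peak at depth 75 between two
bins and shift the reported mode by half a bin). Modes are local maxima
above 50% of the global maximum — the 50% floor stands in for the visual
judgement one applies to such histograms, and 0.05 matches their plotted
resolution. The inferred ploidy is the smallest integer `p` whose expected
dosage fractions `i/p` cover all modes to within half a bin; a tetraploid's
1-, 2- and 3-dose sites put modes at 0.25, 0.50, 0.75.

## Relatedness

Dosages are rescaled per strain to `[0, 2]` (dosage over half the ploidy)
so identity-by-state, `mean(1 − |x_i − x_j|/2)`, is comparable between
diploids and tetraploids. The KING method-of-moments kinship is a diploid
estimator; polyploid genotypes are collapsed to hom-ref / het / hom-alt
(any mixed genotype is het), mirroring how such estimators are applied to
these data in practice. Self-kinship is exactly 0.5; a pair with no
heterozygous sites is undefined and reported `NA`. Trees are classical
neighbor joining on `1 − IBS` (branch lengths may be negative and are not
clamped); PCA operates on mean-centred dosage fractions scaled by
`sqrt(p(1−p))` with missing genotypes mean-imputed and monomorphic sites
dropped.

Diversity statistics let every strain contribute all `p` alleles. Within a
strain, heterozygosity counts unordered allele pairs (`d(p−d)/C(p,2)` per
site); between strains, `d_xy` counts the `p_i p_j` cross pairs. The two
conventions differ by the factor `p/(p−1)` in the limit of identical
strains — two identical tetraploids have `d_xy = 2f(1−f)` per site but
heterozygosity `2f(1−f)·p/(p−1)` — a finite-ploidy subtlety the tests pin
down exactly.

## Divergence dating from shared synonymous variants

The estimator assumes a clock-like tree: focal strain and close relative
split `T_split` generations ago; their lineage and the reference lineage
descend from a common ancestor `T_out` generations back. Variants private
to one strain (present as ≥1 alternate allele in it, absent in the other)
arose on that strain's private branch. Averaging the two private counts
and dividing by the synonymous site total `S` estimates the per-site
length of one private branch; dividing by half the pairwise
focal-reference synonymous divergence `d_pair` — one lineage's share under
a clock — gives the branch fraction `f`, clamped to `[0, 1]`:

```
f = (mean(c_focal, c_rel) / S) / (d_pair / 2)
T_out = d_pair / (2 mu),   T_split = f * T_out
```

`T = d/(2mu)` (not `d/mu`) because both lineages accrue mutations; this is
a stated choice where either reading of "divergence time" exists. Presence
of a variant is "≥1 alternate allele" because variant tables record
presence calls, not dosage-resolved derived-allele counts. Years follow
from the 150–2920 generations-per-year band for domesticated yeast, with
the fast bound floored and the slow bound rounded — with these conventions
18,894 generations maps to 6 and 126 years, which the acceptance suite
checks as exact arithmetic.

The inverse model (`simulate_population`) places Poisson mutation counts on
three branches. The private branches have length `T_split` each. The
"shared" branch — variants carried by both strains but not the reference —
is the full path from the split node down to the common ancestor and up
the reference lineage, `2·T_out − T_split`: mutations on the reference's
own lineage are equally "shared variants" from the table's point of view.
With this bookkeeping the expected pairwise divergence is `2·mu·T_out` per
site and the estimator recovers `f = T_split/T_out` without bias, which
the acceptance suite verifies to within 10% over 20 seeds at expected
branch counts ≥ 200. Shared ancestral heterozygosity (the dominant signal
between closely related beer strains) is injected at rate `theta_anc` as
half-dosage genotypes in both strains; it cancels from the private counts
but *does* inflate `d_pair` (as it would in real data), so the recovery
test states a `theta_anc = 0` world. Default parameters describe the
estimated real-data scale: `mu = 1.67e-10`, `T_out = 1.4e7` generations,
`T_split/T_out = 0.0024`, `theta_anc = 0.002` per site (heterozygosity of
the order seen in beer strains), tetraploid.

## Copy-number variants

Coverage is median-normalized in 250 bp windows (1.0 = baseline ploidy,
supplied externally). Strains with a chromosome-end coverage artifact are
removed first: regressing `log2` coverage (clamped to `[−2, 2]`; zero
coverage floors at −2) on the normalized distance from the chromosome
midpoint, pooled across chromosomes, and dropping strains with slope
outside ±0.15 (strictly outside — a fitted slope of exactly ±0.15 keeps
the strain, with 1e-9 numeric slack).

Segmentation classifies each window to `round(value × ploidy)` clipped to
`[0, 2·ploidy]`, after a 3-window running median. The smoothing is the one
place the implementation adds to the stated rule, and deliberately so: at
baseline ploidy 4 a one-copy gain moves coverage by only 25%, and with
log2 noise of 0.1 raw per-window rounding is only ~85% concordant — below
the >90% run rule, which would shatter every tetraploid gain. The median
restores ~97% concordance and cannot move a boundary by more than one
window; the significance test below still uses raw values. Candidate
segments are maximal merged runs of one non-baseline class with >90%
window concordance, at least 10 kb (40 windows); isolated single-window
strays at segment edges are trimmed so noise does not stretch boundaries.
Each candidate's member windows are compared to all of the strain's
baseline-classified windows with a two-sided Wilcoxon rank-sum test
(p < 0.05); with fewer than 100 baseline windows the segment is flagged
untested rather than silently kept or dropped. The comparison set and
sidedness are package choices where the published description names only
the test.

Group CNV frequencies control clonal redundancy by resampling: 20 rounds
of random-order greedy selection keeping pairwise kinship < 0.18, each
round force-adding one member to any group left empty; a selected strain
carries a reference CNV when a same-type segment covers ≥ 75% of it. The
acceptance suite verifies ≥95% recovery of injected ≥15 kb events with
exact copy number and ≤1-window boundary error at noise 0.1, slope
recovery bias < 0.01, and zero false calls on 20 event-free genomes.

## Structural-variant proximity

Call sets are filtered at support ≥ 15% of depth (a call exactly at the
threshold survives, matching the strict "lower than" removal rule). The
proximity statistic is, for each call, the distance to the closest
same-class call in the mate set on the same chromosome; a call with no
same-chromosome mate scores its chromosome's length — a documented
sentinel that keeps distribution sizes comparable instead of silently
shrinking them. The statistic is asymmetric in its arguments; symmetry
holds for 1:1-matched sets, which is tested.

Distributions are compared to a reference pair with one-sided Mann–Whitney
U tests (normal approximation, tie correction; a `two.sided` switch
exists), BH-corrected across all pair × class tests; `u_ratio` scales U by
its null expectation `n_x n_ref / 2`. Interspersed duplications and
inversions are excluded by the caller (too few calls to compare).

Calibration deserves care. The reference pair in the motivating design is
*the same strain's call set observed twice* (full vs subsampled depth), so
the procedure's null is "the test pair is as matched as the reference
pair". Under that null — simulated as independent fully-shared pairs with
100 bp positional jitter — distances are essentially independent per call
and the test holds its level (measured ≈ 0.05 over 1000-simulation
blocks, inside the binomial 95% CI, acceptance criterion 5). If instead
both pairs are built from *unrelated* uniform call sets, the test is
mildly anticonservative (measured ≈ 0.07 at α = 0.05, stable across call
counts 30–100 and 2–16 chromosomes): nearest-distance vectors are
positively dependent through the shared mate geometry, inflating the rank
statistic's variance. That is a property of rank tests on
nearest-neighbor distances generally; results on weakly related pairs
should be read as descriptive, which is how the discrimination criterion
uses them (matched vs unrelated pairs separate in ≥18/20 seeded runs).

## Split-read translocation scanning

Informative reads have at least one supplementary alignment, no secondary
alignment, and segments on exactly two chromosomes. Each read contributes
one count to the 20 kb bin pair of its two segment midpoints (longest
segment per chromosome). Counts convert to an approximate fraction of
coverage depth via `D = total_read_bases / genome_length` — the natural
depth-at-a-point estimator, stated here because the published description
names the conversion without a formula. Candidates need ≥3 reads and
fraction ≥0.15 (mirroring the SV support filter; both are exposed flags),
survive a control mask built from a collinear dataset, and merge across
adjacent bins.

The power study emulates the repeat problem without an aligner: the read
simulator is an exact-coordinate oracle (error-free reads, exact
truth-derived split mappings — the published error model is irrelevant to
the binning/counting logic under test, a deliberate simplification), and
any alignment segment falling entirely inside a repeat feature that has a
same-strand homologous family copy is demoted to secondary, which removes
its read at selection. Reciprocal translocations cut each breakpoint
interval at its midpoint by default (where within the element the junction
sits is not specified in the motivating design; the midpoint makes both
products full-length chimeras), conserve total genome length, and are
involutions — applying the same translocation twice restores the genome,
which is tested. The stated read world for the power comparison is the
post-length-filter regime: lengths Normal(3000, 2300) truncated to
[8000, 20000] bp at effective depth 10. Mean read length (~9 kb) is then
below twice the 6 kb repeat length, so a junction-spanning read often ends
inside the repeat and is lost; measured power at 20 replicates is 1.0 at
genic breakpoints and ~0.6–0.8 at repeat breakpoints, reproducing the
qualitative published contrast, and collinear genomes yield zero
candidates across 20 seeds.

## Growth rates

The growth rate of a curve is the linear-interpolated 98th percentile of
OLS slopes over all 5-timepoint sliding windows whose signed Pearson r
exceeds 0.8 (zero-variance windows score r = 0 and never pass; declining
windows never pass). Slopes are fitted on raw OD — the original wording
names no transform, and the choice is documented rather than silent. For a
noiseless logistic curve sampled at 15-minute intervals the statistic lands
within 5% of the analytic maximum slope `rK/4`, which the acceptance suite
checks against the closed form.

The percentile definition has an inherent noise sensitivity worth knowing:
with OD noise of sd 0.01, individual window slopes scatter with sd ≈
0.013 OD/h, and the 98th percentile of ~90 such slopes sits ≈ +6% above
the true maximum (an order-statistic bias), pushing roughly a fifth of
curves past a 10% error band. At plate-realistic noise (sd 0.005) recovery
is within 10% in 100% of 50 seeded curves, which is what the test suite
pins; the bias at higher noise is a property of the published statistic,
not of this implementation.

## What the generators do not emulate

Synthetic reads are error-free with exact mappings; there is no
recombination, selection, GC bias, mappability structure, or nanopore
error profile. Coverage noise is log-normal and independent across windows
except for the deliberate end-slope artifact. SV call sets have uniform
positions rather than repeat-associated clustering. A green test therefore
establishes the correctness of the statistics, filters and detection
logic under their stated models — not robustness to every artifact of
real sequencing data.
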