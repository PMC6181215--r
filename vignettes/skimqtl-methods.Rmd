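---
title: "skimqtl: models, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{skimqtl: models, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`skimqtl` analyses biparental recombinant inbred line (RIL) populations
genotyped by low-coverage ("skim") resequencing: sliding-window genotype
calling, bin-map construction, linkage mapping, interval/composite interval
QTL mapping with permutation thresholds, mixed-model GWAS, ANOVA-based
quantitative genetics, and QTL-region haplotype clustering. A
pedigree-explicit simulator provides ground truth for every stage. This
vignette records the statistical models, the parameter defaults and why
they were chosen, the numerical conventions, and what the test suite does
and does not establish.

# The simulator: a stated world

`simulate_ril_genomes()` advances each line independently from the F1 of a
biparental cross through `generation − 1` rounds of selfing (default F8,
i.e. an F7:8 population). Each meiosis draws a crossover count from
Poisson(genetic length in Morgans) with positions uniform on the cM scale
— the count-location model with no interference. Consequences worth being
explicit about:

* pairwise recombination between simulated loci follows **Haldane's** map
  function, while the analysis side uses **Kosambi** (as the motivating
  study did). A Kosambi-consistent multilocus crossover process does not
  exist; the mismatch compresses re-estimated map lengths by a predictable
  10–15%, and the linkage-map tests assert the exact two-locus
  selfing-chain expectation rather than pretending the two scales agree.
* residual heterozygosity at F7:8 is `(1/2)^7 ≈ 0.78%` per locus in
  expectation, verified against the exact 16-state two-locus selfing chain
  in the tests.
* true crossover positions are retained, so breakpoint detection can be
  validated against an oracle rather than against itself.

The skim observation model (`observe_skim()`) is call-level: each SNP in
each line yields a call with probability `observation_rate` (default 0.3,
emulating ~0.3× coverage where nearly every covered site is covered once),
and a call is flipped with probability `error_rate`. The study does not
state a genotyping-error rate; the default 0.5% is a stand-in, exposed in
the model object and varied in the tests. Heterozygous sites emit one
allele at random — a single read cannot reveal heterozygosity.

Phenotypes follow the balanced two-way model the downstream ANOVA assumes:
`y = µ + env_j + Σ a_q x_q + g_i + ge_ij + e_ijk` with `x ∈ {−1, 0, +1}`
(B = wild-parent allele = +1, so a positive additive effect means the wild
allele raises the trait). The default scenario plants, per the motivating
design: a pleiotropic chromosome-20 locus with protein effect +1.2 and oil
effect −0.8 (opposite signs, as in the published protein/oil QTL pair), a
chromosome-8 sucrose locus, minor QTL, and a fully penetrant Mendelian
seed-coat locus on chromosome 8 used as a GWAS positive control. Variance
components were chosen once to give entry-mean heritabilities around
0.85–0.92, typical for seed-composition traits in multi-environment trials;
4 environments × 2 replicates matches the published trial structure. Lines
heterozygous at the Mendelian locus segregate for the binary trait and are
recorded as missing — a line-level binary phenotype does not exist for
them.

Default SNP density is one tenth of the ~91k-SNP design (457 evenly spaced
SNPs per 50-Mb chromosome) to keep test runtimes small; the bin-map
acceptance tests use the full ~10-kb spacing because bin resolution is a
function of density (see below).

# Window calling, breakpoints and bins

The window rule is the published one: 18 consecutive **observed** calls per
window ("18-bp" in the original description is read as 18 calls — a span of 18 base pairs
cannot contain 12 alleles), call `A` or `B` when ≥ 12 calls agree, else
undetermined (`U`); step 1 observed call for maximal resolution; windows
are anchored at their central SNP. `U` rather than heterozygous is
deliberate: at F7:8 true heterozygosity is rare and skim data cannot
distinguish it from noise.

A breakpoint is a transition between consecutive maximal `A` and `B` runs;
intervening `U` windows widen the reported interval, and `A–U–A` emits
nothing. The interval endpoints are window centers — an interval, not a
false-precision midpoint.

**Resolution limit.** A parental segment shorter than 12 observed SNPs can
never produce an informative window, so junctions flanked by such segments
are invisible *to the method itself*, not to this implementation. The
oracle-equivalence acceptance test therefore asserts exact 1–1 containment
for junctions whose flanking homozygous runs have ≥ 12 observed SNPs, plus
the absence of spurious detections, rather than a blanket "all junctions".

**Bins.** Breakpoint intervals from all lines are overlaid on a 100-kb
grid; grid cells touched by any interval are "recombinant", and bin
boundaries are placed at the start of every maximal recombinant run, so one
isolated breakpoint splits a chromosome into exactly two bins (this matches
a brute-force construction that splits at every distinct population
breakpoint interval, which the tests enumerate by hand). Each line's bin
genotype is its **majority** informative window call within the bin. The
alternative — scoring a line `U` in any bin overlapping its own breakpoint
— turns out to be self-defeating: every breakpoint lies in some bin's
recombinant head, so the transitioning line would always be `U` exactly
where its genotype change shows, every adjacent-bin recombination fraction
would estimate to zero, and the linkage map would collapse. The majority
rule assigns the line to the parent covering most of the bin, which is how
the change registers between neighbouring bins.

Bin-map granularity depends on SNP density relative to the window span: at
0.3× observation and 10-kb SNP spacing the undecided band around a clean
junction is ~6 observed SNPs (~200 kb), i.e. one to three grid cells. At
much sparser densities breakpoint intervals span megabases, recombinant
runs merge, and few large bins remain — visible in the reduced-scale
examples and intentional, not a defect.

# Linkage map

Markers start in physical order (the reference genome is known for this
design; de-novo ordering is deliberately not reimplemented). Adjacent-pair
recombination fractions use lines informative for both markers (`U` =
missing); the observed difference fraction `R` is inverted by the selfed-RIL
fixation formula `r = R/(2 − 2R)` (Haldane–Waddington) and accumulated with
Kosambi. Pairs with fewer than 10 informative lines are flagged unreliable.
`ripple_check()` scores all permutations within a sliding window (default
3) by the sum of adjacent recombination fractions and applies strict
improvements until a full pass is stable; SARF is non-increasing by
construction.

# QTL scans

Haley–Knott regression was chosen over an EM mixture likelihood: for RIL
designs the two are near-identical, and the regression form is testable
against an exact least-squares oracle (the tests demand agreement to 1e-8
at complete-data marker positions). At a test position the expected
genotype score is imputed per line from its nearest informative flanking
markers through the map function and the RIL fixation transform; lines with
no informative marker on a chromosome get score 0 (no information). `LOD =
(n/2)·log₁₀(RSS₀/RSS₁)`; the additive effect is the regression coefficient
on the score (half the homozygote class gap, wild allele positive); `R² =
1 − RSS₁/RSS₀`.

CIM selects up to `n_cofactors` markers by greedy forward RSS minimization
(capped below `n/5` as an overfitting guard) and excludes cofactors within
`cofactor_window_cm` (default 10 cM) of the test position; with zero
cofactors it reduces exactly to interval mapping, which is asserted.

Permutation thresholds permute line means across lines — after averaging,
so any environment structure is kept intact — and take the empirical
`1 − α` quantile (type-1, so `α = 1` returns the minimum) of genome-wide
max LOD over ≥ 100 permutations. Calibration is verified: over 400 null
genome scans the exceedance rate of the 5% threshold must lie in
0.05 ± 0.02.

Peaks above threshold are merged within 10 cM and named `q<Tr>_<chrom>`
(`qPro_20` style). The published table merges QTL across environments
without stating a rule; 10 cM is this package's documented choice. Total
PVE for a QTL set is the joint linear model's `R²` × 100, with collinear
peak markers dropped. Epistasis is a defined two-locus interaction F-test
(`y ~ x1*x2`), replacing the original mixed-model software by an explicit,
testable contrast; pairs with any two-locus cell under 3 lines are skipped.

# GWAS

`K = ZZᵀ / (2Σ p(1−p))` (VanRaden), mean-imputed per SNP, monomorphic SNPs
excluded. The mixed model is fitted once by REML on the eigenbasis of `K`
(profiling the variance ratio), then each SNP is tested by GLS with the
ratio fixed and the residual scale re-estimated per SNP — the EMMAX-style
approximation. That per-SNP rescaling is what makes the `K = I`, zero-PC
case collapse *exactly* to OLS t-tests, which the tests exploit as a
reduction oracle. No compression is applied: at n ≈ 188 each line is its
own group. SNPs with MAF < 0.05 are excluded before testing (the GWAS-side
filter of the motivating study; the bin-map side uses MAF ≥ 0.2 — both are
exposed). The Bonferroni threshold is literally `α/m`; the motivating study prints
P ≤ 1.1 × 10⁻⁶ for 91,342 SNPs at α = 0.05, which corresponds to an
unexplained effective test count of ~45k rather than 91,342 — the formula,
not the printed number, is implemented.

# Variance components, heritability, correlations

Balanced-design expected mean squares: `σ² = MS_error`,
`σ²_ge = (MS_GE − MS_error)/r`, `σ²_g = (MS_G − MS_GE)/(re)`; the
environment F-test uses the replication-within-environment mean square as
denominator. Negative moment estimates are truncated to zero and flagged
(raw values kept). `H² = σ²g/(σ²g + σ²ge/e + σ²/(re))` on an entry-mean
basis, hence in [0, 1] after truncation. The genetic covariance for `rG`
uses the cross-product identity `cov_g(x,y) = [σ²g(x+y) − σ²g(x) −
σ²g(y)]/2`, the method-of-moments analogue of MANOVA cross-products; `rG`
is undefined (flagged) when either trait's genetic variance is zero. Only
balanced designs are supported — the simulator always produces them, and
unbalanced data get an instructive error. A REML fit (lme4) serves as an
independent cross-check oracle in the tests, never as the implementation.

# Haplotype clustering

Distance is the Hamming mismatch fraction over sites where both lines are
called (pairs sharing no sites get the uninformative value 0.5); linkage is
average. Neither choice is stated in the motivating study; they are the common
defaults for biallelic haplotype matrices and both are arguments. Labels
are canonicalized by cluster size then lexicographically smallest member,
so partitions are invariant to line and SNP order (asserted). The published
"two clusters, then subclusters" reading maps to `k = 2` followed by
re-clustering within each cluster; both routes are tested. Group trait
summaries are formatted `mean ± SD`, with one-way ANOVA and pairwise Welch
t-tests.

# Numerical conventions

* Coordinates: 1-based bp internally and in VCF; BED output is 0-based
  half-open; region extraction is half-open `start ≤ pos < end`.
* Bin ids are `bin_<chrom>_<start+1>` (1-based starts, matching the
  published marker style).
* `r = R/(2 − 2R)` is clamped below 0.5; Kosambi rejects `r ≥ 0.5`.
* Seeds: every stochastic entry point takes an explicit `seed`; identical
  seeds give bit-identical output (asserted).

# What a green suite does and does not establish

The simulator draws genotypes from the idealized SSD model (no
interference, uniform cM–bp relation per chromosome, independent lines, no
segregation distortion, no shared pedigree structure beyond the cross) and
phenotypes from a Gaussian additive model. Green tests therefore establish
that the pipeline's algorithms implement their definitions and recover
truth under the stated world — not that real skim data meet these
assumptions. In particular: real recombination shows interference and
hot/cold spots (bin sizes will be more heterogeneous), real call errors are
not independent flips, selection during inbreeding distorts segregation
ratios, and the uniform cM–bp map makes simulated bins more regular than
real ones. The published headline numbers (91,342 SNPs, 4,070 bins,
Table-1 LODs, r = 0.57) depend on undeposited data and are consequently
not reproduction targets anywhere in the suite.

# Known limitations

* Method-of-moments components require balanced data; no mixed-model
  fallback for unbalanced trials.
* `estimate_rf()` assumes selfed-RIL fixation; other pedigree types are out
  of scope.
* The epistasis test is a fixed-effect interaction contrast, not a
  mixed-model genome scan.
* Ripple is a local-order verification, not a de-novo ordering algorithm.
* The CLI is a thin convenience wrapper; programmatic use is the primary
  interface.
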