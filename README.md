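# skimqtl

QTL analysis for recombinant inbred line (RIL) populations genotyped by
**skim sequencing** — whole-genome resequencing at very low depth (~0.3×),
which yields sparse, noisy per-SNP calls instead of clean genotypes.

The package is written for quantitative geneticists working with biparental
inbred populations (the motivating design is an interspecific soybean cross,
*Glycine max* Williams 82 × *G. soja* PI 483460B, 188 F7:8 lines by single
seed descent) and implements the full analysis chain:

1. **Sliding-window genotype calling and bin mapping.** SNP calls are coded
   by parent of origin (`A`/`B`). Windows of 18 consecutive observed calls
   are called homozygous for a parent when ≥ 12 calls agree, otherwise
   undetermined. Transitions between `A` and `B` runs are recombination
   breakpoints; breakpoint intervals from all lines are compared over a
   100-kb grid and intervals lacking recombination in the entire population
   are merged into **bins**, each represented by one marker
   (`bin_<chrom>_<start>`).
2. **Linkage map.** Adjacent-bin recombination fractions `R` are converted
   to per-meiosis fractions for selfed RILs by `r = R/(2 − 2R)` and to cM by
   the Kosambi function `d = 25·ln[(1+2r)/(1−2r)]`; marker order (initialized
   from the physical map) is verified by sum-of-adjacent-rf (SARF) ripple.
3. **QTL scans.** Interval mapping by Haley–Knott regression on expected
   genotype scores, `LOD = (n/2)·log₁₀(RSS₀/RSS₁)`; composite interval
   mapping with forward-selected cofactors; genome-wide permutation LOD
   thresholds; joint-model PVE; a two-locus epistasis F-test.
4. **GWAS.** Mixed linear model `y = PCβ + u + e`, `u ~ N(0, Kσ²g)` with the
   VanRaden kinship `K = ZZᵀ / 2Σp(1−p)`, variance ratio estimated once by
   REML and per-SNP Wald tests (EMMAX-style), Bonferroni threshold `α/m`.
5. **Quantitative genetics.** Balanced two-way ANOVA variance components,
   broad-sense heritability on an entry-mean basis
   `H² = σ²g / (σ²g + σ²ge/e + σ²/(re))`, phenotypic and genetic
   correlations (`rG = cov_g(x,y)/√(σ²gx σ²gy)` via expected cross-products),
   and platform-agreement correlation.
6. **Haplotype analysis.** Hierarchical clustering of a QTL region on the
   shared-site Hamming distance, with trait-by-haplotype ANOVA and Welch
   t-tests.

Because the original sequencing and phenotype data were never deposited, the
package ships a first-class **simulator**: an explicit single-seed-descent
pedigree with Poisson crossovers (so true breakpoints exist as test
oracles), a call-level skim observation model (observation rate ≈ coverage,
small flip-error rate), and balanced multi-environment phenotypes with
planted additive QTL — including a pleiotropic protein/oil locus with
opposite-sign effects and a fully penetrant Mendelian seed-coat locus.

## Worked example

A reduced-scale scenario (100 lines, 3 chromosomes, 2,500 SNPs each — one
tenth of the full design's SNP density):

```r
library(skimqtl)
sc  <- default_scenario(n_lines = 100, n_chrom = 3, snps_per_chrom = 2500)
sim <- simulate_ril_genomes(sc$map, sc$ped, seed = 1)
obs <- filter_snps(observe_skim(sim, sc$skim, seed = 2), maf_min = 0.2)
bm  <- build_bins(detect_breakpoints(call_windows(obs)), sc$map)
mk  <- bin_to_markers(bm)
lmap <- build_linkage_map(mk$markers, mk$positions)
ph  <- simulate_phenotypes(sim, sc$pheno, seed = 3)

scan <- interval_scan(mk$markers, lmap, ph, "protein")
thr  <- permutation_threshold(mk$markers, lmap, ph, "protein",
                              n_perm = 1000, seed = 4)
call_peaks(scan, thr)
```

which prints (abridged):

```
Bin map: 49 bins over 3 chromosome(s); 100 lines
Linkage map: 49 markers on 3 chromosome(s), total 273 cM ( kosambi )
QTL scan for 'protein': 320 positions, n = 100, max LOD = 12.69
Permutation threshold for 'protein': LOD 2.3 (alpha = 0.05, 1000 permutations)
     qtl   trait environment chrom cm marker      lod   effect       r2
1 qPro_2 protein        <NA>     2 68   <NA> 12.69013 1.036481 0.442561
```

The 49 bins are the recombination-free intervals of this population; the
protein scan recovers the planted major locus (simulated at 34 Mb ≈ 75 cM
on chromosome 2 with additive effect +1.2, wild-parent allele increasing
protein) as `qPro_2` with LOD 12.7 far above the genome-wide 5% permutation
threshold of 2.3, an estimated additive effect of +1.04 and 44% of the
line-mean variance explained. Variance components and heritability:

```r
vc <- anova_components(ph, "protein")   # s2g 2.09, s2ge 0.57, s2 0.75
heritability(vc)$H2                     # 0.898 (entry-mean basis)
correlations(ph, "protein", "oil")      # r_p -0.58, r_G -0.65 (pleiotropy)
```

## Command line

```sh
inst/cli/skimqtl simulate --config scenario.json --seed 3 --out run/
inst/cli/skimqtl binmap --vcf run/genotypes.vcf --out run/
inst/cli/skimqtl scan --markers run/markers.tsv --bed run/bins.bed \
    --pheno run/phenotypes.tsv --trait protein --n-perm 1000 --seed 7 --out run/
inst/cli/skimqtl stats --pheno run/phenotypes.tsv --out run/
```

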