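# helper: a random complete marker set with a linkage map, plus phenotypes
sim_scan_fixture <- function(n_lines = 80, n_snps = 30, length_cm = 100,
                             seed = 1, qtl_col = NULL, effect = 0,
                             sd_noise = 1) {
  set.seed(seed)
  map <- make_map(n_chrom = 1, length_cm = length_cm, n_snps = n_snps)
  sim <- simulate_ril_genomes(map, pedigree_params(n_lines, 12), seed = seed)
  mk <- geno_to_markers(sim$geno)
  positions <- data.frame(chrom = "1", pos = sim$snps$pos,
                          marker = colnames(mk), stringsAsFactors = FALSE)
  lmap <- build_linkage_map(mk, positions)
  x <- sim$geno - 1
  y <- stats::rnorm(n_lines, 0, sd_noise)
  if (!is.null(qtl_col)) y <- y + effect * x[, qtl_col]
  pheno <- data.frame(line = rownames(mk), trait = "t", environment = "env1",
                      replicate = 1, value = y, stringsAsFactors = FALSE)
  list(mk = mk, lmap = lmap, pheno = pheno, sim = sim, y = y)
}

test_that("scan LOD at marker positions equals the regression oracle", {
  # 100 random fixtures: every marker position of several random scans,
  # compared against an independent lm()-based LOD
  checked <- 0
  for (seed in 1:7) {
    fx <- sim_scan_fixture(n_lines = 60, n_snps = 20, seed = seed)
    sc <- interval_scan(fx$mk, fx$lmap, fx$pheno, "t", step_cm = 1e6)
    res <- sc$result[!is.na(sc$result$marker), ]
    for (j in seq_len(nrow(res))) {
      x <- marker_to_num(fx$mk[, res$marker[j]])
      if (anyNA(x) || stats::sd(x) == 0) next   # oracle needs complete data
      expect_equal(res$lod[j], lod_lm(x, fx$y), tolerance = 1e-8)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 100)
})

test_that("additive effect and R2 match the class-mean definitions", {
  fx <- sim_scan_fixture(n_lines = 100, n_snps = 10, seed = 3,
                         qtl_col = 5, effect = 1)
  sc <- interval_scan(fx$mk, fx$lmap, fx$pheno, "t", step_cm = 1e6)
  res <- sc$result
  j <- 5
  x <- fx$sim$geno[, j] - 1
  a_oracle <- (mean(fx$y[x == 1]) - mean(fx$y[x == -1])) / 2
  # complete biallelic data: regression slope equals half the class gap
  expect_equal(res$effect[j], a_oracle, tolerance = 1e-8)
  expect_equal(res$r2[j], summary(stats::lm(fx$y ~ x))$r.squared,
               tolerance = 1e-8)
  # B-allele increasing convention: planted positive effect stays positive
  expect_gt(res$effect[j], 0)
})

test_that("LOD is invariant to affine phenotype transforms", {
  fx <- sim_scan_fixture(seed = 4, qtl_col = 10, effect = 0.8)
  sc1 <- interval_scan(fx$mk, fx$lmap, fx$pheno, "t")
  ph2 <- fx$pheno
  ph2$value <- -2.5 * ph2$value + 7
  sc2 <- interval_scan(fx$mk, fx$lmap, ph2, "t")
  expect_equal(sc1$result$lod, sc2$result$lod, tolerance = 1e-10)
  expect_equal(sc2$result$effect, -2.5 * sc1$result$effect,
               tolerance = 1e-10)
})

test_that("null phenotypes stay below the permutation threshold", {
  fx <- sim_scan_fixture(n_lines = 100, n_snps = 40, seed = 6)
  sc <- interval_scan(fx$mk, fx$lmap, fx$pheno, "t")
  thr <- permutation_threshold(fx$mk, fx$lmap, fx$pheno, "t",
                               n_perm = 300, seed = 11)
  expect_lt(max(sc$result$lod), thr$threshold + 1.5)
  expect_equal(nrow(call_peaks(sc, thr$threshold + 1.5)), 0L)
})

test_that("permutation threshold is reproducible, honours alpha = 1", {
  fx <- sim_scan_fixture(seed = 7)
  t1 <- permutation_threshold(fx$mk, fx$lmap, fx$pheno, "t",
                              n_perm = 120, seed = 5)
  t2 <- permutation_threshold(fx$mk, fx$lmap, fx$pheno, "t",
                              n_perm = 120, seed = 5)
  expect_identical(t1$threshold, t2$threshold)
  tmin <- permutation_threshold(fx$mk, fx$lmap, fx$pheno, "t",
                                n_perm = 120, alpha = 1, seed = 5)
  expect_equal(tmin$threshold, min(tmin$max_lods))
  expect_error(permutation_threshold(fx$mk, fx$lmap, fx$pheno, "t",
                                     n_perm = 50), "n_perm")
})

test_that("CIM with zero cofactors reduces to interval mapping", {
  fx <- sim_scan_fixture(seed = 8, qtl_col = 12, effect = 0.7)
  im <- interval_scan(fx$mk, fx$lmap, fx$pheno, "t")
  cim0 <- cim_scan(fx$mk, fx$lmap, fx$pheno, "t", n_cofactors = 0)
  expect_equal(cim0$result$lod, im$result$lod, tolerance = 1e-10)
  expect_equal(cim0$result$effect, im$result$effect, tolerance = 1e-10)
})

test_that("CIM guards against overfitting and excludes local cofactors", {
  fx <- sim_scan_fixture(n_lines = 40, seed = 9)
  expect_error(cim_scan(fx$mk, fx$lmap, fx$pheno, "t", n_cofactors = 10),
               "n_lines / 5")
  # a cofactor at/near the test position must be excluded there: the LOD
  # at the selected cofactor's own position must match plain IM locally
  fx2 <- sim_scan_fixture(n_lines = 120, n_snps = 20, seed = 10,
                          qtl_col = 10, effect = 1.2)
  cim1 <- cim_scan(fx2$mk, fx2$lmap, fx2$pheno, "t", n_cofactors = 1,
                   cofactor_window_cm = 10)
  expect_length(cim1$cofactors, 1L)
  im <- interval_scan(fx2$mk, fx2$lmap, fx2$pheno, "t")
  at_cof <- which(cim1$result$marker == cim1$cofactors[1])
  expect_equal(cim1$result$lod[at_cof], im$result$lod[at_cof],
               tolerance = 1e-10)
  expect_gt(cim1$result$lod[at_cof], 3)
})

test_that("CIM separates two linked QTL that IM blurs", {
  set.seed(42)
  map <- make_map(n_chrom = 1, length_cm = 100, n_snps = 21)
  sim <- simulate_ril_genomes(map, pedigree_params(500, 12), seed = 42)
  mk <- geno_to_markers(sim$geno)
  positions <- data.frame(chrom = "1", pos = sim$snps$pos,
                          marker = colnames(mk), stringsAsFactors = FALSE)
  lmap <- build_linkage_map(mk, positions)
  x <- sim$geno - 1
  # two QTL 40 cM apart (markers at 30 and 70 cM; 5 cM marker spacing)
  q1 <- 7; q2 <- 15
  y <- 0.6 * x[, q1] + 0.6 * x[, q2] + stats::rnorm(500)
  ph <- data.frame(line = rownames(mk), trait = "t", environment = "e1",
                   replicate = 1, value = y, stringsAsFactors = FALSE)
  cim <- cim_scan(mk, lmap, ph, "t", n_cofactors = 4,
                  cofactor_window_cm = 15)
  true_cm <- lmap$table$cm[c(q1, q2)]
  peaks <- call_peaks(cim, threshold = 3, merge_cm = 10)
  expect_gte(nrow(peaks), 2L)
  for (tc in true_cm)
    expect_true(any(abs(peaks$cm - tc) <= 10))
})

test_that("joint-QTL PVE matches single- and two-locus expectations", {
  fx <- sim_scan_fixture(n_lines = 150, n_snps = 10, seed = 12,
                         qtl_col = 4, effect = 1)
  sc <- interval_scan(fx$mk, fx$lmap, fx$pheno, "t", step_cm = 1e6)
  mk_name <- colnames(fx$mk)[4]
  pve1 <- multi_qtl_pve(fx$mk, fx$pheno, "t", mk_name)
  expect_equal(pve1$pve, 100 * sc$result$r2[4], tolerance = 1e-8)
  # two distant markers: joint PVE <= sum of marginals (plus slack)
  mk2 <- colnames(fx$mk)[c(2, 9)]
  pvej <- multi_qtl_pve(fx$mk, fx$pheno, "t", mk2)
  marg <- sapply(c(2, 9), function(j) sc$result$r2[j])
  expect_lte(pvej$pve, 100 * sum(marg) + 5)
  # collinear markers are dropped with a warning
  dup <- cbind(fx$mk, dup = fx$mk[, 4])
  colnames(dup)[ncol(dup)] <- "dup"
  expect_warning(multi_qtl_pve(dup, fx$pheno, "t", c(mk_name, "dup")),
                 "collinear")
})

test_that("epistasis scan is calibrated and detects planted interactions", {
  set.seed(77)
  map <- make_map(n_chrom = 2, length_cm = 100, n_snps = 6)
  sim <- simulate_ril_genomes(map, pedigree_params(300, 12), seed = 77)
  mk <- geno_to_markers(sim$geno)
  x <- sim$geno - 1
  # purely additive: no interaction should fire at alpha = 0.001
  y_add <- 0.5 * x[, 2] + 0.5 * x[, 8] + stats::rnorm(300)
  ph <- data.frame(line = rownames(mk), trait = "t", environment = "e1",
                   replicate = 1, value = y_add, stringsAsFactors = FALSE)
  et <- epistasis_scan(mk, ph, "t", colnames(mk)[c(2, 5, 8, 11)])
  expect_true(all(!et$significant[!et$skipped]))
  # planted multiplicative interaction, 1 SD effect: detected
  y_int <- x[, 2] * x[, 8] + stats::rnorm(300)
  ph$value <- y_int
  et2 <- epistasis_scan(mk, ph, "t",
                        cbind(colnames(mk)[2], colnames(mk)[8]))
  expect_false(et2$skipped[1])
  expect_true(et2$significant[1])
  # self-pair rejected; sparse cells skipped
  expect_error(epistasis_scan(mk, ph, "t",
                              cbind(colnames(mk)[2], colnames(mk)[2])),
               "itself")
  mk_sparse <- mk
  mk_sparse[3:300, 5] <- mk_sparse[3:300, 2]  # near-perfect LD, empty cells
  et3 <- epistasis_scan(mk_sparse, ph, "t",
                        cbind(colnames(mk)[2], colnames(mk)[5]))
  expect_true(et3$skipped[1])
})

test_that("a pleiotropic locus gives coincident, opposite-sign peaks", {
  sc <- default_scenario(n_lines = 188, n_chrom = 4, snps_per_chrom = 120)
  sim <- simulate_ril_genomes(sc$map, sc$ped, seed = 19)
  mk <- geno_to_markers(sim$geno)
  positions <- data.frame(chrom = sim$snps$chrom, pos = sim$snps$pos,
                          marker = colnames(mk), stringsAsFactors = FALSE)
  lmap <- build_linkage_map(mk, positions)
  ph <- simulate_phenotypes(sim, sc$pheno, seed = 20)
  sp <- interval_scan(mk, lmap, ph, "protein")
  so <- interval_scan(mk, lmap, ph, "oil")
  # shared locus: chromosome wrap puts the protein/oil QTL on chrom 4
  pk_p <- call_peaks(sp, 3); pk_o <- call_peaks(so, 3)
  pp <- pk_p[pk_p$chrom == "4", ][1, ]
  po <- pk_o[pk_o$chrom == "4", ][1, ]
  expect_lt(abs(pp$cm - po$cm), 10)
  expect_gt(pp$effect, 0)
  expect_lt(po$effect, 0)
  # and the QTL naming convention
  expect_equal(pp$qtl, "qPro_4")
  expect_equal(po$qtl, "qOil_4")
})

test_that("bin-level and SNP-level scans localize the same planted QTL", {
  # density matters here: bin resolution requires SNP spacing much finer
  # than the window span, as in the full design (~10 kb spacing)
  sc <- default_scenario(n_lines = 60, n_chrom = 2, snps_per_chrom = 2000,
                         observation_rate = 1, error_rate = 0)
  sim <- simulate_ril_genomes(sc$map, sc$ped, seed = 23)
  ph <- simulate_phenotypes(sim, sc$pheno, seed = 24)
  # dense per-SNP scan on true genotypes
  mk_snp <- geno_to_markers(sim$geno)
  pos_snp <- data.frame(chrom = sim$snps$chrom, pos = sim$snps$pos,
                        marker = colnames(mk_snp), stringsAsFactors = FALSE)
  lmap_snp <- build_linkage_map(mk_snp, pos_snp)
  # bin-level scan from the full pipeline
  obs <- observe_skim(sim, sc$skim, seed = 25)
  bm <- build_bins(detect_breakpoints(call_windows(obs)), sc$map)
  mkb <- bin_to_markers(bm)
  lmap_bin <- build_linkage_map(mkb$markers, mkb$positions)
  # protein: its major planted QTL wraps onto chromosome 2 at 34 Mb and
  # is the only QTL on that chromosome (oil has two linked ones there)
  s_snp <- interval_scan(mk_snp, lmap_snp, ph, "protein")
  s_bin <- interval_scan(mkb$markers, lmap_bin, ph, "protein")
  # compare at marker positions (peaks on the marker grid)
  r_snp <- s_snp$result[!is.na(s_snp$result$marker), ]
  r_bin <- s_bin$result[!is.na(s_bin$result$marker), ]
  top_snp <- r_snp[which.max(r_snp$lod), ]
  top_bin <- r_bin[which.max(r_bin$lod), ]
  expect_equal(top_snp$chrom, top_bin$chrom)
  # peak bin contains (or neighbours) the peak SNP position
  bp_snp <- sim$snps$pos[match(top_snp$marker, colnames(mk_snp))]
  peak_bin <- bm$bins[match(top_bin$marker, bm$bins$bin_id), ]
  expect_lt(abs((peak_bin$start + peak_bin$end) / 2 - bp_snp), 5e6)
})
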