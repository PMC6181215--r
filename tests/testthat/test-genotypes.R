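test_that("filter_snps applies the MAF rule over non-missing calls", {
  # 100 lines, 5 SNPs with B-allele counts 50/25/19/0/50 -> MAFs
  # 0.50, 0.25, 0.19, 0.00, 0.50: exactly 3 survive at maf_min = 0.2
  # (enumerated by hand before implementing)
  n <- 100
  counts <- c(50, 25, 19, 0, 50)
  calls <- sapply(counts, function(k) c(rep(1L, k), rep(0L, n - k)))
  g <- ab_genotypes(calls, data.frame(chrom = "1", pos = 1:5 * 100))
  f <- filter_snps(g, maf_min = 0.2)
  expect_equal(nrow(f$snps), 3L)
  expect_equal(attr(f, "n_snps_removed"), 2L)
  # MAF exactly at the threshold is retained; just below is removed
  calls2 <- sapply(c(20, 19), function(k) c(rep(1L, k), rep(0L, n - k)))
  g2 <- ab_genotypes(calls2, data.frame(chrom = "1", pos = c(100, 200)))
  expect_equal(nrow(filter_snps(g2, 0.2)$snps), 1L)
  # MAF uses non-missing calls only: 10 B, 10 A, 80 missing -> MAF 0.5
  calls3 <- cbind(c(rep(1L, 10), rep(0L, 10), rep(NA, 80)),
                  c(rep(1L, 50), rep(0L, 50)))
  g3 <- ab_genotypes(calls3, data.frame(chrom = "1", pos = c(100, 200)))
  expect_equal(nrow(filter_snps(g3, 0.4)$snps), 2L)
})

test_that("filter_snps drops high-missingness lines after the SNP step", {
  n_snp <- 40
  calls <- matrix(rep(c(0L, 1L), each = 3), 6, n_snp)  # every SNP 3A/3B
  calls[1, 1:4] <- NA                      # line 1: 10% missing
  g <- ab_genotypes(calls, data.frame(chrom = "1", pos = 1:n_snp * 10))
  f <- filter_snps(g, maf_min = 0.2, line_missing_max = 0.05)
  expect_equal(length(f$lines), 5L)
  expect_equal(attr(f, "n_lines_removed"), 1L)
  expect_error(filter_snps(g, maf_min = 0.9), "MAF")
})

test_that("window calls follow the 18/12 homozygosity rule", {
  # 18 A calls -> A
  g <- make_ab(paste(rep("A", 18), collapse = ""))
  tr <- call_windows(g)
  expect_equal(tr$tracks[[1]][["1"]]$call, "A")
  # 12 A + 6 B -> A (12-or-more rule); 11 A + 7 B -> U
  g12 <- make_ab(paste(c(rep("A", 12), rep("B", 6)), collapse = ""))
  expect_equal(call_windows(g12)$tracks[[1]][["1"]]$call, "A")
  g11 <- make_ab(paste(c(rep("A", 11), rep("B", 7)), collapse = ""))
  expect_equal(call_windows(g11)$tracks[[1]][["1"]]$call, "U")
  # symmetric for B
  gB <- make_ab(paste(c(rep("B", 12), rep("A", 6)), collapse = ""))
  expect_equal(call_windows(gB)$tracks[[1]][["1"]]$call, "B")
})

test_that("windows slide over observed calls only and respect spans", {
  # 20 observed calls interleaved with missing: 3 windows of 18, spans in
  # observed-SNP coordinates
  row <- paste(rep("A.", 20), collapse = "")   # A at odd positions
  g <- make_ab(row)
  tr <- call_windows(g)$tracks[[1]][["1"]]
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$start_bp, c(1, 3, 5) * 1000)
  expect_equal(tr$end_bp, c(35, 37, 39) * 1000)
  expect_true(all(tr$call == "A"))
  # fewer than window_size observed calls: empty track with warning
  g_short <- make_ab(paste(rep("A", 10), collapse = ""))
  expect_warning(tr2 <- call_windows(g_short), "undetermined")
  expect_equal(nrow(tr2$tracks[[1]][["1"]]), 0L)
  expect_error(call_windows(g, window_size = 10, homozygous_min = 12),
               "homozygous_min")
})

test_that("breakpoints are transitions between A and B runs", {
  # A,A,A,B,B -> one breakpoint between windows 3 and 4
  bs <- detect_breakpoints(make_track(list(L1 = "AAABB")))
  expect_equal(nrow(bs$breakpoints), 1L)
  expect_equal(bs$breakpoints$left_bp, 3000)
  expect_equal(bs$breakpoints$right_bp, 4000)
  expect_equal(bs$breakpoints$from, "A")
  # all A -> none; A U A -> none (U does not break a run)
  expect_equal(nrow(detect_breakpoints(make_track(list(L1 = "AAAAA")))$breakpoints), 0L)
  expect_equal(nrow(detect_breakpoints(make_track(list(L1 = "AAUAA")))$breakpoints), 0L)
  # A U B -> one breakpoint widened over the U window
  bs2 <- detect_breakpoints(make_track(list(L1 = "AAUBB")))
  expect_equal(nrow(bs2$breakpoints), 1L)
  expect_equal(bs2$breakpoints$left_bp, 2000)
  expect_equal(bs2$breakpoints$right_bp, 4000)
  # multiple transitions
  bs3 <- detect_breakpoints(make_track(list(L1 = "AABBBAA")))
  expect_equal(bs3$breakpoints$from, c("A", "B"))
})

test_that("noiseless complete data: detected breakpoints match true junctions", {
  # with observation_rate = 1 and error_rate = 0, every resolvable true
  # junction (flanking homozygous runs >= homozygous_min SNPs) must be
  # contained in exactly one detected interval, and every detected
  # interval must contain a true junction
  map <- make_map(n_chrom = 2, length_cm = 110, n_snps = 600)
  sim <- simulate_ril_genomes(map, pedigree_params(20, 8), seed = 31)
  obs <- observe_skim(sim, skim_model(1, 0), seed = 1)
  bset <- detect_breakpoints(call_windows(obs))
  det <- bset$breakpoints
  truth <- resolvable_junctions(sim, min_run = 12)
  for (i in seq_len(nrow(truth))) {
    hits <- which(det$line == truth$line[i] & det$chrom == truth$chrom[i] &
                    det$left_bp <= truth$pos[i] & det$right_bp >= truth$pos[i])
    expect_equal(length(hits), 1L)
  }
  # no spurious breakpoints: every detected interval contains a true junction
  all_j <- sim$crossovers
  for (i in seq_len(nrow(det))) {
    hits <- which(all_j$line == det$line[i] & all_j$chrom == det$chrom[i] &
                    all_j$pos >= det$left_bp[i] & all_j$pos <= det$right_bp[i])
    expect_gte(length(hits), 1L)
  }
})

test_that("bins merge non-recombinant intervals; boundaries at breakpoints", {
  map <- genmap_spec(data.frame(chrom = "1", length_bp = 1e6, length_cm = 10),
                     list("1" = seq(1e4, 99e4, by = 1e4)))
  # no breakpoints: one bin spanning the chromosome
  track <- make_track(list(L1 = strrep("A", 50), L2 = strrep("B", 50)),
                      centers = seq(1e4, 99e4, length.out = 50))
  bs0 <- make_bset(data.frame(line = character(), chrom = character(),
                              left_bp = numeric(), right_bp = numeric(),
                              stringsAsFactors = FALSE), track)
  bm0 <- build_bins(bs0, map, interval_bp = 1e5)
  expect_equal(nrow(bm0$bins), 1L)
  expect_equal(bm0$bins$start, 0)
  expect_equal(bm0$bins$end, 1e6)
  expect_equal(unname(bm0$geno[, 1]), c("A", "B"))
  # one line with one breakpoint inside grid interval 5 ([4e5, 5e5)):
  # exactly two bins split at that interval's start
  calls1 <- paste0(strrep("A", 22), strrep("B", 28))
  track1 <- make_track(list(L1 = calls1, L2 = strrep("B", 50)),
                       centers = seq(1e4, 99e4, length.out = 50))
  bp1 <- data.frame(line = "L1", chrom = "1", left_bp = 4.3e5,
                    right_bp = 4.5e5, stringsAsFactors = FALSE)
  bm1 <- build_bins(make_bset(bp1, track1), map, interval_bp = 1e5)
  expect_equal(nrow(bm1$bins), 2L)
  expect_equal(bm1$bins$start, c(0, 4e5))
  expect_equal(unname(bm1$geno["L1", ]), c("A", "B"))
  expect_equal(unname(bm1$geno["L2", ]), c("B", "B"))
  expect_equal(bm1$bins$bin_id, c("bin_1_1", "bin_1_400001"))
})

test_that("bin construction matches the brute-force oracle on toys", {
  # hand-enumerated 20-line toy: breakpoints in well-separated intervals
  map <- genmap_spec(data.frame(chrom = "1", length_bp = 2e6, length_cm = 20),
                     list("1" = seq(1e4, 199e4, by = 1e4)))
  centers <- seq(1e4, 199e4, length.out = 100)
  lines <- sprintf("T%02d", 1:20)
  bp_at <- c(3.05e5, 9.55e5, 15.05e5)    # three recombinant intervals
  calls <- stats::setNames(vector("list", 20), lines)
  bps <- list()
  for (i in 1:20) {
    calls[[i]] <- strrep(if (i %% 2) "A" else "B", 100)
  }
  for (k in seq_along(bp_at)) {
    ln <- lines[k]
    flip_from <- which(centers > bp_at[k])[1]
    calls[[ln]] <- paste0(strrep("A", flip_from - 1),
                          strrep("B", 100 - flip_from + 1))
    bps[[k]] <- data.frame(line = ln, chrom = "1",
                           left_bp = bp_at[k] - 1e4, right_bp = bp_at[k] + 1e4,
                           stringsAsFactors = FALSE)
  }
  track <- make_track(calls, centers = centers)
  bset <- make_bset(do.call(rbind, bps), track)
  bm <- build_bins(bset, map, interval_bp = 1e5)
  oracle <- brute_force_bins(bset$breakpoints, c("1" = 2e6), 1e5)
  expect_equal(bm$bins$start, oracle$start)
  expect_equal(bm$bins$end, oracle$end)
  expect_equal(nrow(bm$bins), 4L)
  # adjacent bins differ in at least one line
  for (j in seq_len(nrow(bm$bins) - 1))
    expect_true(any(bm$geno[, j] != bm$geno[, j + 1]))
})

test_that("bin markers carry the id convention and round-trip as text", {
  map <- make_map(n_chrom = 1, length_bp = 1e6, length_cm = 10, n_snps = 60)
  sim <- simulate_ril_genomes(map, pedigree_params(15, 8), seed = 12)
  obs <- observe_skim(sim, skim_model(1, 0), seed = 2)
  bm <- build_bins(detect_breakpoints(call_windows(obs)), map)
  mk <- bin_to_markers(bm)
  expect_true(all(grepl("^bin_1_\\d+$", colnames(mk$markers))))
  expect_equal(mk$positions$pos, mk$bed$start + 1L)
  expect_equal(mk$bed$end[nrow(mk$bed)], 1e6)
  tmp_m <- tempfile(fileext = ".tsv"); tmp_b <- tempfile(fileext = ".bed")
  write_markers(mk, tmp_m); write_bed(mk, tmp_b)
  expect_identical(read_markers(tmp_m), mk$markers)
  bed2 <- read_bed(tmp_b)
  expect_equal(bed2$start, mk$bed$start)
  expect_equal(bed2$name, mk$bed$name)
})

test_that("merged non-recombinant runs contain no transitions; bins match brute force", {
  # error-free data: grid intervals not overlapped by any breakpoint
  # (re-derived brute-force here) must contain no A<->B transition of any
  # line, and build_bins must split exactly at the recombinant-run starts
  map <- make_map(n_chrom = 1, length_cm = 110, n_snps = 500)
  sim <- simulate_ril_genomes(map, pedigree_params(25, 8), seed = 77)
  obs <- observe_skim(sim, skim_model(1, 0), seed = 3)
  bset <- detect_breakpoints(call_windows(obs))
  bm <- build_bins(bset, map)
  oracle <- brute_force_bins(bset$breakpoints, c("1" = 1e7), 1e5)
  expect_equal(bm$bins$start, oracle$start)
  expect_equal(bm$bins$end, oracle$end)
  # non-recombinant grid cells (brute-force flags)
  det <- bset$breakpoints
  edges <- seq(0, 1e7, by = 1e5)
  recomb <- vapply(seq_len(length(edges) - 1), function(k)
    any(det$left_bp < edges[k + 1] & det$right_bp > edges[k]), logical(1))
  # no breakpoint interval lies entirely within a non-recombinant run
  for (i in seq_len(nrow(det))) {
    ks <- which(edges[-length(edges)] < det$right_bp[i] &
                  edges[-1] > det$left_bp[i])
    expect_true(any(recomb[ks]))
  }
})

test_that("more call noise never reduces undetermined window calls", {
  map <- make_map(n_chrom = 1, length_cm = 100, n_snps = 400)
  sim <- simulate_ril_genomes(map, pedigree_params(20, 8), seed = 8)
  u_count <- function(err, seed) {
    obs <- observe_skim(sim, skim_model(0.9, err), seed = seed)
    tr <- call_windows(obs)
    sum(vapply(tr$tracks, function(l) sum(l[["1"]]$call == "U"), numeric(1)))
  }
  # expectation over seeds: average over a small fixed seed set
  u0 <- mean(vapply(1:3, function(s) u_count(0, s), numeric(1)))
  u5 <- mean(vapply(1:3, function(s) u_count(0.05, s), numeric(1)))
  expect_lte(u0, u5)
})
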