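# Independent oracles used to freeze expected values.  These deliberately
# re-derive quantities by brute force / closed form, not via the package's
# own code paths.

# ---- two-locus selfing Markov chain -----------------------------------
# An individual is an ordered pair of two-locus haplotypes; haplotypes are
# indexed 1..4 = (0,0), (0,1), (1,0), (1,1) with alleles at (locus1,
# locus2).  Selfing: both offspring haplotypes are iid gametes of the
# parent; a gamete is a parental haplotype w.p. (1-r)/2 each or a
# recombinant w.p. r/2 each.  Returns the F_generation distribution over
# the 16 ordered pairs, starting from the F1 (AB / ab).
two_locus_selfing <- function(r, generation) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  hap_index <- function(a1, a2) 1 + 2 * a1 + a2
  # gamete distribution for each ordered parent pair (16 x 4)
  G <- matrix(0, 16, 4)
  for (h1 in 1:4) for (h2 in 1:4) {
    s <- (h1 - 1) * 4 + h2
    G[s, h1] <- G[s, h1] + (1 - r) / 2
    G[s, h2] <- G[s, h2] + (1 - r) / 2
    rec1 <- hap_index(haps[h1, 1], haps[h2, 2])
    rec2 <- hap_index(haps[h2, 1], haps[h1, 2])
    G[s, rec1] <- G[s, rec1] + r / 2
    G[s, rec2] <- G[s, rec2] + r / 2
  }
  v <- rep(0, 16)
  v[(1 - 1) * 4 + 4] <- 1               # F1 = (AB, ab)
  for (t in seq_len(generation - 1)) {
    # offspring haplotypes are iid *given the parent*, so the next
    # distribution is accumulated per parent state
    nxt <- rep(0, 16)
    for (s in which(v > 0)) {
      gp <- G[s, ]
      nxt <- nxt + v[s] * as.vector(outer(gp, gp))
    }
    # outer(gp, gp)[h1, h2] laid out column-major = index (h2-1)*4+h1;
    # symmetric in h1/h2 so the ordering convention cancels
    v <- nxt
  }
  v
}

# joint genotype distribution (dosage at locus1, locus2 in 0/1/2) at F_g
two_locus_genotype_probs <- function(r, generation) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  v <- two_locus_selfing(r, generation)
  P <- matrix(0, 3, 3)
  for (h1 in 1:4) for (h2 in 1:4) {
    s <- (h1 - 1) * 4 + h2
    d1 <- haps[h1, 1] + haps[h2, 1]
    d2 <- haps[h1, 2] + haps[h2, 2]
    P[d1 + 1, d2 + 1] <- P[d1 + 1, d2 + 1] + v[s]
  }
  P
}

# P(two loci carry different parental homozygous genotypes | both
# homozygous) at F_g -- what an A/B-coded RIL marker pair shows
expected_R_hom <- function(r, generation) {
  P <- two_locus_genotype_probs(r, generation)
  num <- P[1, 3] + P[3, 1]
  den <- P[1, 1] + P[1, 3] + P[3, 1] + P[3, 3]
  num / den
}

# expected A<->B junction count per line for one chromosome, summing the
# adjacent-SNP transition probability (Haldane per-meiosis r from the cM
# gap; heterozygous gaps make this a close approximation, see comments in
# test-popsim.R)
expected_junctions <- function(pos_cm, generation) {
  d <- diff(pos_cm)
  r <- (1 - exp(-2 * d / 100)) / 2
  sum(vapply(r, function(ri) {
    P <- two_locus_genotype_probs(ri, generation)
    P[1, 3] + P[3, 1]
  }, numeric(1)))
}

# LOD of a single-marker least-squares regression, the interval-scan
# oracle at marker positions
lod_lm <- function(x, y) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  (n / 2) * log10(rss0 / rss1)
}

# resolvable true junctions: those whose flanking homozygous runs each
# contain at least `min_run` observed SNPs (the window rule cannot
# represent shorter parental segments)
resolvable_junctions <- function(sim, min_run = 12) {
  keep <- logical(nrow(sim$crossovers))
  if (!nrow(sim$crossovers)) return(sim$crossovers)
  for (cc in unique(sim$snps$chrom)) {
    idx <- which(sim$snps$chrom == cc)
    pos <- sim$snps$pos[idx]
    for (ln in rownames(sim$geno)) {
      rows <- which(sim$crossovers$line == ln & sim$crossovers$chrom == cc)
      if (!length(rows)) next
      g <- sim$geno[ln, idx]
      hom <- which(g != 1L)
      rl <- rle(g[hom])
      run_len <- rl$lengths
      # junction j sits between runs j and j+1
      ok <- run_len[-length(run_len)] >= min_run & run_len[-1] >= min_run
      keep[rows] <- ok
    }
  }
  sim$crossovers[keep, , drop = FALSE]
}

# brute-force bin construction: split each chromosome at the start of
# every grid interval overlapped by any population breakpoint interval
brute_force_bins <- function(breakpoints, chrom_len, interval_bp = 1e5) {
  out <- list()
  for (cc in names(chrom_len)) {
    len <- chrom_len[[cc]]
    edges <- seq(0, len, by = interval_bp)
    if (edges[length(edges)] < len) edges <- c(edges, len)
    bpc <- breakpoints[breakpoints$chrom == cc, , drop = FALSE]
    recomb <- rep(FALSE, length(edges) - 1)
    for (j in seq_len(nrow(bpc))) {
      ks <- which(edges[-length(edges)] < bpc$right_bp[j] &
                    edges[-1] > bpc$left_bp[j])
      recomb[ks] <- TRUE
    }
    starts <- 0
    for (k in seq_along(recomb)) {
      if (recomb[k] && (k == 1 || !recomb[k - 1]) && edges[k] > 0)
        starts <- c(starts, edges[k])
    }
    out[[cc]] <- data.frame(chrom = cc, start = starts,
                            end = c(starts[-1], len),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
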