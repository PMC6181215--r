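#' Extract the SNPs of a genomic region
#'
#' Subsets a genotype matrix to the SNPs of one region using half-open
#' coordinates: `start <= pos < end` (1-based positions, as in VCF).
#'
#' @param g an [ab_genotypes()] object, or a lines x SNPs matrix with a
#'   `snps` data.frame `(chrom, pos)` supplied separately.
#' @param chrom chromosome id.
#' @param start,end region bounds in bp; `end` must exceed `start`.
#' @param snps SNP table when `g` is a bare matrix.
#' @return a matrix of the region's columns (same storage as the input),
#'   with the matching `snps` rows as attribute `snps`.
#' @export
extract_region <- function(g, chrom, start, end, snps = NULL) {
  if (inherits(g, "ab_genotypes")) {
    snps <- g$snps
    mat <- g$calls
  } else {
    mat <- g
    if (is.null(snps)) stop("supply `snps` with a bare matrix", call. = FALSE)
  }
  if (end <= start) stop("region must have positive width (start < end)",
                         call. = FALSE)
  sel <- snps$chrom == as.character(chrom) & snps$pos >= start & snps$pos < end
  if (!any(sel)) stop("no SNPs in ", chrom, ":", start, "-", end,
                      call. = FALSE)
  out <- mat[, sel, drop = FALSE]
  attr(out, "snps") <- snps[sel, , drop = FALSE]
  out
}

#' Hierarchical clustering of haplotypes over a region
#'
#' Agglomerative clustering of lines on the allele-sharing distance:
#' the Hamming distance over sites where both lines are non-missing,
#' normalized by the number of shared sites.  Cluster labels are
#' canonicalized (numbered by decreasing cluster size, ties broken by the
#' smallest member name), so the partition is invariant to line and SNP
#' order.
#'
#' @param region a matrix from [extract_region()] (or any lines x SNPs
#'   matrix coded 0/1/`NA` or `"A"`/`"B"`/`NA`).
#' @param k number of clusters to cut; alternatively supply `h`, a
#'   dendrogram cut height.
#' @param h optional cut height (overrides `k`).
#' @param linkage hclust agglomeration method (default `"average"`).
#' @return object of class `haplotype_grouping`: list with `labels` (named
#'   integer vector), `k`, `hclust`, `dist` and `region_snps`.
#' @export
cluster_haplotypes <- function(region, k = 2, h = NULL,
                               linkage = "average") {
  mat <- if (is.character(region)) {
    m <- matrix(NA_real_, nrow(region), ncol(region),
                dimnames = dimnames(region))
    m[region == "A"] <- 0; m[region == "B"] <- 1
    m
  } else {
    m <- region; storage.mode(m) <- "double"; m
  }
  if (nrow(mat) < 2L) stop("need at least 2 lines", call. = FALSE)
  if (ncol(mat) < 1L) stop("need at least 1 SNP", call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("L%03d", seq_len(nrow(mat)))
  dm <- hamming_distance(mat)
  if (is.null(h) && k > 1 && max(dm) < 1e-12)
    stop("lines are too similar to form ", k, " clusters", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  labels <- if (!is.null(h)) stats::cutree(hc, h = h) else
    stats::cutree(hc, k = k)
  if (is.null(h) && length(unique(labels)) < k)
    stop("lines are too similar to form ", k, " clusters", call. = FALSE)
  labels <- canonical_labels(labels)
  structure(list(labels = labels, k = length(unique(labels)), hclust = hc,
                 dist = dm, region_snps = attr(region, "snps")),
            class = "haplotype_grouping")
}

## pairwise normalized Hamming distance over shared non-missing sites
hamming_distance <- function(mat) {
  obs <- !is.na(mat)
  m0 <- mat
  m0[!obs] <- 0
  shared <- tcrossprod(obs * 1)                  # sites both observed
  same11 <- tcrossprod(m0 * obs)                 # both B
  same00 <- tcrossprod((1 - m0) * obs)           # both A
  diffs <- shared - same11 - same00
  d <- ifelse(shared > 0, diffs / shared, 0.5)
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

canonical_labels <- function(labels) {
  sizes <- table(labels)
  firsts <- vapply(names(sizes), function(l)
    min(names(labels)[labels == l]), character(1))
  ord <- order(-as.integer(sizes), firsts)
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- remap[as.character(labels)]
  names(out) <- names(labels)
  out
}

#' @export
print.haplotype_grouping <- function(x, ...) {
  cat("Haplotype grouping:", length(x$labels), "lines in", x$k,
      "cluster(s); sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Write a haplotype dendrogram in newick format
#'
#' @param grouping a [cluster_haplotypes()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram <- function(grouping, path) {
  phy <- ape::as.phylo(grouping$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Trait statistics by haplotype group
#'
#' One-way ANOVA of the trait across haplotype clusters plus pairwise
#' Welch t-tests; groups with fewer than 2 lines are excluded with a
#' warning.  Group means are also formatted `mean +/- SD`.
#'
#' @param grouping a [cluster_haplotypes()] result (or a named label
#'   vector).
#' @param values named numeric trait vector over (a superset of) the
#'   clustered lines.
#' @return list with `groups` (data.frame `cluster, n, mean, sd, label`),
#'   `anova_p`, `anova_f` and `pairwise` (data.frame of Welch tests).
#' @export
trait_by_haplotype <- function(grouping, values) {
  labels <- if (inherits(grouping, "haplotype_grouping")) grouping$labels
  else grouping
  common <- intersect(names(labels), names(values))
  labels <- labels[common]
  v <- as.numeric(values[common])
  names(v) <- common
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding cluster(s) with fewer than 2 lines: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% as.integer(small))
    labels <- labels[keep]; v <- v[keep]
  }
  if (length(unique(labels)) < 2L)
    stop("need at least two clusters with >= 2 lines each", call. = FALSE)
  groups <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    vi <- v[labels == l]
    data.frame(cluster = l, n = length(vi), mean = mean(vi),
               sd = stats::sd(vi),
               label = sprintf("%.2f ± %.1f", mean(vi), stats::sd(vi)),
               stringsAsFactors = FALSE)
  }))
  av <- stats::anova(stats::lm(v ~ factor(labels)))
  cl <- sort(unique(labels))
  pw <- do.call(rbind, lapply(utils::combn(seq_along(cl), 2, simplify = FALSE),
                              function(ij) {
    a <- v[labels == cl[ij[1L]]]; b <- v[labels == cl[ij[2L]]]
    tt <- stats::t.test(a, b)          # Welch, two-sided
    data.frame(cluster1 = cl[ij[1L]], cluster2 = cl[ij[2L]],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(groups = groups, anova_f = av$`F value`[1L], anova_p = av$`Pr(>F)`[1L],
       pairwise = pw)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two clusterings of the same items, corrected for
#' chance; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b cluster label vectors of equal length (matched by name when
#'   both are named).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
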