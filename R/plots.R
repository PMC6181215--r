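## Base-graphics diagnostic plots: bin mosaic, LOD tracks, Manhattan / QQ.

#' Bin-map mosaic plot
#'
#' Lines (rows) by genomic position (columns), coloured by parent of
#' origin: A = orange, B = blue, undetermined = grey -- the classic RIL
#' mosaic view of a bin map.
#'
#' @param bm a [build_bins()] result.
#' @param chrom chromosome to draw (default: first).
#' @param ... passed to [graphics::image()].
#' @export
plot_bin_mosaic <- function(bm, chrom = NULL, ...) {
  stopifnot(inherits(bm, "bin_map"))
  if (is.null(chrom)) chrom <- bm$bins$chrom[1L]
  sel <- bm$bins$chrom == chrom
  g <- bm$geno[, sel, drop = FALSE]
  z <- matrix(0L, nrow(g), ncol(g))
  z[g == "A"] <- 1L
  z[g == "B"] <- 2L
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)), z = t(z),
                  col = c("grey85", "darkorange", "steelblue"),
                  xlab = paste("bin index, chromosome", chrom),
                  ylab = "line", ...)
  invisible(NULL)
}

#' LOD track plot for a QTL scan
#'
#' @param scan a `qtl_scan`.
#' @param threshold optional LOD threshold drawn as a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @export
plot_lod <- function(scan, threshold = NULL, ...) {
  stopifnot(inherits(scan, "qtl_scan"))
  res <- scan$result
  chroms <- unique(res$chrom)
  offset <- 0
  xs <- numeric(nrow(res))
  for (cc in chroms) {
    i <- res$chrom == cc
    xs[i] <- res$cm[i] + offset
    offset <- max(xs[i]) + 5
  }
  graphics::plot(xs, res$lod, type = "l", xlab = "position (cM, concatenated)",
                 ylab = "LOD", main = scan$trait, ...)
  if (!is.null(threshold)) {
    if (inherits(threshold, "permutation_threshold"))
      threshold <- threshold$threshold
    graphics::abline(h = threshold, lty = 2, col = "red")
  }
  invisible(NULL)
}

#' Manhattan and QQ plots for GWAS results
#'
#' @param gw a `gwas_result`.
#' @param threshold optional p-value threshold (e.g.
#'   [bonferroni_threshold()]) drawn as a line at `-log10(threshold)`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(gw, threshold = NULL, ...) {
  stopifnot(inherits(gw, "gwas_result"))
  res <- gw$result
  chroms <- unique(res$chrom)
  col <- grDevices::adjustcolor(c("grey30", "steelblue"), 0.7)
  xs <- seq_len(nrow(res))
  ci <- match(res$chrom, chroms)
  graphics::plot(xs, -log10(res$p), pch = 16, cex = 0.5,
                 col = col[1 + ci %% 2], xlab = "SNP index",
                 ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  invisible(NULL)
}

#' @rdname plot_manhattan
#' @export
plot_qq <- function(gw, ...) {
  stopifnot(inherits(gw, "gwas_result"))
  p <- sort(gw$result$p)
  exp_p <- stats::ppoints(length(p))
  graphics::plot(-log10(exp_p), -log10(p), pch = 16, cex = 0.5,
                 xlab = expression(expected - log[10](p)),
                 ylab = expression(observed - log[10](p)), ...)
  graphics::abline(0, 1, col = "red")
  invisible(NULL)
}
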