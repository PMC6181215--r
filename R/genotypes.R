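#' Parent-coded genotype observations
#'
#' Container for per-line, per-SNP skim calls coded by parent of origin:
#' `A` (Williams-82-type allele), `B` (PI-type allele) or missing.  Calls
#' are stored as an integer matrix (0 = A, 1 = B, `NA` = missing) with SNPs
#' sorted by chromosome and position.
#'
#' @param calls lines x SNPs matrix, either integer 0/1/`NA` or character
#'   `"A"`/`"B"`/`NA`.
#' @param snps data.frame with columns `chrom`, `pos` (1-based bp), one row
#'   per column of `calls`, sorted within chromosome.
#' @param lines character vector of line identifiers (defaults to
#'   `rownames(calls)`).
#' @return an object of class `ab_genotypes`.
#' @export
ab_genotypes <- function(calls, snps, lines = rownames(calls)) {
  stopifnot(is.matrix(calls), is.data.frame(snps),
            all(c("chrom", "pos") %in% names(snps)),
            ncol(calls) == nrow(snps))
  if (is.character(calls)) {
    m <- matrix(NA_integer_, nrow(calls), ncol(calls))
    m[calls == "A"] <- 0L
    m[calls == "B"] <- 1L
    bad <- !is.na(calls) & !(calls %in% c("A", "B"))
    if (any(bad)) stop("calls must be 'A', 'B' or NA", call. = FALSE)
    calls <- m
  }
  storage.mode(calls) <- "integer"
  if (any(!is.na(calls) & !(calls %in% c(0L, 1L))))
    stop("integer calls must be 0 (A), 1 (B) or NA", call. = FALSE)
  if (is.null(lines)) lines <- sprintf("L%03d", seq_len(nrow(calls)))
  snps$chrom <- as.character(snps$chrom)
  o <- order(match(snps$chrom, unique(snps$chrom)), snps$pos)
  if (any(o != seq_along(o))) {
    snps <- snps[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  if (any(stats::ave(snps$pos, snps$chrom, FUN = function(p) c(1, diff(p))) <= 0))
    stop("SNP positions must be strictly increasing within a chromosome",
         call. = FALSE)
  dimnames(calls) <- list(lines, paste(snps$chrom, snps$pos, sep = "_"))
  rownames(snps) <- NULL
  structure(list(calls = calls, snps = snps, lines = lines),
            class = "ab_genotypes")
}

#' @export
print.ab_genotypes <- function(x, ...) {
  cat("Parent-coded genotypes: ", length(x$lines), " lines x ",
      nrow(x$snps), " SNPs on ", length(unique(x$snps$chrom)),
      " chromosome(s); ", sprintf("%.1f%%", 100 * mean(is.na(x$calls))),
      " missing\n", sep = "")
  invisible(x)
}

#' Filter SNPs by minor allele frequency, then lines by missingness
#'
#' Two-step filter applied in a fixed order: (1) SNPs whose minor allele
#' frequency, computed over non-missing calls only, falls below `maf_min`
#' are removed (SNPs with no calls at all are removed too); (2) lines whose
#' missing-call fraction over the retained SNPs is `>= line_missing_max`
#' are removed.
#'
#' @param g an [ab_genotypes()] object.
#' @param maf_min minimum minor allele frequency to retain a SNP
#'   (default 0.2).
#' @param line_missing_max lines with missing fraction at or above this
#'   value are dropped (default 1, i.e. no line filtering; the skim design
#'   this package targets used 0.05 on per-line SNP coverage).
#' @return a filtered `ab_genotypes` object with attributes
#'   `n_snps_removed` and `n_lines_removed`.
#' @export
filter_snps <- function(g, maf_min = 0.2, line_missing_max = 1) {
  stopifnot(inherits(g, "ab_genotypes"))
  if (maf_min < 0 || maf_min > 1 || line_missing_max < 0 || line_missing_max > 1)
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  f <- colMeans(g$calls == 1L, na.rm = TRUE)       # B-allele frequency
  maf <- pmin(f, 1 - f)
  keep_snp <- !is.na(maf) & maf >= maf_min
  if (!any(keep_snp)) stop("no SNPs survive the MAF filter", call. = FALSE)
  calls <- g$calls[, keep_snp, drop = FALSE]
  miss <- rowMeans(is.na(calls))
  keep_line <- miss < line_missing_max
  if (!any(keep_line)) stop("no lines survive the missingness filter",
                            call. = FALSE)
  out <- ab_genotypes(calls[keep_line, , drop = FALSE],
                      g$snps[keep_snp, , drop = FALSE],
                      g$lines[keep_line])
  attr(out, "n_snps_removed") <- sum(!keep_snp)
  attr(out, "n_lines_removed") <- sum(!keep_line)
  out
}

#' Sliding-window genotype calling over observed skim calls
#'
#' For each line and chromosome, windows of `window_size` consecutive
#' *observed* (non-missing) calls are slid along the chromosome in steps of
#' `step` observed calls.  A window containing at least `homozygous_min`
#' A calls is called `A`, at least `homozygous_min` B calls `B`, and `U`
#' (undetermined) otherwise.  Window calls are anchored at the position of
#' the window's central observed SNP.  Chromosome ends with fewer than
#' `window_size` observed calls yield no windows; a line-chromosome with
#' fewer than `window_size` observed calls in total is reported entirely
#' undetermined, with a warning.
#'
#' The defaults (18-call windows, 12-call homozygosity rule) follow the
#' sliding-window genotyping rule of Huang et al. (2009) as applied to
#' skim-sequenced soybean RILs; at F7:8 residual heterozygosity is rare and
#' windows that satisfy neither homozygosity rule are left undetermined
#' rather than called heterozygous.
#'
#' @param g an [ab_genotypes()] object.
#' @param window_size number of observed calls per window (default 18).
#' @param homozygous_min minimum same-parent calls for a homozygous window
#'   call (default 12; must not exceed `window_size`).
#' @param step slide step in observed calls (default 1).
#' @return an object of class `window_track`: list with `tracks[[line]][[chrom]]`
#'   data.frames `(start_bp, center_bp, end_bp, call)`, plus the inputs'
#'   line/chromosome tables.
#' @export
call_windows <- function(g, window_size = 18, homozygous_min = 12, step = 1) {
  stopifnot(inherits(g, "ab_genotypes"))
  if (homozygous_min > window_size)
    stop("homozygous_min must not exceed window_size", call. = FALSE)
  if (window_size < 1 || step < 1) stop("window_size and step must be >= 1",
                                        call. = FALSE)
  chroms <- unique(g$snps$chrom)
  idx_by_chrom <- split(seq_len(nrow(g$snps)), g$snps$chrom)[chroms]
  ctr <- as.integer(floor((window_size - 1) / 2))   # 0-based central offset
  tracks <- vector("list", length(g$lines))
  names(tracks) <- g$lines
  n_short <- 0L
  for (i in seq_along(g$lines)) {
    per_chrom <- vector("list", length(chroms))
    names(per_chrom) <- chroms
    for (cc in chroms) {
      idx <- idx_by_chrom[[cc]]
      calls <- g$calls[i, idx]
      obs <- which(!is.na(calls))
      if (length(obs) < window_size) {
        if (length(obs) > 0L) n_short <- n_short + 1L
        per_chrom[[cc]] <- data.frame(start_bp = numeric(0),
                                      center_bp = numeric(0),
                                      end_bp = numeric(0),
                                      call = character(0),
                                      stringsAsFactors = FALSE)
        next
      }
      pos <- g$snps$pos[idx][obs]
      b <- calls[obs]                      # 0/1 over observed calls
      starts <- seq.int(1L, length(obs) - window_size + 1L, by = step)
      cs <- c(0L, cumsum(b))
      nB <- cs[starts + window_size] - cs[starts]
      nA <- window_size - nB
      call <- rep("U", length(starts))
      call[nA >= homozygous_min] <- "A"
      call[nB >= homozygous_min] <- "B"
      per_chrom[[cc]] <- data.frame(
        start_bp = pos[starts],
        center_bp = pos[starts + ctr],
        end_bp = pos[starts + window_size - 1L],
        call = call, stringsAsFactors = FALSE)
    }
    tracks[[i]] <- per_chrom
  }
  if (n_short > 0L)
    warning(n_short, " line-chromosome(s) had fewer than ", window_size,
            " observed calls and were left entirely undetermined")
  structure(list(tracks = tracks, lines = g$lines, chroms = chroms,
                 window_size = window_size, homozygous_min = homozygous_min,
                 step = step),
            class = "window_track")
}

#' Detect recombination breakpoints from window-call tracks
#'
#' A breakpoint is a transition between consecutive maximal runs of `A` and
#' `B` window calls along a chromosome.  Undetermined (`U`) windows between
#' the two runs widen the breakpoint interval but do not themselves emit
#' transitions, so a pattern `A..A U..U A..A` yields no breakpoint.  The
#' breakpoint interval is reported as
#' `(center of the last window of the left run, center of the first window
#' of the right run)`; the underlying crossover lies within it at the
#' resolution the window rule permits.
#'
#' @param track a [call_windows()] result.
#' @return object of class `breakpoint_set`: list with `breakpoints`, a
#'   data.frame `(line, chrom, left_bp, right_bp, from, to)` with intervals
#'   ordered and non-overlapping within each line-chromosome, and the input
#'   `tracks` (needed by [build_bins()] to genotype lines per bin).
#' @export
detect_breakpoints <- function(track) {
  stopifnot(inherits(track, "window_track"))
  rows <- list()
  for (ln in track$lines) {
    for (cc in track$chroms) {
      tr <- track$tracks[[ln]][[cc]]
      inf <- tr[tr$call != "U", , drop = FALSE]
      if (nrow(inf) < 2L) next
      rl <- rle(inf$call)
      if (length(rl$lengths) < 2L) next
      ends <- cumsum(rl$lengths)
      starts <- c(1L, ends[-length(ends)] + 1L)
      for (j in seq_len(length(rl$lengths) - 1L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          line = ln, chrom = cc,
          left_bp = inf$center_bp[ends[j]],
          right_bp = inf$center_bp[starts[j + 1L]],
          from = rl$values[j], to = rl$values[j + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  bp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line = character(), chrom = character(),
               left_bp = numeric(), right_bp = numeric(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  rownames(bp) <- NULL
  structure(list(breakpoints = bp, tracks = track),
            class = "breakpoint_set")
}

#' @export
print.breakpoint_set <- function(x, ...) {
  cat("Breakpoint set:", nrow(x$breakpoints), "breakpoints over",
      length(x$tracks$lines), "lines\n")
  invisible(x)
}

#' Build a population-level bin map from breakpoints
#'
#' Each chromosome is divided into a grid of `interval_bp` intervals (100
#' kb by default).  A grid interval is flagged recombinant when any line's
#' breakpoint interval overlaps it.  Intervals lacking recombination in the
#' entire population are merged: bin boundaries are placed at the start of
#' every maximal run of recombinant grid intervals, so a single isolated
#' breakpoint splits the chromosome into exactly two bins.  Each line's bin
#' genotype is the majority window call over the bin (`A`/`B`), or `U` when
#' the line's informative calls within the bin tie or are absent; a line
#' whose own breakpoint falls in the bin's recombinant head is thus
#' assigned the parent covering most of the bin.
#'
#' @param bset a [detect_breakpoints()] result.
#' @param map a [genmap_spec()] giving chromosome lengths.
#' @param interval_bp grid resolution in bp (default 100000).
#' @return object of class `bin_map`: list with `bins`, a data.frame
#'   `(chrom, start, end, bin_id)` using 0-based half-open coordinates and
#'   ids `bin_<chrom>_<start+1>`, and `geno`, a lines x bins character
#'   matrix in `{A, B, U}`.
#' @export
build_bins <- function(bset, map, interval_bp = 1e5) {
  stopifnot(inherits(bset, "breakpoint_set"), inherits(map, "genmap_spec"))
  track <- bset$tracks
  bp <- bset$breakpoints
  bins_list <- list()
  for (cc in track$chroms) {
    len <- map$chromosomes$length_bp[map$chromosomes$chrom == cc]
    edges <- seq(0, len, by = interval_bp)
    if (edges[length(edges)] < len) edges <- c(edges, len)
    n_int <- length(edges) - 1L
    recomb <- rep(FALSE, n_int)
    bpc <- bp[bp$chrom == cc, , drop = FALSE]
    if (nrow(bpc)) {
      for (j in seq_len(nrow(bpc))) {
        # grid intervals [edges[k], edges[k+1]) overlapping the open
        # breakpoint interval (left_bp, right_bp)
        lo <- max(1L, findInterval(bpc$left_bp[j], edges))
        hi <- min(n_int, findInterval(bpc$right_bp[j], edges,
                                      left.open = TRUE))
        if (hi < lo) hi <- lo
        recomb[lo:hi] <- TRUE
      }
    }
    # new bin starts where a maximal recombinant run begins
    newbin <- recomb & !c(FALSE, recomb[-n_int])
    bin_idx <- cumsum(c(TRUE, newbin[-1L]))
    starts <- edges[which(!duplicated(bin_idx))]
    ends <- c(starts[-1L], len)
    bins_list[[cc]] <- data.frame(chrom = cc, start = starts, end = ends,
                                  stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bins_list)
  bins$bin_id <- sprintf("bin_%s_%d", bins$chrom, as.integer(bins$start) + 1L)
  rownames(bins) <- NULL
  geno <- matrix("U", length(track$lines), nrow(bins),
                 dimnames = list(track$lines, bins$bin_id))
  for (i in seq_along(track$lines)) {
    for (cc in track$chroms) {
      tr <- track$tracks[[track$lines[i]]][[cc]]
      brows <- which(bins$chrom == cc)
      if (nrow(tr) == 0L) next
      geno[i, brows] <- vapply(brows, function(b) {
        bin_call(tr, bins$start[b], bins$end[b])
      }, character(1))
    }
  }
  structure(list(bins = bins, geno = geno, interval_bp = interval_bp),
            class = "bin_map")
}

## genotype of one line in one bin from its window track: the majority
## informative window call centred in [start, end); ties are undetermined.
## A line transitioning inside the bin's recombinant head is therefore
## assigned the parent covering most of the bin (a strict "undetermined
## when the line's breakpoint overlaps the bin" rule would zero out every
## adjacent-bin recombination fraction and degenerate the linkage map).
## If no window is centred inside the bin, agreeing flanking calls are
## used.
bin_call <- function(tr, start, end) {
  inside <- tr$call[tr$center_bp > start & tr$center_bp <= end]
  nA <- sum(inside == "A"); nB <- sum(inside == "B")
  if (nA > nB) return("A")
  if (nB > nA) return("B")
  if (nA > 0L) return("U")                 # tie
  # no informative window centred inside: use flanking calls
  left <- tr$call[tr$center_bp <= start]
  right <- tr$call[tr$center_bp > end]
  lv <- if (length(left)) left[length(left)] else NA_character_
  rv <- if (length(right)) right[1L] else NA_character_
  if (!is.na(lv) && !is.na(rv) && lv == rv && lv != "U") return(lv)
  if (is.na(lv) && !is.na(rv) && rv != "U") return(rv)
  if (is.na(rv) && !is.na(lv) && lv != "U") return(lv)
  "U"
}

#' @export
print.bin_map <- function(x, ...) {
  cat("Bin map:", nrow(x$bins), "bins over",
      length(unique(x$bins$chrom)), "chromosome(s);",
      nrow(x$geno), "lines\n")
  invisible(x)
}

#' Extract one representative marker per bin
#'
#' @param bm a [build_bins()] result.
#' @return list with `markers` (lines x bins character matrix in
#'   `{A, B, U}`, columns named `bin_<chrom>_<start>`), `positions`
#'   (data.frame `chrom`, `pos` = 1-based bin start, `marker`), and `bed`
#'   (0-based half-open bin intervals).
#' @export
bin_to_markers <- function(bm) {
  stopifnot(inherits(bm, "bin_map"))
  list(markers = bm$geno,
       positions = data.frame(chrom = bm$bins$chrom,
                              pos = as.integer(bm$bins$start) + 1L,
                              marker = bm$bins$bin_id,
                              stringsAsFactors = FALSE),
       bed = data.frame(chrom = bm$bins$chrom,
                        start = as.integer(bm$bins$start),
                        end = as.integer(bm$bins$end),
                        name = bm$bins$bin_id,
                        stringsAsFactors = FALSE))
}
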