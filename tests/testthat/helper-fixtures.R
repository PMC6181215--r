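# shared fixture builders (everything is generated in code; no data files)

# ab_genotypes from a character matrix given as strings, e.g.
# make_ab(c("AABB", "A.BB")) -> 2 lines x 4 SNPs ('.' = missing)
make_ab <- function(rows, chrom = "1", pos = NULL) {
  mat <- do.call(rbind, strsplit(rows, ""))
  mat[mat == "."] <- NA
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 1000L
  ab_genotypes(mat, data.frame(chrom = chrom, pos = pos),
               sprintf("L%02d", seq_len(nrow(mat))))
}

# a window_track built by hand: `calls` is a character vector per line,
# window centres at 1000 * seq_along
make_track <- function(calls_by_line, chrom = "1", centers = NULL) {
  lines <- names(calls_by_line)
  if (is.null(lines)) {
    lines <- sprintf("L%02d", seq_along(calls_by_line))
    names(calls_by_line) <- lines
  }
  tracks <- lapply(calls_by_line, function(cl) {
    cl <- strsplit(cl, "")[[1]]
    ctr <- if (is.null(centers)) seq_along(cl) * 1000 else centers
    tr <- data.frame(start_bp = ctr - 500, center_bp = ctr,
                     end_bp = ctr + 500, call = cl,
                     stringsAsFactors = FALSE)
    stats::setNames(list(tr), chrom)
  })
  structure(list(tracks = tracks, lines = lines, chroms = chrom,
                 window_size = 18, homozygous_min = 12, step = 1),
            class = "window_track")
}

# a breakpoint_set built directly from a data.frame of intervals plus a
# window track (for build_bins genotyping)
make_bset <- function(breakpoints, track) {
  structure(list(breakpoints = breakpoints, tracks = track),
            class = "breakpoint_set")
}

# map spec with evenly spaced SNPs
make_map <- function(n_chrom = 1, length_bp = 1e7, length_cm = 100,
                     n_snps = 100) {
  chroms <- as.character(seq_len(n_chrom))
  pos <- round(seq(1e3, length_bp - 1e3, length.out = n_snps))
  genmap_spec(data.frame(chrom = chroms, length_bp = length_bp,
                         length_cm = length_cm),
              stats::setNames(rep(list(pos), n_chrom), chroms))
}

# character A/B/U marker matrix from true RIL genotypes
geno_to_markers <- function(geno) {
  m <- matrix("U", nrow(geno), ncol(geno), dimnames = dimnames(geno))
  m[geno == 0L] <- "A"
  m[geno == 2L] <- "B"
  m
}
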