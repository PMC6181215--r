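#' Genetic map specification
#'
#' Describes the genome on which populations are simulated and analysed:
#' chromosome physical and genetic lengths plus SNP coordinates.  Physical
#' (bp) and genetic (cM) scales are related by linear interpolation along
#' each chromosome, i.e. a locally uniform recombination rate.
#'
#' @param chromosomes data.frame with columns `chrom` (identifier),
#'   `length_bp` (physical length) and `length_cm` (genetic length, may be 0
#'   for a non-recombining chromosome).
#' @param snp_positions named list, one sorted integer vector of 1-based bp
#'   coordinates per chromosome; at least two SNPs per chromosome, strictly
#'   increasing.
#' @param mapping_function `"kosambi"` (default) or `"haldane"`; used
#'   downstream when converting genetic distances to recombination
#'   probabilities.
#' @return an object of class `genmap_spec`.
#' @seealso [simulate_ril_genomes()], [default_scenario()]
#' @export
genmap_spec <- function(chromosomes, snp_positions,
                        mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp", "length_cm") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicate chromosome ids", call. = FALSE)
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cm < 0))
    stop("chromosome lengths must be positive (genetic length may be 0)",
         call. = FALSE)
  if (!setequal(names(snp_positions), chromosomes$chrom))
    stop("snp_positions must be a named list matching `chromosomes$chrom`",
         call. = FALSE)
  for (cc in chromosomes$chrom) {
    p <- snp_positions[[cc]]
    if (length(p) < 2L)
      stop("chromosome ", cc, ": need at least 2 SNPs", call. = FALSE)
    if (any(diff(p) <= 0))
      stop("chromosome ", cc, ": SNP positions must be strictly increasing",
           call. = FALSE)
    if (p[1L] < 1L || p[length(p)] > chromosomes$length_bp[chromosomes$chrom == cc])
      stop("chromosome ", cc, ": SNP positions outside chromosome",
           call. = FALSE)
  }
  structure(list(chromosomes = chromosomes,
                 snp_positions = lapply(snp_positions, as.numeric),
                 mapping_function = mapping_function),
            class = "genmap_spec")
}

#' @export
print.genmap_spec <- function(x, ...) {
  cat("Genetic map:", nrow(x$chromosomes), "chromosome(s),",
      sum(lengths(x$snp_positions)), "SNPs,",
      round(sum(x$chromosomes$length_cm), 1), "cM /",
      round(sum(x$chromosomes$length_bp) / 1e6, 1), "Mb,",
      x$mapping_function, "mapping function\n")
  invisible(x)
}

## bp <-> cM by linear interpolation within a chromosome
bp_to_cm <- function(map, chrom, bp) {
  i <- match(chrom, map$chromosomes$chrom)
  bp * map$chromosomes$length_cm[i] / map$chromosomes$length_bp[i]
}

cm_to_bp <- function(map, chrom, cm) {
  i <- match(chrom, map$chromosomes$chrom)
  if (map$chromosomes$length_cm[i] == 0) return(rep(NA_real_, length(cm)))
  cm * map$chromosomes$length_bp[i] / map$chromosomes$length_cm[i]
}

## SNP table in (chrom, pos) order
snp_table <- function(map) {
  chroms <- map$chromosomes$chrom
  data.frame(
    chrom = rep(chroms, lengths(map$snp_positions[chroms])),
    pos = unlist(map$snp_positions[chroms], use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
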