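## Text I/O for the pipeline's standard formats: parent-coded VCF,
## tidy phenotype TSV, marker matrix TSV, bin BED and breakpoint TSV.

#' Write parent-coded genotypes as VCF
#'
#' One sample per line; the Williams-82-type A allele is REF, the PI-type B
#' allele is ALT, calls are emitted as `0/0`, `1/1` or `./.` in the GT
#' field.  REF/ALT bases are placeholders (`A`/`T`): only parent-of-origin
#' information is meaningful for this design.
#'
#' @param g an [ab_genotypes()] object.
#' @param path output file (`.vcf`).
#' @return the path, invisibly.
#' @export
write_ab_vcf <- function(g, path) {
  stopifnot(inherits(g, "ab_genotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=skimqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(g$snps$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$lines), collapse = "\t")), con)
  gt <- matrix("./.", nrow(g$snps), length(g$lines))
  calls <- t(g$calls)
  gt[calls == 0L & !is.na(calls)] <- "0/0"
  gt[calls == 1L & !is.na(calls)] <- "1/1"
  body <- paste(g$snps$chrom, g$snps$pos,
                paste0(g$snps$chrom, "_", g$snps$pos),
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a parent-coded VCF
#'
#' Reads GT calls with `VariantAnnotation` and maps homozygous REF to A,
#' homozygous ALT to B and anything else (missing or heterozygous) to
#' missing.
#'
#' @param path a VCF file as written by [write_ab_vcf()] (or any
#'   GT-bearing VCF of a biparental homozygous population).
#' @return an [ab_genotypes()] object.
#' @export
read_ab_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_ab_vcf() requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  snps <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), stringsAsFactors = FALSE)
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt))
  tg <- t(gt)
  calls[tg %in% c("0/0", "0|0")] <- 0L
  calls[tg %in% c("1/1", "1|1")] <- 1L
  ab_genotypes(calls, snps, colnames(gt))
}

#' Phenotype, marker, breakpoint and BED text I/O
#'
#' Plain TSV writers/readers for the pipeline's tables: tidy phenotypes
#' `(line, trait, environment, replicate, value)`, bin marker matrices
#' (lines x markers, `A`/`B`/`U`), breakpoints and BED bin boundaries
#' (0-based half-open).
#'
#' @param x the object to write (see details).
#' @param path file path.
#' @return writers return the path invisibly; readers return the parsed
#'   object.
#' @name skimqtl-io
NULL

#' @rdname skimqtl-io
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname skimqtl-io
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(line = "character",
                                   environment = "character"))
}

#' @rdname skimqtl-io
#' @export
write_markers <- function(x, path) {
  m <- if (is.list(x) && !is.null(x$markers)) x$markers else x
  df <- data.frame(line = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname skimqtl-io
#' @export
read_markers <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$line
  m
}

#' @rdname skimqtl-io
#' @export
write_bed <- function(x, path) {
  bed <- if (is.list(x) && !is.null(x$bed)) x$bed else x
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname skimqtl-io
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "name")[seq_len(min(4, ncol(df)))]
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname skimqtl-io
#' @export
write_breakpoints <- function(x, path) {
  bp <- if (inherits(x, "breakpoint_set")) x$breakpoints else x
  utils::write.table(bp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname skimqtl-io
#' @export
write_scan <- function(x, path) {
  res <- if (inherits(x, "qtl_scan")) x$result else x
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
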