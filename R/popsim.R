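#' Pedigree parameters for a single-seed-descent RIL population
#'
#' @param n_lines number of recombinant inbred lines (>= 2).
#' @param generation F-generation at which lines are genotyped; the default
#'   8 corresponds to an F7:8 population, i.e. seven rounds of selfing from
#'   the F1, leaving expected residual heterozygosity of `(1/2)^7` per locus.
#' @return an object of class `pedigree_params`.
#' @export
pedigree_params <- function(n_lines = 188, generation = 8) {
  if (n_lines < 2) stop("n_lines must be >= 2", call. = FALSE)
  if (generation < 2) stop("generation must be >= 2 (F1 carries no fixed recombination)",
                           call. = FALSE)
  structure(list(n_lines = as.integer(n_lines),
                 generation = as.integer(generation)),
            class = "pedigree_params")
}

#' Skim-coverage observation model
#'
#' Call-level emulation of low-coverage resequencing: each SNP in each line
#' is observed independently with probability `observation_rate` (at ~0.3x
#' coverage most sites are covered by at most one read), and an observed
#' call is flipped to the other parental allele with probability
#' `error_rate`.  Heterozygous sites, when present, yield one of the two
#' alleles with equal probability, as a single sequencing read would.
#'
#' @param observation_rate probability in `[0,1]` that a SNP yields any call.
#' @param error_rate probability in `[0,1]` that an observed call is flipped.
#' @return an object of class `skim_model`.
#' @export
skim_model <- function(observation_rate = 0.3, error_rate = 0.005) {
  if (observation_rate < 0 || observation_rate > 1 ||
      error_rate < 0 || error_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(observation_rate = observation_rate,
                 error_rate = error_rate),
            class = "skim_model")
}

#' Trait specification for the phenotype simulator
#'
#' @param name trait name.
#' @param mu overall trait mean (per cent for composition traits).
#' @param qtl data.frame with columns `chrom`, `pos`, `effect`: planted
#'   additive QTL.  The effect is the coefficient on the `{-1, 0, +1}`
#'   genotype score, so the two homozygote classes differ by `2 * effect`
#'   and a positive effect means the PI-type (B) allele raises the trait.
#' @param var_g_residual polygenic line variance not attributable to the
#'   planted QTL.
#' @param var_ge genotype-by-environment interaction variance.
#' @param var_e residual (within-plot) error variance.
#' @return an object of class `trait_spec`.
#' @export
trait_spec <- function(name, mu = 0, qtl = NULL, var_g_residual = 0,
                       var_ge = 0, var_e = 1) {
  if (!is.null(qtl)) {
    stopifnot(is.data.frame(qtl),
              all(c("chrom", "pos", "effect") %in% names(qtl)))
    qtl$chrom <- as.character(qtl$chrom)
  }
  if (var_g_residual < 0 || var_ge < 0 || var_e < 0)
    stop("variance components must be >= 0", call. = FALSE)
  structure(list(name = name, mu = mu, qtl = qtl,
                 var_g_residual = var_g_residual, var_ge = var_ge,
                 var_e = var_e),
            class = "trait_spec")
}

#' Multi-environment phenotype model
#'
#' Balanced multi-environment trial: every line is observed in every
#' environment and replicate.  Environments act as fixed shifts; the random
#' part of each trait follows
#' `y = mu + env + sum(a_q x_q) + g(line) + ge(line, env) + e`, matching the
#' two-way ANOVA with replication used by [anova_components()].
#'
#' @param traits list of [trait_spec()] objects.
#' @param n_environments,n_replicates balanced design dimensions (>= 1).
#' @param env_effects optional numeric vector of fixed environment effects
#'   (length `n_environments`); default is a centred unit-spaced sequence.
#' @param mendelian_locus optional `list(chrom =, pos =)` of a fully
#'   penetrant binary locus (seed-coat analogue): lines homozygous for the
#'   B (PI-type) allele at the nearest SNP score 1, all others 0.
#' @param mendelian_name trait name for the binary trait.
#' @return an object of class `phenotype_model`.
#' @export
phenotype_model <- function(traits, n_environments = 4, n_replicates = 2,
                            env_effects = NULL, mendelian_locus = NULL,
                            mendelian_name = "seed_coat") {
  stopifnot(is.list(traits), length(traits) >= 1,
            all(vapply(traits, inherits, TRUE, "trait_spec")))
  if (n_environments < 1 || n_replicates < 1)
    stop("need at least one environment and one replicate (balanced design)",
         call. = FALSE)
  if (is.null(env_effects))
    env_effects <- seq_len(n_environments) - (n_environments + 1) / 2
  if (length(env_effects) != n_environments)
    stop("env_effects must have length n_environments", call. = FALSE)
  structure(list(traits = traits,
                 n_environments = as.integer(n_environments),
                 n_replicates = as.integer(n_replicates),
                 env_effects = env_effects,
                 mendelian_locus = mendelian_locus,
                 mendelian_name = mendelian_name),
            class = "phenotype_model")
}

## ---- haplotype mosaics ----------------------------------------------------
## A haplotype is a step function along one chromosome (cM scale):
## list(breaks = interior change points, origins = parental origin 0/1 per
## segment, length(origins) == length(breaks) + 1).

hap_pure <- function(origin) list(breaks = numeric(0), origins = origin)

hap_origin_at <- function(h, cm) {
  h$origins[findInterval(cm, h$breaks) + 1L]
}

hap_simplify <- function(h) {
  if (length(h$breaks) == 0L) return(h)
  keep <- diff(h$origins) != 0L
  list(breaks = h$breaks[keep], origins = h$origins[c(TRUE, keep)])
}

## One meiosis under the count-location model: crossover count is
## Poisson(genetic length in Morgans), positions uniform on the cM scale,
## no interference.  Returns a single recombinant gamete.
meiosis <- function(h1, h2, length_cm) {
  ncx <- if (length_cm > 0) stats::rpois(1L, length_cm / 100) else 0L
  start <- sample.int(2L, 1L)
  if (ncx == 0L) return(if (start == 1L) h1 else h2)
  cx <- sort(stats::runif(ncx, 0, length_cm))
  breaks <- sort(unique(c(h1$breaks, h2$breaks, cx)))
  mids <- (c(0, breaks) + c(breaks, length_cm)) / 2
  active <- 1L + (start - 1L + findInterval(mids, cx)) %% 2L
  o1 <- hap_origin_at(h1, mids)
  o2 <- hap_origin_at(h2, mids)
  hap_simplify(list(breaks = breaks, origins = ifelse(active == 1L, o1, o2)))
}

#' Simulate a single-seed-descent RIL population
#'
#' Starting from the F1 of a biparental cross (one chromosome from each
#' parent), each line is advanced by `generation - 1` rounds of selfing,
#' with both gametes of every meiosis drawn under a Poisson count-location
#' crossover model (rate = genetic length in Morgans, positions uniform in
#' cM, no interference).  The pedigree is simulated explicitly so that true
#' recombination breakpoints are available for validating the
#' breakpoint-detection pipeline.
#'
#' @param map a [genmap_spec()].
#' @param ped a [pedigree_params()].
#' @param seed optional integer seed.
#' @return an object of class `ril_sim`: a list with
#' \describe{
#'   \item{geno}{integer matrix (lines x SNPs) of B-allele dosage: 0 =
#'     Williams-82-type (A) homozygote, 2 = PI-type (B) homozygote,
#'     1 = residual heterozygote.}
#'   \item{snps}{data.frame `(chrom, pos)` in map order.}
#'   \item{crossovers}{data.frame of true genotype junctions per line:
#'     `(line, chrom, left_bp, right_bp, pos)` where `left_bp`/`right_bp`
#'     are the last/first homozygous SNPs flanking the transition and `pos`
#'     is the interval midpoint.  Transitions bridged by a residual
#'     heterozygous tract are reported as a single junction spanning it.}
#'   \item{map, ped}{the inputs.}
#' }
#' @export
simulate_ril_genomes <- function(map, ped, seed = NULL) {
  stopifnot(inherits(map, "genmap_spec"), inherits(ped, "pedigree_params"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- map$chromosomes$chrom
  lens_cm <- map$chromosomes$length_cm
  lens_bp <- map$chromosomes$length_bp
  lines <- sprintf("RIL%03d", seq_len(ped$n_lines))
  snps <- snp_table(map)
  nsnp <- nrow(snps)
  geno <- matrix(NA_integer_, ped$n_lines, nsnp,
                 dimnames = list(lines, paste(snps$chrom, snps$pos, sep = "_")))
  col_off <- c(0L, cumsum(lengths(map$snp_positions[chroms])))
  for (i in seq_len(ped$n_lines)) {
    for (ci in seq_along(chroms)) {
      h1 <- hap_pure(0L); h2 <- hap_pure(1L)
      for (t in seq_len(ped$generation - 1L)) {
        n1 <- meiosis(h1, h2, lens_cm[ci])
        n2 <- meiosis(h1, h2, lens_cm[ci])
        h1 <- n1; h2 <- n2
      }
      pos_cm <- map$snp_positions[[chroms[ci]]] * lens_cm[ci] / lens_bp[ci]
      geno[i, (col_off[ci] + 1L):col_off[ci + 1L]] <-
        hap_origin_at(h1, pos_cm) + hap_origin_at(h2, pos_cm)
    }
  }
  structure(list(geno = geno, snps = snps,
                 crossovers = true_junctions(geno, snps, lines),
                 map = map, ped = ped),
            class = "ril_sim")
}

## Genotype-level junctions: transitions between homozygous A and B runs,
## heterozygous sites treated as gaps that widen the reported interval.
true_junctions <- function(geno, snps, lines) {
  out <- vector("list", length(lines) * length(unique(snps$chrom)))
  k <- 0L
  for (cc in unique(snps$chrom)) {
    idx <- which(snps$chrom == cc)
    pos <- snps$pos[idx]
    for (i in seq_along(lines)) {
      g <- geno[i, idx]
      hom <- which(g != 1L)
      if (length(hom) < 2L) next
      gh <- g[hom]
      ch <- which(diff(gh) != 0L)
      if (length(ch) == 0L) next
      k <- k + 1L
      out[[k]] <- data.frame(
        line = lines[i], chrom = cc,
        left_bp = pos[hom[ch]], right_bp = pos[hom[ch + 1L]],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(line = character(), chrom = character(),
                      left_bp = numeric(), right_bp = numeric(),
                      pos = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res$pos <- (res$left_bp + res$right_bp) / 2
  rownames(res) <- NULL
  res
}

#' @export
print.ril_sim <- function(x, ...) {
  cat("RIL simulation: ", nrow(x$geno), " F", x$ped$generation,
      " lines x ", ncol(x$geno), " SNPs, ",
      nrow(x$crossovers), " true junctions, residual het ",
      sprintf("%.2f%%", 100 * mean(x$geno == 1L)), "\n", sep = "")
  invisible(x)
}

#' Apply the skim-coverage observation model to true genotypes
#'
#' Converts true genotypes into sparse, noisy parent-coded calls: each
#' SNP-by-line entry is missing with probability
#' `1 - observation_rate`; observed homozygous sites yield the parental
#' allele, flipped with probability `error_rate`; observed heterozygous
#' sites yield either allele with equal probability (a single read cannot
#' detect heterozygosity).
#'
#' @param sim a `ril_sim` object (or an integer dosage matrix with a
#'   matching `snps` data.frame supplied via `snps`).
#' @param model a [skim_model()].
#' @param seed optional integer seed (deterministic output under a fixed
#'   seed).
#' @param snps SNP table when `sim` is a bare matrix.
#' @return an [ab_genotypes()] object.
#' @export
observe_skim <- function(sim, model, seed = NULL, snps = NULL) {
  stopifnot(inherits(model, "skim_model"))
  if (inherits(sim, "ril_sim")) {
    geno <- sim$geno; snps <- sim$snps
  } else {
    geno <- sim
    if (is.null(snps)) stop("supply `snps` with a bare genotype matrix",
                            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(geno)
  observed <- stats::runif(n) < model$observation_rate
  allele <- geno / 2                       # 0 or 1 for homozygotes
  het <- geno == 1L
  if (any(het)) allele[het] <- stats::rbinom(sum(het), 1L, 0.5)
  flip <- stats::runif(n) < model$error_rate
  calls <- matrix(as.integer(ifelse(observed, ifelse(flip, 1 - allele, allele), NA)),
                  nrow(geno), ncol(geno), dimnames = dimnames(geno))
  ab_genotypes(calls, snps, rownames(geno))
}

#' Simulate balanced multi-environment phenotypes
#'
#' Generates `y_ijk = mu + env_j + sum_q a_q x_iq + g_i + ge_ij + e_ijk` for
#' every continuous trait, with `x` the `{-1, 0, +1}` genotype score at the
#' SNP nearest each planted QTL, `g ~ N(0, var_g_residual)`,
#' `ge ~ N(0, var_ge)` and `e ~ N(0, var_e)`.  The optional Mendelian locus
#' produces a binary trait, constant over environments and replicates:
#' 1 for B-homozygous lines, 0 for A-homozygous lines, and missing for
#' lines still heterozygous at the locus (such lines segregate for the
#' trait and have no line-level phenotype).
#'
#' @param sim a `ril_sim` object.
#' @param model a [phenotype_model()].
#' @param seed optional integer seed.
#' @return tidy data.frame `(line, trait, environment, replicate, value)`,
#'   balanced by construction.
#' @export
simulate_phenotypes <- function(sim, model, seed = NULL) {
  stopifnot(inherits(sim, "ril_sim"), inherits(model, "phenotype_model"))
  if (!is.null(seed)) set.seed(seed)
  lines <- rownames(sim$geno)
  n <- length(lines)
  e <- model$n_environments
  r <- model$n_replicates
  envs <- sprintf("env%d", seq_len(e))
  out <- list()
  for (tr in model$traits) {
    genetic <- rep(0, n)
    if (!is.null(tr$qtl) && nrow(tr$qtl) > 0) {
      for (q in seq_len(nrow(tr$qtl))) {
        j <- nearest_snp(sim$snps, tr$qtl$chrom[q], tr$qtl$pos[q])
        genetic <- genetic + tr$qtl$effect[q] * (sim$geno[, j] - 1)
      }
    }
    g <- stats::rnorm(n, 0, sqrt(tr$var_g_residual))
    ge <- matrix(stats::rnorm(n * e, 0, sqrt(tr$var_ge)), n, e)
    err <- array(stats::rnorm(n * e * r, 0, sqrt(tr$var_e)), c(n, e, r))
    for (j in seq_len(e)) for (k in seq_len(r)) {
      out[[length(out) + 1L]] <- data.frame(
        line = lines, trait = tr$name, environment = envs[j], replicate = k,
        value = tr$mu + model$env_effects[j] + genetic + g + ge[, j] + err[, j, k],
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(model$mendelian_locus)) {
    j <- nearest_snp(sim$snps, model$mendelian_locus$chrom,
                     model$mendelian_locus$pos)
    # lines still heterozygous at the locus segregate for the trait and
    # cannot be scored as a line-level binary: recorded as missing
    bin <- as.numeric(sim$geno[, j] == 2L)
    bin[sim$geno[, j] == 1L] <- NA
    for (jj in seq_len(e)) for (k in seq_len(r)) {
      out[[length(out) + 1L]] <- data.frame(
        line = lines, trait = model$mendelian_name, environment = envs[jj],
        replicate = k, value = bin, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

nearest_snp <- function(snps, chrom, pos) {
  idx <- which(snps$chrom == as.character(chrom))
  if (length(idx) == 0L)
    stop("QTL chromosome '", chrom, "' not on the map", call. = FALSE)
  idx[which.min(abs(snps$pos[idx] - pos))]
}

#' Default simulation scenario
#'
#' A ready-made scenario mirroring the interspecific soybean RIL design the
#' package targets: 188 F7:8 lines on 20 chromosomes, skim observation rate
#' 0.3 with 0.5\% call error, three seed-composition traits measured in 4
#' environments x 2 replicates, a pleiotropic protein/oil locus on
#' chromosome 20 with opposite-sign effects, a sucrose locus on chromosome
#' 8, and a fully penetrant binary seed-coat locus on chromosome 8.  SNP
#' density defaults to roughly one tenth of the ~91k-SNP full design
#' (457 SNPs per chromosome, evenly spaced) to keep test runtimes small;
#' pass `snps_per_chrom = 4567` for full density.
#'
#' @param n_lines,generation pedigree; defaults 188 F7:8 lines.
#' @param n_chrom,chrom_length_bp,chrom_length_cm genome dimensions;
#'   defaults 20 chromosomes of 50 Mb / 110 cM.
#' @param snps_per_chrom evenly spaced SNP count per chromosome.
#' @param observation_rate,error_rate skim observation model.
#' @return list with components `map`, `ped`, `skim`, `pheno`.
#' @export
default_scenario <- function(n_lines = 188, generation = 8, n_chrom = 20,
                             chrom_length_bp = 5e7, chrom_length_cm = 110,
                             snps_per_chrom = 457,
                             observation_rate = 0.3, error_rate = 0.005) {
  chroms <- as.character(seq_len(n_chrom))
  pos <- round(seq(1e4, chrom_length_bp - 1e4, length.out = snps_per_chrom))
  map <- genmap_spec(
    data.frame(chrom = chroms, length_bp = chrom_length_bp,
               length_cm = chrom_length_cm),
    stats::setNames(rep(list(pos), n_chrom), chroms))
  # canonical QTL chromosomes (soybean numbering), wrapped onto the
  # available chromosomes when the scenario is scaled down
  ch <- function(orig) as.character((orig - 1L) %% n_chrom + 1L)
  at <- function(pos) pmin(pos, chrom_length_bp - 1e4)
  traits <- list(
    trait_spec("protein", mu = 42,
               qtl = data.frame(chrom = ch(c(20L, 19L)),
                                pos = at(c(3.4e7, 1.2e6)),
                                effect = c(1.2, 0.55)),
               var_g_residual = 1.0, var_ge = 0.5, var_e = 0.8),
    trait_spec("oil", mu = 19,
               qtl = data.frame(chrom = ch(c(20L, 2L)),
                                pos = at(c(3.4e7, 4.56e7)),
                                effect = c(-0.8, 0.25)),
               var_g_residual = 0.5, var_ge = 0.3, var_e = 0.4),
    trait_spec("sucrose", mu = 5.5,
               qtl = data.frame(chrom = ch(c(8L, 6L)),
                                pos = at(c(8.0e6, 3.8e7)),
                                effect = c(0.45, 0.25)),
               var_g_residual = 0.3, var_ge = 0.2, var_e = 0.3))
  list(map = map,
       ped = pedigree_params(n_lines, generation),
       skim = skim_model(observation_rate, error_rate),
       pheno = phenotype_model(traits, n_environments = 4, n_replicates = 2,
                               mendelian_locus = list(chrom = ch(8L),
                                                      pos = at(8.5e6))))
}
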