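## Interval mapping by Haley-Knott regression on expected genotype scores,
## plus composite interval mapping, permutation thresholds, joint-QTL PVE
## and a two-locus epistasis test.

#' Per-line trait means
#'
#' Averages replicates (and environments, when `environment` is `NULL`)
#' into one value per line, the unit on which all scans operate.
#'
#' @param pheno tidy phenotype data.frame
#'   `(line, trait, environment, replicate, value)`.
#' @param trait trait name.
#' @param environment environment id, or `NULL` for the across-environment
#'   line mean.
#' @return named numeric vector of line means.
#' @export
line_means <- function(pheno, trait, environment = NULL) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!is.null(environment))
    d <- d[d$environment == environment, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no phenotype records for trait '", trait, "'", call. = FALSE)
  tapply(d$value, d$line, mean)
}

## expected B-dosage score in [-1, 1] at arbitrary test positions,
## imputed per line from its nearest informative flanking markers
scan_design <- function(markers, mapdf, step_cm = 1,
                        mapping_function = "kosambi") {
  num <- apply(markers, 2L, marker_to_num)
  rownames(num) <- rownames(markers)
  mf <- map_function(mapping_function)
  ril_R <- function(d) { r <- mf$to_r(d); 2 * r / (1 + 2 * r) }
  pos_list <- list()
  S_list <- list()
  for (cc in unique(mapdf$chrom)) {
    rows <- which(mapdf$chrom == cc)
    mc <- mapdf$cm[rows]
    cols <- match(mapdf$marker[rows], colnames(num))
    grid <- if (max(mc) > min(mc))
      sort(unique(c(mc, seq(min(mc), max(mc), by = step_cm)))) else mc[1L]
    S <- matrix(0, nrow(num), length(grid))
    for (i in seq_len(nrow(num))) {
      v <- num[i, cols]
      obs <- which(!is.na(v))
      if (length(obs) == 0L) next           # score stays 0 (p = 1/2)
      oc <- mc[obs]; ov <- v[obs]
      li <- findInterval(grid, oc)
      ri <- li + 1L
      has_l <- li >= 1L
      has_r <- ri <= length(obs)
      plB <- rep(1, length(grid)); plA <- rep(1, length(grid))
      if (any(has_l)) {
        RL <- ril_R(grid[has_l] - oc[li[has_l]])
        bL <- ov[li[has_l]] == 1
        plB[has_l] <- ifelse(bL, 1 - RL, RL)
        plA[has_l] <- ifelse(bL, RL, 1 - RL)
      }
      prB <- rep(1, length(grid)); prA <- rep(1, length(grid))
      if (any(has_r)) {
        RR <- ril_R(oc[ri[has_r]] - grid[has_r])
        bR <- ov[ri[has_r]] == 1
        prB[has_r] <- ifelse(bR, 1 - RR, RR)
        prA[has_r] <- ifelse(bR, RR, 1 - RR)
      }
      p <- (plB * prB) / (plB * prB + plA * prA)
      p[!has_l & !has_r] <- 0.5
      S[i, ] <- 2 * p - 1
    }
    at_marker <- match(grid, mc)
    pos_list[[cc]] <- data.frame(
      chrom = cc, cm = grid,
      marker = ifelse(is.na(at_marker), NA_character_,
                      mapdf$marker[rows][at_marker]),
      stringsAsFactors = FALSE)
    S_list[[cc]] <- S
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  list(positions = positions, S = do.call(cbind, S_list))
}

## single-regressor LOD / effect / R^2 for every column of S against y
scan_stats <- function(S, y) {
  n <- length(y)
  sd_s <- apply(S, 2L, stats::sd)
  mono <- sd_s == 0
  r <- rep(NA_real_, ncol(S))
  if (any(!mono)) r[!mono] <- as.vector(stats::cor(S[, !mono, drop = FALSE], y))
  r2 <- r^2
  lod <- -(n / 2) * log10(1 - r2)
  effect <- r * stats::sd(y) / sd_s
  lod[mono] <- 0; r2[mono] <- 0; effect[mono] <- NA_real_
  list(lod = lod, effect = effect, r2 = r2, monomorphic = mono)
}

#' Interval mapping scan (Haley-Knott regression)
#'
#' At every test position (marker positions plus a `step_cm` grid) the
#' expected `{-1,+1}` genotype score is imputed per line from its nearest
#' informative flanking markers, using the map function to convert cM
#' distances into selfed-RIL recombination probabilities, and the trait
#' line means are regressed on the score.  Reported per position:
#' `LOD = (n/2) log10(RSS0 / RSS1)`, the additive effect (half the
#' difference between homozygote class means, positive when the PI-type B
#' allele raises the trait) and `R^2 = 1 - RSS1/RSS0`.
#'
#' @param markers lines x markers matrix in `{A, B, U}`.
#' @param map a [build_linkage_map()] result (or its `table`).
#' @param pheno tidy phenotype table.
#' @param trait,environment passed to [line_means()].
#' @param step_cm scan grid step (default 1 cM).
#' @return object of class `qtl_scan`: list with `result` (data.frame
#'   `chrom, cm, marker, lod, effect, r2`), `trait`, `environment`, `n`.
#' @export
interval_scan <- function(markers, map, pheno, trait, environment = NULL,
                          step_cm = 1) {
  mapdf <- map_table(map)
  y <- line_means(pheno, trait, environment)
  common <- intersect(rownames(markers), names(y))
  if (length(common) < 3L)
    stop("need at least 3 lines shared between markers and phenotypes",
         call. = FALSE)
  des <- scan_design(markers[common, , drop = FALSE], mapdf, step_cm,
                     attr_mapfun(map))
  st <- scan_stats(des$S, as.numeric(y[common]))
  if (any(st$monomorphic))
    warning(sum(st$monomorphic), " monomorphic position(s) skipped")
  res <- cbind(des$positions,
               data.frame(lod = st$lod, effect = st$effect, r2 = st$r2))
  structure(list(result = res, trait = trait, environment = environment,
                 n = length(common), lines = common),
            class = "qtl_scan")
}

map_table <- function(map) {
  if (inherits(map, "linkage_map")) map$table else map
}

attr_mapfun <- function(map) {
  if (inherits(map, "linkage_map")) map$mapping_function else "kosambi"
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("QTL scan for '", x$trait, "'",
      if (!is.null(x$environment)) paste0(" in ", x$environment),
      ": ", nrow(x$result), " positions, n = ", x$n,
      ", max LOD = ", round(max(x$result$lod, na.rm = TRUE), 2), "\n",
      sep = "")
  invisible(x)
}

#' Composite interval mapping with forward-selected cofactors
#'
#' Cofactor markers are chosen by forward selection (greedy residual
#' sum-of-squares minimization) among the marker columns, up to
#' `n_cofactors`.  The genome scan then proceeds as in [interval_scan()]
#' with the cofactors as covariates, except that cofactors within
#' `cofactor_window_cm` of the test position (on the same chromosome) are
#' excluded from the model at that position.  With `n_cofactors = 0` the
#' scan reduces exactly to interval mapping.
#'
#' @inheritParams interval_scan
#' @param n_cofactors maximum number of cofactors; must be below
#'   `n_lines / 5` (overfitting guard).
#' @param cofactor_window_cm exclusion window around the test position
#'   (default 10 cM).
#' @return a `qtl_scan` object whose `cofactors` element lists the selected
#'   markers.
#' @export
cim_scan <- function(markers, map, pheno, trait, environment = NULL,
                     step_cm = 1, n_cofactors = 5, cofactor_window_cm = 10) {
  mapdf <- map_table(map)
  y <- line_means(pheno, trait, environment)
  common <- intersect(rownames(markers), names(y))
  n <- length(common)
  if (n_cofactors >= n / 5)
    stop("n_cofactors must be below n_lines / 5", call. = FALSE)
  yv <- as.numeric(y[common])
  num <- apply(markers[common, , drop = FALSE], 2L, marker_to_num)
  num <- apply(num, 2L, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  num <- num[, colnames(markers), drop = FALSE]
  cof <- character(0)
  if (n_cofactors > 0) {
    avail <- colnames(num)[apply(num, 2L, stats::sd) > 0]
    X <- matrix(1, n, 1)
    repeat {
      if (length(cof) >= n_cofactors || length(avail) == 0L) break
      rss <- vapply(avail, function(mk) {
        fit <- stats::lm.fit(cbind(X, num[, mk]), yv)
        sum(fit$residuals^2)
      }, numeric(1))
      best <- names(which.min(rss))
      base_rss <- sum(stats::lm.fit(X, yv)$residuals^2)
      if (min(rss) >= base_rss * (1 - 1e-10)) break
      cof <- c(cof, best)
      X <- cbind(X, num[, best])
      avail <- setdiff(avail, best)
    }
  }
  des <- scan_design(markers[common, , drop = FALSE], mapdf, step_cm,
                     attr_mapfun(map))
  cof_pos <- mapdf[match(cof, mapdf$marker), c("chrom", "cm")]
  P <- nrow(des$positions)
  lod <- effect <- r2 <- numeric(P)
  for (p in seq_len(P)) {
    keep <- which(!(cof_pos$chrom == des$positions$chrom[p] &
                      abs(cof_pos$cm - des$positions$cm[p]) <= cofactor_window_cm))
    X0 <- cbind(rep(1, n), if (length(keep)) num[, cof[keep], drop = FALSE])
    s <- des$S[, p]
    if (stats::sd(s) == 0) { lod[p] <- 0; r2[p] <- 0; effect[p] <- NA; next }
    f0 <- stats::lm.fit(X0, yv)
    f1 <- stats::lm.fit(cbind(X0, s), yv)
    rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
    lod[p] <- (n / 2) * log10(rss0 / rss1)
    effect[p] <- f1$coefficients[length(f1$coefficients)]
    r2[p] <- 1 - rss1 / rss0
  }
  res <- cbind(des$positions, data.frame(lod = lod, effect = effect, r2 = r2))
  structure(list(result = res, trait = trait, environment = environment,
                 n = n, lines = common, cofactors = cof,
                 cofactor_window_cm = cofactor_window_cm),
            class = "qtl_scan")
}

#' Genome-wide permutation LOD threshold
#'
#' Trait line means are permuted across lines (keeping any environment
#' structure intact, since permutation happens after averaging to line
#' level); each permutation is scanned genome-wide and the empirical
#' `1 - alpha` quantile of the per-permutation maximum LOD is the
#' threshold.  `alpha = 1` returns the minimum of the max-LODs.
#'
#' @inheritParams interval_scan
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed optional integer seed; fixed seeds give identical thresholds.
#' @return object of class `permutation_threshold`: list
#'   `(trait, environment, n_perm, alpha, threshold, max_lods)`.
#' @export
permutation_threshold <- function(markers, map, pheno, trait,
                                  environment = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = NULL, step_cm = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  mapdf <- map_table(map)
  y <- line_means(pheno, trait, environment)
  common <- intersect(rownames(markers), names(y))
  yv <- as.numeric(y[common])
  n <- length(yv)
  des <- scan_design(markers[common, , drop = FALSE], mapdf, step_cm,
                     attr_mapfun(map))
  if (!is.null(seed)) set.seed(seed)
  Yperm <- replicate(n_perm, yv[sample.int(n)])
  keep <- apply(des$S, 2L, stats::sd) > 0
  C <- stats::cor(des$S[, keep, drop = FALSE], Yperm)
  lods <- -(n / 2) * log10(1 - C^2)
  max_lods <- apply(lods, 2L, max)
  threshold <- stats::quantile(max_lods, 1 - alpha, type = 1, names = FALSE)
  structure(list(trait = trait, environment = environment, n_perm = n_perm,
                 alpha = alpha, threshold = threshold, max_lods = max_lods),
            class = "permutation_threshold")
}

#' @export
print.permutation_threshold <- function(x, ...) {
  cat("Permutation threshold for '", x$trait, "': LOD ",
      round(x$threshold, 2), " (alpha = ", x$alpha, ", ", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Call QTL peaks from a scan
#'
#' Positions exceeding the threshold are grouped into contiguous
#' significant segments per chromosome; the maximum-LOD position of each
#' segment is reported as a peak.  Peaks on the same chromosome within
#' `merge_cm` of each other are merged (highest LOD wins).  QTL are named
#' `q<Tr>_<chrom>` from the first three letters of the trait.
#'
#' @param scan a `qtl_scan`.
#' @param threshold LOD threshold (e.g. from [permutation_threshold()]).
#' @param merge_cm merge radius for nearby peaks (default 10 cM).
#' @return data.frame `(qtl, trait, environment, chrom, cm, marker, lod,
#'   effect, r2)`, zero rows when nothing exceeds the threshold.
#' @export
call_peaks <- function(scan, threshold, merge_cm = 10) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (inherits(threshold, "permutation_threshold"))
    threshold <- threshold$threshold
  res <- scan$result
  rows <- list()
  for (cc in unique(res$chrom)) {
    d <- res[res$chrom == cc, , drop = FALSE]
    sig <- !is.na(d$lod) & d$lod >= threshold
    if (!any(sig)) next
    seg <- cumsum(c(TRUE, diff(sig) != 0))
    for (s in unique(seg[sig])) {
      dd <- d[seg == s & sig, , drop = FALSE]
      rows[[length(rows) + 1L]] <- dd[which.max(dd$lod), , drop = FALSE]
    }
  }
  if (!length(rows))
    return(data.frame(qtl = character(), trait = character(),
                      environment = character(), chrom = character(),
                      cm = numeric(), marker = character(), lod = numeric(),
                      effect = numeric(), r2 = numeric(),
                      stringsAsFactors = FALSE))
  pk <- do.call(rbind, rows)
  # merge peaks closer than merge_cm on the same chromosome
  pk <- pk[order(pk$chrom, pk$cm), , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (cc in unique(pk$chrom)) {
    i <- which(pk$chrom == cc)
    j <- 1L
    while (j < length(i)) {
      if (pk$cm[i[j + 1L]] - pk$cm[i[j]] <= merge_cm) {
        drop_j <- if (pk$lod[i[j]] >= pk$lod[i[j + 1L]]) j + 1L else j
        keep[i[drop_j]] <- FALSE
        i <- i[-drop_j]
      } else j <- j + 1L
    }
  }
  pk <- pk[keep, , drop = FALSE]
  abbr <- paste0(toupper(substr(scan$trait, 1, 1)), substr(scan$trait, 2, 3))
  data.frame(qtl = sprintf("q%s_%s", abbr, pk$chrom),
             trait = scan$trait,
             environment = if (is.null(scan$environment)) NA_character_ else
               scan$environment,
             pk[, c("chrom", "cm", "marker", "lod", "effect", "r2")],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Total phenotypic variance explained by a set of QTL
#'
#' Joint linear model of the trait line means on all peak markers
#' simultaneously; the total PVE is the model `R^2` in per cent.  Collinear
#' peak markers are dropped with a warning.
#'
#' @inheritParams interval_scan
#' @param peak_markers character vector of marker names (>= 1).
#' @return list `(pve, r2, markers_used, dropped)`.
#' @export
multi_qtl_pve <- function(markers, pheno, trait, peak_markers,
                          environment = NULL) {
  if (length(peak_markers) < 1L) stop("need at least one peak marker",
                                      call. = FALSE)
  y <- line_means(pheno, trait, environment)
  common <- intersect(rownames(markers), names(y))
  num <- sapply(peak_markers, function(mk)
    marker_to_num(markers[common, mk]))
  num <- apply(as.matrix(num), 2L, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  fit <- stats::lm(as.numeric(y[common]) ~ num)
  co <- stats::coef(fit)[-1L]
  dropped <- peak_markers[is.na(co)]
  if (length(dropped))
    warning("dropped collinear peak marker(s): ",
            paste(dropped, collapse = ", "))
  r2 <- summary(fit)$r.squared
  list(pve = 100 * r2, r2 = r2,
       markers_used = setdiff(peak_markers, dropped), dropped = dropped)
}

#' Two-locus epistasis test
#'
#' For each pair of loci, the trait line means are fitted with the
#' two-locus linear model `y ~ x1 + x2 + x1:x2` and the interaction term is
#' tested with an F-test.  This is a defined-regression replacement for
#' mixed-model epistasis software: it tests the same additive-by-additive
#' interaction contrast.  Pairs with any two-locus genotype cell containing
#' fewer than `min_cell` lines are skipped.
#'
#' @inheritParams interval_scan
#' @param loci character vector of marker names (all unordered pairs are
#'   tested) or a two-column matrix/data.frame of explicit pairs.
#' @param alpha significance level for flagging interactions
#'   (default 0.001).
#' @param min_cell minimum lines per two-locus cell (default 3).
#' @return data.frame `(locus1, locus2, n, f, p, significant, skipped)`.
#' @export
epistasis_scan <- function(markers, pheno, trait, loci, environment = NULL,
                           alpha = 0.001, min_cell = 3) {
  if (is.character(loci)) {
    if (length(loci) < 2L) stop("need at least two loci", call. = FALSE)
    pairs <- t(utils::combn(loci, 2L))
  } else {
    pairs <- as.matrix(loci)
    stopifnot(ncol(pairs) == 2L)
  }
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("a locus cannot be paired with itself", call. = FALSE)
  y <- line_means(pheno, trait, environment)
  common <- intersect(rownames(markers), names(y))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    x1 <- marker_to_num(markers[common, pairs[i, 1L]])
    x2 <- marker_to_num(markers[common, pairs[i, 2L]])
    ok <- !is.na(x1) & !is.na(x2)
    cells <- table(x1[ok], x2[ok])
    base <- data.frame(locus1 = pairs[i, 1L], locus2 = pairs[i, 2L],
                       n = sum(ok), f = NA_real_, p = NA_real_,
                       significant = NA, skipped = TRUE,
                       stringsAsFactors = FALSE)
    if (nrow(cells) < 2L || ncol(cells) < 2L || any(cells < min_cell))
      return(base)
    yy <- as.numeric(y[common])[ok]
    full <- stats::lm(yy ~ x1[ok] * x2[ok])
    av <- stats::anova(full)
    base$f <- av$`F value`[3L]
    base$p <- av$`Pr(>F)`[3L]
    base$significant <- base$p <= alpha
    base$skipped <- FALSE
    base
  })
  do.call(rbind, out)
}
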