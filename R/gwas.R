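#' VanRaden genomic relationship (kinship) matrix
#'
#' `K = Z Z' / (2 * sum(p_k (1 - p_k)))` where `Z` is the genotype dosage
#' matrix centred at `2 p_k` and `p_k` the B-allele frequency of SNP `k`.
#' Missing calls are mean-imputed per SNP; monomorphic SNPs are excluded.
#'
#' @param X lines x SNPs dosage matrix on a 0..2 scale (an RIL population
#'   coded A/B maps to 0/2), or an [ab_genotypes()] object.
#' @return symmetric n x n matrix of class `kinship_matrix` with attributes
#'   `method = "VanRaden"` and `n_snps`.
#' @export
vanraden_kinship <- function(X) {
  X <- dosage_matrix(X)
  if (ncol(X) < 2L) stop("need at least two SNPs", call. = FALSE)
  X <- apply(X, 2L, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic", call. = FALSE)
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2L, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  attr(K, "method") <- "VanRaden"
  attr(K, "n_snps") <- sum(poly)
  class(K) <- c("kinship_matrix", "matrix")
  K
}

dosage_matrix <- function(X) {
  if (inherits(X, "ab_genotypes")) {
    D <- 2 * X$calls
    rownames(D) <- X$lines
    storage.mode(D) <- "double"
    return(D)
  }
  if (is.character(X)) {
    D <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
    D[X == "A"] <- 0; D[X == "B"] <- 2
    return(D)
  }
  storage.mode(X) <- "double"
  X
}

#' Mixed-linear-model association scan
#'
#' Fits the null model `y = PC beta + u + e` with `u ~ N(0, sigma_g^2 K)`
#' once by restricted maximum likelihood (profiled over the variance ratio
#' on the eigenbasis of `K`), then tests each SNP by generalized least
#' squares with the variance ratio held fixed -- the standard EMMAX-style
#' approximation.  The residual scale is re-estimated per SNP, so with
#' `K = I` and no PCs the test reduces exactly to ordinary least-squares
#' regression.  Population structure covariates are the leading principal
#' components of the centred genotype matrix.
#'
#' @param X lines x SNPs dosage matrix (0..2) or [ab_genotypes()]; missing
#'   calls are mean-imputed per SNP.
#' @param y named numeric phenotype vector over the same lines (e.g. from
#'   [line_means()]); lines with missing phenotypes are dropped.
#' @param K kinship matrix from [vanraden_kinship()] (or any symmetric PSD
#'   matrix over the lines).
#' @param n_pcs number of genotype principal components as fixed covariates
#'   (default 3).
#' @param maf_min SNPs below this minor allele frequency are excluded
#'   before testing (default 0.05).
#' @return object of class `gwas_result`: list with `result` (data.frame
#'   `snp, chrom, pos, maf, beta, se, p`), `vc` (variance components),
#'   `lambda_gc` (genomic inflation factor) and `n`.
#' @export
mlm_scan <- function(X, y, K, n_pcs = 3, maf_min = 0.05) {
  snps <- if (inherits(X, "ab_genotypes")) X$snps else NULL
  D <- dosage_matrix(X)
  lines <- rownames(D)
  if (is.null(names(y)))
    stop("y must be named by line", call. = FALSE)
  lines <- lines[lines %in% names(y)[is.finite(y)]]
  if (length(lines) < 10)
    stop("fewer than 10 lines with both genotype and phenotype",
         call. = FALSE)
  D <- D[lines, , drop = FALSE]
  y <- as.numeric(y[lines])
  n <- length(y)
  D <- apply(D, 2L, function(col) {
    if (all(is.na(col))) return(rep(0, length(col)))
    col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  p_all <- colMeans(D) / 2
  maf <- pmin(p_all, 1 - p_all)
  keep <- maf >= maf_min & maf > 0
  if (!any(keep)) stop("no SNPs pass the MAF filter", call. = FALSE)
  X0 <- matrix(1, n, 1)
  if (n_pcs > 0) {
    Z <- sweep(D[, keep, drop = FALSE], 2L, colMeans(D[, keep, drop = FALSE]))
    pcs <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                              drop = FALSE]
    X0 <- cbind(X0, pcs)
  }
  eg <- eigen(as.matrix(K)[lines, lines], symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- crossprod(U, y)
  X0r <- crossprod(U, X0)
  reml <- function(log_lambda) {
    lambda <- exp(log_lambda)
    xi <- lambda * d + 1
    w <- 1 / xi
    fit <- stats::lm.wfit(X0r, yr, w)
    rss <- sum(w * fit$residuals^2)
    XtWX <- crossprod(X0r, X0r * w)
    p0 <- ncol(X0r)
    0.5 * ((n - p0) * log(rss) + sum(log(xi)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml, c(-12, 12))
  if (!is.finite(opt$objective))
    stop("REML optimization did not converge; check K for validity",
         call. = FALSE)
  lambda <- exp(opt$minimum)
  xi <- lambda * d + 1
  w <- 1 / xi
  fit0 <- stats::lm.wfit(X0r, yr, w)
  sigma_e2 <- sum(w * fit0$residuals^2) / (n - ncol(X0r))
  sigma_g2 <- lambda * sigma_e2
  # per-SNP GLS on the rotated, whitened data (scale re-estimated per SNP)
  sw <- sqrt(w)
  yws <- yr * sw
  X0w <- X0r * sw
  m <- sum(keep)
  beta <- se <- pval <- rep(NA_real_, m)
  Dr <- crossprod(U, D[, keep, drop = FALSE])
  dfree <- n - ncol(X0) - 1L
  for (j in seq_len(m)) {
    Xw <- cbind(X0w, Dr[, j] * sw)
    ft <- stats::lm.fit(Xw, yws)
    if (ft$rank < ncol(Xw)) next
    rss <- sum(ft$residuals^2)
    s2 <- rss / dfree
    XtXinv <- solve(crossprod(Xw))
    k <- ncol(Xw)
    beta[j] <- ft$coefficients[k]
    se[j] <- sqrt(s2 * XtXinv[k, k])
    pval[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), dfree)
  }
  chi <- stats::qchisq(pval, 1, lower.tail = FALSE)
  lambda_gc <- stats::median(chi, na.rm = TRUE) / stats::qchisq(0.5, 1)
  res <- data.frame(snp = colnames(D)[keep],
                    chrom = if (!is.null(snps)) snps$chrom[keep] else NA,
                    pos = if (!is.null(snps)) snps$pos[keep] else NA,
                    maf = maf[keep], beta = beta, se = se, p = pval,
                    stringsAsFactors = FALSE)
  structure(list(result = res,
                 vc = c(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                        lambda = lambda),
                 lambda_gc = lambda_gc, n = n, n_pcs = n_pcs),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("MLM GWAS: ", nrow(x$result), " SNPs, n = ", x$n,
      ", lambda_GC = ", round(x$lambda_gc, 3),
      ", min p = ", format(min(x$result$p, na.rm = TRUE), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return the per-test p-value threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (any(n_tests < 1)) stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}
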