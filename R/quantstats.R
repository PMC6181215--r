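#' ANOVA variance components for a balanced multi-environment trial
#'
#' Two-way ANOVA with replication within environment for the model
#' `y = mu + env + rep(env) + geno + geno:env + error`, environments fixed,
#' genotypes and genotype-by-environment random.  Expected mean squares for
#' the balanced case give `sigma2 = MS_error`,
#' `sigma2_ge = (MS_GE - MS_error) / r` and
#' `sigma2_g = (MS_G - MS_GE) / (r e)`.  The environment F-statistic uses
#' the replication-within-environment mean square as its denominator.
#' Negative method-of-moments estimates are truncated to zero and flagged.
#'
#' @param pheno tidy phenotype data.frame
#'   `(line, trait, environment, replicate, value)`.
#' @param trait trait name.
#' @return object of class `variance_components`: list with `s2g`, `s2ge`,
#'   `s2`, design sizes `g`, `e`, `r`, the raw (untruncated) estimates,
#'   `truncated` flags, mean squares and the environment F-test.
#' @export
anova_components <- function(pheno, trait) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for trait '", trait, "'", call. = FALSE)
  counts <- table(d$line, d$environment)
  r <- unique(as.vector(counts))
  if (length(r) != 1L)
    stop("unbalanced design: every line x environment must have the same ",
         "number of replicates (rebalance or analyse line means)",
         call. = FALSE)
  g <- nrow(counts); e <- ncol(counts)
  if (r < 1L) stop("empty cells in the design", call. = FALSE)
  grand <- mean(d$value)
  m_ge <- tapply(d$value, list(d$line, d$environment), mean)
  m_g <- rowMeans(m_ge)
  m_e <- colMeans(m_ge)
  ms_g <- r * e * sum((m_g - grand)^2) / (g - 1)
  ms_ge <- if (e > 1)
    r * sum((m_ge - outer(m_g, rep(1, e)) -
               outer(rep(1, g), m_e) + grand)^2) / ((g - 1) * (e - 1))
  else NA_real_
  # replication within environment and residual
  m_er <- tapply(d$value, list(d$environment, d$replicate), mean)
  ms_rep <- if (r > 1)
    g * sum((m_er - rowMeans(m_er))^2) / (e * (r - 1)) else NA_real_
  cellmean <- m_ge[cbind(match(d$line, rownames(m_ge)),
                         match(d$environment, colnames(m_ge)))]
  repmean <- m_er[cbind(match(d$environment, rownames(m_er)),
                        match(as.character(d$replicate), colnames(m_er)))]
  envmean <- m_e[match(d$environment, names(m_e))]
  resid <- d$value - cellmean - repmean + envmean
  df_res <- (g - 1) * (r - 1) * e
  ms_err <- if (df_res > 0) sum(resid^2) / df_res else 0
  ms_env <- r * g * sum((m_e - grand)^2) / max(e - 1, 1)
  raw <- c(s2g = if (e > 1) (ms_g - ms_ge) / (r * e) else
             (ms_g - ms_err) / (r * e),
           s2ge = if (e > 1) (ms_ge - ms_err) / r else 0,
           s2 = ms_err)
  comp <- pmax(raw, 0)
  f_env <- if (!is.na(ms_rep) && ms_rep > 0) ms_env / ms_rep else NA_real_
  structure(list(s2g = comp[["s2g"]], s2ge = comp[["s2ge"]], s2 = comp[["s2"]],
                 g = g, e = e, r = r, raw = raw,
                 truncated = raw < 0,
                 mean_squares = c(genotype = ms_g, gxe = ms_ge,
                                  rep_in_env = ms_rep, error = ms_err,
                                  environment = ms_env),
                 f_environment = f_env,
                 f_env_p = if (is.na(f_env)) NA_real_ else
                   stats::pf(f_env, e - 1, e * (r - 1), lower.tail = FALSE)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$g, " lines x ", x$e, " env x ", x$r,
      " reps):\n", sep = "")
  cat(sprintf("  s2g  = %.4f%s\n", x$s2g,
              if (x$truncated[["s2g"]]) " (truncated)" else ""))
  cat(sprintf("  s2ge = %.4f%s\n", x$s2ge,
              if (x$truncated[["s2ge"]]) " (truncated)" else ""))
  cat(sprintf("  s2   = %.4f\n", x$s2))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = s2g / (s2g + s2ge / e + s2 / (r e))` (Nyquist/Baker entry-mean
#' formulation).  Because the components entering the formula are truncated
#' at zero, `H2` always lies in `[0, 1]`.
#'
#' @param vc a [anova_components()] result, or a list/vector with elements
#'   `s2g`, `s2ge`, `s2` plus `e` and `r` (supplied separately if absent).
#' @param e,r design sizes, taken from `vc` when available.
#' @return list `(H2, defined)`; `defined = FALSE` (and `H2 = NA`) when all
#'   components are zero.
#' @export
heritability <- function(vc, e = NULL, r = NULL) {
  s2g <- vc$s2g; s2ge <- vc$s2ge; s2 <- vc$s2
  if (is.null(e)) e <- vc$e
  if (is.null(r)) r <- vc$r
  if (is.null(e) || is.null(r) || e < 1 || r < 1)
    stop("e and r must be >= 1", call. = FALSE)
  denom <- s2g + s2ge / e + s2 / (r * e)
  if (denom == 0) return(list(H2 = NA_real_, defined = FALSE))
  list(H2 = s2g / denom, defined = TRUE)
}

#' Phenotypic and genetic correlation between two traits
#'
#' The phenotypic correlation is the Pearson correlation of line means
#' taken across environments and replicates.  The genetic correlation is
#' `rG = cov_g(x, y) / sqrt(s2g_x s2g_y)`, with the genotypic covariance
#' estimated from the expected-cross-product identity
#' `cov_g(x, y) = (s2g(x + y) - s2g(x) - s2g(y)) / 2`, i.e. the MANOVA
#' cross-product analogue of the variance component equations.
#'
#' @param pheno tidy phenotype table containing both traits on the same
#'   balanced design.
#' @param trait_x,trait_y trait names.
#' @return list `(r_phenotypic, p_phenotypic, r_genetic, defined, n)`;
#'   `defined = FALSE` when either trait has zero genetic variance.
#' @export
correlations <- function(pheno, trait_x, trait_y) {
  mx <- line_means(pheno, trait_x)
  my <- line_means(pheno, trait_y)
  common <- intersect(names(mx), names(my))
  ct <- if (stats::sd(mx[common]) > 0 && stats::sd(my[common]) > 0)
    stats::cor.test(mx[common], my[common])
  else list(estimate = NA_real_, p.value = NA_real_)
  vx <- anova_components(pheno, trait_x)
  vy <- anova_components(pheno, trait_y)
  dx <- pheno[pheno$trait == trait_x, , drop = FALSE]
  dy <- pheno[pheno$trait == trait_y, , drop = FALSE]
  key <- function(d) paste(d$line, d$environment, d$replicate)
  i <- match(key(dx), key(dy))
  dsum <- dx
  dsum$value <- dx$value + dy$value[i]
  dsum$trait <- ".sum"
  vs <- anova_components(dsum, ".sum")
  covg <- (vs$raw[["s2g"]] - vx$raw[["s2g"]] - vy$raw[["s2g"]]) / 2
  if (vx$s2g <= 0 || vy$s2g <= 0)
    return(list(r_phenotypic = unname(ct$estimate),
                p_phenotypic = ct$p.value,
                r_genetic = NA_real_, defined = FALSE, n = length(common)))
  rg <- covg / sqrt(vx$raw[["s2g"]] * vy$raw[["s2g"]])
  list(r_phenotypic = unname(ct$estimate), p_phenotypic = ct$p.value,
       r_genetic = rg, defined = TRUE, n = length(common))
}

#' Agreement between two measurement platforms
#'
#' Pearson correlation between paired measurements of the same samples on
#' two platforms (e.g. near-infrared spectroscopy versus HPLC), with test
#' p-value.
#'
#' @param x,y paired numeric vectors (n >= 3 after removing missing pairs).
#' @return list `(r, p, n)`.
#' @export
platform_agreement <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 paired values", call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
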