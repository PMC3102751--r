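# Haplotype-specific reporter (luciferase) analysis.
#
# Random-intercept model: luminescence = haplotype (fixed) + preparation
# (random) + residual. With a single grouping factor the REML/ML criteria
# profile down to one dimension (the variance ratio lambda = sigma_prep^2 /
# sigma_e^2): V = I + lambda Z Z' is block diagonal with blocks
# I + lambda J_m, so GLS sums, log|V| and the profiled deviance are closed
# form given lambda, and a 1-D optimizer does the rest. The haplotype term is
# tested by a GLS F statistic with containment denominator degrees of freedom
# (#preparations - #haplotypes), which for balanced designs is the exact
# hierarchical-ANOVA test and stays valid (conservative-to-exact) for any
# between-prep variance; the ML likelihood-ratio chi-squared p-value is also
# reported but is anticonservative with few preparations. The cost of
# validity is power: a two-haplotype contrast at 3 preps per haplotype has
# only 4 denominator df.

# Profiled log-likelihood machinery for y = X b + Z u + e with one grouping
# factor. Returns GLS quantities at a given variance ratio lambda.
gls_quantities <- function(y, X, group, lambda) {
  n <- length(y)
  groups <- split(seq_len(n), group)
  XtVX <- crossprod(X); XtVy <- crossprod(X, y); ytVy <- sum(y^2)
  logdet <- 0
  for (idx in groups) {
    m <- length(idx)
    w <- lambda / (1 + lambda * m)
    sx <- colSums(X[idx, , drop = FALSE]); sy <- sum(y[idx])
    XtVX <- XtVX - w * tcrossprod(sx)
    XtVy <- XtVy - w * sx * sy
    ytVy <- ytVy - w * sy^2
    logdet <- logdet + log1p(lambda * m)
  }
  b <- solve(XtVX, XtVy)
  rss <- ytVy - sum(b * XtVy)
  list(beta = as.numeric(b), XtVX = XtVX, rss = max(rss, 1e-300),
       logdet = logdet)
}

neg2_profiled <- function(loglambda, y, X, group, reml) {
  lambda <- exp(loglambda)
  q <- gls_quantities(y, X, group, lambda)
  n <- length(y); p <- ncol(X)
  if (reml) {
    df <- n - p
    q$logdet + determinant(q$XtVX, logarithm = TRUE)$modulus[1] +
      df * log(q$rss / df) + df
  } else {
    q$logdet + n * log(q$rss / n) + n
  }
}

fit_onegroup <- function(y, X, group, reml = TRUE) {
  opt <- stats::optimize(neg2_profiled, interval = c(-12, 12), y = y, X = X,
                         group = group, reml = reml, tol = 1e-10)
  # compare against the lambda -> 0 boundary (no between-group variance)
  at0 <- neg2_profiled(-Inf + 0, y, X, group, reml)
  lambda <- exp(opt$minimum)
  obj <- opt$objective
  if (!is.finite(at0)) at0 <- neg2_profiled(log(1e-12), y, X, group, reml)
  if (at0 <= obj + 1e-10) { lambda <- 0; obj <- at0 }
  q <- gls_quantities(y, X, group, lambda)
  n <- length(y); p <- ncol(X)
  sigma2 <- q$rss / if (reml) (n - p) else n
  list(lambda = lambda, sigma2_resid = sigma2,
       sigma2_group = lambda * sigma2, beta = q$beta, XtVX = q$XtVX,
       neg2loglik = obj, reml = reml, n = n, p = p)
}

#' Fit the haplotype reporter mixed model
#'
#' Restricted-maximum-likelihood fit of
#' `luminescence ~ haplotype + (1 | prep)` via the profiled one-dimensional
#' deviance, with the boundary (zero between-prep variance) checked
#' explicitly. The haplotype term's p-value is a GLS F test with containment
#' denominator df (`#preps - #haplotypes`, exact for balanced designs and
#' valid for any between-prep variance; when no prep df remain the residual
#' df are used); the ML likelihood-ratio chi-squared p-value is reported
#' alongside but is anticonservative with few preparations. When
#' every haplotype has a single preparation the between-prep variance is
#' inestimable and the model degrades to OLS with a warning.
#'
#' @param plate a `reporter_plate` data.frame (`region_id`, `haplotype_id`,
#'   `prep_id`, `replicate_index`, `luminescence`).
#' @param alpha significance threshold for the haplotype term (default
#'   0.001).
#'
#' @return list of class `reporter_fit`: haplotype means and contrasts
#'   (vs the reference haplotype), variance components, `f_stat`, `df`,
#'   `p_value` (F), `p_lrt`, `significant`.
#' @export
fit_reporter_model <- function(plate, alpha = 0.001) {
  hap <- factor(plate$haplotype_id)
  prep <- factor(plate$prep_id)
  y <- plate$luminescence
  assert_that(nlevels(hap) >= 2, "need at least 2 haplotypes")
  n_prep <- nlevels(prep)
  X <- stats::model.matrix(~ hap)
  single_prep <- n_prep == nlevels(hap) &&
    all(tapply(prep, hap, function(p) length(unique(p))) == 1)
  if (single_prep) {
    warnf("one preparation per haplotype; between-prep variance inestimable, using OLS")
    fit0 <- stats::lm(y ~ 1)
    fit1 <- stats::lm(y ~ hap)
    an <- stats::anova(fit0, fit1)
    fstat <- an$F[2]; df2 <- fit1$df.residual
    p_f <- an$`Pr(>F)`[2]
    lrt <- as.numeric(2 * (stats::logLik(fit1) - stats::logLik(fit0)))
    beta <- stats::coef(fit1)
    vc <- c(prep = 0, residual = summary(fit1)$sigma^2)
    lambda <- 0
  } else {
    reml <- fit_onegroup(y, X, prep, reml = TRUE)
    vc <- c(prep = reml$sigma2_group, residual = reml$sigma2_resid)
    lambda <- reml$lambda
    beta <- stats::setNames(reml$beta, colnames(X))
    # GLS F test for the haplotype contrasts at the REML variance ratio
    qf <- gls_quantities(y, X, prep, reml$lambda)
    C <- diag(ncol(X))[-1, , drop = FALSE]
    cb <- C %*% qf$beta
    Vcb <- C %*% solve(qf$XtVX) %*% t(C) * reml$sigma2_resid
    df1 <- nrow(C)
    fstat <- as.numeric(t(cb) %*% solve(Vcb, cb)) / df1
    df2 <- n_prep - nlevels(hap)
    if (df2 < 1) df2 <- length(y) - nlevels(hap)
    p_f <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    ml1 <- fit_onegroup(y, X, prep, reml = FALSE)
    ml0 <- fit_onegroup(y, matrix(1, length(y), 1), prep, reml = FALSE)
    lrt <- ml0$neg2loglik - ml1$neg2loglik
  }
  p_lrt <- stats::pchisq(max(lrt, 0), df = nlevels(hap) - 1,
                         lower.tail = FALSE)
  hap_means <- stats::setNames(
    c(beta[1], beta[1] + beta[-1]), levels(hap))
  structure(list(region_id = plate$region_id[1],
                 haplotype_means = hap_means,
                 contrasts = stats::setNames(beta[-1], levels(hap)[-1]),
                 var_prep = unname(vc["prep"]),
                 var_residual = unname(vc["residual"]),
                 lambda = lambda,
                 f_stat = fstat, df = c(nlevels(hap) - 1, df2),
                 p_value = p_f, p_lrt = p_lrt, alpha = alpha,
                 significant = p_f < alpha),
            class = "reporter_fit")
}

#' @export
print.reporter_fit <- function(x, ...) {
  cat(sprintf(paste0("<reporter_fit> %s: %d haplotypes, F(%d, %g) = %.3f, ",
                     "p = %.3g%s; var(prep) = %.4g, var(resid) = %.4g\n"),
              x$region_id, length(x$haplotype_means), x$df[1], x$df[2],
              x$f_stat, x$p_value, if (x$significant) " *" else "",
              x$var_prep, x$var_residual))
  invisible(x)
}

#' Direction concordance between reporter and eQTL effects
#'
#' TRUE when the fitted haplotype contrast carrying the eQTL's alternate
#' allele has the same sign as the eQTL coefficient (both on the
#' higher-with-alt-allele convention). Haplotypes not in the map are
#' excluded with a warning.
#'
#' @param fit a [fit_reporter_model()] result.
#' @param eqtl_beta signed eQTL effect (log2 expression per alt allele).
#' @param haplotype_alleles named vector mapping haplotype id to allele
#'   (`"ref"`/`"alt"`) at the eQTL SNP.
#'
#' @return list: `concordant` flag, `reporter_contrast` (mean alt minus mean
#'   ref haplotype activity), `significant_and_concordant`.
#' @export
concordance_with_eqtl <- function(fit, eqtl_beta, haplotype_alleles) {
  haps <- names(fit$haplotype_means)
  mapped <- haps[haps %in% names(haplotype_alleles)]
  if (length(mapped) < length(haps))
    warnf("unmapped haplotypes excluded: %s",
          paste(setdiff(haps, mapped), collapse = ", "))
  al <- haplotype_alleles[mapped]
  assert_that(all(c("ref", "alt") %in% al),
              "need both ref and alt haplotypes mapped")
  contrast <- mean(fit$haplotype_means[mapped][al == "alt"]) -
    mean(fit$haplotype_means[mapped][al == "ref"])
  conc <- sign(contrast) == sign(eqtl_beta)
  list(concordant = conc, reporter_contrast = contrast,
       significant_and_concordant = conc && fit$significant)
}
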