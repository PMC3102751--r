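# Covariate modelling: demographic adjustment, surrogate variables,
# within-population inverse-normal transformation and Storey q-values.
#
# The full crossed random-effects model (individual replicates, probes within
# probesets) is approximated by replicate averaging and per-probe centering
# before ordinary least squares; on balanced designs this leaves fixed-effect
# estimates unchanged while avoiding a crossed-REML fit per gene.

#' Average technical replicates within samples
#'
#' @param expr an [expression_matrix()].
#' @return An [expression_matrix()] with one column per sample.
#' @export
average_replicates <- function(expr) {
  if (is.null(expr$replicate_ids)) return(expr)
  samples <- unique(expr$sample_ids)
  out <- vapply(samples, function(s)
    rowMeans(expr$values[, expr$sample_ids == s, drop = FALSE]),
    numeric(nrow(expr$values)))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), samples))
  expression_matrix(out, expr$probe_meta, sample_ids = samples)
}

#' Fit the demographic covariate model per gene
#'
#' Technical replicates are averaged within individuals; each probe row is
#' the response of an ordinary least-squares fit on the fixed terms (age, sex
#' coded male = 1, standardized ancestry columns, optional batch factor and
#' any surrogate variables supplied). Returns residuals (exactly orthogonal
#' to the fitted columns), per-gene estimates and t-test p-values.
#'
#' @param expr an [expression_matrix()] (probes or probesets in rows).
#' @param dem demographics data.frame (`sample_id`, `age`, `sex`,
#'   ancestry columns matched by `ancestry_cols`, optional `batch`).
#' @param terms fixed terms to include, subset of
#'   `c("age", "sex", "ancestry", "batch")`.
#' @param ancestry_cols names of ancestry covariate columns in `dem`.
#' @param svs optional samples x k matrix of surrogate variables appended to
#'   the design.
#'
#' @return list of class `adjusted_phenotypes`: `residuals` (genes x
#'   samples), `stats` (gene, term, beta, se, t, p), `design`, `sample_ids`,
#'   `n_svs`, `transformed`.
#' @export
fit_covariate_model <- function(expr, dem,
                                terms = c("age", "sex", "ancestry"),
                                ancestry_cols = "ancestry", svs = NULL) {
  expr <- average_replicates(expr)
  samples <- expr$sample_ids
  di <- match(samples, dem$sample_id)
  assert_that(!anyNA(di), "demographics missing for some expression samples")
  dem <- dem[di, , drop = FALSE]
  X <- matrix(1, length(samples), 1, dimnames = list(samples, "intercept"))
  if ("age" %in% terms) X <- cbind(X, age = dem$age)
  if ("sex" %in% terms) X <- cbind(X, sex = as.numeric(dem$sex == "male"))
  if ("ancestry" %in% terms)
    for (ac in ancestry_cols) {
      v <- dem[[ac]]
      X <- cbind(X, scale(v)[, 1])
      colnames(X)[ncol(X)] <- ac
    }
  if ("batch" %in% terms && !is.null(dem$batch)) {
    B <- stats::model.matrix(~ factor(dem$batch))[, -1, drop = FALSE]
    colnames(B) <- paste0("batch", seq_len(ncol(B)))
    X <- cbind(X, B)
  }
  if (!is.null(svs)) {
    svs <- as.matrix(svs)
    colnames(svs) <- paste0("sv", seq_len(ncol(svs)))
    X <- cbind(X, svs)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warnf("dropping aliased design columns: %s", paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  n <- nrow(X); p <- ncol(X)
  assert_that(n > p, "need more samples (%d) than design columns (%d)", n, p)
  Y <- t(expr$values)                               # samples x genes
  coef <- qr.coef(qrX, Y)
  fitted <- X %*% coef
  res <- Y - fitted
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  XtXinv_diag <- stats::setNames(diag(chol2inv(chol(crossprod(X)))),
                                 colnames(X))
  se <- sqrt(outer(XtXinv_diag, sigma2))
  rownames(se) <- colnames(X)
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  report_terms <- setdiff(colnames(X), "intercept")
  stats_df <- do.call(rbind, lapply(report_terms, function(tm)
    data.frame(gene = rownames(expr$values), term = tm,
               beta = coef[tm, ], se = se[tm, ], t = tval[tm, ],
               p = pval[tm, ], row.names = NULL, stringsAsFactors = FALSE)))
  structure(list(residuals = t(res), stats = stats_df, design = X,
                 sample_ids = samples, n_svs = if (is.null(svs)) 0 else ncol(svs),
                 df_residual = n - p, transformed = FALSE),
            class = "adjusted_phenotypes")
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat(sprintf("<adjusted_phenotypes> %d genes x %d samples (%d SVs%s)\n",
              nrow(x$residuals), length(x$sample_ids), x$n_svs,
              if (x$transformed) ", quantile-transformed" else ""))
  invisible(x)
}

#' Estimate surrogate variables by permutation-thresholded SVD
#'
#' Singular value decomposition of the gene-standardized residual matrix; the
#' number of retained components is chosen by comparing each component's
#' variance share with its null distribution obtained from `n_perm`
#' independent within-row permutations of the residuals (components are kept
#' while their empirical p-value is below `alpha`, stopping at the first
#' failure). Returned scores are orthogonalized against the known covariates
#' and scaled to unit variance.
#'
#' @param residuals genes x samples matrix already adjusted for known
#'   covariates.
#' @param known_covariates optional samples x q matrix; scores are made
#'   orthogonal to these columns.
#' @param n_perm number of permutations (default 100).
#' @param alpha retention threshold on the empirical p-value (default 0.05).
#' @param max_k maximum number of components examined.
#' @param seed integer seed for the permutation draws.
#'
#' @return samples x k matrix of surrogate variables (0 columns if none
#'   retained).
#' @export
estimate_surrogate_variables <- function(residuals, known_covariates = NULL,
                                         n_perm = 100, alpha = 0.05,
                                         max_k = 10, seed = 1L) {
  assert_that(all(is.finite(residuals)), "residuals must be finite")
  R <- residuals
  sds <- apply(R, 1, stats::sd)
  R <- R[sds > 0, , drop = FALSE]
  R <- t(scale(t(R)))                     # gene-standardized
  n <- ncol(R)
  max_k <- min(max_k, n - 1, nrow(R) - 1)
  d_obs <- svd(R, nu = 0, nv = 0)$d
  share_obs <- d_obs^2 / sum(d_obs^2)
  with_seed(seed, {
    null_shares <- matrix(0, n_perm, max_k)
    for (b in seq_len(n_perm)) {
      P <- t(apply(R, 1, sample))
      P <- t(scale(t(P)))
      dp <- svd(P, nu = 0, nv = 0)$d
      null_shares[b, ] <- (dp^2 / sum(dp^2))[seq_len(max_k)]
    }
  })
  k <- 0
  for (j in seq_len(max_k)) {
    p_j <- (1 + sum(null_shares[, j] >= share_obs[j])) / (n_perm + 1)
    if (p_j < alpha) k <- j else break
  }
  if (k == 0)
    return(matrix(0, n, 0, dimnames = list(colnames(residuals), NULL)))
  V <- svd(R, nu = 0, nv = k)$v
  if (!is.null(known_covariates) && ncol(as.matrix(known_covariates)) > 0) {
    K <- as.matrix(known_covariates)
    V <- V - K %*% qr.coef(qr(K), V)
  }
  V <- scale(V)[, , drop = FALSE]
  dimnames(V) <- list(colnames(residuals), paste0("SV", seq_len(k)))
  V
}

#' Within-population inverse-normal transform
#'
#' Within each group, values are replaced by Blom-offset normal quantiles
#' `qnorm((rank - 3/8) / (n + 1/4))`; ties receive the mean of their ranks.
#' Constant groups map to zero with a warning.
#'
#' @param values numeric vector.
#' @param groups population labels (default: one group).
#'
#' @return transformed vector of the same length.
#' @export
quantile_normal_transform <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  assert_that(all(table(groups) >= 2), "each group needs >= 2 values")
  out <- numeric(length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- values[idx]
    if (length(unique(v)) == 1) {
      warnf("constant values in group %s; returning zeros", g)
      out[idx] <- 0
    } else {
      r <- rank(v, ties.method = "average")
      out[idx] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
    }
  }
  out
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` from the tail counts
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over a lambda grid,
#' smoothed by a cubic polynomial and evaluated at the largest lambda
#' (clipped to (0, 1]), then computes
#' `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j`. With fewer than 100
#' p-values the smoother is unstable and `pi0` falls back to 1 (with a
#' warning), which reduces the q-values to Benjamini-Hochberg.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param lambda_grid grid for the pi0 fit (default `seq(0.05, 0.95, 0.05)`).
#' @param pi0 optional fixed `pi0` overriding estimation.
#'
#' @return list of class `fdr_result`: `pvalues`, `qvalues`, `pi0`,
#'   `lambda_grid`.
#' @export
storey_qvalues <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  assert_that(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]")
  m <- length(pvals)
  if (is.null(pi0)) {
    if (m < 100) {
      warnf("fewer than 100 p-values; using pi0 = 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda_grid, function(l) mean(pvals > l) / (1 - l),
                      numeric(1))
      fit <- stats::lm(pi0_l ~ stats::poly(lambda_grid, 3, raw = TRUE))
      pi0 <- stats::predict(fit, newdata = data.frame(
        lambda_grid = max(lambda_grid)))[[1]]
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(pvals)
  q_sorted <- pi0 * m * pvals[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(pvalues = pvals, qvalues = q, pi0 = pi0,
                 lambda_grid = lambda_grid), class = "fdr_result")
}

#' Per-gene demographic association
#'
#' Linear-regression t-test of each gene's adjusted expression on one
#' demographic variable, with Storey q-value FDR flags. The sex effect sign
#' follows the male = 1 coding (positive = higher in males).
#'
#' @param adjusted an `adjusted_phenotypes` object (use residuals from a fit
#'   that excluded the tested variable) or a genes x samples matrix.
#' @param dem demographics data.frame aligned by `sample_id`.
#' @param variable `"age"` or `"sex"`.
#' @param fdr flag threshold on the q-value (default 0.05).
#'
#' @return data.frame (`gene`, `beta`, `se`, `t`, `p`, `q`, `significant`).
#' @export
demographic_association <- function(adjusted, dem, variable = c("age", "sex"),
                                    fdr = 0.05) {
  variable <- match.arg(variable)
  Y <- if (inherits(adjusted, "adjusted_phenotypes")) adjusted$residuals
       else as.matrix(adjusted)
  samples <- colnames(Y)
  di <- match(samples, dem$sample_id)
  assert_that(!anyNA(di), "demographics missing for some samples")
  x <- if (variable == "age") dem$age[di] else
    as.numeric(dem$sex[di] == "male")
  assert_that(stats::sd(x) > 0, "variable %s is constant", variable)
  n <- length(x)
  xc <- x - mean(x)
  yc <- Y - rowMeans(Y)
  sxx <- sum(xc^2)
  beta <- as.numeric(yc %*% xc) / sxx
  rss <- rowSums(yc^2) - beta^2 * sxx
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  q <- suppressWarnings(storey_qvalues(p)$qvalues)
  data.frame(gene = rownames(Y), beta = beta, se = se, t = tval, p = p,
             q = q, significant = q < fdr, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' One-step panel adjustment
#'
#' Convenience wrapper chaining the covariate fit, surrogate-variable
#' estimation on the residuals, a refit including the surrogate variables,
#' and (optionally) the within-population inverse-normal transform — the
#' residual phenotypes used by the eQTL scans.
#'
#' @param panel a [study_panel()].
#' @param expr optional [expression_matrix()] overriding the panel's (e.g.
#'   probeset-level values).
#' @param use_sva estimate and adjust for surrogate variables.
#' @param qnorm apply the within-population inverse-normal transform (by
#'   default, on for panels with more than one population).
#' @param sva_args list of arguments forwarded to
#'   [estimate_surrogate_variables()].
#' @param terms fixed terms, as in [fit_covariate_model()].
#'
#' @return An `adjusted_phenotypes` object.
#' @export
adjust_panel <- function(panel, expr = NULL, use_sva = TRUE, qnorm = NULL,
                         sva_args = list(), terms = c("age", "sex", "ancestry")) {
  expr <- expr %||% panel$expression
  dem <- panel$demographics
  fit <- fit_covariate_model(expr, dem, terms = terms)
  if (use_sva) {
    svs <- do.call(estimate_surrogate_variables,
                   c(list(residuals = fit$residuals,
                          known_covariates = fit$design), sva_args))
    if (ncol(svs) > 0)
      fit <- fit_covariate_model(expr, dem, terms = terms, svs = svs)
  }
  qnorm <- qnorm %||% (length(unique(dem$population)) > 1)
  if (qnorm) {
    pops <- dem$population[match(fit$sample_ids, dem$sample_id)]
    if (min(table(pops)) < 2) pops <- rep("all", length(pops))
    fit$residuals <- t(apply(fit$residuals, 1, quantile_normal_transform,
                             groups = pops))
    colnames(fit$residuals) <- fit$sample_ids
    fit$transformed <- TRUE
  }
  fit
}
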