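# Cross-panel replication assessment, baselines and diagnostics.
#
# Replication of a discovery association means: the same SNP, tested in the
# replication panel, has p < 0.05 (strict) and a coefficient of the same
# sign. Concordance-only flags (sign agreement regardless of p) are kept
# alongside, because 50% of true-null discoveries are sign-concordant in one
# panel and 75% in at least one of two -- the analytic fact behind the
# concordance adjustments.

#' Assess replication of discovery associations
#'
#' Joins discovery statistics with per-panel replication statistics and
#' derives the replication flags. A record replicates in a panel when it was
#' tested there, `p < p_thresh` and the effect signs agree. `either`/`both`
#' flags are computed over the panels in which the record was tested;
#' records with a zero discovery coefficient are flagged indeterminate and
#' excluded from rates.
#'
#' @param discovery data.frame with `gene_id`, `snp_id`, `log10_bf`, `beta`
#'   (discovery coefficient), `p` (e.g. the `best` table of a
#'   [cis_scan()]), plus any determinant columns to carry through.
#' @param panels named list of replication statistics, each a data.frame
#'   with `gene_id`, `snp_id`, `beta`, `p`, `tested` (see
#'   [pair_association()]).
#' @param p_thresh nominal replication p threshold (default 0.05, strict).
#'
#' @return data.frame of class `replication_records`: one row per discovery
#'   record with per-panel `beta_<k>`, `p_<k>`, `tested_<k>`,
#'   `replicated_<k>`, `concordant_<k>` and the combined `tested_all`,
#'   `replicated_either`, `replicated_both`, `concordant_either`,
#'   `indeterminate`.
#' @export
assess_replication <- function(discovery, panels, p_thresh = 0.05) {
  assert_that(length(panels) >= 1, "need at least one replication panel")
  if (is.null(names(panels)) || any(names(panels) == ""))
    names(panels) <- paste0("panel", seq_along(panels))
  rec <- discovery
  names(rec)[names(rec) == "beta"] <- "beta_d"
  names(rec)[names(rec) == "p"] <- "p_d"
  rec$indeterminate <- is.na(rec$beta_d) | rec$beta_d == 0
  rep_flags <- conc_flags <- tested <- matrix(FALSE, nrow(rec), length(panels))
  for (k in seq_along(panels)) {
    pk <- panels[[k]]
    m <- match(paste(rec$gene_id, rec$snp_id),
               paste(pk$gene_id, pk$snp_id))
    beta_r <- pk$beta[m]; p_r <- pk$p[m]
    tk <- !is.na(m) & !is.na(pk$tested[m]) & pk$tested[m]
    conc <- tk & !rec$indeterminate & sign(beta_r) == sign(rec$beta_d)
    conc[is.na(conc)] <- FALSE
    repl <- conc & !is.na(p_r) & p_r < p_thresh
    nm <- names(panels)[k]
    rec[[paste0("beta_", nm)]] <- beta_r
    rec[[paste0("p_", nm)]] <- p_r
    rec[[paste0("tested_", nm)]] <- tk
    rec[[paste0("replicated_", nm)]] <- repl
    rec[[paste0("concordant_", nm)]] <- conc
    tested[, k] <- tk; rep_flags[, k] <- repl; conc_flags[, k] <- conc
  }
  rec$tested_all <- rowSums(tested) == length(panels)
  rec$replicated_either <- rowSums(rep_flags) >= 1
  rec$replicated_both <- rowSums(rep_flags) == length(panels)
  rec$concordant_either <- rowSums(conc_flags) >= 1
  rec$concordant_both <- rowSums(conc_flags) == length(panels)
  class(rec) <- c("replication_records", "data.frame")
  attr(rec, "panel_names") <- names(panels)
  attr(rec, "p_thresh") <- p_thresh
  rec
}

#' Replication rate as a function of the discovery Bayes factor
#'
#' `rate(t)` is the fraction of eligible records (tested in all panels, not
#' indeterminate, `log10_bf >= t`) that replicated, per panel and under the
#' either/both standards; denominators are shared across curves. Empty
#' threshold bins yield missing rates.
#'
#' @param records a `replication_records` data.frame.
#' @param bf_grid thresholds on the discovery log10 BF.
#' @param flavor which flag to trace: a panel name, `"either"` or `"both"`
#'   (default all of them).
#'
#' @return data.frame of class `replication_curve` (`threshold`, `flavor`,
#'   `n_eligible`, `n_replicated`, `rate`, `se`).
#' @export
replication_rate_curve <- function(records, bf_grid = seq(0, 20, by = 1),
                                   flavor = NULL) {
  panel_names <- attr(records, "panel_names")
  flavors <- flavor %||% c(panel_names, "either", "both")
  elig <- records$tested_all & !records$indeterminate &
    !is.na(records$log10_bf)
  assert_that(any(elig & records$log10_bf >= min(bf_grid)),
              "no eligible records above the lowest threshold")
  out <- NULL
  for (fl in flavors) {
    col <- switch(fl, either = "replicated_either", both = "replicated_both",
                  paste0("replicated_", fl))
    for (t in bf_grid) {
      sel <- elig & records$log10_bf >= t
      n <- sum(sel); r <- sum(records[[col]][sel])
      rate <- if (n > 0) r / n else NA_real_
      out <- rbind(out, data.frame(
        threshold = t, flavor = fl, n_eligible = n, n_replicated = r,
        rate = rate,
        se = if (n > 0) sqrt(rate * (1 - rate) / n) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("replication_curve", "data.frame")
  out
}

#' Concordance-based adjusted replication estimate
#'
#' Adjusts a raw sign-concordance rate for the fact that half of all
#' false-positive discoveries are sign-concordant in a single replication
#' panel (and three quarters in at least one of two panels): the adjusted
#' estimate is `1 - 2 (1 - c)` for a single panel and `1 - 4 (1 - c)` under
#' the either-of-two standard, floored at 0.
#'
#' @param concordance observed concordance rate in `[0, 1]`.
#' @param scheme `"single_panel"` or `"either_of_two"`.
#'
#' @return adjusted replication estimate in `[0, 1]`.
#' @export
concordance_adjustment <- function(concordance,
                                   scheme = c("single_panel", "either_of_two")) {
  scheme <- match.arg(scheme)
  assert_that(all(concordance >= 0 & concordance <= 1),
              "concordance must lie in [0, 1]")
  mult <- if (scheme == "single_panel") 2 else 4
  pmax(0, 1 - mult * (1 - concordance))
}

#' Demographically matched resampling sets
#'
#' Builds `n_sets` subsets of the source panel matched to a target
#' demographic table: for every target individual, one source individual of
#' the same sex and population with age within `age_tol` years is drawn
#' without replacement (within a set; sets are independent). Infeasible
#' target rows raise an error naming the row; partial sets are never
#' returned.
#'
#' @param panel a [study_panel()] (source of samples).
#' @param target demographics data.frame to match (`sample_id`, `age`,
#'   `sex`, `population`); its row count sets the subset size.
#' @param n_sets number of sets (default 100).
#' @param age_tol age matching tolerance in years (default 3).
#' @param seed integer seed.
#'
#' @return list of character vectors of source sample ids, each of length
#'   `nrow(target)`.
#' @export
matched_resample <- function(panel, target, n_sets = 100, age_tol = 3,
                             seed = 1L) {
  src <- panel$demographics
  elig <- lapply(seq_len(nrow(target)), function(i)
    src$sample_id[src$sex == target$sex[i] &
                    src$population == target$population[i] &
                    abs(src$age - target$age[i]) <= age_tol])
  bad <- which(vapply(elig, length, 1L) == 0)
  if (length(bad))
    stopf("no eligible match for target row %d (%s, %s, age %.1f)",
          bad[1], target$sex[bad[1]], target$population[bad[1]],
          target$age[bad[1]])
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      m <- bipartite_match(lapply(elig, sample))
      if (anyNA(m))
        stopf("no complete sex/population/age matching exists for set %d", s)
      m
    })
  })
}

# Kuhn's augmenting-path maximum bipartite matching. `adj` lists, per target
# row, the eligible source ids (pre-shuffled for a randomized matching).
# Returns the matched source id per target (NA where unmatchable).
bipartite_match <- function(adj) {
  all_src <- unique(unlist(adj))
  owner <- stats::setNames(rep(NA_integer_, length(all_src)), all_src)
  visited <- NULL
  augment <- function(i) {
    for (src in adj[[i]]) {
      if (visited[[src]]) next
      visited[[src]] <<- TRUE
      j <- owner[[src]]
      if (is.na(j) || augment(j)) {
        owner[[src]] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in order(vapply(adj, length, 1L))) {
    visited <- stats::setNames(rep(FALSE, length(all_src)), all_src)
    augment(i)
  }
  assigned <- rep(NA_character_, length(adj))
  matched <- !is.na(owner)
  assigned[owner[matched]] <- names(owner)[matched]
  assigned
}

#' Resampling-based replication baseline
#'
#' For every discovery gene and every resampled subset of the discovery
#' panel, recomputes the single-SNP coefficient and p-value on the subset
#' (covariate residuals fixed from the full panel) and scores replication as
#' sign concordance with the full-panel coefficient plus `p < p_thresh`.
#' Also records the full/resampled coefficient ratio for winner's-curse
#' diagnostics. Subsets in which the SNP is monomorphic are skipped and
#' counted.
#'
#' @param adjusted full-panel adjusted phenotypes.
#' @param genotypes full-panel [genotype_matrix()].
#' @param discovery discovery best-SNP table (`gene_id`, `snp_id`, `beta`,
#'   `log10_bf`).
#' @param sample_sets list of sample-id subsets (from [matched_resample()]).
#' @param p_thresh replication p threshold (default 0.05).
#'
#' @return list of class `resampling_baseline`: `per_gene` (gene, n_resamples,
#'   n_replicating, n_skipped, sim_rate, mean_ratio), `draws` (long table of
#'   per-resample coefficients and ratios), `p_thresh`.
#' @export
resampling_baseline <- function(adjusted, genotypes, discovery, sample_sets,
                                p_thresh = 0.05) {
  Y <- gene_table(adjusted)
  G <- genotypes$dosages
  keep <- !is.na(discovery$snp_id) & !is.na(discovery$beta) &
    discovery$beta != 0
  disc <- discovery[keep, , drop = FALSE]
  draws <- vector("list", nrow(disc))
  per_gene <- data.frame(gene_id = disc$gene_id, log10_bf = disc$log10_bf,
                         n_resamples = length(sample_sets), n_replicating = 0L,
                         n_skipped = 0L, sim_rate = NA_real_,
                         mean_ratio = NA_real_, stringsAsFactors = FALSE)
  set_idx <- lapply(sample_sets, function(s) match(s, rownames(G)))
  for (i in seq_len(nrow(disc))) {
    gid <- disc$gene_id[i]; sid <- disc$snp_id[i]
    y_full <- Y[gid, match(rownames(G), colnames(Y))]
    g <- G[, sid]
    res <- lapply(seq_along(set_idx), function(s) {
      idx <- set_idx[[s]]
      gs <- g[idx]
      if (stats::var(gs) == 0) return(NULL)
      ys <- y_full[idx]
      fit <- single_snp_lm(ys, gs)
      data.frame(gene_id = gid, set = s, beta = fit$beta, p = fit$p,
                 ratio = disc$beta[i] / fit$beta,
                 replicated = fit$p < p_thresh &
                   sign(fit$beta) == sign(disc$beta[i]),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    skipped <- length(set_idx) - NROW(res)
    per_gene$n_skipped[i] <- skipped
    if (NROW(res)) {
      per_gene$n_replicating[i] <- sum(res$replicated)
      per_gene$sim_rate[i] <- mean(res$replicated)
      per_gene$mean_ratio[i] <- mean(res$ratio)
      draws[[i]] <- res
    }
  }
  structure(list(per_gene = per_gene, draws = do.call(rbind, draws),
                 p_thresh = p_thresh),
            class = "resampling_baseline")
}

#' Simulated replication rate by Bayes-factor threshold
#'
#' @param baseline a [resampling_baseline()].
#' @param bf_grid thresholds on the discovery log10 BF.
#' @return data.frame (`threshold`, `n_genes`, `sim_rate`).
#' @export
baseline_rate_curve <- function(baseline, bf_grid = seq(0, 20, by = 1)) {
  pg <- baseline$per_gene
  do.call(rbind, lapply(bf_grid, function(t) {
    sel <- !is.na(pg$sim_rate) & pg$log10_bf >= t
    data.frame(threshold = t, n_genes = sum(sel),
               sim_rate = if (any(sel)) mean(pg$sim_rate[sel]) else NA_real_)
  }))
}

#' Winner's-curse diagnostic table
#'
#' Bins the per-resample full/resampled coefficient ratios and reports the
#' simulated replication rate per ratio bin within each discovery BF
#' stratum. Ratios above 1 are draws in which the resampled coefficient was
#' smaller than the full-data one, i.e. simulated shrinkage; sign-flipped
#' ratios (negative) are binned separately.
#'
#' @param baseline a [resampling_baseline()].
#' @param ratio_breaks bin edges for positive ratios.
#' @param bf_strata lower edges of discovery log10 BF strata.
#'
#' @return data.frame (`bf_stratum`, `ratio_bin`, `n`, `rate`); empty bins
#'   are reported with missing rates.
#' @export
winners_curse_analysis <- function(baseline,
                                   ratio_breaks = c(0, 0.5, 0.8, 1, 1.25, 2,
                                                    Inf),
                                   bf_strata = c(0, 5, 10)) {
  d <- baseline$draws
  pg <- baseline$per_gene
  d$log10_bf <- pg$log10_bf[match(d$gene_id, pg$gene_id)]
  d$stratum <- cut(d$log10_bf, breaks = c(bf_strata, Inf), right = FALSE,
                   labels = paste0("BF>=", bf_strata))
  d$ratio_bin <- ifelse(d$ratio < 0, "sign_flip",
                        as.character(cut(d$ratio, breaks = ratio_breaks)))
  grid <- expand.grid(bf_stratum = levels(d$stratum),
                      ratio_bin = c(levels(cut(1, ratio_breaks)), "sign_flip"),
                      stringsAsFactors = FALSE)
  grid$n <- 0L; grid$rate <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- d$stratum == grid$bf_stratum[i] & d$ratio_bin == grid$ratio_bin[i]
    grid$n[i] <- sum(sel, na.rm = TRUE)
    if (grid$n[i] > 0) grid$rate[i] <- mean(d$replicated[sel], na.rm = TRUE)
  }
  grid
}

#' Logistic model of replication determinants
#'
#' Logistic regression of `replicated_either` on candidate determinants
#' among eligible records with discovery `log10_bf > bf_min`, with optional
#' forward-backward stepwise selection by AIC and per-term likelihood-ratio
#' p-values. Complete separation is detected and reported; the model is then
#' refit with a small ridge penalty and flagged.
#'
#' @param records a `replication_records` data.frame carrying the
#'   determinant columns.
#' @param terms determinant column names (e.g. `log10_bf`, `abs_tss`,
#'   `mean_expr`, `cv_expr`, `probe_snp`, `maf`, `imputed`).
#' @param interactions optional character vector of `a:b` interaction terms.
#' @param stepwise run AIC stepwise selection (default FALSE).
#' @param bf_min restrict to records with discovery log10 BF above this
#'   (default 5; use `-Inf` for all).
#'
#' @return list of class `determinant_model`: `fit` (glm), `lrt` (per-term
#'   LRT chi-squared p-values), `separation` flag, `n`, `formula`.
#' @export
replication_determinants <- function(records, terms,
                                     interactions = character(0),
                                     stepwise = FALSE, bf_min = 5) {
  elig <- records$tested_all & !records$indeterminate &
    !is.na(records$log10_bf) & records$log10_bf > bf_min
  d <- as.data.frame(records)[elig, , drop = FALSE]
  d$.y <- records$replicated_either[elig]
  assert_that(length(unique(d$.y)) == 2,
              "need both replicated and non-replicated records")
  rhs <- paste(c(terms, interactions), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  glm_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        glm_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  separation <- glm_warned || !fit$converged ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (separation) {
    fit <- ridge_logistic(form, d)
  }
  if (stepwise && !separation) {
    fit <- stats::step(fit, trace = 0,
                       scope = list(lower = .y ~ 1, upper = form),
                       direction = "both")
  }
  lrt <- if (!separation && length(attr(stats::terms(fit), "term.labels")))
    stats::drop1(fit, test = "LRT") else NULL
  structure(list(fit = fit, lrt = lrt, separation = separation, n = nrow(d),
                 formula = form), class = "determinant_model")
}

# Minimal ridge-penalized logistic IRLS used only as a separation fallback.
ridge_logistic <- function(formula, data, lambda = 1e-2, maxit = 100) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  b <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    grad <- crossprod(X, y - mu) - pen %*% b
    H <- crossprod(X * W, X) + pen
    step <- solve(H, grad)
    b <- b + step
    if (max(abs(step)) < 1e-8) break
  }
  structure(list(coefficients = stats::setNames(as.numeric(b), colnames(X)),
                 penalty = lambda, converged = it < maxit, ridge = TRUE),
            class = "ridge_logistic")
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' hit set and a gene category within a universe.
#'
#' @param hit_set,category,universe character vectors of gene ids
#'   (`hit_set` and `category` must be subsets of `universe`).
#'
#' @return p-value.
#' @export
enrichment_hypergeometric <- function(hit_set, category, universe) {
  assert_that(length(universe) > 0, "empty universe")
  assert_that(all(hit_set %in% universe) && all(category %in% universe),
              "hit_set and category must be subsets of the universe")
  hit_set <- unique(hit_set); category <- unique(category)
  q <- length(intersect(hit_set, category))
  stats::phyper(q - 1, length(category),
                length(universe) - length(category), length(hit_set),
                lower.tail = FALSE)
}

#' Cross-panel effect-size correlation
#'
#' Rank (or Pearson) correlation between discovery and replication
#' coefficients among eligible records.
#'
#' @param records a `replication_records` data.frame.
#' @param panel replication panel name (a `beta_<panel>` column must exist).
#' @param method correlation method (default `"spearman"`).
#'
#' @return correlation coefficient, or `NA` when undefined.
#' @export
effect_correlation <- function(records, panel, method = "spearman") {
  b_r <- records[[paste0("beta_", panel)]]
  sel <- records$tested_all & !records$indeterminate & !is.na(b_r)
  x <- records$beta_d[sel]; y <- b_r[sel]
  assert_that(length(x) >= 3, "need at least 3 paired coefficients")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Attribute non-replication to probe hybridization artifacts
#'
#' Per discovery-BF stratum, compares replication rates of records whose
#' probes do or do not overlap a variant and expresses the difference on the
#' non-replication scale: the attributable fraction is
#' `(nonrep_with - nonrep_without) / nonrep_with`. Also fits the logistic
#' probe-SNP x BF interaction model. Strata with fewer than 10 records per
#' arm are flagged low-confidence.
#'
#' @param records a `replication_records` data.frame with a `probe_snp`
#'   column (count or flag of in-probe variants).
#' @param bf_strata lower edges of discovery log10 BF strata.
#'
#' @return list of class `artifact_attribution`: `table` (per-stratum rates
#'   and attributable fraction), `interaction_p` (probe-SNP x BF LRT p).
#' @export
probe_artifact_attribution <- function(records, bf_strata = c(0, 5, 10)) {
  assert_that(!is.null(records$probe_snp), "records need a probe_snp column")
  elig <- records$tested_all & !records$indeterminate &
    !is.na(records$log10_bf)
  d <- as.data.frame(records)[elig, , drop = FALSE]
  d$has_snp <- d$probe_snp > 0
  tab <- do.call(rbind, lapply(bf_strata, function(t) {
    s <- d[d$log10_bf >= t, , drop = FALSE]
    rw <- mean(s$replicated_either[s$has_snp])
    ro <- mean(s$replicated_either[!s$has_snp])
    data.frame(bf_min = t,
               n_with = sum(s$has_snp), n_without = sum(!s$has_snp),
               rate_with = rw, rate_without = ro,
               attributable_frac =
                 if (!is.na(rw) && !is.na(ro) && (1 - rw) > 0)
                   ((1 - rw) - (1 - ro)) / (1 - rw) else NA_real_,
               low_confidence = sum(s$has_snp) < 10 || sum(!s$has_snp) < 10,
               stringsAsFactors = FALSE)
  }))
  interaction_p <- NA_real_
  if (length(unique(d$replicated_either)) == 2 &&
      length(unique(d$has_snp)) == 2) {
    # perfect per-arm replication makes the interaction fit separate; the
    # LRT p is still reported, separation warnings are expected noise here
    f1 <- suppressWarnings(stats::glm(replicated_either ~ log10_bf * has_snp,
                                      family = stats::binomial(), data = d))
    f0 <- suppressWarnings(stats::glm(replicated_either ~ log10_bf + has_snp,
                                      family = stats::binomial(), data = d))
    interaction_p <- stats::anova(f0, f1, test = "LRT")$`Pr(>Chi)`[2]
  }
  structure(list(table = tab, interaction_p = interaction_p),
            class = "artifact_attribution")
}
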