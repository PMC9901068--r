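#' Standardize an expression matrix gene-wise
#'
#' Converts a genes x samples log2 expression matrix into per-gene Z-scores
#' across samples (mean 0, SD 1 with the n-1 denominator), within a single
#' cohort. Zero-variance genes are dropped with a warning.
#'
#' @param expression numeric genes x samples matrix.
#' @return standardized matrix of the same shape (minus dropped genes).
#' @export
standardize_expression <- function(expression) {
  stop_if_not(is.matrix(expression) && is.numeric(expression),
              "'expression' must be a numeric matrix")
  stop_if_not(ncol(expression) >= 2, "need at least 2 samples to standardize")
  v <- apply(expression, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    expression <- expression[v > 0, , drop = FALSE]
  }
  t(scale(t(expression)))
}

#' Compute polytranscriptomic scores across p-value thresholds
#'
#' For each threshold t, PTS of sample s is the sum over genes with TWAS
#' p <= t of (TWAS Z weight) x (standardized observed expression Z of the
#' gene in s). Genes absent from the target expression matrix are skipped;
#' the number of genes actually used is recorded per threshold. A threshold
#' at which no weighted gene overlaps the expression data yields missing
#' scores with a warning.
#'
#' @param expr_z standardized expression matrix from
#'   [standardize_expression()].
#' @param weights gene weight table (`gene_id`, `Z`, `p`), typically from
#'   [average_duplicate_genes()].
#' @param thresholds numeric vector of p-value cutoffs.
#' @return list with `scores` (samples x thresholds matrix, columns named by
#'   threshold) and `n_genes_used` (integer vector per threshold).
#' @export
compute_pts <- function(expr_z, weights,
                        thresholds = c(1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1,
                                       0.5, 1)) {
  overlap <- intersect(weights$gene_id, rownames(expr_z))
  stop_if_not(length(overlap) >= 1,
              "no overlap between weight genes and expression genes")
  scores <- matrix(NA_real_, ncol(expr_z), length(thresholds),
                   dimnames = list(colnames(expr_z),
                                   format(thresholds, scientific = TRUE,
                                          trim = TRUE)))
  n_used <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    w <- weights[weights$p <= thresholds[k] &
                   weights$gene_id %in% overlap, , drop = FALSE]
    n_used[k] <- nrow(w)
    if (nrow(w) == 0) {
      warning(sprintf("no genes pass threshold %g; scores set to NA",
                      thresholds[k]))
      next
    }
    scores[, k] <- as.vector(crossprod(expr_z[w$gene_id, , drop = FALSE], w$Z))
  }
  list(scores = scores, n_genes_used = n_used)
}

#' Convert observed-scale R-squared to the liability scale
#'
#' Ascertainment-corrected transformation for binary outcomes analysed by
#' linear regression on the observed 0/1 scale (Lee et al. 2012,
#' Genet. Epidemiol. 36:214-224). With t the upper-K quantile of the
#' standard normal, z the normal density at t, and m = z/K:
#' C = K(1-K)/z^2 x K(1-K)/(P(1-P)),
#' theta = m (P-K)/(1-K) (m (P-K)/(1-K) - t),
#' R2_liability = C R2_obs / (1 + C theta R2_obs).
#'
#' @param r2_obs observed-scale R-squared in [0, 1].
#' @param K population prevalence in (0, 1).
#' @param P sample case fraction in (0, 1).
#' @return liability-scale R-squared.
#' @export
obs_to_liability_r2 <- function(r2_obs, K, P) {
  stop_if_not(all(r2_obs >= 0 & r2_obs <= 1), "'r2_obs' must lie in [0, 1]")
  stop_if_not(all(K > 0 & K < 1), "'K' must lie in (0, 1)")
  stop_if_not(all(P > 0 & P < 1), "'P' must lie in (0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
  d <- m * (P - K) / (1 - K)
  theta <- d * (d - t)
  C * r2_obs / (1 + C * theta * r2_obs)
}

#' Test PTS association with an outcome by linear regression
#'
#' Ordinary least squares of the outcome on the PTS plus covariates (sex by
#' default). Binary outcomes are coded 0/1 (control/spinal = 0, case/bulbar
#' = 1) and still fitted by linear regression, as the liability conversion
#' presumes an observed-scale linear R-squared. Clinical outcomes (site of
#' onset, age at onset, survival) are analysed within cases only. The
#' reported R2 is the incremental R-squared of the PTS over the
#' covariate-only model; for binary outcomes it is additionally converted to
#' the liability scale with prevalence `K`.
#'
#' @param pts named numeric vector of scores (names = sample ids).
#' @param phenotypes phenotype table with `sample_id`, `status`, `sex`,
#'   `site_of_onset`, `age_at_onset`, `survival`.
#' @param outcome one of `"case_control"`, `"site_of_onset"`,
#'   `"age_at_onset"`, `"survival"`.
#' @param covariates character vector of phenotype columns to adjust for.
#' @param K population prevalence for the liability conversion; defaults to
#'   1/300 for case-control and 0.5 for site of onset.
#' @return one-row data.frame: `outcome`, `beta`, `se`, `p`, `r2_obs`,
#'   `r2_liability` (NA for continuous outcomes), `n`, `K`, `P`.
#' @export
associate <- function(pts, phenotypes,
                      outcome = c("case_control", "site_of_onset",
                                  "age_at_onset", "survival"),
                      covariates = "sex", K = NULL) {
  outcome <- match.arg(outcome)
  phen <- phenotypes[match(names(pts), phenotypes$sample_id), , drop = FALSE]
  stop_if_not(!anyNA(phen$sample_id), "PTS sample ids missing from phenotypes")
  binary <- outcome %in% c("case_control", "site_of_onset")
  y <- switch(outcome,
              case_control = as.numeric(phen$status),
              site_of_onset = ifelse(phen$site_of_onset == "bulbar", 1,
                                     ifelse(phen$site_of_onset == "spinal", 0,
                                            NA_real_)),
              age_at_onset = as.numeric(phen$age_at_onset),
              survival = as.numeric(phen$survival))
  if (outcome != "case_control") {
    y[phen$status != 1] <- NA  # clinical outcomes within cases only
  }
  covs <- phen[, covariates, drop = FALSE]
  rownames(covs) <- NULL
  df <- data.frame(y = y, pts = as.numeric(pts), covs)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  stop_if_not(nrow(df) > length(covariates) + 2,
              "too few non-missing samples for the regression")
  stop_if_not(stats::var(df$y) > 0, "outcome is constant")
  stop_if_not(stats::var(df$pts) > 0, "PTS is constant")

  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(paste("y ~ pts +", rhs_cov)), data = df)
  base <- stats::lm(stats::as.formula(paste("y ~", rhs_cov)), data = df)
  sm <- summary(full)
  co <- sm$coefficients["pts", ]
  r2_obs <- max(0, sm$r.squared - summary(base)$r.squared)
  P <- if (binary) mean(df$y) else NA_real_
  if (is.null(K)) {
    K <- switch(outcome, case_control = 1 / 300, site_of_onset = 0.5,
                NA_real_)
  }
  r2_liab <- if (binary) obs_to_liability_r2(r2_obs, K, P) else NA_real_
  data.frame(outcome = outcome, beta = co[["Estimate"]],
             se = co[["Std. Error"]], p = co[["Pr(>|t|)"]],
             r2_obs = r2_obs, r2_liability = r2_liab,
             n = nrow(df), K = if (binary) K else NA_real_, P = P,
             stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools per-cohort estimates with weights 1/se^2:
#' pooled beta = sum(b_i/se_i^2) / sum(1/se_i^2),
#' pooled se = sqrt(1 / sum(1/se_i^2)), p from the normal approximation.
#'
#' @param beta numeric vector of estimates.
#' @param se numeric vector of standard errors (all > 0).
#' @return list `beta`, `se`, `p`, `n_studies`.
#' @export
ivw_meta <- function(beta, se) {
  stop_if_not(length(beta) == length(se) && length(beta) >= 1,
              "'beta' and 'se' must be non-empty and of equal length")
  stop_if_not(all(se > 0), "all standard errors must be > 0")
  w <- 1 / se^2
  b <- sum(beta * w) / sum(w)
  s <- sqrt(1 / sum(w))
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)),
       n_studies = length(beta))
}

#' Build stratified PTS weight tables from retained TWAS associations
#'
#' Applies the tissue stratification (all panels, blood-only, brain-only)
#' and the colocalisation restriction (any, or PP4 > 0.8 only) to a retained
#' association set, then averages duplicate-gene Z-scores within each
#' stratum.
#'
#' @param retained retained association rows after clumping (must carry
#'   `tissue_class` and `PP4`).
#' @param tissues tissue strata to build (subset of `all`, `blood`,
#'   `brain`).
#' @param coloc colocalisation strata (subset of `any`, `coloc_only`).
#' @param pp4_threshold PP4 cutoff for `coloc_only` (strictly greater).
#' @return named list of weight tables keyed `tissue.coloc`.
#' @export
build_pts_weights <- function(retained,
                              tissues = c("all", "blood", "brain"),
                              coloc = c("any", "coloc_only"),
                              pp4_threshold = 0.8) {
  if (inherits(retained, "clump_result")) retained <- retained$retained
  out <- list()
  for (ti in tissues) {
    rows_t <- if (ti == "all") retained else
      retained[retained$tissue_class == ti, , drop = FALSE]
    for (cl in coloc) {
      rows <- if (cl == "any") rows_t else
        rows_t[!is.na(rows_t$PP4) & rows_t$PP4 > pp4_threshold, , drop = FALSE]
      out[[paste(ti, cl, sep = ".")]] <- average_duplicate_genes(rows)
    }
  }
  out
}

#' Meta-analyse PTS association results across cohorts
#'
#' Groups per-cohort [associate()] results by outcome, stratum and
#' threshold, pools beta/se by [ivw_meta()], and summarises R-squared as the
#' sample-size-weighted mean of the per-cohort values.
#'
#' @param results data.frame of stacked per-cohort association rows with
#'   columns `cohort`, `stratum`, `threshold` plus the [associate()] output
#'   columns.
#' @return data.frame with one row per (outcome, stratum, threshold).
#' @export
meta_pts <- function(results) {
  key <- interaction(results$outcome, results$stratum, results$threshold,
                     drop = TRUE)
  rows <- lapply(levels(key), function(lev) {
    g <- results[key == lev, , drop = FALSE]
    m <- ivw_meta(g$beta, g$se)
    data.frame(outcome = g$outcome[1], stratum = g$stratum[1],
               threshold = g$threshold[1],
               beta = m$beta, se = m$se, p = m$p,
               r2_obs = sum(g$r2_obs * g$n) / sum(g$n),
               r2_liability = if (all(is.na(g$r2_liability))) NA_real_ else
                 sum(g$r2_liability * g$n) / sum(g$n),
               n = sum(g$n), n_cohorts = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
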