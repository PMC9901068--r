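#' Per-gene correlation of expression with case-control status
#'
#' Pearson (point-biserial) correlation between observed expression and
#' binary case-control status, per gene, with the Fisher-z standard error
#' 1/sqrt(n-3) and a two-sided p-value from the z statistic. Constant genes
#' are skipped; perfect correlations are shrunk to +/-(1 - 1e-12) before the
#' Fisher transform. Covariates, if given, are regressed out of both
#' expression and status first (partial correlation); the default is
#' unadjusted.
#'
#' @param expression genes x samples matrix (log2 or standardized).
#' @param status 0/1 vector aligned with the sample columns.
#' @param covariates optional data.frame of per-sample covariates.
#' @return data.frame `gene_id`, `r`, `z` (Fisher), `se_z`, `n`, `p`.
#' @export
de_correlation <- function(expression, status, covariates = NULL) {
  stop_if_not(length(status) == ncol(expression),
              "status length must match the number of samples")
  stop_if_not(all(status %in% c(0, 1)), "status must be binary 0/1")
  stop_if_not(length(status) >= 3, "need at least 3 samples")
  y <- as.numeric(status)
  X <- t(expression)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = covariates)
    y <- stats::resid(stats::lm.fit(mm, y))
    X <- apply(X, 2, function(col) stats::resid(stats::lm.fit(mm, col)))
  }
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("skipping %d constant gene(s)", sum(v == 0)))
    X <- X[, v > 0, drop = FALSE]
  }
  r <- as.vector(stats::cor(X, y))
  if (any(abs(r) >= 1)) {
    warning("perfect correlation shrunk before Fisher transform")
    r <- sign(r) * pmin(abs(r), 1 - 1e-12)
  }
  n <- length(y)
  z <- atanh(r)
  se_z <- 1 / sqrt(n - 3)
  data.frame(gene_id = colnames(X), r = r, z = z, se_z = se_z, n = n,
             p = 2 * stats::pnorm(-abs(z / se_z)),
             stringsAsFactors = FALSE)
}

#' Meta-analyse per-cohort differential-expression correlations
#'
#' Inverse-variance-weighted pooling per gene, by default on the Fisher-z
#' scale with weights n-3 (the raw-r scale is available for sensitivity).
#' The pooled z is back-transformed to r and Benjamini-Hochberg correction
#' is applied across all genes.
#'
#' @param cohort_results list of per-cohort [de_correlation()] tables.
#' @param scale `"fisher_z"` (default) or `"raw"`.
#' @return data.frame `gene_id`, `r`, `z`, `se`, `p`, `q`, `n_cohorts`.
#' @export
meta_de <- function(cohort_results, scale = c("fisher_z", "raw")) {
  scale <- match.arg(scale)
  all_rows <- do.call(rbind, cohort_results)
  rows <- lapply(split(all_rows, all_rows$gene_id), function(g) {
    est <- if (scale == "fisher_z") g$z else g$r
    m <- ivw_meta(est, g$se_z)
    pooled_z <- m$beta
    data.frame(gene_id = g$gene_id[1],
               r = if (scale == "fisher_z") tanh(pooled_z) else pooled_z,
               z = pooled_z, se = m$se, p = m$p, n_cohorts = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify concordance of predicted and observed differential expression
#'
#' For each high-confidence TWAS gene with observed differential-expression
#' data: if the observed meta q-value is below `fdr`, the gene is
#' `concordant` when the TWAS Z and the observed meta correlation share a
#' sign and `discordant` otherwise; genes without observed FDR significance
#' are `observed_not_significant`. Genes with TWAS Z exactly 0 have no
#' defined direction and are excluded with a warning.
#'
#' @param gene_z gene-level TWAS table (`gene_id`, `Z`) restricted to
#'   high-confidence genes.
#' @param de_meta output of [meta_de()].
#' @param fdr observed-significance threshold on q (default 0.05).
#' @return data.frame `gene_id`, `twas_sign`, `observed_sign`, `call`;
#'   summary counts attached as attribute `counts`.
#' @export
classify_concordance <- function(gene_z, de_meta, fdr = 0.05) {
  zero <- gene_z$Z == 0
  if (any(zero)) {
    warning(sprintf("excluding %d gene(s) with TWAS Z = 0 (undefined sign)",
                    sum(zero)))
    gene_z <- gene_z[!zero, , drop = FALSE]
  }
  merged <- merge(gene_z, de_meta, by = "gene_id")
  sig <- merged$q < fdr
  call <- ifelse(!sig, "observed_not_significant",
                 ifelse(sign(merged$Z) == sign(merged$r),
                        "concordant", "discordant"))
  out <- data.frame(gene_id = merged$gene_id,
                    twas_sign = sign(merged$Z),
                    observed_sign = sign(merged$r),
                    call = call, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    concordant = sum(call == "concordant"),
    discordant = sum(call == "discordant"),
    observed_not_significant = sum(call == "observed_not_significant")
  )
  out
}
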