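#' Code directional drug-gene interactions
#'
#' Maps action labels to signed codes: 'DECREASED_EXPRESSION',
#' 'NEGATIVE_RESPONSE' and 'OPPOSITE_RESPONSE' to -1 (drug decreases gene
#' activity); 'INCREASED_EXPRESSION' and 'POSITIVE_RESPONSE' to +1 (drug
#' increases gene activity); every other label to 0 (no directional
#' evidence). Total and idempotent: recoding a coded table is a no-op.
#'
#' @param interactions data.frame with an `action_label` column.
#' @return the input with a `coded_direction` column in \{-1, 0, 1\}; a
#'   tally of unrecognised labels is reported via `message()`.
#' @export
code_directions <- function(interactions) {
  lab <- interactions$action_label
  code <- integer(length(lab))
  code[lab %in% .decrease_labels] <- -1L
  code[lab %in% .increase_labels] <- 1L
  unknown <- !(lab %in% c(.decrease_labels, .increase_labels,
                          .neutral_labels))
  if (any(unknown)) {
    tal <- table(lab[unknown])
    message("labels coded 0 (no directional evidence): ",
            paste(sprintf("%s (%d)", names(tal), tal), collapse = ", "))
  }
  interactions$coded_direction <- code
  interactions
}

# Build the error-covariance matrix for a drug's tested genes: identity with
# known predicted-expression correlations filled in off-diagonal.
gene_covariance <- function(genes, gene_correlations) {
  V <- diag(length(genes))
  dimnames(V) <- list(genes, genes)
  if (!is.null(gene_correlations) && nrow(gene_correlations)) {
    gc <- gene_correlations[gene_correlations$gene_a %in% genes &
                              gene_correlations$gene_b %in% genes, ,
                            drop = FALSE]
    if (nrow(gc)) {
      V[cbind(gc$gene_a, gc$gene_b)] <- gc$r
      V[cbind(gc$gene_b, gc$gene_a)] <- gc$r
    }
  }
  V
}

#' Collapse unit-level predicted correlations to the gene level
#'
#' Averages the predicted-expression correlations of all (panel) unit pairs
#' of two genes, giving the gene-level co-regulation matrix entries used by
#' [directional_enrichment()].
#'
#' @param correlations unit-pair table from
#'   [pairwise_predicted_correlation()].
#' @return data.frame `gene_a`, `gene_b`, `r` (unordered gene pairs,
#'   excluding same-gene pairs).
#' @export
gene_correlation_from_units <- function(correlations) {
  if (nrow(correlations) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  }
  split_gene <- function(u) vapply(strsplit(u, "::", fixed = TRUE), `[`, "", 1)
  ga <- split_gene(correlations$unit_a)
  gb <- split_gene(correlations$unit_b)
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]; r <- correlations$r[keep]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  key <- paste(ga, gb, sep = "\r")
  agg <- tapply(r, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1),
             gene_b = vapply(parts, `[`, "", 2),
             r = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Directional, co-regulation-aware drug enrichment
#'
#' For each drug with at least `min_genes` target genes that have TWAS
#' statistics, regresses the gene-level TWAS Z-scores on the drug's coded
#' direction vector by generalized least squares, with error covariance
#' equal to the predicted-expression correlation matrix restricted to the
#' tested genes (identity beyond known pairs). The reported enrichment Z is
#' the negated slope Z so that, given the TWAS convention (positive gene Z =
#' increased expression raises risk), a positive enrichment Z means the
#' drug-induced expression profile is predicted to reduce risk (protective).
#' With identity covariance the test reduces exactly to the OLS slope
#' t-test. This is a documented surrogate for direction-aware TWAS gene-set
#' enrichment; it is not claimed to be bit-compatible with any external
#' mixed-model implementation.
#'
#' @param gene_z gene-level TWAS table (`gene_id`, `Z`), typically from
#'   [average_duplicate_genes()].
#' @param coded_interactions output of [code_directions()].
#' @param gene_correlations optional gene-pair table from
#'   [gene_correlation_from_units()].
#' @param min_genes minimum number of target genes with statistics
#'   (default 2).
#' @param ridge_eps initial ridge added to a non-positive-definite
#'   covariance (escalated tenfold until factorization succeeds).
#' @return data.frame `drug_id`, `method` (`"directional_twas"`), `Z`, `p`,
#'   `n_genes_tested`; drugs failing the gene filter or with a constant
#'   direction vector are skipped.
#' @export
directional_enrichment <- function(gene_z, coded_interactions,
                                   gene_correlations = NULL, min_genes = 2,
                                   ridge_eps = 1e-8) {
  stop_if_not("coded_direction" %in% names(coded_interactions),
              "run code_directions() first")
  zmap <- stats::setNames(gene_z$Z, gene_z$gene_id)
  rows <- list()
  for (drug in unique(coded_interactions$drug_id)) {
    tg <- coded_interactions[coded_interactions$drug_id == drug, , drop = FALSE]
    tg <- tg[!duplicated(tg$gene_id), , drop = FALSE]
    tg <- tg[tg$gene_id %in% names(zmap), , drop = FALSE]
    n <- nrow(tg)
    if (n < min_genes) next
    d <- tg$coded_direction
    if (stats::var(d) == 0) next  # slope inestimable
    z <- zmap[tg$gene_id]
    V <- gene_covariance(tg$gene_id, gene_correlations)
    ch <- NULL
    eps <- ridge_eps
    repeat {
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (!is.null(ch)) break
      if (eps > 1e-2) stop("covariance not stabilisable for drug ", drug)
      message(sprintf("ridge-stabilising covariance for %s (eps = %g)",
                      drug, eps))
      V <- V + diag(eps, n)
      eps <- eps * 10
    }
    Vi <- chol2inv(ch)
    X <- cbind(1, d)
    XtVi <- crossprod(X, Vi)
    B <- solve(XtVi %*% X, XtVi %*% z)
    if (n > 2) {
      resid <- z - X %*% B
      sigma2 <- as.numeric(crossprod(resid, Vi %*% resid)) / (n - 2)
      se <- sqrt(sigma2 * solve(XtVi %*% X)[2, 2])
      tstat <- B[2] / se
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    } else {
      # with exactly 2 genes the residual df is zero, so use the unit null
      # variance of TWAS Z-scores instead of an estimated error variance
      se <- sqrt(solve(XtVi %*% X)[2, 2])
      tstat <- B[2] / se
      p <- 2 * stats::pnorm(-abs(tstat))
    }
    rows[[drug]] <- data.frame(
      drug_id = drug, method = "directional_twas",
      Z = -tstat, p = p,
      n_genes_tested = n, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(drug_id = character(), method = character(),
                      Z = numeric(), p = numeric(),
                      n_genes_tested = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Import externally computed per-drug enrichment statistics
#'
#' Normalizes MAGMA- or co-regulation-score-style per-drug outputs into the
#' common enrichment format. A missing Z column is back-filled from the
#' one-sided p-value as the upper normal quantile (larger Z = stronger
#' enrichment); a missing p is filled from Z one-sided.
#'
#' @param table data.frame with `drug_id` and at least one of `Z`, `p`.
#' @param method `"external_magma"` or `"external_gcsc"`.
#' @return data.frame `drug_id`, `method`, `Z`, `p` (plus `n_genes_tested`
#'   if present in the input).
#' @export
import_external_enrichment <- function(table,
                                       method = c("external_magma",
                                                  "external_gcsc")) {
  method <- match.arg(method)
  stop_if_not("drug_id" %in% names(table), "'drug_id' column required")
  stop_if_not(any(c("Z", "p") %in% names(table)),
              "either 'Z' or 'p' must be present")
  stop_if_not(!anyDuplicated(table$drug_id), "duplicate drug rows")
  Z <- if ("Z" %in% names(table)) table$Z else
    stats::qnorm(1 - table$p)  # one-sided convention: larger Z = enriched
  p <- if ("p" %in% names(table)) table$p else stats::pnorm(-Z)
  out <- data.frame(drug_id = table$drug_id, method = method, Z = Z, p = p,
                    stringsAsFactors = FALSE)
  if ("n_genes_tested" %in% names(table)) {
    out$n_genes_tested <- table$n_genes_tested
  }
  out
}

#' FDR-correct drug enrichment results within method
#'
#' Benjamini-Hochberg q-values computed separately per enrichment method.
#'
#' @param enrichments stacked enrichment rows with `method` and `p`.
#' @return the input with a `q` column.
#' @export
fdr_drugs <- function(enrichments) {
  fdr_correct(enrichments, grouping = "method")
}

# standardized rank-sum statistic with tie correction (reported as the
# signed group Z; positive = in-group statistics rank higher)
rank_sum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (W - mu) / sqrt(sigma2)
}

#' ATC pharmacological-class enrichment by rank-sum test
#'
#' For each level-3 ATC group with at least `min_drugs` drugs carrying an
#' enrichment statistic, compares the in-group drug statistics against all
#' other drugs with a Wilcoxon rank-sum (Mann-Whitney) test. External
#' (unsigned) methods use a one-sided test (group greater); the directional
#' method uses a two-sided test, and the signed standardized group Z is
#' reported so the direction of class enrichment is preserved. The exact
#' distribution is used when both sides have at most 25 drugs and there are
#' no ties; otherwise the normal approximation with tie correction.
#' Benjamini-Hochberg correction is applied across tested groups.
#'
#' @param enrichments per-drug enrichment rows of a single method (`drug_id`,
#'   `method`, `Z`).
#' @param atc_map drug-to-ATC table (`drug_id`, `atc_code`; one code per
#'   drug).
#' @param min_drugs minimum group size (default 5).
#' @return data.frame `atc_code`, `method`, `n_drugs_in_group`, `W`, `Z`,
#'   `p`, `q`; empty (with a warning) when no group passes the size filter.
#' @export
atc_wilcoxon <- function(enrichments, atc_map, min_drugs = 5) {
  stop_if_not(length(unique(enrichments$method)) <= 1,
              "run atc_wilcoxon() per enrichment method")
  stop_if_not(!anyDuplicated(atc_map$drug_id),
              "each drug must map to exactly one ATC code")
  merged <- merge(enrichments, atc_map, by = "drug_id")
  stop_if_not(!anyDuplicated(merged$drug_id),
              "each drug must have exactly one enrichment statistic")
  method <- merged$method[1]
  alt <- if (identical(method, "directional_twas")) "two.sided" else "greater"
  sizes <- table(merged$atc_code)
  groups <- names(sizes)[sizes >= min_drugs]
  if (length(groups) == 0) {
    warning("no ATC group passes the minimum size filter")
    return(data.frame(atc_code = character(), method = character(),
                      n_drugs_in_group = integer(), W = numeric(),
                      Z = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(groups, function(g) {
    x <- merged$Z[merged$atc_code == g]
    y <- merged$Z[merged$atc_code != g]
    exact <- length(x) <= 25 && length(y) <= 25 &&
      !any(duplicated(c(x, y)))
    wt <- stats::wilcox.test(x, y, alternative = alt, exact = exact,
                             correct = !exact)
    data.frame(atc_code = g, method = method,
               n_drugs_in_group = length(x),
               W = unname(wt$statistic), Z = rank_sum_z(x, y),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
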