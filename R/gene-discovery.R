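#' Benjamini-Hochberg correction within method strata
#'
#' Adds FDR-adjusted q-values to a TWAS/PWAS association table. Correction
#' pools all expression panels within each (method, molecular type) stratum
#' -- i.e. across all expression panels for FUSION and for SMR separately,
#' with protein (PWAS) panels corrected apart from expression panels.
#'
#' @param associations data.frame with at least `p` plus the grouping
#'   columns.
#' @param grouping character vector of column names defining the correction
#'   strata.
#' @return the input with a `q` column added.
#' @export
fdr_correct <- function(associations, grouping = c("method", "molecular_type")) {
  stop_if_not(all(grouping %in% names(associations)),
              "grouping columns missing from 'associations'")
  p <- associations$p
  stop_if_not(is.numeric(p) && all(!is.na(p)) && all(p > 0 & p <= 1),
              "all p-values must lie in (0, 1]")
  key <- interaction(associations[grouping], drop = TRUE)
  q <- numeric(length(p))
  for (lev in levels(key)) {
    i <- key == lev
    q[i] <- stats::p.adjust(p[i], method = "BH")
  }
  associations$q <- q
  associations
}

#' Colocalisation filter on posterior probabilities
#'
#' Passes when the posterior probability of a shared causal variant dominates
#' that of linkage: PP4 / (PP3 + PP4) strictly greater than `ratio`.
#'
#' @param PP3,PP4 coloc posterior probabilities (vectors allowed).
#' @param ratio threshold for the PP4 ratio (default 0.8).
#' @return logical vector.
#' @export
coloc_pass <- function(PP3, PP4, ratio = 0.8) {
  stop_if_not(all(!is.na(PP3)) && all(!is.na(PP4)),
              "PP3 and PP4 must be non-missing")
  stop_if_not(all(PP3 >= 0) && all(PP4 >= 0), "PP3 and PP4 must be >= 0")
  if (any(PP3 + PP4 == 0)) {
    stop("PP3 + PP4 = 0: colocalisation ratio undefined", call. = FALSE)
  }
  PP4 / (PP3 + PP4) > ratio
}

#' HEIDI heterogeneity filter
#'
#' An SMR association is consistent with a single shared causal variant when
#' the HEIDI p-value strictly exceeds `threshold`.
#'
#' @param heidi_p HEIDI p-values (vector allowed).
#' @param threshold default 0.05.
#' @return logical vector.
#' @export
heidi_pass <- function(heidi_p, threshold = 0.05) {
  if (any(is.na(heidi_p))) {
    stop("missing HEIDI p-value on an SMR row", call. = FALSE)
  }
  heidi_p > threshold
}

#' Credible-set containment in a gene interval
#'
#' Tests whether every variant of a fine-mapping credible set lies within a
#' gene's body interval (1-based inclusive, same chromosome). An optional
#' symmetric flanking window can widen the interval; the default is the bare
#' gene body.
#'
#' @param cs_chrom,cs_pos chromosome and positions of the credible-set
#'   variants.
#' @param gene_chrom,gene_start,gene_end the gene interval.
#' @param window flanking window in bp added to both sides (default 0).
#' @return single logical.
#' @export
credible_set_contained <- function(cs_chrom, cs_pos, gene_chrom, gene_start,
                                   gene_end, window = 0) {
  stop_if_not(length(cs_pos) >= 1, "credible set must be non-empty")
  all(cs_chrom == gene_chrom) &&
    all(cs_pos >= gene_start - window & cs_pos <= gene_end + window)
}

#' Call high-confidence genes from fine-mapping, TWAS and PWAS evidence
#'
#' A gene is called high-confidence if it satisfies any of three criteria:
#' (1) the gene contains all variants of a 95% credible set;
#' (2) an FDR-significant FUSION TWAS/PWAS association that colocalises
#'     (PP4/(PP3+PP4) > 0.8);
#' (3) an FDR-significant SMR association that colocalises
#'     (HEIDI p > 0.05).
#' All thresholds are strict inequalities.
#'
#' @param associations FDR-annotated table from [fdr_correct()].
#' @param credible_sets credible-set variant table (`locus_id`, `chrom`,
#'   `pos`), or `NULL`.
#' @param gene_map gene interval table (`gene_id`, `chrom`, `start`, `end`).
#' @param fdr_threshold q-value cutoff defining FDR significance.
#' @param coloc_ratio PP4-ratio threshold.
#' @param heidi_threshold HEIDI p-value threshold.
#' @param window credible-set containment flanking window in bp.
#' @return data.frame of called genes with logical evidence flags
#'   `credible_set`, `fusion_coloc`, `smr_heidi` and the number of
#'   supporting association rows; the unique-gene count is attached as
#'   attribute `n_genes`.
#' @export
call_high_confidence <- function(associations, credible_sets, gene_map,
                                 fdr_threshold = 0.05, coloc_ratio = 0.8,
                                 heidi_threshold = 0.05, window = 0) {
  stop_if_not("q" %in% names(associations),
              "run fdr_correct() before calling high-confidence genes")
  fus <- associations$method == "FUSION" & associations$q < fdr_threshold &
    !is.na(associations$PP3) & !is.na(associations$PP4)
  if (any(fus)) {
    fus[fus] <- coloc_pass(associations$PP3[fus], associations$PP4[fus],
                           ratio = coloc_ratio)
  }
  smr_rows <- associations$method == "SMR"
  if (any(smr_rows & is.na(associations$heidi_p))) {
    stop("missing HEIDI p-value on an SMR row", call. = FALSE)
  }
  smr <- smr_rows & associations$q < fdr_threshold &
    !is.na(associations$heidi_p) & associations$heidi_p > heidi_threshold

  fus_genes <- unique(associations$gene_id[fus])
  smr_genes <- unique(associations$gene_id[smr])

  cs_genes <- character(0)
  if (!is.null(credible_sets) && nrow(credible_sets) > 0) {
    for (loc in unique(credible_sets$locus_id)) {
      cs <- credible_sets[credible_sets$locus_id == loc, ]
      hit <- vapply(seq_len(nrow(gene_map)), function(i) {
        g <- gene_map[i, ]
        credible_set_contained(cs$chrom, cs$pos, g$chrom, g$start, g$end,
                               window = window)
      }, logical(1))
      cs_genes <- union(cs_genes, gene_map$gene_id[hit])
    }
  }

  called <- sort(unique(c(fus_genes, smr_genes, cs_genes)))
  support <- table(associations$gene_id[(fus | smr)])
  out <- data.frame(
    gene_id = called,
    credible_set = called %in% cs_genes,
    fusion_coloc = called %in% fus_genes,
    smr_heidi = called %in% smr_genes,
    n_supporting_rows = as.integer(support[called]),
    stringsAsFactors = FALSE
  )
  out$n_supporting_rows[is.na(out$n_supporting_rows)] <- 0L
  rownames(out) <- NULL
  attr(out, "n_genes") <- length(called)
  out
}
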