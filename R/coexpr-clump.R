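#' Predict expression into a reference genotype panel
#'
#' For every (gene, panel) SNP-weight model, computes the per-individual
#' linear predictor (sum of allele count x weight over the model's variants)
#' in the reference panel, then standardizes it to mean 0, SD 1 across
#' individuals. Units whose predicted expression has zero variance (e.g. all
#' weights zero) are excluded with a warning.
#'
#' @param weights long-format weight table (`gene_id`, `panel_id`,
#'   `variant_id`, `weight`).
#' @param genotypes reference allele-count matrix (individuals x variants,
#'   columns named by variant id).
#' @return matrix individuals x units, columns named `gene::panel`,
#'   standardized; the unit table is attached as attribute `units`.
#' @export
predict_expression <- function(weights, genotypes) {
  missing_v <- setdiff(unique(weights$variant_id), colnames(genotypes))
  stop_if_not(length(missing_v) == 0,
              sprintf("%d weight variants absent from the genotype matrix",
                      length(missing_v)))
  weights$unit <- unit_id(weights$gene_id, weights$panel_id)
  units <- unique(weights[c("unit", "gene_id", "panel_id")])
  pred <- matrix(NA_real_, nrow(genotypes), nrow(units),
                 dimnames = list(rownames(genotypes), units$unit))
  for (i in seq_len(nrow(units))) {
    w <- weights[weights$unit == units$unit[i], ]
    pred[, i] <- as.vector(genotypes[, w$variant_id, drop = FALSE] %*% w$weight)
  }
  v <- apply(pred, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d unit(s) with zero-variance predicted expression: %s",
                    sum(v == 0), paste(units$unit[v == 0], collapse = ", ")))
    pred <- pred[, v > 0, drop = FALSE]
    units <- units[v > 0, , drop = FALSE]
  }
  pred <- scale(pred)
  attr(pred, "scaled:center") <- NULL
  attr(pred, "scaled:scale") <- NULL
  attr(pred, "units") <- units
  pred
}

#' Pairwise predicted-expression correlations within a proximity window
#'
#' Computes the Pearson correlation of predicted expression for every pair of
#' (gene, panel) units whose genes lie on the same chromosome within
#' `window_bp` of each other (distance measured between gene start
#' coordinates by default, or midpoints). Pairs outside the window are not
#' emitted and are treated as r = 0 by [clump()]. Different panel models of
#' the same gene are distance-0 pairs and always eligible.
#'
#' @param predicted standardized unit matrix from [predict_expression()].
#' @param gene_map gene interval table (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp proximity window in bp (default 500000).
#' @param anchor `"start"` (default) or `"midpoint"`: coordinate used to
#'   measure inter-gene distance.
#' @return data.frame `unit_a`, `unit_b`, `r` (each unordered pair once).
#' @export
pairwise_predicted_correlation <- function(predicted, gene_map,
                                           window_bp = 5e5,
                                           anchor = c("start", "midpoint")) {
  anchor <- match.arg(anchor)
  stop_if_not(!anyNA(predicted), "predicted expression contains missing values")
  units <- attr(predicted, "units")
  if (is.null(units)) {
    parts <- strsplit(colnames(predicted), "::", fixed = TRUE)
    units <- data.frame(unit = colnames(predicted),
                        gene_id = vapply(parts, `[`, "", 1),
                        panel_id = vapply(parts, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  pos <- if (anchor == "start") gene_map$start else
    (gene_map$start + gene_map$end) / 2
  gidx <- match(units$gene_id, gene_map$gene_id)
  stop_if_not(!anyNA(gidx), "unit gene missing from gene map")
  chrom <- gene_map$chrom[gidx]
  coord <- pos[gidx]
  n <- ncol(predicted)
  res <- vector("list", n)
  for (i in seq_len(max(0, n - 1))) {
    j <- which(seq_len(n) > i & chrom == chrom[i] &
                 abs(coord - coord[i]) <= window_bp)
    if (length(j) == 0) next
    r <- as.vector(stats::cor(predicted[, i], predicted[, j, drop = FALSE]))
    res[[i]] <- data.frame(unit_a = colnames(predicted)[i],
                           unit_b = colnames(predicted)[j],
                           r = r, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(unit_a = character(), unit_b = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# deterministic clump ordering: ascending p, then larger |Z|, then
# lexicographic (gene, panel)
clump_order <- function(associations) {
  order(associations$p, -abs(associations$Z), associations$gene_id,
        associations$panel_id)
}

#' Greedy clumping of TWAS associations on predicted-expression correlation
#'
#' Ranks associations by ascending p-value (ties broken by larger absolute Z,
#' then lexicographic gene and panel id), takes the best remaining
#' association as the lead, removes every unit whose predicted-expression
#' correlation with the lead strictly exceeds `r_thresh`, and repeats until
#' the list is exhausted. Pairs absent from `correlations` (outside the
#' proximity window) are treated as r = 0 and never clumped together.
#'
#' @param associations TWAS association table (`gene_id`, `panel_id`, `Z`,
#'   `p`, plus any carried columns).
#' @param correlations pair table from [pairwise_predicted_correlation()].
#' @param r_thresh correlation threshold (default 0.95); removal requires
#'   r strictly greater.
#' @param known_units optional character vector of unit ids for which
#'   predicted expression exists; associations outside it are retained with
#'   a warning (they cannot be clumped).
#' @return list of class `clump_result`: `retained` (association rows kept),
#'   `removed` (data.frame `unit`, `lead_unit`).
#' @export
clump <- function(associations, correlations, r_thresh = 0.95,
                  known_units = NULL) {
  associations$unit <- unit_id(associations$gene_id, associations$panel_id)
  stop_if_not(!anyDuplicated(associations$unit),
              "duplicate (gene, panel) units in associations")
  unclumpable <- character(0)
  if (!is.null(known_units)) {
    unclumpable <- setdiff(associations$unit, known_units)
    if (length(unclumpable)) {
      warning(sprintf("%d association(s) have no predicted-expression unit and are retained unclumped",
                      length(unclumpable)))
    }
  }
  # symmetric adjacency restricted to pairs above threshold
  hi <- correlations[correlations$r > r_thresh, , drop = FALSE]
  adj <- split(c(hi$unit_b, hi$unit_a), c(hi$unit_a, hi$unit_b))

  ord <- associations[clump_order(associations), , drop = FALSE]
  active <- !(ord$unit %in% unclumpable)
  alive <- rep(TRUE, nrow(ord))
  removed_unit <- character(0)
  removed_lead <- character(0)
  keep <- logical(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (!active[i]) next
    partners <- adj[[ord$unit[i]]]
    if (is.null(partners)) next
    victim <- which(alive & !keep & active & ord$unit %in% partners)
    if (length(victim)) {
      alive[victim] <- FALSE
      removed_unit <- c(removed_unit, ord$unit[victim])
      removed_lead <- c(removed_lead, rep(ord$unit[i], length(victim)))
    }
  }
  res <- list(
    retained = ord[keep, , drop = FALSE],
    removed = data.frame(unit = removed_unit, lead_unit = removed_lead,
                         stringsAsFactors = FALSE)
  )
  rownames(res$retained) <- NULL
  class(res) <- "clump_result"
  res
}

#' Average duplicate-gene Z-scores after clumping
#'
#' A gene retained in multiple panels after clumping contributes the
#' arithmetic mean of its retained TWAS Z-scores; the gene-level p-value used
#' for subsequent thresholding is the two-sided normal tail of the averaged
#' Z. Genes fully removed by clumping are absent.
#'
#' @param retained retained association rows (a `clump_result$retained`
#'   data.frame, or any association subset with `gene_id` and `Z`).
#' @return data.frame `gene_id`, `Z` (mean), `p`, `n_panels`.
#' @export
average_duplicate_genes <- function(retained) {
  if (inherits(retained, "clump_result")) retained <- retained$retained
  if (nrow(retained) == 0) {
    return(data.frame(gene_id = character(), Z = numeric(), p = numeric(),
                      n_panels = integer(), stringsAsFactors = FALSE))
  }
  z <- tapply(retained$Z, retained$gene_id, mean)
  n <- tapply(retained$Z, retained$gene_id, length)
  out <- data.frame(gene_id = names(z), Z = as.numeric(z),
                    p = 2 * stats::pnorm(-abs(as.numeric(z))),
                    n_panels = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
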