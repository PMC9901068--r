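# Independent reference implementations used as oracles. These recompute
# quantities from first principles (explicit matrix solves, on-the-fly
# correlations, a second transcription of the liability formula) and never
# call the package's own code paths for the quantity they check.

# Exhaustive greedy clump: re-ranks from scratch and recomputes each pair's
# Pearson correlation directly from the predicted-expression matrix, with no
# precomputed pair structure.
oracle_clump <- function(assoc, pred, gene_map, r_thresh = 0.95,
                         window = 5e5) {
  assoc$unit <- paste(assoc$gene_id, assoc$panel_id, sep = "::")
  pos <- stats::setNames(gene_map$start, gene_map$gene_id)
  chr <- stats::setNames(gene_map$chrom, gene_map$gene_id)
  remaining <- assoc[order(assoc$p, -abs(assoc$Z), assoc$gene_id,
                           assoc$panel_id), , drop = FALSE]
  retained <- character(0)
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    retained <- c(retained, lead$unit)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- vapply(seq_len(nrow(remaining)), function(i) {
      u <- remaining[i, ]
      if (chr[[u$gene_id]] != chr[[lead$gene_id]]) return(FALSE)
      if (abs(pos[[u$gene_id]] - pos[[lead$gene_id]]) > window) return(FALSE)
      stats::cor(pred[, u$unit], pred[, lead$unit]) > r_thresh
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(retained)
}

# Second, independent transcription of the ascertainment-corrected
# observed-to-liability R^2 transformation.
oracle_liability <- function(r2, K, P) {
  thd <- stats::qnorm(K, lower.tail = FALSE)
  height <- stats::dnorm(thd)
  i_mean <- height / K
  cc <- K * (1 - K) / height^2 * K * (1 - K) / (P * (1 - P))
  d <- i_mean * (P - K) / (1 - K)
  cc * r2 / (1 + cc * d * (d - thd) * r2)
}

# Direct GLS solve via explicit matrix inversion of V (no Cholesky).
oracle_gls_slope <- function(z, d, V) {
  X <- cbind(1, d)
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% z
}

# Random clumping instance: latent-factor predicted expression so pairwise
# correlations span [0, 1], genes on two chromosomes with mixed proximity,
# and a random association table. Units are (gene, panel) pairs.
random_clump_instance <- function(seed, max_units = 50) {
  set.seed(seed)
  n_genes <- sample(3:25, 1)
  gene_map <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
    start = sample.int(2e6, n_genes),
    stringsAsFactors = FALSE
  )
  gene_map$end <- gene_map$start + 1e4
  in_b <- stats::runif(n_genes) < 0.5
  units <- rbind(
    data.frame(gene_id = gene_map$gene_id, panel_id = "pA",
               stringsAsFactors = FALSE),
    data.frame(gene_id = gene_map$gene_id[in_b],
               panel_id = rep("pB", sum(in_b)), stringsAsFactors = FALSE)
  )
  units <- units[seq_len(min(nrow(units), max_units)), , drop = FALSE]
  n_ind <- 40
  k <- max(1, n_genes %/% 3)
  factors <- matrix(stats::rnorm(n_ind * k), n_ind, k)
  noise_sd <- sample(c(0.05, 0.3, 1), nrow(units), TRUE)
  pred <- vapply(seq_len(nrow(units)), function(i) {
    f <- factors[, sample.int(k, 1)]
    x <- f + stats::rnorm(n_ind, 0, noise_sd[i])
    (x - mean(x)) / stats::sd(x)
  }, numeric(n_ind))
  colnames(pred) <- paste(units$gene_id, units$panel_id, sep = "::")
  assoc <- data.frame(
    gene_id = units$gene_id, panel_id = units$panel_id,
    Z = stats::rnorm(nrow(units)), p = stats::runif(nrow(units)),
    stringsAsFactors = FALSE
  )
  list(gene_map = gene_map, pred = pred, assoc = assoc)
}
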