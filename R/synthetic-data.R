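#' Configuration for the synthetic-data generators
#'
#' Builds and validates the configuration object consumed by all
#' `generate_*()` functions. The defaults describe a small but realistic
#' post-GWAS study: a few hundred genes spread over several chromosomes,
#' TWAS/SMR associations from a mixture of blood and brain expression panels,
#' a 1KG-like reference genotype panel for predicting expression, two
#' case-control whole-blood expression cohorts on different array platforms,
#' and a DrugTargetor-like drug-gene interaction database with level-3 ATC
#' codes.
#'
#' @param n_genes number of genes to simulate.
#' @param n_chromosomes number of chromosomes genes are spread over.
#' @param chrom_length chromosome length in bp (1-based coordinates).
#' @param n_panels number of expression panels contributing TWAS results.
#' @param panel_tissue_classes character vector of length `n_panels` with
#'   values in `{"blood","brain"}`; defaults to alternating classes.
#' @param panel_methods character vector of length `n_panels` with values in
#'   `{"FUSION","SMR"}`; defaults to alternating methods.
#' @param panel_coverage probability that a given gene has a model in a given
#'   panel (every gene is guaranteed at least one panel).
#' @param n_ref_samples number of reference-panel individuals used for
#'   predicted-expression correlations.
#' @param snps_per_gene number of cis variants per gene model.
#' @param maf_range lower and upper bound of the uniform minor-allele
#'   frequency distribution for reference variants.
#' @param prop_signal_genes fraction of genes with a true TWAS signal.
#' @param twas_effect_sd magnitude of the mean TWAS Z for signal genes.
#' @param prop_coloc fraction of signal genes that truly colocalise.
#' @param cross_panel_similarity probability that all panels of a gene share
#'   (nearly identical) SNP weights, inducing predicted-expression
#'   correlations above the clumping threshold.
#' @param n_cases,n_controls per-cohort sample sizes.
#' @param de_effect_size standardized mean case-control expression shift for
#'   signal genes (log2 scale, units of residual SD).
#' @param prop_concordant fraction of signal genes whose observed shift has
#'   the same sign as the TWAS Z (the remainder shift in the opposite
#'   direction, creating discordant genes).
#' @param n_credible_sets number of fine-mapping 95% credible sets.
#' @param prop_contained fraction of credible sets fully contained in their
#'   target gene body.
#' @param n_drugs,n_atc_groups drug-database dimensions.
#' @param genes_per_drug_mean Poisson mean of the number of gene targets per
#'   drug.
#' @param prop_protective_drugs,prop_harmful_drugs fractions of drugs planted
#'   as protective (anti-aligned with the risk expression signature) or
#'   harmful (aligned).
#' @param drug_direction_fidelity fraction of a planted drug's directional
#'   interactions that follow its protective/harmful direction.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L,
                             n_chromosomes = 5L,
                             chrom_length = 5e7,
                             n_panels = 4L,
                             panel_tissue_classes = NULL,
                             panel_methods = NULL,
                             panel_coverage = 0.6,
                             n_ref_samples = 200L,
                             snps_per_gene = 10L,
                             maf_range = c(0.05, 0.5),
                             prop_signal_genes = 0.1,
                             twas_effect_sd = 4,
                             prop_coloc = 0.5,
                             cross_panel_similarity = 0.5,
                             n_cases = 300L,
                             n_controls = 300L,
                             de_effect_size = 0.3,
                             prop_concordant = 0.7,
                             n_credible_sets = 5L,
                             prop_contained = 0.6,
                             n_drugs = 60L,
                             n_atc_groups = 8L,
                             genes_per_drug_mean = 5,
                             prop_protective_drugs = 0.15,
                             prop_harmful_drugs = 0.15,
                             drug_direction_fidelity = 0.9,
                             seed = 1L) {
  check_count(n_genes, "n_genes")
  check_count(n_chromosomes, "n_chromosomes")
  check_positive(chrom_length, "chrom_length")
  check_count(n_panels, "n_panels")
  check_count(n_ref_samples, "n_ref_samples")
  check_count(snps_per_gene, "snps_per_gene")
  check_count(n_cases, "n_cases")
  check_count(n_controls, "n_controls")
  check_count(n_credible_sets, "n_credible_sets", min = 0L)
  check_count(n_drugs, "n_drugs")
  check_count(n_atc_groups, "n_atc_groups")
  check_fraction(prop_signal_genes, "prop_signal_genes")
  check_fraction(prop_coloc, "prop_coloc")
  check_fraction(panel_coverage, "panel_coverage")
  check_fraction(cross_panel_similarity, "cross_panel_similarity")
  check_fraction(prop_concordant, "prop_concordant")
  check_fraction(prop_contained, "prop_contained")
  check_fraction(prop_protective_drugs, "prop_protective_drugs")
  check_fraction(prop_harmful_drugs, "prop_harmful_drugs")
  check_fraction(drug_direction_fidelity, "drug_direction_fidelity")
  check_positive(twas_effect_sd, "twas_effect_sd")
  check_positive(genes_per_drug_mean, "genes_per_drug_mean")
  stop_if_not(de_effect_size >= 0, "'de_effect_size' must be >= 0")
  stop_if_not(n_atc_groups <= n_drugs,
              "'n_atc_groups' must not exceed 'n_drugs'")
  stop_if_not(prop_protective_drugs + prop_harmful_drugs <= 1,
              "protective + harmful drug fractions must not exceed 1")
  stop_if_not(length(maf_range) == 2 && all(maf_range > 0 & maf_range <= 0.5) &&
                maf_range[1] <= maf_range[2],
              "'maf_range' must be an increasing pair within (0, 0.5]")

  if (is.null(panel_tissue_classes)) {
    panel_tissue_classes <- rep(c("blood", "brain"), length.out = n_panels)
  }
  stop_if_not(length(panel_tissue_classes) == n_panels &&
                all(panel_tissue_classes %in% c("blood", "brain")),
              "'panel_tissue_classes' must have one of {blood, brain} per panel")
  if (is.null(panel_methods)) {
    panel_methods <- rep(c("FUSION", "SMR"), length.out = n_panels)
  }
  stop_if_not(length(panel_methods) == n_panels &&
                all(panel_methods %in% c("FUSION", "SMR")),
              "'panel_methods' must have one of {FUSION, SMR} per panel")

  cfg <- list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, n_panels = as.integer(n_panels),
    panel_tissue_classes = panel_tissue_classes, panel_methods = panel_methods,
    panel_coverage = panel_coverage, n_ref_samples = as.integer(n_ref_samples),
    snps_per_gene = as.integer(snps_per_gene), maf_range = maf_range,
    prop_signal_genes = prop_signal_genes, twas_effect_sd = twas_effect_sd,
    prop_coloc = prop_coloc, cross_panel_similarity = cross_panel_similarity,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    de_effect_size = de_effect_size, prop_concordant = prop_concordant,
    n_credible_sets = as.integer(n_credible_sets),
    prop_contained = prop_contained,
    n_drugs = as.integer(n_drugs), n_atc_groups = as.integer(n_atc_groups),
    genes_per_drug_mean = genes_per_drug_mean,
    prop_protective_drugs = prop_protective_drugs,
    prop_harmful_drugs = prop_harmful_drugs,
    drug_direction_fidelity = drug_direction_fidelity,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a gene map
#'
#' Places non-overlapping genes on `n_chromosomes` chromosomes, sorted by
#' position. Coordinates are 1-based inclusive. Inter-gene gaps are drawn so
#' that many neighbours fall within a 500 kb window of each other (exercising
#' the proximity logic of predicted-expression clumping) while others do not.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
generate_gene_map <- function(config) {
  set.seed(stage_seed(config$seed, 1L))
  n_per_chr <- tabulate(rep(seq_len(config$n_chromosomes),
                            length.out = config$n_genes),
                        nbins = config$n_chromosomes)
  rows <- vector("list", config$n_chromosomes)
  idx <- 0L
  for (chr in seq_len(config$n_chromosomes)) {
    n <- n_per_chr[chr]
    if (n == 0L) next
    gaps <- round(stats::runif(n, 2e4, 3e5))
    lens <- round(stats::runif(n, 5e3, 5e4))
    starts <- cumsum(gaps + c(0, lens[-n]))
    ends <- starts + lens - 1
    if (any(ends > config$chrom_length)) {
      stop("gene map does not fit: increase 'chrom_length' or reduce 'n_genes'",
           call. = FALSE)
    }
    rows[[chr]] <- data.frame(
      gene_id = sprintf("G%04d", idx + seq_len(n)),
      chrom = sprintf("chr%d", chr),
      start = starts, end = ends,
      stringsAsFactors = FALSE
    )
    idx <- idx + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate reference-panel genotypes
#'
#' Simulates an unlinked reference genotype panel (allele counts in
#' \{0, 1, 2\}) with `snps_per_gene` cis variants per gene and minor allele
#' frequencies drawn from Uniform(0.05, 0.5). Variants are independent
#' binomial draws: linkage realism is unnecessary because downstream clumping
#' operates on predicted-expression correlation, which is induced through
#' shared SNP-weight vectors. Zero-variance variant columns are redrawn.
#'
#' @param config a [synthetic_config()].
#' @param gene_map output of [generate_gene_map()].
#' @return list with `genotypes` (n_ref_samples x n_variants matrix, columns
#'   named by variant id) and `variants` (data.frame: `variant_id`,
#'   `gene_id`, `chrom`, `pos`, `maf`).
#' @export
generate_reference_genotypes <- function(config, gene_map) {
  set.seed(stage_seed(config$seed, 2L))
  m <- config$snps_per_gene
  n <- config$n_ref_samples
  variants <- do.call(rbind, lapply(seq_len(nrow(gene_map)), function(i) {
    g <- gene_map[i, ]
    pos <- sort(sample(seq(g$start, g$end), m,
                       replace = (g$end - g$start + 1) < m))
    data.frame(
      variant_id = sprintf("%s_v%02d", g$gene_id, seq_len(m)),
      gene_id = g$gene_id, chrom = g$chrom, pos = pos,
      maf = stats::runif(m, config$maf_range[1], config$maf_range[2]),
      stringsAsFactors = FALSE
    )
  }))
  geno <- vapply(variants$maf, function(f) stats::rbinom(n, 2L, f), numeric(n))
  # redraw monomorphic columns (possible at small n)
  for (attempt in 1:20) {
    bad <- which(apply(geno, 2, stats::var) == 0)
    if (length(bad) == 0L) break
    geno[, bad] <- vapply(variants$maf[bad],
                          function(f) stats::rbinom(n, 2L, f), numeric(n))
  }
  colnames(geno) <- variants$variant_id
  rownames(geno) <- sprintf("S%04d", seq_len(n))
  list(genotypes = geno, variants = variants)
}

#' Generate TWAS/PWAS association results with SNP-weight models
#'
#' Emulates FUSION- and SMR-style per-gene association tables across multiple
#' expression panels. Signal genes receive Z ~ Normal(direction x
#' `twas_effect_sd`, 1) in each panel where they have a model; null genes
#' receive Z ~ Normal(0, 1); p is the two-sided normal tail of Z. A
#' `prop_coloc` subset of signal genes truly colocalises: their FUSION rows
#' get PP4 near 1 (with small PP3) and their SMR rows get HEIDI p > 0.05;
#' non-colocalising genes get the converse. Per-(gene, panel) SNP-weight
#' vectors are drawn with configurable cross-panel similarity so that
#' predicted-expression correlations between duplicate gene models span the
#' clumping threshold.
#'
#' @param config a [synthetic_config()].
#' @param gene_map output of [generate_gene_map()].
#' @param genotypes output of [generate_reference_genotypes()], or `NULL` to
#'   skip SNP-weight generation (e.g. when only association-level structure
#'   is needed).
#' @return list with `associations` (TWAS table), `weights` (long
#'   data.frame: `gene_id`, `panel_id`, `variant_id`, `weight`, or `NULL`)
#'   and `truth` (per-gene ground truth: `gene_id`, `signal`, `direction`,
#'   `coloc`, `shared_weights`).
#' @export
generate_twas_results <- function(config, gene_map, genotypes = NULL) {
  set.seed(stage_seed(config$seed, 3L))
  n_genes <- nrow(gene_map)
  n_sig <- round(config$prop_signal_genes * n_genes)
  if (n_sig < 1) {
    warning("prop_signal_genes x n_genes < 1: generating a pure-null dataset")
    n_sig <- 0L
  }
  signal_ids <- sort(sample(gene_map$gene_id, n_sig))
  truth <- data.frame(
    gene_id = gene_map$gene_id,
    signal = gene_map$gene_id %in% signal_ids,
    stringsAsFactors = FALSE
  )
  truth$direction <- ifelse(truth$signal, sample(c(-1, 1), n_genes, TRUE), 0)
  truth$coloc <- truth$signal & stats::runif(n_genes) < config$prop_coloc
  truth$shared_weights <- stats::runif(n_genes) < config$cross_panel_similarity

  panels <- sprintf("panel%d_%s", seq_len(config$n_panels),
                    config$panel_tissue_classes)
  # gene x panel presence; every gene keeps at least one panel
  present <- matrix(stats::runif(n_genes * config$n_panels) <
                      config$panel_coverage,
                    n_genes, config$n_panels)
  none <- which(rowSums(present) == 0L)
  if (length(none)) {
    present[cbind(none, sample.int(config$n_panels, length(none), TRUE))] <- TRUE
  }

  assoc <- vector("list", config$n_panels)
  for (j in seq_len(config$n_panels)) {
    keep <- which(present[, j])
    mu <- truth$direction[keep] * config$twas_effect_sd
    z <- stats::rnorm(length(keep), mu, 1)
    coloc <- truth$coloc[keep]
    is_fusion <- config$panel_methods[j] == "FUSION"
    df <- data.frame(
      gene_id = gene_map$gene_id[keep],
      panel_id = panels[j],
      tissue_class = config$panel_tissue_classes[j],
      method = config$panel_methods[j],
      molecular_type = "expression",
      Z = z,
      p = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE
    )
    if (is_fusion) {
      pp4 <- ifelse(coloc, stats::rbeta(length(keep), 40, 2),
                    stats::runif(length(keep), 0, 0.5))
      pp3 <- ifelse(coloc, (1 - pp4) * stats::runif(length(keep), 0, 0.5),
                    pmin(1 - pp4, stats::runif(length(keep), 0.3, 0.6)))
      df$PP3 <- pp3
      df$PP4 <- pp4
      df$heidi_p <- NA_real_
    } else {
      # SMR rows carry HEIDI; colocalising genes also get high PP4 so the
      # PP4-stratified scoring path can use SMR associations.
      df$PP3 <- NA_real_
      df$PP4 <- ifelse(coloc, stats::rbeta(length(keep), 40, 2),
                       stats::runif(length(keep), 0, 0.5))
      df$heidi_p <- ifelse(coloc, stats::runif(length(keep), 0.1, 1),
                           stats::runif(length(keep), 0, 0.04))
    }
    assoc[[j]] <- df
  }
  associations <- do.call(rbind, assoc)
  rownames(associations) <- NULL

  weights <- NULL
  if (!is.null(genotypes)) {
    variants <- genotypes$variants
    vsplit <- split(variants$variant_id, variants$gene_id)
    wrows <- vector("list", n_genes * config$n_panels)
    k <- 0L
    for (i in seq_len(n_genes)) {
      gid <- gene_map$gene_id[i]
      vids <- vsplit[[gid]]
      base <- stats::rnorm(length(vids))
      for (j in seq_len(config$n_panels)) {
        if (!present[i, j]) next
        w <- if (truth$shared_weights[i]) {
          base + stats::rnorm(length(vids), 0, 0.02)
        } else {
          stats::rnorm(length(vids))
        }
        if (all(w == 0)) w[1] <- 1
        k <- k + 1L
        wrows[[k]] <- data.frame(gene_id = gid, panel_id = panels[j],
                                 variant_id = vids, weight = w,
                                 stringsAsFactors = FALSE)
      }
    }
    weights <- do.call(rbind, wrows[seq_len(k)])
    rownames(weights) <- NULL
  }

  list(associations = associations, weights = weights, truth = truth)
}

#' Generate fine-mapping 95% credible sets
#'
#' Produces SuSiE-style credible-set variant tables targeted at (mostly
#' signal) genes. A `prop_contained` fraction of sets lie fully within the
#' target gene body; the remainder include one variant beyond the gene end,
#' so they fail the containment criterion.
#'
#' @param config a [synthetic_config()].
#' @param gene_map output of [generate_gene_map()].
#' @param twas_truth `truth` component of [generate_twas_results()].
#' @return list with `credible_sets` (data.frame: `locus_id`, `variant_id`,
#'   `chrom`, `pos`, `coverage`) and `truth` (`locus_id`, `gene_id`,
#'   `contained`).
#' @export
generate_credible_sets <- function(config, gene_map, twas_truth) {
  set.seed(stage_seed(config$seed, 4L))
  n <- min(config$n_credible_sets, nrow(gene_map))
  if (n == 0L) {
    empty <- data.frame(locus_id = character(), variant_id = character(),
                        chrom = character(), pos = integer(),
                        coverage = character(), stringsAsFactors = FALSE)
    return(list(credible_sets = empty,
                truth = data.frame(locus_id = character(),
                                   gene_id = character(),
                                   contained = logical())))
  }
  pool <- twas_truth$gene_id[twas_truth$signal]
  if (length(pool) < n) pool <- c(pool, setdiff(gene_map$gene_id, pool))
  target <- sample(pool, n)
  contained <- stats::runif(n) < config$prop_contained
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gene_map[gene_map$gene_id == target[i], ]
    size <- sample(2:4, 1)
    pos <- sort(sample(seq(g$start, g$end), size))
    if (!contained[i]) pos[size] <- g$end + sample(1e3:5e4, 1)
    rows[[i]] <- data.frame(
      locus_id = sprintf("L%02d", i),
      variant_id = sprintf("L%02d_cs%d", i, seq_len(size)),
      chrom = g$chrom, pos = pos, coverage = "95",
      stringsAsFactors = FALSE
    )
  }
  list(credible_sets = do.call(rbind, rows),
       truth = data.frame(locus_id = sprintf("L%02d", seq_len(n)),
                          gene_id = target, contained = contained,
                          stringsAsFactors = FALSE))
}

#' Generate two case-control expression cohorts
#'
#' Emulates two whole-blood expression studies of the same case-control
#' series measured on different array platforms (cohort ids `GPL6947` and
#' `GPL10558`). Expression is on the log2 scale (probe-averaging is assumed
#' upstream). For a `prop_concordant` subset of signal genes, cases shift by
#' `+de_effect_size x sign(TWAS direction)`; the remaining signal genes shift
#' by the opposite sign, creating discordant genes. Phenotypes comprise
#' case-control status, sex, site of onset (cases), age at onset (cases) and
#' uncensored survival in years (cases, log-normal).
#'
#' @param config a [synthetic_config()].
#' @param twas_truth `truth` component of [generate_twas_results()].
#' @return list with `cohorts` (named list per cohort: `cohort_id`,
#'   `expression` genes x samples matrix, `phenotypes` data.frame) and
#'   `truth` (per-gene `de_shift` and `concordant` flag).
#' @export
generate_expression_cohorts <- function(config, twas_truth) {
  stop_if_not(config$n_cases >= 1 && config$n_controls >= 1,
              "n_cases and n_controls must both be >= 1")
  set.seed(stage_seed(config$seed, 5L))
  genes <- twas_truth$gene_id
  concordant <- twas_truth$signal & stats::runif(nrow(twas_truth)) <
    config$prop_concordant
  shift <- ifelse(twas_truth$signal,
                  config$de_effect_size * twas_truth$direction *
                    ifelse(concordant, 1, -1),
                  0)
  truth <- data.frame(gene_id = genes, de_shift = shift,
                      concordant = concordant, stringsAsFactors = FALSE)

  make_cohort <- function(cohort_id) {
    n <- config$n_cases + config$n_controls
    status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
    ids <- sprintf("%s_s%04d", cohort_id, seq_len(n))
    mu <- stats::rnorm(length(genes), 8, 2)
    expr <- matrix(stats::rnorm(length(genes) * n), length(genes), n)
    expr <- expr + mu + outer(shift, as.numeric(status))
    dimnames(expr) <- list(genes, ids)
    is_case <- status == 1L
    phen <- data.frame(
      sample_id = ids,
      status = status,
      sex = sample(c("F", "M"), n, TRUE),
      site_of_onset = ifelse(is_case,
                             sample(c("spinal", "bulbar"), n, TRUE,
                                    prob = c(0.7, 0.3)),
                             NA_character_),
      age_at_onset = ifelse(is_case, round(stats::rnorm(n, 60, 10), 1),
                            NA_real_),
      survival = ifelse(is_case, round(stats::rlnorm(n, log(2.5), 0.5), 2),
                        NA_real_),
      stringsAsFactors = FALSE
    )
    list(cohort_id = cohort_id, expression = expr, phenotypes = phen)
  }
  cohorts <- list(GPL6947 = make_cohort("GPL6947"),
                  GPL10558 = make_cohort("GPL10558"))
  list(cohorts = cohorts, truth = truth)
}

# action-label vocabularies used by the drug-database generator
.decrease_labels <- c("DECREASED_EXPRESSION", "NEGATIVE_RESPONSE",
                      "OPPOSITE_RESPONSE")
.increase_labels <- c("INCREASED_EXPRESSION", "POSITIVE_RESPONSE")
.neutral_labels <- c("BINDING", "MODULATOR", "COFACTOR")

#' Generate a drug-gene interaction database
#'
#' Emulates a DrugTargetor-style table of drug-gene interactions with
#' directional action labels and one level-3 ATC code per drug. Planted
#' "protective" drugs preferentially target signal genes with an action
#' direction opposite to the gene's true TWAS direction (down-regulating
#' risk-raising genes); "harmful" drugs align with it; neutral drugs target
#' random genes with random labels. A subset of ATC groups is enriched for
#' protective drugs.
#'
#' @param config a [synthetic_config()].
#' @param twas_truth `truth` component of [generate_twas_results()].
#' @return list with `interactions` (data.frame: `drug_id`, `gene_id`,
#'   `action_label`, `atc_code`), `atc_map` (`drug_id`, `atc_code`) and
#'   `truth` (`drugs`: per-drug class; `atc`: per-group enrichment flag).
#' @export
generate_drug_database <- function(config, twas_truth) {
  stop_if_not(config$n_atc_groups <= config$n_drugs,
              "'n_atc_groups' must not exceed 'n_drugs'")
  set.seed(stage_seed(config$seed, 6L))
  n_drugs <- config$n_drugs
  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  n_prot <- round(config$prop_protective_drugs * n_drugs)
  n_harm <- round(config$prop_harmful_drugs * n_drugs)
  classes <- sample(c(rep("protective", n_prot), rep("harmful", n_harm),
                      rep("neutral", n_drugs - n_prot - n_harm)))

  atc_codes <- sprintf("C%02d%s", seq_len(config$n_atc_groups),
                       LETTERS[(seq_len(config$n_atc_groups) - 1L) %% 26 + 1L])
  n_enriched <- max(1L, round(0.25 * config$n_atc_groups))
  enriched <- atc_codes[seq_len(n_enriched)]
  assign_atc <- function(class) {
    if (class == "protective" && stats::runif(1) < 0.8) {
      sample(enriched, 1)
    } else {
      sample(atc_codes, 1)
    }
  }
  atc <- unname(vapply(classes, assign_atc, character(1)))

  signal_ids <- twas_truth$gene_id[twas_truth$signal]
  direction <- stats::setNames(twas_truth$direction, twas_truth$gene_id)
  all_genes <- twas_truth$gene_id

  pick_label <- function(code) {
    if (code < 0) sample(.decrease_labels, 1)
    else if (code > 0) sample(.increase_labels, 1)
    else sample(.neutral_labels, 1)
  }

  rows <- vector("list", n_drugs)
  for (i in seq_len(n_drugs)) {
    cls <- classes[i]
    n_t <- stats::rpois(1, config$genes_per_drug_mean)
    if (cls != "neutral") n_t <- max(n_t, 2L)
    if (n_t == 0L) next
    if (cls == "neutral" || length(signal_ids) == 0L) {
      targets <- sample(all_genes, min(n_t, length(all_genes)))
      codes <- sample(c(-1L, 0L, 1L), length(targets), TRUE,
                      prob = c(0.3, 0.4, 0.3))
    } else {
      n_sig_t <- min(length(signal_ids), max(2L, round(0.8 * n_t)))
      targets <- c(sample(signal_ids, n_sig_t),
                   if (n_t > n_sig_t)
                     sample(setdiff(all_genes, signal_ids), n_t - n_sig_t))
      want <- if (cls == "protective") -direction[targets] else direction[targets]
      want[want == 0] <- sample(c(-1L, 1L), sum(want == 0), TRUE)
      follow <- stats::runif(length(targets)) < config$drug_direction_fidelity
      codes <- ifelse(follow, want,
                      sample(c(-1L, 1L), length(targets), TRUE))
    }
    codes <- unname(codes)
    rows[[i]] <- data.frame(
      drug_id = drug_ids[i], gene_id = targets,
      action_label = vapply(codes, pick_label, character(1)),
      atc_code = atc[i], stringsAsFactors = FALSE
    )
  }
  interactions <- do.call(rbind, rows)
  rownames(interactions) <- NULL
  list(
    interactions = interactions,
    atc_map = data.frame(drug_id = drug_ids, atc_code = atc,
                         stringsAsFactors = FALSE),
    truth = list(
      drugs = data.frame(drug_id = drug_ids, class = classes, atc_code = atc,
                         stringsAsFactors = FALSE),
      atc = data.frame(atc_code = atc_codes,
                       enriched = atc_codes %in% enriched,
                       stringsAsFactors = FALSE)
    )
  )
}

#' Generate the full synthetic dataset
#'
#' Runs every generator in order and returns all pipeline inputs plus ground
#' truth. A pure function of the configuration (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return list with components `config`, `gene_map`, `genotypes`,
#'   `variants`, `twas`, `credible_sets`, `expression`, `drugs`.
#' @export
simulate_all <- function(config = synthetic_config()) {
  gene_map <- generate_gene_map(config)
  ref <- generate_reference_genotypes(config, gene_map)
  twas <- generate_twas_results(config, gene_map, ref)
  cs <- generate_credible_sets(config, gene_map, twas$truth)
  expr <- generate_expression_cohorts(config, twas$truth)
  drugs <- generate_drug_database(config, twas$truth)
  list(config = config, gene_map = gene_map,
       genotypes = ref$genotypes, variants = ref$variants,
       twas = twas, credible_sets = cs, expression = expr, drugs = drugs)
}
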