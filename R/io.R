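# Plain-text readers and writers for every pipeline input.
# All coordinate-bearing files carry a '# coordinates: 1-based inclusive'
# comment header; readers skip '#' comment lines.

write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

matrix_to_df <- function(m, id_col) {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  df
}

df_to_matrix <- function(df, id_col) {
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Writes every pipeline input as headered TSV (drug interactions as CSV,
#' mirroring the column roles of a DrugTargetor export) together with the
#' ground-truth tables, so that generated data round-trips exactly through
#' [read_synthetic_data()].
#'
#' @param sim output of [simulate_all()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written (relative paths).
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coord <- "coordinates: 1-based inclusive"
  p <- function(f) file.path(dir, f)
  write_tsv(sim$gene_map, p("gene_map.tsv"), coord)
  write_tsv(sim$variants, p("variants.tsv"), coord)
  write_tsv(matrix_to_df(sim$genotypes, "sample_id"), p("genotypes.tsv"))
  write_tsv(sim$twas$associations, p("twas_associations.tsv"))
  write_tsv(sim$twas$weights, p("snp_weights.tsv"))
  write_tsv(sim$credible_sets$credible_sets, p("credible_sets.tsv"), coord)
  for (co in sim$expression$cohorts) {
    write_tsv(matrix_to_df(co$expression, "gene_id"),
              p(sprintf("expression_%s.tsv", co$cohort_id)))
    write_tsv(co$phenotypes, p(sprintf("phenotypes_%s.tsv", co$cohort_id)))
  }
  utils::write.csv(sim$drugs$interactions, p("drug_gene_interactions.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tsv(sim$drugs$atc_map, p("atc_map.tsv"))
  write_tsv(sim$twas$truth, p("truth_genes.tsv"))
  write_tsv(sim$expression$truth, p("truth_expression.tsv"))
  write_tsv(sim$credible_sets$truth, p("truth_credible_sets.tsv"))
  write_tsv(sim$drugs$truth$drugs, p("truth_drugs.tsv"))
  write_tsv(sim$drugs$truth$atc, p("truth_atc.tsv"))
  invisible(list.files(dir))
}

#' Read a synthetic dataset back from disk
#'
#' Inverse of [write_synthetic_data()]; recovers all inputs and recorded
#' ground truths.
#'
#' @param dir directory written by [write_synthetic_data()].
#' @return list shaped like the output of [simulate_all()] (without the
#'   config element).
#' @export
read_synthetic_data <- function(dir) {
  p <- function(f) file.path(dir, f)
  cohort_files <- list.files(dir, pattern = "^expression_.*\\.tsv$")
  cohort_ids <- sub("^expression_(.*)\\.tsv$", "\\1", cohort_files)
  cohorts <- lapply(cohort_ids, function(id) {
    list(cohort_id = id,
         expression = df_to_matrix(read_tsv(p(sprintf("expression_%s.tsv", id))),
                                   "gene_id"),
         phenotypes = read_tsv(p(sprintf("phenotypes_%s.tsv", id))))
  })
  names(cohorts) <- cohort_ids
  list(
    gene_map = read_tsv(p("gene_map.tsv")),
    variants = read_tsv(p("variants.tsv")),
    genotypes = df_to_matrix(read_tsv(p("genotypes.tsv")), "sample_id"),
    twas = list(associations = read_tsv(p("twas_associations.tsv")),
                weights = read_tsv(p("snp_weights.tsv")),
                truth = read_tsv(p("truth_genes.tsv"))),
    credible_sets = list(credible_sets = read_tsv(p("credible_sets.tsv")),
                         truth = read_tsv(p("truth_credible_sets.tsv"))),
    expression = list(cohorts = cohorts,
                      truth = read_tsv(p("truth_expression.tsv"))),
    drugs = list(interactions = utils::read.csv(p("drug_gene_interactions.csv"),
                                                stringsAsFactors = FALSE),
                 atc_map = read_tsv(p("atc_map.tsv")),
                 truth = list(drugs = read_tsv(p("truth_drugs.tsv")),
                              atc = read_tsv(p("truth_atc.tsv"))))
  )
}
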