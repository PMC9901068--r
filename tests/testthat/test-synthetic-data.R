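small_config <- function(..., seed = 11L) {
  synthetic_config(n_genes = 40L, n_chromosomes = 2L, n_panels = 2L,
                   n_ref_samples = 50L, snps_per_gene = 4L,
                   n_cases = 30L, n_controls = 30L,
                   n_drugs = 15L, n_atc_groups = 3L, seed = seed, ...)
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config()
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$gene_map, s2$gene_map)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$twas, s2$twas)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$drugs, s2$drugs)
  s3 <- simulate_all(small_config(seed = 12L))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("gene map places non-overlapping, sorted genes within budget", {
  gm <- generate_gene_map(small_config())
  expect_true(all(gm$start < gm$end))
  for (ch in unique(gm$chrom)) {
    g <- gm[gm$chrom == ch, ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))  # no overlap
  }
  gm1 <- generate_gene_map(synthetic_config(n_genes = 10L,
                                            n_chromosomes = 1L, seed = 1L))
  expect_equal(length(unique(gm1$chrom)), 1L)
  expect_error(generate_gene_map(synthetic_config(n_genes = 500L,
                                                  n_chromosomes = 1L,
                                                  chrom_length = 1e6)),
               "does not fit")
})

test_that("reference genotypes are allele counts with the expected frequency", {
  cfg <- small_config()
  ref <- generate_reference_genotypes(cfg, generate_gene_map(cfg))
  expect_true(all(ref$genotypes %in% 0:2))
  expect_true(all(apply(ref$genotypes, 2, var) > 0))
  expect_equal(nrow(ref$variants), cfg$n_genes * cfg$snps_per_gene)
  # binomial sampling oracle: at maf 0.5 a column mean is 1.0 within 3 SE
  cfg2 <- synthetic_config(n_genes = 2L, n_ref_samples = 10000L,
                           snps_per_gene = 3L, maf_range = c(0.5, 0.5),
                           seed = 3L)
  ref2 <- generate_reference_genotypes(cfg2, generate_gene_map(cfg2))
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(ref2$genotypes) - 1) < 3 * se))
})

test_that("TWAS generator has calibrated nulls and consistent bookkeeping", {
  # pure null: |Z| > 1.96 in about 5% of 10,000 genes
  cfg0 <- synthetic_config(n_genes = 10000L, n_chromosomes = 25L,
                           chrom_length = 2e8, n_panels = 1L,
                           panel_coverage = 1, prop_signal_genes = 0,
                           seed = 5L)
  gm0 <- generate_gene_map(cfg0)
  tw0 <- suppressWarnings(generate_twas_results(cfg0, gm0))
  frac <- mean(abs(tw0$associations$Z) > 1.96)
  expect_lt(abs(frac - 0.05), 3.5 * sqrt(0.05 * 0.95 / 10000))
  expect_warning(generate_twas_results(cfg0, gm0), "pure-null")

  cfg <- small_config()
  gm <- generate_gene_map(cfg)
  tw <- generate_twas_results(cfg, gm, generate_reference_genotypes(cfg, gm))
  a <- tw$associations
  # p is the two-sided normal tail of Z
  expect_equal(a$p, 2 * pnorm(-abs(a$Z)), tolerance = 1e-12)
  # recorded direction matches the sign of the mean of the generated Z
  sig <- tw$truth[tw$truth$signal, ]
  mean_z <- tapply(a$Z, a$gene_id, mean)[sig$gene_id]
  expect_true(all(sign(mean_z) == sig$direction))
  # every weight variant exists in the variant table
  expect_true(all(tw$weights$variant_id %in%
                    sprintf("%s_v%02d", rep(gm$gene_id, each = 4), 1:4)))
})

test_that("expression cohorts embed the configured case-control shifts", {
  cfg <- small_config(prop_concordant = 1, de_effect_size = 0.4)
  gm <- generate_gene_map(cfg)
  tw <- generate_twas_results(cfg, gm)
  ex <- generate_expression_cohorts(cfg, tw$truth)
  expect_length(ex$cohorts, 2L)
  sig <- merge(ex$truth, tw$truth, by = "gene_id")
  sig <- sig[sig$signal, ]
  # with full concordance every shift sign equals the TWAS direction
  expect_true(all(sign(sig$de_shift) == sig$direction))
  expect_true(all(abs(sig$de_shift) == 0.4))
  # null construction: zero effect leaves case-control differences centred on 0
  cfg0 <- small_config(de_effect_size = 0)
  ex0 <- generate_expression_cohorts(cfg0, tw$truth)
  expect_true(all(ex0$truth$de_shift == 0))
  co <- ex0$cohorts[[1]]
  d <- rowMeans(co$expression[, co$phenotypes$status == 1]) -
    rowMeans(co$expression[, co$phenotypes$status == 0])
  expect_lt(abs(mean(d)), 0.1)
  # phenotype table is aligned and complete for cases
  ph <- ex$cohorts$GPL6947$phenotypes
  expect_identical(ph$sample_id, colnames(ex$cohorts$GPL6947$expression))
  expect_true(all(!is.na(ph$survival[ph$status == 1])))
  expect_true(all(ph$survival[ph$status == 1] > 0))
})

test_that("drug database respects ATC mapping and planted directionality", {
  cfg <- small_config(prop_signal_genes = 0.4, drug_direction_fidelity = 1,
                      prop_protective_drugs = 0.3)
  gm <- generate_gene_map(cfg)
  tw <- generate_twas_results(cfg, gm)
  db <- generate_drug_database(cfg, tw$truth)
  # each drug has exactly one ATC code
  expect_false(anyDuplicated(db$atc_map$drug_id) > 0)
  per_drug <- tapply(db$interactions$atc_code, db$interactions$drug_id,
                     function(x) length(unique(x)))
  expect_true(all(per_drug == 1))
  # protective drugs anti-align with the true TWAS direction
  coded <- code_directions(db$interactions)
  prot <- db$truth$drugs$drug_id[db$truth$drugs$class == "protective"]
  dirs <- setNames(tw$truth$direction, tw$truth$gene_id)
  rows <- coded[coded$drug_id %in% prot & coded$coded_direction != 0, ]
  rows <- rows[dirs[rows$gene_id] != 0, ]
  anti <- rows$coded_direction * dirs[rows$gene_id] < 0
  expect_gt(mean(anti), 0.9)
  expect_error(
    generate_drug_database(small_config(n_drugs = 2L, n_atc_groups = 3L),
                           tw$truth))
})

test_that("generated data round-trips through disk exactly", {
  dir <- withr::local_tempdir()
  sim <- simulate_all(small_config())
  write_synthetic_data(sim, dir)
  back <- read_synthetic_data(dir)
  expect_equal(back$gene_map, sim$gene_map)
  expect_equal(back$twas$truth, sim$twas$truth)
  expect_equal(back$expression$truth, sim$expression$truth)
  expect_equal(back$drugs$truth$drugs, sim$drugs$truth$drugs)
  expect_equal(back$drugs$truth$atc, sim$drugs$truth$atc)
  expect_equal(back$credible_sets$truth, sim$credible_sets$truth)
  expect_equal(back$genotypes, sim$genotypes)
  expect_equal(back$twas$associations$Z, sim$twas$associations$Z,
               tolerance = 1e-12)
})
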