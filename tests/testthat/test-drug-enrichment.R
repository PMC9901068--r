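test_that("action labels map to signed codes exactly and idempotently", {
  tab <- data.frame(
    drug_id = "D1", gene_id = sprintf("g%d", 1:7),
    action_label = c("DECREASED_EXPRESSION", "NEGATIVE_RESPONSE",
                     "OPPOSITE_RESPONSE", "INCREASED_EXPRESSION",
                     "POSITIVE_RESPONSE", "BINDING", "SOME_NEW_LABEL"),
    stringsAsFactors = FALSE
  )
  expect_message(coded <- code_directions(tab), "SOME_NEW_LABEL")
  expect_equal(coded$coded_direction, c(-1L, -1L, -1L, 1L, 1L, 0L, 0L))
  # recoding a coded table is a no-op
  expect_identical(code_directions(coded)$coded_direction,
                   coded$coded_direction)
})

test_that("GLS with identity covariance reduces to the OLS slope test", {
  set.seed(4)
  n <- 12
  gene_z <- data.frame(gene_id = sprintf("g%02d", 1:n), Z = rnorm(n),
                       stringsAsFactors = FALSE)
  coded <- data.frame(drug_id = "D1", gene_id = gene_z$gene_id,
                      coded_direction = sample(c(-1L, 0L, 1L), n, TRUE),
                      stringsAsFactors = FALSE)
  res <- directional_enrichment(gene_z, coded)
  fit <- summary(lm(gene_z$Z ~ coded$coded_direction))$coefficients
  expect_equal(-res$Z, unname(fit[2, "t value"]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit[2, "Pr(>|t|)"]), tolerance = 1e-8)
  expect_equal(res$n_genes_tested, n)
})

test_that("a drug opposing the risk signature scores protective", {
  gene_z <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       Z = c(3, 3, -3, -3), stringsAsFactors = FALSE)
  coded <- data.frame(drug_id = "D1", gene_id = gene_z$gene_id,
                      coded_direction = c(-1L, -1L, 1L, 1L),
                      stringsAsFactors = FALSE)
  expect_gt(directional_enrichment(gene_z, coded)$Z, 0)
  # the aligned drug is harmful (negative enrichment Z)
  coded$coded_direction <- -coded$coded_direction
  expect_lt(directional_enrichment(gene_z, coded)$Z, 0)
})

test_that("GLS estimates match a brute-force matrix oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1)
    genes <- sprintf("g%02d", 1:n)
    gene_z <- data.frame(gene_id = genes, Z = rnorm(n),
                         stringsAsFactors = FALSE)
    d <- sample(c(-1L, 0L, 1L), n, TRUE)
    if (var(d) == 0) d[1] <- -1L; if (var(d) == 0) d[2] <- 1L
    coded <- data.frame(drug_id = "D1", gene_id = genes,
                        coded_direction = d, stringsAsFactors = FALSE)
    # random positive-definite correlation among a few pairs
    V <- diag(n)
    pairs <- if (n >= 4) list(c(1, 2), c(3, 4)) else list(c(1, 2))
    gc <- do.call(rbind, lapply(pairs, function(pr) {
      r <- runif(1, -0.5, 0.5)
      V[pr[1], pr[2]] <<- r; V[pr[2], pr[1]] <<- r
      data.frame(gene_a = genes[pr[1]], gene_b = genes[pr[2]], r = r,
                 stringsAsFactors = FALSE)
    }))
    res <- directional_enrichment(gene_z, coded, gene_correlations = gc)
    B <- oracle_gls_slope(gene_z$Z, d, V)
    # recover the slope from the reported Z and p by refitting se
    X <- cbind(1, d)
    Vi <- solve(V)
    resid <- gene_z$Z - X %*% B
    sigma2 <- as.numeric(t(resid) %*% Vi %*% resid) / (n - 2)
    se <- sqrt(sigma2 * solve(t(X) %*% Vi %*% X)[2, 2])
    expect_equal(res$Z, as.numeric(-B[2] / se), tolerance = 1e-8)
  }
})

test_that("the minimum-gene filter and skip rules apply", {
  gene_z <- data.frame(gene_id = c("g1", "g2", "g3"), Z = c(1, -2, 0.5),
                       stringsAsFactors = FALSE)
  coded <- data.frame(
    drug_id = c("D1", "D1", "D2", "D3", "D3"),
    gene_id = c("g1", "g2", "g1", "gX", "g3"),
    coded_direction = c(-1L, 1L, 1L, -1L, 1L),
    stringsAsFactors = FALSE
  )
  res <- directional_enrichment(gene_z, coded)
  # D2 has one gene; D3 has one gene with statistics (gX is unknown)
  expect_equal(res$drug_id, "D1")
  expect_equal(res$n_genes_tested, 2L)
})

test_that("external enrichment import normalizes Z and p", {
  tab <- data.frame(drug_id = c("dA", "dB"), Z = c(2.5, -1),
                    stringsAsFactors = FALSE)
  out <- import_external_enrichment(tab, "external_magma")
  expect_equal(out$Z, c(2.5, -1))
  expect_equal(out$p, pnorm(-c(2.5, -1)))
  # one-sided p back-fills Z as the upper normal quantile
  out2 <- import_external_enrichment(
    data.frame(drug_id = "dC", p = 0.025), "external_gcsc")
  expect_equal(out2$Z, qnorm(0.975), tolerance = 1e-9)
  expect_error(import_external_enrichment(
    data.frame(drug_id = c("dA", "dA"), Z = c(1, 2)), "external_magma"),
    "duplicate")
  expect_error(import_external_enrichment(
    data.frame(drug_id = "dA"), "external_magma"), "'Z' or 'p'")
})

test_that("ATC rank-sum testing matches exact enumeration and filters", {
  enr <- data.frame(drug_id = sprintf("d%d", 1:5), method = "external_magma",
                    Z = c(3, 4, -1, 0, 1), stringsAsFactors = FALSE)
  atc <- data.frame(drug_id = enr$drug_id,
                    atc_code = c("C01A", "C01A", "C02B", "C02B", "C02B"),
                    stringsAsFactors = FALSE)
  res <- atc_wilcoxon(enr, atc, min_drugs = 2)
  g <- res[res$atc_code == "C01A", ]
  # group {3,4} vs {-1,0,1}, one-sided: p = 1 / choose(5, 2) = 0.1
  expect_equal(g$p, 0.1, tolerance = 1e-12)
  expect_gt(g$Z, 0)
  # a group smaller than min_drugs is excluded
  res5 <- atc_wilcoxon(enr, atc, min_drugs = 3)
  expect_false("C01A" %in% res5$atc_code)
  expect_warning(atc_wilcoxon(enr, atc, min_drugs = 6), "no ATC group")
  # directional method is two-sided
  enr2 <- enr; enr2$method <- "directional_twas"
  res2 <- atc_wilcoxon(enr2, atc, min_drugs = 2)
  expect_equal(res2$p[res2$atc_code == "C01A"], 0.2, tolerance = 1e-12)
})

test_that("drug FDR correction applies BH within method", {
  enr <- data.frame(drug_id = sprintf("d%d", 1:4), method = "external_magma",
                    Z = 1, p = c(0.01, 0.02, 0.03, 0.04),
                    stringsAsFactors = FALSE)
  expect_equal(fdr_drugs(enr)$q, rep(0.04, 4))
  both <- rbind(enr, transform(enr, method = "external_gcsc", p = p / 10))
  q <- fdr_drugs(both)$q
  expect_equal(q[1:4], rep(0.04, 4))
  expect_equal(q[5:8], rep(0.004, 4))
})
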