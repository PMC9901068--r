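toy_phen <- function(n, cases = n / 2, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", 1:n),
             status = c(rep(1L, cases), rep(0L, n - cases)),
             sex = sample(c("F", "M"), n, TRUE),
             site_of_onset = NA_character_, age_at_onset = NA_real_,
             survival = NA_real_, stringsAsFactors = FALSE)
}

test_that("expression standardization gives per-gene z-scores", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(10, 10, 10, 10), g3 = c(5, 9, 1, 5))
  expect_warning(z <- standardize_expression(m), "zero-variance")
  expect_false("g2" %in% rownames(z))
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
  # two samples: z = (-1/sqrt(2), 1/sqrt(2)) with the n-1 denominator
  z2 <- standardize_expression(matrix(c(3, 7), 1, 2,
                                      dimnames = list("g", c("a", "b"))))
  expect_equal(as.vector(z2), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(standardize_expression(matrix(1, 1, 1)), "2 samples")
})

test_that("PTS is the thresholded weighted sum of expression z-scores", {
  expr_z <- rbind(gA = c(1.5, -0.5), gB = c(1, 2))
  colnames(expr_z) <- c("s1", "s2")
  w <- data.frame(gene_id = c("gA", "gB"), Z = c(2, -1),
                  p = c(1e-4, 0.03), stringsAsFactors = FALSE)
  pts <- compute_pts(expr_z, w, thresholds = c(1e-3, 1))
  # only gA passes 1e-3: single-term score
  expect_equal(unname(pts$scores[, 1]), c(3, -1))
  expect_equal(pts$n_genes_used, c(1L, 2L))
  # both pass at 1: (2, -1) . (1, 1) = 1 for sample s2? s1: 2*1.5 - 1*1 = 2
  expect_equal(unname(pts$scores[, 2]), c(2 * 1.5 - 1, 2 * (-0.5) - 2))
  expect_warning(p0 <- compute_pts(expr_z, w, thresholds = c(1e-6, 1)),
                 "no genes pass")
  expect_true(all(is.na(p0$scores[, 1])))
  expect_error(compute_pts(expr_z, data.frame(gene_id = "gX", Z = 1, p = 1)),
               "no overlap")
})

test_that("PTS association reports the incremental R2 of the score", {
  phen <- toy_phen(200)
  set.seed(2)
  # score identical to the outcome, no covariates: perfect fit
  pts <- setNames(as.numeric(phen$status), phen$sample_id)
  res <- associate(pts, phen, "case_control", covariates = character(0))
  expect_equal(res$r2_obs, 1, tolerance = 1e-12)
  expect_equal(res$P, 0.5)
  # a covariate that is itself the outcome leaves nothing to explain
  phen2 <- phen
  phen2$copy <- phen2$status
  res2 <- associate(setNames(rnorm(200) + phen2$status, phen$sample_id),
                    phen2, "case_control", covariates = "copy")
  expect_lt(res2$r2_obs, 1e-12)
  expect_error(associate(pts, transform(phen, status = 1L), "case_control"),
               "constant")
})

test_that("scaling the weights rescales scores but not inference", {
  set.seed(3)
  expr_z <- matrix(rnorm(50 * 40), 50, 40,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%03d", 1:40)))
  w <- data.frame(gene_id = rownames(expr_z), Z = rnorm(50),
                  p = runif(50), stringsAsFactors = FALSE)
  phen <- toy_phen(40, cases = 20, seed = 3)
  s1 <- compute_pts(expr_z, w, thresholds = 1)$scores[, 1]
  w2 <- w; w2$Z <- w2$Z * 3
  s2 <- compute_pts(expr_z, w2, thresholds = 1)$scores[, 1]
  expect_equal(s2, 3 * s1, tolerance = 1e-12)
  a1 <- associate(setNames(s1, colnames(expr_z)), phen, "case_control")
  a2 <- associate(setNames(s2, colnames(expr_z)), phen, "case_control")
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
  expect_equal(a1$r2_obs, a2$r2_obs, tolerance = 1e-12)
})

test_that("liability conversion matches its closed form", {
  # zero maps to zero
  expect_equal(obs_to_liability_r2(0, 0.01, 0.5), 0)
  # K = P: no ascertainment, so the transform is exactly C * r2
  expect_equal(obs_to_liability_r2(0.1, 0.5, 0.5), 0.25 / dnorm(0)^2 * 0.1,
               tolerance = 1e-12)
  expect_equal(obs_to_liability_r2(0.1, 0.5, 0.5), 0.15707963, tolerance = 1e-7)
  k <- 0.2
  C <- k * (1 - k) / dnorm(qnorm(1 - k))^2 * k * (1 - k) / (k * (1 - k))
  expect_equal(obs_to_liability_r2(0.3, k, k), C * 0.3, tolerance = 1e-12)
  # agreement with an independently coded oracle across a grid
  grid <- expand.grid(r2 = c(0, 0.01, 0.04, 0.2, 0.5),
                      K = c(1 / 300, 0.01, 0.1, 0.5),
                      P = c(0.2, 0.5, 0.7))
  expect_equal(obs_to_liability_r2(grid$r2, grid$K, grid$P),
               oracle_liability(grid$r2, grid$K, grid$P), tolerance = 1e-10)
  expect_error(obs_to_liability_r2(0.1, 0, 0.5), "K")
  expect_error(obs_to_liability_r2(1.2, 0.1, 0.5), "r2_obs")
})

test_that("inverse-variance meta-analysis matches hand-computed pooling", {
  m <- ivw_meta(c(1, 3), c(1, 1))
  expect_equal(m$beta, 2)
  expect_equal(m$se, sqrt(0.5), tolerance = 1e-12)
  m2 <- ivw_meta(c(1, 3), c(1, 2))
  expect_equal(m2$beta, 1.4, tolerance = 1e-12)
  expect_equal(m2$se, 0.894427191, tolerance = 1e-9)
  # single study is the identity
  m3 <- ivw_meta(2.5, 0.7)
  expect_equal(m3$beta, 2.5)
  expect_equal(m3$se, 0.7)
  # pooled se never exceeds the smallest input se
  expect_lte(m2$se, 2)
  expect_error(ivw_meta(1, 0), "standard errors")
})

test_that("stratified weight tables respect tissue and colocalisation", {
  ret <- data.frame(
    gene_id = c("A", "A", "B", "C"), panel_id = c("p1", "p2", "p1", "p3"),
    tissue_class = c("blood", "brain", "blood", "brain"),
    Z = c(2, 4, -3, 1), p = c(0.01, 0.001, 0.001, 0.5),
    PP4 = c(0.9, 0.5, 0.95, NA), stringsAsFactors = FALSE
  )
  w <- build_pts_weights(ret)
  expect_equal(w$all.any$Z[w$all.any$gene_id == "A"], 3)
  expect_equal(sort(w$blood.any$gene_id), c("A", "B"))
  expect_equal(w$blood.any$Z[w$blood.any$gene_id == "A"], 2)
  # coloc stratum keeps only PP4 > 0.8 rows; NA PP4 drops out
  expect_equal(sort(w$all.coloc_only$gene_id), c("A", "B"))
  expect_equal(w$all.coloc_only$Z[w$all.coloc_only$gene_id == "A"], 2)
  expect_equal(nrow(w$brain.coloc_only), 0)
})
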