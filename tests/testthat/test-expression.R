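test_that("quantile normalization forces identical column distributions", {
  m <- cbind(s1 = c(1, 3), s2 = c(2, 4))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  ident <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(ident), ident)

  set.seed(22)
  big <- matrix(rnorm(500 * 6, sd = 1:6), 500, 6, byrow = TRUE)
  qb <- quantile_normalize(big)
  sorted <- apply(qb, 2, sort)
  for (j in 2:6) expect_identical(sorted[, j], sorted[, 1])
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("expressed calls combine detection p-values by Fisher's method", {
  # all p = 0.5 across 4 samples: combined p high, not expressed
  det <- matrix(0.5, 2, 4)
  cond <- rep("tissue", 4)
  ec <- expressed_call(det, cond)
  expect_false(any(ec))
  # four samples at p = 0.05: -2 sum log p = 23.97, df 8, p ~ 0.0023
  det2 <- matrix(0.05, 1, 4)
  ec2 <- expressed_call(det2, cond)
  p <- unname(attr(ec2, "combined_p")[1, 1])
  expect_equal(-2 * 4 * log(0.05), 23.97, tolerance = 1e-3)
  expect_equal(p, pchisq(-2 * 4 * log(0.05), 8, lower.tail = FALSE))
  expect_equal(p, 0.0023, tolerance = 0.02)
  expect_true(ec2[1, 1])
  # p = 1 exactly is handled without infinities
  det3 <- matrix(c(1, 1e-320, 0.5, 1), 1, 4)
  expect_true(is.finite(attr(expressed_call(det3, cond),
                             "combined_p")[1, 1]))
})

test_that("paired t-tests match the t-distribution oracle", {
  # paired log2 differences [1,2,3,4]: t = 3.873, df 3, p ~ 0.0305
  m <- rbind(gene1 = c(0, 0, 0, 0, 1, 2, 3, 4))
  colnames(m) <- c(paste0("t", 1:4), paste0("c", 1:4))
  pairs <- data.frame(tissue = paste0("t", 1:4), culture = paste0("c", 1:4))
  de <- paired_de(rbind(m, other = rnorm(8)), pairs)
  expect_equal(de$t[1], 2.5 / (sd(1:4) / 2))
  expect_equal(de$t[1], 3.873, tolerance = 1e-3)
  expect_equal(de$p[1], 2 * pt(-3.873, 3), tolerance = 1e-3)
  expect_equal(de$p[1], 0.0305, tolerance = 1e-2)

  # identical paired columns: zero-variance differences are flagged
  m3 <- cbind(a = c(1, 2), b = c(3, 4), a2 = c(1, 2), b2 = c(3, 4))
  de3 <- paired_de(m3, data.frame(tissue = c("a", "b"),
                                  culture = c("a2", "b2")))
  expect_true(all(de3$zero_variance))
  expect_true(all(is.na(de3$p)))
})

test_that("paired DE is invariant to swapping condition labels (t sign flips)", {
  set.seed(23)
  m <- matrix(rnorm(100 * 8, 8), 100, 8)
  colnames(m) <- c(paste0("t", 1:4), paste0("c", 1:4))
  pairs <- data.frame(tissue = paste0("t", 1:4), culture = paste0("c", 1:4))
  d1 <- paired_de(m, pairs)
  d2 <- paired_de(m, data.frame(tissue = pairs$culture,
                                culture = pairs$tissue))
  expect_equal(d2$t, -d1$t)
  expect_equal(d2$p, d1$p)
  expect_equal(d2$log2fc, -d1$log2fc)
})

test_that("strict DE calls respect the fold-change threshold", {
  sim <- default_sim()
  ex <- simulate_expression(sim$genome, sim$cfg)
  de <- paired_de(quantile_normalize(ex$log2), ex$pairs)
  if (any(de$strict))
    expect_true(all(abs(de$log2fc[de$strict]) > log2(1.5)))
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})

test_that("PCA summary gets degenerate and closed-form cases right", {
  # samples on a line in gene space: PC1 explains everything
  base <- rnorm(50)
  m <- sapply(c(0, 1, 2, 3), function(k) base + k * seq(0, 1, length = 50))
  ps <- pca_summary(m)
  expect_equal(ps$var_frac[1], 1.0, tolerance = 1e-10)

  # 3-sample toy against the closed-form 2x2 eigendecomposition
  m2 <- rbind(g1 = c(0, 1, 3), g2 = c(2, 0, 1))
  cv <- cov(t(m2 - rowMeans(m2)))
  tr <- sum(diag(cv)); dt <- det(cv)
  ev <- c((tr + sqrt(tr^2 - 4 * dt)) / 2, (tr - sqrt(tr^2 - 4 * dt)) / 2)
  ps2 <- pca_summary(m2)
  expect_equal(ps2$var_frac[1:2], ev / sum(ev), tolerance = 1e-10)
})

test_that("default synthetic expression: PC1 separates the conditions", {
  sim <- default_sim()
  ex <- simulate_expression(sim$genome, sim$cfg)
  ps <- pca_summary(quantile_normalize(ex$log2))
  expect_gt(ps$var_frac[1], ps$var_frac[2])
  pc1 <- ps$scores[, 1]
  ti <- ex$samples$condition == "tissue"
  expect_true(max(pc1[ti]) < min(pc1[!ti]) ||
                min(pc1[ti]) > max(pc1[!ti]))
})

test_that("5hmC-expression association matches enumeration and the planted link", {
  # identical groups: p = 1
  v <- c(a = 1, b = 2, c = 1, d = 2)
  ex_flag <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  expect_equal(hmc_expression_association(v, ex_flag)$p, 1)
  # expressed [3,4,5] vs silent [1,2]: exact two-sided p by enumeration
  v2 <- c(a = 3, b = 4, c = 5, d = 1, e = 2)
  f2 <- c(a = TRUE, b = TRUE, c = TRUE, d = FALSE, e = FALSE)
  got <- hmc_expression_association(v2, f2)
  expect_equal(got$p, 0.2)
  expect_equal(got$p, oracle_mw_exact_p(c(3, 4, 5), c(1, 2)))
  expect_error(hmc_expression_association(v2, rep(TRUE, 5)), "non-empty")

  # planted boost: association holds in tissue AND culture
  sim <- default_sim()
  ex <- simulate_expression(sim$genome, sim$cfg)
  expressed <- setNames(ex$truth$expressed, ex$truth$gene_id)
  for (cond in c("tissue", "culture")) {
    ge <- genic_enrichment(hmedip:::condition_mean_track(
      tracks_of(sim, cond, "5hmC")), sim$genome$annotation, "body")
    a <- hmc_expression_association(setNames(ge$median, ge$gene_id),
                                    expressed)
    expect_lt(a$p, 0.01)
    expect_gt(a$median_diff, 0)
  }
})

test_that("variance explained is r^2 with sane degenerate behaviour", {
  x <- rnorm(50)
  expect_equal(variance_explained(x, x)$r2, 1)
  set.seed(24)
  ve <- variance_explained(rnorm(5000), rnorm(5000))
  expect_lt(ve$r2, 0.002)
  expect_warning(z <- variance_explained(rep(1, 10), rnorm(10)),
                 "constant")
  expect_true(is.na(z$r2))

  # decoupled planted 5hmC loss and DE: both effects large, r^2 small
  sim <- default_sim()
  ex <- simulate_expression(sim$genome, sim$cfg)
  de <- paired_de(quantile_normalize(ex$log2), ex$pairs)
  gt <- genic_enrichment(hmedip:::condition_mean_track(
    tracks_of(sim, "tissue", "5hmC")), sim$genome$annotation, "body")
  gc <- genic_enrichment(hmedip:::condition_mean_track(
    tracks_of(sim, "culture", "5hmC")), sim$genome$annotation, "body")
  ve2 <- variance_explained(gc$median - gt$median, de$log2fc)
  expect_lt(ve2$r2, 0.05)
})
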