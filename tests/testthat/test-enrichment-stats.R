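test_that("windowed medians tile chromosomes and match the sort oracle", {
  const <- enrichment_track(rep("c", 100), 0:99 * 1000, rep(1.7, 100))
  wm <- windowed_median(const, 2e4)
  expect_true(all(wm$median == 1.7))

  toy <- enrichment_track(rep("c", 10), 0:9 * 250, c(1, 2, 3, 10, 5:10))
  wm2 <- windowed_median(toy, 1000)  # first window covers probes 1-4
  expect_equal(wm2$median[1], median(c(1, 2, 3, 10)))
  expect_equal(wm2$median[1], 2.5)
  # empty windows flagged missing
  gap <- enrichment_track(rep("c", 4), c(0, 100, 5000, 5100), 1:4)
  wm3 <- windowed_median(gap, 1000,
                         layout = genome_layout("c", 6000))
  expect_equal(wm3$n_probes, c(2L, 0L, 0L, 0L, 0L, 2L))
  expect_true(all(is.na(wm3$median[2:5])))
})

test_that("tissue and culture 5mC windowed medians are conserved", {
  sim <- default_sim()
  a <- windowed_median(hmedip:::condition_mean_track(
    tracks_of(sim, "tissue", "5mC")), 2e6, sim$genome$layout)
  b <- windowed_median(hmedip:::condition_mean_track(
    tracks_of(sim, "culture", "5mC")), 2e6, sim$genome$layout)
  expect_gt(cor(a$median, b$median, use = "complete.obs"), 0.9)
})

test_that("genic enrichment equals the brute-force interval-scan medians", {
  cfg <- tiny_config(seed = 15, n_rep = 1)
  g <- make_genome(cfg)
  tr <- simulate_tracks(g, cfg, marks = "5hmC")$tissue_5hmC_rep1
  ge <- genic_enrichment(tr, g$annotation, "body")
  genes <- g$annotation$genes
  oracle <- vapply(seq_len(nrow(genes)), function(i) {
    v <- tr$score[tr$chrom == genes$chrom[i] & tr$pos >= genes$start[i] &
                    tr$pos < genes$end[i]]
    if (length(v)) median(v) else NA_real_
  }, 0)
  expect_equal(ge$median, oracle)
  expect_true(all(ge$tested == (ge$n_probes >= 5)))

  # gene spanning probes [0, 0, 1] -> median 0
  ann1 <- gene_annotation(data.frame(gene_id = "g", chrom = "c",
                                     strand = "+", start = 0, end = 750))
  t1 <- enrichment_track(rep("c", 4), 0:3 * 250, c(0, 0, 1, 9))
  expect_equal(genic_enrichment(t1, ann1, "body", min_probes = 3)$median, 0)
})

test_that("planted genic 5hmC effect is recovered within tolerance", {
  sim <- default_sim()
  fl <- attr(sim$tracks, "flags")
  ti <- hmedip:::condition_mean_track(tracks_of(sim, "tissue", "5hmC"))
  ge <- genic_enrichment(ti, sim$genome$annotation, "body")
  genes <- sim$genome$annotation$genes
  plain <- !genes$expressed & !genes$imprinted_like
  expect_equal(mean(ge$median[plain & ge$tested], na.rm = TRUE), 1.0,
               tolerance = 0.05)
})

test_that("differential testing matches enumeration on toys", {
  ann <- gene_annotation(data.frame(gene_id = "g", chrom = "c",
                                    strand = "+", start = 0, end = 800))
  mk <- function(sc) enrichment_track(rep("c", 3), 0:2 * 250, sc,
                                      condition = "x", mark = "5hmC")
  tab <- differential_genic(list(mk(c(1, 2, 3))), list(mk(c(4, 5, 6))),
                            ann, "body", min_probes = 3)
  expect_equal(tab$p, 0.1)
  expect_equal(tab$p, oracle_mw_exact_p(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(tab$delta, 3)
  expect_equal(tab$direction, "gain")

  # identical groups: p = 1, delta = 0
  tab0 <- differential_genic(list(mk(c(1, 2, 3))), list(mk(c(1, 2, 3))),
                             ann, "body", min_probes = 3)
  expect_equal(tab0$p, 1)
  expect_equal(tab0$delta, 0)
  expect_true(is.na(tab0$direction))
})

test_that("BH adjustment matches the step-up oracle to 1e-12", {
  set.seed(16)
  for (n in c(1, 7, 100, 1000)) {
    p <- runif(n)^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # adjusted >= raw always
  p <- runif(200)
  expect_true(all(p.adjust(p, "BH") >= p))
})

test_that("BH controls empirical FDR on null-plus-planted simulations", {
  set.seed(17)
  fdp <- replicate(40, {
    p <- c(runif(1800), rbeta(200, 0.05, 1))
    truth <- rep(c(FALSE, TRUE), c(1800, 200))
    rej <- p.adjust(p, "BH") < 0.05
    if (any(rej)) sum(rej & !truth) / sum(rej) else 0
  })
  expect_lt(mean(fdp), 0.05 + 3 * sd(fdp) / sqrt(length(fdp)))
})

test_that("Mann-Whitney p-values are uniform under the null", {
  set.seed(18)
  n_genes <- 10000
  p <- vapply(seq_len(n_genes), function(i) {
    x <- rnorm(25); y <- rnorm(25)
    hmedip:::mw_test(x, y)$p
  }, 0)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-based differential results are monotone-transform invariant", {
  cfg <- tiny_config(seed = 19, n_rep = 1)
  g <- make_genome(cfg)
  tr <- simulate_tracks(g, cfg, marks = "5hmC")
  ti <- tr[grep("tissue", names(tr))]
  cu <- tr[grep("culture", names(tr))]
  tab <- differential_genic(ti, cu, g$annotation, "body")
  mono <- function(t) hmedip:::with_scores(t, t$score + t$score^3)
  tab2 <- differential_genic(lapply(ti, mono), lapply(cu, mono),
                             g$annotation, "body")
  expect_equal(tab2$p, tab$p)
  expect_equal(tab2$u, tab$u)
  expect_equal(tab2$direction, tab$direction)
})

test_that("autocorrelation profiles behave like the simulation oracle", {
  set.seed(20)
  # white noise: acf beyond lag 0 inside the 3/sqrt(n) band
  wn <- enrichment_track(rep("c", 20000), 0:19999 * 250, rnorm(20000))
  a <- track_acf(wn, 10)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf[-1]) < 3 / sqrt(20000)))
  expect_true(all(a$acf >= -1 & a$acf <= 1))

  # 7-probe running-median-smoothed white noise vs a 1e6-sample oracle
  big <- runmed(rnorm(1e6), 7)
  oracle_acf1 <- acf(big, lag.max = 1, plot = FALSE)$acf[2]
  sm <- running_median(wn, 7)
  expect_equal(track_acf(sm, 3)$acf[2], oracle_acf1, tolerance = 0.015)

  # constant track: undefined, flagged
  const <- enrichment_track(rep("c", 200), 0:199, rep(1, 200))
  expect_warning(ac <- track_acf(const, 5), "constant")
  expect_true(all(is.na(ac$acf)))

  # per-chromosome computation: a probe-count-weighted mean, not a
  # concatenated series
  two <- enrichment_track(rep(c("a", "b"), each = 5000),
                          rep(0:4999 * 250, 2), rnorm(10000))
  aa <- track_acf(two, 5)
  sep <- (track_acf(two[two$chrom == "a", ], 5)$acf +
            track_acf(two[two$chrom == "b", ], 5)$acf) / 2
  expect_equal(aa$acf, sep)
})

test_that("Ward clustering matches naive agglomeration on the 1-D toy", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  cl <- cluster_samples(x, k = 2)
  expect_equal(sort(cl$hclust$height), oracle_ward_heights(c(0, 1, 10, 11)))
  expect_equal(unname(cl$labels), c(1, 1, 2, 2))
  # two identical samples and one distant: the identical pair merges first
  y <- matrix(c(5, 5, 50), ncol = 1)
  hc <- cluster_samples(y)$hclust
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_error(cluster_samples(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)),
               "issing")
})

test_that("cross-condition correlation matches the rank-formula oracle", {
  t_of <- function(y) enrichment_track(rep("c", length(y)),
                                       seq_along(y) * 10, y)
  expect_equal(track_correlation(t_of(1:5), t_of(1:5))$estimate, 1)
  expect_equal(track_correlation(t_of(1:5), t_of(5:1))$estimate, -1)
  # rho = 1 - 6 sum d^2 / (n (n^2-1))
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(track_correlation(t_of(x), t_of(y))$estimate,
               1 - 6 * d2 / (4 * 15))
  expect_equal(track_correlation(t_of(x), t_of(y))$estimate, 0.6)
  expect_error(track_correlation(t_of(1:2), t_of(1:2)), "3 paired")
  expect_error(track_correlation(t_of(1:5),
                                 enrichment_track(rep("c", 5),
                                                  1:5 * 11, 1:5)),
               "probe universe")
})

test_that("binned coverage matches the definition and the all-pairs oracle", {
  lay <- genome_layout("c", 10000)
  # RPM definition: 50 of 1e6 reads in one bin -> 50 RPM (scaled down:
  # 50 of 1000 reads -> 50000 RPM)
  reads <- data.frame(chrom = "c", start = c(rep(100, 50), rep(9000, 950)),
                      end = c(rep(200, 50), rep(9100, 950)))
  cov <- bin_coverage(reads, lay, 250)
  expect_equal(cov$score[1], 50 * 1e6 / 1000)
  # a read spanning a bin boundary counts in both bins
  r2 <- data.frame(chrom = "c", start = 100, end = 300)
  cov2 <- bin_coverage(r2, lay, 250)
  expect_equal(cov2$score[1:3], c(1e6, 1e6, 0))
  # boundary: read ending exactly at a bin start does not enter it
  r3 <- data.frame(chrom = "c", start = 0, end = 250)
  expect_equal(bin_coverage(r3, lay, 250)$score[2], 0)

  set.seed(21)
  n <- 10000
  s <- sample.int(9900, n, replace = TRUE) - 1
  rr <- data.frame(chrom = sample(c("c"), n, TRUE), start = s,
                   end = s + sample.int(300, n, replace = TRUE))
  got <- bin_coverage(rr, lay, 250)
  bins <- data.frame(start = 0:39 * 250, end = 1:40 * 250)
  oracle <- vapply(seq_len(40), function(b)
    sum(rr$start < bins$end[b] & bins$start[b] < rr$end), 0)
  expect_equal(got$score, oracle * 1e6 / n)
  expect_error(bin_coverage(rr[0, ], lay, 250), "zero reads")

  expect_equal(low_count_filter(c(0, 3, 7), c(1, 6, 0)),
               c(FALSE, TRUE, TRUE))
})
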