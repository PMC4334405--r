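test_that("genome generation is deterministic and respects its geometry", {
  cfg <- sim_config(seed = 7)
  g <- make_genome(cfg)
  # 2 x 25 Mb at 250 bp spacing -> 200,000 probes
  expect_equal(nrow(g$probes), 200000)
  expect_equal(nrow(g$annotation$genes), 400)
  g2 <- make_genome(sim_config(seed = 7))
  expect_identical(g$annotation$genes, g2$annotation$genes)
  expect_identical(g$probes, g2$probes)

  genes <- g$annotation$genes
  # genes placed without overlap (per chromosome)
  for (ch in unique(genes$chrom)) {
    d <- genes[genes$chrom == ch, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # contiguous cluster block on one chromosome
  ci <- which(genes$cluster_member)
  expect_equal(ci, min(ci):max(ci))
  expect_equal(length(unique(genes$chrom[ci])), 1)
  # genic probe fraction ~ n_genes * mean length / genome size
  fl <- hmedip:::probe_flags(g)
  expect_equal(mean(fl$genic), 400 * 20000 / 50e6, tolerance = 0.15)
  # exons inside transcripts is enforced by the constructor; spot-check
  ex <- g$annotation$exons
  i <- match(ex$gene_id, genes$gene_id)
  expect_true(all(ex$start >= genes$start[i] & ex$end <= genes$end[i]))

  expect_error(make_genome(sim_config(n_genes = 5000)), "cannot place")
})

test_that("planted 5hmC attenuation and protected loci appear in the tracks", {
  sim <- default_sim()
  fl <- attr(sim$tracks, "flags")
  ti <- hmedip:::condition_mean_track(tracks_of(sim, "tissue", "5hmC"))
  cu <- hmedip:::condition_mean_track(tracks_of(sim, "culture", "5hmC"))
  genic <- fl$genic & !fl$expressed & !fl$protected
  # tissue genic mean ~ mu_g; culture ~ alpha * mu_g (drop ~ 0.9)
  expect_equal(mean(ti$score[genic]), 1.0, tolerance = 0.05)
  expect_equal(mean(ti$score[genic]) - mean(cu$score[genic]), 0.9,
               tolerance = 0.05)
  # protected (imprinted-like) loci retain full enrichment in culture
  expect_equal(mean(cu$score[fl$protected]),
               mean(ti$score[fl$protected]), tolerance = 0.1)
  expect_gt(mean(cu$score[fl$protected]), 0.8)
})

test_that("alpha = 1 leaves the two conditions equivalent (null case)", {
  cfg <- tiny_config(seed = 5, alpha = 1, delta_promoter = 0, n_rep = 2)
  g <- make_genome(cfg)
  tr <- simulate_tracks(g, cfg, marks = "5hmC")
  fl <- attr(tr, "flags")
  ti <- tr$tissue_5hmC_rep1; cu <- tr$culture_5hmC_rep1
  se <- sqrt(2) * cfg$sigma / sqrt(sum(fl$genic))
  expect_lt(abs(mean(ti$score[fl$genic]) - mean(cu$score[fl$genic])),
            3 * se)
})

test_that("shared 5mC profile is conserved across conditions (rho >= 0.95)", {
  sim <- default_sim()
  a <- running_median(sim$tracks$tissue_5mC_rep1, 7)
  b <- running_median(sim$tracks$culture_5mC_rep1, 7)
  rho_m <- track_correlation(a, b, "spearman")$estimate
  expect_gte(rho_m, 0.95)
  # and 5hmC correlation is far lower in every seeded run
  ah <- running_median(sim$tracks$tissue_5hmC_rep1, 7)
  bh <- running_median(sim$tracks$culture_5hmC_rep1, 7)
  expect_lt(track_correlation(ah, bh, "spearman")$estimate, rho_m - 0.3)
})

test_that("track simulation is reproducible under a fixed seed", {
  cfg <- tiny_config(seed = 11, n_rep = 1)
  g <- make_genome(cfg)
  t1 <- simulate_tracks(g, cfg, marks = "5hmC")
  t2 <- simulate_tracks(g, cfg, marks = "5hmC")
  expect_identical(t1$tissue_5hmC_rep1$score, t2$tissue_5hmC_rep1$score)
})

test_that("null expression config gives nominal type-I error", {
  genes <- data.frame(gene_id = sprintf("g%05d", 1:10000),
                      expressed = TRUE)
  cfg <- sim_config(seed = 21, frac_de = 0)
  ex <- simulate_expression(genes, cfg)
  de <- paired_de(quantile_normalize(ex$log2), ex$pairs)
  rate <- mean(de$p < 0.01, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.015)
})

test_that("planted expression structure is recovered", {
  sim <- default_sim()
  ex <- simulate_expression(sim$genome, sim$cfg)
  # ~90% of planted changes below two-fold (3 binomial SE band)
  frac2 <- mean(abs(ex$truth$log2fc[ex$truth$de]) < 1)
  expect_lt(abs(frac2 - 0.9),
            3 * sqrt(0.9 * 0.1 / sum(ex$truth$de)))
  qn <- quantile_normalize(ex$log2)
  de <- paired_de(qn, ex$pairs)
  called <- de$de
  expect_gt(sum(called), 30)
  # direction of every called gene matches the planted direction
  dir_ok <- sign(de$log2fc[called]) ==
    ifelse(ex$truth$direction[called] == "up", 1, -1)
  expect_true(all(dir_ok, na.rm = TRUE))
  # up:down ratio within binomial error of the planted 53:47 split
  n <- sum(called)
  up <- sum(de$log2fc[called] > 0)
  expect_lt(abs(up / n - 0.53), 3 * sqrt(0.53 * 0.47 / n) + 0.02)
  # expressed-call fraction matches the planted expressed fraction +/- 2%
  ec <- expressed_call(ex$detection, ex$samples$condition)
  expect_equal(mean(ec[, "tissue"]), mean(ex$truth$expressed),
               tolerance = 0.021)
})

test_that("clone simulation obeys its planted probabilities", {
  # methylation probability 0 -> 0% methylation
  cs0 <- simulate_clones(10, 0, conv_fail = 0, n_clones = 5, seed = 2)
  s0 <- filter_and_summarize(cs0)
  expect_equal(s0$overall, 0)
  # probability 0.5, 20 CpGs x 20 clones: overall within exact binomial CI
  cs <- simulate_clones(20, 0.5, conv_fail = 0, n_clones = 20, seed = 3)
  s <- filter_and_summarize(cs)
  ci <- stats::binom.test(round(s$overall / 100 * 400), 400)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
  # conversion failure 0.1: exclusion fraction near the closed-form
  # binomial tail P(Bin(20, 0.1) >= 2) (rate < 0.95 means >= 2 of 20 fail)
  # 20 CpGs so duplicate removal is a measure-zero event and does not
  # bias the retained population's conversion distribution
  cs2 <- simulate_clones(20, 0.5, conv_fail = 0.1, n_clones = 400,
                         seed = 4, n_noncpg = 20)
  s2 <- filter_and_summarize(cs2)
  drop_frac <- s2$n_removed_conversion /
    (400 - s2$n_removed_dup)
  expected <- stats::pbinom(1, 20, 0.1, lower.tail = FALSE)
  expect_equal(drop_frac, expected,
               tolerance = 3 * sqrt(expected * (1 - expected) / 400) /
                 expected)
})
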