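#' Simulation configuration
#'
#' Bundles every parameter of the synthetic tissue/culture experiment. The
#' defaults emulate the study design the package targets: four paired
#' replicates per condition on a 2 x 25 Mb probe grid at 250 bp spacing
#' (200,000 probes), a genic 5hmC enrichment of 1.0 (log2-ratio units) over
#' background noise SD 0.5, a 10-fold culture attenuation of the 5hmC effect
#' (`alpha = 0.1`) sparing a small set of protected imprinted-like loci, a
#' shared smooth 5mC profile conserved across conditions (cross-condition
#' Spearman correlation ~0.98) with a clustered set of promoters gaining 5mC
#' in culture, and mostly-small (90% under two-fold) bidirectional expression
#' changes.
#'
#' @param seed integer master seed; stage seeds are derived with
#'   [stage_seed()], so identical configs give identical outputs.
#' @param n_chrom,chrom_length,probe_spacing probe grid geometry (bp).
#' @param n_genes,gene_length_range,exons_per_gene gene complement.
#' @param n_rep paired replicates per condition (replicates 1..n_rep/2 are
#'   male, the rest female; sex is metadata only unless `sex_effect > 0`).
#' @param mu_genic genic 5hmC enrichment (score units) in tissue.
#' @param sigma per-probe replicate noise SD (score units).
#' @param alpha culture attenuation multiplier on the genic 5hmC effect,
#'   in (0, 1]; 0.1 emulates a ~10-fold loss.
#' @param frac_protected fraction of genes whose 5hmC is protected from
#'   attenuation (imprinted-like loci).
#' @param mu_genic_5mc genic 5mC enrichment (both conditions).
#' @param latent_sd,latent_window SD (score units) and smoothing window
#'   (probes) of the shared long-range 5mC profile.
#' @param frac_promoter_gain fraction of promoters gaining 5mC in culture;
#'   gain promoters are drawn from the clustered (Hox-like) gene block first.
#' @param delta_promoter promoter 5mC gain in culture (score units;
#'   default 2 * `sigma`).
#' @param cluster_size number of contiguous cluster-member genes.
#' @param frac_expressed fraction of expressed genes.
#' @param expr_hmc_boost extra genic 5hmC on expressed genes (score units).
#' @param sex_effect,sex_probe_frac optional male-offset (score units) on a
#'   random probe subset of the 5mC tracks; default off.
#' @param dye_bias quadratic dye-bias coefficients (intercept, linear,
#'   quadratic in centered mean log-intensity A) for the raw two-channel
#'   mode; `a_mean`/`a_sd` set the A distribution.
#' @param frac_de,frac_up,lfc_sd expression: fraction of expressed genes
#'   differentially expressed, fraction of those up-regulated, and SD of the
#'   half-normal log2 fold-change magnitude (default log2(2)/qnorm(0.95), so
#'   ~90% of changes are below two-fold).
#' @param expr_noise_sd,pair_sd,sample_offset_sd,sex_gene_frac,sex_effect_expr
#'   expression noise structure: residual SD, shared pair-effect SD,
#'   per-sample global offset SD (removed by quantile normalization), and a
#'   weak sex signature (fraction of genes, offset).
#' @param clone_n_cpg,clone_n_noncpg,clone_meth_prob,clone_conv_fail,n_clones
#'   bisulfite clone simulation: CpG count, non-CpG cytosine count, per-CpG
#'   methylation probability (scalar or vector), conversion failure rate,
#'   clones per region.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2, chrom_length = 25e6, probe_spacing = 250,
                       n_genes = 400, gene_length_range = c(10000, 30000),
                       exons_per_gene = c(3, 8),
                       n_rep = 4,
                       mu_genic = 1.0, sigma = 0.5, alpha = 0.1,
                       frac_protected = 0.02,
                       mu_genic_5mc = 0.5,
                       latent_sd = 1.75, latent_window = 1601,
                       frac_promoter_gain = 0.025, delta_promoter = 2 * sigma,
                       cluster_size = 10,
                       frac_expressed = 0.7, expr_hmc_boost = 0.5,
                       sex_effect = 0, sex_probe_frac = 0.05,
                       dye_bias = c(0.3, 0.2, 0.05), a_mean = 10, a_sd = 1,
                       frac_de = 0.45, frac_up = 0.53,
                       lfc_sd = log2(2) / stats::qnorm(0.95),
                       expr_noise_sd = 0.05, pair_sd = 0.2,
                       sample_offset_sd = 0.3,
                       sex_gene_frac = 0.05, sex_effect_expr = 0.25,
                       clone_n_cpg = 20, clone_n_noncpg = 20,
                       clone_meth_prob = 0.5, clone_conv_fail = 0.02,
                       n_clones = 20) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha <= 1, sigma > 0,
            frac_protected >= 0, frac_protected <= 1,
            frac_promoter_gain >= 0, frac_promoter_gain <= 1,
            frac_expressed >= 0, frac_expressed <= 1,
            frac_de >= 0, frac_de <= 1, frac_up >= 0, frac_up <= 1,
            all(clone_meth_prob >= 0), all(clone_meth_prob <= 1),
            clone_conv_fail >= 0, clone_conv_fail <= 1,
            n_rep >= 1, n_chrom >= 1, probe_spacing > 0)
  structure(cfg, class = "sim_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic hash of (seed, stage name) kept below 2^31, so adding a
#' stage never perturbs the randomness of the others.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

# Running mean with shrinking windows at the edges (window = odd probe count)
.runmean <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Generate the synthetic genome, gene annotation and probe grid
#'
#' Genes are placed without overlap (one gene per equal-width slot, at a
#' random offset leaving room for the promoter), a contiguous block of
#' `cluster_size` genes is flagged `cluster_member` (the Hox-like cluster
#' whose promoters gain 5mC in culture), a random subset is flagged
#' `imprinted_like` (protected from 5hmC attenuation), and each gene gets a
#' random exon/intron structure. The probe grid spans every chromosome at
#' fixed spacing.
#'
#' @param config a [sim_config()].
#' @return List of class `dip_genome` with elements `layout`
#'   ([genome_layout()]), `annotation` ([gene_annotation()]), `probes`
#'   (data frame `chrom`, `pos`) and `config`.
#' @export
make_genome <- function(config = sim_config()) {
  set.seed(stage_seed(config$seed, "genome"))
  layout <- genome_layout(paste0("chr", seq_len(config$n_chrom)),
                          rep(config$chrom_length, config$n_chrom))
  npp <- floor(config$chrom_length / config$probe_spacing)
  probes <- data.frame(
    chrom = rep(layout$chrom, each = npp),
    pos = rep((seq_len(npp) - 1) * config$probe_spacing, config$n_chrom),
    stringsAsFactors = FALSE)

  per_chr <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  margin <- 2500  # room for promoter/strand flip on either side
  max_len <- max(config$gene_length_range)
  rows <- list()
  for (ci in seq_len(config$n_chrom)) {
    ng <- per_chr[ci]
    if (ng == 0) next
    slot <- floor(config$chrom_length / ng)
    if (slot < max_len + 2 * margin + 1)
      stop(sprintf(paste0("cannot place %d genes of length up to %d bp on a ",
                          "%d bp chromosome (need slots of %d bp, have %d)"),
                   ng, max_len, config$chrom_length,
                   max_len + 2 * margin + 1, slot))
    len <- round(stats::runif(ng, config$gene_length_range[1],
                              config$gene_length_range[2]))
    off <- margin + floor(stats::runif(ng) * (slot - len - 2 * margin))
    start <- (seq_len(ng) - 1) * slot + off
    rows[[ci]] <- data.frame(
      gene_id = sprintf("g%s_%03d", ci, seq_len(ng)),
      chrom = layout$chrom[ci], strand = sample(c("+", "-"), ng, TRUE),
      start = start, end = start + len, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  n <- nrow(genes)

  cs <- min(config$cluster_size, n)
  cstart <- sample.int(n - cs + 1, 1)
  # keep the cluster within one chromosome
  while (length(unique(genes$chrom[cstart:(cstart + cs - 1)])) > 1)
    cstart <- sample.int(n - cs + 1, 1)
  genes$cluster_member <- FALSE
  genes$cluster_member[cstart:(cstart + cs - 1)] <- TRUE

  n_imp <- round(config$frac_protected * n)
  imp_pool <- which(!genes$cluster_member)
  genes$imprinted_like <- FALSE
  if (n_imp > 0)
    genes$imprinted_like[sample(imp_pool, min(n_imp, length(imp_pool)))] <- TRUE

  n_gain <- round(config$frac_promoter_gain * n)
  gain <- which(genes$cluster_member)[seq_len(min(cs, n_gain))]
  if (n_gain > cs)
    gain <- c(gain, sample(which(!genes$cluster_member), n_gain - cs))
  genes$gains_5mc <- FALSE
  genes$gains_5mc[gain] <- TRUE

  genes$expressed <- stats::runif(n) < config$frac_expressed

  ex <- lapply(seq_len(n), function(i) {
    k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
    b <- sort(sample(seq(genes$start[i] + 1, genes$end[i] - 1), 2 * k))
    data.frame(gene_id = genes$gene_id[i],
               start = c(genes$start[i], b[seq_len(k - 1) * 2]),
               end = b[seq_len(k) * 2 - 1],
               stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, ex)
  rownames(exons) <- NULL

  structure(list(layout = layout,
                 annotation = gene_annotation(genes, exons),
                 probes = probes, config = config),
            class = "dip_genome")
}

#' @export
print.dip_genome <- function(x, ...) {
  cat(sprintf("dip_genome: %d chromosomes, %d probes (%d bp spacing), %d genes\n",
              nrow(x$layout), nrow(x$probes), x$config$probe_spacing,
              nrow(x$annotation$genes)))
  invisible(x)
}

# Per-probe planted structure: gene membership and derived flags.
probe_flags <- function(genome) {
  genes <- genome$annotation$genes
  probes <- genome$probes
  gene_idx <- integer(nrow(probes))
  gain_prom <- logical(nrow(probes))
  for (ch in unique(probes$chrom)) {
    sel <- which(probes$chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) next
    i <- findInterval(probes$pos[sel], g$start)
    inside <- i > 0 & probes$pos[sel] < g$end[pmax(i, 1)]
    gene_idx[sel[inside]] <- match(g$gene_id[i[inside]], genes$gene_id)
    gp <- g[g$gains_5mc, ]
    if (nrow(gp)) {
      o <- order(gp$promoter_start)
      j <- findInterval(probes$pos[sel], gp$promoter_start[o])
      gain_prom[sel] <- j > 0 & probes$pos[sel] < gp$promoter_end[o][pmax(j, 1)]
    }
  }
  genic <- gene_idx > 0
  data.frame(
    gene_idx = gene_idx,
    genic = genic,
    expressed = genic & genes$expressed[pmax(gene_idx, 1)],
    protected = genic & genes$imprinted_like[pmax(gene_idx, 1)],
    gain_promoter = gain_prom)
}

#' Simulate tissue/culture enrichment tracks
#'
#' Plants the study's signal structure on the probe grid. For 5hmC, genic
#' probes carry `mu_genic` (plus `expr_hmc_boost` for expressed genes) over
#' N(0, sigma) background in tissue; in culture the effect is multiplied by
#' `alpha` except at protected imprinted-like loci, which retain it in full.
#' For 5mC, all samples share a smooth long-range profile plus a genic
#' enrichment, identical in expectation across conditions except at the
#' flagged gain promoters, which add `delta_promoter` in culture. Replicate
#' noise is independent N(0, sigma) everywhere.
#'
#' @param genome a [make_genome()] result.
#' @param config a [sim_config()]; defaults to the genome's.
#' @param marks which marks to simulate.
#' @return Named list of [enrichment_track()] (class `track_set`), names
#'   `<condition>_<mark>_rep<i>`, with the per-probe planted structure in
#'   `attr(, "flags")`.
#' @export
simulate_tracks <- function(genome, config = genome$config,
                            marks = c("5hmC", "5mC")) {
  set.seed(stage_seed(config$seed, "tracks"))
  fl <- probe_flags(genome)
  np <- nrow(genome$probes)
  chrom <- genome$probes$chrom

  # shared smooth 5mC profile, identical in every sample
  latent <- unlist(lapply(split(stats::rnorm(np), chrom), function(z) {
    L <- .runmean(z, min(config$latent_window, 2 * (length(z) %/% 2) - 1))
    L / stats::sd(L) * config$latent_sd
  }), use.names = FALSE)
  sex_probe <- stats::runif(np) < config$sex_probe_frac

  e_hmc <- config$mu_genic * fl$genic + config$expr_hmc_boost * fl$expressed
  mu <- list(
    tissue_5hmC  = e_hmc,
    culture_5hmC = ifelse(fl$protected, e_hmc, config$alpha * e_hmc),
    tissue_5mC   = latent + config$mu_genic_5mc * fl$genic,
    culture_5mC  = latent + config$mu_genic_5mc * fl$genic +
                   config$delta_promoter * fl$gain_promoter)

  sexes <- rep(c("M", "F"), c(ceiling(config$n_rep / 2),
                              floor(config$n_rep / 2)))
  tracks <- list()
  for (cond in c("tissue", "culture")) {
    for (mk in marks) {
      base <- mu[[paste(cond, mk, sep = "_")]]
      for (r in seq_len(config$n_rep)) {
        sc <- base + stats::rnorm(np, 0, config$sigma)
        if (mk == "5mC" && config$sex_effect > 0 && sexes[r] == "M")
          sc <- sc + config$sex_effect * sex_probe
        id <- sprintf("%s_%s_rep%d", cond, mk, r)
        tracks[[id]] <- enrichment_track(
          chrom, genome$probes$pos, sc, sample_id = id, condition = cond,
          mark = mk, replicate = sprintf("rep%d_%s", r, sexes[r]))
      }
    }
  }
  structure(tracks, flags = fl, sexes = sexes, class = "track_set")
}

#' Simulate raw two-channel intensities from a track
#'
#' Converts a (true) log-ratio track into per-probe IP/input intensities
#' with a smooth quadratic intensity-dependent dye bias added to M — the
#' curved MA cloud [lowess_normalize()] exists to remove.
#'
#' @param track an [enrichment_track()] of true M values.
#' @param config a [sim_config()] (uses `dye_bias`, `a_mean`, `a_sd`,
#'   `seed`).
#' @return Data frame `chrom`, `pos`, `ip`, `input`.
#' @export
simulate_two_channel <- function(track, config = sim_config()) {
  set.seed(stage_seed(config$seed, paste0("twochannel_",
                                          attr(track, "sample_id"))))
  n <- nrow(track)
  a <- stats::rnorm(n, config$a_mean, config$a_sd)
  z <- a - mean(a)
  m <- track$score + config$dye_bias[1] + config$dye_bias[2] * z +
    config$dye_bias[3] * z^2
  data.frame(chrom = track$chrom, pos = track$pos,
             ip = 2^(a + m / 2), input = 2^(a - m / 2),
             stringsAsFactors = FALSE)
}

#' Simulate the paired expression experiment
#'
#' Expressed genes get a high baseline and low detection p-values; a silent
#' subset gets a low baseline and uniform detection p-values. A fraction
#' `frac_de` of expressed genes is differentially expressed with
#' half-normal log2 fold changes (~90% under two-fold by default) split
#' `frac_up`:(1-`frac_up`) between up and down. Samples carry per-sample
#' global offsets (for quantile normalization to remove), shared pair
#' effects, and a weak sex signature.
#'
#' @param genome a [make_genome()] result (gene complement is taken from
#'   it) or a `gene_annotation` gene table with `gene_id` and `expressed`.
#' @param config a [sim_config()].
#' @return List of class `expression_sim`: `log2` (genes x samples),
#'   `detection` (matching detection p-values), `samples` (metadata),
#'   `pairs` (tissue/culture sample pairing) and `truth` (planted labels).
#' @export
simulate_expression <- function(genome, config = NULL) {
  if (inherits(genome, "dip_genome")) {
    if (is.null(config)) config <- genome$config
    genes <- genome$annotation$genes
  } else {
    genes <- genome
    if (is.null(config)) config <- sim_config()
  }
  set.seed(stage_seed(config$seed, "expression"))
  n <- nrow(genes)
  expressed <- genes$expressed
  nr <- config$n_rep
  sexes <- rep(c("M", "F"), c(ceiling(nr / 2), floor(nr / 2)))
  samples <- data.frame(
    sample_id = c(sprintf("tissue_rep%d", seq_len(nr)),
                  sprintf("culture_rep%d", seq_len(nr))),
    condition = rep(c("tissue", "culture"), each = nr),
    replicate = rep(seq_len(nr), 2), sex = rep(sexes, 2),
    stringsAsFactors = FALSE)
  pairs <- data.frame(tissue = samples$sample_id[seq_len(nr)],
                      culture = samples$sample_id[nr + seq_len(nr)],
                      stringsAsFactors = FALSE)

  base <- ifelse(expressed, stats::rnorm(n, 8, 1.5), stats::rnorm(n, 4, 0.5))
  de <- rep(FALSE, n)
  idx_expr <- which(expressed)
  n_de <- round(config$frac_de * length(idx_expr))
  de[sample(idx_expr, n_de)] <- TRUE
  up <- de & (stats::runif(n) < config$frac_up)
  lfc <- numeric(n)
  lfc[de] <- abs(stats::rnorm(sum(de), 0, config$lfc_sd)) *
    ifelse(up[de], 1, -1)
  sex_gene <- stats::runif(n) < config$sex_gene_frac
  pair_eff <- matrix(stats::rnorm(n * nr, 0, config$pair_sd), n, nr)
  offset <- stats::rnorm(2 * nr, 0, config$sample_offset_sd)

  m <- matrix(0, n, 2 * nr, dimnames = list(genes$gene_id,
                                            samples$sample_id))
  detection <- matrix(0, n, 2 * nr, dimnames = dimnames(m))
  for (s in seq_len(2 * nr)) {
    cond <- samples$condition[s]; r <- samples$replicate[s]
    mu <- base + (cond == "culture") * lfc + pair_eff[, r] + offset[s] +
      config$sex_effect_expr * sex_gene * (samples$sex[s] == "M")
    m[, s] <- mu + stats::rnorm(n, 0, config$expr_noise_sd)
    detection[, s] <- ifelse(expressed, stats::runif(n, 0, 0.005),
                             stats::runif(n))
  }
  truth <- data.frame(gene_id = genes$gene_id, expressed = expressed,
                      de = de, direction = ifelse(!de, NA_character_,
                                                  ifelse(up, "up", "down")),
                      log2fc = lfc, stringsAsFactors = FALSE)
  structure(list(log2 = m, detection = detection, samples = samples,
                 pairs = pairs, truth = truth), class = "expression_sim")
}

#' Simulate bisulfite clone sequences for one region
#'
#' Builds a reference with `n_cpg` CpG dinucleotides and `n_noncpg`
#' non-CpG cytosines, then draws each clone's CpG methylation states
#' independently from `meth_prob` and lets each non-CpG cytosine fail to
#' convert with probability `conv_fail`.
#'
#' @param n_cpg number of CpG sites.
#' @param meth_prob per-CpG methylation probability (scalar or length
#'   `n_cpg`).
#' @param conv_fail bisulfite conversion failure rate for non-CpG
#'   cytosines.
#' @param n_clones number of clones.
#' @param seed integer seed.
#' @param n_noncpg number of non-CpG cytosines in the reference.
#' @return List of class `clone_sim`: `reference`, `clones` (named
#'   character vector) and `truth` (planted states).
#' @export
simulate_clones <- function(n_cpg, meth_prob = 0.5, conv_fail = 0.02,
                            n_clones = 20, seed = 1, n_noncpg = 20) {
  stopifnot(all(meth_prob >= 0), all(meth_prob <= 1),
            conv_fail >= 0, conv_fail <= 1)
  set.seed(stage_seed(seed, "clones"))
  meth_prob <- rep_len(meth_prob, n_cpg)
  units <- sample(c(rep("TACG", n_cpg), rep("TACT", n_noncpg)))
  is_cpg_unit <- units == "TACG"
  reference <- paste(units, collapse = "")
  meth <- matrix(stats::rbinom(n_clones * n_cpg, 1,
                               rep(meth_prob, each = n_clones)) == 1,
                 n_clones, n_cpg)
  fail <- matrix(stats::rbinom(n_clones * n_noncpg, 1, conv_fail) == 1,
                 n_clones, n_noncpg)
  clones <- vapply(seq_len(n_clones), function(i) {
    u <- units
    u[is_cpg_unit] <- ifelse(meth[i, ], "TACG", "TATG")
    u[!is_cpg_unit] <- ifelse(fail[i, ], "TACT", "TATT")
    paste(u, collapse = "")
  }, "")
  names(clones) <- sprintf("clone%02d", seq_len(n_clones))
  structure(list(reference = reference, clones = clones,
                 truth = list(meth_prob = meth_prob, meth = meth,
                              conversion_failed = fail)),
            class = "clone_sim")
}
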