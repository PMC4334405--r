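# Independent brute-force oracles and shared fixtures. Every oracle here
# re-derives its quantity by the most direct route available (exhaustive
# scan, enumeration, closed form), independent of the package's code path.

# small genome for unit tests (fast: 16k probes)
tiny_config <- function(seed = 42, ...) {
  sim_config(seed = seed, chrom_length = 2e6, n_genes = 20, ...)
}

# full default-scale simulation, cached per seed so acceptance blocks can
# share one realization
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 101, ...) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(seed = seed, ...)
    genome <- make_genome(cfg)
    .sim_cache[[key]] <- list(cfg = cfg, genome = genome,
                              tracks = simulate_tracks(genome, cfg))
  }
  .sim_cache[[key]]
}

tracks_of <- function(sim, cond, mark)
  sim$tracks[grep(paste0("^", cond, "_", mark, "_"), names(sim$tracks))]

# exhaustive interval-membership compartment oracle
oracle_compartment <- function(chrom, pos, annotation) {
  genes <- annotation$genes
  exons <- annotation$exons
  vapply(seq_along(pos), function(i) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (any(pos[i] >= g$promoter_start & pos[i] < g$promoter_end))
      return("promoter")
    e <- exons[exons$gene_id %in% g$gene_id, , drop = FALSE]
    if (any(pos[i] >= e$start & pos[i] < e$end)) return("exon")
    if (any(pos[i] >= g$start & pos[i] < g$end)) return("intron")
    "intergenic"
  }, "")
}

# O(n^2) all-pairs interval overlap oracle (half-open)
oracle_overlap_fraction <- function(a, b) {
  if (nrow(a) == 0) return(0)
  hit <- vapply(seq_len(nrow(a)), function(i)
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end),
    TRUE)
  mean(hit)
}

# per-point tricube weighted-least-squares LOWESS oracle via lm.wfit
oracle_lowess <- function(x, y, span = 0.3, iterations = 3) {
  n <- length(x)
  k <- ceiling(span * n)
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:iterations) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      idx <- order(d)[seq_len(k)]
      h <- max(d[idx])
      w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, k)
      w <- w * rw[idx]
      if (sum(w) <= 0) { fit[i] <- y[i]; next }
      co <- stats::lm.wfit(cbind(1, x[idx]), y[idx], w)$coefficients
      fit[i] <- if (is.na(co[2])) co[1] else co[1] + co[2] * x[i]
    }
    if (it == iterations) break
    res <- y - fit
    s <- stats::median(abs(res))
    if (s <= 0) break
    u <- res / (6 * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  fit
}

# naive O(n^3) Ward agglomeration in 1-D; returns sorted merge heights
# using the ward.D2 convention h = sqrt(2 |A||B|/(|A|+|B|) ||mA - mB||^2)
oracle_ward_heights <- function(x) {
  clusters <- as.list(x)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
                  (mean(a) - mean(b))^2)
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# Benjamini-Hochberg step-up oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(pmin(1, n / seq_len(n) * p[o]))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">"))
  }
  us <- utils::combn(length(pooled), m, u_of)
  u_obs <- sum(outer(x, y, ">"))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# direct chi-square statistic
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
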