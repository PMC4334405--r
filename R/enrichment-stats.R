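#' Median score in non-overlapping genomic windows
#'
#' Tiles each chromosome with non-overlapping windows from position 0 and
#' reports the median probe score per window (the 2 Mb heatmap summary).
#' Windows containing no probes are flagged missing.
#'
#' @param track an [enrichment_track()].
#' @param window window size in bp (default 2e6).
#' @param layout optional [genome_layout()]; when given, the tiling covers
#'   whole chromosomes, otherwise it stops at the last probe.
#' @return Data frame `chrom`, `start`, `end`, `n_probes`, `median`.
#' @export
windowed_median <- function(track, window = 2e6, layout = NULL) {
  stopifnot(window > 0)
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch
    pos <- track$pos[sel]; sc <- track$score[sel]
    len <- if (!is.null(layout)) layout$length[match(ch, layout$chrom)]
           else max(pos) + 1
    nwin <- ceiling(len / window)
    wi <- factor(floor(pos / window), levels = 0:(nwin - 1))
    med <- tapply(sc, wi, stats::median, na.rm = TRUE)
    np <- tapply(sc, wi, length)
    np[is.na(np)] <- 0
    out[[ch]] <- data.frame(
      chrom = ch, start = (0:(nwin - 1)) * window,
      end = pmin((1:nwin) * window, len),
      n_probes = as.integer(np), median = as.numeric(med),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Probe scores per gene region (a probe inside several regions contributes
# to each). Returns a list of score vectors indexed by gene, for region =
# transcript body or promoter.
.gene_probe_scores <- function(track, annotation, region) {
  genes <- annotation$genes
  if (region == "body") {
    rs <- genes$start; re <- genes$end
  } else {
    rs <- genes$promoter_start; re <- genes$promoter_end
  }
  res <- rep(list(numeric(0)), nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    sel <- which(track$chrom == ch)
    if (length(sel) == 0) next
    ov <- IRanges::findOverlaps(.iranges(track$pos[sel],
                                         track$pos[sel] + 1),
                                .iranges(rs[gi], re[gi]))
    hit <- split(track$score[sel][S4Vectors::queryHits(ov)],
                 gi[S4Vectors::subjectHits(ov)])
    res[as.integer(names(hit))] <- hit
  }
  names(res) <- genes$gene_id
  res
}

#' Per-gene enrichment (median probe score over a gene region)
#'
#' Gene-body or promoter enrichment is the median track score over the
#' probes whose position falls in the region. Genes with fewer than
#' `min_probes` probes are flagged untested; genes with no probes get a
#' missing value.
#'
#' @param track an [enrichment_track()].
#' @param annotation a [gene_annotation()].
#' @param region `"body"` or `"promoter"`.
#' @param min_probes minimum probes for a gene to be tested (default 5).
#' @return Data frame `gene_id`, `n_probes`, `median`, `tested`.
#' @export
genic_enrichment <- function(track, annotation,
                             region = c("body", "promoter"),
                             min_probes = 5) {
  region <- match.arg(region)
  sc <- .gene_probe_scores(track, annotation, region)
  np <- lengths(sc)
  data.frame(gene_id = annotation$genes$gene_id, n_probes = np,
             median = vapply(sc, function(v)
               if (length(v)) stats::median(v, na.rm = TRUE) else NA_real_,
               0),
             tested = np >= min_probes,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Two-sided Mann-Whitney U. Exact enumeration (via the exact U null
# distribution) when the combined sample size is <= 20 and untied;
# otherwise the normal approximation with tie correction.
mw_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  exact <- (length(x) + length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(u = unname(ht$statistic), p = ht$p.value)
}

# Average replicate tracks probe-wise (common probe universe required).
condition_mean_track <- function(tracks) {
  ref <- tracks[[1]]
  for (t in tracks[-1])
    if (!identical(t$chrom, ref$chrom) || !identical(t$pos, ref$pos))
      stop("tracks must share a probe universe")
  sc <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "score")))
  meta <- track_meta(ref)
  enrichment_track(ref$chrom, ref$pos, sc,
                   sample_id = paste0(meta$condition, "_", meta$mark,
                                      "_mean"),
                   condition = meta$condition, mark = meta$mark,
                   replicate = "mean")
}

#' Per-gene differential enrichment between conditions
#'
#' For each gene region, replicate tracks are first averaged probe-wise
#' within each condition; the gene's per-probe tissue means and per-probe
#' culture means are then compared as two samples with a two-sided
#' Mann-Whitney U test (exact for small untied samples, normal
#' approximation with tie correction otherwise). P-values are
#' Benjamini-Hochberg adjusted across all tested genes; the effect size is
#' delta = median(culture) - median(tissue); `top_change` flags the top
#' `top_frac` absolute deltas among tested genes.
#'
#' @param tissue_tracks,culture_tracks lists of replicate
#'   [enrichment_track()]s sharing one probe universe.
#' @param annotation a [gene_annotation()].
#' @param region `"body"` or `"promoter"`.
#' @param alpha significance level on the chosen p-value (default 0.01).
#' @param top_frac fraction of tested genes flagged as top changes
#'   (default 0.05).
#' @param min_probes minimum probes per region to test a gene.
#' @param sig_on `"adjusted"` (default; the gene-body convention) or
#'   `"raw"` (the promoter convention, where rank-test granularity makes
#'   adjusted calls unattainable for small probe counts).
#' @return Data frame of class `differential_table`: `gene_id`, `region`,
#'   `n_probes`, `median_tissue`, `median_culture`, `delta`, `u`, `p`,
#'   `p_adj`, `significant`, `top_change`, `direction`.
#' @export
differential_genic <- function(tissue_tracks, culture_tracks, annotation,
                               region = c("body", "promoter"),
                               alpha = 0.01, top_frac = 0.05,
                               min_probes = 5,
                               sig_on = c("adjusted", "raw")) {
  region <- match.arg(region)
  sig_on <- match.arg(sig_on)
  mt <- condition_mean_track(tissue_tracks)
  mc <- condition_mean_track(culture_tracks)
  st <- .gene_probe_scores(mt, annotation, region)
  sc <- .gene_probe_scores(mc, annotation, region)
  genes <- annotation$genes
  n <- nrow(genes)
  np <- pmin(lengths(st), lengths(sc))
  tested <- np >= min_probes
  u <- p <- med_t <- med_c <- rep(NA_real_, n)
  for (i in which(tested)) {
    med_t[i] <- stats::median(st[[i]], na.rm = TRUE)
    med_c[i] <- stats::median(sc[[i]], na.rm = TRUE)
    ht <- mw_test(sc[[i]], st[[i]])   # U of culture vs tissue
    u[i] <- ht$u; p[i] <- ht$p
  }
  p_adj <- rep(NA_real_, n)
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  delta <- med_c - med_t
  sig <- if (sig_on == "adjusted") p_adj < alpha else p < alpha
  sig[!tested] <- NA
  k <- ceiling(top_frac * sum(tested))
  cut <- sort(abs(delta[tested]), decreasing = TRUE)[k]
  top <- tested & !is.na(delta) & abs(delta) >= cut
  res <- data.frame(gene_id = genes$gene_id, region = region,
                    n_probes = np, median_tissue = med_t,
                    median_culture = med_c, delta = delta, u = u, p = p,
                    p_adj = p_adj, significant = sig, top_change = top,
                    direction = ifelse(is.na(delta) | delta == 0,
                                       NA_character_,
                                       ifelse(delta > 0, "gain", "loss")),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, alpha = alpha, top_frac = top_frac, sig_on = sig_on,
            class = c("differential_table", "data.frame"))
}

#' Signed counts of significant promoter/genic changes per mark
#'
#' Summarizes one differential table per mark into counts of significant
#' gains and losses and the gain fraction — the promoter-shift view
#' (gain-skew of 5mC but not 5hmC in culture).
#'
#' @param ... named [differential_genic()] tables (e.g. `` `5mC` = ``,
#'   `` `5hmC` = ``).
#' @return Data frame `mark`, `n_gain`, `n_loss`, `gain_fraction`.
#' @export
promoter_shift_summary <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "data.frame")) tabs <- tabs[[1]]
  out <- lapply(names(tabs), function(mk) {
    d <- tabs[[mk]]
    sig <- !is.na(d$significant) & d$significant & !is.na(d$direction)
    ng <- sum(sig & d$direction == "gain")
    nl <- sum(sig & d$direction == "loss")
    data.frame(mark = mk, n_gain = ng, n_loss = nl,
               gain_fraction = if (ng + nl > 0) ng / (ng + nl) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Autocorrelation profile of a track
#'
#' Standard biased sample autocorrelation of the probe-ordered score
#' sequence, computed per chromosome and combined as a probe-count-weighted
#' mean (concatenating chromosomes would create artificial junction
#' correlations). Lags are in probe units.
#'
#' @param track an [enrichment_track()].
#' @param max_lag maximum lag in probes (default 50).
#' @return Data frame of class `acf_profile` (`lag`, `acf`); a
#'   zero-variance (constant) track yields NA values with a warning.
#' @export
track_acf <- function(track, max_lag = 50) {
  chunks <- split(track$score, factor(track$chrom, unique(track$chrom)))
  acfs <- lapply(chunks, function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= max_lag)
      stop("need more than max_lag probes per chromosome")
    if (stats::sd(x) == 0) return(rep(NA_real_, max_lag + 1))
    drop(stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf)
  })
  if (any(vapply(acfs, anyNA, TRUE)))
    warning("constant chromosome(s): autocorrelation undefined")
  wt <- lengths(chunks)
  vals <- colSums(do.call(rbind, acfs) * wt) / sum(wt)
  meta <- track_meta(track)
  structure(data.frame(lag = 0:max_lag, acf = vals, row.names = NULL),
            meta = meta, class = c("acf_profile", "data.frame"))
}

#' @export
plot.acf_profile <- function(x, ...) {
  graphics::plot(x$lag, x$acf, type = "h", xlab = "lag (probes)",
                 ylab = "autocorrelation", ylim = c(min(0, x$acf), 1), ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Ward clustering of samples
#'
#' Agglomerative clustering with Euclidean distance and Ward's minimum
#' variance criterion (`hclust` method `ward.D2`, whose merge heights are
#' the square roots of the Ward cost). Ties are resolved by `hclust`'s
#' deterministic order-dependent rule, so results are reproducible for a
#' fixed input order.
#'
#' @param x numeric matrix (samples in rows) or a named list of
#'   [enrichment_track()]s on one probe universe (scores become the
#'   feature columns).
#' @param k optional number of groups for flat labels.
#' @return List of class `sample_clustering`: `hclust`, and `labels` when
#'   `k` is given.
#' @export
cluster_samples <- function(x, k = NULL) {
  if (is.list(x) && !is.matrix(x) && inherits(x[[1]], "enrichment_track"))
    x <- do.call(rbind, lapply(x, `[[`, "score"))
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (anyNA(x))
    stop("missing values: impute or filter features before clustering")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(hclust = hc,
                 labels = if (!is.null(k)) stats::cutree(hc, k = k)),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("sample_clustering (Ward / Euclidean):\n")
  print(x$hclust$merge)
  if (!is.null(x$labels)) print(x$labels)
  invisible(x)
}

#' Cross-condition correlation of two tracks
#'
#' Rank (Spearman) or linear (Pearson) correlation of paired probe scores
#' from two tracks sharing a probe universe.
#'
#' @param a,b [enrichment_track()]s on identical positions.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate`, `p`, `method`, `n`.
#' @export
track_correlation <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(a$chrom, b$chrom) || !identical(a$pos, b$pos))
    stop("tracks must share a probe universe")
  ok <- !is.na(a$score) & !is.na(b$score)
  if (sum(ok) < 3) stop("need at least 3 paired probes")
  ht <- suppressWarnings(stats::cor.test(a$score[ok], b$score[ok],
                                         method = method, exact = FALSE))
  list(estimate = unname(ht$estimate), p = ht$p.value, method = method,
       n = sum(ok))
}

#' Bin read intervals into a reads-per-million coverage track
#'
#' Counts reads overlapping each non-overlapping genomic bin (a read
#' spanning a bin boundary is counted in every bin it overlaps) and
#' normalizes to reads per million: count * 1e6 / total reads.
#'
#' @param reads data frame of read intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from a BED3 file.
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @inheritParams enrichment_track
#' @return An [enrichment_track()] of RPM values with positions at bin
#'   starts.
#' @export
bin_coverage <- function(reads, layout, bin_size,
                         sample_id = NA_character_,
                         condition = NA_character_,
                         mark = NA_character_) {
  stopifnot(bin_size > 0)
  total <- nrow(reads)
  if (total == 0) stop("zero reads: coverage undefined")
  if (any(reads$end <= reads$start)) stop("read end must exceed start")
  out <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    nbin <- ceiling(layout$length[i] / bin_size)
    counts <- integer(nbin)
    r <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(r)) {
      b0 <- pmax(floor(r$start / bin_size), 0) + 1
      b1 <- pmin(floor((r$end - 1) / bin_size), nbin - 1) + 1
      for (off in 0:max(b1 - b0)) {
        sel <- b0 + off <= b1
        if (!any(sel)) break
        counts <- counts + tabulate(b0[sel] + off, nbins = nbin)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, pos = (0:(nbin - 1)) * bin_size,
                            score = counts * 1e6 / total,
                            stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  enrichment_track(d$chrom, d$pos, d$score, sample_id = sample_id,
                   condition = condition, mark = mark)
}

#' Read BED3 read intervals
#' @param path BED file (chrom, start, end; no header).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(d[[1]]), start = d[[2]], end = d[[3]],
             stringsAsFactors = FALSE)
}

#' Low-count exclusion for paired coverage summaries
#'
#' The sequencing-mode analog of the tested-gene rule: regions with fewer
#' than `min_count` reads in BOTH samples are excluded.
#'
#' @param counts_a,counts_b per-region read counts of the two samples.
#' @param min_count exclusion threshold (default 5).
#' @return Logical keep-vector.
#' @export
low_count_filter <- function(counts_a, counts_b, min_count = 5) {
  counts_a >= min_count | counts_b >= min_count
}
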