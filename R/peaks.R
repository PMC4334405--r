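#' Peak-caller configuration
#'
#' The window rule: any region of `window` consecutive probes in which at
#' least `min_above` probes have a score strictly greater than the
#' `percentile`-th percentile of that sample's scores (genome-wide) is
#' peak-positive; overlapping or adjacent positive windows are merged into
#' maximal peaks.
#'
#' @param window probe count per window (default 5).
#' @param min_above minimum above-threshold probes per window (default 4).
#' @param percentile threshold percentile in (0, 100), computed by linear
#'   interpolation between order statistics (default 90).
#' @param permutations genome-wide score permutations used by
#'   [estimate_fdr()] (default 20).
#' @param seed seed for the permutations.
#' @return List of class `peak_config`.
#' @export
peak_config <- function(window = 5, min_above = 4, percentile = 90,
                        permutations = 20, seed = 1) {
  stopifnot(min_above >= 1, min_above <= window,
            percentile > 0, percentile < 100, permutations >= 1)
  structure(list(window = window, min_above = min_above,
                 percentile = percentile, permutations = permutations,
                 seed = seed),
            class = "peak_config")
}

#' Call percentile-window peaks on a track
#'
#' Applies the window rule of [peak_config()] to a (typically
#' running-median smoothed) track. The threshold is the `percentile`-th
#' percentile of the track's scores over all probes genome-wide; the strict
#' inequality means a constant track yields no peaks. Window positivity is
#' evaluated at every start offset; positive windows sharing probes or
#' abutting are merged, and the peak interval spans from the first to one
#' past the last probe of the merged windows. Probes inside peaks are the
#' "peak probes". Chromosomes with fewer than `window` probes are skipped
#' with a warning.
#'
#' @param track an [enrichment_track()].
#' @param config a [peak_config()].
#' @param threshold optional fixed threshold value overriding the
#'   percentile (used by [estimate_fdr()] to retain the observed
#'   threshold under permutation).
#' @return Data frame of class `peak_set` (`chrom`, `start`, `end`,
#'   `n_probes`, `mean_score`), with the threshold, config and sample
#'   metadata as attributes. `sum(x$n_probes)` is the peak-probe count.
#' @export
call_peaks <- function(track, config = peak_config(), threshold = NULL) {
  if (is.null(threshold))
    threshold <- stats::quantile(track$score, config$percentile / 100,
                                 na.rm = TRUE, names = FALSE, type = 7)
  w <- config$window
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- track$chrom == ch
    pos <- track$pos[sel]
    sc <- track$score[sel]
    n <- length(sc)
    if (n < w) {
      warning("chromosome ", ch, " has fewer than ", w, " probes; skipped")
      next
    }
    above <- as.integer(!is.na(sc) & sc > threshold)
    cnt <- cumsum(above)
    win <- cnt[w:n] - c(0, cnt)[seq_len(n - w + 1)]  # above-count per window
    start_idx <- which(win >= config$min_above)
    if (length(start_idx) == 0) next
    # probes covered by any positive window
    delta <- integer(n + 1)
    delta[start_idx] <- delta[start_idx] + 1L
    delta[start_idx + w] <- delta[start_idx + w] - 1L
    covered <- cumsum(delta[seq_len(n)]) > 0
    r <- rle(covered)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    keep <- r$values
    out[[ch]] <- data.frame(
      chrom = ch,
      start = pos[starts_i[keep]],
      end = pos[ends_i[keep]] + 1,
      n_probes = ends_i[keep] - starts_i[keep] + 1L,
      mean_score = vapply(which(keep), function(j)
        mean(sc[starts_i[j]:ends_i[j]], na.rm = TRUE), 0),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_probes = integer(), mean_score = numeric())
  rownames(res) <- NULL
  structure(res, threshold = threshold, config = config,
            meta = track_meta(track), class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks, %d peak probes (threshold %.4f)\n",
              nrow(x), sum(x$n_probes), attr(x, "threshold")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Total peak probes in a peak set
#' @param peaks a [call_peaks()] result.
#' @return Integer count.
#' @export
n_peak_probes <- function(peaks) sum(peaks$n_probes)

#' Closed-form null rate of the window rule
#'
#' Probability that a fixed window of `window` independent scores has at
#' least `min_above` of them above the threshold, when each score exceeds
#' it independently with probability 1 - percentile/100:
#' sum over j >= min_above of C(w, j) q^j (1-q)^(w-j). A companion
#' cross-check for the permutation FDR: the expected fraction of probes
#' falsely inside peaks is bounded by `window` times this rate.
#'
#' @param config a [peak_config()].
#' @return Probability in \[0, 1\].
#' @export
null_window_rate <- function(config = peak_config()) {
  q <- 1 - config$percentile / 100
  j <- config$min_above:config$window
  sum(choose(config$window, j) * q^j * (1 - q)^(config$window - j))
}

#' Permutation-based empirical FDR of the peak caller
#'
#' Calls peaks on the observed track, then for each of
#' `config$permutations` rounds shuffles the probe-score assignment
#' genome-wide (positions fixed, scores permuted), re-calls peaks with the
#' SAME threshold value (the permuted track has the same score
#' distribution, but its spatial clustering — what the window rule detects
#' — is destroyed), and counts null peak probes. The estimate is
#' mean(null peak probes) / observed peak probes.
#'
#' @param track an [enrichment_track()] (smoothed, by pipeline
#'   convention).
#' @param config a [peak_config()]; `config$seed` makes the permutations
#'   reproducible.
#' @return List of class `fdr_estimate`: `fdr`, `observed`, `null_counts`
#'   (per permutation), `threshold`, `peaks`, `config`. When no peaks are
#'   observed the estimate is undefined (`fdr = Inf`, `defined = FALSE`).
#' @export
estimate_fdr <- function(track, config = peak_config()) {
  peaks <- call_peaks(track, config)
  observed <- n_peak_probes(peaks)
  thr <- attr(peaks, "threshold")
  set.seed(config$seed)
  null_counts <- vapply(seq_len(config$permutations), function(b) {
    perm <- with_scores(track, sample(track$score))
    suppressWarnings(n_peak_probes(call_peaks(perm, config,
                                              threshold = thr)))
  }, 0)
  defined <- observed > 0
  if (!defined)
    warning("no observed peaks: FDR undefined")
  structure(list(fdr = if (defined) mean(null_counts) / observed else Inf,
                 observed = observed, null_counts = null_counts,
                 threshold = thr, peaks = peaks, config = config,
                 defined = defined),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(paste0("fdr_estimate: %d observed peak probes, mean null ",
                     "%.1f over %d permutations\n  FDR = %s\n"),
              x$observed, mean(x$null_counts), length(x$null_counts),
              if (x$defined) sprintf("%.4g", x$fdr) else "undefined"))
  invisible(x)
}

#' Peak probes per genomic compartment
#'
#' Counts the track's probes that fall inside peaks, split by compartment
#' (promoter/exon/intron/intergenic precedence of
#' [assign_compartment()]).
#'
#' @param peaks a [call_peaks()] result.
#' @param track the [enrichment_track()] the peaks were called on.
#' @param annotation a [gene_annotation()].
#' @return Named integer vector over the four compartments.
#' @export
peak_probe_summary <- function(peaks, track, annotation) {
  inside <- rep(FALSE, nrow(track))
  for (ch in unique(peaks$chrom)) {
    sel <- which(track$chrom == ch)
    p <- peaks[peaks$chrom == ch, ]
    i <- findInterval(track$pos[sel], p$start)
    inside[sel] <- i > 0 & track$pos[sel] < p$end[pmax(i, 1)]
  }
  comp <- assign_compartment(track$chrom[inside], track$pos[inside],
                             annotation)
  table(comp)
}

#' Chi-square test for a compartment shift between two peak sets
#'
#' Compares two conditions' peak-probe compartment counts with a 2 x c
#' chi-square test (no continuity correction). Cells with expected count
#' below 5 attach a warning.
#'
#' @param counts_a,counts_b compartment counts ([peak_probe_summary()]
#'   results or named vectors on the same categories).
#' @return `htest` from [stats::chisq.test()].
#' @export
compartment_shift_test <- function(counts_a, counts_b) {
  tab <- rbind(as.numeric(counts_a), as.numeric(counts_b))
  keep <- colSums(tab) > 0
  ht <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE],
                                           correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected cell count below 5; chi-square approximation weak")
  ht
}
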