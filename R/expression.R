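#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to the same score distribution: each
#' column's sorted values are replaced by the across-column mean of sorted
#' values, with ties receiving the mean of their would-be positions
#' (`limma::normalizeQuantiles`).
#'
#' @param m numeric genes x samples matrix of log2 intensities (at least
#'   two columns, no missing values).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (anyNA(m)) stop("missing values not supported")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Expressed/not-expressed calls from detection p-values
#'
#' Combines each gene's per-sample detection p-values within a condition by
#' Fisher's method (-2 sum log p ~ chi-square with 2k df) and calls the
#' gene expressed in that condition when the combined p-value is below
#' `alpha`. P-values are clamped away from 0 to avoid infinities; p = 1 is
#' allowed.
#'
#' @param detection genes x samples matrix of detection p-values.
#' @param condition character vector assigning each column to a condition.
#' @param alpha combined-p threshold (default 0.01).
#' @return Logical genes x conditions matrix, with the combined p-values
#'   in `attr(, "combined_p")`.
#' @export
expressed_call <- function(detection, condition, alpha = 0.01) {
  stopifnot(ncol(detection) == length(condition))
  conds <- unique(condition)
  p <- sapply(conds, function(cc) {
    d <- detection[, condition == cc, drop = FALSE]
    d <- pmin(pmax(d, 1e-300), 1)
    stat <- -2 * rowSums(log(d))
    stats::pchisq(stat, df = 2 * ncol(d), lower.tail = FALSE)
  })
  p <- matrix(p, ncol = length(conds),
              dimnames = list(rownames(detection), conds))
  structure(p < alpha, combined_p = p)
}

#' Paired differential expression (per-gene paired t-test)
#'
#' Two-sided paired t-tests on per-pair log2 differences
#' (culture - tissue), Benjamini-Hochberg adjusted. The fold change is the
#' ratio of linear-scale condition means. `de` flags adjusted p < `alpha`;
#' `strict` additionally requires an absolute linear fold change above
#' `fc_threshold`. Genes whose paired differences have zero variance get an
#' undefined test and are flagged.
#'
#' @param m quantile-normalized genes x samples log2 matrix with column
#'   names matching `pairs`.
#' @param pairs data frame with columns `tissue` and `culture` naming the
#'   paired sample columns (a bijection between conditions).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param fc_threshold linear fold-change threshold for `strict`
#'   (default 1.5).
#' @return Data frame of class `de_table`: `gene_id`, `t`, `df`, `p`,
#'   `p_adj`, `log2fc`, `de`, `strict`, `zero_variance`.
#' @export
paired_de <- function(m, pairs, alpha = 0.01, fc_threshold = 1.5) {
  stopifnot(all(pairs$tissue %in% colnames(m)),
            all(pairs$culture %in% colnames(m)),
            !anyDuplicated(pairs$tissue), !anyDuplicated(pairs$culture))
  k <- nrow(pairs)
  if (k < 2) stop("need at least 2 pairs")
  d <- m[, pairs$culture, drop = FALSE] - m[, pairs$tissue, drop = FALSE]
  mu <- rowMeans(d)
  s <- sqrt(rowSums((d - mu)^2) / (k - 1))
  zv <- s == 0
  tstat <- ifelse(zv, NA_real_, mu / (s / sqrt(k)))
  p <- 2 * stats::pt(-abs(tstat), df = k - 1)
  p_adj <- rep(NA_real_, length(p))
  p_adj[!zv] <- stats::p.adjust(p[!zv], method = "BH")
  fc <- rowMeans(2^m[, pairs$culture, drop = FALSE]) /
    rowMeans(2^m[, pairs$tissue, drop = FALSE])
  de <- !is.na(p_adj) & p_adj < alpha
  strict <- de & pmax(fc, 1 / fc) > fc_threshold
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("gene%d", seq_len(nrow(m)))
  structure(data.frame(gene_id = ids, t = tstat, df = k - 1,
                       p = p, p_adj = p_adj, log2fc = log2(fc), de = de,
                       strict = strict, zero_variance = zv,
                       stringsAsFactors = FALSE, row.names = NULL),
            alpha = alpha, fc_threshold = fc_threshold,
            class = c("de_table", "data.frame"))
}

#' Principal-component summary of samples
#'
#' Covariance PCA of gene-centred sample profiles (samples as
#' observations), with variance-explained fractions and a Ward clustering
#' of the leading component scores.
#'
#' @param m genes x samples matrix.
#' @param n_cluster_pc components used for the clustering (default 2).
#' @return List of class `pca_summary`: `scores` (samples x PCs),
#'   `var_frac`, `clustering` ([cluster_samples()] result).
#' @export
pca_summary <- function(m, n_cluster_pc = 2) {
  if (ncol(m) < 3) stop("need at least 3 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  npc <- min(n_cluster_pc, ncol(pc$x))
  cl <- cluster_samples(pc$x[, seq_len(npc), drop = FALSE])
  structure(list(scores = pc$x, var_frac = var_frac, clustering = cl),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  vf <- x$var_frac[seq_len(min(4, length(x$var_frac)))]
  cat("pca_summary: variance explained",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf),
            collapse = ", "), "\n")
  invisible(x)
}

#' Association between genic 5hmC and expression state
#'
#' Two-sided Mann-Whitney test comparing genic 5hmC of expressed versus
#' non-expressed genes (per condition).
#'
#' @param genic_hmc named numeric vector of per-gene 5hmC enrichment.
#' @param expressed named logical vector on the same genes.
#' @return List: `p`, `median_diff` (expressed - silent), `n_expressed`,
#'   `n_silent`.
#' @export
hmc_expression_association <- function(genic_hmc, expressed) {
  if (!is.null(names(genic_hmc)) && !is.null(names(expressed)))
    expressed <- expressed[names(genic_hmc)]
  ok <- !is.na(genic_hmc) & !is.na(expressed)
  x <- genic_hmc[ok & expressed]
  y <- genic_hmc[ok & !expressed]
  if (length(x) == 0 || length(y) == 0)
    stop("both expressed and silent groups must be non-empty")
  ht <- mw_test(x, y)
  list(p = ht$p, median_diff = stats::median(x) - stats::median(y),
       n_expressed = length(x), n_silent = length(y))
}

#' Variance in 5hmC change explained by expression change
#'
#' Squared Pearson correlation of per-gene deltas (change in genic 5hmC
#' versus change in expression), with the two-sided correlation test.
#'
#' @param delta_hmc,delta_expr paired per-gene deltas.
#' @return List: `r2`, `r`, `p`, `n`; constant input yields NA with a
#'   warning.
#' @export
variance_explained <- function(delta_hmc, delta_expr) {
  ok <- !is.na(delta_hmc) & !is.na(delta_expr)
  x <- delta_hmc[ok]; y <- delta_expr[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant delta vector: r^2 undefined")
    return(list(r2 = NA_real_, r = NA_real_, p = NA_real_, n = length(x)))
  }
  ht <- stats::cor.test(x, y)
  list(r2 = unname(ht$estimate)^2, r = unname(ht$estimate),
       p = ht$p.value, n = length(x))
}

#' Volcano plot of a differential-expression table
#'
#' Scatter of log2 fold change against -log10 raw p with the conventional
#' thresholds drawn (p = alpha, fold change = fc_threshold).
#'
#' @param de a [paired_de()] table.
#' @param ... passed to [graphics::plot()].
#' @return The table, invisibly.
#' @export
volcano_plot <- function(de, ...) {
  ok <- !de$zero_variance
  graphics::plot(de$log2fc[ok], -log10(de$p[ok]),
                 xlab = "log2 fold change", ylab = "-log10 p",
                 pch = 16, cex = 0.4,
                 col = ifelse(de$strict[ok], "red3", "grey40"), ...)
  graphics::abline(h = -log10(attr(de, "alpha")), lty = 2)
  graphics::abline(v = c(-1, 1) * log2(attr(de, "fc_threshold")), lty = 2)
  invisible(de)
}
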