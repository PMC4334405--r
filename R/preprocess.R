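#' M and A values of a two-channel array
#'
#' @param ip,input positive per-probe intensities of the enriched (IP) and
#'   input channels.
#' @return Data frame with `m` = log2(ip/input) and `a` = mean log2
#'   intensity.
#' @export
ma_values <- function(ip, input) {
  if (any(ip <= 0) || any(input <= 0)) stop("intensities must be positive")
  data.frame(m = log2(ip / input), a = 0.5 * log2(ip * input))
}

#' Locally weighted scatterplot smoothing (tricube local linear fit)
#'
#' At each point the fit is a weighted least-squares line over the
#' `ceiling(span * n)` nearest neighbours in `x`, with tricube weights in
#' the x-distance to the furthest neighbour, iterated with bisquare
#' robustness weights. The fit is evaluated exactly at every point (no
#' interpolation), so cost grows as n * span * n; intended for per-array
#' normalization at up to a few tens of thousands of probes.
#'
#' @param x,y predictor (A values) and response (M values).
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @param iterations robustness iterations (0 = plain tricube fit).
#' @return Numeric vector of fitted values, in input order.
#' @export
lowess_fit <- function(x, y, span = 0.3, iterations = 3) {
  n <- length(x)
  stopifnot(length(y) == n, span > 0, span <= 1)
  k <- ceiling(span * n)
  if (k < 5) stop("span too small: local neighbourhoods need >= 5 points")
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in 0:iterations) {
    lo <- 1L
    for (i in seq_len(n)) {
      # slide [lo, lo+k-1] to the k nearest neighbours of xs[i]
      while (lo + k - 1 < n &&
             xs[lo + k] - xs[i] < xs[i] - xs[lo]) lo <- lo + 1L
      idx <- lo:(lo + k - 1)
      d <- abs(xs[idx] - xs[i])
      h <- max(d)
      w <- if (h > 0) (1 - pmin(d / h, 1)^3)^3 else rep(1, k)
      w <- w * rw[idx]
      sw <- sum(w)
      if (sw <= 0) { fit[i] <- ys[i]; next }
      xm <- sum(w * xs[idx]) / sw
      ym <- sum(w * ys[idx]) / sw
      sxx <- sum(w * (xs[idx] - xm)^2)
      fit[i] <- if (sxx > 1e-12 * max(1, xm^2))
        ym + sum(w * (xs[idx] - xm) * (ys[idx] - ym)) / sxx * (xs[i] - xm)
      else ym
    }
    if (it == iterations) break
    res <- ys - fit
    s <- stats::median(abs(res))
    if (s <= 0) break
    u <- res / (6 * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  out <- numeric(n)
  out[o] <- fit
  out
}

#' LOWESS-normalize a two-channel array
#'
#' Removes the intensity-dependent dye trend: fits M on A by [lowess_fit()]
#' and returns the residual M values as an enrichment track. Normalization
#' is per array.
#'
#' @param raw data frame with columns `chrom`, `pos`, `ip`, `input` (raw
#'   two-channel mode), or `chrom`, `pos`, `m`, `a` (precomputed M/A).
#' @param span,iterations passed to [lowess_fit()].
#' @inheritParams enrichment_track
#' @return An [enrichment_track()] of residual M values, in input probe
#'   order.
#' @export
lowess_normalize <- function(raw, span = 0.3, iterations = 3,
                             sample_id = NA_character_,
                             condition = NA_character_,
                             mark = NA_character_,
                             replicate = NA_character_) {
  if (all(c("ip", "input") %in% names(raw))) {
    ma <- ma_values(raw$ip, raw$input)
  } else if (all(c("m", "a") %in% names(raw))) {
    ma <- raw[c("m", "a")]
  } else stop("need columns ip/input or m/a")
  if (nrow(raw) < 20) stop("need at least 20 probes to normalize")
  trend <- lowess_fit(ma$a, ma$m, span = span, iterations = iterations)
  enrichment_track(raw$chrom, raw$pos, ma$m - trend,
                   sample_id = sample_id, condition = condition,
                   mark = mark, replicate = replicate)
}

#' Running-median smoothing of a track
#'
#' Replaces each probe's score by the median of the window of `window`
#' probes centred on it, within its chromosome. Edges use the available
#' (shrinking) symmetric window, so no probe is dropped. At the package's
#' default 250 bp probe spacing the 7-probe window spans 1,750 bp.
#'
#' @param track an [enrichment_track()].
#' @param window odd probe count (default 7).
#' @return Smoothed [enrichment_track()].
#' @export
running_median <- function(track, window = 7) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  sm <- unlist(lapply(split(track$score,
                            factor(track$chrom, unique(track$chrom))),
                      .runmed_shrink, k = window), use.names = FALSE)
  with_scores(track, sm)
}

# running median, shrinking symmetric windows at chromosome edges
.runmed_shrink <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  if (n <= k || k == 1) {
    return(vapply(seq_len(n), function(i)
      stats::median(x[max(1, i - h):min(n, i + h)]), 0))
  }
  s <- stats::runmed(x, k, endrule = "keep")
  edge <- c(seq_len(h), (n - h + 1):n)
  s[edge] <- vapply(edge, function(i)
    stats::median(x[max(1, i - h):min(n, i + h)]), 0)
  s
}
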