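#' In-silico bisulfite conversion of a reference sequence
#'
#' Every cytosine not followed by G becomes T; CpG cytosines are retained
#' as ambiguous (IUPAC Y = C or T). Positions are 0-based on the
#' reference.
#'
#' @param reference A/C/G/T nucleotide string (ambiguity codes are an
#'   error).
#' @return List of class `bis_frame`: `converted` (string), `cpg_pos`
#'   (0-based positions of CpG cytosines), `noncpg_c_pos` (0-based
#'   positions of non-CpG cytosines), `length`.
#' @export
in_silico_convert <- function(reference) {
  b <- strsplit(toupper(reference), "")[[1]]
  if (length(b) && any(!(b %in% c("A", "C", "G", "T"))))
    stop("reference must contain only A/C/G/T (no ambiguity codes)")
  is_c <- b == "C"
  next_g <- c(b[-1] == "G", FALSE)
  cpg <- which(is_c & next_g)
  noncpg <- which(is_c & !next_g)
  conv <- b
  conv[noncpg] <- "T"
  conv[cpg] <- "Y"
  structure(list(converted = paste(conv, collapse = ""),
                 cpg_pos = cpg - 1L, noncpg_c_pos = noncpg - 1L,
                 length = length(b)),
            class = "bis_frame")
}

#' Call per-CpG methylation states for one clone
#'
#' Positional comparison against the in-silico converted reference (no
#' indels: a clone of a different length is rejected). At each CpG
#' position C means methylated, T unmethylated, anything else missing. The
#' conversion rate is the fraction of the reference's non-CpG cytosines
#' read as T in the clone.
#'
#' @param clone nucleotide string.
#' @param frame an [in_silico_convert()] result.
#' @return List: `ok`, `reason` (when rejected), `states` (factor meth /
#'   unmeth / NA per CpG), `conversion_rate`.
#' @export
call_clone <- function(clone, frame) {
  b <- strsplit(toupper(clone), "")[[1]]
  if (length(b) != frame$length)
    return(list(ok = FALSE,
                reason = sprintf("length mismatch (%d vs reference %d)",
                                 length(b), frame$length)))
  at_cpg <- b[frame$cpg_pos + 1]
  states <- ifelse(at_cpg == "C", "meth",
                   ifelse(at_cpg == "T", "unmeth", NA_character_))
  at_non <- b[frame$noncpg_c_pos + 1]
  n_non <- length(frame$noncpg_c_pos)
  conv <- if (n_non > 0) sum(at_non == "T") / n_non else NA_real_
  list(ok = TRUE, states = factor(states, levels = c("meth", "unmeth")),
       conversion_rate = conv)
}

#' Build a clone set from sequences
#'
#' Applies [call_clone()] to every clone; length-mismatched clones are
#' dropped with a warning (their ids and reasons are kept in
#' `attr(, "rejected")`).
#'
#' @param clones named character vector of clone sequences.
#' @param frame an [in_silico_convert()] result.
#' @return List of class `clone_set`: `states` (clones x CpG matrix,
#'   TRUE = methylated), `conversion_rate`, `sequences`, `frame`.
#' @export
clone_set <- function(clones, frame) {
  if (is.null(names(clones)))
    names(clones) <- sprintf("clone%02d", seq_along(clones))
  calls <- lapply(clones, call_clone, frame = frame)
  ok <- vapply(calls, `[[`, TRUE, "ok")
  rejected <- data.frame(
    clone = names(clones)[!ok],
    reason = vapply(calls[!ok], `[[`, "", "reason"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!ok))
    warning(sum(!ok), " clone(s) rejected: ",
            paste(rejected$clone, collapse = ", "))
  st <- do.call(rbind, lapply(calls[ok], function(cl)
    cl$states == "meth"))
  if (is.null(st)) st <- matrix(NA, 0, length(frame$cpg_pos))
  rownames(st) <- names(clones)[ok]
  structure(list(states = st,
                 conversion_rate = vapply(calls[ok], `[[`, 0,
                                          "conversion_rate"),
                 sequences = clones[ok], frame = frame),
            rejected = rejected, class = "clone_set")
}

#' Filter clones and summarize CpG methylation
#'
#' Applies the clone QC filters — exact-duplicate removal (identical
#' sequences, or identical CpG patterns with `dedup_on = "pattern"`,
#' keeping the first of each group; the retained set is independent of
#' input order up to which representative is kept) and exclusion of clones
#' with a conversion rate strictly below `min_conversion` (a clone at
#' exactly the threshold is retained) — then reports per-CpG and overall
#' percent methylation over the retained clones. Missing calls at a CpG
#' are excluded from both numerator and denominator.
#'
#' @param clones a [clone_set()] (or a `clone_sim` from
#'   [simulate_clones()], in which case the frame is derived from its
#'   reference).
#' @param min_conversion conversion-rate threshold (default 0.95).
#' @param dedup_on `"sequence"` (default) or `"pattern"`.
#' @return List of class `clone_summary`: `retained` (ids), `n_removed_dup`,
#'   `n_removed_conversion`, `per_cpg` (percent methylation per CpG),
#'   `overall` (pooled percent), `defined`.
#' @export
filter_and_summarize <- function(clones, min_conversion = 0.95,
                                 dedup_on = c("sequence", "pattern")) {
  dedup_on <- match.arg(dedup_on)
  if (inherits(clones, "clone_sim"))
    clones <- clone_set(clones$clones, in_silico_convert(clones$reference))
  stopifnot(inherits(clones, "clone_set"))
  if (nrow(clones$states) == 0) stop("need at least 1 called clone")
  key <- if (dedup_on == "sequence") unname(clones$sequences) else
    apply(clones$states, 1, function(s)
      paste(ifelse(is.na(s), "x", ifelse(s, "M", "u")), collapse = ""))
  keep_dup <- !duplicated(key)
  keep_conv <- is.na(clones$conversion_rate) |
    clones$conversion_rate >= min_conversion
  keep <- keep_dup & keep_conv
  st <- clones$states[keep, , drop = FALSE]
  n_meth <- colSums(st, na.rm = TRUE)
  n_call <- colSums(!is.na(st))
  per_cpg <- ifelse(n_call > 0, 100 * n_meth / n_call, NA_real_)
  defined <- sum(keep) > 0 && sum(n_call) > 0
  if (!defined) warning("no clones retained: summary undefined")
  structure(list(retained = rownames(st),
                 n_removed_dup = sum(!keep_dup),
                 n_removed_conversion = sum(keep_dup & !keep_conv),
                 per_cpg = per_cpg, n_called = n_call,
                 overall = if (defined) 100 * sum(n_meth) / sum(n_call)
                           else NA_real_,
                 defined = defined, states = st),
            class = "clone_summary")
}

#' @export
print.clone_summary <- function(x, ...) {
  cat(sprintf(paste0("clone_summary: %d retained (%d duplicate, %d ",
                     "low-conversion removed)\n"),
              length(x$retained), x$n_removed_dup,
              x$n_removed_conversion))
  if (x$defined)
    cat(sprintf("  overall CpG methylation: %.1f%%\n", x$overall))
  else cat("  summary undefined (no retained clones)\n")
  invisible(x)
}

#' Text lollipop rendering of a clone x CpG matrix
#'
#' One row per retained clone; filled circles are methylated CpGs, open
#' circles unmethylated, dots missing calls.
#'
#' @param summary a [filter_and_summarize()] result.
#' @return Character vector of rendered lines (also printed).
#' @export
lollipop_text <- function(summary) {
  st <- summary$states
  lines <- vapply(seq_len(nrow(st)), function(i) {
    glyph <- ifelse(is.na(st[i, ]), ".", ifelse(st[i, ], "●", "○"))
    paste0(format(rownames(st)[i], width = 10), " ",
           paste(glyph, collapse = ""))
  }, "")
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Read clone sequences from FASTA
#'
#' One record per clone; the reference region is a separate single-record
#' FASTA.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_clone_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
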