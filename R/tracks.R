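#' Construct an enrichment track
#'
#' An enrichment track is the universal signal carrier of the package: an
#' ordered set of genomic positions (probe centers for tiling arrays, bin
#' starts for binned sequencing coverage) with one real-valued score per
#' position (a log2 IP/input ratio, or reads per million). Coordinates are
#' 0-based throughout.
#'
#' @param chrom character vector of chromosome names, one per position.
#' @param pos integer-valued base-pair coordinates; must be strictly
#'   increasing within each chromosome (rows are re-sorted if not).
#' @param score numeric enrichment score, one per position. Non-finite
#'   values are allowed but flagged as missing (`NA`).
#' @param sample_id,condition,mark,replicate sample metadata carried as
#'   attributes. `condition` is typically `"tissue"` or `"culture"`,
#'   `mark` `"5mC"` or `"5hmC"`.
#' @return A data frame of class `enrichment_track` with columns `chrom`,
#'   `pos`, `score` and metadata attributes.
#' @export
enrichment_track <- function(chrom, pos, score,
                             sample_id = NA_character_,
                             condition = NA_character_,
                             mark = NA_character_,
                             replicate = NA_character_) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(score))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  score <- as.numeric(score)
  score[!is.finite(score)] <- NA_real_
  df <- data.frame(chrom = chrom, pos = pos, score = score,
                   stringsAsFactors = FALSE)
  o <- order(factor(df$chrom, levels = unique(df$chrom)), df$pos)
  if (is.unsorted(o)) df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicated positions within a chromosome")
  structure(df,
            sample_id = sample_id, condition = condition,
            mark = mark, replicate = replicate,
            class = c("enrichment_track", "data.frame"))
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("enrichment_track: %d positions on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  meta <- track_meta(x)
  cat(sprintf("  sample: %s  condition: %s  mark: %s  replicate: %s\n",
              meta$sample_id, meta$condition, meta$mark, meta$replicate))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Sample metadata of a track
#' @param track an [enrichment_track()].
#' @return Named list with `sample_id`, `condition`, `mark`, `replicate`.
#' @export
track_meta <- function(track) {
  list(sample_id = attr(track, "sample_id"),
       condition = attr(track, "condition"),
       mark = attr(track, "mark"),
       replicate = attr(track, "replicate"))
}

# Rebuild a track with new scores, keeping coordinates and metadata.
with_scores <- function(track, score) {
  meta <- track_meta(track)
  enrichment_track(track$chrom, track$pos, score,
                   sample_id = meta$sample_id, condition = meta$condition,
                   mark = meta$mark, replicate = meta$replicate)
}

#' Read an enrichment track from a bedGraph or TSV file
#'
#' Accepts 4-column bedGraph (`chrom start end score`, no header) or a
#' headered TSV with columns `chrom`, `start` (or `pos`), optional `end`,
#' and `score`. The position kept is the interval start. Rows are sorted
#' by chromosome and position (with a warning when the input was unsorted);
#' rows with a non-numeric score abort with the offending line number.
#'
#' @param path file to read.
#' @inheritParams enrichment_track
#' @return An [enrichment_track()].
#' @export
read_track <- function(path, sample_id = NA_character_,
                       condition = NA_character_, mark = NA_character_,
                       replicate = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty track file: ", path)
    return(enrichment_track(character(), numeric(), numeric(),
                            sample_id, condition, mark, replicate))
  }
  first <- strsplit(lines[[1]], "\t|,| +")[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[2])))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(body, "\t|,| +")
  ncol <- lengths(fields)
  if (any(ncol < 3)) stop("malformed row at line ",
                          which(ncol < 3)[1] + offset, " of ", path)
  if (has_header) {
    cn <- tolower(first)
    ci_chrom <- match(TRUE, cn %in% c("chrom", "chr", "chromosome"))
    ci_pos <- match(TRUE, cn %in% c("start", "pos", "position"))
    ci_score <- match(TRUE, cn %in% c("score", "value"))
    if (is.na(ci_chrom) || is.na(ci_pos) || is.na(ci_score))
      stop("header must name chrom, start/pos and score columns")
  } else {
    ci_chrom <- 1L; ci_pos <- 2L
    ci_score <- ifelse(ncol >= 4, 4L, 3L)  # bedGraph vs chrom,pos,score
  }
  chrom <- vapply(fields, `[[`, "", ci_chrom)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", ci_pos)))
  sci <- if (length(ci_score) == 1L) rep(ci_score, length(fields)) else ci_score
  score_chr <- mapply(function(f, i) f[[i]], fields, sci)
  score <- suppressWarnings(as.numeric(score_chr))
  bad <- which(is.na(score) & !(toupper(score_chr) %in% c("NA", "NAN", ".")))
  if (length(bad))
    stop("non-numeric score at line ", bad[1] + offset, " of ", path,
         ": '", score_chr[bad[1]], "'")
  bad_pos <- which(is.na(pos))
  if (length(bad_pos))
    stop("non-numeric position at line ", bad_pos[1] + offset, " of ", path)
  o <- order(factor(chrom, levels = unique(chrom)), pos)
  if (is.unsorted(o)) {
    warning("unsorted input track ", path, "; sorting")
    chrom <- chrom[o]; pos <- pos[o]; score <- score[o]
  }
  enrichment_track(chrom, pos, score, sample_id, condition, mark, replicate)
}

#' Write an enrichment track
#'
#' @param track an [enrichment_track()].
#' @param path output file.
#' @param format `"bedgraph"` (chrom, start, start+span, score; no header)
#'   or `"tsv"` (headered chrom/start/score).
#' @param span interval width used for the bedGraph `end` column.
#' @param digits decimal places written for scores.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "tsv"),
                        span = 1, digits = 6) {
  format <- match.arg(format)
  sc <- formatC(track$score, digits = digits, format = "f")
  sc[is.na(track$score)] <- "NA"
  if (format == "bedgraph") {
    out <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$pos),
                   as.integer(track$pos + span), sc)
  } else {
    out <- c("chrom\tstart\tscore",
             sprintf("%s\t%d\t%s", track$chrom, as.integer(track$pos), sc))
  }
  writeLines(out, path)
  invisible(path)
}
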