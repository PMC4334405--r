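#' Genome layout
#'
#' Ordered chromosome names and lengths. All coordinates in the package are
#' 0-based, half-open (BED convention).
#'
#' @param chrom unique chromosome names.
#' @param length chromosome lengths in base pairs (> 0).
#' @return Data frame of class `genome_layout`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = as.numeric(length),
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Gene annotation table
#'
#' Builds the strand-aware gene model used for compartment assignment and
#' per-gene enrichment. The promoter is anchored at the strand-aware TSS
#' and spans `promoter_up` bp upstream and `promoter_down` bp downstream
#' (half-open). Exons are supplied as a separate interval table.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open transcript interval)
#'   and optional logical flags (`imprinted_like`, `cluster_member`, ...).
#' @param exons data frame with columns `gene_id`, `start`, `end`; intervals
#'   must fall inside the owning transcript.
#' @param promoter_up,promoter_down promoter extent upstream/downstream of
#'   the TSS, in bp.
#' @return List of class `gene_annotation` with elements `genes` (including
#'   derived `promoter_start`/`promoter_end`) and `exons`.
#' @export
gene_annotation <- function(genes, exons = NULL,
                            promoter_up = 2000, promoter_down = 500) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$promoter_start <- ifelse(genes$strand == "+",
                                 tss - promoter_up, tss - promoter_down)
  genes$promoter_end <- ifelse(genes$strand == "+",
                               tss + promoter_down, tss + promoter_up)
  genes$promoter_start <- pmax(genes$promoter_start, 0)
  if (is.null(exons))
    exons <- data.frame(gene_id = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
  i <- match(exons$gene_id, genes$gene_id)
  if (anyNA(i)) stop("exon gene_id not in gene table")
  if (any(exons$start < genes$start[i] | exons$end > genes$end[i]))
    stop("exons must lie within their transcript interval")
  structure(list(genes = genes, exons = exons,
                 promoter_up = promoter_up, promoter_down = promoter_down),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons, promoter [TSS-%d, TSS+%d)\n",
              nrow(x$genes), nrow(x$exons), x$promoter_up, x$promoter_down))
  invisible(x)
}

# 0-based half-open [start, end) interval table -> IRanges (1-based closed).
.iranges <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

#' Assign genomic compartments to positions
#'
#' Each position receives exactly one label with precedence
#' promoter > exon > intron > intergenic (an "intron" is any position inside
#' a transcript but in no exon and no promoter). Positions on chromosomes
#' absent from the annotation are intergenic, with a warning.
#'
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @param annotation a [gene_annotation()].
#' @return Factor with levels promoter, exon, intron, intergenic.
#' @export
assign_compartment <- function(chrom, pos, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"),
            length(chrom) == length(pos))
  genes <- annotation$genes
  exons <- annotation$exons
  exon_chrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  lab <- rep("intergenic", length(pos))
  known <- unique(genes$chrom)
  if (any(!(chrom %in% known)) && length(pos) > 0)
    warning("positions on chromosomes absent from annotation: intergenic")
  for (ch in intersect(unique(chrom), known)) {
    sel <- which(chrom == ch)
    q <- .iranges(pos[sel], pos[sel] + 1)
    g <- genes[genes$chrom == ch, ]
    in_prom <- IRanges::overlapsAny(q, .iranges(g$promoter_start,
                                                g$promoter_end))
    in_body <- IRanges::overlapsAny(q, .iranges(g$start, g$end))
    e <- exons[exon_chrom == ch, ]
    in_exon <- if (nrow(e)) IRanges::overlapsAny(q, .iranges(e$start, e$end))
               else rep(FALSE, length(sel))
    lab[sel][in_body] <- "intron"
    lab[sel][in_exon] <- "exon"
    lab[sel][in_prom] <- "promoter"
  }
  factor(lab, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Merge overlapping or adjacent intervals
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return Data frame of sorted, disjoint merged intervals.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[c("chrom", "start", "end")])
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    r <- IRanges::reduce(.iranges(d$start, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of intervals in A overlapping B
#'
#' The fraction of (merged) intervals in `a` that share at least one base
#' with some interval of `b`. Intervals are half-open, so `[0,100)` and
#' `[100,200)` do not overlap. An empty `a` yields 0 with a warning.
#'
#' @param a,b interval tables (`chrom`, `start`, `end`) or [call_peaks()]
#'   results.
#' @return A number in \[0, 1\].
#' @export
interval_overlap_fraction <- function(a, b) {
  a <- merge_intervals(as.data.frame(a)[c("chrom", "start", "end")])
  b <- merge_intervals(as.data.frame(b)[c("chrom", "start", "end")])
  if (nrow(a) == 0) {
    warning("empty interval set A: overlap fraction defined as 0")
    return(0)
  }
  hit <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- a$chrom == ch
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) next
    hit[ia] <- IRanges::overlapsAny(.iranges(a$start[ia], a$end[ia]),
                                    .iranges(bb$start, bb$end))
  }
  mean(hit)
}

#' Read gene annotation from a BED6-like TSV
#'
#' Expects tab-separated columns `chrom start end gene_id score strand`
#' (BED6, no header). Exon structure is not carried by BED6; the result has
#' an empty exon table.
#'
#' @param path file to read.
#' @inheritParams gene_annotation
#' @return A [gene_annotation()].
#' @export
read_gene_bed <- function(path, promoter_up = 2000, promoter_down = 500) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 6) stop("expected BED6: chrom start end name score strand")
  genes <- data.frame(gene_id = as.character(d[[4]]), chrom = d[[1]],
                      strand = d[[6]], start = d[[2]], end = d[[3]],
                      stringsAsFactors = FALSE)
  gene_annotation(genes, promoter_up = promoter_up,
                  promoter_down = promoter_down)
}

#' Write peaks as BED
#'
#' BED3+2: chrom, start, end, probe count, mean score.
#' @param peaks a [call_peaks()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(peaks, path) {
  out <- sprintf("%s\t%d\t%d\t%d\t%.4f", peaks$chrom,
                 as.integer(peaks$start), as.integer(peaks$end),
                 peaks$n_probes, peaks$mean_score)
  writeLines(out, path)
  invisible(path)
}
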