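#' Pipeline configuration
#'
#' Bundles the stage toggles and parameter blocks for an end-to-end run:
#' simulate -> smooth -> peaks/FDR -> differential -> expression ->
#' report. Stage seeds are derived from the single `seed` in the
#' simulation config via [stage_seed()], so the run is fully reproducible.
#'
#' @param outdir output directory (created if needed).
#' @param sim a [sim_config()].
#' @param peak a [peak_config()].
#' @param stages character subset of
#'   `c("simulate", "smooth", "peaks", "differential", "expression")`;
#'   later stages require the earlier ones.
#' @param smooth_window running-median window (probes) for peak calling.
#' @param alpha significance level for the differential stages.
#' @param write_tracks whether to write every simulated track to disk
#'   (bedGraph); off by default to keep runs light.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("hmedip_run_"),
                            sim = sim_config(),
                            peak = peak_config(seed = sim$seed),
                            stages = c("simulate", "smooth", "peaks",
                                       "differential", "expression"),
                            smooth_window = 7, alpha = 0.01,
                            write_tracks = FALSE) {
  known <- c("simulate", "smooth", "peaks", "differential", "expression")
  stopifnot(all(stages %in% known))
  need <- known[seq_len(max(match(stages, known)))]
  missing <- setdiff(setdiff(need, "simulate"), stages)
  # every enabled stage consumes the output of all earlier ones
  if (!("simulate" %in% stages) && length(stages) > 0)
    stop("enabled stage(s) ", paste(stages, collapse = ", "),
         " require the simulate stage (no external track input configured)")
  if (length(missing))
    stop("stage dependency unsatisfied: need ",
         paste(missing, collapse = ", "))
  structure(list(outdir = outdir, sim = sim, peak = peak, stages = stages,
                 smooth_window = smooth_window, alpha = alpha,
                 write_tracks = write_tracks),
            class = "pipeline_config")
}

.manifest_add <- function(manifest, stage, path) {
  manifest$files[[basename(path)]] <- list(
    stage = stage, path = basename(path),
    md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order, writing every result
#' as plain text (TSV/bedGraph/JSON) under `config$outdir`, and returns a
#' manifest listing each output with its MD5 checksum, the parameters and
#' the stage seeds. Identical config and seed give identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return List of class `run_manifest` (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(
    utils::packageVersion("hmedip")),
    seed = config$sim$seed,
    stages = config$stages, parameters = list(
      sim = unclass(config$sim), peak = unclass(config$peak),
      smooth_window = config$smooth_window, alpha = config$alpha),
    stage_seeds = stats::setNames(
      lapply(c("genome", "tracks", "expression"),
             function(s) stage_seed(config$sim$seed, s)),
      c("genome", "tracks", "expression")),
    files = list())

  genome <- make_genome(config$sim)
  tracks <- simulate_tracks(genome, config$sim)

  g <- genome$annotation$genes
  utils::write.table(
    data.frame(g$chrom, g$start, g$end, g$gene_id, 0, g$strand),
    out("genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  manifest <- .manifest_add(manifest, "simulate", out("genes.bed"))
  truth <- list(seed = config$sim$seed,
                mu_genic = config$sim$mu_genic, alpha = config$sim$alpha,
                delta_promoter = config$sim$delta_promoter,
                imprinted_like = g$gene_id[g$imprinted_like],
                cluster_member = g$gene_id[g$cluster_member],
                gains_5mc = g$gene_id[g$gains_5mc],
                expressed = g$gene_id[g$expressed])
  jsonlite::write_json(truth, out("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- .manifest_add(manifest, "simulate", out("ground_truth.json"))
  if (config$write_tracks) {
    for (nm in names(tracks)) {
      write_track(tracks[[nm]], out(paste0(nm, ".bedGraph")),
                  span = config$sim$probe_spacing)
      manifest <- .manifest_add(manifest, "simulate",
                                out(paste0(nm, ".bedGraph")))
    }
  }

  by_group <- function(cond, mk) tracks[vapply(tracks, function(t)
    identical(attr(t, "condition"), cond) &&
      identical(attr(t, "mark"), mk), TRUE)]

  if ("peaks" %in% config$stages) {
    pk_rows <- list()
    for (mk in c("5hmC", "5mC")) for (cond in c("tissue", "culture")) {
      grp <- by_group(cond, mk)
      for (nm in names(grp)) {
        sm <- if ("smooth" %in% config$stages)
          running_median(grp[[nm]], config$smooth_window) else grp[[nm]]
        pk <- call_peaks(sm, config$peak)
        pk_rows[[nm]] <- data.frame(sample = nm, condition = cond,
                                    mark = mk, n_peaks = nrow(pk),
                                    peak_probes = n_peak_probes(pk),
                                    stringsAsFactors = FALSE)
      }
    }
    peak_summary <- do.call(rbind, pk_rows)
    utils::write.table(peak_summary, out("peak_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "peaks", out("peak_summary.tsv"))

    rep1 <- by_group("tissue", "5hmC")[[1]]
    sm1 <- if ("smooth" %in% config$stages)
      running_median(rep1, config$smooth_window) else rep1
    fdr <- estimate_fdr(sm1, config$peak)
    jsonlite::write_json(
      list(sample = attr(rep1, "sample_id"), observed = fdr$observed,
           null_counts = fdr$null_counts, fdr = fdr$fdr,
           threshold = fdr$threshold, seed = config$peak$seed),
      out("fdr.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- .manifest_add(manifest, "peaks", out("fdr.json"))
  }

  if ("differential" %in% config$stages) {
    for (mk in c("5hmC", "5mC")) for (reg in c("body", "promoter")) {
      tab <- differential_genic(
        by_group("tissue", mk), by_group("culture", mk),
        genome$annotation, region = reg, alpha = config$alpha,
        sig_on = if (reg == "promoter") "raw" else "adjusted")
      f <- out(sprintf("differential_%s_%s.tsv", mk, reg))
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- .manifest_add(manifest, "differential", f)
    }
  }

  if ("expression" %in% config$stages) {
    ex <- simulate_expression(genome, config$sim)
    qn <- quantile_normalize(ex$log2)
    de <- paired_de(qn, ex$pairs, alpha = config$alpha)
    utils::write.table(de, out("expression_de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- .manifest_add(manifest, "expression",
                              out("expression_de.tsv"))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(c(manifest, list(outdir = config$outdir)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, %d files in %s\n", x$seed,
              length(x$files), x$outdir))
  for (f in x$files) cat(sprintf("  [%s] %s  %s\n", f$stage, f$path, f$md5))
  invisible(x)
}

#' Human-readable run report
#'
#' Summarizes a completed run from its manifest and output files: peak
#' and peak-probe counts per sample, the FDR estimate, significant-gene
#' counts per mark and region, and expression DE counts. Every number is
#' cross-referenced to the file it was read from; sections whose stage did
#' not run are marked absent.
#'
#' @param manifest a [run_pipeline()] result (or the parsed
#'   `manifest.json` plus `outdir`).
#' @param path optional file to write the report to.
#' @return Character vector of report lines, invisibly.
#' @export
write_report <- function(manifest, path = NULL) {
  outdir <- manifest$outdir
  have <- function(f) f %in% names(manifest$files)
  ln <- c(sprintf("hmedip run report (seed %d)", manifest$seed),
          sprintf("stages: %s", paste(manifest$stages, collapse = ", ")),
          "")
  if (have("peak_summary.tsv")) {
    ps <- utils::read.table(file.path(outdir, "peak_summary.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ln <- c(ln, "Peak calling [peak_summary.tsv]:",
            sprintf("  %-22s %6d peaks  %8d peak probes",
                    ps$sample, ps$n_peaks, ps$peak_probes))
    if (have("fdr.json")) {
      fd <- jsonlite::read_json(file.path(outdir, "fdr.json"),
                                simplifyVector = TRUE)
      ln <- c(ln, sprintf(
        "  empirical FDR (%s): %.4g (observed %d, mean null %.1f) [fdr.json]",
        fd$sample, fd$fdr, fd$observed, mean(fd$null_counts)))
    }
    ln <- c(ln, "")
  } else ln <- c(ln, "Peak calling: absent", "")
  diff_files <- grep("^differential_", names(manifest$files), value = TRUE)
  if (length(diff_files)) {
    ln <- c(ln, "Differential enrichment:")
    for (f in sort(diff_files)) {
      d <- utils::read.table(file.path(outdir, f), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
      ln <- c(ln, sprintf(
        "  %-32s %4d tested, %4d significant (%d gain / %d loss) [%s]",
        sub("differential_", "", sub(".tsv", "", f)),
        sum(!is.na(d$p)), sum(d$significant, na.rm = TRUE),
        sum(d$significant & d$direction == "gain", na.rm = TRUE),
        sum(d$significant & d$direction == "loss", na.rm = TRUE), f))
    }
    ln <- c(ln, "")
  } else ln <- c(ln, "Differential enrichment: absent", "")
  if (have("expression_de.tsv")) {
    d <- utils::read.table(file.path(outdir, "expression_de.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    ln <- c(ln, "Expression [expression_de.tsv]:",
            sprintf("  %d genes, %d DE (%d up / %d down), %d strict",
                    nrow(d), sum(d$de), sum(d$de & d$log2fc > 0),
                    sum(d$de & d$log2fc < 0), sum(d$strict)), "")
  } else ln <- c(ln, "Expression: absent", "")
  if (!is.null(path)) writeLines(ln, path)
  invisible(ln)
}
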