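# hmedip

Tissue-versus-culture DNA modification profiling from tiling-array
enrichment tracks.

## What this package is for

When primary cells are adapted to culture, genomic
5-hydroxymethylcytosine (5hmC) collapses globally within days — roughly
ten-fold — while 5-methylcytosine (5mC) stays almost perfectly conserved
except for focal promoter hypermethylation at clustered developmental
loci. `hmedip` implements the complete analysis pipeline for
characterizing this asymmetry from DNA-immunoprecipitation tiling-array
data (hMeDIP-chip / MeDIP-chip log2 IP/input tracks over paired
tissue/culture replicates), for epigenomics analysts who want each stage
as a reusable, tested function:

* **Preprocessing** — per-array LOWESS (tricube local-linear)
  normalization of two-channel intensities; 7-probe running-median
  smoothing.
* **Peak calling** — the percentile-window rule: a peak is any run of
  *w* = 5 consecutive probes with at least *k* = 4 scores strictly above
  the sample's 90th percentile, merged into maximal peaks. Its null rate
  has the closed form Σ_{j≥k} C(w,j) q^j (1−q)^(w−j), q = 0.1, i.e.
  4.6×10⁻⁴ per window (≤ 0.23% of probes falsely in peaks), and an
  empirical permutation FDR (mean null peak probes / observed peak
  probes over genome-wide score shuffles).
* **Differential enrichment** — per-gene two-sided Mann-Whitney U tests
  on per-probe condition means over gene bodies or promoters, with
  Benjamini–Hochberg adjustment, median-difference effect sizes, and
  top-5%-|Δ| flags.
* **Diagnostics** — windowed medians (2 Mb), autocorrelation profiles,
  Ward/Euclidean sample clustering, Spearman cross-condition
  correlation, reads-per-million bin coverage for enrichment
  sequencing.
* **Expression** — quantile normalization, Fisher-combined detection
  calls, paired t-tests with BH adjustment and fold-change filters,
  covariance PCA, association of genic 5hmC with expression state.
* **Bisulfite clones** — in-silico converted reference, positional
  clone calls, duplicate removal, the <95% conversion-rate exclusion,
  per-CpG and pooled percent methylation.
* **Synthetic data** — a fully seeded generator that plants the study
  structure (genic 5hmC attenuated ten-fold in culture, protected
  imprinted-like loci, a conserved smooth 5mC profile with clustered
  promoter gains, mostly-<2-fold bidirectional expression changes) so
  the entire pipeline is verifiable without external data.

## Worked example

```r
library(hmedip)

cfg    <- sim_config(seed = 1)        # default study conditions
genome <- make_genome(cfg)            # 2 x 25 Mb, 250 bp grid, 400 genes
tracks <- simulate_tracks(genome, cfg)

smoothed <- running_median(tracks$tissue_5hmC_rep1, window = 7)
peaks    <- call_peaks(smoothed, peak_config())
peaks
#> peak_set: 835 peaks, 21482 peak probes (threshold 1.2702)

estimate_fdr(smoothed, peak_config(seed = 1))
#> fdr_estimate: 21482 observed peak probes, mean null 341.1 over 20 permutations
#>   FDR = 0.01588
null_window_rate(peak_config())
#> [1] 0.00046

body_5hmc <- differential_genic(
  tracks[grep("tissue_5hmC", names(tracks))],
  tracks[grep("culture_5hmC", names(tracks))],
  genome$annotation, region = "body")
#> 392 of 400 tested gene bodies significantly altered; 100% of the
#> significant-and-substantial (top 5% |delta|) genes are losses

prom_5mc <- differential_genic(
  tracks[grep("tissue_5mC", names(tracks))],
  tracks[grep("culture_5mC", names(tracks))],
  genome$annotation, region = "promoter", sig_on = "raw")
prom_5hmc <- differential_genic(
  tracks[grep("tissue_5hmC", names(tracks))],
  tracks[grep("culture_5hmC", names(tracks))],
  genome$annotation, region = "promoter", sig_on = "raw")
promoter_shift_summary(`5mC` = prom_5mc, `5hmC` = prom_5hmc)
#>   mark n_gain n_loss gain_fraction
#> 1  5mC     10      2     0.8333333
#> 2 5hmC      0      4     0.0000000

track_correlation(running_median(tracks$tissue_5mC_rep1, 7),
                  running_median(tracks$culture_5mC_rep1, 7))$estimate
#> [1] 0.981
```

Reading the numbers: on the tissue-like 5hmC track, ~10% of probes sit
in peaks concentrated in gene bodies; shuffling the scores leaves only
~341 of 21,482 peak probes, and the permutation FDR is ~0.016 (see the
methods vignette for why this ratio is floored near 0.015 while the
closed-form expected false fraction, 5 × 4.6×10⁻⁴ = 0.23%, meets the
< 1% bound). Nearly all gene bodies lose 5hmC in culture and every
substantial significant change is a loss; promoters show the opposite
asymmetry for 5mC (10 gains — the planted Hox-like cluster — against 2
background losses), while the 5mC profile itself is conserved between
conditions (Spearman ρ = 0.98).

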