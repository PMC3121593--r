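# diauxielfq

Label-free quantitative proteomics of the bacterial glucose–lactose
diauxic shift, as a tested and reusable R pipeline.

## The problem

When *E. coli* grows on a glucose/lactose mixture it consumes glucose
first, pauses for 20–30 minutes when glucose runs out, induces the
lactose machinery (most visibly β-galactosidase, *lacZ*), and resumes
growth on lactose. Following the whole proteome through this shift with
label-free LC-MS means solving a chain of small, error-prone problems:
filtering peptide-spectrum matches by score, estimating the false
discovery rate from decoys, warping each run's retention-time axis onto
a master run using shared identified peptides, extracting an intensity
for every peptide from every run by an m/z × RT window, rolling
peptides up to proteins using only unshared peptides, normalizing
against the most abundant protein and the earliest time point, aligning
replicate time axes to the onset of the shift, clustering expression
profiles into up/down/unchanged groups, and painting mean log2 ratios
onto KEGG pathway maps.

`diauxielfq` implements each stage as a tibble-in/tibble-out function,
plus a synthetic-data generator that emulates the entire experiment
(growth curves, tryptic peptides, per-run feature maps with monotone RT
distortion, identification lists with decoys and known contamination) so
that every stage can be validated against ground truth without any
instrument data.

## The core quantities

- **Decoy FDR**: `estimate_fdr()` returns D/T, decoy over target counts
  at the current score cut (default cut: ion score ≥ 25).
- **RT warp**: a strictly monotone piecewise-linear map fitted to anchor
  peptides by nonnegative least squares with iterative outlier rejection.
- **Extraction**: windowed maximum — the most intense feature within
  5 ppm and 1 min of the identified peptide.
- **Protein abundance**: sum of unique-peptide intensities; normalized
  per sample by the reference protein and per replicate by the earliest
  time point; then log2.
- **Fold recovery**: `2^(mean post-shift log2 ratio)` — for the lacZ
  analogue this should recover the ~16-fold induction of
  β-galactosidase.
- **Colors**: log2 ratio +2.5 → `#00FF00`, 0 → `#FFFF00`, −2.5 →
  `#FF0000`, linear in RGB between, clamped outside.

## Worked example

```r
library(diauxielfq)
p <- run_pipeline(n_proteins = 200, seed = 42, verbose = TRUE)
#> proteome: 200 proteins, 3256 tryptic peptides
#> simulated 237090 features, 197834 identifications over 81 runs
#> score >= 25 filter: 197834 -> 140603 ids (FDR 0.111 -> 0.026)
#> merged to 7580 (peptide, charge) records (5436 targets)
#> protein matrix: 200 proteins (reference ECP0173)
#> lacZ analogue ECP0010: recovered fold change 15.19
```

The log tells the story: ~198k per-run identifications collapse to
7,580 (peptide, charge) records after the score-25 filter, with the
decoy-estimated FDR dropping from 11.1% to 2.6% through the filter.
All 200 proteins are quantified, and the lacZ analogue — simulated with
a 16-fold induction — is recovered at 15.2-fold from the noisy,
dropout-ridden data.

```r
p$onsets[, c("replicate_id", "onset_min", "od_at_onset")]
#>   replicate_id onset_min od_at_onset
#> 1 r1                 250       0.588
#> 2 r2                 240       0.578
#> 3 r3                 240       0.590
```

Each replicate's diauxic onset is detected from its growth curve
(true glucose exhaustion is at 235 min; calls land on the nearest
sampled plateau point, at about one quarter of the final OD of ~2.3).

```r
table(tidy(p$clusters)$class)
#> down flat   up
#>   39  125   36
```

Clustering the onset-aligned log2 profiles into three groups recovers
approximately the simulated 20%/20%/60% up/down/flat composition.

```r
ratio_to_color(c(-2.5, 0, 1.25, 2.5))
#> "#FF0000" "#FFFF00" "#80FF00" "#00FF00"
```

`export_pathway_colors()` writes these, one `entry bg,fg` line per
protein, in the format the KEGG pathway mapper accepts.

Plot helpers: `autoplot()` on growth curves, warps and cluster results;
`plot_protein_profile()` for single proteins; `tidy()`/`glance()` on
warps, cluster results and pipeline objects.

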