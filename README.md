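# glycoEMT

Quantitative tooling for studying how N-glycosylation and the
epithelial–mesenchymal transition (EMT) interact — e.g. in PD-L1–mediated
immune evasion of breast cancer cells. The package is aimed at proteomics and
cancer-biology analysts who need three small, well-defined computations done
reproducibly:

1. **N-glycan site occupancy from MS peptide intensities.** PNGase F removes
   N-linked glycans and converts the occupied Asn (N) into Asp (D), shifting
   the peptide's monoisotopic mass by +0.984016 Da. With reference-peptide
   normalized intensities — `IN` (native N×T peptide, PNGase F run), `INF`
   (deamidated D×T peptide, PNGase F run) and `IND` (D×T peptide from a
   control run without PNGase F, i.e. spontaneous deamidation) — site
   occupancy is

   ```
   occupancy (%) = (INF − IND) / (IN + INF) × 100
   ```

   100% occupancy implies `IN = 0` with `IND = 0`. The package computes
   monoisotopic masses and m/z, extracts ion chromatograms in inclusive
   ±ppm windows, integrates them trapezoidally, normalizes protein amount
   across samples with the two PD-L1 reference peptides
   `DQLSLGNAALQITDVK` (m/z 843.4570, 2+) and `AEVIWTSSDHQVLSGK`
   (m/z 586.3003, 3+), and applies the formula with clamping and QC flags.

2. **EMT signature scoring of expression matrices.** Raw (RSEM-like) values
   are log2-transformed and gene-wise median-centered; a sample's EMT score is
   the mean log ratio of the mesenchymal-arm genes minus the mean of the
   epithelial-arm genes (higher = more mesenchymal). Gene–score and gene–gene
   Pearson correlations and the conventional heat-map color ramps
   (black/red/green for expression, gray/yellow/blue for scores) are included.

3. **Small study metrics.** IHC quantitative score = percent-positive (0–100)
   × intensity grade (0–3); tumor volume = l × w² / 2; MFI fold change =
   treated / control.

Seeded simulators generate MS runs with a known true occupancy and
deamidation rate, expression matrices with a two-group EMT structure, and
co-expressed IHC tables, so every stage is testable against ground truth
without any external download.

## Worked example

```r
library(glycoEMT)

# simulate 3 replicate MS runs at true occupancy 50%, 10% spontaneous
# deamidation, 5% intensity CV; render as spectra and quantify back
pt  <- simulate_occupancy_runs(theta = 0.5, d = 0.1, noise_cv = 0.05,
                               n_replicates = 3, seed = 11)
sp  <- simulate_spectra(pt, mz_jitter_ppm = 2, n_scans = 60, seed = 12)
occ <- occupancy_from_peak_table(xic_quantify(sp, ppm_tol = 10))
occ[, c("site_id", "sample_id", "IN", "INF", "IND", "occupancy_percent")]
#>   site_id sample_id        IN       INF        IND occupancy_percent
#> 1   site1       S01 0.4363593 0.5500442 0.04766018          50.93089
#> 2   site1       S02 0.4569870 0.5324216 0.05024669          48.73365
#> 3   site1       S03 0.4474842 0.5781391 0.05023771          51.47127

# EMT scoring of a simulated two-group matrix (arm effect 1 log2 unit)
sig <- default_emt_signature()
m   <- simulate_expression(sig, n_epithelial = 50, n_mesenchymal = 50,
                           effect = 1, seed = 1)
sc  <- emt_score(log_ratio_transform(m), sig)
tapply(sc$emt_score, attr(m, "group"), mean)
#>  epithelial mesenchymal
#>  -1.0173818   0.9602581
```

The recovered occupancies sit within 1.5 percentage points of the true 50%,
and the mesenchymal group scores about 2 log2 units above the epithelial group
— twice the per-arm effect, as the score construction implies.

The command-line wrapper (`inst/cli/glycoEMT.R`) exposes the same stages as
`occupancy`, `emt`, `metrics` and `simulate` subcommands; every run writes a
JSON log with its inputs, parameters and a hash of the constants table.

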