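---
title: "Methods: glycan site-occupancy quantification and EMT scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan site-occupancy quantification and EMT scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoEMT)
```

## The occupancy model

An N-glycosylation sequon (N-X-S/T) is occupied in some fraction of the
protein molecules in a sample. Enzymatic de-glycosylation with PNGase F
converts each occupied asparagine to aspartate, so after digestion the
sequon-containing tryptic peptide appears in two forms: the native N×T form
(molecules that were never glycosylated) and the D×T form (molecules whose
glycan was removed). Asparagine also deamidates spontaneously at a low rate,
which would inflate the D×T signal; a control digest without PNGase F
measures that background. With intensities normalized for protein amount,

$$\mathrm{occupancy\ (\%)} = \frac{I_{NF} - I_{ND}}{I_N + I_{NF}} \times 100,$$

where $I_N$ is the native-peptide intensity after PNGase F, $I_{NF}$ the
deamidated-peptide intensity after PNGase F, and $I_{ND}$ the
deamidated-peptide intensity from the no-enzyme control. The estimator
assumes the N×T and D×T forms of the same peptide have approximately equal
recovery and MS response — reasonable because they differ by a single atom
substitution — and that the spontaneous deamidation accrued in the control
matches that in the treated sample. Full occupancy corresponds to $I_N = 0$
with $I_{ND} = 0$.

`compute_site_occupancy()` clamps the raw percentage to $[0, 100]$ and flags
rather than drops pathological cases: `negative_raw` when $I_{ND} > I_{NF}$
(control deamidation exceeding the treated signal, possible at low occupancy
and high noise), `zero_denominator` when $I_N + I_{NF} = 0$ (occupancy is
reported as `NA`), and `low_signal` when the denominator falls below a
configurable absolute floor, by default $10^{-6}$ of the baseline sample's
mean reference intensity — intensities that small make the ratio meaningless
whatever its value.

### Mass and m/z conventions

Peptide masses are sums of standard monoisotopic residue masses plus one
water (18.010565 Da); ions are protonated with 1.00727646 Da per charge. The
N→D conversion is modeled with its exact monoisotopic delta, +0.984016 Da,
not the nominal one mass unit: at m/z ~500–850 with 10 ppm extraction
windows, the ~0.016 Da discrepancy of the nominal value would be several
window widths. The two normalization peptides, DQLSLGNAALQITDVK and
AEVIWTSSDHQVLSGK, are used at charges 2+ and 3+ — the states that reproduce
their reported m/z values (843.4570 and 586.3003) from the residue masses.
Our exact computation gives 843.45706 for the first peptide, one unit in the
fourth decimal above the reported figure, which was evidently rounded or
computed from lower-precision residue tables; the package keeps the exact
masses.

### XIC extraction and quantity

`extract_xic()` sums, per scan, all centroid intensities inside the closed
interval `target_mz * (1 ± ppm_tol * 1e-6)`; ties at the boundary are
included. Each ion is quantified as the **trapezoidal area** of its trace
(`integrate_trace()`), not the apex height: area is robust to the density and
phase of retention-time sampling, which matters for synthetic spectra with
few scans. A single-point trace returns that point's intensity so that
one-scan data degrade gracefully; an empty trace is 0. Default tolerance is
10 ppm. No retention-time alignment, isotope-envelope deconvolution or MS/MS
matching is attempted; each peptide form is one ion at one charge state.

### Normalization

`normalize_to_reference()` computes, per sample, the arithmetic mean of the
reference-peptide intensities and scales all of the sample's measurements by
`baseline mean / sample mean`, with the baseline defaulting to the first
sample in input order. Both run conditions of a sample are normalized with
that sample's own pooled reference intensities — whether the control run
shares the treated run's baseline is not something the estimator fixes, and
pooling uses all the reference signal available. A sample with zero mean
reference intensity, or missing a reference peptide entirely, is a hard
error: there is no defensible scale for it.

## The EMT score

Raw expression (RSEM-like, non-negative) is transformed gene-wise:
$\log_2(x + c)$ with pseudocount $c = 1$ by default, then centered at the
gene's **median** across samples, so 0 means "unchanged relative to the
cohort" — the convention the color legend assumes. Median centering was
chosen over mean centering for robustness to the heavy right tail of
expression data; both are exposed (`center =`). The score of a sample is

$$\mathrm{EMT} = \overline{\log_2\text{ratio}}_{\text{mesenchymal arm}} -
  \overline{\log_2\text{ratio}}_{\text{epithelial arm}},$$

so swapping the arms negates the score exactly, and permuting genes within an
arm changes nothing. Signature genes missing from a matrix are dropped with a
warning and reported as per-arm coverage; only an arm with zero matches is an
error. Matching is exact and case-sensitive after whitespace stripping — no
alias resolution.

The packaged signature (`inst/extdata/emt_signature_synthetic.tsv`) is a
synthetic stand-in with the canonical shape of published core-EMT signatures
— 20 mesenchymal and 17 epithelial genes, populated with widely used EMT
markers (VIM, ZEB1/2, SNAI1/2, TWIST1/2, CDH2, ... vs CDH1, EPCAM, GRHL2,
claudins, keratins, ...). It is a structural fixture for testing the scoring
machinery, not a reproduction of any specific published list; analyses of
real data should supply their own signature file.

Correlations (gene–score, gene–gene, IHC marker–marker) are Pearson with
two-sided p-values via `stats::cor.test()`, requiring $n \ge 3$ and
non-constant vectors; Spearman is available for the ordinal-leaning IHC
scores. Heat-map colors are linear two-sided ramps saturating at `vmax`
(default 3 log2 units for expression, 1 for scores — purely presentational):
black→red/green for expression, gray→yellow/blue for EMT scores.

## Study metrics

IHC score = percent-positive × intensity grade, with the grade restricted to
the integer scale 0–3 (composite fractional intensities are rejected; the
digital-imaging details behind the grade are abstracted into a single ordinal
per specimen). Tumor volume = $l w^2/2$; if the caliper columns are reversed
($w > l$) the arguments are swapped with a warning rather than an error,
since the formula's intent is unambiguous. MFI fold change is the plain ratio
treated/control.

## What the simulators emulate — and what they do not

`simulate_occupancy_runs()` draws, per replicate sample of abundance $A$,
noise-free expectations $I_N = A(1-\theta)(1-d)$,
$I_{NF} = A(\theta + (1-\theta)d)$, $I_{ND} = A(1-\theta)d$, with true
occupancy $\theta$ and spontaneous deamidation fraction $d$ — latent
parameters of the generator, not observables. Noise is multiplicative
log-normal with unit mean and a given CV, applied independently per
measurement: MS intensities are positive and roughly CV-stable, and no noise
model is prescribed by the estimator itself. Defaults emulate a small
targeted experiment: $d = 0.1$, CV 5%, 3 replicates. Exact zeros stay zero,
preserving the boundary cases $\theta \in \{0, 1\}$.

`simulate_spectra()` renders each table intensity as a Gaussian elution peak
(default $\sigma$ = 0.2 min over a 60-scan grid spanning ±4σ) at the ion's
theoretical m/z with optional per-centroid ppm jitter, scaled so the
trapezoidal XIC area equals the table intensity; with ≥50 scans and jitter
≤2 ppm the round trip is within 2%. `simulate_expression()` adds ±`effect`
log2 shifts to the signature arms in the mesenchymal group (so the expected
group score difference is `2 * effect`), injects genes with a requested
point-biserial correlation to the group label, and exponentiates back to raw
space; baselines are uniform on log2 ∈ [5, 12]. `simulate_ihc()` discretizes
an exchangeable latent Gaussian into percent (via the normal CDF) and grade
(latent quantile cuts at 0.25/0.5/0.75, frozen for reproducibility) — the
observed score correlation is therefore attenuated relative to the latent
one (≈0.54 observed at latent 0.6, by large-n simulation).

These fixtures are structural, not realistic: no isotope envelopes,
chimeric spectra, missing values, batch effects, real TCGA marginal
distributions, or gene–gene correlation beyond what the group structure
induces. Passing tests demonstrate that the estimators recover known ground
truth under their own assumptions, not that those assumptions hold in any
particular real dataset.

## Numerical choices and problem sizes

All simulation-backed tests run at deliberately small sizes — 3 MS
replicates with 60-scan spectra, 30–100-sample expression matrices, 200
repetitions for null calibration of the gene–score correlation (empirical
rejection 5% at the 5% level), 129–1000 IHC specimens — sizes a targeted
experiment would actually produce, and enough for the tolerances asserted
(occupancy recovery within 2–3 percentage points, score separation within
±0.2 of its expectation). Determinism is enforced throughout: every
stochastic function takes a seed and restores the caller's RNG state, and
pipeline runs with identical inputs are byte-identical, with a JSON log
recording inputs, parameters, package version and a hash of the constants
table.

## Known limitations

* One ion per peptide form: no miscleavage variants, no charge-state
  summation. Fine for defined targeted peptides; real discovery data would
  need both.
* Occupancy per site is estimated independently; peptides bearing multiple
  sequons would confound the native/deamidated dichotomy.
* The mzML reader requires the optional `mzR` package and centroided MS1
  data; profile-mode spectra are not peak-picked.
* The EMT score treats arms as exchangeable gene sets; no gene weighting or
  re-derivation of the signature is attempted.
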