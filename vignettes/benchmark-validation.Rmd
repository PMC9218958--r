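---
title: "Validating nontargeted feature detection with isotopologue-ratio benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating nontargeted feature detection with isotopologue-ratio benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irbench)
```

## The model

Nontargeted feature detection (NFD) turns raw LC-MS runs into feature
tables through peak picking, alignment, gap-filling and filtering. Each of
these steps loses, splits or mis-quantifies some true peaks, and the loss
rate depends strongly on tool and parameter choice. `irbench` quantifies
those losses against a *benchmark*: a set of peaks whose existence and
abundance are established independently of any peak picker.

The key idea is that isotopologue abundance ratios are physical constants
of a molecular formula. If a molecule is identified by targeted analysis
(formula plus retention-time boundaries per file), the most abundant
isotopologue (MAIT) anchors the molecule, and every lower-abundance
isotopologue (LAIT) whose predicted ratio exceeds an abundance floor can be
extracted from the raw data and *checked*: its observed ratio to the MAIT
must agree with theory. A LAIT whose observed-over-predicted ratio deviates
(for example because the MAIT saturates the detector, or an interference
inflates the LAIT) is excluded, so surviving peaks are quantitatively
trustworthy without fitting any explicit saturation or interference model.

### Isotopologue pattern prediction

For a charged species the package expands, per element, the exact
multinomial distribution of its atoms over the element's stable isotopes,
convolves the per-element distributions, and aggregates the result by
nominal mass shift (abundance-weighted m/z). Aggregation by nominal shift
reflects what centroided MS1 data can resolve: the fine structure within an
isotopologue (e.g. ^13^C vs ^15^N substitutions) collapses into one
centroid. m/z values subtract one electron mass per positive charge (and
add per negative charge), which matters at sub-mDa accuracy on modern
instruments. The isotope masses and abundances are an embedded, versioned
snapshot of the IUPAC/CIAAW recommended values so results cannot drift with
an external dependency.

Numerical choices: terms below 1e-18 relative abundance are pruned during
the expansion, which keeps retained ratios accurate to better than 1e-12
relative (the test suite verifies < 1e-9 against exhaustive per-atom
enumeration on 500 random formulas); aggregated isotopologues closer than
`merge_tol` (default 1e-4 Th) are merged abundance-weighted, which is only
ever triggered at multiple charges.

### Benchmark acceptance filters

For every molecule × file × adduct the MAIT ion chromatogram is extracted
inside the targeted boundaries (default tolerance 5 ppm; the summed
intensity of all in-tolerance centroids per spectrum, with zero-filled
points where none match). A LAIT is accepted only if all four filters pass,
with strict inequalities:

| filter | threshold | unit |
|---|---|---|
| Pearson correlation with the MAIT trace | > 0.85 | — |
| IR bias from peak areas | < 35 | % |
| IR bias from peak heights | < 30 | % |
| abs(height bias − area bias) | < 30 | percentage points |

The correlation is computed on the shared scan grid of the two traces
inside the boundaries, zero-filled points included — both traces come from
the same spectra, so no interpolation is needed; a constant trace has no
defined correlation and is rejected as such. The height-vs-area filter uses
the absolute difference of the two (absolute) biases; whether the original
convention is signed is not documented anywhere we could find, so the
choice is fixed here and echoed in every export. A group whose MAIT peak
has fewer than four non-zero points is dropped entirely and logged.

Peak shape descriptors follow the standard definitions: trapezoidal area,
FWHM by linear interpolation at half height on both flanks, the zigzag
index

$$\mathrm{zigzag} = \sum_{i=2}^{N-1} \frac{(2I_i - I_{i-1} - I_{i+1})^2}{N\,I_{max}^2}$$

and sharpness as the sum of relative successive rises on the leading flank
plus relative successive drops on the trailing flank, on raw (unsmoothed)
points. The zigzag and sharpness formulas are fixed in code because the
field cites them in several variants.

### Matching and metrics

Matching rules against NFD output are deliberately simple, deterministic
and configurable, and are echoed in all output metadata:

* **pre-alignment**: an NFD peak matches a benchmark peak if its m/z is
  within 10 ppm and the retention-time intervals overlap by at least 20 %
  of the benchmark peak's duration. With two or more matches whose mutual
  border falls inside the FWHM window around the apex, the peak counts as
  *split* (the operational form of "borders set close to the apex"). The
  best single match — largest overlap, ties by closest m/z, then input
  order — supplies the matched abundance, making the result independent of
  row order.
* **post-alignment**: a feature matches on m/z (10 ppm) and consensus
  retention time (default tolerance: half the benchmark peak's FWHM); it is
  found if its abundance in that file is present, with gap-filled entries
  counted as found but flagged and reported separately, since tools differ
  in whether gap-filling should "rescue" a miss.

Metrics are proportions over accepted benchmark peaks: found (splits count
as found and are also reported on their own), split, and IR accuracy — an
NFD-derived isotopologue ratio is recovered if its bias is less than 20
percentage points above the corresponding benchmark bias, so NFD tools are
not penalized for imperfections already present in the benchmark. Metrics
with no assessable input are reported as `NA`, never coerced to zero.
Both orientations (found/missed, accurate/inaccurate) appear in the tidy
export to avoid sign confusion.

### Bootstrap confidence intervals

All proportions receive percentile bootstrap intervals (default R = 1000,
level 0.99) obtained by resampling benchmark *molecules* with replacement:
the isotopologues of one molecule share a trace and are not independent, so
the molecule is the exchangeable unit. The percentile method (rather than
BCa) matches the plain resampling approach these intervals are meant to
mirror and keeps the procedure transparent. A fixed seed makes the interval
deterministic; a single-molecule benchmark yields a degenerate interval
with a warning.

### Replicate precision and label filters

`cv_metrics()` computes per-feature coefficients of variation across
replicate injections using the sample standard deviation (n − 1); features
with any missing replicate value or a zero mean fail regardless of CV, and
nCV30/pCV30 count features with CV strictly below 30 %. The label filter
(`evaluate_feature_filter()`) generalizes quality-classifier workflows:
a feature is retained if at least `min_good` of its per-file peaks carry
the good label, and recovery metrics can be recomputed on the retained set.

## The simulator and what passing tests mean

The simulator is first-class code, not a fixture: it writes centroided MS1
mzML (via `mzR`) in which each roster molecule contributes one co-eluting
trace per predicted isotopologue above the floor. Its defaults are the
study conditions used throughout the tests: 20 molecules per scene, apex
heights log-uniform over slightly more than four orders of magnitude
(1e3–2e7 counts, endpoints pinned so the configured span is realized
exactly), Gaussian peaks of 6 s FWHM sampled every 0.5 s, zero noise, no
saturation. Where stress is needed, scenes turn on multiplicative noise
(`intensity × (1 + N(0, cv))`), an additive half-normal floor, per-centroid
m/z jitter in ppm, an exponentially modified Gaussian shape for tailing,
or a hard saturation ceiling with per-trace flags.

Ground truth is exact by construction: planted bounds are apex ± 4σ
(extended by 4τ for EMG), and the truth area is the trapezoid of the
planted trace on the actual scan grid, so a perfect integrator reproduces
it. The corrupter damages the derived tables *by explicit list* — peaks to
drop, split (cut position as a fraction of duration), mis-integrate (area
multiplier), abundances to blank, labels to flip, retention-time shifts per
file — and `expected_metrics()` converts a plan into the exact values every
metric must take, including second-order effects such as a split MAIT
corrupting the ratios of its LAITs.

What the simulator does *not* emulate: chromatographic drift between runs,
chimeric spectra, adduct equilibria, electronic spike noise, background
ion clutter, and profile-mode data. Passing tests therefore demonstrate
that the bookkeeping, filters and statistics are correct under controlled
conditions — not that any particular real data set will show particular
error rates.

## Problem sizes and numerical conventions

The validation studies (test suite and `scripts/acceptance.R`) use: 500
random formulas (≤ 25 atoms over C, H, N, O, S, P, Cl) for the
pattern-prediction oracle; 20-molecule clean scenes for end-to-end
recovery; a 50-molecule, 100-peak scene (formulas chosen to carry exactly
two isotopologues above a 0.05 floor) for the corruption ledger; 200
synthetic scenes of 40 molecules with bootstrap R = 400 for interval
coverage; and molecule counts 10/50/200 with 20 replicates for the
width-vs-size behaviour. These sizes give stable results while keeping a
full run in the minutes range on a single core.

Conventions fixed throughout: retention times in seconds everywhere
(dialect readers convert minute-based tables on import; XCMS-style tables
are already in seconds); intensities within an m/z tolerance window are
summed, which is robust to centroid splitting; zero-filled points
participate in trapezoids and correlations; all filter comparisons are
strict; scan indices are internal only.

## Open choices made here

* The adduct registry defaults to [M+H]+, [M+Na]+, [M+K]+, [M+NH4]+,
  [M+2H]2+, [M−H]−, [M+Cl]− and is user-extendable; which adducts a given
  study should cover is a chemistry question the package cannot answer.
* The EIC m/z tolerance (5 ppm), match tolerances (10 ppm, 0.2 overlap,
  FWHM/2) are explicit, documented defaults — comparable across runs
  because they are echoed in output metadata.
* Gap-filled abundances count as found *and* are reported separately, so
  either convention can be read off one report.

## Known limitations

Benchmark quality is bounded by the targeted input: wrong formulas or
boundaries produce a wrong benchmark (garbage in, validated-looking
garbage out). Molecules whose LAITs all fall below the abundance floor
contribute only their MAIT, so IR accuracy is undefined for them. The
split-peak definition requires the benchmark FWHM to be measurable; very
sparse peaks (< 4 points) never enter the benchmark at all. And the
simulator's clean conditions are a best case: real-data error rates can
only be measured on real data with a real targeted evaluation behind the
benchmark.
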