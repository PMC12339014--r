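---
title: "Isotope-ratio analysis on Orbitrap instruments: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-ratio analysis on Orbitrap instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbidelta)
```

`orbidelta` turns per-scan Orbitrap intensity/noise readings of molecular
isotopologues into calibrated δ¹³C values. This vignette explains the
models behind each stage, the parameters that matter, the design choices
that were genuinely open, and what the synthetic test bed does and does
not establish about real data.

## From signal-to-noise to ion counts

Orbitrap peak intensities are reported in arbitrary units together with a
noise figure. The estimated number of ions behind a peak is

$$\mathrm{count} = \frac{S}{N} \cdot c \cdot
  \left(\frac{R_n}{r}\right)^{a} \cdot \mu^{b}$$

where $c = 3$ is the noise-equivalent charge constant (experimentally
determined at the reference resolution $R_n = 240{,}000$), $r$ the working
resolution, and $\mu$ the number of microscans. Printed statements of this
relation sometimes read as if the resolution and microscan factors entered
linearly; the protocol literature this conversion derives from uses
square-root scaling, which is also what thermal-noise averaging predicts.
We default to $a = b = 0.5$ and expose both exponents in
`ion_count_config()` (set both to 1 for the linear reading). The choice is
immaterial for isotope ratios: both isotopologues of a scan share $c$,
$r$, $\mu$, so every constant cancels and the per-scan ratio is exactly
`(S₁₃/N₁₃)/(S₁₂/N₁₂)` (`scan_ratios()`). The exponents only matter for
absolute count estimates, which feed the shot-noise error model.

The monitored ratio is ¹³C₁/M₀ by default. Its expectation is
$19\,r_{13}$-fold the atomic ¹³C/¹²C ratio for a 19-carbon ion, but the
multiplier cancels in sample–standard bracketing, so no single-atom
correction is needed anywhere.

## Isotopologue fine structure

`fine_structure()` expands the complete isotopologue distribution of a
formula (plus adduct atoms — a proton adds one hydrogen site, a sodium
contributes a monoisotopic atom) by exact per-element multinomial
expansion, crossed over elements with optional pruning (default
`1e-6`). Pruning removes rows from the output but never renormalises:
reported abundances are always exact terms of the full expansion. For
C₁₉H₃₈O₂ [M+H]⁺ this gives M₀ 80.76%, ¹³C₁ 16.60%, ¹³C₂ 1.62% and ¹⁸O₁
0.33% under current IUPAC abundances. Published descriptions of this
spectrum print M₀ 80.18%, ¹³C 5.35% and ¹³C₂ 0.15%; these three values are
mutually inconsistent with any standard isotope table for this formula
(the ¹⁸O value is the only reproducible one), so the package documents the
discrepancy rather than forcing agreement, and the isotope table is an
explicit, swappable input (`iupac_isotopes()`, `read_isotope_table()`).

Species within one resolution element (FWHM $= m/z \,/\, r$) of another
are flagged `resolved = FALSE` but never merged: at $r = 60{,}000$ the
¹³C₁/²H₁ pair (3.0 mDa apart at $m/z$ 300) is such a case. Merging would
misattribute deuterium signal to carbon; flagging leaves the decision with
the analyst.

## Scan tables, extraction, contamination

The primary input format is an open tab-delimited scan table
(`read_scan_table()`/`write_scan_table()`): `#`-prefixed metadata lines,
then `scan, time_min, tic, S_<label>, N_<label>…` per scan. Doubles are
written with 17 significant digits and parsed with the C library's
correctly-rounded `strtod`, so the round trip is bit-exact — important
because downstream tests compare filtered scan sets, not file bytes.
Centroided spectra (any source that yields per-peak m/z, intensity and
noise, e.g. an mzML centroid read) are reduced to scan tables by
`extract_signals()`: per scan and species, the most intense peak within
±5 ppm (default) of the species m/z. Missing peaks become S = 0 with the
window's median noise, flagged — rows are never deleted, so scan
accounting survives and the outlier filter decides later. Whether vendor
noise figures are per-peak or per-spectrum varies; the schema carries one
noise per species per scan and simply replicates a spectrum-level figure
when that is all a source provides.

`contamination_fraction()` measures the intensity share inside the
monitored window not assigned to any monitored species. Runs whose median
exceeds 10% are flagged rather than rejected: mass-resolved coisolated
species do not bias the ratio arithmetic directly, but they can modulate
ionisation efficiency, so the flag marks results whose accuracy rests on
an untestable assumption.

## Outlier rejection and aggregation

The filter (`filter_outlier_scans()`) excludes scans whose TIC deviates
from the block median by more than `k_tic = 5` robust standard deviations
(MAD-scaled) or whose ratio deviates by more than `k_ratio = 3`, in a
single pass. A single pass is deliberate: iterated rejection on
shot-noise-limited data walks toward over-trimming, while one conservative
pass removes electrospray dropouts and bubbles without touching the
Poisson core. `k = Inf` disables either screen.

Two block aggregators are provided. `ratio_of_sums` (default) divides
summed numerator counts by summed denominator counts; it weights scans by
their ion content and has lower small-count bias (the bias of a ratio
estimator scales with the inverse of the *total* denominator count rather
than the per-scan count). `mean_of_ratios` weights scans equally and is
therefore exactly invariant under arbitrary per-scan intensity rescalings
common to both species; `ratio_of_sums` shares that invariance only for
uniform rescaling. Both are reported; they agree exactly whenever per-scan
counts are proportional.

## Sessions, bracketing, calibration

A dual-inlet session alternates reference and sample in timed blocks
(default seven 5-minute blocks, R,S,R,S,R,S,R — starting and ending on the
reference so every sample block is bracketed). Scans are assigned to
blocks by half-open time intervals `[start, end)` — a boundary scan
belongs to the later block — and 30 s are trimmed from each block edge to
discard valve-switch transients (the transient length is not quantified
in the source literature; 30 s at 1 scan/s costs 20% of a block and is
configurable). Flow-injection sessions instead occupy 15-minute slots per
injection with a broad ~10-minute plateau; `detect_plateau()` keeps the
longest contiguous window with TIC at least half (default) the plateau
level, estimated as the median TIC of the top-half scans — a robust level
estimate that ignores ramps and gaps — and trims its edges likewise.

`bracket_delta()` references each sample block to its two flanking
reference blocks, either as their plain mean (`adjacent_mean`, default)
or interpolated in time to the sample block's midpoint (`interpolate`).
The published session designs state alternation but not the combination
rule; `adjacent_mean` is the default because with symmetric schedules the
two coincide for linear drift, and the mean is less sensitive to a single
noisy reference block. Multiplicative source drift common to both
isotopologues cancels identically in either scheme because it never
reaches the per-scan ratio in the first place.

The session estimate is the mean of the per-sample-block deltas with SD
across blocks (within-session dispersion). Replicate bracketed runs are
combined by `combine_replicates()` with a Student-t interval over the
pooled block deltas (e.g. nine values from three runs of three sample
blocks), matching how replicate confidence intervals are conventionally
reported for such designs; note the nine values are not fully independent
(blocks within a run share reference blocks), so the nominal 95% interval
is mildly approximate — the session-level coverage test in the suite
quantifies this on synthetic data. Group differences use Welch's unequal
variance t-test (`compare_groups()`), the conservative default when no
test is named; zero-variance identical groups return p = 1 by convention.

VPDB anchoring is the exact multiplicative composition
$\delta_{V} = \delta + \delta_{std} + \delta\,\delta_{std}/1000$
(`to_vpdb()`, with exact inverse `from_vpdb()`); it composes
associatively across chained standards to within 1e-9 ‰.

## Method evaluation

`mae()` and `evaluate_standards()` produce per-standard residues
(measured − expected) and their mean absolute error. The bundled
`orbitrap_standard_results()` table reports both the residues as
originally published and residues recomputed from the δ columns; for one
standard (Std 9) the two disagree by ~0.5 ‰ in every section — its printed
residue is not derivable from its printed δ and reference values — so the
dual-inlet [M+Na]⁺ MAE of 0.72 ‰ reproduces from the printed residue
column but not from the δ columns. Both numbers are reported side by side
rather than silently choosing one.

## The synthetic session generator

`simulate_session()` is the forward model of everything above, with known
ground truth. Per scan, each monitored species' expected count is
`flux × abundance × drift(t) × envelope(t)`; the abundances come from the
exact fine structure under the role's carbon composition, realised by
shifting only the ¹³C/¹²C pair of the isotope table to the configured δ
(`shift_carbon_delta()`) — ¹⁸O and ²H stay at reference values because the
measurement targets δ¹³C. Counts are Poisson draws (or exact expectations
with `poisson = FALSE`, which makes the forward–inverse chain exact to
1e-6 ‰ and is the first thing the test suite checks). Counts are converted
to S/N through the same Eq-1 relation the analysis inverts; the absolute
noise level is log-normal per scan (σ = 0.1) around a scale set by a
nominal base-peak S/N of 500 — no noise statistics are published for this
acquisition mode, and the value only fixes arbitrary units since analysis
consumes S/N only. Contamination, when configured, appears in simulated
centroid spectra (`simulate_spectra()`) as one coisolated peak at +0.5 Da
off the base species carrying the configured window fraction. All
randomness flows from one integer seed; identical seed and configuration
give bit-identical tables.

Defaults mirror the acquisition this workflow targets: resolution 60,000,
two microscans, 1-second scans, seven 5-minute dual-inlet blocks,
reference at −27.8 ‰ vs VPDB, sodiated-to-protonated intensity ratio 10.
The default flux of 5×10⁵ ions per scan is an AGC-target-scale choice;
published settings do not pin down realised per-scan ion totals, so flux
is an explicit parameter everywhere. The precision tests and the
acceptance script use 1.5×10⁵ total ions per scan, putting ≥10⁵ ions in
the monoisotopic peak.

`predict_precision()` gives the counting-statistics floor
$SE_\delta \approx 1000\sqrt{2}\sqrt{1/C_{minor} + 1/C_{major}} /
\sqrt{n_{sample}}$ with $C$ the retained ions per block per species; the
$\sqrt2$ charges both the sample and reference sides. A correlation-exact
derivation for the default seven-block schedule gives a coefficient ~4%
smaller; the simple formula is kept because it is scheme-independent and
the test suite verifies it against empirical scatter over 50 seeded
sessions to within 25%.

**What the simulator does not emulate:** space charge and peak
coalescence, AGC feedback and injection-time variation, detector
nonlinearity, ionisation-efficiency modulation by coisolated species
(contamination only adds signal; it does not suppress the analyte), ESI
isotope fractionation, and chromatographic structure. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimation chain under shot-noise-limited conditions — the regime the
method claims — not robustness to these instrument effects; the published
real-sample values (vegetable-butter δ¹³C, group p-values) require the
original instrument data and are represented here only by the calibration
constants and evaluation tables.

## Numerical choices and degenerate inputs

Fine-structure probabilities are computed in log space
(`lgamma`-multinomial), so 100-atom formulas stay exact to 1e-9 in total
probability. Ties in peak assignment resolve to the more intense peak
with a multiplicity flag. Scans with zero denominator signal are masked
(`zero_base_peak`), never dropped, and a block whose retained scan count
falls below `min_scans` (default 10) is an error rather than a silent
small-n estimate. The MAD filter treats a zero MAD (constant series) as
"no outliers". Problem sizes in the test suite are chosen so the full
suite runs in minutes: precision-calibration properties use seven 1-minute
blocks over 50 seeds, the acceptance-level recovery check uses the full
7 × 5-minute schedule over 10 seeds.

## Known limitations

Single-anchor calibration only (one working standard; no two-point scale
normalisation). No position-specific or clumped-isotope quantities — the
molecular-average δ¹³C is the target. The ¹³C₁ species is unresolved from
²H₁ at the default resolution; the package flags this but the monitored
M+1 ratio inherits a small constant ²H contribution that cancels in
bracketing to the extent the hydrogen composition of sample and reference
match. Vendor RAW decoding is out of scope; the open scan-table schema or
any centroid-peak source stands in its place.
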