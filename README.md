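# orbidelta

Compound-specific carbon isotope ratios (δ¹³C) from Orbitrap mass
spectrometry, by sample–standard bracketing.

Conventional isotope-ratio mass spectrometry (IRMS) combusts the analyte to
CO₂ before measurement, so it reports a bulk average and destroys all
molecular information. High-resolution Orbitrap analyzers with soft
electrospray ionization resolve the individual isotopologues of an intact
molecular ion — for a fatty acid methyl ester such as methyl stearate
(C₁₉H₃₈O₂, measured as [M+H]⁺ or [M+Na]⁺), the monoisotopic peak M₀, the
singly and doubly ¹³C-substituted peaks, and the ¹⁸O peak — which makes
isotope-ratio measurement possible directly from solution, without
combustion or chromatographic conversion. `orbidelta` implements the full
data-analysis chain for such measurements, for users who have per-scan
intensity/noise readings of the monitored isotopologues and want calibrated
δ¹³C values with defensible uncertainties.

## The method

Orbitrap intensities come with a per-peak noise figure. The number of ions
behind a peak is estimated from its signal-to-noise ratio as

    count = (S/N) · c · (Rn/r)^a · μ^b

with noise-equivalent charge constant `c = 3` determined at the reference
resolution `Rn = 240,000`, working resolution `r`, and `μ` microscans
(exponents `a = b = 0.5` by default, configurable). The isotope ratio of a
scan is the ratio of ion counts, and because the constants are shared by
both isotopologues it collapses exactly to

    R = (S₁₃C / N₁₃C) / (S₁₂C / N₁₂C).

Per-scan ratios are screened by a robust (MAD-scaled) outlier filter on
total ion current and on the ratio itself, then aggregated per measurement
block — either as a count-weighted ratio of summed ion counts (default) or
as a mean of per-scan ratios. A session alternates reference and sample
introductions (a seven-block dual-inlet schedule, or flow-injection slots
whose usable plateau is detected automatically); each sample block is
bracketed by its two neighbouring reference blocks:

    δ¹³C_sample/std = (R_sample / R_ref − 1) × 1000   [‰]

which cancels source drift. Results are anchored to the Vienna Pee Dee
Belemnite scale through the working standard's calibrated value via the
exact composition `δ_VPDB = δ + δ_std + δ·δ_std/1000`.

The package also contains an exact isotopologue fine-structure calculator
(per-element multinomial expansion for arbitrary formulas, adducts and
charges), method-evaluation utilities (residues and mean absolute error
against reference standards, replicate t-intervals, Welch group
comparison), and a seeded Poisson shot-noise session simulator with a
closed-form counting-statistics precision prediction — the test bed for
every downstream stage.

## Worked example

Simulate a shot-noise-limited dual-inlet session with known ground truth
and process it end to end:

```r
library(orbidelta)

fine_structure("C19H38O2", adduct = "H", resolution = 60000)
#> # A tibble: 5 × 4      (head)
#>   label abundance    mz resolved
#> 1 M0      0.808    299. TRUE
#> 2 13C1    0.166    300. FALSE
#> 3 13C2    0.0162   301. FALSE
#> 4 2H1     0.00362  300. FALSE
#> 5 18O1    0.00332  301. FALSE

cfg <- sim_config(seed = 5, flux = 1.5e5, delta_sample_vpdb = -29.0)
run <- simulate_session(cfg)   # 2100 scans, 7 alternating 5-min blocks
res <- process_session(run)
res
#> <delta_result>
#>   delta-13C vs working standard:  -0.6210 permil (SD 0.4770, n = 3)
#>   delta-13C vs VPDB:             -28.4037 permil

tidy(res)
#> # A tibble: 3 × 5
#>   block ratio ratio_ref delta_permil delta_vpdb
#> 1     2 0.206     0.206      -0.818       -28.6
#> 2     4 0.206     0.206      -0.0770      -27.9
#> 3     6 0.206     0.206      -0.968       -28.7
```

The monoisotopic ion carries ~81% of the isotopologue abundance and the
¹³C₁ peak ~17%, so the monitored ratio sits near 0.206; the recovered
session δ of −0.62 ± 0.28 ‰ (SE) against the working standard compares
with a configured truth of −1.23 ‰ and a shot-noise prediction
(`predict_precision(cfg)`) of 0.37 ‰ — agreement at the one-sigma level,
which is what counting statistics allows at 1.5×10⁵ ions per scan. Note
`resolved = FALSE` on ¹³C₁: at a resolution of 60,000 the ¹³C and ²H
isotopologues are within one resolution element and are flagged, not
merged.

Evaluating published dual-inlet [M+Na]⁺ standard measurements against
their IRMS reference values:

```r
di_na <- dplyr::filter(orbitrap_standard_results(),
                       mode == "dual_inlet", adduct == "Na")
ev <- evaluate_standards(di_na)
round(c(ev$mae_reported, ev$mae_recomputed), 2)
#> [1] 0.72 0.78
```

(The two MAEs differ because one published standard's residue is
inconsistent with its own δ columns; see the vignette.)

A thin command-line wrapper over the same functions is installed at
`inst/cli/orbidelta.R` with subcommands `isotopes`, `simulate`, `extract`,
`ratios`, `process` and `evaluate`.

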