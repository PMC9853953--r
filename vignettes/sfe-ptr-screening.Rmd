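---
title: "Screening single-cell lipid extracts with SFE-PTR MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening single-cell lipid extracts with SFE-PTR MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfeptr)
```

## The measurement and the processing problem

In SFE-PTR MS, a sample (for instance a single adherent cell dried onto a
stainless-steel frit) is eluted by supercritical CO₂ directly into a
proton-transfer-reaction ion source, and a TOF analyser records a
centroided spectrum every 0.15 s. Water chemical ionization is soft and
adduct-poor: analytes appear essentially as protonated/deprotonated
molecules, electron-transfer radical ions, or hydroxide-exchange ions.
The data-processing task is to decide, for every observed m/z, whether
it is *sample-derived* (it elutes as a pulse while the extraction runs),
*background* (reagent and instrument ions, present from the start and
suppressed once analytes arrive), or an artefact shared with a blank
run; then to annotate sample ions with candidate molecular formulas and
convert their counts into amounts.

`sfeptr` implements that chain as small composable stages, each testable
against a synthetic generator with known ground truth.

## Synthetic study conditions

The generator (`generate_run()`) is the package's test bench and also a
convenient demonstration data source. It draws, per ion and per scan,
Poisson counts around a deterministic mean profile:

* **Sample ions** elute as a Gaussian pulse. "Bell-shaped" is all that
  can be said generally about an extraction elution profile; the
  Gaussian is the simplest bell, and its FWHM (`2.3548 σ`) gives the
  half-height bookkeeping a closed form to test against.
* **Background and lock-mass ions** hold a constant per-scan level until
  a decay onset, then fall exponentially — the signature of reagent-ion
  depletion once analytes reach the source. Both kinds share one default
  decay rate (0.05 s⁻¹): ionization suppression acts on everything
  present in the source, and a separate, much slower rate would make the
  decaying trace itself resemble an extremely broad elution peak — a
  genuine ambiguity of any shape-based classifier that the defaults
  deliberately avoid probing.

Default conditions (`study_run_config()`): a 180 s run at the 0.15 s
scan interval (1200 scans); sample pulses centred at 90 s with σ = 6 s
and 20 000 expected total counts each; background at 50 counts/scan
decaying from 60 s; a lock-mass ion at 60 counts/scan; per-scan m/z
jitter of 1 mDa (σ); optional third-order polynomial mass-axis
distortion. The run length, pulse width and intensities are free
parameters of the instrument and sample; these values give peaks of
~10⁴ counts — the scale reported for single-cell ions — with elution
comfortably inside the run, and keep a full 100-run Monte-Carlo
affordable on one CPU within a test session.

Draw order is fixed (per ion: all Poisson counts, then all jitter
values) so a `(config, seed)` pair regenerates a run exactly.

What the generator does **not** emulate: isotope patterns (monoisotopic
peaks only), charge states above 1 (PTR gives singly charged ions),
profile-mode waveforms and the peak-detect/average duality of the
digitizer (the analysis consumes centroided counts), retention drift,
and ionization suppression between co-eluting species. Passing tests on
synthetic runs therefore demonstrate the correctness of the processing
chain under Poisson counting statistics — not robustness to matrix
effects or calibration drift in real acquisitions.

## Mass axis

TOF physics makes m/z proportional to the square of flight time, so
`fit_tof_calibration()` fits `sqrt(m/z)` as a third-order polynomial of
an abstract monotone flight-time axis (a `form = "direct"` switch fits
m/z itself). Four references interpolate exactly; more are fitted by
least squares, with residuals reported in mDa. The fitted polynomial
must be strictly increasing on its domain; violations are flagged.

Lock-mass correction is single-point and multiplicative: the reference
centroid is located in the co-added spectrum within ±20 mDa (default,
configurable) of its exact m/z, and all m/z values are rescaled by
`exact/observed`. One reference per polarity per run is the realistic
budget; a multiplicative factor is exact for a pure scale error and
first-order correct for small offsets at the reference mass. The
correction is idempotent to numerical precision. Built-in references
(P321, P621, tetracosenoic acid) recompute their exact m/z from formula
and ion species — never from a typed-in constant.

## Screening

Co-addition bins scan peaks on a 5 mDa grid (counts-weighted centroids,
counts conserved); mass-peak detection merges centroids closer than one
bin width and applies a count threshold. Five mDa matches the blank
tolerance and is about twice the per-scan jitter; it is configurable.

`detect_elution_peak()` operationalises "shows a bell-shaped peak":
moving-average smoothing (default 5 scans), baseline = median of the
smoothed trace, apex = its global maximum, acceptance iff the Poisson
signal-to-noise `(apex − baseline)/√(baseline + 1) ≥ 3` **and** the
trace crosses below half of (apex − baseline) on both sides of the apex
within the run. The two-sided half-height requirement is what separates
a pulse from a decaying plateau: a background trace has no left-side
crossing. The area is the sum of raw counts between the interpolated
half-height crossings.

One numerical property worth knowing: with a smoothing window much
shorter than the peak, the apex estimate is the maximum of a noisy
trace and overshoots the true apex, which raises the half-height level
and biases the area low by roughly 2 % at 10⁴-count peaks. A smoothing
window of about a quarter of the expected FWHM (e.g. 21 scans for a
14 s peak) removes the bias without distorting the width (the
moving-average widening of σ is `w²Δt²/12`, under 0.1 % here). The
package default stays at 5 scans — short windows are the safe choice
when peak widths are unknown — and the area-recovery tests use the
width-matched window.

Classification: *sample* iff a peak is detected; else *background* iff
the mean of the first 10 % of scans exceeds twice the mean of the last
10 % (and is positive); else *unclassified*. The decile fractions and
the 2× ratio are pragmatic defaults, configurable. Blank matching then
demotes any ion with a blank-run counterpart within ±5 mDa to
*blank-matched*, ties resolved to the lower m/z.

## Annotation

`normalize_structures()` prepares an SDF (V2000) database: per record it
keeps the largest connected fragment (desalting — counter-ions in salt
forms are disconnected fragments), substitutes isotope-labelled atoms
(D/T) with the principal isotope, fills implicit hydrogens using
standard MDL valences (smallest standard valence ≥ the bond-order sum),
computes the Hill-notation formula, drops masses > 1200 Da, and pools
identical formulas with a structure count. Kekulé structures are
assumed; records with aromatic/query bond orders or unknown elements
are skipped and counted. Structure parsing itself is delegated to
`ChemmineR`.

Ion species carry exact mass bookkeeping: `[M+H]+ = +1.0072765` Da
(proton), `[M]+ = −0.0005486` Da (electron loss), `[M−OH]+ =
−17.0032882` Da (hydroxide), and the exact negatives of these for
negative mode, so positive/negative deltas cancel exactly. `[M+NH4]+`
exists behind a switch (off by default — ammonium adduction is seen for
some standards, not in cell screening). Matching uses
`|observed − theoretical| ≤ 3 mDa` by default. The alternative reading
of the gate — each ion's own replicate SD as its tolerance — is
implemented (`gate = "replicate_sd"`); the fixed 3 mDa window is the
default because a replicate SD from n = 3 is itself too noisy to act as
a gate. Matches report `isomer_extra`, the number of further structures
sharing the formula: formula-level annotation cannot resolve isomers,
and the count makes that ambiguity explicit.

The packaged SDF generator (`make_structure_fixture()`) emits fatty-acid
records with deliberate corner cases — a sodium salt as a two-fragment
record, a d3-labelled acid, positional isomers sharing C20H32O2, an
over-long chain beyond 1200 Da — so every normalisation branch is
exercised without shipping a database.

## Quantitation

Ion counting is Poisson, so `N` counts carry a relative error `1/√N`;
100 counts ↔ 10 %. The response curve is a least-squares line through
the origin (`slope = Σ(a·y)/Σ(a²)`): at zero amount a blank-corrected
signal is zero, and the LOQ definition — the amount yielding 100
counts, `LOQ = 100/slope` — presumes proportionality. A free-intercept
switch exists for diagnostics. Replicate spread is reported as RSD with
the sample (n−1) standard deviation, the convention that reproduces the
reported spread of the triplicate counts (22589, 1352, 2568 → 135 %).
Amount estimates are `counts/slope`; at zero counts the amount is zero
and the counting error undefined.

## Degenerate inputs and tie-breaks

* Empty co-add time range → empty spectrum, not an error; empty blank →
  screening passes through unchanged.
* All-zero XIC → *unclassified* (no peak, no decay evidence).
* Zero-count bins centroid at the unweighted mean (cannot weight by
  zero).
* Equidistant blank matches tie-break to the lower m/z; fragment-size
  ties in desalting keep the first fragment.
* Calibration inversion requires a monotone model and refuses otherwise.

## Problem sizes used in the test-bench

Monte-Carlo assertions use 100–200 seeded replicates of the default
180 s / 1200-scan run (classification recovery, count conservation,
Poisson expectation, LOQ recovery), 1000-ion random lists for the
brute-force matching oracles, and a few dozen SDF records for the
annotation branches; each suite runs in seconds on one CPU.

## Known limitations

* The elution-peak detector finds the single global maximum; co-eluting
  multi-modal XICs are not deconvolved.
* The half-height area estimator's small negative bias at short
  smoothing windows (above) is inherent to max-of-noise apex
  estimation; width-matched smoothing is the recommended remedy.
* Lock-mass correction is a single scale factor; it cannot fix
  mass-dependent (polynomial) distortion residuals within a run.
* Implicit-hydrogen filling covers neutral Kekulé structures with
  standard valences; charged atoms and aromatic bond records are
  skipped rather than guessed.
* Amount estimates inherit the response curve's compound specificity:
  applying one compound's curve to another ion's counts is only an
  order-of-magnitude statement.
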