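---
title: "SIP-RACS analysis: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SIP-RACS analysis: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipracs)
```

## The problem

In DNA stable-isotope probing (SIP), a microbial community is incubated with
a ¹³C-labelled substrate; organisms that assimilate the substrate build the
heavy isotope into their DNA, which raises its buoyant density (BD) in a CsCl
gradient. After isopycnic ultracentrifugation the gradient is collected as a
series of fractions (14 per tube here), and the DNA of active degraders is
over-represented in the *heavy* fractions of the ¹³C treatment relative to a
¹²C control. Raman-activated cell sorting (RACS) then confirms assimilation
at single-cell resolution: cells that incorporated ¹³C show a redshift of the
phenylalanine ring-breathing band from ~1001 cm⁻¹ towards ~968 cm⁻¹, and such
cells can be sorted for genomics and cultivation.

`sipracs` implements the complete desk-side chain — gradient modelling,
enrichment calling, spectral classification, and cultivation/consortium
design — together with seeded simulators that stand in for the wet-lab
inputs.

## The gradient model and window detection

Each taxon's DNA mass is modelled as a Gaussian over BD, centred at

```
mu = bd_unlabelled_mean + atom_fraction * bd_full_label_shift
```

with within-taxon dispersion `bd_within_taxon_sd`. Defaults:

* `bd_unlabelled_mean = 1.7066` g/ml — the midpoint of the conventional
  light window (1.7042–1.7089 g/ml).
* `bd_full_label_shift = 0.0311` g/ml — the distance between the light and
  heavy window midpoints (1.70655 to 1.73765 g/ml). The source observations
  never state the full-label shift directly, so the shift that maps an
  unlabelled taxon onto the heavy window is the natural choice.
* `bd_within_taxon_sd = 0.006` g/ml — narrow enough that the two windows
  separate cleanly, consistent with a distinct heavy 16S copy peak in
  labelled treatments.

The mass is discretised onto the 14-point BD grid using bin edges halfway
between grid points (outer edges open), which conserves each taxon's total
mass exactly. Multiplicative lognormal noise (default log-sd 0.2, a typical
compositional replicate-to-replicate scatter; no value is stated anywhere, so
this was chosen once and kept) is applied per taxon and fraction and the
per-taxon totals are then restored, so conservation holds to 1e-9 by
construction. Both treatments consume the same seed, which makes a
zero-labelling experiment exactly symmetric between ¹²C and ¹³C — a property
the test suite exploits.

`identify_windows()` normalises each run's 16S copies to its total (the two
treatments may differ in recovery), then takes as the **heavy window** the BD
span of the longest contiguous block of fractions above `bd_split = 1.72`
g/ml where the ¹³C signal exceeds the ¹²C signal by `ratio_min = 1.5`. The
source describes this comparison only qualitatively, so both knobs are
explicit parameters with a printed-window fallback (`fallback = TRUE`) when
no block qualifies. The **light window** rule ("the top-copy contiguous
block") is likewise underdefined; we take the contiguous run of sub-split
fractions containing the ¹²C copy peak, extended while copies stay above 50%
of the peak — a half-maximum criterion familiar from peak integration.
Windows are closed intervals; a window may degenerate to a single density
when one fraction qualifies (the strictly-ordered variant would reject the
legitimate "all copies in the top fraction" case).

## The REF statistic

For each ASV,

```
REF = (A13_heavy / A13_light) / (A12_heavy / A12_light)
```

where each `A` is the **unweighted mean** of the ASV's relative abundance
over the fractions classified into that window for that treatment. The mean
(rather than a sum or copy-weighted mean) is scale-stable across window
sizes; whether the original analysis averaged replicates or weighted by qPCR
copies is unstated, so both the aggregation and a copy-weighting alternative
are left to the caller by supplying a modified fraction table. A pseudocount
(default 1e-6) is added to all four terms *only when at least one of them is
zero*, so worked examples with positive abundances are reproduced exactly
(3.09 and 3.34 for the two active ASVs).

Calling: ASVs are ranked by mean relative abundance over all windowed
fractions of both treatments (descending, ties broken lexicographically —
the ranking basis for "top 100" is not defined at source, so it is documented
and configurable here), and an ASV is *active* when its rank is at most
`top_n = 100` **and** REF strictly exceeds `threshold = 2.0` (strict, per the
"REF > 2.0" rule). REF is scale-invariant within each treatment pair and
inverts when the treatments are swapped; both properties are enforced by
tests.

## Raman preprocessing and classification

The chain is order-fixed: asymmetric-least-squares (ALS) baseline correction,
then vector normalisation to unit Euclidean norm, making band intensities
comparable across cells and invariant to acquisition gain.

* **ALS** (`lam = 1e5`, `p = 0.01`, 10 iterations): the original spectra were
  preprocessed in a proprietary package with unstated parameters; ALS with
  these canonical settings is the standard open equivalent. The solver
  exploits the pentadiagonal structure of the penalised system (banded
  Cholesky in C++), so classifying an 800-cell screen takes seconds. ALS is
  only numerically idempotent: a second pass changes a corrected trace by
  well under 1% (RMS, relative to the input range), because the asymmetry
  always seeks a baseline slightly below the data.
* **Band detection**: local maxima (strictly greater than both neighbours;
  plateau points are not peaks) with topographic prominence; within the
  labelled window 955–980 cm⁻¹ and the unlabelled window 990–1010 cm⁻¹ the
  highest-prominence peak is retained if its prominence reaches `k = 3` times
  the noise scale, estimated as the MAD of first differences in the band-free
  1500–1700 cm⁻¹ region (the simulator's accessory bands at 1090 and 1450
  cm⁻¹ deliberately avoid it). The labelled window brackets both reported
  redshift values — the "to 968 cm⁻¹" shift and the "−37 cm⁻¹" shift (which
  would imply 964–966 cm⁻¹); that internal inconsistency in the source is
  recorded, not resolved, and both band positions are parameters.
* **Decision rule**: a cell is labelled when a labelled-window band exists
  and is taller than any unlabelled-window band. The reported shift is
  relative to the 1001 cm⁻¹ unlabelled biomarker.
* **Group comparison**: one-way ANOVA of the normalised intensities at 968
  and 1001 cm⁻¹ across labelled-¹³C, unlabelled-¹³C and ¹²C cells.

## Consortium and medium design

`recommend_medium()` applies a packaged, editable keyword-rule table:
vitamin-metabolism genes (A, B1, B2, B3, B6, B7, B12, lipoic acid) trigger a
10 ml/L vitamin stock; trace-metal transport genes (Ca, Cu, Zn, Co, Na, Mo,
Ni) a 10 ml/L mineral stock; an aminoglycoside-resistance gene 5 mg/L
streptomycin (the antibiotic suppresses competitors the target resists); and
L-lactate dehydrogenase 50 mM L-lactate. The source names gene families, not
identifiers, hence keyword matching; each supplement records the annotation
that triggered it.

`design_ratios()` snaps the log2 abundance ratio of two strains to the
nearest of the tested CFU mixing ratios {2:1, 1:1, 1:2}; exact midpoints
(within 1e-9 on the log2 scale, absorbing floating-point noise) snap toward
1:1. `degradation_efficiency()` reports raw removal `100 (c0 − ct)/c0`,
clipped at 0 from below; whether the original percentages subtract sterile
control losses is unstated, so a control-corrected mode exists but is off by
default.

## What the simulators emulate — and what they do not

The gradient simulator reproduces the *structure* the analysis assumes:
Gaussian BD profiles, the BD shift with atom fraction, compositional
renormalisation per fraction, and a copy total per fraction. It does **not**
model PCR/chimera bias, replicate microcosms, GC-dependent BD (the
Schildkraut relation), or read-level sequencing noise. The spectra simulator
produces pseudo-Voigt bands (50/50 Gaussian/Lorentzian, FWHM 8 cm⁻¹ — a
typical Raman lineshape; the source is silent on lineshape), a polynomial
fluorescence baseline, and white Gaussian noise (default sd 0.05 against a
unit-amplitude band, i.e. SNR ≈ 20, a realistic single-cell acquisition); it
does not model cosmic rays, detector response, wavenumber miscalibration or
partial labelling with mixed bands. A green recovery test therefore
establishes that the pipeline inverts its own stated generative model — not
that it would perform identically on instrument data.

Ground-truth labels live only in spectrum metadata and the fixture manifest;
no classifier or caller reads them, so recovery tests are leakage-free.

## Numerical choices and degenerate inputs

* Mass conservation tolerance 1e-9; unit-norm tolerance 1e-9.
* A constant-BD gradient is flagged `degenerate` rather than fitted.
* An all-zero spectrum cannot be normalised and is rejected; a flat spectrum
  yields no band calls.
* REF with all four abundances zero and zero pseudocount is undefined and
  rejected.
* Fewer ASVs than `top_n` reduces `top_n` with a warning.
* Readers reject negative abundances, non-numeric cells (with row/column in
  the message), duplicated `(cell_id, wavenumber)` pairs, and cells with
  fewer than 50 points; column sums off unity by more than 1e-4 warn.

## Known limitations

* Window detection assumes matched fraction numbers across treatments and a
  single contiguous heavy region; split heavy peaks would be truncated to the
  longest block.
* REF is a point statistic; no replicate-level variance or bootstrap is
  provided, matching the original point-value reporting.
* The medium rule table is keyword-based and English-language; KO/EC-aware
  matching would need an annotation ontology.
* ALS endpoints can flex on very short spectra; the readers' 50-point minimum
  keeps the solver well-conditioned.
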