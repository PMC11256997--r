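# sipracs

Analysis toolkit for **¹³C DNA stable-isotope probing (SIP)** experiments
coupled to **Raman-activated cell sorting (RACS)**, aimed at microbial
ecologists who want to identify which community members actively assimilate a
labelled substrate (e.g. the PAH phenanthrene), confirm the assimilation at
single-cell resolution, and turn the findings into cultivation and consortium
designs.

The package covers the full desk-side analysis chain:

1. **Gradient modelling** — fit the buoyant density (BD) vs fraction-number
   relationship of a CsCl gradient and detect the *light* and *heavy* DNA
   windows by comparing total-copy-normalised 16S qPCR profiles between the
   ¹²C control and ¹³C treatment (packaged defaults: light 1.7042–1.7089,
   heavy 1.7342–1.7411 g/ml).
2. **Enrichment calling** — the relative enrichment factor per ASV,

   REF = (A13_heavy / A13_light) / (A12_heavy / A12_light),

   where each *A* is the ASV's mean relative abundance over the fractions in
   that window; ASVs with REF > 2.0 among the top 100 ASVs are called active
   degraders.
3. **Single-cell Raman classification** — asymmetric-least-squares baseline
   correction, vector normalisation, and prominence-based detection of the
   phenylalanine ring-breathing band: ~1001 cm⁻¹ in unlabelled cells,
   redshifted to ~968 cm⁻¹ upon ¹³C incorporation. Labelled cells are listed
   in a sorting manifest.
4. **Consortium design** — genome-directed medium supplements (vitamin and
   mineral stocks, 5 mg/L streptomycin, 50 mM L-lactate) from gene
   annotations, two-strain inoculation ratios snapped to {2:1, 1:1, 1:2}, and
   degradation-efficiency accounting.
5. **Synthetic data** — seeded simulators for two-treatment SIP gradients and
   single-cell Raman spectra, with ground truth stored in metadata, replacing
   the wet-lab inputs so the whole chain is testable offline.

## Worked example

```r
library(sipracs)

# REF for the two active degraders, from their window-aggregated abundances
compute_ref(0.309, 0.100, 0.050, 0.050, pseudocount = 0)
#> [1] 3.09
compute_ref(0.334, 0.100, 0.080, 0.080, pseudocount = 0)
#> [1] 3.34

# a 100-taxon community with two fully 13C-labelled taxa
sim <- simulate_gradient_experiment(paper_mimic_gradient_config(seed = 1))
w <- identify_windows(sim$run_12C, sim$run_13C)
w
#> fraction windows (g/ml): light [1.7000, 1.7100], heavy [1.7300, 1.7550]

calls <- call_active_degraders(sim$asv_table, w, sim$fractions)
calls$asv_id[calls$active]
#> [1] "ASV_029" "ASV_037"

# single-cell screen: 800 cells, 60 truly labelled
spectra <- simulate_spectra(sim_spectra_config(seed = 7, n_cells = 800,
                                               n_labelled = 60))
label_calls <- classify_cells(spectra)
sum(label_calls$labelled)
#> [1] 60

# genome-directed medium design
recommend_medium(c("aminoglycoside resistance protein",
                   "L-lactate dehydrogenase"))
#> medium recipe — base: modified minimal (MM) medium
#>   + 5 mg/L streptomycin  [aminoglycoside_resistance: aminoglycoside resistance protein]
#>   + 50 mM L-lactate  [lactate_dehydrogenase: L-lactate dehydrogenase]

design_ratios(0.10, 0.05)
#> consortium design: JB-1:JB-2 = 2:1 (log2 abundance ratio 1.000)
```

The `identify_windows()` output above means the detected heavy window
(1.730–1.755 g/ml) brackets the conventional heavy range and the calling step
recovered exactly the two taxa that were configured as labelled; the census
classification recovered all 60 labelled cells with no false positives.

An end-to-end run over on-disk files (ASV TSV, fraction CSV, spectra CSV) is
available through `write_fixture()`, `pipeline_config()` and
`run_pipeline()`, which writes `windows.json`, `ref_calls.tsv`,
`label_calls.tsv`, `sorting_manifest.txt`, `medium.json`, `ratios.json` and a
JSON report.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package: the two worked REF statistics; the detected band positions on
noiseless labelled and unlabelled synthetic cells after the full
preprocessing chain; and the number of cells called labelled when the
800-cell screening census (60 truly labelled, default noise, seed 7) is
simulated and classified. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/sip-racs-methods.Rmd` documents the models, the defaults and their
rationale, what the simulators do and do not emulate, and known limitations.
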