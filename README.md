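# phagoquant

Rule-based quantification of high-content microglial assays, built for
studies of phagocytosis, autophagy and inflammatory signalling in
iPSC-derived microglia — and for anyone who needs the same readouts from
multi-channel 2D fluorescence fields with a fully testable, scriptable
pipeline instead of a commercial image-analysis ruleset.

## What it computes

**Phagocytosis (beads/cell).** Nuclei are detected by a fluorescence
threshold, hole filling, morphological smoothing (shrink/grow by 2 px), and
a size + shape classification: only objects whose *elliptical fit* — the
Jaccard overlap with their moment-equivalent equal-area ellipse — exceeds
0.8 count as nuclei. Accepted nuclei are expanded by 50 px into disjoint
perinuclear zones; pHrodo particles are detected inside the zones by
local-contrast (white top-hat) segmentation, and a particle is retained only
when its mean intensity is **strictly more than 2-fold over background**.
The per-field phagocytic index is

    beads/cell = retained spots / accepted nuclei,

aggregated as mean ± SEM per genotype and timepoint over the 15-minute,
0–135 min acquisition grid.

**Autophagy.** Puncta-per-cell counts (p62/LC3-style), and tandem
mCherry–GFP reporter classification: dual-positive puncta are
autophagosomes, mCherry-only puncta are autolysosomes (GFP quenched after
lysosomal fusion); their ratio reports autophagic flux.

**NF-kB translocation.** Per cell, the pixels above an Otsu threshold on
the NF-kB channel colocalized with the nucleus, plus a continuous nuclear
signal fraction.

**GFP-Trap TMT interactome.** From an 8-plex protein-group table (4 control
vs 4 GFP channels): contaminant/reverse/min-2-peptide filtering, log2
transform, per-protein Welch's *t* (closed form, Welch–Satterthwaite df),
permutation-based FDR at 1% and 5% over the balanced label relabelings, and
interactor calling as *fold enrichment > 2.0 AND 1% FDR* (top set: fold ≥
3.0, k = 50).

Every stage is exercised against a synthetic generator
(`simulateField`, `simulateReporterField`, `simulateNfkbField`,
`simulateTmt`) that emits complete ground truth, so recovery, filter
boundaries and FDR calibration are all testable without any external data.
See the methods vignette (`vignettes/phagoquant-methods.Rmd`) for the
models, parameter provenance and design decisions.

## Worked example

```r
library(phagoquant)

cfg <- imagingSimConfig(nNuclei = 12, fieldShape = c(256, 256))
sim <- simulateField(cfg, genotype = "fast", timepoint = 90, seed = 42)
q   <- quantifyPhagocytosis(sim$field)
q$nuclei
#> NucleusSet: 12 objects, 12 accepted as nuclei
q$record
#>  genotype condition timepoint n_nuclei n_spots beads_per_cell
#>      fast untreated        90       12      54            4.5
```

All 12 simulated nuclei were accepted by the size/shape gates, 54 particles
survived the 2-fold filter, and the field's phagocytic index is 4.5
beads/cell — identical to the generator's truth for this field (54 true
particles, 12 nuclei; the 8 sub-threshold decoys were all rejected), and
consistent with the kinetic mean 6·(1−e^(−0.03·90)) ≈ 5.6 for a single
Poisson field.

```r
se  <- simulateTmt(tmtSimConfig(nProteins = 500, nTrueInteractors = 10,
                                interactorLog2fc = 3, backgroundLog2Sd = 0.3),
                   seed = 1)
res <- tmtEnrichment(se, seed = 1)
head(res[order(res$qvalue, -res$log2fc),
         c("id", "log2fc", "t", "p_value", "qvalue")])
#>         id   log2fc        t      p_value      qvalue
#> 181 P00187 3.355475 20.52891 8.466313e-06 0.003676471
#> 456 P00471 3.159996 10.87537 1.695706e-04 0.003676471
#> 297 P00307 3.068487 20.76149 1.317316e-06 0.003676471
#> ...
callInteractors(res, foldMin = 2, fdrLevel = 0.01)
#> 10 ids — exactly the spiked truth set
```

A thin command-line front-end is included at
`inst/scripts/phagoquant.R`:

```sh
Rscript inst/scripts/phagoquant.R phago --out out/ --seed 1 --fields 5 --report
Rscript inst/scripts/phagoquant.R interactome --table groups.tsv --design design.csv --out out/
```

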