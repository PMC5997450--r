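# neuromast

Quantitative analysis of the synaptic microcircuit of the zebrafish
lateral-line neuromast, reconstructed from serial blockface
electron-microscopy (SBFSEM) annotations.

Each neuromast contains 8–20 mechanosensory hair cells in two
subpopulations, one sensitive to *rostrad* (head-ward) and one to *caudad*
(tail-ward) water motion, innervated by roughly nine afferent axonal
branches and one efferent terminal. Afferent neurons wire with striking
polarity specificity: nearly every ribbon synapse, and most of the membrane
contact area, connects a hair cell to terminals of the matching
sensitivity. This package implements the full quantitative pipeline for
such reconstructions, for connectomics researchers who start from
segmented contour annotations rather than raw image volumes:

- **Contact geometry** — membrane contact areas from per-section contour
  traces (nm coordinates, 30 nm sections, 6 nm pixels). Two membranes are
  in contact wherever their traces are separated by *less than 60 nm* (the
  tracing precision) *and no other trace intervenes*; per-section contact
  lengths integrate to areas as `area = Σ length × section thickness`. A
  dense-sampling brute-force oracle verifies the fast algorithm.
- **Circuit annotation** — efferent identification (contacts every mature
  hair cell, zero ribbon appositions, vesicle-filled bouton plus
  postsynaptic cistern), entering-terminal flags (crossed the basal
  lamina), ribbon-partner assignment (largest apposition area wins; areas
  within 10% are split 0.5/0.5), and terminal polarity preference (majority
  of ribbon weight, contact-area fallback on ties).
- **Connectome statistics** — polarity specificity of ribbons / contacts /
  perisynaptic associations stratified by hair-cell age, redundancy
  (partners per cell), dominance (the terminal holding the largest share of
  a cell's or subpopulation's synapses), sibling exclusivity, shared
  innervation across anteroposterior positions, branch counts, and
  two-tailed Student's *t* tests with SEMs.
- **Age classification** — a from-scratch CART decision tree (Gini
  impurity, axis-aligned splits, 70/30 train/test split) assigning
  post-mitotic age classes (0–5 h, 5–15 h, >15 h) from four morphometric
  features: cell area, cell volume, total ribbon volume, apical contact
  area.
- **Synthetic data** — generators for connectomes (wild-type, *trilobite*,
  Notch-overexpression wiring rules), contour-trace stacks with closed-form
  contact areas, and age cohorts, each with a planted ground-truth ledger
  so every stage is testable without EM volumes.

## Worked example

```r
library(neuromast)

g    <- generate_connectome(genotype_model(), seed = 42)   # one wild type
conn <- annotate_connectome(g$connectome)
print(conn)
#> Neuromast connectome 'SYN42' (wild-type)
#>   hair cells : 10 (6 mature)
#>   terminals  : 11 (10 afferent, 1 efferent, 0 unclassified)
#>   ribbons    : 21 (21 assigned)
#>   contacts   : 32 pairs, 2.96e+06 nm^2 total
#>   perisynaptic pairs: 30

specificity_stats(conn)
#> Specificity report (grouping: polarity)
#>   ribbons: 21 total, 1 apposed to opposite-preference terminals
#>   weighted ribbon specificity : 0.952
#>   contact-area specificity    : 0.839
#>   perisynaptic specificity    : 0.577
```

The ten hair cells sit in five sibling pairs; the annotation stage
recovered exactly one efferent terminal (so 10 entering branches) and
assigned all 21 ribbon synapses. One ribbon was apposed to a terminal of
the opposite polarity preference — this specimen's draw from the planted
specificity-error rate of 4/344 — giving a weighted ribbon specificity of
0.952 for this single organ; contact-area specificity (0.84 here) is
lower because membrane contact is planted as less selective than synapse
formation, and perisynaptic occupancy (~0.5–0.6) is essentially unselective,
as both polarities occupy each cell's compartment.

For a full multi-specimen run with JSON reports, GraphML wiring diagrams,
and a reproducibility manifest:

```r
res <- run_pipeline(run_config(mode = "synthetic", n_specimens = 8,
                               seed = 7, out_dir = "out"))
```

or from a shell: `Rscript inst/scripts/run_pipeline.R --mode synthetic
--genotype wild-type --seed 7 --out out/`. Loading measured annotation
tables instead uses `--mode tables --input dir1/,dir2/` with the TSV
schema documented in `?load_annotation_tables`.

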