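# sporoquant

Quantification pipelines for metabolic differentiation and mother-cell →
forespore metabolite trafficking in sporulating *Bacillus subtilis*.

## The problem

Sporulation begins with an asymmetric division that yields two sister cells
in one sporangium: a small forespore, which becomes the dormant spore, and a
large mother cell, which engulfs and nurtures it. The two cells divide
metabolic labour — the forespore sheds biosynthetic capacity while the
mother cell keeps supplying it with building blocks through the SpoIIIA–SpoIIQ
(A-Q) intercellular channel. Testing that picture quantitatively requires a
set of single-cell measurements that this package implements for anyone
working with fluorescence microscopy of sporangia and cell-specific
proteomics:

- **Segmentation & pairing** — dual-threshold segmentation of the FM 4-64
  membrane channel (high threshold → forespores via their bright double
  membrane, low threshold → whole sporangia, subtraction → mother cells) and
  strict distance-then-orientation pairing of forespores to mother cells.
- **Ratiometry** — background-subtracted forespore/mother-cell reporter
  concentration ratios, with per-pixel-mean or volume-normalized
  (spherocylinder / prolate-spheroid) concentration proxies, plus depletion
  time courses normalized to 1 at the first frame.
- **BONCAT** — per-cell protein-synthesis readout: sum-projected sections,
  cell mean minus (background mean + 2 SD), divided by the cell-type
  reference median.
- **Engulfment & phase-bright scoring** — engulfed forespores from the
  permeable-minus-impermeable dye difference image with DAPI exclusion;
  phase-bright spores strictly above 0.1 AU background-subtracted phase
  intensity.
- **FRAP/FLIP** — corrected fluorescence recovery
  `cFR(t) = (r(t) − r_b)/(r_0 − r_b)` anchored at 1 (prebleach) and 0
  (first postbleach); acquisition-bleaching standard curves from distal
  cells; corrected fluorescence-loss series; and exchange-rate estimation on
  the two-compartment model `dA_fs/dt = k (c_mc − c_fs)`, whose
  concentration difference decays as `exp(−k (1/v_fs + 1/v_mc) t)`.
- **Cell-specific SILAC** — heavy-arginine incorporation fractions of
  mother-cell (σE/σK) vs forespore (σF/σG) peptides with vegetative
  (SigA/SigH/Spo0A) precedence, Wilson 95% intervals, and fold changes over
  a control.

Because the raw data behind these assays are not deposited in
machine-readable form, the package ships seeded generators that emit
ground-truthed synthetic microscopy fields, two-compartment photobleaching
traces, and SILAC peptide tables; every estimator is validated against that
ground truth.

## Worked example

Simulate a small field, segment and pair it, and measure concentration
ratios (true forespore:mother-cell ratio 50/200 = 0.25):

```r
library(sporoquant)

p <- sporangium_image_params(n_sporangia = 3, reporter_conc_fs = 50,
                             reporter_conc_mc = 200, seed = 11)
sim <- generate_sporangium_image(p)
parts <- segment_membrane(sim$stack)
mothers <- derive_mother_cells(parts$whole_cells, parts$forespores, sim$stack)
pairs <- pair_sporangia(parts$forespores, mothers)
pairs
#> segmented_sporangia: 3 pairs (0 forespores / 0 mother cells unmatched)

bg <- estimate_background(sim$stack, "reporter")
ratios <- concentration_ratio(pairs, sim$stack, bg)
round(ratios[, c("fs_label", "mc_label", "fs_conc", "mc_conc", "ratio")], 3)
#>   fs_label mc_label fs_conc mc_conc ratio
#> 1        1        1  51.024 195.592 0.261
#> 2        2        2  50.082 198.633 0.252
#> 3        3        3  57.771 197.063 0.293
```

Each row is one sporangium: background-subtracted mean reporter
concentrations (AU) for forespore and mother cell and their ratio — the
estimates scatter around the true 0.25 under Poisson + read noise.

Simulate a FRAP experiment (forespore bleach, exchange coefficient
k = 0.01 fL/s) and recover the rate from the corrected fluorescence
recovery:

```r
frap <- generate_photobleach_trace(photobleach_params(k = 0.01, seed = 11))
cfr <- compute_cfr(frap$trace)
estimate_exchange_rate(cfr, v_fs = 0.35, v_mc = 3)
#> exchange_fit: k = 0.008552 fL/s (rate 0.02728 /s, plateau 0.896, RMS 0.138)
```

`rate = k (1/v_fs + 1/v_mc)` is the relaxation rate of the concentration
difference; the plateau 0.896 = v_mc/(v_fs+v_mc) is where recovery saturates
because bleached molecules are gone from the shared pool. At measurement
noise SNR ≈ 10 a single replicate lands within ~15% of the true k; medians
over replicate cohorts are tested to 10%.

A full simulate-then-analyse pipeline (images, FRAP, FLIP, SILAC) is driven
by a YAML config:

```sh
Rscript inst/scripts/sporoquant.R inst/extdata/demo_pipeline.yaml --out demo_out
```

which writes per-stage CSV/TIFF/JSON outputs and a run manifest with seeds,
record counts and output hashes.

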