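# mtarray

Quantification of paraxial microtubule arrays from track and trace data.

When muscle cells differentiate they elongate and rebuild their microtubule
cytoskeleton into a *paraxial array* — filaments running parallel to the long
axis of the cell — and the degree of that alignment tracks the cell's ability
to elongate and fuse. mtarray is for cell biologists who already have the
upstream image analysis done (traced filaments, tracked comets and marks,
annotated filament encounters, gradient fraction readings) and need the
downstream quantification to be explicit, tested and reproducible:

* **Orientation** — angles of filament segments and growth tracks to the cell
  axis; the Kuiper alignment index
  `K = d1 + d2 = sup(F̂ − F) + sup(F − F̂)` of the weighted angle ECDF
  against the uniform CDF on the axis-referenced support; band fractions and
  an axial asymmetry index; per-track growth speed and duration.
* **Motility** — sliding-event detection from photoactivated-mark
  trajectories (events score when a mark moves > 0.5 µm from its rest
  reference; fast events exceed 700 nm/s), paraxial / off-axis / looping
  classification, event frequencies, and decomposition of fluorescence
  dissipation into depolymerisation, transport and bleaching rates via
  single-exponential half-life fits (t½ = ln 2 / k) under a
  taxol / azide / taxol+azide drug design.
* **In vitro assays** — zippering-versus-crossing classification of dynamic
  filament encounters (≥ 2 µm co-alignment past the contact, polarity-aware;
  antiparallel above 90°), angle-resolved zippering histograms, gliding
  speeds, bundle survival under motor forces, and intensity-based bundle
  scoring (> 2.3 µm and > 3× a single filament).
* **Hydrodynamics** — glycerol-gradient calibration with standards,
  sedimentation coefficients from fraction profiles, and frictional ratios
  `f/f_min = 0.00361 · M^(2/3) / S`.
* **Morphology** — tip-to-tip cell length statistics, fusion index
  (fraction of cells with ≥ 3 nuclei), and the orderliness-versus-length
  regression of K against mean cell length.
* **Synthetic data** — seeded generators for every input class with ground
  truth (von Mises filament networks, Poisson sliding events, separable decay
  channels, angle-dependent zippering, exponential bundle breakup, Gaussian
  gradient bands), so the whole pipeline is testable without external data.

## Worked example

```r
library(mtarray)

# a synthetic differentiated-cell filament network, kappa = 4, 150 filaments
cfg <- synth_config(seed = 1, kappa = 4, n_filaments = 150)
net <- gen_filament_network(cfg)
smp <- filament_angles(net$filaments, net$geometry)
kuiper_statistic(smp)
#> <kuiper_result> K = 0.6773 (d1 = 0.3406, d2 = 0.3368), n_eff = 1195
fraction_within(smp, 15)   # 0.709: ~70% of filament length within 15 deg of the axis
asymmetry_index(smp)       # 0.99: essentially all mass in the axial quadrants

# sliding events from photoactivated marks
mk <- gen_mark_trajectories(synth_config(seed = 1, slide_rate = 1, n_marks = 40))
events <- do.call(rbind, lapply(split(mk$marks, mk$marks$region_id), function(tr) {
  ev <- detect_events(tr)            # 0.5-um displacement rule
  ev[, setdiff(names(ev), "path")]
}))
event_frequency(events, n_regions = 40, observed_time_min = 1)$rate
#> 1.225 events per activated region per minute

# shape analysis of a 99-kDa protein sedimenting at 3.6 S
frictional_ratio(99000, 3.6)
#> <sedimentation_result> S = 3.6 S, M = 9.9e+04 Da, S_max = 7.73 S, f/f_min = 2.15
```

`K` near 0.68 says the simulated array is strongly aligned (an isotropic
network of this size gives K ≈ 0.1); an `f/f_min` of 2.1–2.2 says the protein
is far from a compact sphere — a highly elongated monomer.

The full pipeline runs from one config and writes per-stage CSVs, a
consolidated `summary.json` (byte-identical for a given seed) and a Markdown
report:

```r
run_pipeline(list(seed = 1, outdir = "out"))
write_report("out/summary.json", "out/report.md")
```

See `vignettes/microtubule-array-quantification.Rmd` for the models, default
parameters and design decisions.

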