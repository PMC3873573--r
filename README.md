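# aggflux

Quantifying the flux of huntingtin exon 1 (Httex1) molecules between
monomer, oligomer and inclusion states in cell populations.

Expansion of the polyglutamine (polyQ) tract of Httex1 beyond ~36 glutamines
drives aggregation into micrometre-scale inclusions, and how that flux
relates to cell death is a central question in Huntington-disease cell
biology. `aggflux` re-implements, as a tested and reusable R pipeline, a
flow-cytometry and biophysics platform for measuring that flux in
transfected Neuro2a-like cells:

* **Pulse-shape analysis (PulSA)** — a cell whose Cerulean-tagged Httex1 is
  concentrated in an inclusion transits the cytometer laser as a near-point
  source, giving a narrower, taller pulse than a cell with dispersed
  protein. Gating pulse width against height separates inclusion-bearing
  (`i`) from dispersed (`ni`) cells.
* **A bicistronic reporter** — membrane-anchored mKate2-F is translated from
  the same transcript as Httex1-Cerulean, so transfected cells that have
  died and *leached* their cytosol (L population) remain detectable, as do
  free inclusions with cell remnants (D population, high Cerulean / low
  mKate2). With the membrane-permeability stain SYTOX, total death is
  estimated as

  ```
  death rate = ( |SYTOX+|  +  |SYTOX- ∩ L|  +  |SYTOX- ∩ D| ) / ( |M| + |L| + |D| )
  ```

  with each D event counted as the remnant of one cell.
* **FlAsH reactivity** — the biarsenical dye binds a tetracysteine tag on
  Httex1 only in the monomer, so poor-FlAsH-reactive cells without an
  inclusion (PFR,ni) mark an oligomer-enriched intermediate state.
* **ls-g\*(s) sedimentation-velocity analysis** — radial scans are fitted
  with a distribution of non-diffusing step boundaries (boundary position
  `r_m·exp(ω²st)`, plateau diluted by `exp(−2ω²st)`) by non-negative least
  squares with a smoothness penalty, plus the Svedberg solvent correction to
  s20,w. In 2 M sucrose at 3,000 rpm only inclusions sediment, which turns a
  two-component fit (flat + boundary) into an inclusion-fraction estimator.
* **Size-exclusion chromatography** — a large-pore (S1000-class) column
  occludes inclusions and resolves the broad oligomer peak from the monomer
  peak; a two-Gaussian fit quantifies both pools.
* **The three-class molecular partition** combines the two assays:
  `p_mono = (1−p_inc)·m/(m+o)`, `p_olig = (1−p_inc)·o/(m+o)`.

Because no raw data are deposited with the source study, the package ships a
first-class stochastic simulator of the whole platform — cell populations
with expression-, time- and polyQ-dependent inclusion kinetics, chaperone
(hsp40/hsp70) treatment arms, and instrument models for cytometer pulses,
ultracentrifuge scans and chromatograms — so that every analysis stage is
exercised against known ground truth.

## Worked example

Simulate a 46Q arm at 46 h post-transfection, derive every gate from
simulated control tubes, and read out death rates and the molecular
partition:

```r
library(aggflux)
panel <- panel_config()

# 25Q (non-aggregating) control arm: calibration for every reference gate
ctl_cells <- simulate_population(sim_config(polyQ_length = 25, n_cells = 3000,
                                            time_points = 46, seed = 3))
ctl_events    <- cells_to_events(ctl_cells, panel, seed = 4)
untransfected <- cells_to_events(ctl_cells[0, ], panel,
                                 n_untransfected = 2000, seed = 5)
unstained     <- cells_to_events(ctl_cells[0, ], panel, n_untransfected = 2000,
                                 stain_sytox = FALSE, seed = 6)

# 46Q sample arm at 46 h
cells  <- simulate_population(sim_config(polyQ_length = 46, n_cells = 5000,
                                         time_points = 46, seed = 11))
events <- cells_to_events(cells, panel, n_untransfected = 400,
                          n_particles = 200, seed = 12)
gates  <- derive_gateset(events, untransfected, unstained, ctl_events)
labels <- apply_gates(events, gates)

dr <- death_rate(labels, "all")
cat(sprintf("death rate (all): %.3f  [SYTOX+ %d, SYTOX-L %d, SYTOX-D %d of %d]\n",
            dr$rate, dr$n_sytox_pos, dr$n_leached_sytox_neg,
            dr$n_debris_sytox_neg, dr$denominator))
cat(sprintf("death rate (i):   %.3f\n", death_rate(labels, "i")$rate))
cat(sprintf("death rate (ni):  %.3f\n", death_rate(labels, "ni")$rate))
cat(sprintf("PFR,ni fraction:  %.4f%%\n",
            100 * pfr_ni_fraction(labels)$fraction))

# biochemical partition of the same population's lysate
lysate <- pool_lysate(cells[cells$time == 46, ])
chrom  <- simulate_chromatogram(lysate, noise_sd = 0.02 * lysate$total_signal / 100)
scans  <- simulate_radial_scans(
  data.frame(s = c(0, 3000),
             signal = c(1 - lysate$p_inc, lysate$p_inc) * lysate$total_signal),
  rotor_rpm = 3000, scan_times = seq(200, 6000, length.out = 8),
  noise_sd = 0.005 * lysate$total_signal)
part <- combine_partition(decompose_pools(chrom),
                          inclusion_fraction(scans)$p_inc)
cat(sprintf("molecular partition: monomer %.3f, oligomer %.3f, inclusion %.3f\n",
            part$p_mono, part$p_olig, part$p_inc))
cat(sprintf("simulator truth:     monomer %.3f, oligomer %.3f, inclusion %.3f\n",
            lysate$p_mono, lysate$p_olig, lysate$p_inc))
```

Output:

```
death rate (all): 0.196  [SYTOX+ 2461, SYTOX-L 493, SYTOX-D 244 of 16300]
death rate (i):   0.530
death rate (ni):  0.133
PFR,ni fraction:  0.5890%
molecular partition: monomer 0.776, oligomer 0.001, inclusion 0.223
simulator truth:     monomer 0.786, oligomer 0.001, inclusion 0.213
```

Reading this: of 16,300 gated transfected events, 19.6% are dead by the
summed SYTOX/L/D rule; cells carrying an inclusion die at four times the
rate of cells without one (53.0% vs 13.3% at 46 h); about 0.6% of
transfected cells are oligomer-enriched intermediates; and the
chromatogram + sedimentation pipeline recovers the population's molecular
partition to about ±0.01 per class.

`run_pipeline()` (or `inst/scripts/aggflux.R`) chains the same stages for
several chaperone arms from a YAML config and writes tidy CSVs plus a JSON
run manifest; reruns with the same config and seed reproduce every CSV
byte-for-byte.

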