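# rampfold

Analysis of single-molecule force-ramp (optical-tweezers) experiments on
higher-order DNA structures, built around the dissection of the two stacked
G-quadruplexes in the human telomerase (hTERT) promoter. The package is for
single-molecule biophysicists who need to go from force–extension records to
folded-species inventories, unfolding pathways and tertiary-interaction free
energies — and for method developers who want a faithful synthetic twin of
such experiments to validate analysis code against known ground truth.

## What it computes

A molecule tethered between two dsDNA handles (2028 + 2690 bp) is ramped at
5.5 pN/s. Each unfolding event appears as an extension jump at rupture force
F, characterised by its change in contour length

    ΔL = Δx / φ_ss(F),

where φ_ss is the fractional extension of ssDNA from the Marko–Siggia
worm-like chain, F = (kT/P)[1/(4(1−x/L)²) − 1/4 + x/L]. ΔL converts to the
number of nucleotides in the folded structure through a straight-line map
calibrated on nine published (nt, ΔL) pairs (slope ≈ 0.371 nm/nt, intercept
≈ −0.23 nm). The toolbox then provides:

* **Rupture detection** — robust jump detection on F–X traces, ΔL with
  standard errors, ΔL–force plots, and the 65 pN overstretching plateau as a
  single-tether fingerprint.
* **PoDNano** — population deconvolution at nanometre resolution: each
  event's ΔL is expanded with a Gaussian kernel scaled by its standard
  error; local maxima of the summed-kernel density, recorded over thousands
  of bootstrap resamples and clustered at the basins of their own
  distribution, identify the predominant ΔL populations.
* **Pathway reconstruction** — full-fold trace selection, ΔL binning (4 nm
  bins), rank ordering, and aggregation into a directed acyclic transition
  graph with per-state outgoing percentages and cooperative-unfolding
  fractions.
* **Energetics** — nonequilibrium unfolding works W = F·Δx − ΔG_stretch and
  the Jarzynski estimator ΔG = −kT ln⟨e^(−W/kT)⟩ with bootstrap errors;
  the stacking (quadruplex–quadruplex) free energy follows as the
  difference between the cooperative and quadruplex-only populations.
* **A synthetic-data generator** — Bell–Evans rupture kinetics
  (k(F) = k₀ e^(F·Δx‡/kT)) on hierarchical species with refolding
  heterogeneity, cooperative merging, premature tether breaks, force noise
  and the overstretching fingerprint; zero-force rates are calibrated so
  each species' simulated work distribution is Jarzynski-consistent with
  its stated folding free energy. Built-in twins cover the NMS1-4,
  NMS5-12, hTERT1-12 and truncated constructs.

## Worked example

```r
library(rampfold)

sc  <- builtin_scenarios("NMS1-4")          # 5' G-quadruplex twin
sim <- simulate_ramps(sc, n_cycles = 150, seed = 42)

stretch <- Filter(function(t) t$direction == "stretch", sim$traces)
events  <- do.call(rbind, lapply(stretch, detect_ruptures))

pops <- podnano_deconvolve(events$delta_l_nm, events$delta_l_se_nm,
                           n_resamples = 2000,
                           conversion = calibrate_conversion())
pops
#> 3 Delta-L population(s):
#>     4.97 nm (spread 0.00, p = 0.21, 14 nt, freq 1.00)
#>     6.45 nm (spread 0.00, p = 0.53, 18 nt, freq 1.00)
#>     7.56 nm (spread 0.00, p = 0.26, 21 nt, freq 1.00)
```

The three populations are the 14-nt triplex intermediate, the 18-nt
quadruplex, and the 21-nt cooperative species in which the quadruplex and
the 3-nt stacking contact with its neighbour unfold in one step; the
1.1 nm spacing between the two largest ΔL populations is the signature of
that inter-quadruplex contact. Feeding the first-rupture works of the two
larger populations to the Jarzynski estimator recovers the stacking energy:

```r
ev  <- simulate_events(sc, n_cycles = 900, seed = 46)$events
qt  <- ev[ev$rank == 1 & ev$species == "QQI3+G4_18", ]
q   <- ev[ev$rank == 1 & ev$species == "G4_18", ]
tertiary_energy(unfolding_work(qt$f_rupture_pn, qt$delta_x_nm, qt$delta_l_nm),
                unfolding_work(q$f_rupture_pn, q$delta_x_nm, q$delta_l_nm))$delta_g_tertiary
#> [1] 2.01677
```

i.e. ~2 kcal/mol of stacking stabilisation, the value the twin was
generated with. The end-to-end pipeline (`cmd_simulate()` /
`cmd_analyze()`, or `inst/cli/rampfold.R` from a shell) writes trace files,
event tables, population tables, a GraphML pathway graph and a JSON
summary with full provenance.

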