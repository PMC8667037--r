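# origamikin

Simulation and image-analysis toolkit for the assembly kinetics of
membrane-anchored DNA origami superstructures.

DNA origami monomers tethered to a supported lipid bilayer diffuse in 2D
(D ≈ 0.2 µm²/s) and are cross-linked into superstructures by connector
oligonucleotides. *Scaffold connectors* bind unique scaffold loops — one
productive register, orientation-specific, hairpin-prone. *Repeat
connectors* (oligo-T stickers binding A₇ staple extensions) offer
`s − 7 + 1` binding reading frames for an `s`-nt sticker, cannot form
hairpins, and accelerate superstructure assembly by roughly an order of
magnitude. This package reproduces that comparison end to end on synthetic
data, for researchers developing or validating fluctuation-based readouts
of membrane-bound assembly.

The pipeline:

1. **Connector model** — effective association rate
   `k_eff = k_base · n_frames · a_hairpin · m_valence`, folded with
   concentration into a per-contact link rate.
2. **Diffusion–aggregation simulator** — Brownian monomers on a periodic
   domain, connector-rule-dependent irreversible bonding (scaffold:
   head-to-tail, near-parallel, unbranched; repeat: any orientation,
   branching allowed), rigid clusters with size-scaled mobility
   (`D1/n` or Saffman–Delbrück) and optional jamming above a size
   threshold.
3. **Movie renderer** — Gaussian-PSF TIRF camera model (130 nm pixels,
   30 Hz, Poisson + read noise), multi-page 16-bit TIFF with JSON metadata.
4. **Correlation pipeline** — the fluctuation statistic
   `C = ⟨δF(t)·δF(t+1)⟩ / ⟨F − offset⟩²` per observation window, its time
   course over incubation, and a bounded logistic-decay fit whose `t_half`
   is the characteristic immobilization (assembly) timescale.
5. **SPT pipeline** — localization, mutual-nearest-neighbor track linking,
   time-averaged MSD, and `D = slope/4` with a free intercept.
6. **Orchestration** — condition tables (scaffold ± linker, sticker lengths
   6–9 nt, all-T 14–80 nt, the T_N mix), replicated experiments, CSV/JSON/TIFF
   artifacts, full seed reproducibility.

## Worked example

Simulate a repeat-connector condition, image it, and extract the assembly
timescale:

```r
library(origamikin)

# 9-nt oligo-T sticker against the 7-nt A7 docking extension
reading_frames(9, 7)
#> [1] 3

dock  <- docking_spec()                     # A7, 4 sites/edge, 2 edges
conn  <- connector_spec("repeat", total_length = 40, concentration = 250)
model <- rate_model(base_on_rate = 1.76e4)
link_rate_from_connector(model, conn, dock) # per-second contact link rate
#> [1] 0.1496

sched <- data.frame(start = c(5, 30, 60, 95, 135, 180, 230, 285, 345, 410),
                    n_frames = 60, frame_rate = 30)
cfg <- sim_config(domain_side = 8.32, n_monomers = 150, D1 = 0.2, dt = 0.015,
                  capture_radius = 0.1,
                  link_rate = link_rate_from_connector(model, conn, dock),
                  immobilize_above = 8, rng_seed = 42, total_time = 420,
                  observation_schedule = sched)
traj <- run_assembly(cfg)

opt <- optics_config(frames_per_window = 60)
cam <- camera_config()
stacks <- lapply(seq_along(traj$windows), function(i)
  render_stack(traj$windows[[i]], opt, cam, brightness = 5, seed = 100 + i))

tc <- correlation_timecourse(stacks, condition = "T40-like")
round(tc$value, 2)
#>  [1] 0.88 1.20 1.32 1.57 1.18 1.14 0.82 0.53 0.58 0.18

fit_assembly_timescale(tc)
#> <kinetics_fit> t_half = 232 s (width 52.3 s), C 1.42 -> 0.27
```

The correlation parameter rises as mobile oligomers form (few bright
particles fluctuate more than many dim ones), then collapses as assemblies
immobilize; `t_half` of the logistic decay is the assembly timescale used
to compare connector designs. `run_experiment()` wraps the whole loop over
conditions × replicates and writes TIFF stacks, per-window CSV time
courses, JSON fit reports and a summary table.

Mobility before cross-linking, the SPT readout:

```r
tracks <- simulate_tracks(200, 100, D = 0.2, dt = 1/20,
                          loc_noise_sd = 0.02, seed = 61)
estimate_D(msd_tracks(tracks, max_lag = 8, dt = 1/20))
#> <diffusion_fit> D = 0.197 um^2/s (intercept 0.00213 um^2, 200 tracks)
```

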