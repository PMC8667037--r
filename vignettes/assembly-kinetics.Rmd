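---
title: "Quantifying connector-mediated DNA origami assembly on membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying connector-mediated DNA origami assembly on membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNA origami monomers anchored to a supported lipid bilayer (SLB) diffuse in
two dimensions (monomer diffusion coefficient around 0.2 µm²/s) and can be
cross-linked into micrometer-scale superstructures by short "connector"
oligonucleotides. Two connector strategies behave very differently:

* **Scaffold connectors** hybridize to specific scaffold loops on two
  monomers. Binding is site- and orientation-specific (assemblies are
  parallel), but each connector has exactly one productive register and its
  unique sequence can fold into hairpins that sequester it.
* **Repeat connectors** are low-complexity strands (oligo-T, optionally with
  an internal oligo-C spacer) that bind short oligo-A staple extensions
  (`A7`) presented on the origami edges. A sticker of `s` nucleotides offers
  `s − 7 + 1` *reading frames* against the 7-nt docking extension, cannot
  form hairpins, and binds any docking site in any orientation (which also
  permits branching).

Experimentally, repeat connectors assemble superstructures roughly an order
of magnitude faster than scaffold connectors. This package provides a fully
synthetic, tested pipeline for reproducing and probing that comparison: a
mechanistic rate model for connector binding, a stochastic 2D
diffusion–aggregation simulator, a TIRF camera-movie renderer, the temporal
image-correlation statistic with its immobilization-timescale fit, and an
SPT/MSD mobility stage.

## The effective-rate model

The mechanistic claims are (i) multiple reading frames raise the local
effective concentration of productive registers, and (ii) low-complexity
sequences avoid hairpin penalties. No rate law is prescribed by those
observations, so the package adopts the simplest consistent product form:

$$k_\mathrm{eff} = k_\mathrm{base} \cdot n_\mathrm{frames} \cdot
  a_\mathrm{hairpin} \cdot m_\mathrm{valence}$$

with `k_base` the hybridization on-rate of one perfectly matched register
(per-molar per-second), `n_frames` from `reading_frames()` (1 for scaffold
connectors; computed from the sticker length for repeat connectors, using
the full strand length for spacer-free all-T connectors, where any register
can serve either binding partner), `a_hairpin ∈ (0, 1]` a user-supplied
accessibility factor (no secondary-structure prediction is performed — the
hairpin penalty of a scaffold connector is an input, and its default of 0.2
in `paper_condition_table()` is a free calibration knob), and
`m_valence ≥ 1` for edges presenting several docking extensions. Competition
between docking sites for overlapping registers on one connector is
captured separately by `max_simultaneous_occupancy()`. The simulator never
sees connectors explicitly: `k_eff × concentration` collapses into a single
first-order `link_rate` per eligible edge pair in contact, because the
experimental readout (particle-level assembly kinetics) does not resolve
connector occupancy.

## The diffusion–aggregation simulator

Monomers live on a periodic square domain (default 20 × 20 µm; the bundled
experiment configurations use 8.32 µm, exactly the 64-pixel camera field) and
perform Brownian motion integrated with the Euler–Maruyama step
`sd = sqrt(2 D dt)`. The default step `dt = 1 ms` with a 0.1 µm capture
radius satisfies the step-resolution condition `sqrt(2 D1 dt) < r_capture`
(a particle cannot tunnel through the capture zone); configurations that
violate it are rejected. Heavier test configurations use `dt = 15–20 ms`
with correspondingly checked radii.

Binding: every pair of monomers on different clusters within the capture
radius is a contact, and each contact binds with probability
`1 − exp(−link_rate · dt)` per step, subject to the connector rule. The
scaffold rule requires head-to-tail edge pairing of near-parallel monomers
(±30° by default; the experiments report parallel-only assemblies without
stating an angular criterion) and at most one partner per edge, so scaffold
assemblies can never branch. The repeat rule accepts any edge pair at any
orientation, and a fully occupied edge accepts an extra partner with
`branch_probability` (default 0.25 — branching is observed but is clearly
rarer than linear growth). Bonds are permanent: assemblies survive connector
washout experimentally, so the off-rate is zero.

Clusters are rigid (internal flexing is unresolvable at 130 nm pixels) and
translate with a size-dependent diffusion coefficient, either `D1/n`
(default) or a Saffman–Delbrück-style logarithmic decay. Because desk-scale
simulations hold only ~150 monomers, pure size scaling can never reproduce
the experimentally observed freezing of large assemblies (clusters of
thousands of monomers, jamming, pinning); the simulator therefore has an
explicit `immobilize_above` threshold: clusters larger than this are pinned
(D = 0) while still accepting bonds from mobile partners. The bundled
configurations use `immobilize_above = 8`. This is the package's own
desk-scale surrogate for an emergent experimental phenomenon, and it is the
main reason simulated timescale *ratios* between conditions are compressed
relative to the pure rate-law expectation (see "Known limitations").

## The camera model

`render_stack()` turns an observation window of the trajectory into a
camera movie matching the acquisition geometry used for correlation imaging:
130 nm pixels, 30 Hz, 300-frame windows (the heavier tests use 60–100 frame
windows), with the laser shuttered between windows so only scheduled windows
exist. The PSF is an isotropic Gaussian (σ = 150 nm, a typical high-NA
visible-light value; the real instrument's PSF is unpublished) integrated
exactly over each pixel. Expected counts are
`offset + gain · photons`; realized counts add Poisson shot noise and
Gaussian read noise and are clipped at zero. Gain, offset and noise defaults
are generic (the real camera's values are unpublished) and are recorded in
the JSON metadata sidecar of every written TIFF. Each monomer carries 5
fluorophore units by default (a 5× docking site quasi-irreversibly labeled);
cluster brightness is additive. One mid-frame position per frame is used —
at 0.2 µm²/s and 33 ms exposure, motion blur is sub-pixel. In-memory stacks
are unclipped floating point; 16-bit TIFF output saturates at 65535, which
is tested.

## The correlation statistic

The exact published formula for the fluctuation statistic lives in
supporting material that is not part of this package's inputs. The package
defines the correlation parameter as the pixel-averaged lag-1 temporal
autocovariance of per-pixel detrended intensity, normalized by the squared
offset-corrected global mean:

$$C = \frac{\langle \delta F(x,t)\,\delta F(x,t+1)\rangle_{x,t}}
  {\langle F - \mathrm{offset}\rangle^2}$$

This choice reproduces every qualitative property claimed for the
statistic: it reports fluctuation amplitude (few bright particles fluctuate
more than many dim ones at equal total brightness, so C grows roughly
proportionally to oligomer size at fixed fluorophore budget and inversely
with particle density); it vanishes for immobile scenes (δF ≡ 0 up to
noise); and because the lag is at least one frame, temporally uncorrelated
detector noise cancels in expectation rather than inflating C. Detrending
is per-pixel mean removal by default (order 1 removes a linear drift);
mean removal leaves a small-sample bias of −σ²_noise/T in the lag-1
autocovariance, which is orders of magnitude below real-scene values at 60+
frames and is quantified in the tests. Windows are analyzed independently —
the laser is shuttered between windows, so cross-window detrending would be
meaningless.

`fit_assembly_timescale()` summarizes a correlation time course by the
characteristic immobilization time: the decaying phase is fitted with a
logistic decay

$$C(t) = C_\mathrm{base} + \frac{C_\mathrm{peak} - C_\mathrm{base}}
  {1 + e^{(t - t_{1/2})/w}}$$

and `t_half` is reported. A fit is attempted only when the trace actually
decays — the relative drop from peak to post-peak minimum must reach 50%
(configurable); flat traces report `fitted = FALSE`, mirroring the
fitted-versus-acquired bookkeeping used when comparing conditions.
Numerically, the peak is located on a 3-point running mean (one noisy
window must not anchor the decay segment), the Levenberg–Marquardt fit is
restarted from a small grid of initializations, and parameters are bounded:
`C_peak` within 5% of the observed peak, `t_half` inside the observed decay
segment, `w` below the segment span. Unbounded fits readily invent a peak
above all observed data and slide `t_half` toward zero on noisy traces;
with these bounds the noiseless self-consistency test recovers all four
parameters to better than one part in 10⁶, and with 5% multiplicative noise
on 24 points `t_half` is recovered within 10% in at least 95% of seeded
replicates.

## The SPT stage

Mobility is verified the way it is measured experimentally: sparse bright
particles are localized per frame (local maxima above a robust
median + k·MAD threshold, intensity-weighted centroid within a window),
linked frame-to-frame by greedy mutual-nearest-neighbor assignment with no
gap closing (sparse labeling, about 1 in 20, makes collisions rare), and
summarized by the time-averaged, ensemble-averaged MSD. The diffusion
coefficient is the slope/4 of an ordinary least-squares line through the
first 4 lags with a free intercept — the intercept absorbs the static
localization-error term 4σ², so leaving it free is the standard guard
against localization-noise bias; the fit range is the package's choice.
Continuous visibility is assumed (imager-exchange labeling defeats
bleaching). The estimator is bias-tested across D ∈ {0.05, 0.2, 1.0} µm²/s
at 200 tracks × 100 steps and recovers the 0.2 µm²/s membrane-monomer
ground truth within 10% under 20 nm localization noise.

## What the synthetic data does and does not emulate

The generators emulate: 2D Brownian motion at membrane-realistic
mobilities, connector-rule-dependent irreversible aggregation with
branching and orientation constraints, additive cluster brightness,
Gaussian-PSF imaging at 130 nm/30 Hz with Poisson + Gaussian camera noise,
shuttered multi-window acquisition, and monomer/oligomer mixtures at fixed
fluorophore budget for sensitivity sweeps.

They do not emulate: hydrodynamic or crowding interactions between mobile
clusters, cluster shape (clusters are rendered from their frozen member
positions but detected as point contacts), EMCCD excess noise or sCMOS
pixel maps, TIRF evanescent-depth effects, photophysics (blinking,
bleaching beyond a global exponential), imperfect labeling stoichiometry,
or sequence-level thermodynamics. Passing tests therefore demonstrate the
internal consistency and statistical behavior of the analysis chain on an
idealized membrane, not instrument-level realism.

## Problem sizes and design choices

Simulation problem sizes were chosen as the smallest that give stable
statistics for each property: 150 monomers on an 8.32 µm domain (about
2.2 monomers/µm², a workable imaging density) for end-to-end kinetics, with
60-frame observation windows; 10 replicates per condition for the
order-of-magnitude comparison; 200 × 100-step tracks for SPT calibration;
2000 fluorophores per cell for sensitivity sweeps. The contact-detection
inner loop is compiled (Rcpp) since it is the O(N²) hot path of the
stepper.

Open choices resolved by this package, with reasons:

* **Link rates for the 10×-ratio benchmark** (0.15 vs 1.5 s⁻¹ per contact):
  chosen so that even the faster condition stays predominantly
  reaction-limited (per contact-episode binding probability well below 1),
  because only then does a rate ratio map onto a timescale ratio. The
  absolute values put the slow condition's timescale near 270 s, which is
  desk-scale affordable.
* **Pinning threshold 8**: small enough that clusters pin while still
  mobile, avoiding a regime where mid-size clusters (10–25 monomers) are
  too slow to merge yet too fluctuating to read as immobile — a regime in
  which the correlation decay stalls for reasons unrelated to connector
  kinetics.
* **First observation window at 2–10 s**: experimentally the first window
  lags connector addition by about 10 s (pipetting and shutter); simulated
  schedules respect an initial delay and otherwise space windows densely
  enough to resolve each condition's decay.

## Known limitations

* Simulated timescale ratios are compressed relative to the rate-law
  expectation: a 10× link-rate ratio yields a fitted-timescale ratio near 6
  under the bundled conditions (within the intended factor-of-2 band).
  The compression is dynamical — 2D diffusion makes contacts bursty, so the
  faster condition partially saturates its contact episodes, and the final
  accretion of monomers onto pinned clusters is partly encounter-limited.
  Pushing both rates lower decompresses the ratio asymptotically but costs
  simulated time quadratically; the bundled choice is the measured
  compromise.
* The correlation parameter per window is itself a random variable over
  cluster configurations; with ~10² objects per field its window-to-window
  scatter is substantial. The fit's robustness features exist precisely
  because desk-scale fields contain far fewer particles than a 700 × 700
  pixel experimental field.
* `immobilize_above` is a surrogate, not a measured quantity; conclusions
  about absolute timescales should not lean on it, only comparisons between
  conditions sharing it.
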