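---
title: "Models and methods: stochastic cargo loading on IFT trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: stochastic cargo loading on IFT trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iftcargo)
```

## The question and the statistic

Anterograde intraflagellar transport (IFT) trains leave the flagellar base
at roughly one per second. A cargo species c occupies a fraction
$P(c) = n_c / (T \cdot r)$ of the trains observed over $T$ seconds at train
rate $r$ (the field's convention treats $T$ seconds at $r = 1/\mathrm{s}$
as exactly $T$ trains). Two hypotheses about how unrelated cargoes get on
trains make different predictions about their *co-occurrence*:

* **Stochastic loading** — every train binds each cargo independently, so
  the probability that one train carries both cargoes is
  $P(\mathrm{co}) = P(A)\,P(B)$.
* **Subclass loading** — both cargoes ride only an "open" fraction $f$ of
  trains. If marginals are preserved (open trains load with probability
  $P(c)/f$), then $P(\mathrm{co}) = P(A)P(B)/f$: an enrichment of exactly
  $1/f$ over the independence prediction, capped at $\min(P(A), P(B))$.

`cotransport_test()` computes the marginals, the observed cotransport
probability $P(\mathrm{co,obs}) = n_\mathrm{co}/(T r)$, the calculated
probability $P(A)P(B)$ (always from *unrounded* marginals), the accompanying
fractions, and an independence test. `expected_cotransport_probability()`
gives the model predictions; `power_analysis()` measures how reliably a
given experiment separates them.

Note that under any model in which both cargoes ride only open trains the
enrichment is $1/f$ *whether or not* marginals can be preserved: if
$P(c)/f > 1$ the open trains saturate, the realized marginal shrinks to
$f$, and the ratio of observed to calculated probability is still $1/f$.
The simulator therefore offers `subclass_saturation = "error"` (reject a
configuration whose marginals cannot be preserved — the strict contract)
and `"cap"` (saturate open trains), and the power analysis uses the capped
form so that extreme subclasses can be simulated at all.

## Independence testing

The `duration * train_rate` trains are classified into the 2×2 table
(both, A only, B only, neither). The default test is Fisher's exact test,
conditioning on both margins — appropriate because the marginals are
themselves estimated. A permutation test (cargo-A labels shuffled over
trains; equivalently hypergeometric resampling of $n_\mathrm{co}$, two-sided
by distance from expectation) and a binomial test
($n_\mathrm{co}$ against $\mathrm{Bin}(N, \hat p_A \hat p_B)$; mirrors the
product calculation most directly but is anti-conservative because the
marginals are plugged in) are provided.

Two refinements matter only for calibration studies and are off by default:
`midp = TRUE` replaces the exact p-value by the mid-p variant (half weight
on the observed outcome), removing the conservatism that makes discrete
exact p-values non-uniform under the null; `use_observed_trains = TRUE`
conditions on the realized train count of a simulated record instead of the
$T \cdot r$ convention, which is the correct number of trials when it is
known. With both, null p-values from the simulator are uniform to the
resolution of a Kolmogorov–Smirnov test at 500 replicates (checked in the
test suite).

## The traffic simulator

`sim_config()` bundles the generator parameters. Defaults are the measured
values for the ARMC2 cargo adapter in regenerating flagella; where the
measurements provide no value the default is a documented modeling choice.

| parameter | default | unit | status |
|---|---|---|---|
| `train_rate` | 1.0 | trains/s | measured (~60/min) |
| `antero_velocity_mean`, `_sd` | 1.71, 0.24 | µm/s | measured |
| `tip_dwell_mean`, `_sd` | 2.3, 1.8 | s | measured |
| `retro_fraction` (release preset) | 1/15 | — | measured (adapter) |
| docked/diffuse/retro (axonemal preset) | 12/15, 2/15, 1/15 | — | measured |
| `pool_dwell_mean`, `_sd` | 19, 7.7 | s | measured (FRAP gap) |
| `flagellum_length` | 7.3 | µm | measured (regenerating mean) |
| `retro_velocity` | 3.0 | µm/s | choice (typical retrograde IFT) |
| `diffusion_coeff` | 2.0 | µm²/s | choice (not measured) |
| `two_copy_prob` | 0.1 | — | choice (two-copy trains seen qualitatively) |
| `length_response` | identity | — | choice; logistic preset anchored at 44 and 0.9 events/min |

Arrivals are homogeneous Poisson by default; a `"regular"` spacing option
reproduces the idealization in which $T$ seconds are exactly $T$ trains.
Velocities are drawn per train from a normal truncated away from zero.

**Dwell times are gamma distributed.** The configured dwell mean is an
*empirical mean* (2.3 s), so the generator must realize that mean exactly.
A normal clipped or truncated at zero realizes a larger mean (2.39 or
2.66 s respectively for mean 2.3, SD 1.8); a gamma with matching mean and
SD is non-negative, waiting-time shaped, and exact in both moments. The
same draw is used for the basal-pool dwell.

After its tip dwell a cargo follows its release partition: diffusive return
is simulated as reflected one-dimensional Brownian motion on
$[0, L]$ (reflecting tip, absorbing base, Euler steps of
`diffusion_dt` = 0.02 s); docking places the cargo at a subdistal site
0.3–1 µm from the tip where it remains stationary; retrograde return runs
base-ward at `retro_velocity`.

The FRAP experiment (`simulate_pool_bleach()`) darkens the cargo on all
trains departing within one pool-dwell draw of the bleach, then resumes
fluorescent carriage (optionally thinned, since recovery of the adapter was
observed to be incomplete). The measured gap — time from bleach to the
first fluorescent departure — therefore includes the residual wait for the
next carrying train (≈1.4 s at regenerating traffic) on top of the pool
dwell; this discreteness is a property of the experiment, not an estimator
bias, and is left uncorrected.

## The kymograph renderer

`render_kymograph()` produces the two-channel time × position image that a
10 fps TIRF recording of one flagellum would give: each fluorophore copy
contributes a pixel-integrated Gaussian profile (`psf_sigma_px` = 1 px at
`pixel_size` = 0.16 µm, representative of a 60×/NA 1.49 setup) with mean
integrated intensity `photons_per_particle` per frame; exposure is
integrated over `substeps` = 10 sub-frame position samples, so fast
diffusing cargo is motion-blurred exactly as in a real finite-exposure
camera frame — this is why returning cargo looks like a faint haze rather
than a sharp track, in the synthetic images as in real ones. Each copy
photobleaches in a single step at an exponential time (per-channel rate;
two-copy trains show two-step bleaching). Poisson shot noise and Gaussian
read noise are applied last. The image is padded by `pad_px` columns on
each side of the flagellum so point-spread tails stay inside the frame (the
calibration records the offset; column `origin_px + 1` is the base).

Noise-free mode returns the expected image; in that mode rendering is
exactly linear in the trajectory set and photon flux is conserved, both of
which are asserted in the test suite.

## Track extraction

`extract_tracks()` recovers particle tracks in five passes:

1. **Peak detection** per frame: local maxima above a global threshold
   (median + `k_mad` × MAD of the off-flagellum padding columns — at
   regenerating traffic most of the flagellum is signal, so an in-frame
   background estimate would be badly biased), with non-maximum suppression,
   subpixel centroid refinement, and a *local* pedestal subtraction for
   amplitudes (the diffusing-cargo haze raises the local background by tens
   of counts).
2. **Velocity-gated linking**: greedy one-to-one nearest-neighbor
   assignment by prediction error, gap tolerance `gap_frames`.
3. **Stitching** of fragments whose line extrapolations agree.
4. **Line growing**: a track endpoint still in clean directed motion is
   extended along its fitted line through the peak field, healing runs
   broken by crossings and the crowded tip cluster; the extension must be
   well supported (≥60% of spanned frames) or it is reverted.
5. **Duplicate removal**, both of whole tracks on the same line and of
   duplicate *event* status among complementary fragments of one run (same
   slope *and* intercept ⇒ same train).

Each track is segmented by local slope into anterograde / retrograde /
stationary / diffusive motion. An anterograde run qualifies as a transport
event through one of three rules, tuned against ground truth and documented
in `extract_params()`: a *long* run (≥20 frames, ≥4.5 µm, ≥75% detection
density) tolerating crossing wobble; a *clean* run (trimmed residual ≤
`run_resid_px` = 0.6 px) covering ≥ `min_run_um` = 3 µm (relaxed to 1 µm at
the recording boundaries); or a *clean medium* run (≥10 frames, ≥80%
density, residual ≤0.5 px, ≥1.6 µm, velocity in the plausible anterograde
band). The displacement and linearity requirements are what keep the
diffusive background — which the velocity-gated linker can chain into
deceptively straight short pseudo-runs — out of the event count.

**Apparent multiplicity.** Two trains departing within ~0.2 s at similar
velocity merge into one bright track that no tracker can split. The
integrated run flux, in units of one fluorophore, flags such tracks;
`measure_transport()` counts them with multiplicity two. Trains carrying
two copies of the cargo are an unavoidable confound of this correction (a
two-copy single train also has flux 2), which is why the default
`two_copy_prob` matters for frequency accuracy and is kept at the modest
0.1.

## Tip dwell under crowded traffic

At 44 events/min with a mean dwell of 2.3 s, about 1.7 particles dwell at
the tip simultaneously, and released cargo diffusing near the reflecting
tip lingers within a pixel of the dwell site. Reading dwells per track (the
operational definition: time from a run's arrival at the tip zone to the
first displacement > `move_px`) then fails in both directions: merged tip
peaks hand one particle's dwell to another track, and censoring cuts long
dwells. `measure_transport()` still reports the per-track numbers (they are
correct for sparse recordings), but the estimator of record for dense
traffic is `estimate_tip_dwell()`:

* a temporal running median (5 frames) keeps the static dwell signal and
  suppresses moving particles (arrivals, departures, diffusive passers-by);
* a zero-mean (balanced) matched filter centered on the tip converts the
  filtered image to fluorophores-at-tip per frame, rejecting the flat and
  linearly sloped haze pedestal; rounding to integers suppresses residual
  fractional contamination;
* Little's law turns the occupancy integral into a mean dwell: total
  dwell-time divided by arriving fluorophores, where arrivals are the
  anterograde events whose fitted lines reach the tip within the recording
  (tracks are often lost inside the tip cluster before the dwell registers)
  weighted by their flux multiplicity;
* single-step photobleaching truncates observed dwells; the known bleach
  rate gives a first-order correction
  $m \leftarrow m\,(1 + \beta\,(m^2+s^2)/(2m))$.

Validated against ground truth in the round-trip tests, this estimator
recovers the configured 2.3 s mean within a few hundredths of a second
pooled over twelve 60-s flagella.

## Long-short (paired) flagella

`simulate_long_short()` draws cohorts of cells regrowing one flagellum
while the other shortens. The preset mean model is linear in the length
difference ΔL, anchored for both flagella at 14.4 events/min at ΔL = 0 (the
frequency measured in length-arrested half-length flagella) and calibrated
so the population means equal the measured group means exactly: 29.1
(short) and 8.9 (long) events/min for the control condition, 33 and 10.2
under cycloheximide. Cell-to-cell noise is gamma (non-negative, mean-exact)
and sized so the *total* group SDs match the measured 16/6.8 (control) and
13.2/8.1 (cycloheximide) after accounting for the ΔL-driven variance.

A design note: a frequency model driven by a flagellum's *own length* alone
(the logistic preset shared with the simulator's `length_response`) cannot
reproduce these data — long flagella of long-short cells transport at
8.9 events/min while steady-state full-length flagella of the same length
transport at 0.9 events/min. Whether the controlling variable is the length
difference or the own length relative to a set point is not separable from
the available measurements; the default preset therefore models the
measured ΔL relationship directly, and `freq_model` accepts any function of
(own length, signed difference) for users who want to explore alternatives.

## Display rounding

The published probability tables round half-up to two significant figures,
with two departures that `round_like_paper()` and `reproduce_table1()`
honor rather than hide: the worked three-figure marginal 243/905 is printed
as 0.268 (a truncation; round-half-up gives 0.269), and the product
0.2685 × 0.1171 = 0.0314 is printed as 0.03 (two decimals).
`reproduce_table1()` therefore verifies each computed cell against the
printed string *at that string's own decimal precision*, accepting either
rounding convention; all computation is done at full precision and rounding
is purely a display concern.

## Problem sizes and what the tests show

The test suite validates the statistic on the packaged counts (exact), the
simulator against closed forms (60–200 replicates at T = 1000–1622 s;
marginal preservation at T = 10⁵), test calibration with 500 null
replicates, the imaging round trip on twelve 60-s flagella at
44 events/min (frequency within ±10%, velocity within ±0.1 µm/s, tip dwell
within ±0.3 s, track recall and precision ≥0.9), 50 pool-bleach replicates,
and 10⁴-cell long-short cohorts. These sizes keep the default run to a few
minutes on one CPU while leaving comfortable statistical margins.

Passing them shows that the pipeline is self-consistent — that the
extractor recovers what the generator put in, under the generator's
idealizations. It does not show performance on real recordings, which add
flagellar drift and bending, uneven TIRF illumination, chlorophyll
autofluorescence, camera artifacts, mid-flagellum loading/unloading and
velocity changes, none of which are modeled. The extractor flags
base-to-tip completeness implicitly through its displacement rules, but
ambiguous partial events — reported but not quantified in the source
data — remain a judgment call in any analysis.

## Known limitations

* The subclass model is exchangeable across cargoes (one shared open
  fraction); cargo-specific subclasses would need a per-cargo `f`.
* The occupancy dwell estimator needs the imaging configuration (photon
  yield, bleach rate); for measured kymographs those must be calibrated
  independently.
* Cotransport calling uses a fixed spatial tolerance (2 px) and temporal
  overlap (50%); both are explicit parameters, and sensitivity to the
  tolerance should be reported alongside any borderline result.
* The renderer's camera model is representative (gain 1, Gaussian read
  noise), not fitted to a specific sensor.
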