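# iftcargo

Cargo proteins of the ciliary axoneme reach their assembly sites by riding
anterograde intraflagellar transport (IFT) trains. A central question about
this traffic is whether different cargoes — say, the radial-spoke adapter
ARMC2 and the dynein adapter IDA3 in *Chlamydomonas reinhardtii* — are
loaded onto a **specialized subclass of trains** or **stochastically onto
any train**. The two hypotheses are indistinguishable from single-channel
data, but two-color TIRF imaging separates them through cargo
*co-occurrence*: if each train carries cargo A with probability
P(A) and cargo B with probability P(B), then under independent (stochastic)
loading

```
P(cotransport, calculated) = P(A) x P(B)
```

whereas if both cargoes ride only an "open" fraction *f* of trains, the
observed cotransport probability is enriched to `P(A) P(B) / f` — a factor
1/f above the independence prediction. Marginals are estimated with the
train-counting convention of the field: at an anterograde train frequency of
1/s, T seconds of recording correspond to T trains, so `P(A) = nA / T`.

`iftcargo` implements this analysis end to end, for both measured counts
and fully synthetic experiments:

* **Traffic simulator** (`simulate_traffic()`) — Poisson (or regular) train
  arrivals at ~1/s carrying 0–2 copies of each cargo under either loading
  model, with flagellar-length-dependent loading, anterograde runs at
  1.71 ± 0.24 µm/s, a 2.3 ± 1.8 s tip dwell, and diffusive, docked or
  retrograde return (`build_trajectory()`).
* **Kymograph renderer** (`render_kymograph()`) — calibrated two-channel
  time × position images at 10 fps with pixel-integrated Gaussian spots,
  exposure-integrated motion blur, single-step photobleaching, Poisson shot
  noise and read noise; 16-bit TIFF + JSON calibration I/O.
* **Track extractor** (`extract_tracks()`, `measure_transport()`,
  `call_cotransports()`) — peak detection, velocity-gated linking, fragment
  stitching and line growing, motion classification, transport frequencies,
  velocities, tip dwells (including an occupancy-based estimator for dense
  traffic) and two-channel cotransport calling.
* **Cotransport statistic** (`cotransport_test()`) — the probability
  arithmetic above plus exact (Fisher), permutation and binomial
  independence tests, and `power_analysis()` for model discrimination.
* **FRAP and paired-flagella experiments** — basal-pool bleaching and
  traffic-gap detection (`simulate_pool_bleach()`, `detect_traffic_gap()`),
  and the long-short flagella frequency-versus-length-difference analysis
  (`simulate_long_short()`, `fit_trend()`).

The published four-row count table ships with the package
(`table1_counts()`); `reproduce_table1()` recomputes every derived
probability from the raw counts and verifies it against the printed value.

## Worked example

```r
library(iftcargo)

rec <- count_record("RSP3-NG / ARMC2-mS (regenerating)",
                    n_a = 578, n_b = 130, n_co = 104, duration = 1622,
                    cargo_a = "ARMC2-mS", cargo_b = "RSP3-NG")
cotransport_test(rec)
```

```
	IFT cargo cotransport analysis

data: RSP3-NG / ARMC2-mS (regenerating) (nA = 578, nB = 130, nCo = 104, 1622 trains)
P(ARMC2-mS) = 0.356, P(RSP3-NG) = 0.0801
P(cotransport observed)   = 0.0641
P(cotransport calculated) = 0.0286  (= pA x pB, independence)
enrichment (obs/calc) = 2.24
independence test (fisher): p = 3.53e-27
```

The adapter and its own cargo co-migrate far more often than chance (the
80% of RSP3-NG transports accompanied by ARMC2-mS reflect a physical
adapter–cargo complex). Two *unrelated* cargoes behave differently —
simulate a regenerating flagellum under stochastic loading and re-analyze:

```r
cfg <- sim_config(duration = 905, seed = 7,
                  cargoes = list(cargo_spec("ARMC2", p_load = 0.27, channel = 1L),
                                 cargo_spec("IDA3",  p_load = 0.12, channel = 2L)))
cotransport_test(cotransport_counts(simulate_traffic(cfg)))
```

```
	IFT cargo cotransport analysis

data: simulated (nA = 278, nB = 122, nCo = 39, 905 trains)
P(ARMC2) = 0.307, P(IDA3) = 0.135
P(cotransport observed)   = 0.0431
P(cotransport calculated) = 0.0414  (= pA x pB, independence)
enrichment (obs/calc) = 1.04
independence test (fisher): p = 0.752
```

Observed ≈ calculated: no evidence for a shared train subclass, matching
the published conclusion for the ARMC2/IDA3 and ARMC2/IC2 pairs.

A command-line wrapper is installed at `exec/iftcargo` with subcommands
`simulate`, `render`, `extract`, `stats`, `table1`, `power`, `longshort`
and `roundtrip`.

## Vignette

`vignettes/cotransport-methods.Rmd` documents the generative model, every
tunable parameter with units and defaults, the extraction algorithm and its
event-qualification rules, the dense-traffic tip-dwell estimator, and the
design decisions and limitations.
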