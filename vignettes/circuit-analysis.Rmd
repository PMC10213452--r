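---
title: "Analysing spike activity in ring-shaped MEA circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spike activity in ring-shaped MEA circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mearing)
```

## The experimental system and what this package computes

`mearing` analyses extracellular recordings of small, topologically
constrained neuronal circuits cultured on 60-electrode microelectrode
arrays (MEAs). A PDMS microstructure confines neurons into 15 circuits
of four cylindrical nodes each; the microchannels connecting the nodes
are shaped so that axons preferentially grow clockwise around the ring,
and each channel passes over one electrode. Positions on the ring are
numbered clockwise 1 (top-left), 2 (top-right), 3 (bottom-right),
4 (bottom-left), so clockwise propagation is 1→2→3→4→1.

The package implements the full analysis chain for such recordings:

1. **Spike detection** from raw 20 kHz voltage traces.
2. **Spontaneous metrics**: per-electrode mean firing rate (MFR) and the
   active-electrode classification.
3. **Spike-pair directionality**: the per-circuit percentage of
   clockwise consecutive spike pairs.
4. **Stimulation analysis**: stacked peri-stimulus rasters,
   activity-inducing classification, induced spikes per stimulus.
5. **Magnesium dose-response**: MFR and evoked activity versus
   extracellular Mg²⁺, with exponential decay-constant fits, trend
   tests, recovery comparison and stability (CV) comparison.
6. A **statistical battery** (two-proportion Z, Mann–Whitney U,
   Mann–Kendall, Fisher's method) implemented self-contained so every
   reported p-value is auditable.
7. A **synthetic-recording generator** with known ground truth, which is
   the package's data source for validation: the original recordings of
   this experimental paradigm are not publicly deposited, so every stage
   is validated against simulated data whose generative parameters are
   known exactly.

## Spike detection

Raw traces are high-pass filtered with a 2nd-order Butterworth filter at
300 Hz. Filtering is a **causal forward pass** by default, mimicking an
online acquisition chain; the sub-millisecond phase lag is irrelevant at
the 5 ms pairing scale of the downstream analysis. A zero-phase
forward–backward pass is available via
`detection_params(zero_phase = TRUE)`. Each channel's first sample is
subtracted before filtering; by linearity this changes nothing except
that a recording with a constant offset no longer produces a startup
step transient, making detection exactly invariant to DC offsets.

Baseline noise is estimated per electrode with the median absolute
deviation, normalised by 0.6745 (`sigma = MAD/0.6745`), the standard
convention for spike data: for Gaussian noise this consistently
estimates the noise SD while being robust to the spikes themselves. The
un-normalised MAD is available via `mad_normalize = FALSE` — the choice
between the two conventions is deliberately a switch rather than a
hard-coded guess, because published threshold descriptions are often
ambiguous on this point.

A spike is a **positive local-maximum sample** exceeding
`7 × sigma`. Plateaus (possible after discretisation) take their first
sample, a deterministic tie-break. Successive events within 2 ms are
discarded scanning in time order, the earliest of a run surviving, so
detected spike times per electrode are always spaced by at least the
dead time. When a stimulation protocol is supplied, samples within 2 ms
after each pulse onset are blanked from the peak search; without
blanking, a ±500 mV stimulation pulse would dominate detection on any
trace that contains the artifact.

## Spontaneous activity

`mean_firing_rate()` is spike count over recording time; an electrode is
**active** if its MFR is *strictly above* 0.1 Hz. Group summaries
(`aggregate_condition()`) compute the percentage of active electrodes
over all included electrodes, but the mean MFR (± SEM) over *active
electrodes only*; a group with no active electrode reports an absent
mean rather than 0, which would otherwise drag condition curves towards
zero. Whether a circuit is "independent" (no stray axonal connections to
neighbours) is a microscopy judgement in the original workflow; here it
enters as an explicit logical inclusion mask, which reproduces the
filtering without pretending to automate image review.

## Spike-pair directionality

For each circuit, the spikes of its active electrodes are merged into
one time-sorted stream. Every pair of **consecutive** spikes in the
merged stream separated by strictly less than 5 ms yields one pair —
"consecutive" means adjacent in the stream, not all pairs within the
window, so a chain of k spikes yields k−1 overlapping pairs. The 5 ms
window approximates the synaptic latency between two neurons of a
circuit; the simulator caps its propagation latencies at 4.5 ms so that
ground truth and statistic coincide in the noiseless limit, the 0.5 ms
gap absorbing detection timing error.

Pairs on adjacent electrodes are classified clockwise (1→2, 2→3, 3→4,
4→1) or counter-clockwise (the reverses); pairs on the same electrode or
on diagonals (1↔3, 2↔4) carry no direction and enter the non-directional
fraction. Two spikes with *identical* timestamps on different electrodes
(possible at 20 kHz discretisation) have genuinely undefined order; they
are ordered by ascending ring position, flagged `ambiguous`, and
excluded from the clockwise/counter-clockwise counts.

The per-circuit percentage of clockwise pairs is computed out of the
directional pairs only, and group summaries average these percentages
**unweighted across circuits** — a circuit with ten times the firing
rate does not get ten times the vote. Circuits with no directional pairs
are excluded from the mean and tallied separately.

This statistic is deliberately descriptive: no causal claim about
information flow between electrodes is made or supported.

## Stimulation-evoked activity

The standard stimulation paradigm is a 400 µs ±500 mV biphasic pulse at
4 Hz for 2 min — 480 repeats per set — applied sequentially to each
electrode of a circuit with 30 s idle between sets.
`build_raster()` assigns every spike on the circuit's four electrodes to
the latest pulse strictly before it, with latency in **(0, 250] ms**:
open at 0 because a spike at the pulse sample is indistinguishable from
artifact, closed at 250 because at 4 Hz the windows exactly tile the
inter-pulse interval (a spike falling exactly on the next pulse onset
belongs to the previous window at latency 250 ms). Windows longer than
the inter-pulse interval are rejected outright, since they would
double-assign spikes.

A stimulated electrode is **activity-inducing** if the set evoked at
least 480 spikes summed over all four circuit electrodes — at least one
spike per stimulus on average. The boundary is an exact integer
comparison. The stimulated electrode's own spikes are included in the
sum; its trace is protected by artifact blanking rather than excluded.
Automated detection of latency "bands" in the raster is out of scope;
the raster object and its plot expose them visually.

## Magnesium dose-response

The addition protocol starts from 0.81 mM Mg²⁺ in 1.1 ml of medium and
adds 2.75 µl of 1 M MgCl₂ per step. `concentration_after_addition()`
returns both the **nominal** concentration (baseline + stock·V/V, the
+2.5 mM per step that dose axes report: 0.81, 3.31, 5.81, 8.31,
10.81 mM) and the **exact** dilution value, which is always slightly
lower because the added volume dilutes the medium (3.30 vs 3.31 mM after
the first step). Curves are indexed by nominal concentration for
comparability with printed axes.

`fit_exponential()` fits `mean(c) = A·exp(−c/τ)` to the mean trace by
Levenberg–Marquardt least squares with a deterministic initialisation
(A₀ = mean at the lowest concentration, τ₀ = concentration span,
relative tolerance 1e−8) — well-conditioned on 5-point traces and
reproducible to the last bit. A flat trace is reported as `no_decay`
(τ unidentifiable) rather than some huge unstable number; non-positive
means trigger a direct nonlinear fit with a warning. No offset term is
fitted by default; with five points an offset is barely identifiable and
the no-offset decay is the parsimonious choice.

Trend against concentration uses the Mann–Kendall test **one-sided for a
decrease** by default. This is a deliberate choice: on a 5-point trace
the exact two-sided null distribution of S is so coarse that even a
strictly decreasing sequence only reaches p = 1/60, and a single
inversion pushes two-sided p above 0.05 — a directional hypothesis
(suppression) is both the scientific question and the only test with
usable power at this length. Recovery after the final medium change is
compared to the initial session with a two-sided Mann–Whitney U test,
and the stability of spontaneous versus evoked metrics is compared with
the coefficient of variation (`100·sd/mean`).

## The statistical battery

All four tests are implemented in the package rather than wrapped, so
their conventions are explicit:

* **Two-proportion Z**: pooled variance by default (unpooled via a
  flag); degenerate pooled proportions (0 or 1) return p = 1 with a
  warning. No multiple-testing correction is applied by default, with
  `p.adjust` available to callers who want one.
* **Mann–Whitney U**: midrank ties; exact p from the full null
  distribution of U (computed by the standard counting recursion and
  cached per sample-size pair) whenever there are no ties and
  `n·m ≤ 400`; otherwise the tie-corrected normal approximation with
  continuity correction. The exact branch reproduces the classic
  fully-separated 5-vs-5 value p = 2/252 ≈ 0.0079.
* **Mann–Kendall**: exact tail for tie-free sequences of length ≤ 10 via
  the inversion-number (Mahonian) distribution — on short dose or
  developmental traces the normal approximation is not trustworthy —
  and the tie-corrected, continuity-corrected normal approximation
  beyond. "On means" usage is simply the test applied to the sequence of
  group means across ordered sessions.
* **Fisher's method**: χ² = −2Σln p with 2k degrees of freedom.

The test suite verifies these against independent oracles
(`wilcox.test`, `prop.test`, `pchisq`, exhaustive enumeration) and
checks empirical type-I error calibration at α = 0.05 under null
simulations (2000 replicates per test; all three land within
0.05 ± 0.02).

## The synthetic-recording generator

The generator is the package's ground-truth data source. It emulates:

* **Background firing**: homogeneous Poisson per electrode, default
  2 Hz — a typical rate for an active electrode in mature cultures of
  this kind.
* **Propagation**: each spike independently triggers a spike on its
  clockwise neighbour with probability `p_forward` (default 0.3) and
  counter-clockwise with `p_backward` (default 0.1), latency uniform on
  [0.5, 4.5] ms; propagated spikes propagate in turn (a branching
  cascade). The defaults give an expected clockwise fraction of
  0.3/0.4 = 75%, in the clockwise-dominant regime these circuits
  exhibit. Modelling propagation as a branching process rather than
  explicit synapses is deliberate: the analysis only ever observes
  pairwise latencies, and the branching form gives an analytically known
  ground-truth clockwise fraction. Supercritical configurations
  (`p_forward + p_backward ≥ 1`) warn, and ≥ 1.5 is a hard error.
* **Evoked responses**: per pulse and per "band" (mean latency, jitter
  SD, response probability), one spike on each circuit electrode —
  consistent latencies appear as vertical bands in the stacked raster.
  Extra "late" activity is Poisson in the (15, 250] ms window,
  reflecting the synaptically mediated late response.
* **Magnesium suppression**: rates and response probabilities scale by
  `exp(−c/τ)` with τ = 3 mM by default; an optional flag exempts bands
  with latency ≤ 15 ms, mimicking early, possibly directly evoked
  spikes that persist at high Mg²⁺. The exponential form mirrors the
  exponential *fit* used in the analysis; it is a modelling choice, not
  a mechanistic claim about NMDA-receptor block.
* **Trace rendering**: each spike stamps a biphasic template (positive
  peak 60 µV, width 1 ms, near-zero net area so the 300 Hz high-pass
  passes the peak largely unattenuated) onto its channel, plus white
  Gaussian noise (SD 6 µV — a 10× peak-to-noise ratio typical of
  microchannel recordings, which have high SNR). The stimulus artifact
  is *not* rendered by default.

Reproducibility: every operation draws from its own RNG stream derived
from `(seed, operation tag)` — and rendering from
`(seed, channel id)` — so a single channel can be re-rendered
identically without replaying the whole array, and large arrays can be
processed channel-by-channel in bounded memory.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: bursting and other non-Poisson interval
structure, rate non-stationarity, electrode-to-electrode amplitude and
noise heterogeneity, waveform variability and overlapping spikes from
multiple units, stimulus artifacts, and slow developmental drift.
Validation against it demonstrates that the analysis chain is correct
*given its assumptions*, not that those assumptions hold for any
particular culture.

## Numerical choices and degenerate inputs

* Times are seconds (floats, '.' decimal separator in files); sample
  indices are 0-based in time conversion (`t = (i−1)/fs` for R's 1-based
  `i`); the event time is the detected *peak* sample, not the threshold
  crossing.
* The pairing window is strict (`Δt < 5 ms`); the post-stimulus window
  is `(0, 250]`; the active threshold is strict (`MFR > 0.1 Hz`); the
  activity-inducing boundary is `total ≥ 480`, exact in integers.
* SEM over fewer than two values, the mean over an empty active set, and
  the clockwise percentage of a circuit without directional pairs are
  all reported absent (`NA`), never coerced to 0.
* A flat trace at noise estimation (σ = 0) is an error directing the
  user to inspect the channel, not a silent zero threshold.

## Problem sizes used in validation

The shipped tests validate detection on a full 60-electrode, 300 s
rendered array (~36 000 spikes; recall and precision both ≥ 95% with
timing error ≤ 0.25 ms), directionality recovery on 20 circuits × 300 s
(recovered mean within ±5 points of the configured 75%, null within ±3
of 50%), dose-response recovery on 10 independent 5-concentration
sessions of 20 electrodes × 120 s (median τ within 20% of the configured
3 mM), and oracle equivalence of pair extraction, peak detection and
raster assignment on 500 randomised small instances. These sizes give
comfortable statistical margins while keeping a full validation run in
the minutes range on one CPU.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1, duration = 300)
res <- run_pipeline(cfg, out_dir = "run1")
res$directionality$summary
make_report(res, "run1/report.pdf")
```

The manifest written next to the tables echoes the seed and parameters;
re-running with the same config reproduces byte-identical outputs.
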