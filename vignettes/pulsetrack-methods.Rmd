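---
title: "Models and methods behind pulsetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pulsetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetrack)
```

This vignette documents the models, parameter choices and numerical
conventions of the package: what the synthetic-movie generator emulates
(and what it deliberately does not), how each analysis step is defined,
and where a genuinely open design choice was settled.

## The pulsed-pH assay in one paragraph

TfR-pHluorin is fluorescent at pH 7.4 and quenched at pH 5.5 unless
enclosed in a sealed vesicle. Alternating the perfusate pH every imaging
cycle therefore interleaves a *structural* channel (pH 7.4: all
clathrin-coated structures, "TfR7") with a *functional* channel (pH 5.5:
only internalised, acid-protected receptor, "TfR5"). Membrane scission is
detected as the abrupt appearance of a TfR5 spot; the appearance cycle
defines t = 0 for that event. A reporter channel (an mCherry fusion)
sampled once per cycle provides the recruitment kinetics that are averaged
across events.

## The synthetic-movie generator

`sim_config()` fixes the study conditions; `simulate_movie()` renders
them. The generator is first-class, tested code: every acceptance-style
property in the test suite runs the full analysis against its ground
truth.

**Temporal structure.** One timepoint is one pH pair; each channel is
sampled every `dt = 2` s, and the raw stack stores the pH 7.4 and pH 5.5
frames interleaved. The default movie has 400 cycles (~13 min), matching
the perfusion-block length used with this assay; `segment_blocks()`
defaults to 400-frame blocks for the same reason. The acquisition time of
cycle *k* is (k−1)·dt, timestamped at the pH 7.4 frame.

**CCS nucleation and scission.** CCS nucleate as a spatial Poisson process
(default 0.02 CCS µm⁻² min⁻¹, giving ~40 structures in the default
96-px/0.13-µm field) at uniform positions with a hard-core exclusion
radius (`min_separation = 6` px — distinct diffraction-limited structures)
and a 10-px border margin so measurement apertures always fit. Waiting
times from nucleation to the first scission, and between successive
scissions at a persistent CCS, are iid exponential with mean
`inter_scission_interval = 100` s — a renewal process consistent with
observed WT maturation times of ~100 s and with the observation that the
two waiting times are equivalent. After each scission the CCS terminates
with probability `p_terminal = 0.5`; terminal structures stay visible
through the cycle at which their scission is first seen and disappear
afterwards.

**Event-time quantisation.** Scission times are snapped to the sampling
grid. The movie cannot represent sub-cycle timing: an event drawn between
two cycle times would render its kernel at an unidentifiable sub-sample
phase, which only blurs event-aligned averages without adding realism. All
event-aligned quantities are therefore defined on cycle times, and the
noiseless extraction oracle (each aligned trace equals the kernel exactly)
holds.

**Channels.** TfR7 renders a Gaussian spot (`psf_sigma = 1.5` px, peak
`ccs_amp = 60` counts) at every live CCS. TfR5 renders a spot from each
scission onwards, decaying exponentially with `tfr5_decay_tau = 10` s
(vesicle departure and uncoating; the decay constant is configurable
because published movies show decay without quantifying it). The reporter
renders, per event, the deterministic kernel evaluated at t − t0, plus a
stochastic flicker at every live CCS.

**The recruitment kernel** (`kinetic_profile()`) has three parts:

* *flicker*: a symmetric two-state telegraph process (switching rate
  0.2 s⁻¹, amplitude 30 counts) while the CCS is alive — transient,
  low-amplitude association long before scission. Published descriptions
  of flickering are qualitative, so amplitude and rate are free
  parameters of this artifact.
* *burst*: piecewise-exponential rise (τ = 8 s) to a peak of 100 counts at
  −2 s, then exponential decay (τ = 5 s) — the simplest asymmetric shape
  matching a burst that peaks 2–4 s before vesicle detection.
* *early enrichment*: an optional plateau (default 0; 40 counts in the
  `early_enriched` preset) over the 90 s preceding each scission,
  emulating mutants that are stably pre-recruited.

`kinetic_presets()` bundles three phenotypes (`wt`, `slow_burst`,
`early_enriched`) used by the clustering studies.

**Noise.** Poisson photon noise on the clean image followed by additive
Gaussian read noise (sd 3 counts) on a background of 100 counts. At the
default spot amplitude of 60 counts the detection SNR is ≈ 5 — a
realistic working regime, deliberately not comfortable. `noise = FALSE`
disables both for closed-form oracles.

**What the generator does not emulate:** reporter photobleaching, stage
drift, cell-edge geometry, CCS motility (structures are static), spatially
varying background, and clustered (non-Poisson) nucleation. Passing tests
therefore demonstrate correctness of the analysis chain under the stated
statistical model, not robustness to these real-data complications.

## Detection, tracking, measurement

`detect_spots()` is a Laplacian-of-Gaussian detector at the PSF scale:
local maxima of the negated, σ²-normalised LoG response, refined to
subpixel position by an intensity-weighted centroid in a
(2·⌈3σ⌉+1)² window after local-background subtraction. Two screens apply:

* an *absolute response threshold* `k_sigma` (default 4) in units of the
  robust (MAD) noise sd of the response map. A matched Gaussian spot of
  peak amplitude *a* has LoG response a/2, so the default keeps spots down
  to eight response-noise sds of amplitude while the expected number of
  false maxima per frame stays well below one. Lower thresholds were
  evaluated and degrade overall event recovery: the extra spurious
  detections trip the pre-quiet veto around genuine events.
* a *per-spot SNR* screen, SNR = (peak − annulus mean)/annulus sd over an
  annulus of radii (3σ, 3σ+2) px, with `snr_min = 2`.

`link_tracks()` is greedy nearest-neighbour linking: per cycle
transition, candidate pairs are processed in ascending Euclidean distance
(deterministic tie-break), assignments beyond `max_disp = 4` px are
forbidden, and a track survives up to `max_gap = 2` missing cycles. On
sparse fields (spacing > 2·max_disp) greedy assignment coincides with
exhaustive minimum-cost matching, which the tests verify by enumeration.

`measure_roi()` reports mean(disc of radius 3 px) − mean(annulus 5–8 px)
per cycle, never clipped. Because a disc mean attenuates a Gaussian peak,
`roi_psf_gain()` computes the exact aperture gain for the actual pixel
grid and subpixel centre; `extract_aligned_traces()` divides by it so that
aligned traces are in peak-amplitude units, directly comparable to kernel
amplitudes. The ROI geometry itself is a package default (no published
geometry exists for this assay).

## Scission calling

Candidates arise from two sources. *Track starts*: a TfR5 track whose
first detection is preceded by `pre_quiet = 3` cycles free of TfR5
detections within `max_disp` of the start position (tracks starting too
early to verify the quiet window yield no candidate). *Re-brightenings*:
successive scissions at one persistent CCS can be so close in time that
the new acid-resistant spot appears while the previous vesicle's spot is
still decaying; the tracker then continues the old track and no track
start exists. These events are recovered as abrupt fluorescence increases
within an ongoing track — a detected cycle whose ROI value steps above the
mean of the three preceding cycles by ≥ 3 of their sds. This is the same
fluorescence-change logic as the screening step, applied within a track;
without it, roughly one in fifteen events (those following a sibling
within ~15 s) is structurally invisible.

Screening (`screen_candidates()`) then enforces, with conservative and
configurable defaults: detection SNR ≥ 2 at t0; track persistence ≥ 3
cycles; and a fluorescence step value(t0) − mean(pre-window) ≥ 3 sd of the
pre-window. Rejected candidates carry a reason code.

`associate_and_classify()` assigns the nearest TfR7 track spanning t0
within 3 px as host. An event is *terminal* if the host track's last
detection falls within `closure_window = 10` s after t0, *non-terminal*
otherwise; if the movie itself ends inside the closure window the call is
undefined (`NA`) and excluded from terminal statistics — classifying such
events would be guessing. Ordinals number events by time within each
host. Events are assigned to the perfusion block containing t0.

## Recruitment signatures

`ensemble_signature()` computes the pointwise mean and SEM over
non-missing entries of the aligned-trace matrix (out-of-movie samples are
flagged missing, never zero-filled). SEM with a single contributing event
is defined as 0 and visible through `n_per_timepoint`.

`random_envelope()` builds the null reference by randomising event *time*,
not position: each event keeps its (x, y) and receives a t0 drawn
uniformly from the cycles at which the whole analysis window fits. This
preserves each location's background structure, which position
randomisation would destroy. B = 1000 resamples and the pointwise 2.5/97.5
percentiles give the 95% envelope; the construction is seeded. The exact
construction used historically with this assay is not published;
time-randomisation is this package's explicit choice.

`normalize_to_random()` rescales a signature so 0 is the envelope centre
and 1 its upper limit, making conditions with different expression levels
comparable; it is invariant under affine transforms of the reporter
channel. `peak_records()` takes each event's argmax in a window (default
−20..20 s; ties resolve to the earliest time; optional boxcar smoothing,
default off since no published smoothing exists). `signature_slope()` is
the OLS slope of the mean over an interval; `signature_amplitude()` is the
peak of the mean over [−20, +4] s minus the early baseline (−82 to −42 s),
offset-invariant by construction.

The default analysis window (−82, +40) s covers the plotted range of
published signatures and contains the clustering window.

## Clustering of recruitment signatures

Curves are restricted to the pre-scission window [−82, 0] s (42 samples at
2 s) — the shape of build-up, not post-scission decay, distinguishes
kinetic phenotypes. The distance is the raw (un-centred) cosine distance;
"correlation" and "cosine" are often conflated in this context, so the
centred variant (1 − Pearson) is exposed behind `centered = TRUE` and the
un-centred form is the default. A zero-norm curve is an error naming its
label.

`average_linkage()` implements UPGMA directly on the distance matrix
(inter-cluster distance = unweighted mean of member pairwise distances;
WPGMA behind `weighted = TRUE`), with ties broken by lexicographic order
of each cluster's smallest member label so trees are reproducible. The
result is `hclust`-compatible (`cutree`, `cophenetic`, `plot` all work);
the test suite cross-checks heights and cophenetic matrices against
`stats::hclust` as an independent reference. `cophenetic_correlation()`
computes the merge height of each pair's lowest common cluster explicitly
and correlates it with the input distances. Newick export goes through
`ape`.

## CCS maturation kinetics

`build_histories()` keeps TfR7 tracks that formed de novo — starting at
least `start_margin = 10` s after the movie start, since a track present
earlier may predate acquisition — and host at least one accepted event.
`time_to_nth()` reports mean ± sd of the time from nucleation to the n-th
event over histories reaching n (n ≤ 3 by default). Histories truncated by
the movie end contribute to every n they reach; no censoring model is
applied, a simplification that biases late-n means slightly downward in
short movies. The renewal simulation used to validate linearity
(`simulate_ccs_histories()`) therefore runs with `p_terminal = 0` so all
histories reach n = 3 — the natural condition for measuring multi-event
maturation kinetics — and recovers the configured mean interval as the
regression slope. Per-event variability is reported; per-cell pooling is
left to the caller.

## FRAP

`bleach_correct()` divides the bleach ROI by the reference ROI (normalised
to its pre-bleach mean), cancelling acquisition photobleaching exactly for
a shared exponential decay, then rescales so the pre-bleach mean is 1
(I₀ = 1). `fit_recovery()` fits F(t) = 1 − A·e^(−Kt) to the post-bleach
series by Levenberg–Marquardt least squares (initial A = 1 − F(0), initial
K from the half-recovery time with a 0.1 s⁻¹ fallback, three perturbed
restarts), and errors with diagnostics on degenerate traces (K or A
indistinguishable from 0). The half-time is ln 2 / K by definition, so
half_time · K = ln 2 holds identically for every fit.

Two modelling notes. First, the two-parameter model has plateau 1 by
construction; a non-unit plateau (immobile fraction, imperfect
normalisation) folds into the fitted A. The generator therefore defaults
to `bleach_floor = 0` and exposes a `mobile` plateau parameter for
emulating incomplete recovery; the three-parameter variant
(`model = "floor"`) fits a free plateau when needed. Second, the mobile
fraction is measured from the *data*, not the fit: 100 · I_t with I_t the
mean of the last 10 post-bleach corrected frames ("following recovery" is
not otherwise quantified; a tail average is less noisy than a single
endpoint). Values outside [0, 100] are reported but flagged. Frame rate
defaults to 1 Hz with 10 pre- and 100 post-bleach frames.

## Pipeline and reproducibility

`run_pipeline()` runs simulate → detect → signature → kinetics → frap from
one nested configuration (R list or YAML), writes CSV/JSON outputs and a
manifest with parameters, seed and MD5 hashes of every output. All
randomness flows from the single root seed through named substreams
(`substream_seed()`), so reruns are bitwise identical and stages are
independently reproducible. A stage failure aborts with the stage name;
completed outputs persist.

## Problem sizes and numerical choices

The validation studies use: 20 movies (96 px, 400 cycles) for detection
recall/precision; ≥ 500 pooled events for signature recovery; 50 replicate
null movies at B = 1000 for envelope calibration; 5 movies at
p_terminal = 0.5 for classification accuracy; 3 kinetic classes × 3
replicates for clustering; 500 renewal histories for maturation slopes;
200 noisy traces (5% noise) for FRAP recovery. These sizes give the
boundary quantities (recall, coverage, median errors) standard errors
comfortably below the margins being checked while keeping a full run on a
single CPU in minutes.

Numerical conventions: pixel coordinates are 1-based (R convention) with
x = column, y = row, and the pixel centre at the integer coordinate;
cycle indices are 1-based with cycle k at time (k−1)·dt; TIFF stacks are
written as 32-bit float after affine scaling to [0, 1] (offset and scale
recorded in the JSON sidecar), so round-trips are exact to float32
quantisation (~10⁻⁵ counts at default ranges); linking and merge
tie-breaks are deterministic (ascending distance; lexicographic labels);
cosine distances are clamped at 0 against negative round-off.

## Known limitations

* The detector assumes a known, isotropic Gaussian PSF scale; strongly
  defocused or elongated spots will be mislocalised.
* Events closer than ~2 cycles at the same CCS merge into one call; the
  re-brightening source recovers gaps ≳ 6 s but not simultaneous events.
* No censoring correction in maturation statistics (see above).
* The random envelope assumes event positions are fixed landmarks; if
  real CCS drift, the null would need motion-aware resampling.
* FRAP fitting covers reaction-dominant recovery; diffusion-dominated
  models (e.g. Soumpasis) are out of scope.
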