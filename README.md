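# pulsetrack

Quantitative analysis of single membrane-scission events in
clathrin-mediated endocytosis (CME) from **pulsed-pH TIRF microscopy**, with
a fully seeded synthetic-movie generator for validation against known ground
truth.

## The assay and the problem

In the pulsed-pH assay, cells expressing transferrin receptor fused to
pHluorin (TfR-phl) are imaged by TIRF microscopy while the perfusate
alternates between pH 7.4 and pH 5.5 every imaging cycle (2 s). At pH 7.4
the receptor is fluorescent wherever it sits, so clathrin-coated structures
(CCS) appear as spots ("TfR7"). At pH 5.5 all surface fluorescence is
quenched; only receptor enclosed in a sealed, internalised vesicle remains
bright ("TfR5"). **Membrane scission** — the moment a clathrin-coated
vesicle pinches off — therefore manifests as the abrupt appearance of an
acid-resistant TfR5 spot, giving single-event time resolution for vesicle
formation. A co-expressed mCherry-tagged reporter (dynamin, endophilin,
actin, ...) is imaged in parallel, and aligning its fluorescence to many
scission times t = 0 yields an **ensemble recruitment signature**: the
average kinetics of that protein's recruitment relative to scission.

The package is for microscopists and image analysts who want a tested,
scriptable reimplementation of this analysis chain:

1. **Synthetic movies** (`simulate_movie()`): alternating-pH stacks with
   CCS nucleation (spatial Poisson process), renewal-process scission
   events, terminal/non-terminal CCS fates, a parameterised reporter
   recruitment kernel (flicker + pre-scission burst + optional early
   enrichment), PSF rendering, Poisson + Gaussian noise, and complete
   ground truth.
2. **Movie I/O** (`load_movie()`, `save_movie()`, `deinterlace()`,
   `segment_blocks()`): TIFF stacks with a JSON sidecar; de-interlacing
   into pH 7.4 / pH 5.5 series; 400-frame perfusion blocks.
3. **Detection and tracking** (`detect_spots()`, `link_tracks()`,
   `measure_roi()`): Laplacian-of-Gaussian spot detection with subpixel
   centroids and SNR screening; greedy nearest-neighbour linking with gap
   closing; disc-minus-annulus fluorescence traces.
4. **Scission calling** (`call_scissions()`): candidate TfR5 appearances
   (new tracks and within-track re-brightenings), screened for S/N,
   persistence and fluorescence change; association to host TfR7 CCS;
   terminal vs non-terminal classification; incidence rates per
   µm² per minute.
5. **Recruitment signatures** (`ensemble_signature()`,
   `random_envelope()`): event-aligned mean ± SEM with a randomised 95%
   confidence envelope (event times resampled uniformly, positions kept);
   peak-time histograms, recruitment slopes, burst amplitudes.
6. **Clustering** (`cosine_distance_matrix()`, `average_linkage()`,
   `cophenetic_correlation()`): pairwise cosine distances
   d(i,j) = 1 − uᵢ·uⱼ/(‖uᵢ‖‖uⱼ‖) of pre-scission curves (−82 s to 0),
   UPGMA dendrograms with deterministic tie-breaking, cophenetic
   validation, Newick export.
7. **CCS maturation kinetics** (`build_histories()`, `time_to_nth()`):
   time from de novo CCS nucleation to the n-th hosted scission.
8. **FRAP** (`bleach_correct()`, `fit_recovery()`, `mobile_fraction()`):
   reference-ROI bleach correction, nonlinear fit of
   F(t) = 1 − A·e^(−Kt), half-time ln 2 / K, tail-average mobile
   fraction.

A `run_pipeline()` orchestrator executes simulate → detect → signature →
kinetics → frap from a single YAML/list configuration with one root seed
and writes a manifest with output hashes; reruns are bitwise identical.

## Worked example

```r
library(pulsetrack)

cfg <- sim_config(n_cycles = 200, field_size = 80, nucleation_rate = 0.04)
sim <- simulate_movie(cfg, seed = 42)
sim$movie
#> ph_movie: 80 x 80 px, 400 frames (200 cycles), dt = 2 s, 0.13 um/px
#>   blocks: 1; reporter channel: present

res <- call_scissions(sim$movie)
m <- match_events(res$events, sim$truth$scissions)
#> 34 events called of 35 true: recall 0.97, precision 1.00
#> 20 terminal, 12 non-terminal (2 undefined at the movie end)

tr  <- extract_aligned_traces(sim$movie$reporter, res$events,
                              window = c(-82, 40), dt = 2)
sig <- with_envelope(ensemble_signature(tr),
                     random_envelope(sim$movie$reporter, res$events,
                                     c(-82, 40), 2, B = 1000, seed = 1))
sig
#> recruitment_signature: 62 timepoints (-82..40 s), max n = 34
#>   peak mean 113.27 at t_rel = -2 s; envelope: present
```

The reporter burst peaks 2 s before vesicle detection, matching the
generator's kernel (`burst_peak_offset = -2`); the peak mean is the burst
amplitude (100 counts) on top of the flicker baseline. FRAP fitting:

```r
f <- fit_frap(simulate_frap_trace(frap_sim_config(A = 0.8, K = 0.2,
                                                  noise_sd = 30),
                                  seed = 3)$trace)
f
#> FRAP recovery fit (standard model): F(t) = 1 - A exp(-K t)
#>   A = 0.8314, K = 0.2070 /s, half-time = 3.35 s
#>   mobile fraction = 99.6% (tail mean), RSS = 0.0958
```

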