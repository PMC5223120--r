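# antArena

Semi-automated monitoring of seed dispersal by ants (myrmecochory) from
stitched time-lapse imagery — an R package for laboratory arenas where
millimetre-scale diaspores are carried metres from a nest.

Studying myrmecochory requires resolving 1–2.5 mm seeds anywhere on a
multi-square-metre arena, over days, and telling them apart from the
4–6 mm ants that move them. `antArena` implements the full measurement
chain for that problem, for behavioural ecologists running controlled
dispersal experiments:

* **Stitching** — two overlapping camera views are equalized by an
  additive luminosity offset to the global mean, registered with a
  homography estimated by the normalized DLT from checkerboard
  correspondences, optionally undistorted with a radial lens model
  (r<sub>c</sub> = r(1 + k₁r² + k₂r⁴)), and composited along a *hard
  stitch line* — no blending, so no seed is ever duplicated or blurred.
* **Detection** — per-pixel modal-RGB background over 15 frames;
  a pixel is a candidate when its Euclidean RGB distance to the background
  exceeds a threshold *and* it is dark; a 2-of-3 temporal persistence
  filter separates static seeds from moving ants; connected components of
  5–19 px (1–2.5 mm at 0.677 mm/pixel) are seeds, larger persistent blobs
  are discarded static ants, and the moving remainder are ants.
* **Platform census** — dark-blob counting of diaspores remaining on the
  foraging platform (ant-sized blobs subtracted) and directed
  line-crossing counts of ant trajectories at the bridge gate.
* **Tracking** — seed detections are linked into occupancy *episodes*
  (duration λ = occupied frames × Δt), yielding rejection dynamics and
  minimum redispersal distances (nearest episode opening within 2 frames
  of a closure).
* **Spatial statistics** — nearest-neighbour G-function
  G(d) = #{NNᵢ ≤ d}/n with no edge correction inside a 5 cm border
  buffer; Monte-Carlo envelopes from fixed-n CSR (binomial) simulations;
  the Diggle–Cressie–Loosmore–Ford test with one-sided upper alternative,
  u = ∫₀^dmax (Ĝ − Ḡ_sim)² dd and exact rank p-value
  p = rank/(n_sim + 1); characteristic clustering vs CSR distances
  (NNdist_cluster, NNdist_CSR); Rayleigh, Kuiper, Watson and Rao spacing
  uniformity tests; radial density profiles.
* **Simulator** — agent-based isotropic centrifugal dropping: *blind*
  carriers drop at a drawn target distance, *reactive* carriers drop as
  soon as a previously dropped seed lies within a 5 mm perception range.
* **Synthetic scenes** — a ground-truthed renderer (noisy floor, scheduled
  seeds, walking ants, two-camera split with known homography) used by the
  whole test suite; no external data needed anywhere.

## Worked example

```r
library(antArena)

# 1. render a ground-truthed scene: 12 seeds appear at frame 3
truth  <- randomScene(nSeeds = 12, arenaRadiusCm = 6, noiseSigma = 5,
                      seedAppear = 3, seed = 1)
frames <- lapply(1:5, function(f) renderFrame(truth, f))

# 2. modal background from the seed-free frames, then the full pipeline
bg  <- buildBackground(frames[1:2])
det <- detectSequence(frames[3:5], bg, nestCentre = sceneNestCentre(truth))
det[[2]]
#> FrameDetections: frame 2 (t = 30 min): 12 seed(s), 1 ant(s), 0 discarded

head(seeds(det[[2]]), 3)
#>       x_px     y_px size_px      x_cm      y_cm
#> 1 15.50000  87.5000      12 -4.942100  0.067700
#> 2 37.00000  42.5000      12 -3.486550  3.114200
#> 3 45.36364 157.0909      11 -2.920332 -4.643605
```

All 12 scheduled seeds are recovered with blob sizes inside the 5–19 px
gate and centimetre coordinates relative to the nest. (The stray 1-pixel
"ant" is an isolated noise pixel: ants carry no size threshold, and the
persistence filter plus size gate protect only the seed class.)

```r
# 3. spatial analysis of a dispersal pattern (simulated, reactive dropping)
sim <- simulateDispersal(dispersalConfig("reactive", nSeeds = 200, seed = 1))
res <- analyzePattern(sim$pattern, buffer = 5, nSim = 999, seed = 1)
res$dclf
#> DCLF test (upper): U = 0.2602, rank = 1, p = 0.001 -> clustered

round(res$characteristic$nndist_cluster, 2)
#> median     q1     q3      n
#>   4.41   0.47   6.60  91.00
round(res$characteristic$nndist_csr, 2)
#>   median       q1       q3        n
#>     7.55     5.16     9.64 91220.00
round(res$summary, 1)
#> median     q1     q3      n
#>  124.6   87.5  158.7  190.0
```

The reactive pattern is the most extreme among its 999 CSR simulations
(rank 1, p = 0.001 → clustered); seeds in the clustered fraction sit at a
median nearest-neighbour distance of 4.4 cm versus 7.6 cm for the same
fraction under CSR, and half of the seeds lie within ~125 cm of the nest.

A thin command-line wrapper over the same functions ships in
`inst/scripts/arena-tools.R` (subcommands `stitch`, `detect`, `track`,
`stats`, `simulate`, `synth`).

## Package layout

S4 containers with validity checks (`ArenaFrame`, `BackgroundModel`,
`FrameDetections`, `PointPattern`, `EnvelopeResult`, `DCLFResult`,
`SceneTruth`, `PlatformROI`) carry the data between modules; accessors
(`pixels()`, `seeds()`, `ants()`, `coords()`, …) rather than slot access.
See the methods vignette (`vignettes/arena-methods.Rmd`) for the models,
parameter choices, numerical conventions and known limitations.
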