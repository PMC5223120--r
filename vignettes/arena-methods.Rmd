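---
title: "Monitoring seed dispersal by ants: methods and design notes"
author: "antArena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring seed dispersal by ants: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Myrmecochory — seed dispersal by ants — couples millimetre-scale objects
(diaspores of 1–2.5 mm, workers of 4–6 mm) with metre-scale dispersal
distances. Monitoring it in a laboratory arena therefore needs imagery that
is simultaneously wide (a disc two metres in radius) and fine
(sub-millimetre pixels), plus image analysis that can tell a static seed
from a moving ant in time-lapse frames taken minutes apart. `antArena`
implements that pipeline end to end:

1. **stitching** two overlapping camera views into one high-resolution
   composite with homogeneous exposure and a hard stitch line;
2. **detection** of seeds and ants by background subtraction, darkness
   segmentation, temporal persistence and size-gated blob classification;
3. **platform** censuses (remaining diaspores, ant in/out flow at a gate);
4. **tracking** of seed occupancy episodes, rejection dynamics and
   redispersal distances;
5. **spatial statistics** on rejected-seed patterns (nearest-neighbour
   G-function, CSR envelopes, DCLF test, characteristic distances,
   circular uniformity, radial density);
6. an agent-based **simulator** of blind versus reactive centrifugal seed
   dropping;
7. a **synthetic-scene generator** that renders ground-truthed arena
   imagery so that every stage above is testable without external data.

# Stitching

Two cameras image the arena with an overlapping band. Exposure differs
between cameras, so all captured images are first shifted by an additive
luminance offset to the global mean luminance (luminance = mean of R, G,
B). An additive offset is exposure-like, preserves within-image contrast
ordering exactly, and is reversible away from the 0–255 clip.

The geometric link between views is a homography estimated from
checkerboard correspondences by the normalized direct linear transform
(both point sets are centred and scaled to mean distance $\sqrt2$, the
$2n\times 9$ system solved by SVD). Corner extraction itself is out of
scope: the estimator consumes ready-made point pairs (CSV). Lens
distortion is handled by a two-coefficient radial model
$r_c = r(1 + k_1 r^2 + k_2 r^4)$; producing a corrected image inverts the
model per output pixel by Newton iteration and samples bilinearly.

Compositing deliberately does **not** blend: blending can duplicate or
blur a seed that projects slightly differently in the two views. Instead a
*stitch line* partitions the composite — every pixel originates from
exactly one camera. The default line is the perpendicular bisector of the
two image centres in composite coordinates; any polyline can be supplied.
The composite covers the joint bounding box of view A's corners and view
B's warped corners, with view B resampled bilinearly (nearest-neighbour
available for bit-exact tests).

# Detection

* **Background.** The static background is the per-pixel *modal* RGB
  triplet over a set of frames (15 by convention). Ties are broken towards
  the lexicographically smallest triplet, a deterministic and testable
  rule; with continuous sensor noise the mode degenerates towards that
  tie-break, which biases the background slightly dark — harmless here
  because detection requires pixels to be both *changed* and *dark*.
  Residual artefacts can be overwritten with manual patches, mirroring
  manual background cleaning.
* **Segmentation.** A pixel is *changed* when its Euclidean RGB distance
  to the background strictly exceeds `diffThreshold` (default 40 grey
  levels), and *dark* when its luminance is at most `darkThreshold`
  (default 90). The thresholds are not published values; the defaults are
  robust for dark seeds on a light floor, and the validation benchmarks pin
  pipeline behaviour through synthetic scenes rather than through these
  numbers.
* **Persistence.** Seeds are static; ants move. A pixel is retained when
  present in at least two of three consecutive segmented masks, the output
  being aligned with the middle frame. The first and last frames of a
  sequence consequently get no seed detections. An ant that displaces by
  more than its body length per frame shares no pixels between consecutive
  frames and is eliminated entirely.
* **Blobs and the size gate.** Connected components (8-connectivity by
  default; seeds are compact) of the persistent mask with 5–19 pixels are
  seeds — at 0.677 mm/pixel this brackets rounded seeds 1–2.5 mm wide.
  Persistent blobs outside the gate are discarded as static ants or
  stains. Components of the non-persistent (moving) part of the frame's
  mask are ants, with no size threshold.

Pixel coordinates are 0-based, x rightward, y downward; arena coordinates
are centimetres relative to the nest centre with y pointing up,
`cm = (px - nest) * resolution / 10`.

# Tracking

Detections are linked into *episodes* — one seed occupying one place over a
contiguous frame interval. A detection within `matchRadiusPx` (default
3 px ≈ 2 mm; seeds are static, anything farther is a redispersal) of an
open episode continues it, the episode position being the running mean;
the first frame with no match closes the episode. Durations count occupied
frames, $\lambda = (\text{last} - \text{first} + 1)\,\Delta t$, so a seed
seen in two consecutive 10-minute frames has $\lambda = 20$ min — matching
the convention under which the shortest measurable residence is one frame
interval times two observations.

The minimum redispersal distance of an episode closing at frame $t$ is the
distance to the nearest episode opening within the next two frames
(20 minutes at $\Delta t = 10$); with no candidate the value is undefined
(`NA`), never zero-filled. Episodes spanning an imaging gap (inter-frame
interval above 1.5 $\Delta t$, e.g. a night pause) are flagged `gap = TRUE`
so duration statistics can exclude them; whether truncated episodes should
enter duration summaries is genuinely ambiguous, so the flag leaves the
choice to the analyst.

# Spatial statistics

Only seeds at least 5 cm from the arena border are analysed (a disc of
radius $R - 5$), which avoids edge bias without edge-correcting the
estimator: the **G-function** is the raw empirical CDF of
nearest-neighbour distances, $G(d) = \#\{NN_i \le d\}/n$, and the
*identical* estimator is applied to observed and simulated patterns, so
the comparison is internally unbiased.

The CSR null is a *binomial* process — exactly $n$ points uniform in the
region, honouring "the same number of seeds" — simulated `nSim` times
(1000 by convention). The pointwise envelope is the min/max of the
simulated curves; the distance grid is 512 equal steps from 0 to the
region diameter. Note that a min/max envelope of $m$ simulations is a
*pointwise* band: the probability that a CSR curve escapes it **somewhere**
is far above $2/(m+1)$ (the suite measures roughly 30% at $m = 99$), which
is why significance is never read off the envelope but from the DCLF test,
and why envelope displays use the full 1000 simulations.

The **DCLF test** integrates the squared deviation of $G$ from the
simulation mean up to $d_{\max}$ (default: the 95th percentile of pooled
simulated NN distances; the integration range is not prescribed anywhere,
so it is configurable). With the one-sided *upper* alternative only
positive deviations (excess short distances, i.e. clustering) contribute.
Each simulation's statistic is computed against the mean of the *other*
simulations, preserving exchangeability, so the Monte-Carlo rank test is
exact: $p = \mathrm{rank}/(n_{sim}+1)$ with rank $= 1 +$ the number of
simulated statistics exceeding the observed one; rank 1 among 1000
simulations prints as $p = 0.001$. Suite calibration: empirical type-I
error within $[0.03, 0.08]$ at $\alpha = 0.05$ under CSR, and ≥95% power
against Thomas cluster patterns (20 parents × 10 offspring, σ = 3 cm, in a
195 cm disc).

When a pattern is declared clustered, the *characteristic clustering
distance* summarizes the clustered fraction: $f^\star$ is the largest
observed $G$ value at distances where the observed curve lies strictly
above the envelope's upper bound; observed NN distances up to their
$f^\star$ quantile give the cluster summary (median [Q1; Q3], type-7
quantiles throughout so summaries are bit-reproducible), and the same
per-simulation fraction pooled over simulations gives the CSR reference.
The construction of "the fraction of distances above the envelope" admits
more than one reading; this one is used consistently and deliberately
documented here.

**Circular statistics.** Four uniformity tests on the polar angles of
seeds around the nest: Rayleigh (mean resultant length with the standard
series p-value), Kuiper and Watson $U^2$ (rotation-invariant EDF tests
with their modified-statistic asymptotic p-values), and Rao's spacing.
For Rao's spacing no closed-form p-value exists; instead of hard-coded
critical tables the null distribution is simulated once per sample size
(2000 uniform samples, fixed internal seed, cached), giving a Monte-Carlo
p-value that is exact up to simulation error and self-contained.

**Radial density** groups seeds into 10 cm concentric rings (half-open
$[kw, (k+1)w)$) and divides counts by ring areas clipped to the region.

# The dispersal simulator

Carriers leave the nest one at a time at a uniformly random heading — the
random orientation of ants leaving a nest — and walk outward in straight
0.25 cm steps towards a target distance drawn from the drop-distance law.
*Blind* carriers drop exactly at the target; *reactive* carriers drop at
the current position the first time a previously dropped seed lies within
the perception range (5 mm by default). The step never exceeds the
perception range, so a perception disc cannot be stepped over; with
perception 0 the reactive model reduces to the blind one exactly (same
random draws). Redispersal is deliberately absent from the simulator.

The drop-distance law is a genuine design choice: the underlying
supplementary model specification is not available. The default is
**uniform-area** ($r = R\sqrt U$), under which blind dropping *is* CSR on
the arena disc — consistent with blind dropping only rarely being declared
clustered — and whose median distance $R/\sqrt2 \approx 138$ cm for the
195 cm analysis disc echoes observed median seed distances. A truncated
exponential law (mean 141 cm) is available as an option; note that its
point density diverges like $e^{-r/\mu}/r$ near the nest, so against a
uniform-disc CSR null even blind dropping would be flagged clustered
almost always — a property of the law, not of the dropping behaviour,
and the reason it is not the default.

Classification of simulated patterns reuses the spatial-statistics module
unchanged (5 cm buffer, envelope of 99 simulations, DCLF upper test at
$\alpha = 0.05$).

# The synthetic-scene generator

The generator emulates what the detection pipeline actually faces: a light
floor (mean 200 grey levels) with Gaussian pixel noise (default σ = 5),
dark objects (luminance ≈ 30), per-camera luminance offsets (default
±10 grey levels) in two-view mode with ≥20% overlap and a known
ground-truth homography, seeds appearing and disappearing on schedule, and
ants performing a bounded random walk displacing at least one body length
per frame. Rendering is deterministic given the scene seed, with an
independent noise stream per frame and per camera.

Seed rasterization is an *empirical calibration, not disc geometry*: an
ideal 1 mm disc at 0.677 mm/pixel covers fewer than 2 pixels, yet real
seeds of that size segment into ≥5 pixels (penumbra, compression
artefacts, imperfect focus). The rendered core radius is therefore an
affine function of physical width tuned once so that default segmentation
yields blob sizes spanning roughly 7–18 px across widths 1–2.5 mm,
inside the published 5–19 px gate with margin for noise. Ants are capsules
whose dark core exceeds the gate (so *static* ants are discarded by size,
as in the real system).

What the generator does **not** emulate: shadows, paper texture, wall
reflections, lens vignetting, compression artefacts, or ant legs/antennae.
Passing the synthetic benchmarks therefore demonstrates the pipeline's
logic (stitching equivalence, persistence filtering, size gating,
episode recovery) under controlled noise — it does not certify detection
rates on any particular real imaging setup.

# Benchmark problem sizes

The standard detection benchmark renders 20 two-view layouts of 58 seeds
each (the size of the reference manual-validation sample) in a
15.5 cm-radius scene at 0.677 mm/pixel — small enough to render quickly,
large enough that 58 seeds sit at realistic separations. The
discrimination benchmark uses 14 sequences of 3 ants in a 22 cm-radius
scene (42 ants, 70 persistence triplets), keeping the ant density near the
monitored system's (a few ants per thousand cm²). Density matters: in an
overcrowded scene two *different* ants can cross the same pixels in
consecutive frames, which the 2-of-3 persistence rule cannot distinguish
from a static object. That failure mode is a genuine property of
persistence filtering at high density, listed below as a limitation.

# Known limitations

* Persistence filtering confuses two different ants crossing the same
  location in consecutive frames with a static object; specificity claims
  hold at realistic ant densities.
* The blob-size ↔ physical-size mapping is empirical; transferring the
  5–19 px gate to another resolution requires recalibration.
* The modal background degenerates to the lexicographic tie-break under
  continuous noise; it works here because detection also requires
  darkness, but scenes with dark floors would need a different tie rule.
* Min/max envelopes are pointwise; only the DCLF rank test carries
  significance.
* The simulator's drop-distance law and straight radial paths are design
  choices; comparisons of simulated versus observed cluster-to-nest
  distances are therefore not meaningful contracts.
* Night gaps are flagged, not modelled; episodes spanning them are
  excluded from duration statistics by default.
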