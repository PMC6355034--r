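---
title: "Models and methods behind casakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind casakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casakit)
```

casakit is a computer-assisted sperm analysis (CASA) toolkit built
around four analyses — motility kinematics, directional-bias
(chemotaxis/thermotaxis/rheotaxis) testing, head morphometry and
live/dead viability counting — plus a persistent-random-walk simulator
that generates fully synthetic ground-truth data for all of them. This
vignette explains the models, the estimators, the tunable parameters and
the numerical conventions, and states explicitly what the synthetic
validation does and does not demonstrate.

## The persistent random walk simulator

Each virtual cell carries a position $(x, y)$ (px) and a heading $\psi$
(rad). Per frame (the integration step is fixed at one frame, so all
rates are per frame):

$$\psi' = \psi - \frac{\beta}{\tau}\,\sin(\psi) + \sqrt{2 D_{rot}}\, z,
\qquad z \sim \mathcal N(0, 1),$$
$$x' = x + v_0 \cos\psi', \qquad y' = y + v_0 \sin\psi'.$$

$D_{rot}$ (rad²/frame) is the rotational diffusion coefficient; $v_0$
(px/frame) the constant swimming speed; the $-(\beta/\tau)\sin\psi$ term
relaxes the heading toward the $+x$ axis (a uniform external field) at
rate $\beta/\tau$, with the sign of $\beta$ selecting the direction.
Only a fraction of the population — the `responsiveness`, mimicking the
capacitated subpopulation — feels $\beta$; the remaining cells swim with
$\beta = 0$. Defaults are the reference validation configuration: 100
cells, 500 frames, $D_{rot} = 0.1$, $v_0 = 3$, $\beta = 0$,
800 × 800 px arena.

Choices a user should know about:

* **Update order.** The heading update is applied first and the
  displacement of the same step uses the new heading. Any consistent
  Euler scheme is acceptable; this one is fixed for reproducibility.
* **$\tau$ defaults to 1 frame**, so $\beta$ alone sets the alignment
  rate; only $\beta$ values are conventionally reported.
* **Initial headings.** `psi0 = "uniform"` draws initial headings
  uniformly on the circle and is the right choice for statistical
  baselines (every displacement angle is then exactly uniform).
  `psi0 = 0` reproduces the reference configuration; with
  $D_{rot} = 0.1$ the heading distribution needs on the order of 50
  frames to forget a common start, and over a 500-frame recording this
  transient raises the expected fraction of displacements within
  ±30° of the axis from 16.67 % to about 17.5 % — most of the gap
  between the idealised 60/360 value and the published pipeline value of
  17.90 % is this transient, not detection noise.
* **Boundaries.** Positions are never reflected; cells may leave the
  arena and are clipped only at render time. Frames use image
  coordinates (origin top-left, x right, y down, 0-based frame index);
  angles follow `atan2(dy, dx)` in that frame.
* **Rendering.** Cells are painted as filled bright ellipses (default
  semi-axes 5 × 4 px, i.e. a 10 × 8 px cell) on a black background,
  major axis along the current heading (estimated from the forward
  displacement). Same seed, same track table, bit for bit.

## Detection and tracking

`segment_frame()` applies an Otsu threshold (computed in-package on a
256-bin histogram of the 0–255 range; agreement with the EBImage
reference implementation is asserted in the test suite), labels
8-connected foreground components with a compiled flood-fill pass,
discards components outside the `[min_cell_size, max_cell_size]` window
(µm²) and returns sub-pixel, intensity-weighted centroids. A polarity
flag (`invert`) accommodates dark-on-bright (bright-field) images.

`link_frames()` is deliberately the simple linker of the classic CASA
lineage: for each pair of consecutive frames, candidate matches are all
blob pairs within the search radius `max_displacement / um_per_px` px,
accepted greedily in ascending distance order (ties broken by blob
index, which is raster order), each blob used at most once. Unmatched
new blobs open tracks; unmatched old tracks end. There is no gap
closing and no motion model: a missed detection terminates the track,
and two cells that cross may merge into one blob for a few frames, which
ends one track and later starts another. This noise source is part of
the validated behaviour (it is visible in the full-pipeline validation
below). Kalman-style tracking is out of scope by design: the aim is a
transparent, deterministic reference implementation.

`filter_tracks()` removes tracks shorter than `min_track_length`
(default 10 frames) and refuses settings where that exceeds the video
length.

## Kinematic parameters

For a trajectory $\{p_t\}_{t=1}^N$ with scale $\mu$ (µm/px) and frame
rate $f$ (fps), the average path $\{q_t\}_{t=1}^{N-w+1}$ is the
rectangular moving average with window $w$ (default 5; valid range 2 to
$N-1$; no edge padding). Then:

* **VSL** $= D(p_1, p_N)\, f \mu / (N-1)$ — net space gain per second.
* **VCL** $= \sum_t D(p_t, p_{t+1})\, f \mu / (N-1)$ — curvilinear
  path speed.
* **VAP** $= \sum_t D(q_t, q_{t+1})\, f \mu / (N-w)$ — average-path
  speed.
* **LIN** $= 100\,\mathrm{VSL}/\mathrm{VCL}$, **WOB**
  $= 100\,\mathrm{VAP}/\mathrm{VCL}$, **STR**
  $= 100\,\mathrm{VSL}/\mathrm{VAP}$; any ratio with a zero denominator
  is reported as `NA` and excluded from population means of that
  parameter only.
* **ALH.** For each average-path segment midpoint
  $qm_t = (q_t + q_{t+1})/2$ the deviation to the nearest raw segment
  drawn from the window $p_t \dots p_{t+w-1}$ (closed point-to-segment
  distance) forms a series; strict local maxima of that series are the
  lateral peaks, and ALH (mean and max) is twice the peak deviation in
  µm — the peak-to-trough convention. A series with no local maxima
  (a straight line) reports 0, which keeps DNC defined.
* **BCF** counts proper transversal crossings between any raw segment
  and any average-path segment, scaled by $f/(N-w)$ to Hz. Collinear
  overlaps and endpoint touches are not crossings. The orientation
  determinants are snapped to zero below a relative tolerance of
  $10^{-9}$ so that a nominally straight path and its own moving
  average (identical up to rounding) produce BCF = 0 rather than
  counting femto-scale wobbles; the test suite pins the count to an
  independent brute-force parametric-intersection oracle on random
  walks.
* **MAD.** Directions are taken from displacements
  $p_t \to p_{t+\Delta}$ (default $\Delta = 1$). The default reading is
  the time average of the absolute wrapped turning angle between
  consecutive directions, in degrees — the quantity the classical
  definition describes in words. The literal algebraic reading of the
  same definition (a plain average of the direction angles themselves)
  is available as `mode = "literal"` for comparison, because the two
  disagree and the field's prose and formula do not match; the
  turning-angle reading is the default as it is the one with the stated
  physical meaning. Zero-length displacements contribute no direction.
* **DNC** $= \mathrm{VCL} \times \mathrm{ALH}_{mean}$ (µm²/s).
* **FD**, the Katz fractal dimension,
  $\log n / (\log n + \log(d/L))$ with $n = N - 1$, $d$ the maximum
  distance from the first point and $L$ the curvilinear length: exactly
  1 for straight lines, approaching 2 for plane-filling walks,
  undefined for stationary tracks.
* **Motile** ⇔ VCL strictly above `min_vcl` (default 10 µm/s) and the
  first and last points differ. **Progressive** ⇔ motile and STR >
  `str_threshold` (default 80 %) and VAP > `vap_threshold` (default
  25 µm/s).

One caveat surfaced by the oracle tests: for a synthetic triangle wave
whose period equals $w$, the ALH deviation series peaks at
$2a/\sqrt{1+a^2}$ rather than at the wave half-amplitude $a$, because
the raw path passes close to every average-path midpoint. ALH as
defined is a beat-envelope proxy, not a literal wave amplitude; the
tests therefore assert equivalence with the definition's own distance
scan and monotonicity in the true amplitude, not a closed-form
recovery.

## Directional-bias (chemotaxis) statistics

For every track, the instantaneous directionality angle $\psi_t$ is the
signed angle between the displacement $p_t \to p_{t+\Delta}$ and the
gradient direction $\theta$ (degrees, wrapped to $(-180, 180]$;
zero-length displacements are skipped). Angles are pooled across all
trajectories of a sample — the statistic is a population total, not a
per-track average. With cone half-amplitude $\gamma$ (default 30°,
closed interval):

* $N^+ = \#\{\psi \in [-\gamma, +\gamma]\}$;
* option 1: $N^- = \#\{\psi \notin [-\gamma, +\gamma]\}$;
* option 2: $N^- = \#\{\psi \in [180-\gamma, 180+\gamma]\}$ (wrapped),
  ignoring side-pointing displacements — for chamber geometries where
  only up- versus down-gradient motion is informative.

The **ch-index** is $100\,N^+/(N^+ + N^-)$; under uniform angles with
$\gamma = 30°$ and option 1 its expectation is $60/360 \times 100
\approx 16.67\,\%$. The **odds value** is $N^+/N^-$ and the **O.R.**
of a test over a control is the ratio of their odds values; 1 means no
difference, above 1 means attraction toward the gradient.

**Bootstrap null.** The decision threshold comes from control
recordings only: each iteration draws two disjoint subsets of
trajectories from the pooled controls, computes each subset's pooled
odds and their ratio, and the 95th percentile of the resampled ratios
(default 10000 iterations) is the threshold; an experimental O.R.
strictly above it is called positive, for a nominal 5 % type-I error.
Iterations with a zero count anywhere are redrawn (bounded, logged in
the result). Trajectories return to the pool between iterations.

The one genuinely open design choice here is the subset size, and it
matters. The null must reproduce the sampling variability of the
statistic being tested, and an experimental O.R. compares two samples
of roughly one recording's worth of trajectories. Subsets of that size
(`subset_size = pool / n_recordings`, the default — 100 trajectories in
the validation configuration) give a null whose spread matches the
pairwise comparison, and the empirical type-I error lands at ≈5 % as
intended. Splitting the pool into two halves instead (also available,
`subset_size = floor(n/2)`) makes each subset's counts so large that
the null collapses around 1; its P95 would sit far inside the
pair-to-pair variability and nearly half of all unbiased pairs would be
called positive. The package therefore defaults to recording-sized
subsets; the half-split remains available for sensitivity analyses.

## Simulation-based validation

`simulate_ch_index()`, `simulate_or_null()` and
`simulate_false_positives()` rerun the validation protocol end to end;
`scripts/acceptance.R` drives them and writes a JSON report. The
problem sizes are the package's chosen validation scale: 400
trajectory-only runs for the uniform baseline; 30 rendered runs for the
full detection–linking pipeline (each run segments 500 frames of
800 × 800 px); 100 control simulations and 10000 resamplings for the
null; 100 independent pairs for the type-I error. Expected outcomes:
the uniform baseline within sampling error of 16.67 %; the rendered
pipeline near 17.5–17.9 % (initial-heading transient plus
crossing/merge noise); the null centred at 1 with SD ≈ 0.05; about 5 %
false positives.

What passing these checks shows: the estimators are internally
consistent, unbiased where they should be, and the decision procedure
holds its nominal error rate on data that satisfies the model. What it
does not show: performance on real microscopy, where illumination
gradients, debris, out-of-focus cells, flagella and drift violate the
synthetic assumptions (uniform background, rigid ellipse cells, no
photometric noise). The synthetic generator emulates cell density,
motion statistics and crossing artifacts; it does not emulate optics.
Settings for real data — especially the size window, `max_displacement`
and `min_vcl` — must be calibrated per microscope and species, ideally
against a second analysis system.

## Morphometry

Stills are segmented like frames; each retained blob is measured as:
mean gray value on the original image (0–255); area = pixel count ×
µ²; perimeter = length of the 8-connected boundary chain with diagonal
steps weighted √2; length and width = maximum and minimum caliper
(Feret) diameters of the convex hull of the boundary pixels, by
rotating calipers, plus a 0.5 px boundary correction (calipers on
pixel centres sit, on average over orientations, about a quarter pixel
inside the true outline on each side; the measured deficit on rendered
ellipses spans 0–0.75 px). Derived ratios: ellipticity $L/W$,
roughness $4\pi A/P^2$, elongation $(L-W)/(L+W)$, regularity
$\pi L W/(4A)$. Two biases are inherent and documented rather than
hidden: the chain-code perimeter overestimates smooth outlines by up to
≈8 % depending on orientation, so roughness of a digital disc lands
near 0.9 rather than 1; and all boundary-based measures lose accuracy
below a few hundred pixels of area. Blobs touching the image border
are flagged `on_border` and still reported. The `exclude` argument is
the semi-automated step: ids the operator rejects after inspection.

## Viability

The red and green channels of a dual-stained fluorescence image are
segmented independently with the same size window; green blobs count as
membrane-intact (viable), red blobs as damaged. A cell visible in both
channels — footprint overlap above half of the smaller blob — is
counted once, assigned to the channel with the higher mean intensity
over the blob footprint (dual-stained cells retain some green signal,
so intensity dominance is the observable proxy for the dominant stain).
The blue channel is ignored. Channel-swap symmetry and invariance to
uniform brightness scaling are asserted in the tests.

## File formats and the command line

Tracks travel as CSV (`track_id, frame, x_px, y_px[, responsive]`);
frame stacks as multi-frame TIFF or globs of single-frame TIFF/PNG/JPEG
images; stills as JPEG/PNG/TIFF; configuration as a single YAML file
with `analysis` and `simulation` sections validated on load (unknown
keys are errors, not silent defaults). `inst/cli/casa.R` exposes
`simulate`, `track`, `motility`, `chemotaxis`, `bootstrap`,
`morphometry` and `viability` subcommands, logs the fully resolved
configuration of every run, and accepts `--start-s/--end-s` to restrict
a video to a time window. AVI containers are not read directly;
convert to TIFF (e.g. `ffmpeg -i in.avi out.tif`) or export per-frame
images.

## Known limitations

* Head-centroid tracking only; no flagellum analysis.
* Greedy frame-to-frame linking without gap closing; dense scenes
  fragment tracks at crossings (quantified, not corrected).
* The gradient is a uniform field along one axis; spatially varying or
  flowing-fluid stimuli are out of scope.
* Hyperactivation is characterised via FD but no cut-off is applied.
* 2-D projection of 3-D motion, as in all conventional CASA.
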