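# casakit

An open, scriptable computer-assisted sperm analysis (CASA) toolkit for
R. Commercial CASA instruments score motility well but are closed,
costly, and blind to *guided* motion — the chemotactic, thermotactic
and rheotactic responses that mark functionally competent spermatozoa.
casakit covers both sides in one package: it tracks motile cells in
microscopy frame stacks, computes the full classical kinematic panel,
tests a population for directional bias with a bootstrap odds-ratio
procedure, measures head morphometry on stained stills, counts
live/dead cells in dual-stained fluorescence images, and ships a
persistent-random-walk simulator that generates ground-truth data so
every stage can be validated without a microscope. It is written for
reproductive-biology labs, CASA methodologists, and anyone tracking
self-propelled cells (bacteria included — only the size window
changes).

## The statistics at the core

**Kinematics.** For a trajectory $\{p_t\}_{t=1}^N$ (scale $\mu$ µm/px,
frame rate $f$) and its moving-average path $\{q_t\}$ (window $w$):

- VSL $= D(p_1,p_N)\,f\mu/(N{-}1)$, VCL $= \sum_t D(p_t,p_{t+1})\,f\mu/(N{-}1)$,
  VAP $= \sum_t D(q_t,q_{t+1})\,f\mu/(N{-}w)$
- LIN $=100\,\frac{VSL}{VCL}$, WOB $=100\,\frac{VAP}{VCL}$, STR $=100\,\frac{VSL}{VAP}$
- ALH (2× peak deviation of the raw path about the average path, µm),
  BCF (raw/average path crossings per second, Hz), MAD (mean absolute
  turning angle, degrees), DNC $= VCL \times ALH_{mean}$, and the Katz
  fractal dimension $FD = \log n\,/\,[\log n + \log(d/L)]$
- motile ⇔ VCL > `min_vcl` with net displacement; progressive ⇔ motile
  with STR and VAP above their thresholds

**Directional bias.** Each displacement gets a signed angle $\psi$ to
the gradient direction $\theta$. With cone half-width $\gamma$,
$N^+ = \#\{\psi \in [-\gamma,+\gamma]\}$ and $N^-$ counts the rest
(option 1) or only the opposite cone (option 2). The ch-index is
$100\,N^+/(N^+{+}N^-)$ (16.67 % under uniformity at $\gamma=30°$), and

$$O.R. = \frac{N^+/N^-\ \text{(test)}}{N_c^+/N_c^-\ \text{(control)}}$$

is compared against the 95th percentile of a bootstrap null built by
repeatedly splitting pooled control trajectories into two disjoint
recording-sized subsets — a positive call carries ≈5 % type-I error.

**Simulation.** Virtual cells follow a persistent random walk:
$\psi' = \psi - (\beta/\tau)\sin\psi + \sqrt{2D_{rot}}\,z$, constant
speed $v_0$, with only a `responsiveness` fraction of the population
feeling the alignment strength $\beta$ (the capacitated
subpopulation). See `vignette("casa-methods")` for every convention
and default.

## Worked example

Simulate a half-responsive chemoattracted population, measure its
kinematics, and test it for directional bias against an unbiased
control:

```r
library(casakit)

s  <- analysis_settings()                       # 60 fps, 1 um/px, gamma 30
p  <- simulation_params(n_cells = 20, n_frames = 120,
                        beta = 1, responsiveness = 0.5)
tracks <- simulate_population(p, seed = 101)

kin <- measure_kinematics(tracks, s)
summarize_kinematics(kin)
#> # A tibble: 1 x 16
#>   n_tracks n_motile pct_motile pct_progressive   vsl   vcl   vap   lin   wob
#>      <int>    <int>      <dbl>           <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1       20       20        100              50  114.   180  167.  63.1  92.6
#>     str alh_mean alh_max   bcf   mad   dnc    fd
#> 1  68.3     1.51    3.28  25.7  24.4  271.  1.15

ctl <- simulate_population(simulation_params(n_cells = 20, n_frames = 120),
                           seed = 202)
res <- chemotaxis_test(tracks, ctl, s, n_resamples = 2000, seed = 303)
res
#> <casa_chemotaxis>
#>   ch-index: test 44.29%  control 18.24%
#>   O.R. 3.5641 vs P95 threshold 1.7106 -> DIRECTIONAL BIAS
```

Reading this: every simulated cell swims (100 % motile) at VCL
180 µm/s (3 px/frame × 60 fps × 1 µm/px — the simulator's exact speed),
and the responsive half straightens toward the gradient, which shows up
as 50 % progressive. The attracted population points 44.3 % of its
displacements within ±30° of the gradient versus 18.2 % for the
control (uniform expectation 16.67 %), and its odds ratio of 3.56 far
exceeds the bootstrap threshold of 1.71 (a wide threshold here — it is
built from a single 20-track control recording; control panels of ~100
recordings give thresholds near 1.09), so the bias call is positive.

`plot_tracks()`, `plot_angle_rose()` and `autoplot()` on a bootstrap
null give the standard figures; `tidy()`/`glance()` return tabular
results. A thin command-line wrapper covers the same pipeline for
shell use:

```sh
Rscript inst/cli/casa.R simulate --config cfg.yaml --out tracks.csv --video vid.tif --seed 1
Rscript inst/cli/casa.R track    --video vid.tif  --config cfg.yaml --out tracked.csv
Rscript inst/cli/casa.R motility --tracks tracked.csv --config cfg.yaml --out kin.csv
```

(Video I/O uses multi-frame TIFF or per-frame image globs; convert AVI
with e.g. `ffmpeg -i in.avi out.tif`.)

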