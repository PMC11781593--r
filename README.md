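# resetdyn

Stochastic resetting — killing a trajectory at random times and
restarting it from its initial condition — can dramatically accelerate
first-passage sampling in molecular simulations whose transition-time
distributions are broad. **resetdyn** implements the *informed* variant
of the protocol for Langevin dynamics on analytic model landscapes:
resets are executed only when a collective variable (CV) says the
trajectory is far from its target, which prunes unproductive excursions
without ever interrupting a trajectory that is about to arrive.

The package is aimed at people developing or studying enhanced-sampling
kinetics methods: it bundles a batched underdamped BAOAB Langevin
integrator with first-passage detection, standard and informed
resetting protocols, a minimal well-tempered Metadynamics engine whose
bias is zeroed at every reset, and — the analytical core — a
trajectory-reweighting predictor that evaluates the mean first-passage
time (MFPT) under *any* resetting rate and threshold using only
trajectories sampled *without* resetting.

## The method in brief

A trajectory with informed resetting at rate $r$ and threshold $c$
splits into $M$ segments: $M-1$ that end in a reset and a final one
that ends in first passage, so

$$\langle\tau\rangle_r \;=\; (\langle M\rangle - 1)\,
  \langle \bar t^{\,r}\rangle \;+\; \langle t^{f}\rangle .$$

Every term is computable from $N$ reset-free trajectories. With
per-step resetting probability
$p(X) = (1 - e^{-r\Delta t})\,\mathbf 1[\mathrm{cv}(X) > c]$ and
survival $\Psi_i(k) = \prod_{j \le k} (1 - p(X_i^j))$:
$\langle M\rangle = \langle \Psi\rangle^{-1}$ from the mean survival at
first passage, $\langle t^f\rangle$ is the survival-reweighted mean of
the reset-free FPTs, and $\langle\bar t^{\,r}\rangle$ averages the
would-be reset-segment lengths $j\Delta t$ with weights
$\Psi_i(j-1)\,p(X_i^j)$. Screening a whole grid of $(r, c)$ protocols
therefore costs almost nothing beyond the reset-free sample itself. The
same machinery, applied to trajectories already accelerated at rate
$r^*$, evaluates $\langle\tau\rangle_r$ at any $r > r^*$
(superposition of exponential clocks), and extrapolation of that curve
to $r = 0$ recovers the unbiased MFPT from accelerated data alone.

The bundled benchmark is a modified Faradjian–Elber surface: a
two-dimensional double well (minima near $x = \pm 3$ Å) whose 12
$k_BT$ ridge carries a narrow 3 $k_BT$ saddle at $y = 0$, with the
$y$ direction stretched tenfold so that finding the saddle is the slow,
entropic part of the transition. On it, informed resetting with the
threshold at the starting well achieves ~56-fold speedup where standard
resetting manages ~15-fold, and combined with Metadynamics the speedup
reaches several hundred-fold.

## Worked example

Build a fast-converging fixture surface, screen resetting protocols on
its reset-free baseline, and check the best prediction by direct
simulation:

```r
library(resetdyn)

fx <- generate_fixture(seed = 42, n_baseline = 150)
glance(fx$baseline)
#> # A tibble: 1 × 6
#>       n n_censored mfpt_ns  sem_ns    cv mean_resets
#>   <int>      <int>   <dbl>   <dbl> <dbl>       <dbl>
#> 1   150          0  0.0825 0.00830  1.23           0

grid <- screen_protocols(fx$baseline,
                         rates_ns = c(1e3, 1e4, 1e5),
                         thresholds = c(2.5, 3, 3.5))
glance(grid)
#>   rate_ns threshold    mfpt_ns  speedup baseline_mfpt_ns n_valid n_cells
#> 1   10000         3 0.02169233 3.804323       0.08252465       9       9

proto <- reset_protocol(1e4, threshold = 3)
ens <- simulate_fpt(fx$surface, sim_config(seed = 9, max_steps = 2e7),
                    n_walkers = 300, protocol = proto)
speedup(fx$baseline, ens)
#> # A tibble: 1 × 4
#>   speedup    se mfpt_baseline_ns mfpt_accelerated_ns
#>     <dbl> <dbl>            <dbl>               <dbl>
#> 1    2.64 0.300           0.0825              0.0312
```

The screen predicts a 3.8-fold acceleration for resetting at
$10^4\,\mathrm{ns}^{-1}$ with threshold 3 Å — resets fire only when
the walker is beyond its starting well — and direct simulation at that
protocol measures 2.6 ± 0.3 (the predicted and simulated MFPTs agree
within the combined sampling errors of this small, 150-trajectory
screen). `predict_mfpt()` exposes the per-protocol
diagnostics (mean segment count, survival, segment durations);
`infer_mfpt()` runs the reverse direction, recovering the unbiased
MFPT from an accelerated ensemble; `ensemble_dtt()` extracts direct
transit times; `autoplot()` methods draw the standard figures.

The full-scale benchmark lives behind `run_experiment()` (speedup
curves over rates and thresholds, rotated-CV Metadynamics comparisons,
inference trade-off scans) and `inst/scripts/resetdyn` provides a thin
command-line front end for COLVAR-style CV series produced by external
MD engines.

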