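# srmsim

Simulation engine for an adaptive **spatial-release-from-masking (SRM)**
speech task — for auditory psychophysicists who want to characterize the
procedure itself (bias, precision, convergence point, duration) without
human subjects or audio hardware.

## The task

SRM is the improvement in speech reception threshold, in dB of
target-to-masker ratio (TMR), when maskers are spatially separated from a
target. The paradigm implemented here measures a *functional spatial
boundary* directly: first a 2-down/1-up staircase tracks the co-located
TMR threshold, then the TMR is fixed 6 or 9 dB below that threshold and a
second staircase adaptively tracks the *separation angle* of two
symmetric maskers until performance returns to criterion. The recovered
angle is the separation needed to realize the targeted release.

The engine simulates every ingredient:

* **Staircase** — transformed up-down (2-down/1-up): two consecutive
  correct responses make the task harder, one incorrect makes it easier;
  it converges on the 70.7 %-correct point. TMR tracks start at +12 dB
  (2 -> 1 dB steps after 3 reversals); angle tracks start at 45°
  (5° -> 2°). Tracks stop at 12 reversals; the threshold is the mean of
  the last 9 reversal values.
* **Continuous stream** — three talkers at 2 words/s; digits (1–10, no 7)
  appear in the target stream roughly every 3 s and are scored against a
  2-s response window; misses and errant presses count as incorrect.
* **Virtual listener** — a probit psychometric surface
  `p(tmr, θ) = γ + (1 − γ − λ) Φ((tmr − m(θ))/σ)` whose midpoint falls
  with separation along a saturating release curve
  `m(θ) = T0 − srm_max (1 − exp(−θ/θ0))`, plus miss/errant rates and a
  population generator for Monte-Carlo cohorts.
* **Spatial audio** — a 24-loudspeaker ring (15° spacing) with
  sine/cosine equal-power panning, symmetric masker scenes, a four-speaker
  rear babble background, and optional multichannel WAV rendering of
  placeholder tokens.
* **Protocol & analysis** — co-located first, fixed-30° validation,
  adaptive-angle conditions, three-track averaging, quiet/babble
  counterbalancing, group summaries, and Monte-Carlo characterization of
  the procedure against analytic ground truth.

## Worked example

Measure one simulated listener's co-located threshold, then the
separation it needs for 6 dB of release:

```r
library(srmsim)
listener <- listener_params(T0 = -2, sigma = 2, srm_max = 10, theta0 = 15,
                            lam = 0, miss_rate = 0, errant_rate = 0)

coloc <- run_condition(listener, condition_spec("quiet", "colocated"),
                       seed = 7)
#> condition colocated_quiet: threshold -1.556 dB TMR (tracks: -1.67, -2.33, -0.67)

ad <- run_condition(listener,
                    condition_spec("quiet", "adaptive_angle", target_srm = 6),
                    colocated_threshold = coloc$threshold, seed = 8)
#> condition adaptive_6dB_quiet: threshold 15.667 deg (tracks: 15.33, 18.00, 13.67)

solve_angle_threshold(listener, coloc$threshold - 6)
#> [1] 15.48  (deg, analytic boundary implied by the listener model)
```

The three co-located tracks average −1.56 dB TMR; the angle condition
then fixes the TMR at −7.56 dB and the tracks recover a boundary of
15.7°, close to the 15.5° the listener model implies analytically. How
trustworthy is that recovery in general? Characterize the procedure:

```r
characterize_procedure(listener,
    condition_spec("quiet", "adaptive_angle", target_srm = 6),
    n_replicates = 500, seed = 9)
#> procedure characterization: adaptive_6dB_quiet (500 replicates)
#>   completion rate 1.000, mean stream time 144.2 s
#>   recovered threshold 15.059 +/- 2.444 deg (truth 13.744, bias +1.314)
#>   mean p(correct) at recovered thresholds: 0.7448
```

So for this listener the procedure recovers the boundary with ~2.4° of
single-track spread and ~+1.3° of bias (here the truth uses the analytic
co-located threshold, while the worked example above anchored on the
measured one), sitting slightly above its nominal 70.7 % convergence
point — the kind of statement the package exists to make. See the
vignette (`vignettes/srm-simulation-methods.Rmd`) for the model, the
defaults and the procedure's measured properties.

A command-line front end over the same functions lives at
`inst/cli/srmsim.R`:

```sh
Rscript inst/cli/srmsim.R run-study --seed 1 --n-listeners 20 --out study
```

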