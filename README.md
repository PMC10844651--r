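# dyadsync

Quantifying dyadic motor synchrony from pose-keypoint time series, and
modelling how human observers perceive it.

When two people play the *mirror game* — one improvises arm movements, the
other matches them as closely as possible in space and time — their motor
synchrony can be measured objectively from tracked body keypoints. Observers
watching short clips of such dyads then estimate the synchrony on a 0–100
slider and rate how much they enjoyed the movement. `dyadsync` implements
the full analysis chain for this paradigm, for researchers in social
cognition, movement science and empirical aesthetics:

1. **Kinematics.** Per frame, each figure's upper-body pose (neck,
   shoulders, elbows, hands) is summarized by the 42 ordered pairwise
   Euclidean joint distances, L2-normalized into a body-centric *pose
   matrix* that is invariant to position, size and rigid motion. Frame
   similarity between the two figures is the cosine of their pose matrices
   (0 = no similarity, 1 = identical), averaged over the 600 frames of a
   10-s, 60-fps clip to give **measured similarity**. Movement
   **predictability** is the mean sample entropy
   SampEn(m = 2, r = 0.2·SD) of the eight wrist coordinate series
   (x, y × left/right wrist × 2 people); values near 0 mean regular,
   predictable movement. Trajectories are smoothed beforehand with a
   Savitzky–Golay filter (window 13 frames, order 2).
2. **Experimental design.** Clip segmentation; high/low-synchrony labelling
   by source task (mirroring vs observing); red/blue and left/right leader
   counterbalancing; splitting a 198-clip pool into two 100-clip subsets
   sharing exactly 2 clips with every leader in both; 153-trial
   per-participant schedules (50 clips × 3 questions + 3 attention checks);
   attention scoring with the ≤ 25 rule and 2-of-3 inclusion.
3. **Rating models.** Accuracy is the *difference value*
   `100 × measured similarity − synchrony estimate` (positive =
   underestimation). A distributional hierarchical Gaussian model gives
   each synchrony condition its own intercept, covariate slopes and
   residual SD, with participant and clip random intercepts:

       d_ijk ~ Normal(α_c + Σ_p β_{c,p} x_p + u_j + v_k, σ_c)

   Enjoyment ratings are bimodal and are modelled in two parts: a
   Bernoulli-logit for "very low enjoyment" (ratings ≤ 10) and a Gaussian
   for "enjoyment per se" (11–100). Posteriors are sampled by built-in
   MCMC (Gibbs plus adaptive Metropolis with reparameterization moves) and
   summarized by posterior means, 95% highest-posterior-density intervals,
   and the posterior mass beyond zero; split-R̂ ≤ 1.05 and ESS ≥ 400 gate
   every reported parameter.
4. **Synthetic data.** A forward-kinematic leader–follower simulator
   (joint-angle sinusoid mixtures, constant bone lengths, lagged noisy
   mirroring vs a near-still observer) and a rater-panel simulator with
   correlated traits and known true coefficients, so the entire pipeline is
   testable end-to-end against ground truth without any data download.

## Worked example

```r
library(dyadsync)

# a synthetic mirror-game clip and its two objective measures
rec <- simulate_dyad(dyad_sim_config("high", seed = 42))
kinematic_summary(rec, clip_id = "demo")
#>   clip_id measured_similarity predictability coverage
#> 1    demo               0.988          0.381        1

# a stimulus pool, a simulated rater panel, and the accuracy model
pool  <- simulate_stimulus_pool(n_clips = 24, prop_high = 0.6,
                                n_leaders = 4, seed = 11)$manifest
panel <- simulate_raters(pool, rater_sim_config(n_raters = 40,
                                                n_clips_per_rater = 24,
                                                seed = 21))
fit <- fit_accuracy_model(panel$accuracy,
                          c("predictability", "body_competence",
                            "autistic_traits"),
                          model_config(seed = 7))
summary(fit)[c(1, 2, 5, 6), c("parameter", "mean", "hpd_lo", "hpd_hi",
                              "mass_beyond_zero")]
#>                    parameter   mean hpd_lo hpd_hi mass_beyond_zero
#> 1                alpha[high] 27.496  23.94 31.012             1.00
#> 2                 alpha[low] 35.221  26.92 42.516             1.00
#> 5 beta[high,body_competence] -0.228  -2.40  1.714             0.58
#> 6  beta[low,body_competence] -2.322  -4.51 -0.126             0.98
```

Reading the output: both condition intercepts sit well above zero, so the
simulated observers underestimate synchrony (by ~27 slider points for
high-synchrony clips, ~35 for low). The panel was generated with a true
body-competence slope of −2 for low synchrony only, and the model recovers
exactly that: the low-synchrony slope's 95% HPD excludes zero while the
high-synchrony slope is indistinguishable from zero. `mass_beyond_zero` is
the fraction of posterior draws on the dominant side of zero.

A full run (simulate → design → schedules → raters → both models → report):

```r
cfg <- pipeline_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)
writeLines(generate_report("run1"))
```

A command-line interface with the same stages lives at
`inst/cli/dyadsync.R` (subcommands `simulate`, `stimuli`, `schedule`,
`pipeline`, `fit-accuracy`, `fit-enjoyment`, `report`).

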