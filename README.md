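# neurodrift

Neurally-informed hierarchical drift-diffusion modelling of perceptual
choice, with single-trial EEG decoding and a ground-truth-known synthetic
data generator.

## What problem this addresses

In cued perceptual categorisation (is this noisy image a face or a car?),
a probability cue shown before the stimulus shifts both choices and
response times. Two mechanisms could produce that shift inside a
sequential-sampling decision: a bias in the **starting point** of evidence
accumulation, or a change in the **drift rate** (the quality/rate of
accumulated evidence). Behaviour alone often cannot separate them. This
package implements the analysis that separates them by *informing* the
decision model with single-trial EEG measures of decision evidence:

1. a sliding-window logistic discriminator finds, at each time point, the
   channel weighting `w_t` that best separates face from car trials; each
   trial's discriminator output `y_it = w_t' x_it` is a signed single-trial
   evidence amplitude (leave-one-out cross-validated, summarised by the
   ROC area Az, with permutation significance and forward-model scalp
   projections `a_t = X y / (y'y)`);
2. two discriminating components are extracted per participant — an Early
   component (peak Az in 150–250 ms) and a Late component (300–500 ms);
3. hierarchical Bayesian Wiener diffusion models are fit to choices and
   response times, with the trial-wise drift rate regressed on the decoded
   amplitudes,

   δ_i = γ0 + γ_Early · y_i^Early + (γ_Late · y_i^Late) · C_i,

   where C_i is the stimulus phase coherence (the Late term alone scales
   with coherence), and cue-specific coefficients; alternative variants
   route the amplitudes to the starting point β instead. Variants are
   compared by DIC and cue effects tested by posterior contrasts.

Because the package targets analysis validation, it ships a first-class
synthetic-data module that generates the whole study — trial design, latent
amplitudes, diffusion behaviour with a 1.25-s deadline, and 64-channel
stimulus-locked epochs — from a known ground truth, so every stage can be
scored against the truth that generated its input.

The Wiener first-passage density (series evaluation), its likelihood and
the Euler path sampler, and the decoder's penalised-logistic inner loop
are implemented in C++ (Rcpp/RcppArmadillo). The diffusion coefficient is
fixed at 1; parameter scales are relative to unit within-trial noise.

## Worked example

```r
library(neurodrift)

gt  <- ground_truth(n_channels = 16, seed = 7)  # known generative truth
tab <- generate_design(n_participants = 1, n_sessions = 1,
                       n_trials_per_session = 200, seed = 2)
tab <- simulate_amplitudes(tab, gt)
ep  <- simulate_epochs(tab, gt, srate = 250)

ser <- sliding_discrimination(ep, as.numeric(tab$stimulus == "face"))
ser
#> Sliding-window discrimination: 111 centres [-0.100, 1.000] s, 200 trials
#>   peak LOO Az = 0.787 at 0.200 s; mean Az = 0.527

comp <- pick_components(ser)
comp
#> Components: Early 200 ms (Az 0.787), Late 350 ms (Az 0.766), 200 trials
cor(comp$forward_early, gt$pattern_early)
#> [1] 0.927763
```

The discriminator peaks at the injected component latencies (200/350 ms),
reaches Az ≈ 0.78 at the default signal-to-noise calibration (chance is
0.5, perfect separation 1.0), and its forward-model scalp projection
correlates 0.93 with the true spatial pattern.

Fitting and comparing model variants on simulated behaviour:

```r
gt  <- ground_truth(seed = 11)
tab <- generate_design(8, 1, 360, seed = 11)
tab <- simulate_amplitudes(tab, gt)
tab <- simulate_behaviour(tab, gt)          # Wiener-diffusion choices/RTs

m <- build_model(model_spec("M3"), hierarchical_data(tab))
s <- sample_posterior(m, n_iter = 3000, burn = 500, thin = 10,
                      chains = 4, seed = 5)
max(gelman_rubin(s))                         # convergence check
recovery_report(gt, s, tab)$coverage         # truth inside 95% CIs
posterior_prob(s, "mu_gamma_late[70F] > mu_gamma_late[30F]")
```

A full simulate → decode → fit run is one call:

```r
cfg <- run_config("runs/demo", seed = 1,
                  stages = c("simulate", "fit"),
                  design = list(n_participants = 8,
                                n_trials_per_session = 360))
report <- run_pipeline(cfg)
```

See `vignettes/neurodrift-methods.Rmd` for the model, priors, sampler
design, generator calibration and known limitations.

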