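---
title: "Methods: neurally-informed drift-diffusion modelling of cued face/car decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neurally-informed drift-diffusion modelling of cued face/car decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In a cued perceptual categorisation task, observers decide whether a noisy
image contains a face or a car. Before each stimulus, a probability cue
(30F / 50F / 70F) announces the probability that the upcoming image is a
face, and the image's phase coherence (0.325 or 0.375) controls how much
sensory evidence it carries. The central question is *where* the prior
probability acts in the decision process: does it bias the starting point
of evidence accumulation, or does it change the rate at which evidence
accumulates?

The package implements the full analysis that answers this question on
synthetic data with known ground truth:

1. **simulate** — generate trial designs, latent single-trial EEG component
   amplitudes, diffusion-model behaviour (choices and response times), and
   multichannel stimulus-locked EEG epochs;
2. **preprocess** — zero-phase band-pass filtering, common-average
   re-referencing, and ocular-artifact removal by subspace projection;
3. **decode** — sliding-window regularised logistic discrimination of
   face versus car from the EEG, leave-one-out single-trial amplitudes,
   Az, permutation significance, forward-model scalp projections, and
   extraction of the Early (150–250 ms) and Late (300–500 ms)
   discriminating components;
4. **fit** — hierarchical Bayesian Wiener diffusion models in which the
   decoded amplitudes regress onto drift rate and/or starting point;
5. **compare** — model selection by the deviance information criterion and
   posterior contrasts of the cue-specific coefficients.

## The diffusion model and its conventions

A trial is modelled as a Wiener diffusion between absorbing boundaries at
0 and $\alpha$ with unit diffusion coefficient, starting at
$\alpha\beta$, drifting at rate $\delta$, with the observed response time
$rt = \text{decision time} + \tau$. The upper boundary is the face
choice. **The diffusion coefficient is fixed at 1**, the convention of the
Wiener-likelihood tooling this analysis style builds on; some DDM software
fixes it at 0.1 instead, which rescales $\alpha$ and $\delta$ by 10. All
coefficient magnitudes quoted below are in unit-noise evidence units.

The defective first-passage density is evaluated by the standard
small-time/large-time series pair, switching to whichever expansion needs
fewer terms for the requested absolute truncation error (default
`tol = 1e-7`, chosen so the typical evaluation needs only a handful of
terms). The lower-boundary density is the reflection
$\beta \to 1-\beta,\ \delta \to -\delta$ of the upper one. The path
sampler is Euler–Maruyama at `dt = 1e-4` s; exactness is not assumed but
verified against the series density by Kolmogorov–Smirnov distance in the
acceptance suite (< 0.01 at $10^5$ paths).

The neural informing follows the drift regression

$$\delta_i = \gamma_0 + \gamma_{Early}\, y_i^{Early} +
 (\gamma_{Late}\, y_i^{Late})\, C_i,$$

with cue-specific coefficients: the coherence level $C_i$ (coded as the
raw proportion, 0.325/0.375) multiplies the Late term only, because only
the Late component's amplitude scales with stimulus coherence. A flag
allows the alternative in which both terms scale. When amplitudes regress
onto the starting point instead, an inverse-logit link
$\beta_i = \text{logit}^{-1}(b_0 + b_E y_E + b_L y_L)$ guarantees
$\beta_i \in (0,1)$; the link is a package decision, made for support
safety. Amplitudes enter the model unstandardised by default; unit-SD
scaling is applied only in the pooled choice regression, where it makes
the two components' coefficients directly comparable.

Six variants are supported: M1 (both amplitudes to starting point), M2
(Early to starting point, Late to drift), M3 (both to drift), M4 (Early
only), M5 (Late only) and B (behaviour-only). Cue-dependence defaults:
starting point, non-decision time and all regression coefficients carry
one group-level (mean, SD) pair per cue; the boundary is shared across
cues. Both choices are flags — the underlying study description leaves
them open, and these defaults express the scientific question (cue effects
on bias versus evidence) with the smallest adequate parameter set. For the
behaviour-only variant all four diffusion parameters are cue-dependent
except the shared boundary, for the same reason.

## The hierarchical model and sampler

Group-level means and SDs get uniform priors: boundary mean in (0.1, 5),
starting-point intercept in (0.1, 0.9), non-decision mean in (0.05, 1.0) s,
regression coefficients in (−10, 10), group SDs in (0.001, 3) — except
that each family's SD prior is capped at half its participant support
width (e.g. 0.48 for the starting point), because a group SD beyond the
support width degenerates the truncated normal into a uniform and the
resulting flat, unidentified ridge both means nothing scientifically and
wrecks chain mixing for weakly-informed families. All bounds are wide
relative to every plausible data-generating value and are configurable.
Participant-level parameters are Normal(mean, SD²) truncated to their
support.

Sampling is adaptive Metropolis-within-Gibbs: single-site random-walk
updates for every group-level and participant-level parameter, with
multiplicative (log-scale) proposals for group SDs, which can be poorly
identified with few participants and then range over orders of magnitude.
Two dedicated reparameterisation moves — a joint translation of a family's
group mean with all its participant values, and a joint rescaling of a
family's group SD with its participant deviations — decorrelate the group
level from the participant level; without them the group-level chains mix
an order of magnitude more slowly. Proposal scales adapt toward 44%
acceptance in batches of 25 iterations during burn-in only, so the
post-burn-in kernel is fixed and targets the exact posterior. Initial
values are drawn from the priors (group SDs from the lower part of their
prior range, since full-range draws make initialisation fail needlessly
against the response deadline) and redrawn up to 50 times until the
posterior is finite.

The reference sampler settings are 11,000 iterations with 1,000 burn-in
and thinning by 50 (200 retained draws per chain, 4 chains). All scaled
analyses in the test and acceptance suites use 3,000 iterations, 500
burn-in, thinning 10 — chosen as the package's desk-scale default so that
a full fit completes in minutes; convergence is always verified by the
split-chain Gelman–Rubin statistic with the working criterion
$\max \hat R \le 1.03$ over group-level parameters.

Model comparison uses the deviance information criterion in the classic
plug-in form, $DIC = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$ evaluated at the posterior mean of all
parameters. Positive/negative effects are declared when more than 95% of
the posterior density of a (group-level) contrast lies on one side of
zero, computed by counting pooled retained draws.

## The decoder

At each window centre $t$ (50-ms windows, 10-ms steps, −100 … 1000 ms),
every sample within ±25 ms is treated as an independent observation of
that trial, and a logistic discriminator
$p = 1/(1+e^{-\mathbf w^\top \mathbf x})$ is fit by Newton's method.
Three numerical decisions matter:

* **Ridge penalty.** An unpenalised fit diverges whenever a window is
  linearly separable (certain at 64 channels and modest trial counts), so
  the likelihood carries a penalty $\lambda_{\text{eff}}\lVert w\rVert^2$
  with $\lambda_{\text{eff}} = \lambda \cdot n_{\text{rows}}$ and default
  $\lambda = 10^{-3}$ — small enough to leave Az essentially unchanged on
  non-separable data, large enough to keep every window well-posed.
* **No intercept.** The discriminator output $y = \mathbf w^\top\mathbf x$
  is a signed evidence amplitude whose zero is the face/car boundary;
  complementing the labels exactly flips $\mathbf w$. For the same reason
  `standardize_amplitudes()` divides by the SD without centring.
* **Held-out amplitude.** Training stacks window samples as independent
  rows, but a single amplitude per held-out trial is needed downstream;
  the package uses the mean of $\mathbf w^\top \mathbf x$ over the
  held-out trial's window samples.

Leave-one-out cross-validation is exact (one refit per held-out trial,
warm-started at the full-data solution); Az is the Mann–Whitney statistic
with ties counted ½. Permutation p-values recompute the LOO Az under
label permutations, $p = (1 + \#\{Az^{perm} \ge Az\})/(n_{perm}+1)$,
per centre without a max-statistic correction (matching per-timepoint
testing at $p < 0.01$). Forward models
$\mathbf a = X\mathbf y/(\mathbf y^\top \mathbf y)$ give the per-channel
coupling between data and component amplitude. Component peaks are the
maximal-Az centres within 150–250 ms (Early) and 300–500 ms (Late), ties
broken toward the earlier centre. When classifiers are trained per
session, amplitudes are pooled across sessions by simple concatenation
(per-session unit-SD scaling is available via
`standardize_amplitudes()` applied per session).

## The synthetic-data generator

The generator emulates the statistical structure of the study — it is the
package's test bed, not a biophysical EEG simulator:

* Design: cues equiprobable; face probability 0.3/0.5/0.7 by cue;
  coherence equiprobable over {0.325, 0.375}; full scale 16 participants ×
  3 sessions × 360 trials (test scale: 8 × 1 × 360 at 250 Hz, the
  package's desk-scale default).
* Amplitudes: $y_{Early} \sim N(s\, m_E, \sigma_y^2)$ and
  $y_{Late} \sim N(s\,(m_{L0} + m_{L1} C), \sigma_y^2)$ with $s = \pm 1$
  for face/car; only the Late separation grows with coherence. The study
  does not report empirical amplitude distributions, so
  $m_E = 1,\ m_{L0}=0,\ m_{L1}=3,\ \sigma_y = 1$ were chosen once so that
  decoding at the default noise level lands at Az ≈ 0.7–0.8, the range the
  real decoders achieve.
* Behaviour: participant-level parameters drawn from the group model;
  drift assembled per trial by the drift regression; choices and RTs from
  the Euler sampler with the 1.25-s deadline; non-responders are marked
  invalid and excluded from all fits. Group defaults
  ($\alpha = 1.2 \pm 0.15$, $\tau = 0.30 \pm 0.04$ s, $\beta = 0.5$,
  $\gamma_0 = (-0.5, 0, 0.5)$, $\gamma_{Early} = 0.5$,
  $\gamma_{Late} = (1.0, 1.5, 2.0)$ across cues) reproduce the study's
  behavioural profile: mean RT ≈ 0.6 s, accuracy ≈ 75–80%, deadline
  misses ≈ 4%, more face choices and faster congruent responses under
  face-favouring cues. The deadline-miss rate matters: excluded
  non-responses censor the RT distribution while the Wiener likelihood
  assumes none, so a generator with heavy censoring would bias
  non-decision time upward and boundary downward in *any* fit of this
  family. At ≈ 4% the residual bias is well inside posterior uncertainty.
  Cue effects are placed in the drift coefficients, with the starting
  point unbiased at 0.5 — the generator expresses the drift-level
  mechanism, and the fitted starting-point cue contrast should
  accordingly stay non-credible.
* Epochs: $x(t) = a_E\, y_E\, g(t;\mu_E) + a_L\, y_L\, g(t;\mu_L) +
  \text{noise}$, with unit-peak Gaussian bumps ($\mu$ = 200/350 ms, SD
  25 ms — component waveforms are a package choice, the study describes
  none), unit-norm smooth random spatial patterns fixed by the master
  seed, and background noise that is AR(1) in time (coefficient 0.95)
  with low-rank shared spatial mixing, stationary SD 1.5 per channel —
  again calibrated once to the Az ≈ 0.7–0.8 operating range. What the
  generator does *not* emulate: volume-conduction physics, 1/f spectra,
  alpha rhythms, non-stationarity, muscle artifacts, or channel-specific
  noise profiles. Passing tests therefore demonstrate the correctness and
  calibration of the *analysis machinery* under the study's statistical
  structure, not robustness to every property of real EEG.
* The ocular calibration recording embeds stereotyped blink and saccade
  deflections (frontally-weighted fixed topographies, half-sine and
  step-like time courses) at known times, so projection learning can be
  tested against a known answer.

All randomness descends from one master seed through labelled hash-derived
stage seeds; identical seeds give bit-identical outputs.

## Preprocessing decisions

Filtering is zero-phase (forward–backward) Butterworth, order 4 per pass,
defaults 0.5–100 Hz, applied to continuous records before epoching, with
reflection padding (about one second) to suppress edge transients. Ocular
removal learns one dominant spatial component per artifact class by PCA of
class-specific calibration segments and projects the data onto the
orthogonal complement of the artifact subspace — algebraically identical
to estimating component time courses by least squares and subtracting
their re-projection. The projection is idempotent and leaves orthogonal
signals untouched; a warning fires when a class's leading component
explains too little segment variance to be a credible stereotyped
artifact.

## Degenerate inputs and edge rules

Non-positive decision times have density zero and make the likelihood
−∞; single-class labels, zero-variance amplitudes, zero-norm forward-model
amplitudes, and configurations in which the non-decision time reaches the
deadline are all rejected with errors. Collinear choice-regression designs
fall back to a small ridge with a warning. Az ties count ½. Window centres
are generated inclusively over [−0.100, 1.000] s and each window is closed
on both ends; a span that cannot cover a centre names the first
uncoverable centre in its error.

## Problem sizes used by the test and acceptance suites

Unit tests run on 100–200-trial, 4–16-channel configurations. The
acceptance suite uses: $10^5$ Euler paths per parameter set for the
density check; 200 trials × 16 channels for the chance-level and
component-recovery checks; 100 noiseless trials for the ceiling check;
two replicate datasets of 8 participants × 360 trials with the
3,000/500/10 sampler for parameter recovery (coverage is averaged over the
replicates because, with 8 participants, single-dataset coverage of the
population truth carries irreducible participant-sampling variance) and
convergence; and ten replicate 4 × 180 datasets with short chains for
model-selection recovery. These sizes are the package's
desk-scale choices; the pipeline itself supports the full study scale.

## Known limitations

* The Wiener likelihood ignores deadline censoring of excluded
  non-response trials; at the default ≈ 4% miss rate the induced bias is
  negligible relative to posterior width, but fits to data with heavy
  censoring would inherit it.
* Inter-trial variability parameters of the full Ratcliff model (sv, sz,
  st) are deliberately absent; participant- and trial-level variability is
  carried by the hierarchy and the neural regressors.
* The sampler is random-walk based; posteriors with strong curvature
  (many more parameters, far fewer trials) would need longer chains than
  the desk-scale defaults.
* DIC is the only model-selection criterion, in the plug-in form; WAIC or
  cross-validation are out of scope.
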