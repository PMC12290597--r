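#' Ground truth for the synthetic study
#'
#' Collects every generative parameter of the synthetic face/car experiment:
#' group-level diffusion parameters, the drift-regression coefficients that
#' tie single-trial EEG component amplitudes to drift rate, the spatial
#' patterns and latencies of the two discriminative EEG components, the
#' amplitude model per stimulus class and coherence, and the background
#' noise model.  The defaults emulate the statistical structure of the
#' face/car cueing experiment: three probability cues (30F/50F/70F), two
#' phase-coherence levels (0.325, 0.375), an Early component near 200 ms and
#' a Late component near 350 ms whose amplitude scales with coherence, and
#' cue effects expressed in the drift rate (starting point unbiased at 0.5).
#'
#' Group means/SDs describe the population from which participant-level
#' parameters are drawn.  `gamma0`, `gamma_early` and `gamma_late` are the
#' cue-specific drift-regression coefficients (intercept, Early slope, Late
#' slope); the Late term is multiplied by the trial's coherence when drift
#' is assembled, so `gamma_late` is on the scale of evidence/s per unit
#' (amplitude x coherence).  Spatial patterns are unit-norm 64-channel
#' vectors (or `n_channels`-vectors) drawn smoothly and deterministically
#' from `seed`.
#'
#' @param n_channels number of EEG channels (64 in the full design).
#' @param alpha_mean,alpha_sd group mean/SD of boundary separation.
#' @param tau_mean,tau_sd group mean/SD of non-decision time (s).
#' @param beta_mean length-3 starting-point intercept per cue (30F/50F/70F).
#' @param beta_sd group SD of the starting point.
#' @param gamma0,gamma0_sd cue-specific drift intercepts and their group SD.
#' @param gamma_early,gamma_early_sd cue-specific Early drift slopes / SD.
#' @param gamma_late,gamma_late_sd cue-specific Late drift slopes / SD.
#' @param early_latency,late_latency component peak latencies (s).
#' @param early_width,late_width temporal SD of the Gaussian component
#'   waveform (s).
#' @param m_early mean Early amplitude magnitude (sign follows stimulus).
#' @param m_late0,m_late1 Late amplitude model: magnitude
#'   `m_late0 + m_late1 * C` at coherence `C`, so Late evidence grows with
#'   stimulus coherence while Early evidence does not.
#' @param amplitude_sd trial-to-trial SD of both component amplitudes.
#' @param noise_scale stationary SD of the background EEG noise per channel
#'   (same units as the projected component signal).
#' @param ar_coef temporal AR(1) coefficient of the background noise.
#' @param spatial_rank rank of the shared low-rank spatial noise mixing.
#' @param blink_scale,saccade_scale amplitudes of the stereotyped ocular
#'   artifacts in the calibration recording.
#' @param epoch_span epoch limits (s) relative to stimulus onset.
#' @param deadline response deadline (s).
#' @param coherence_levels the two phase-coherence levels.
#' @param seed master seed; fixes the spatial patterns and every stream
#'   derived downstream.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(n_channels = 64,
                         alpha_mean = 1.2, alpha_sd = 0.15,
                         tau_mean = 0.30, tau_sd = 0.04,
                         beta_mean = c(0.5, 0.5, 0.5), beta_sd = 0.05,
                         gamma0 = c(-0.5, 0, 0.5), gamma0_sd = 0.3,
                         gamma_early = c(0.5, 0.5, 0.5), gamma_early_sd = 0.2,
                         gamma_late = c(1.0, 1.5, 2.0), gamma_late_sd = 0.3,
                         early_latency = 0.200, late_latency = 0.350,
                         early_width = 0.025, late_width = 0.025,
                         m_early = 1.0, m_late0 = 0.0, m_late1 = 3.0,
                         amplitude_sd = 1.0,
                         noise_scale = 1.5, ar_coef = 0.95, spatial_rank = 4,
                         blink_scale = 40, saccade_scale = 15,
                         epoch_span = c(-0.125, 1.025),
                         deadline = 1.25,
                         coherence_levels = c(0.325, 0.375),
                         seed = 1L) {
  stopifnot(alpha_mean > 0, tau_mean >= 0, alpha_sd > 0, tau_sd > 0,
            beta_sd > 0, amplitude_sd >= 0,
            all(beta_mean > 0 & beta_mean < 1),
            length(beta_mean) == 3, length(gamma0) == 3,
            length(gamma_early) == 3, length(gamma_late) == 3,
            early_latency > epoch_span[1], early_latency < epoch_span[2],
            late_latency > epoch_span[1], late_latency < epoch_span[2],
            early_width > 0, late_width > 0, n_channels >= 2,
            noise_scale >= 0, abs(ar_coef) < 1)
  cues <- cue_levels()
  gt <- structure(list(
    n_channels = as.integer(n_channels),
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    tau_mean = tau_mean, tau_sd = tau_sd,
    beta_mean = setNames(beta_mean, cues), beta_sd = beta_sd,
    gamma0 = setNames(gamma0, cues), gamma0_sd = gamma0_sd,
    gamma_early = setNames(gamma_early, cues), gamma_early_sd = gamma_early_sd,
    gamma_late = setNames(gamma_late, cues), gamma_late_sd = gamma_late_sd,
    early_latency = early_latency, late_latency = late_latency,
    early_width = early_width, late_width = late_width,
    m_early = m_early, m_late0 = m_late0, m_late1 = m_late1,
    amplitude_sd = amplitude_sd,
    noise_scale = noise_scale, ar_coef = ar_coef,
    spatial_rank = as.integer(spatial_rank),
    blink_scale = blink_scale, saccade_scale = saccade_scale,
    epoch_span = epoch_span, deadline = deadline,
    coherence_levels = coherence_levels,
    seed = as.integer(seed)), class = "ground_truth")
  pats <- component_patterns(n_channels, seed)
  gt$pattern_early <- pats$early
  gt$pattern_late <- pats$late
  gt$blink_topography <- pats$blink
  gt$hsaccade_topography <- pats$hsaccade
  gt$vsaccade_topography <- pats$vsaccade
  gt
}

# deterministic smooth unit-norm spatial patterns; ocular topographies are
# weighted toward the low channel indices (the "frontal" end of the montage)
component_patterns <- function(K, seed) {
  rs <- local({
    set.seed(derive_seed(seed, "spatial-patterns"))
    list(e = rnorm(K), l = rnorm(K))
  })
  smooth_unit <- function(x) {
    s <- stats::filter(c(x[1], x[1], x, x[K], x[K]), rep(1 / 5, 5),
                       sides = 2)
    v <- as.numeric(s[3:(K + 2)])
    v / sqrt(sum(v^2))
  }
  idx <- seq_len(K)
  frontal <- exp(-(idx - 1) / (K / 8))
  blink <- frontal / sqrt(sum(frontal^2))
  hs <- frontal * sin(2 * pi * idx / K)
  hs <- hs / sqrt(sum(hs^2))
  vs <- exp(-(idx - 1) / (K / 5)) * cos(pi * idx / K)
  vs <- vs / sqrt(sum(vs^2))
  list(early = smooth_unit(rs$e), late = smooth_unit(rs$l),
       blink = blink, hsaccade = hs, vsaccade = vs)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic study ground truth\n")
  cat(sprintf("  channels: %d, master seed: %d\n", x$n_channels, x$seed))
  cat(sprintf("  diffusion: alpha %.2f (%.2f), tau %.2f (%.2f) s, beta %s\n",
              x$alpha_mean, x$alpha_sd, x$tau_mean, x$tau_sd,
              paste(sprintf("%.2f", x$beta_mean), collapse = "/")))
  cat(sprintf("  drift coefficients (30F/50F/70F): gamma0 %s, gammaE %s, gammaL %s\n",
              paste(sprintf("%.2f", x$gamma0), collapse = "/"),
              paste(sprintf("%.2f", x$gamma_early), collapse = "/"),
              paste(sprintf("%.2f", x$gamma_late), collapse = "/")))
  cat(sprintf("  components: Early %.0f ms, Late %.0f ms; noise SD %.2f (AR %.2f)\n",
              1000 * x$early_latency, 1000 * x$late_latency,
              x$noise_scale, x$ar_coef))
  invisible(x)
}

#' Write / read ground truth as JSON
#'
#' @param gt a [ground_truth()] object.
#' @param path file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns a `ground_truth` object.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- ground_truth(
    n_channels = raw$n_channels,
    alpha_mean = raw$alpha_mean, alpha_sd = raw$alpha_sd,
    tau_mean = raw$tau_mean, tau_sd = raw$tau_sd,
    beta_mean = unlist(raw$beta_mean), beta_sd = raw$beta_sd,
    gamma0 = unlist(raw$gamma0), gamma0_sd = raw$gamma0_sd,
    gamma_early = unlist(raw$gamma_early), gamma_early_sd = raw$gamma_early_sd,
    gamma_late = unlist(raw$gamma_late), gamma_late_sd = raw$gamma_late_sd,
    early_latency = raw$early_latency, late_latency = raw$late_latency,
    early_width = raw$early_width, late_width = raw$late_width,
    m_early = raw$m_early, m_late0 = raw$m_late0, m_late1 = raw$m_late1,
    amplitude_sd = raw$amplitude_sd,
    noise_scale = raw$noise_scale, ar_coef = raw$ar_coef,
    spatial_rank = raw$spatial_rank,
    blink_scale = raw$blink_scale, saccade_scale = raw$saccade_scale,
    epoch_span = unlist(raw$epoch_span), deadline = raw$deadline,
    coherence_levels = unlist(raw$coherence_levels),
    seed = raw$seed)
  gt
}
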