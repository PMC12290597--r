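#' Generate the trial design of the cued face/car experiment
#'
#' Builds the per-trial design table: probability cues (30F/50F/70F) are
#' assigned equiprobably at random, the stimulus category is drawn Bernoulli
#' with face probability 0.3/0.5/0.7 according to the cue, and the
#' phase-coherence level is equiprobable over the two study levels.
#' Amplitude, choice and response-time columns are added as `NA`
#' placeholders for the downstream simulation steps.
#'
#' @param n_participants,n_sessions,n_trials_per_session design counts
#'   (defaults are the full study scale: 16 participants, 3 sessions,
#'   360 trials per session).
#' @param seed integer seed; identical seeds give identical tables.
#' @param coherence_levels the two coherence levels.
#' @return a `trial_table` data.frame with columns `participant`, `session`,
#'   `trial`, `cue`, `stimulus`, `coherence`, `y_early`, `y_late`, `choice`,
#'   `rt`, `valid`.
#' @export
generate_design <- function(n_participants = 16, n_sessions = 3,
                            n_trials_per_session = 360, seed = 1L,
                            coherence_levels = c(0.325, 0.375)) {
  if (n_participants < 1 || n_sessions < 1 || n_trials_per_session < 1)
    stop("all design counts must be >= 1")
  set.seed(derive_seed(seed, "design"))
  n <- n_participants * n_sessions * n_trials_per_session
  tab <- data.frame(
    participant = rep(seq_len(n_participants),
                      each = n_sessions * n_trials_per_session),
    session = rep(rep(seq_len(n_sessions), each = n_trials_per_session),
                  times = n_participants),
    trial = rep(seq_len(n_trials_per_session),
                times = n_participants * n_sessions),
    stringsAsFactors = FALSE)
  tab$cue <- sample(cue_levels(), n, replace = TRUE)
  p_face <- face_prob_by_cue()[tab$cue]
  tab$stimulus <- ifelse(rbinom(n, 1, p_face) == 1, "face", "car")
  tab$coherence <- sample(coherence_levels, n, replace = TRUE)
  tab$y_early <- NA_real_
  tab$y_late <- NA_real_
  tab$choice <- NA_character_
  tab$rt <- NA_real_
  tab$valid <- NA
  class(tab) <- c("trial_table", "data.frame")
  attr(tab, "seed") <- as.integer(seed)
  tab
}

#' Simulate latent single-trial component amplitudes
#'
#' Draws the Early and Late component amplitudes that play the role of the
#' decoded single-trial evidence: high positive values reflect face
#' evidence, high negative values car evidence.  With stimulus sign
#' `s = +1` (face) / `-1` (car),
#' `y_early ~ N(s * m_early, amplitude_sd^2)` and
#' `y_late ~ N(s * (m_late0 + m_late1 * C), amplitude_sd^2)`, so only the
#' Late component separation grows with stimulus coherence `C`.
#'
#' @param table a `trial_table` with `stimulus` and `coherence` columns.
#' @param gt a [ground_truth()] object.
#' @param seed optional integer seed; defaults to a stream derived from the
#'   ground truth's master seed.
#' @return the table with `y_early` and `y_late` filled in.
#' @export
simulate_amplitudes <- function(table, gt, seed = NULL) {
  assert_columns(table, c("stimulus", "coherence"), "trial table")
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(seed %||% derive_seed(gt$seed, "amplitudes"))
  n <- nrow(table)
  s <- ifelse(table$stimulus == "face", 1, -1)
  table$y_early <- s * gt$m_early + rnorm(n, 0, gt$amplitude_sd)
  table$y_late <- s * (gt$m_late0 + gt$m_late1 * table$coherence) +
    rnorm(n, 0, gt$amplitude_sd)
  table
}

#' Draw participant-level diffusion and regression parameters
#'
#' Participant parameters are drawn from the group-level normals of the
#' ground truth (deterministically from the master seed): one shared
#' boundary `alpha` per participant, and cue-specific starting point,
#' non-decision time and drift-regression coefficients.
#'
#' @param gt a [ground_truth()] object.
#' @param n_participants number of participants.
#' @param seed optional integer seed.
#' @return data.frame with one row per (participant, cue).
#' @export
draw_participant_params <- function(gt, n_participants, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), n_participants >= 1)
  set.seed(seed %||% derive_seed(gt$seed, "participants"))
  cues <- cue_levels()
  alpha <- pmax(0.2, rnorm(n_participants, gt$alpha_mean, gt$alpha_sd))
  out <- do.call(rbind, lapply(seq_len(n_participants), function(j) {
    data.frame(
      participant = j, cue = cues,
      alpha = alpha[j],
      beta = pmin(0.95, pmax(0.05,
        rnorm(3, gt$beta_mean[cues], gt$beta_sd))),
      tau = pmax(0.05, rnorm(3, gt$tau_mean, gt$tau_sd)),
      gamma0 = rnorm(3, gt$gamma0[cues], gt$gamma0_sd),
      gamma_early = rnorm(3, gt$gamma_early[cues], gt$gamma_early_sd),
      gamma_late = rnorm(3, gt$gamma_late[cues], gt$gamma_late_sd),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate choices and response times via the Wiener diffusion
#'
#' For every trial the drift rate is assembled by [drift_link()] from the
#' trial's cue-specific coefficients and its latent component amplitudes,
#' and (choice, rt) are drawn from the Euler path sampler with the
#' participant's boundary, starting point and non-decision time.  Paths not
#' absorbed by the deadline become non-responses (`choice = NA`,
#' `valid = FALSE`); the upper boundary is the face choice.
#'
#' @param table a `trial_table` with amplitudes present.
#' @param gt a [ground_truth()] object.
#' @param seed optional integer seed.
#' @param dt Euler step of the path sampler (s).
#' @param params optional pre-drawn participant parameter table from
#'   [draw_participant_params()] (drawn from `gt` if omitted).
#' @return the table with `choice`, `rt`, `valid` filled in; the
#'   participant parameter table is attached as attribute
#'   `"participant_params"`.
#' @export
simulate_behaviour <- function(table, gt, seed = NULL, dt = 1e-4,
                               params = NULL) {
  assert_columns(table, c("participant", "cue", "y_early", "y_late"),
                 "trial table")
  stopifnot(inherits(gt, "ground_truth"))
  if (any(is.na(table$y_early)))
    stop("amplitudes must be simulated before behaviour")
  if (gt$tau_mean >= gt$deadline)
    stop("non-decision time reaches the deadline; no response can register")
  seed <- seed %||% derive_seed(gt$seed, "behaviour")
  if (is.null(params))
    params <- draw_participant_params(gt, max(table$participant), seed = seed)
  set.seed(derive_seed(seed, "diffusion-paths"))
  table$choice <- NA_character_
  table$rt <- NA_real_
  key <- paste(params$participant, params$cue)
  for (j in sort(unique(table$participant))) {
    for (cue in cue_levels()) {
      rows <- which(table$participant == j & table$cue == cue)
      if (length(rows) == 0) next
      pp <- params[match(paste(j, cue), key), ]
      if (any(is.na(pp$alpha)))
        stop(sprintf("no participant parameters for participant %d cue %s",
                     j, cue))
      delta <- drift_link(pp$gamma0, pp$gamma_early, pp$gamma_late,
                          table$y_early[rows], table$y_late[rows],
                          table$coherence[rows])
      sim <- wiener_sample_cpp(length(rows), pp$alpha, pp$beta, pp$tau,
                               delta, dt, gt$deadline)
      table$choice[rows] <- ifelse(is.na(sim$choice), NA_character_,
                                   ifelse(sim$choice == 1L, "face", "car"))
      table$rt[rows] <- sim$rt
    }
  }
  table$valid <- !is.na(table$choice)
  attr(table, "participant_params") <- params
  attr(table, "seed") <- attr(table, "seed") %||% as.integer(gt$seed)
  table
}

#' Simulate stimulus-locked multichannel EEG epochs
#'
#' Each trial's epoch is the sum of the two component signals and
#' autocorrelated background noise:
#' `x(t) = a_E * y_early * g(t; mu_E) + a_L * y_late * g(t; mu_L) + noise`,
#' where `a_E`, `a_L` are the unit-norm spatial patterns, `g` is a
#' unit-peak Gaussian bump at the component latency, and the noise is AR(1)
#' in time with low-rank shared spatial mixing, scaled to stationary SD
#' `gt$noise_scale` per channel.
#'
#' @param table a `trial_table` with amplitudes present.
#' @param gt a [ground_truth()] object.
#' @param srate sampling rate in Hz (>= 100).
#' @param seed optional integer seed.
#' @return an `epoch_set` (see [epoch_set()]).
#' @export
simulate_epochs <- function(table, gt, srate = 250, seed = NULL) {
  assert_columns(table, c("y_early", "y_late"), "trial table")
  stopifnot(inherits(gt, "ground_truth"))
  if (srate < 100) stop("srate must be >= 100 Hz")
  if (gt$epoch_span[1] > -0.125 || gt$epoch_span[2] < 1.025)
    stop("epoch span must cover at least [-0.125, 1.025] s for decoding")
  if (any(is.na(table$y_early)))
    stop("amplitudes must be simulated before epochs")
  set.seed(seed %||% derive_seed(gt$seed, "epochs"))
  S <- ceiling(diff(gt$epoch_span) * srate) + 1L   # last sample >= span end
  times <- gt$epoch_span[1] + (seq_len(S) - 1) / srate
  K <- gt$n_channels
  n <- nrow(table)
  g_e <- exp(-(times - gt$early_latency)^2 / (2 * gt$early_width^2))
  g_l <- exp(-(times - gt$late_latency)^2 / (2 * gt$late_width^2))

  data <- array(0, dim = c(n, K, S))
  # signal: outer products per trial, built channel-major for speed
  sigE <- outer(table$y_early, g_e)           # n x S
  sigL <- outer(table$y_late, g_l)
  for (k in seq_len(K))
    data[, k, ] <- gt$pattern_early[k] * sigE + gt$pattern_late[k] * sigL

  if (gt$noise_scale > 0) {
    A <- matrix(rnorm(K * gt$spatial_rank), K, gt$spatial_rank) /
      sqrt(gt$spatial_rank)
    ch_scale <- gt$noise_scale * sqrt(1 - gt$ar_coef^2) /
      sqrt(1 + rowSums(A^2))
    for (i in seq_len(n)) {
      E <- matrix(rnorm(S * K), S, K) +
        matrix(rnorm(S * gt$spatial_rank), S, gt$spatial_rank) %*% t(A)
      E <- sweep(E, 2, ch_scale, `*`)
      noise <- stats::filter(E, gt$ar_coef, method = "recursive")
      data[i, , ] <- data[i, , ] + t(noise)
    }
  }
  epoch_set(data, srate = srate, times = times,
            channels = sprintf("C%02d", seq_len(K)),
            seed = seed %||% derive_seed(gt$seed, "epochs"))
}

#' Stimulus-locked EEG epoch container
#'
#' @param data numeric array, trials x channels x samples (microvolt-scale
#'   arbitrary units).
#' @param srate sampling rate (Hz).
#' @param times time axis in seconds, 0 = stimulus onset; must be uniform
#'   and strictly increasing with length `dim(data)[3]`.
#' @param channels channel labels, length `dim(data)[2]`.
#' @param seed seed recorded for provenance (optional).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, times, channels, seed = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (length(times) != dim(data)[3])
    stop("time axis length must match the sample dimension")
  if (length(channels) != dim(data)[2])
    stop("channel labels must match the channel dimension")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    stop("time axis must be strictly increasing and uniform")
  structure(list(data = data, srate = srate, times = times,
                 channels = channels, seed = seed),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "EEG epochs: %d trials x %d channels x %d samples @ %g Hz, [%g, %g] s\n",
    d[1], d[2], d[3], x$srate, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Synthetic ocular-artifact calibration recording
#'
#' Builds a continuous multichannel record containing stereotyped blink,
#' horizontal-saccade and vertical-saccade deflections at known event
#' times on top of the background noise model, mimicking the calibration
#' run in which observers blink and make saccades on command.  Used to
#' exercise the ocular projection learning and removal steps against known
#' topographies.
#'
#' @param gt a [ground_truth()] object (holds topographies, scales, noise).
#' @param seed optional integer seed.
#' @param srate sampling rate (Hz).
#' @param n_events number of events per artifact class.
#' @return list with `record` (samples x channels matrix), `srate`, `times`
#'   (s), and `events` (data.frame of `type`, `time`), times strictly
#'   increasing within class.
#' @export
make_calibration_recording <- function(gt, seed = NULL, srate = 250,
                                       n_events = 15) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(seed %||% derive_seed(gt$seed, "calibration"))
  gap <- 1.0
  classes <- c("blink", "hsaccade", "vsaccade")
  n_tot <- n_events * length(classes)
  duration <- (n_tot + 1) * gap
  S <- ceiling(duration * srate)
  K <- gt$n_channels
  times <- (seq_len(S) - 1) / srate

  rec <- matrix(0, S, K)
  if (gt$noise_scale > 0) {
    A <- matrix(rnorm(K * gt$spatial_rank), K, gt$spatial_rank) /
      sqrt(gt$spatial_rank)
    ch_scale <- gt$noise_scale * sqrt(1 - gt$ar_coef^2) /
      sqrt(1 + rowSums(A^2))
    E <- matrix(rnorm(S * K), S, K) +
      matrix(rnorm(S * gt$spatial_rank), S, gt$spatial_rank) %*% t(A)
    E <- sweep(E, 2, ch_scale, `*`)
    rec <- as.matrix(stats::filter(E, gt$ar_coef, method = "recursive"))
  }

  event_type <- rep(classes, times = n_events)[sample(n_tot)]
  event_time <- gap * seq_len(n_tot)
  topo <- list(blink = gt$blink_topography * gt$blink_scale,
               hsaccade = gt$hsaccade_topography * gt$saccade_scale,
               vsaccade = gt$vsaccade_topography * gt$saccade_scale)
  # blink: 300-ms half-sine bump; saccades: 200-ms step-like deflection
  for (e in seq_len(n_tot)) {
    t0 <- event_time[e]
    if (event_type[e] == "blink") {
      idx <- which(times >= t0 & times < t0 + 0.3)
      w <- sin(pi * (times[idx] - t0) / 0.3)
    } else {
      idx <- which(times >= t0 & times < t0 + 0.2)
      w <- pmin(1, (times[idx] - t0) / 0.04)
    }
    amp <- 1 + 0.2 * rnorm(1)
    rec[idx, ] <- rec[idx, ] + outer(w, topo[[event_type[e]]] * amp)
  }
  list(record = rec, srate = srate, times = times,
       events = data.frame(type = event_type, time = event_time,
                           stringsAsFactors = FALSE))
}

#' Write / read a trial table as CSV
#'
#' Column dictionary: `participant`, `session`, `trial` (integers), `cue`
#' (30F/50F/70F), `stimulus` (face/car), `coherence` (proportion),
#' `y_early`/`y_late` (unitless amplitudes), `choice` (face/car or empty
#' for a non-response), `rt` (seconds), `valid` (logical).
#'
#' @param table a `trial_table`.
#' @param path file path.
#' @return `write_trial_table` returns `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  tab
}
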