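test_that("design cues hit the stated face probabilities and counts", {
  tab <- generate_design(1, 1, 90000, seed = 1)   # ~30k trials per cue
  f70 <- mean(tab$stimulus[tab$cue == "70F"] == "face")
  f30 <- mean(tab$stimulus[tab$cue == "30F"] == "face")
  f50 <- mean(tab$stimulus[tab$cue == "50F"] == "face")
  expect_lt(abs(f70 - 0.70), 0.01)
  expect_lt(abs(f30 - 0.30), 0.01)
  expect_lt(abs(f50 - 0.50), 0.01)
  # cue assignment approximately equiprobable
  expect_true(all(abs(table(tab$cue) / nrow(tab) - 1 / 3) < 0.02))

  tab2 <- generate_design(2, 3, 360, seed = 9)
  expect_equal(nrow(tab2), 2160)
  counts <- table(tab2$participant, tab2$session)
  expect_true(all(counts == 360))

  expect_identical(generate_design(1, 1, 3, seed = 5),
                   generate_design(1, 1, 3, seed = 5))
  expect_error(generate_design(0, 1, 10), "counts")
})

test_that("amplitude model separates classes and scales Late with coherence", {
  gt0 <- small_gt(amplitude_sd = 0)
  tab <- generate_design(1, 1, 40, seed = 4)
  tab <- simulate_amplitudes(tab, gt0)
  s <- ifelse(tab$stimulus == "face", 1, -1)
  expect_equal(tab$y_early, s * gt0$m_early, tolerance = 1e-12)
  # flipping all stimulus labels flips the amplitudes exactly
  flip <- tab
  flip$stimulus <- ifelse(tab$stimulus == "face", "car", "face")
  flip <- simulate_amplitudes(flip, gt0)
  expect_equal(flip$y_early, -tab$y_early, tolerance = 1e-12)

  # coherence effect on Late amplitude: closed-form mean difference
  gt <- small_gt()
  big <- generate_design(1, 1, 20000, seed = 6)
  big <- simulate_amplitudes(big, gt)
  f <- big[big$stimulus == "face", ]
  d <- mean(f$y_late[f$coherence == 0.375]) -
    mean(f$y_late[f$coherence == 0.325])
  se <- gt$amplitude_sd * sqrt(1 / sum(f$coherence == 0.375) +
                                 1 / sum(f$coherence == 0.325))
  expect_lt(abs(d - gt$m_late1 * 0.05), 3 * se)
  expect_error(simulate_amplitudes(data.frame(a = 1), gt), "missing")
})

test_that("diffusion behaviour respects symmetry, bias and non-decision time", {
  # no drift regressors, unbiased start -> half the choices are faces
  gt_sym <- ground_truth(n_channels = 16, seed = 21,
                         gamma0 = c(0, 0, 0), gamma0_sd = 1e-9,
                         gamma_early = c(0, 0, 0), gamma_early_sd = 1e-9,
                         gamma_late = c(0, 0, 0), gamma_late_sd = 1e-9,
                         beta_sd = 1e-9, alpha_sd = 1e-9, tau_sd = 1e-9)
  tab <- generate_design(1, 1, 4000, seed = 21)
  tab <- simulate_amplitudes(tab, gt_sym)
  tab <- simulate_behaviour(tab, gt_sym, dt = 5e-4)
  expect_lt(abs(mean(tab$choice == "face", na.rm = TRUE) - 0.5), 0.03)

  # strong drift intercept forces face choices
  gt_bias <- ground_truth(n_channels = 16, seed = 22,
                          m_early = 0, m_late0 = 0, m_late1 = 0,
                          amplitude_sd = 0,
                          gamma0 = c(5, 5, 5), gamma0_sd = 1e-9,
                          gamma_early = c(0, 0, 0), gamma_early_sd = 1e-9,
                          gamma_late = c(0, 0, 0), gamma_late_sd = 1e-9,
                          beta_sd = 1e-9, alpha_sd = 1e-9, tau_sd = 1e-9)
  tab2 <- generate_design(1, 1, 2000, seed = 22)
  tab2 <- simulate_amplitudes(tab2, gt_bias)
  tab2 <- simulate_behaviour(tab2, gt_bias, dt = 5e-4)
  expect_gt(mean(tab2$choice == "face", na.rm = TRUE), 0.95)

  # non-decision offset bounds the response times from below
  gt_tau <- ground_truth(n_channels = 16, seed = 23, tau_mean = 0.3,
                         tau_sd = 1e-9)
  tab3 <- generate_design(1, 1, 300, seed = 23)
  tab3 <- simulate_amplitudes(tab3, gt_tau)
  tab3 <- simulate_behaviour(tab3, gt_tau, dt = 5e-4)
  expect_true(all(tab3$rt >= 0.3, na.rm = TRUE))
  expect_true(all(tab3$rt <= gt_tau$deadline + 1e-9, na.rm = TRUE))
  expect_identical(is.na(tab3$rt), !tab3$valid)

  expect_error(simulate_behaviour(tab3, ground_truth(tau_mean = 1.3)),
               "deadline")
})

test_that("default generative settings hit the intended behavioural
           operating range", {
  fx <- fixture_behaviour()
  tab <- fx$table
  miss <- 1 - mean(tab$valid)
  rt_mean <- mean(tab$rt, na.rm = TRUE)
  acc <- mean((tab$choice == tab$stimulus)[tab$valid])
  expect_lt(miss, 0.08)                 # deadline misses stay rare
  expect_gt(rt_mean, 0.45)
  expect_lt(rt_mean, 0.75)
  expect_gt(acc, 0.65)
  expect_lt(acc, 0.85)
})

test_that("generated response times are right-skewed and cue-congruent", {
  fx <- fixture_behaviour()
  tab <- fx$table[fx$table$valid, ]
  for (cue in unique(tab$cue)) {
    rt <- tab$rt[tab$cue == cue]
    sk <- mean((rt - mean(rt))^3) / sd(rt)^3
    expect_gt(sk, 0)
  }
  # congruent stimuli are answered faster than incongruent ones
  rt70 <- tapply(tab$rt[tab$cue == "70F"], tab$stimulus[tab$cue == "70F"],
                 mean)
  rt30 <- tapply(tab$rt[tab$cue == "30F"], tab$stimulus[tab$cue == "30F"],
                 mean)
  expect_lt(rt70[["face"]], rt70[["car"]])
  expect_lt(rt30[["car"]], rt30[["face"]])
})

test_that("noiseless epochs reconstruct the injected component signals", {
  gt <- ground_truth(n_channels = 12, seed = 13, noise_scale = 0)
  tab <- generate_design(1, 1, 40, seed = 13)
  tab <- simulate_amplitudes(tab, gt)
  ep <- simulate_epochs(tab, gt, srate = 200)    # 5-ms grid hits 200 ms
  i_peak <- which.min(abs(ep$times - gt$early_latency))
  expect_equal(ep$times[i_peak], gt$early_latency, tolerance = 1e-9)
  for (ch in c(1, 5, 12)) {
    expect_equal(ep$data[, ch, i_peak], gt$pattern_early[ch] * tab$y_early,
                 tolerance = 1e-6)
  }
  proj <- as.numeric(ep$data[, , i_peak] %*% gt$pattern_early)
  expect_gt(cor(proj, tab$y_early), 0.999999)
})

test_that("epochs are reproducible under the seed and carry a valid axis", {
  fx <- fixture_epochs()
  ep <- fx$epochs
  expect_true(all(diff(ep$times) > 0))
  expect_lt(diff(range(diff(ep$times))), 1e-9)
  expect_equal(length(ep$channels), dim(ep)[2])
  ep2 <- simulate_epochs(fx$table, fx$gt, srate = 250)
  expect_equal(ep$data, ep2$data, tolerance = 0)
  expect_error(epoch_set(array(0, c(2, 2, 3)), 100, c(0, 0.01), c("a", "b")),
               "time axis")
})

test_that("calibration recordings embed the declared ocular topographies", {
  gt <- small_gt()
  cal <- make_calibration_recording(gt, seed = 31)
  expect_true(all(diff(cal$events$time) > 0))
  # principal spatial component of blink segments matches the topography
  proj <- learn_ocular_projections(cal)
  i_blink <- which(proj$labels == "blink")
  expect_gt(abs(cor(proj$filters[i_blink, ], gt$blink_topography)), 0.95)
  expect_equal(sqrt(rowSums(proj$filters^2)), rep(1, 3), tolerance = 1e-9)

  # zero-amplitude artifacts leave pure background noise and trigger the
  # degenerate-calibration warning
  gt0 <- small_gt(blink_scale = 0, saccade_scale = 0)
  cal0 <- make_calibration_recording(gt0, seed = 31)
  expect_lt(max(abs(cal0$record)), 10 * gt0$noise_scale)
  expect_warning(learn_ocular_projections(cal0), "variance")
})
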