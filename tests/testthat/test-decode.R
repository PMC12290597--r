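# independent oracle: Newton solve of the penalised logistic likelihood
# written directly from the objective, used only at tiny problem sizes
newton_oracle <- function(X, z, lambda_total) {
  w <- rep(0, ncol(X))
  for (i in 1:200) {
    p <- 1 / (1 + exp(-X %*% w))
    g <- t(X) %*% (z - p) - 2 * lambda_total * w
    H <- t(X) %*% (X * as.numeric(p * (1 - p))) +
      diag(2 * lambda_total, ncol(X))
    step <- solve(H, g)
    w <- w + step
    if (sqrt(sum(g^2)) < 1e-10) break
  }
  as.numeric(w)
}

test_that("ridge logistic training matches an independent Newton solve", {
  set.seed(10)
  X <- matrix(rnorm(12), 6, 2)
  z <- c(1, 1, 1, 0, 0, 0)
  fit <- train_logistic(X, z, lambda = 0.05)
  expect_equal(fit$w, newton_oracle(X, z, 0.05 * nrow(X)), tolerance = 1e-6)
  expect_true(fit$converged)
  # label complement flips the weights exactly
  fit2 <- train_logistic(X, 1 - z, lambda = 0.05)
  expect_equal(fit2$w, -fit$w, tolerance = 1e-8)
  # well-separated classes reach training Az = 1
  Xs <- rbind(matrix(rnorm(40, 5), 20, 2), matrix(rnorm(40, -5), 20, 2))
  zs <- rep(c(1, 0), each = 20)
  fs <- train_logistic(Xs, zs, lambda = 1e-3)
  expect_equal(auc(as.numeric(Xs %*% fs$w), zs), 1.0)
  expect_error(train_logistic(X, rep(1, 6)), "classes")
  expect_error(train_logistic(X * NA, z), "finite")
})

test_that("Az follows the Mann-Whitney definition with ties at half", {
  expect_equal(auc(c(2.1, 1.3, -0.5, -1.7), c(1, 1, 0, 0)), 1.0)
  # brute force over all positive/negative pairs
  y <- c(1, -1, 0.5, -0.5); z <- c(1, 0, 0, 1)
  brute <- mean(outer(y[z == 1], y[z == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc(y, z), brute)
  expect_equal(auc(y, z), 0.75)
  expect_equal(auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # invariance to strictly increasing transforms
  set.seed(2)
  yy <- rnorm(40); zz <- rbinom(40, 1, 0.5)
  zz[1:2] <- c(0, 1)
  expect_equal(auc(yy, zz), auc(exp(yy), zz))
  expect_error(auc(yy, rep(1, 40)), "classes")
})

test_that("LOO amplitudes never depend on the held-out trial's label", {
  gt <- small_gt()
  tab <- generate_design(1, 1, 20, seed = 15)
  tab <- simulate_amplitudes(tab, gt)
  ep <- simulate_epochs(tab, gt, srate = 250)
  z <- as.numeric(tab$stimulus == "face")
  s1 <- sliding_discrimination(ep, z, step = 0.05,
                               t_range = c(0.15, 0.25))
  zflip <- z
  zflip[7] <- 1 - z[7]
  s2 <- sliding_discrimination(ep, zflip, step = 0.05,
                               t_range = c(0.15, 0.25))
  # equality holds to solver tolerance (the refits converge from
  # different warm starts)
  for (ci in seq_along(s1$centres))
    expect_equal(s1$y[ci, 7], s2$y[ci, 7], tolerance = 1e-5)
  # three trials -> three LOO folds, one amplitude each
  s3 <- sliding_discrimination(
    epoch_set(ep$data[1:3, , , drop = FALSE], ep$srate, ep$times,
              ep$channels), z[1:3], step = 0.05, t_range = c(0.2, 0.2))
  expect_equal(length(s3$y[1, ]), 3)
})

test_that("series recovers injected components and errors on short spans", {
  fx <- fixture_epochs()
  ser <- fixture_series()
  comp <- pick_components(ser)
  expect_lt(abs(comp$early_time - fx$gt$early_latency), 0.020 + 1e-9)
  expect_lt(abs(comp$late_time - fx$gt$late_latency), 0.020 + 1e-9)
  expect_gt(comp$early_az, 0.65)
  expect_gt(abs(cor(comp$forward_early, fx$gt$pattern_early)), 0.9)
  expect_gt(abs(cor(comp$forward_late, fx$gt$pattern_late)), 0.9)
  expect_error(
    sliding_discrimination(fx$epochs, fx$z, t_range = c(-0.2, 1.0)),
    "-0.200")
  # doubling the ridge never increases the training log-likelihood
  idx <- which(fx$epochs$times >= 0.175 & fx$epochs$times <= 0.225)
  X <- matrix(aperm(fx$epochs$data[, , idx], c(3, 1, 2)),
              nrow = 200 * length(idx))
  zrow <- rep(fx$z, each = length(idx))
  lls <- vapply(c(1e-4, 2e-4, 4e-4, 8e-4, 1.6e-3), function(l)
    train_logistic(X, zrow, lambda = l)$loglik, 0)
  expect_true(all(diff(lls) <= 1e-8))
})

test_that("forward projection follows its defining formula", {
  y <- c(1, -2, 0.5, 3)
  expect_equal(forward_projection(matrix(y, 1), y), 1)
  X <- rbind(y, c(1, 1, 2, -1))   # second channel orthogonal to y
  X[2, ] <- X[2, ] - sum(X[2, ] * y) / sum(y^2) * y
  a <- forward_projection(X, y)
  expect_lt(abs(a[2]), 1e-12)
  set.seed(3)
  X2 <- matrix(rnorm(40), 4, 10)
  y2 <- rnorm(10)
  expect_equal(forward_projection(X2, y2),
               as.numeric(X2 %*% y2 / sum(y2^2)), tolerance = 1e-12)
  expect_error(forward_projection(X2, rep(0, 10)), "zero")
})

test_that("component picking takes window maxima with early tie-breaks", {
  centres <- seq(-0.1, 1.0, by = 0.01)
  az <- rep(0.5, length(centres))
  az[centres > 0.19 & centres < 0.21] <- 0.9
  az[centres > 0.34 & centres < 0.36] <- 0.85
  fake <- structure(list(centres = centres, az = az,
                         y = matrix(0, length(centres), 4),
                         forward = matrix(0, length(centres), 3)),
                    class = "discrimination_series")
  cp <- pick_components(fake)
  expect_equal(cp$early_time, 0.20, tolerance = 1e-9)
  expect_equal(cp$late_time, 0.35, tolerance = 1e-9)
  # flat early window -> earliest centre selected
  fake$az <- rep(0.5, length(centres))
  cp2 <- pick_components(fake)
  expect_equal(cp2$early_time, 0.15, tolerance = 1e-9)
  # monotone rising Az -> late edge of the late window
  fake$az <- seq(0.4, 0.9, length.out = length(centres))
  cp3 <- pick_components(fake)
  expect_equal(cp3$late_time, 0.50, tolerance = 1e-9)
  expect_error(pick_components(fake, early = c(2, 3)), "cover")
})

test_that("permutation p-values detect real structure and stay calibrated", {
  gt0 <- small_gt(noise_scale = 0.3)
  tab <- generate_design(1, 1, 30, seed = 17)
  tab <- simulate_amplitudes(tab, gt0)
  ep <- simulate_epochs(tab, gt0, srate = 250)
  z <- as.numeric(tab$stimulus == "face")
  p <- permutation_pvalue(ep, z, centre = 0.2, n_perm = 199, seed = 3)
  expect_equal(p, 1 / 200, tolerance = 1e-12)
  expect_lt(p, 0.01)
  expect_error(permutation_pvalue(ep, z, 0.2, n_perm = 50), "n_perm")

  # under a true null the p-value is uniform: KS over replicates on a
  # small, fast configuration
  gt_null <- ground_truth(n_channels = 4, seed = 33,
                          m_early = 0, m_late0 = 0, m_late1 = 0)
  tabn <- generate_design(1, 1, 16, seed = 33)
  tabn <- simulate_amplitudes(tabn, gt_null)
  set.seed(99)
  pvals <- vapply(seq_len(80), function(r) {
    epn <- simulate_epochs(tabn, gt_null, srate = 100, seed = 1000 + r)
    zr <- sample(rep(0:1, 8))
    permutation_pvalue(epn, zr, centre = 0.2, n_perm = 100, seed = r)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("amplitude standardisation only rescales", {
  y <- rnorm(50, sd = 4)
  ys <- standardize_amplitudes(y)
  expect_equal(sd(ys), 1, tolerance = 1e-12)
  expect_equal(ys, y / sd(y), tolerance = 1e-12)
  expect_equal(standardize_amplitudes(ys), ys, tolerance = 1e-12)
  expect_error(standardize_amplitudes(rep(2, 5)), "variance")
})

test_that("choice regression attributes predictive power correctly", {
  set.seed(12)
  n <- 3000
  yE <- standardize_amplitudes(rnorm(n))
  yL <- standardize_amplitudes(rnorm(n))
  choice <- rbinom(n, 1, plogis(2 * yL))      # Late drives choice
  cr <- choice_regression(yE, yL, choice)
  co <- cr$coefficients
  rowE <- co[co$term == "y_early", ]
  expect_true(rowE$ci_lo < 0 && rowE$ci_hi > 0)
  lrt <- cr$lrt
  chi_drop_late <- lrt$chisq[lrt$dropped == "y_late"]
  chi_drop_early <- lrt$chisq[lrt$dropped == "y_early"]
  expect_gt(chi_drop_late, chi_drop_early)
  expect_lt(lrt$p[lrt$dropped == "y_late"], 0.001)

  # null calibration: CIs cover zero at roughly the nominal rate
  cover <- replicate(30, {
    ch <- rbinom(400, 1, 0.5)
    cc <- choice_regression(rnorm(400), rnorm(400), ch)$coefficients
    r <- cc[cc$term == "y_early", ]
    r$ci_lo < 0 && r$ci_hi > 0
  })
  expect_gte(mean(cover), 0.8)

  expect_warning(cr2 <- choice_regression(yE, yE, choice), "collinear")
  expect_true(cr2$ridge)
  expect_error(choice_regression(yE, yL, rep(1, n)), "degenerate")
})

test_that("likelihood-ratio test matches the chi-square tail", {
  out <- likelihood_ratio_test(-10, -10, 1)
  expect_equal(out$chisq, 0)
  expect_equal(out$p, 1)
  expect_equal(likelihood_ratio_test(-10, -10 + 3.841 / 2, 1)$p, 0.05,
               tolerance = 1e-3)
  expect_equal(likelihood_ratio_test(-5, -5, 2)$p, 1)
  expect_error(likelihood_ratio_test(-5, -6, 1), "nested")
})

test_that("RT matching trims the stated fractions per cue", {
  set.seed(20)
  mk <- function(cue) data.frame(
    cue = cue, stimulus = rep(c("face", "car"), each = 100),
    rt = runif(200, 0.3, 1.2), valid = TRUE)
  tab <- rbind(mk("30F"), mk("50F"), mk("70F"))
  kept <- rt_matched_subset(tab)
  expect_equal(nrow(kept), 3 * 184)
  expect_equal(nrow(kept) / nrow(tab), 0.92)
  # the removed car trials are the slowest, face the fastest
  slow_car <- tab[tab$cue == "30F" & tab$stimulus == "car", ]
  cut_rt <- sort(slow_car$rt, decreasing = TRUE)[8]
  expect_true(all(kept$rt[kept$cue == "30F" & kept$stimulus == "car"] <
                    cut_rt + 1e-12))
  expect_identical(rt_matched_subset(tab, frac = 0), tab)
  small <- data.frame(cue = "50F", stimulus = "car",
                      rt = runif(25, 0.3, 1), valid = TRUE)
  expect_equal(nrow(rt_matched_subset(small)), 23)
  expect_error(rt_matched_subset(tab, frac = 0.6), "frac")
})
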