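test_that("drift and starting-point links follow their formulas", {
  expect_equal(drift_link(0, 0, 0, 1.3, -2, 0.375), 0)
  expect_equal(drift_link(1, 2, 1, 0.5, 2, 0.375), 2.75)
  expect_equal(drift_link(0, 0.7, 1.1, -0.5, -2, 0.325),
               -drift_link(0, 0.7, 1.1, 0.5, 2, 0.325))
  # coherence multiplies only the flagged terms
  expect_equal(drift_link(0, 2, 0, 1, 0, 0.5, scale_early = TRUE), 1)
  expect_equal(start_link(0, 0, 0, 1, 1), 0.5)
  expect_equal(start_link(4, 0, 0, 0, 0), plogis(4), tolerance = 1e-9)
  set.seed(5)
  b <- start_link(rnorm(100, 0, 5), rnorm(100), rnorm(100), rnorm(100),
                  rnorm(100))
  expect_true(all(b > 0 & b < 1))
})

test_that("model registries match their variant structure", {
  fx <- fixture_small_behaviour()
  d <- hierarchical_data(fx$table)
  mB <- build_model(model_spec("B"), d)
  expect_false(any(grepl("gamma", mB$fam$name)))
  expect_true(any(grepl("^delta", mB$fam$name)))
  m3 <- build_model(model_spec("M3"), d)
  for (base in c("gamma0", "gamma_early", "gamma_late"))
    expect_equal(sum(grepl(sprintf("^mu_%s\\[", base), m3$group_names)), 3)
  m1 <- build_model(model_spec("M1"), d)
  expect_true(all(c("b0", "b_early", "b_late") %in% m1$fam$base))
  expect_false("beta" %in% m1$fam$base)
  m2 <- build_model(model_spec("M2"), d)
  expect_true("b_early" %in% m2$fam$base)
  expect_false("b_late" %in% m2$fam$base)
  expect_true("gamma_late" %in% m2$fam$base)
  expect_false("gamma_early" %in% m2$fam$base)
})

test_that("log-posterior equals a direct prior-plus-likelihood evaluation", {
  fx <- fixture_small_behaviour()
  d <- hierarchical_data(fx$table)
  spec <- model_spec("M3")
  m <- build_model(spec, d)
  nf <- m$n_fam
  set.seed(7)
  mu <- runif(nf, m$fam$mu_lo, m$fam$mu_hi)
  mu[m$fam$base == "tau"] <- 0.2
  mu[m$fam$base == "alpha"] <- 1.5
  mu[m$fam$base == "beta"] <- 0.5
  sg <- runif(nf, 0.05, 0.3)
  P <- matrix(NA_real_, m$n_participants, nf)
  for (j in seq_len(m$n_participants))
    P[j, ] <- pmin(m$fam$sup_hi, pmax(m$fam$sup_lo, rnorm(nf, mu, sg)))

  # independent computation of the same density
  direct_prior <- 0
  for (f in seq_len(nf)) for (j in seq_len(m$n_participants)) {
    Z <- pnorm(m$fam$sup_hi[f], mu[f], sg[f]) -
      pnorm(m$fam$sup_lo[f], mu[f], sg[f])
    direct_prior <- direct_prior +
      dnorm(P[j, f], mu[f], sg[f], log = TRUE) - log(Z)
  }
  direct_ll <- 0
  fam_name <- m$fam$name
  for (j in seq_len(m$n_participants)) {
    rows <- which(d$participant == m$participants[j])
    cue <- d$cue[rows]
    g0 <- P[j, match(sprintf("gamma0[%s]", cue), fam_name)]
    gE <- P[j, match(sprintf("gamma_early[%s]", cue), fam_name)]
    gL <- P[j, match(sprintf("gamma_late[%s]", cue), fam_name)]
    delta <- g0 + gE * d$y_early[rows] +
      gL * d$y_late[rows] * d$coherence[rows]
    beta <- P[j, match(sprintf("beta[%s]", cue), fam_name)]
    tau <- P[j, match(sprintf("tau[%s]", cue), fam_name)]
    alpha <- P[j, match("alpha", fam_name)]
    direct_ll <- direct_ll + wiener_loglik(d$rt[rows], d$face[rows] == 1,
                                           delta, beta, tau, alpha)
  }
  expect_equal(m$log_posterior(c(mu, sg), P), direct_prior + direct_ll,
               tolerance = 1e-8)
  # out-of-bounds group means are rejected outright
  mu_bad <- mu; mu_bad[1] <- m$fam$mu_hi[1] + 1
  expect_identical(m$log_posterior(c(mu_bad, sg), P), -Inf)
})

test_that("sampler is deterministic, respects bounds and retains correctly", {
  fx <- fixture_small_behaviour()
  m <- build_model(model_spec("M3"), hierarchical_data(fx$table))
  s1 <- sample_posterior(m, n_iter = 200, burn = 80, thin = 4, chains = 2,
                         seed = 17)
  s2 <- sample_posterior(m, n_iter = 200, burn = 80, thin = 4, chains = 2,
                         seed = 17)
  expect_identical(s1$draws, s2$draws)
  expect_equal(dim(s1$draws), c(2, 30, length(s1$param_names)))
  expect_equal(dim(s1$loglik), c(2, 30))
  # draws respect the uniform prior bounds
  for (f in seq_len(m$n_fam)) {
    mu_d <- s1$draws[, , paste0("mu_", m$fam$name[f])]
    expect_true(all(mu_d >= m$fam$mu_lo[f] & mu_d <= m$fam$mu_hi[f]))
    sg_d <- s1$draws[, , paste0("sigma_", m$fam$name[f])]
    expect_true(all(sg_d >= m$fam$sigma_lo[f] & sg_d <= m$fam$sigma_hi[f]))
  }
  expect_error(sample_posterior(m, n_iter = 100, burn = 10, thin = 2,
                                chains = 1), "chains")
})

test_that("split-chain R-hat separates mixed from divergent chains", {
  mk_samples <- function(draws, names) {
    structure(list(draws = draws, param_names = names,
                   group_names = names,
                   loglik = matrix(0, dim(draws)[1], dim(draws)[2]),
                   settings = list()), class = "posterior_samples")
  }
  set.seed(31)
  good <- array(rnorm(4 * 200), c(4, 200, 1), dimnames = list(NULL, NULL, "a"))
  expect_lt(gelman_rubin(mk_samples(good, "a"))[["a"]], 1.05)
  bad <- good
  bad[1, , 1] <- bad[1, , 1] + 5
  expect_gt(gelman_rubin(mk_samples(bad, "a"))[["a"]], 1.5)
  const <- array(1, c(2, 50, 1), dimnames = list(NULL, NULL, "a"))
  expect_warning(r <- gelman_rubin(mk_samples(const, "a")), "variance")
  expect_true(is.na(r[["a"]]))
  expect_error(gelman_rubin(mk_samples(good[, 1:5, , drop = FALSE], "a")),
               "draws")
  # chain-label permutation leaves the diagnostic unchanged
  perm <- good[c(3, 1, 4, 2), , , drop = FALSE]
  expect_equal(gelman_rubin(mk_samples(perm, "a")),
               gelman_rubin(mk_samples(good, "a")), tolerance = 1e-12)
})

test_that("DIC penalises complexity via the posterior-mean plug-in", {
  fx <- fixture_small_behaviour()
  m <- build_model(model_spec("M3"), hierarchical_data(fx$table))
  s <- sample_posterior(m, n_iter = 400, burn = 150, thin = 5, chains = 2,
                        seed = 23)
  ic <- dic(s, m)
  expect_equal(ic$dic, ic$dbar + ic$pd, tolerance = 1e-9)
  expect_gt(ic$pd, 0)

  # degenerate posterior: all draws identical -> pD = 0, DIC = Dbar
  theta <- s$draws[1, 1, ]
  deg <- s
  for (ch in 1:2) for (k in seq_len(dim(s$draws)[2]))
    deg$draws[ch, k, ] <- theta
  P <- matrix(theta[m$part_names], nrow = m$n_participants)
  ll0 <- neurodrift:::model_total_ll(m, P)
  deg$loglik[] <- ll0
  ic0 <- dic(deg, m)
  expect_equal(ic0$pd, 0, tolerance = 1e-9)
  expect_equal(ic0$dic, ic0$dbar, tolerance = 1e-9)

  # further thinning moves DIC only within Monte-Carlo error
  half <- s
  keep <- seq(1, dim(s$draws)[2], by = 2)
  half$draws <- s$draws[, keep, , drop = FALSE]
  half$loglik <- s$loglik[, keep, drop = FALSE]
  mc_err <- 3 * sd(-2 * as.vector(s$loglik)) /
    sqrt(length(keep) * 2) * 2
  expect_lt(abs(dic(half, m)$dic - ic$dic), max(mc_err, 10))
})

test_that("posterior contrasts count pooled draws", {
  draws <- array(0, c(2, 3, 2), dimnames = list(NULL, NULL, c("a", "b")))
  draws[, , "a"] <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  draws[, , "b"] <- matrix(c(0, 3, 2, 5, 4, 7), 2, 3)
  s <- structure(list(draws = draws, param_names = c("a", "b"),
                      group_names = c("a", "b")),
                 class = "posterior_samples")
  expect_equal(posterior_prob(s, "a > a"), 0)
  brute <- mean(as.vector(draws[, , "a"]) > as.vector(draws[, , "b"]))
  expect_equal(posterior_prob(s, "a > b"), brute)
  expect_equal(posterior_prob(s, "a < b"), 1 - brute)
  expect_equal(posterior_prob(s, "a > -10"), 1)
  draws2 <- draws
  draws2[, , "a"] <- draws[, , "b"] + 1
  s2 <- structure(list(draws = draws2, param_names = c("a", "b"),
                       group_names = c("a", "b")),
                  class = "posterior_samples")
  expect_equal(posterior_prob(s2, "a > b"), 1)
  expect_error(posterior_prob(s, "zzz > b"), "unknown")
})

test_that("identical specifications produce identical DIC under one seed", {
  fx <- fixture_small_behaviour()
  d <- hierarchical_data(fx$table)
  cmp <- compare_models(list(model_spec("M3"), model_spec("M3")), d,
                        n_iter = 200, burn = 80, thin = 4, chains = 2,
                        seed = 41)
  expect_equal(cmp$table$dic[1], cmp$table$dic[2], tolerance = 1e-9)
  expect_equal(cmp$winner, "M3")
})

test_that("hierarchical data screens malformed trials", {
  fx <- fixture_small_behaviour()
  d <- hierarchical_data(fx$table)
  expect_true(all(d$rt > 0))
  expect_true(all(d$choice %in% c("face", "car")))
  bad <- fx$table
  bad$rt[bad$valid][1] <- -1
  expect_error(hierarchical_data(bad), "positive")
})
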