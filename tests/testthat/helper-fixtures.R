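# Shared fixtures, built lazily and cached for the session so expensive
# simulations (epochs, MCMC fits) are computed once across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small ground truth used by most decoding tests: 16 channels keeps the
# logistic fits fast while preserving the multichannel structure
small_gt <- function(...) {
  ground_truth(n_channels = 16, seed = 7, ...)
}

# 200-trial single-participant epoch set at default noise
fixture_epochs <- function() {
  fixture("epochs200", function() {
    gt <- small_gt()
    tab <- generate_design(1, 1, 200, seed = 2)
    tab <- simulate_amplitudes(tab, gt)
    ep <- simulate_epochs(tab, gt, srate = 250)
    list(gt = gt, table = tab, epochs = ep,
         z = as.numeric(tab$stimulus == "face"))
  })
}

# discrimination series on the true labels of the 200-trial set
fixture_series <- function() {
  fixture("series200", function() {
    fx <- fixture_epochs()
    sliding_discrimination(fx$epochs, fx$z)
  })
}

# behavioural dataset at recovery scale (8 participants x 360 trials) with
# the generating participant parameters attached
fixture_behaviour <- function(data_seed = 11) {
  fixture(paste0("behaviour8x360-", data_seed), function() {
    gt <- ground_truth(seed = data_seed)
    tab <- generate_design(8, 1, 360, seed = data_seed)
    tab <- simulate_amplitudes(tab, gt)
    tab <- simulate_behaviour(tab, gt)
    list(gt = gt, table = tab)
  })
}

# scaled-down M3 fits of two replicate datasets; the first is shared by
# the convergence and starting-point-contrast checks, both feed the
# parameter-recovery coverage check
fixture_m3_fit <- function(data_seed = 11) {
  fixture(paste0("m3fit-", data_seed), function() {
    fx <- fixture_behaviour(data_seed)
    model <- build_model(model_spec("M3"), hierarchical_data(fx$table))
    samples <- sample_posterior(model, n_iter = 3000, burn = 500,
                                thin = 10, chains = 4, seed = 5)
    list(gt = fx$gt, table = fx$table, model = model, samples = samples)
  })
}

# quick small behavioural dataset for cheap hbayes unit tests
fixture_small_behaviour <- function() {
  fixture("behaviour2x120", function() {
    gt <- ground_truth(seed = 3)
    tab <- generate_design(2, 1, 120, seed = 3)
    tab <- simulate_amplitudes(tab, gt)
    tab <- simulate_behaviour(tab, gt)
    list(gt = gt, table = tab)
  })
}
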