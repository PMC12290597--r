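#' Train a windowed logistic discriminator
#'
#' Fits the spatial weight vector `w` that best discriminates two classes
#' of multichannel EEG samples by maximising the Bernoulli log-likelihood
#' of the logistic model `p = 1 / (1 + exp(-w'x))` with a ridge penalty
#' `lambda_eff * ||w||^2`.  Every sample within the window is treated as an
#' independent observation of its trial (rows of `X`).  No intercept is
#' fitted: the discriminator output `y = w'x` is a signed evidence
#' amplitude whose zero marks the class boundary, so complementing the
#' labels exactly flips the sign of `w`.
#'
#' @param X observations x channels matrix (stacked window samples).
#' @param z 0/1 labels per row of `X` (1 = face).
#' @param lambda ridge penalty per observation; the effective penalty is
#'   `lambda * nrow(X)` so that regularisation strength is comparable
#'   across window sample counts.
#' @param tol gradient-norm convergence tolerance.
#' @param maxit maximum Newton iterations.
#' @return list with `w` (channel weights), `converged`, `grad_norm`,
#'   `loglik` (unpenalised).
#' @export
train_logistic <- function(X, z, lambda = 1e-3, tol = 1e-6, maxit = 100) {
  X <- as.matrix(X)
  z <- as.numeric(z)
  if (length(z) != nrow(X)) stop("labels must match rows of X")
  if (any(!is.finite(X)) || any(!is.finite(z)))
    stop("non-finite values in X or z")
  if (length(unique(z)) < 2) stop("both classes must be present")
  if (!all(z %in% c(0, 1))) stop("labels must be 0/1")
  fit <- ridge_logistic_cpp(X, z, lambda * nrow(X), tol, maxit)
  fit$w <- as.numeric(fit$w)
  fit
}

#' Area under the ROC curve (Az)
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive-class amplitude exceeds a randomly chosen negative-class one,
#' with ties counted 1/2.  Az = 0.5 is chance, 1 is perfect separation.
#' Invariant to strictly increasing transforms of `y`.
#'
#' @param y numeric discriminator amplitudes.
#' @param z 0/1 class labels.
#' @return Az in \[0, 1\].
#' @export
auc <- function(y, z) {
  z <- as.numeric(z)
  if (length(unique(z)) < 2) stop("both classes must be present")
  n1 <- sum(z == 1)
  n0 <- sum(z == 0)
  r <- rank(y)
  (sum(r[z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sliding-window LOO discrimination series
#'
#' Slides a 50-ms window in 10-ms steps over the epoch (default centres
#' -0.100 ... 1.000 s), at each centre stacking every sample within
#' +/- half a window of the centre as independent observations, training
#' the ridge-logistic discriminator, and computing each trial's single-trial
#' amplitude by leave-one-out cross-validation: trial `i`'s amplitude is
#' the mean of `w'x` over its window samples under the model trained on the
#' other N-1 trials.  Az is computed on the LOO amplitudes.
#'
#' @param epochs an `epoch_set`.
#' @param z 0/1 labels per trial (1 = face).
#' @param window window length (s).
#' @param step centre spacing (s).
#' @param t_range first and last window centre (s).
#' @param lambda ridge penalty per observation (see [train_logistic()]).
#' @param loo compute leave-one-out amplitudes (set `FALSE` for
#'   training-only amplitudes, used by the permutation null for speed when
#'   requested).
#' @return an object of class `discrimination_series`: `centres`, `az`
#'   (per centre), `y` (centres x trials LOO amplitudes), `y_train`,
#'   `weights` and `forward` (centres x channels), `z`, `p` (permutation
#'   p-values, `NA` until [permutation_pvalue()] fills them), `lambda`.
#' @export
sliding_discrimination <- function(epochs, z, window = 0.050, step = 0.010,
                                   t_range = c(-0.100, 1.000),
                                   lambda = 1e-3, loo = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  z <- as.numeric(z)
  n <- dim(epochs)[1]
  if (length(z) != n) stop("labels must match trial count")
  centres <- seq(t_range[1], t_range[2], by = step)
  half <- window / 2
  tol_t <- 1e-9
  cover <- centres - half >= min(epochs$times) - tol_t &
    centres + half <= max(epochs$times) + tol_t
  if (any(!cover))
    stop(sprintf("epoch span does not cover the window centred at %.3f s",
                 centres[which(!cover)[1]]))
  K <- dim(epochs)[2]
  nc <- length(centres)
  az <- numeric(nc)
  Y <- matrix(NA_real_, nc, n)
  Yt <- matrix(NA_real_, nc, n)
  W <- matrix(NA_real_, nc, K)
  A <- matrix(NA_real_, nc, K)
  for (ci in seq_len(nc)) {
    idx <- which(epochs$times >= centres[ci] - half - tol_t &
                   epochs$times <= centres[ci] + half + tol_t)
    ns <- length(idx)
    # stacked window samples: dims (ns, n, K) flatten with sample fastest,
    # giving trial-major blocks of ns consecutive rows per trial
    X <- matrix(aperm(epochs$data[, , idx, drop = FALSE], c(3, 1, 2)),
                nrow = n * ns, ncol = K)
    trial_id <- rep(seq_len(n), each = ns)
    res <- loo_window_cpp(X, trial_id, z, lambda * nrow(X), 1e-6, 100)
    W[ci, ] <- as.numeric(res$w)
    Yt[ci, ] <- as.numeric(res$y_train)
    Y[ci, ] <- if (loo) as.numeric(res$y_loo) else Yt[ci, ]
    az[ci] <- auc(Y[ci, ], z)
    # forward model from per-trial mean window data and training amplitudes
    Xbar <- t(apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean))
    A[ci, ] <- forward_projection(Xbar, Yt[ci, ])
  }
  structure(list(centres = centres, az = az, y = Y, y_train = Yt,
                 weights = W, forward = A, z = z,
                 p = rep(NA_real_, nc), window = window, step = step,
                 lambda = lambda, channels = epochs$channels),
            class = "discrimination_series")
}

#' @export
print.discrimination_series <- function(x, ...) {
  cat(sprintf(
    "Sliding-window discrimination: %d centres [%.3f, %.3f] s, %d trials\n",
    length(x$centres), min(x$centres), max(x$centres), ncol(x$y)))
  i <- which.max(x$az)
  cat(sprintf("  peak LOO Az = %.3f at %.3f s; mean Az = %.3f\n",
              x$az[i], x$centres[i], mean(x$az)))
  invisible(x)
}

#' Permutation p-value for the discriminator at one window centre
#'
#' Recomputes the LOO Az `n_perm` times under random permutations of the
#' class labels and returns
#' `p = (1 + #\{permuted Az >= observed Az\}) / (n_perm + 1)`.
#'
#' @param epochs an `epoch_set`.
#' @param z 0/1 labels per trial.
#' @param centre window centre (s).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param window,lambda as in [sliding_discrimination()].
#' @return the permutation p-value.
#' @export
permutation_pvalue <- function(epochs, z, centre, n_perm = 1000, seed = 1L,
                               window = 0.050, lambda = 1e-3) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  one_az <- function(zz) {
    s <- sliding_discrimination(epochs, zz, window = window, step = window,
                                t_range = c(centre, centre),
                                lambda = lambda)
    s$az[1]
  }
  observed <- one_az(z)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (one_az(sample(z)) >= observed) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

#' Forward model (scalp projection) of a discriminating component
#'
#' `a = X y / (y'y)`: the per-channel coupling between the observed window
#' data and the component amplitude, interpretable as the component's scalp
#' topography.
#'
#' @param X channels x trials matrix of window data (per-trial means).
#' @param y length-trials component amplitudes (not all zero).
#' @return per-channel forward-model vector.
#' @export
forward_projection <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (ncol(X) != length(y)) stop("X must be channels x trials matching y")
  ss <- sum(y^2)
  if (ss == 0) stop("y has zero norm; forward model undefined")
  as.numeric(X %*% y / ss)
}

#' Extract Early and Late discriminating components
#'
#' Selects, within the Early (150-250 ms) and Late (300-500 ms) search
#' ranges, the window centre with maximal LOO Az (ties broken toward the
#' earlier centre) and returns the single-trial amplitudes at those peaks.
#'
#' @param series a `discrimination_series`.
#' @param early,late search ranges (s).
#' @return an object of class `component_set`: `early_time`, `late_time`,
#'   `early_az`, `late_az`, `y_early`, `y_late`, `forward_early`,
#'   `forward_late`.
#' @export
pick_components <- function(series, early = c(0.15, 0.25),
                            late = c(0.30, 0.50)) {
  stopifnot(inherits(series, "discrimination_series"))
  pick <- function(rng) {
    idx <- which(series$centres >= rng[1] - 1e-9 &
                   series$centres <= rng[2] + 1e-9)
    if (length(idx) == 0)
      stop(sprintf("series does not cover the window [%.2f, %.2f] s",
                   rng[1], rng[2]))
    idx[which.max(series$az[idx])]   # which.max takes the first (earliest)
  }
  ie <- pick(early)
  il <- pick(late)
  structure(list(early_time = series$centres[ie],
                 late_time = series$centres[il],
                 early_az = series$az[ie], late_az = series$az[il],
                 y_early = series$y[ie, ], y_late = series$y[il, ],
                 forward_early = series$forward[ie, ],
                 forward_late = series$forward[il, ]),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf(
    "Components: Early %.0f ms (Az %.3f), Late %.0f ms (Az %.3f), %d trials\n",
    1000 * x$early_time, x$early_az, 1000 * x$late_time, x$late_az,
    length(x$y_early)))
  invisible(x)
}

#' Scale amplitudes to unit standard deviation
#'
#' Divides by the sample SD without centring: the signed zero of a
#' discriminator amplitude is meaningful (it is the face/car boundary), so
#' only the scale is normalised.
#'
#' @param y numeric vector with positive SD.
#' @return `y / sd(y)`.
#' @export
standardize_amplitudes <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) stop("amplitudes have zero variance")
  y / s
}

#' Logistic regression of choice on component amplitudes
#'
#' Pooled logistic regression of face choice on the (standardised) Early
#' and Late amplitudes, with per-predictor coefficients, Wald 95% CIs,
#' odds ratios, and likelihood-ratio tests of each single-predictor model
#' against the full two-predictor model (testing what each component adds
#' over the other).  On a collinear design the fit falls back to a small
#' ridge penalty with a warning.
#'
#' @param y_early,y_late standardised amplitudes.
#' @param face_choice logical or 0/1 vector of face choices.
#' @return list with `coefficients` (data.frame: estimate, se, ci_lo,
#'   ci_hi, odds_ratio, or_ci_lo, or_ci_hi) and `lrt` (data.frame: term
#'   dropped, chisq, df, p).
#' @export
choice_regression <- function(y_early, y_late, face_choice) {
  ch <- as.numeric(face_choice)
  if (length(unique(ch)) < 2) stop("choices are degenerate (single class)")
  df <- data.frame(choice = ch, y_early = y_early, y_late = y_late)
  r <- abs(suppressWarnings(stats::cor(y_early, y_late)))
  if (is.finite(r) && r > 0.999) {
    warning("predictors are collinear; refitting with a small ridge penalty")
    X <- cbind(1, y_early, y_late)
    fit <- ridge_logistic_cpp(X, ch, 1e-3 * nrow(X), 1e-6, 200)
    co <- data.frame(term = c("(Intercept)", "y_early", "y_late"),
                     estimate = as.numeric(fit$w), se = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_,
                     odds_ratio = exp(as.numeric(fit$w)),
                     or_ci_lo = NA_real_, or_ci_hi = NA_real_)
    return(list(coefficients = co, lrt = NULL, ridge = TRUE))
  }
  full <- glm(choice ~ y_early + y_late, family = binomial(), data = df)
  est <- coef(full)
  se <- sqrt(diag(stats::vcov(full)))
  co <- data.frame(term = names(est), estimate = as.numeric(est), se = se,
                   ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                   odds_ratio = exp(est),
                   or_ci_lo = exp(est - 1.96 * se),
                   or_ci_hi = exp(est + 1.96 * se))
  rownames(co) <- NULL
  m_early <- glm(choice ~ y_early, family = binomial(), data = df)
  m_late <- glm(choice ~ y_late, family = binomial(), data = df)
  lrt <- rbind(
    cbind(dropped = "y_late",
          as.data.frame(likelihood_ratio_test(as.numeric(logLik(m_early)),
                                              as.numeric(logLik(full)), 1))),
    cbind(dropped = "y_early",
          as.data.frame(likelihood_ratio_test(as.numeric(logLik(m_late)),
                                              as.numeric(logLik(full)), 1))))
  list(coefficients = co, lrt = lrt, ridge = FALSE)
}

#' Log-likelihood-ratio test of nested models
#'
#' `chisq = -2 (L0 - L1)` compared to the upper tail of a chi-square with
#' `df` degrees of freedom, where `L0` is the log-likelihood of the
#' restricted model and `L1` that of the full model.
#'
#' @param L0,L1 log-likelihoods of the nested and full model (`L1 >= L0`).
#' @param df difference in number of parameters.
#' @return list with `chisq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(L0, L1, df) {
  if (L1 < L0 - 1e-8)
    stop("L1 < L0: models are not nested (or fits did not converge)")
  chisq <- max(0, -2 * (L0 - L1))
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

#' RT-matched trial subset
#'
#' Within each cue condition, removes the `floor(frac * n)` slowest car
#' trials and `floor(frac * n)` fastest face trials (n = per-category valid
#' trial count in that condition), equalising the face/car response-time
#' distributions.  At the default 8% this retains 92% of trials.  Invalid
#' (non-response) trials are dropped.
#'
#' @param table a `trial_table` with `rt` on valid trials.
#' @param frac fraction to trim per category, in \[0, 0.5).
#' @return the retained subset, same class as the input.
#' @export
rt_matched_subset <- function(table, frac = 0.08) {
  if (frac < 0 || frac >= 0.5) stop("frac must lie in [0, 0.5)")
  assert_columns(table, c("cue", "stimulus", "rt"), "trial table")
  valid <- if ("valid" %in% names(table)) table$valid %in% TRUE
           else !is.na(table$rt)
  tab <- table[valid, , drop = FALSE]
  drop <- logical(nrow(tab))
  for (cue in unique(tab$cue)) {
    car_i <- which(tab$cue == cue & tab$stimulus == "car")
    face_i <- which(tab$cue == cue & tab$stimulus == "face")
    n_car <- floor(frac * length(car_i))
    n_face <- floor(frac * length(face_i))
    if (n_car > 0)
      drop[car_i[order(tab$rt[car_i], decreasing = TRUE)[seq_len(n_car)]]] <- TRUE
    if (n_face > 0)
      drop[face_i[order(tab$rt[face_i])[seq_len(n_face)]]] <- TRUE
  }
  tab[!drop, , drop = FALSE]
}
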