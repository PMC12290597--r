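#' Single-trial drift-rate regression
#'
#' Assembles the trial-wise drift rate from the cue-specific regression
#' coefficients and the trial's Early/Late component amplitudes:
#' `delta_i = gamma0 + gamma_early * y_early + (gamma_late * y_late) * C`,
#' where `C` is the trial's phase coherence.  By default only the Late term
#' is multiplied by coherence (the Late component is the one whose
#' amplitude scales with stimulus coherence); both scalings are
#' configurable for the alternative formulation in which the Early term
#' scales too.
#'
#' @param gamma0,gamma_early,gamma_late regression coefficients (scalars or
#'   per-trial vectors).
#' @param y_early,y_late single-trial component amplitudes.
#' @param C phase coherence per trial.
#' @param scale_early,scale_late whether each term is multiplied by `C`.
#' @return per-trial drift rates.
#' @export
drift_link <- function(gamma0, gamma_early, gamma_late, y_early, y_late, C,
                       scale_early = FALSE, scale_late = TRUE) {
  e_term <- gamma_early * y_early
  l_term <- gamma_late * y_late
  gamma0 + (if (scale_early) e_term * C else e_term) +
    (if (scale_late) l_term * C else l_term)
}

#' Single-trial starting-point regression
#'
#' Inverse-logit link mapping the amplitude regression onto the relative
#' starting point, guaranteeing `beta_i` in (0, 1):
#' `beta_i = plogis(b0 + b_early * y_early + b_late * y_late)`.
#'
#' @param b0,b_early,b_late regression coefficients.
#' @param y_early,y_late single-trial component amplitudes.
#' @return per-trial starting points in (0, 1).
#' @export
start_link <- function(b0, b_early, b_late, y_early, y_late) {
  plogis(b0 + b_early * y_early + b_late * y_late)
}

#' Specification of a (neurally-informed) hierarchical DDM variant
#'
#' Six variants are supported: `"M1"` (both amplitudes regress onto the
#' starting point), `"M2"` (Early onto starting point, Late onto drift),
#' `"M3"` (both onto drift), `"M4"` (Early only onto drift), `"M5"` (Late
#' only onto drift) and `"B"` (behaviour-only, no neural regressors).  By
#' default the starting point, non-decision time and all regression
#' coefficients are cue-dependent while the boundary is shared across
#' cues, and only the Late drift term is scaled by coherence.
#'
#' @param variant one of `"M1" ... "M5"`, `"B"`.
#' @param cue_dependent named logical list with entries `alpha`, `beta`,
#'   `tau`, `coef` controlling which parameter families get one group-level
#'   (mu, sigma) pair per cue.
#' @param scale_early,scale_late coherence scaling of each drift term.
#' @param standardize whether amplitudes are scaled to unit SD before
#'   entering the model (they enter raw by default).
#' @param priors named list of uniform prior bounds, entries `alpha`,
#'   `beta`, `tau`, `coef` (group means) and `sigma` (group SDs).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(variant = c("M3", "M1", "M2", "M4", "M5", "B"),
                       cue_dependent = list(alpha = FALSE, beta = TRUE,
                                            tau = TRUE, coef = TRUE),
                       scale_early = FALSE, scale_late = TRUE,
                       standardize = FALSE,
                       priors = list(alpha = c(0.1, 5),
                                     beta = c(0.1, 0.9),
                                     tau = c(0.05, 1.0),
                                     coef = c(-10, 10),
                                     sigma = c(0.001, 3))) {
  variant <- match.arg(variant)
  cd <- utils::modifyList(list(alpha = FALSE, beta = TRUE, tau = TRUE,
                               coef = TRUE), cue_dependent)
  for (nm in c("alpha", "beta", "tau", "coef", "sigma")) {
    b <- priors[[nm]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop(sprintf("prior bounds for '%s' must be finite with lower < upper",
                   nm))
  }
  structure(list(variant = variant, cue_dependent = cd,
                 scale_early = scale_early, scale_late = scale_late,
                 standardize = standardize, priors = priors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  desc <- c(M1 = "y_E, y_L -> starting point",
            M2 = "y_E -> starting point, y_L -> drift",
            M3 = "y_E, y_L -> drift",
            M4 = "y_E -> drift", M5 = "y_L -> drift",
            B = "behaviour only")
  cat(sprintf("HDDM variant %s (%s)\n", x$variant, desc[x$variant]))
  invisible(x)
}

#' Per-trial data container for hierarchical fitting
#'
#' Extracts the valid trials of a `trial_table` into the flat per-trial
#' form used by the hierarchical model: participant, cue, coherence, both
#' amplitudes, binary face choice and response time.
#'
#' @param table a `trial_table` with behaviour and amplitudes present.
#' @return an object of class `hierarchical_data` (a data.frame).
#' @export
hierarchical_data <- function(table) {
  assert_columns(table, c("participant", "cue", "coherence", "y_early",
                          "y_late", "choice", "rt"), "trial table")
  keep <- if ("valid" %in% names(table)) table$valid %in% TRUE
          else !is.na(table$choice)
  d <- as.data.frame(table)[keep, c("participant", "cue", "coherence",
                                    "y_early", "y_late", "choice", "rt")]
  if (nrow(d) == 0) stop("no valid trials")
  if (any(d$rt <= 0) || any(!is.finite(d$rt)))
    stop("response times must be positive and finite on valid trials")
  if (!all(d$choice %in% c("face", "car")))
    stop("choices must be 'face' or 'car' on valid trials")
  if (any(!is.finite(d$y_early)) || any(!is.finite(d$y_late)))
    stop("amplitudes must be finite")
  d$face <- as.integer(d$choice == "face")
  rownames(d) <- NULL
  class(d) <- c("hierarchical_data", "data.frame")
  d
}

# parameter-family table for a given spec: one row per family, each with a
# group-level (mu, sigma) pair and one participant-level value per subject
build_families <- function(spec, cues) {
  pri <- spec$priors
  sup <- list(alpha = c(0.05, 8), beta = c(0.02, 0.98),
              tau = c(0.005, 1.2), coef = c(-15, 15))
  fam <- function(base, kind, by_cue) {
    cue <- if (by_cue) cues else NA_character_
    # group SDs larger than half the participant support width are
    # scientifically meaningless (the truncated normal degenerates to a
    # uniform), so each family's SD prior is capped accordingly
    data.frame(name = if (by_cue) sprintf("%s[%s]", base, cue) else base,
               base = base, cue = cue,
               mu_lo = pri[[kind]][1], mu_hi = pri[[kind]][2],
               sup_lo = sup[[kind]][1], sup_hi = sup[[kind]][2],
               sigma_lo = pri$sigma[1],
               sigma_hi = min(pri$sigma[2],
                              (sup[[kind]][2] - sup[[kind]][1]) / 2),
               stringsAsFactors = FALSE)
  }
  cd <- spec$cue_dependent
  fams <- list(fam("alpha", "alpha", cd$alpha), fam("tau", "tau", cd$tau))
  v <- spec$variant
  if (v %in% c("B", "M3", "M4", "M5"))
    fams <- c(fams, list(fam("beta", "beta", cd$beta)))
  if (v == "M1")
    fams <- c(fams, list(fam("b0", "coef", cd$coef),
                         fam("b_early", "coef", cd$coef),
                         fam("b_late", "coef", cd$coef)))
  if (v == "M2")
    fams <- c(fams, list(fam("b0", "coef", cd$coef),
                         fam("b_early", "coef", cd$coef)))
  if (v %in% c("B", "M1"))
    fams <- c(fams, list(fam("delta", "coef", cd$coef)))
  if (v == "M3")
    fams <- c(fams, list(fam("gamma0", "coef", cd$coef),
                         fam("gamma_early", "coef", cd$coef),
                         fam("gamma_late", "coef", cd$coef)))
  if (v %in% c("M2", "M5"))
    fams <- c(fams, list(fam("gamma0", "coef", cd$coef),
                         fam("gamma_late", "coef", cd$coef)))
  if (v == "M4")
    fams <- c(fams, list(fam("gamma0", "coef", cd$coef),
                         fam("gamma_early", "coef", cd$coef)))
  out <- do.call(rbind, fams)
  rownames(out) <- NULL
  out
}

#' Build a hierarchical drift-diffusion model graph
#'
#' Constructs the hierarchical structure: uniform hyperpriors on every
#' group-level mean and SD (one pair per parameter family, and per cue
#' where flagged); participant-level parameters drawn from
#' `Normal(mu, sigma^2)` truncated to their support; trial-level drift
#' and/or starting point assembled by [drift_link()] / [start_link()]
#' according to the variant; and the Wiener first-passage likelihood of
#' the observed choices and response times.
#'
#' @param spec a [model_spec()].
#' @param data a [hierarchical_data()] (or a `trial_table`, converted).
#' @return an object of class `ddm_model` with the parameter registry, the
#'   per-(participant, cue) likelihood function, and a `log_posterior`
#'   function over the full parameter vector.
#' @export
build_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(data, "trial_table")) data <- hierarchical_data(data)
  stopifnot(inherits(data, "hierarchical_data"))
  cues <- intersect(cue_levels(), unique(data$cue))
  participants <- sort(unique(data$participant))
  np <- length(participants)
  fam <- build_families(spec, cues)
  nf <- nrow(fam)
  yE <- data$y_early
  yL <- data$y_late
  if (spec$standardize) {
    yE <- yE / sd(yE)
    yL <- yL / sd(yL)
  }
  rows <- lapply(participants, function(j)
    lapply(setNames(cues, cues), function(cc)
      which(data$participant == j & data$cue == cc)))
  names(rows) <- as.character(participants)

  # family index lookup by base (+ cue)
  fidx <- function(base, cue) {
    i <- which(fam$base == base & (is.na(fam$cue) | fam$cue == cue))
    if (length(i) != 1) stop("registry lookup failed for ", base)
    i
  }
  fam_for_cue <- lapply(setNames(cues, cues), function(cc)
    vapply(fam$base, function(b) fidx(b, cc), 1L))

  # per-(participant, cue) data caches: the likelihood below is the MCMC
  # hot path, so data.frame subsetting is done once up front
  cache <- lapply(seq_along(participants), function(ji)
    lapply(setNames(cues, cues), function(cc) {
      r <- rows[[ji]][[cc]]
      list(rt = data$rt[r], face = data$face[r], yE = yE[r], yL = yL[r],
           C = data$coherence[r], n = length(r))
    }))

  v <- spec$variant
  fE <- spec$scale_early
  fL <- spec$scale_late
  # likelihood of participant ji's trials in cue cc given its parameter row
  ll_pc <- function(prow, ji, cc) {
    d <- cache[[ji]][[cc]]
    if (d$n == 0) return(0)
    f <- fam_for_cue[[cc]]
    alpha <- prow[[f[["alpha"]]]]
    tau <- prow[[f[["tau"]]]]
    if (v == "M1" || v == "M2") {
      # amplitudes regress onto the starting point through the logit link
      bE <- prow[[f[["b_early"]]]]
      bL <- if (v == "M1") prow[[f[["b_late"]]]] else 0
      beta <- plogis(prow[[f[["b0"]]]] + bE * d$yE + bL * d$yL)
      delta <- if (v == "M1") {
        rep.int(prow[[f[["delta"]]]], d$n)
      } else {
        lt <- prow[[f[["gamma_late"]]]] * d$yL
        prow[[f[["gamma0"]]]] + (if (fL) lt * d$C else lt)
      }
      if (any(beta <= 0) || any(beta >= 1)) return(-Inf)
      return(wiener_loglik_cpp(d$rt, d$face, delta, beta,
                               rep.int(tau, d$n), rep.int(alpha, d$n),
                               1e-7))
    }
    delta <- switch(v,
      B = rep.int(prow[[f[["delta"]]]], d$n),
      M3 = {
        e <- prow[[f[["gamma_early"]]]] * d$yE
        l <- prow[[f[["gamma_late"]]]] * d$yL
        prow[[f[["gamma0"]]]] + (if (fE) e * d$C else e) +
          (if (fL) l * d$C else l)
      },
      M4 = {
        e <- prow[[f[["gamma_early"]]]] * d$yE
        prow[[f[["gamma0"]]]] + (if (fE) e * d$C else e)
      },
      M5 = {
        l <- prow[[f[["gamma_late"]]]] * d$yL
        prow[[f[["gamma0"]]]] + (if (fL) l * d$C else l)
      })
    wiener_loglik_sv_cpp(d$rt, d$face, delta, prow[[f[["beta"]]]], tau,
                         alpha, 1e-7)
  }

  group_names <- c(paste0("mu_", fam$name), paste0("sigma_", fam$name))
  # participant index varies fastest, matching as.vector(P) for the
  # (participants x families) matrix P used by the sampler
  part_names <- as.vector(outer(participants, fam$name,
                                function(p, f) sprintf("%s:%s", f, p)))

  log_trunc_norm <- function(x, mu, sigma, lo, hi) {
    if (x < lo || x > hi) return(-Inf)
    Z <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
    if (Z <= 0) return(-Inf)
    dnorm(x, mu, sigma, log = TRUE) - log(Z)
  }

  # full log posterior over (G, P); G = c(mu_f, sigma_f), P = np x nf
  log_posterior <- function(G, P) {
    mu <- G[seq_len(nf)]
    sg <- G[nf + seq_len(nf)]
    if (any(mu < fam$mu_lo) || any(mu > fam$mu_hi) ||
        any(sg < fam$sigma_lo) || any(sg > fam$sigma_hi)) return(-Inf)
    lp <- 0
    for (f in seq_len(nf)) for (j in seq_len(np)) {
      lp <- lp + log_trunc_norm(P[j, f], mu[f], sg[f],
                                fam$sup_lo[f], fam$sup_hi[f])
      if (!is.finite(lp)) return(-Inf)
    }
    for (j in seq_len(np)) for (cc in cues)
      lp <- lp + ll_pc(P[j, ], j, cc)
    lp
  }

  structure(list(spec = spec, data = data, fam = fam, cues = cues,
                 participants = participants, n_fam = nf,
                 n_participants = np, rows = rows,
                 fam_for_cue = fam_for_cue, ll_pc = ll_pc,
                 group_names = group_names, part_names = part_names,
                 log_trunc_norm = log_trunc_norm,
                 log_posterior = log_posterior),
            class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat(sprintf(
    "Hierarchical DDM (variant %s): %d participants, %d trials, %d families (%d group-level parameters)\n",
    x$spec$variant, x$n_participants, nrow(x$data), x$n_fam, 2 * x$n_fam))
  invisible(x)
}

# total data log-likelihood given a participant-parameter matrix
model_total_ll <- function(model, P) {
  tot <- 0
  for (j in seq_len(model$n_participants)) for (cc in model$cues) {
    tot <- tot + model$ll_pc(P[j, ], j, cc)
    if (!is.finite(tot)) return(-Inf)
  }
  tot
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs
#'
#' Single-site random-walk Metropolis updates over every group-level mean
#' and SD and every participant-level parameter, with proposal scales
#' adapted toward 44% acceptance in batches during burn-in only (the
#' kernel is fixed afterwards, so the retained chain targets the exact
#' posterior).  Retained draws are taken every `thin` iterations after
#' burn-in: `(n_iter - burn) / thin` per chain.  Chain seeds are derived
#' from the master seed.
#'
#' @param model a `ddm_model` from [build_model()].
#' @param n_iter total iterations per chain.
#' @param burn burn-in iterations discarded.
#' @param thin thinning factor.
#' @param chains number of chains (>= 2).
#' @param seed master integer seed.
#' @param init_retries initialisation redraws allowed before giving up.
#' @return an object of class `posterior_samples`: `draws` (chains x
#'   retained x parameters), `loglik` (chains x retained data
#'   log-likelihoods), `param_names`, `group_names`, `settings`,
#'   `acceptance`.
#' @export
sample_posterior <- function(model, n_iter = 11000, burn = 1000, thin = 50,
                             chains = 4, seed = 1L, init_retries = 50) {
  stopifnot(inherits(model, "ddm_model"), chains >= 2, n_iter > burn,
            thin >= 1)
  n_keep <- floor((n_iter - burn) / thin)
  fam <- model$fam
  nf <- model$n_fam
  np <- model$n_participants
  cues <- model$cues
  param_names <- c(model$group_names, model$part_names)
  draws <- array(NA_real_, dim = c(chains, n_keep, length(param_names)),
                 dimnames = list(NULL, NULL, param_names))
  ll_keep <- matrix(NA_real_, chains, n_keep)
  acc_all <- NULL

  ltn <- model$log_trunc_norm

  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, paste0("chain-", ch)))
    st <- init_chain(model, init_retries)
    mu <- st$mu; sg <- st$sg; P <- st$P; LL <- st$LL

    # block registry: group mu (nf), group sigma (nf), participant (np*nf),
    # then per-family translation and scaling reparameterisation moves
    nb <- 2 * nf + np * nf + 2 * nf
    ls <- rep(log(0.1), nb)
    acc <- int_n <- rep(0L, nb)
    batch <- 0L

    kept <- 0L
    for (it in seq_len(n_iter)) {
      b <- 0L
      # group-level updates: participant-prior terms only
      for (f in seq_len(nf)) {
        # truncation bounds are shared within a family, so the normalising
        # constant is common across participants
        prior_sum <- function(m, s) {
          Z <- pnorm(fam$sup_hi[f], m, s) - pnorm(fam$sup_lo[f], m, s)
          if (Z <= 0) return(-Inf)
          sum(dnorm(P[, f], m, s, log = TRUE)) - np * log(Z)
        }
        b <- b + 1L
        prop <- mu[f] + exp(ls[b]) * rnorm(1)
        int_n[b] <- int_n[b] + 1L
        if (prop >= fam$mu_lo[f] && prop <= fam$mu_hi[f]) {
          lr <- prior_sum(prop, sg[f]) - prior_sum(mu[f], sg[f])
          if (is.finite(lr) && log(runif(1)) < lr) {
            mu[f] <- prop; acc[b] <- acc[b] + 1L
          }
        }
        b <- b + 1L
        # group SDs can be poorly identified with few participants and
        # range over orders of magnitude: propose multiplicatively
        # (log-scale random walk, with the Jacobian in the ratio)
        prop <- sg[f] * exp(exp(ls[b]) * rnorm(1))
        int_n[b] <- int_n[b] + 1L
        if (prop >= fam$sigma_lo[f] && prop <= fam$sigma_hi[f]) {
          lr <- prior_sum(mu[f], prop) - prior_sum(mu[f], sg[f]) +
            log(prop) - log(sg[f])
          if (is.finite(lr) && log(runif(1)) < lr) {
            sg[f] <- prop; acc[b] <- acc[b] + 1L
          }
        }
      }
      # participant-level updates: prior + affected-likelihood terms
      for (j in seq_len(np)) {
        for (f in seq_len(nf)) {
          b <- b + 1L
          int_n[b] <- int_n[b] + 1L
          prop <- P[j, f] + exp(ls[b]) * rnorm(1)
          if (prop < fam$sup_lo[f] || prop > fam$sup_hi[f]) next
          aff <- if (is.na(fam$cue[f])) cues else fam$cue[f]
          prow <- P[j, ]
          prow[f] <- prop
          ll_new <- vapply(aff, function(cc) model$ll_pc(prow, j, cc), 0)
          ll_old <- LL[j, aff]
          lr <- sum(ll_new) - sum(ll_old) +
            ltn(prop, mu[f], sg[f], fam$sup_lo[f], fam$sup_hi[f]) -
            ltn(P[j, f], mu[f], sg[f], fam$sup_lo[f], fam$sup_hi[f])
          if (is.finite(lr) && log(runif(1)) < lr) {
            P[j, f] <- prop
            LL[j, aff] <- ll_new
            acc[b] <- acc[b] + 1L
          }
        }
      }
      # hierarchical reparameterisation moves: jointly shift (or rescale)
      # a family's group location (or spread) together with its
      # participant-level values.  These decorrelate the group level from
      # the participant level, which single-site updates explore slowly.
      for (f in seq_len(nf)) {
        aff <- if (is.na(fam$cue[f])) cues else fam$cue[f]
        {
          b <- 2 * nf + np * nf + f
          int_n[b] <- int_n[b] + 1L
          shift <- exp(ls[b]) * rnorm(1)
          mu_new <- mu[f] + shift
          col_new <- P[, f] + shift
          if (mu_new >= fam$mu_lo[f] && mu_new <= fam$mu_hi[f] &&
              all(col_new >= fam$sup_lo[f] & col_new <= fam$sup_hi[f])) {
            Z_old <- pnorm(fam$sup_hi[f], mu[f], sg[f]) -
              pnorm(fam$sup_lo[f], mu[f], sg[f])
            Z_new <- pnorm(fam$sup_hi[f], mu_new, sg[f]) -
              pnorm(fam$sup_lo[f], mu_new, sg[f])
            if (Z_new > 0) {
              ll_new <- matrix(NA_real_, np, length(aff),
                               dimnames = list(NULL, aff))
              for (j in seq_len(np)) {
                prow <- P[j, ]
                prow[f] <- col_new[j]
                for (cc in aff) ll_new[j, cc] <- model$ll_pc(prow, j, cc)
              }
              lr <- sum(ll_new) - sum(LL[, aff]) -
                np * (log(Z_new) - log(Z_old))
              if (is.finite(lr) && log(runif(1)) < lr) {
                mu[f] <- mu_new
                P[, f] <- col_new
                LL[, aff] <- ll_new
                acc[b] <- acc[b] + 1L
              }
            }
          }
        }
        {
          b <- 2 * nf + np * nf + nf + f
          int_n[b] <- int_n[b] + 1L
          cs <- exp(exp(ls[b]) * rnorm(1))
          sg_new <- sg[f] * cs
          col_new <- mu[f] + cs * (P[, f] - mu[f])
          if (sg_new >= fam$sigma_lo[f] && sg_new <= fam$sigma_hi[f] &&
              all(col_new >= fam$sup_lo[f] & col_new <= fam$sup_hi[f])) {
            Z_old <- pnorm(fam$sup_hi[f], mu[f], sg[f]) -
              pnorm(fam$sup_lo[f], mu[f], sg[f])
            Z_new <- pnorm(fam$sup_hi[f], mu[f], sg_new) -
              pnorm(fam$sup_lo[f], mu[f], sg_new)
            if (Z_new > 0) {
              ll_new <- matrix(NA_real_, np, length(aff),
                               dimnames = list(NULL, aff))
              for (j in seq_len(np)) {
                prow <- P[j, ]
                prow[f] <- col_new[j]
                for (cc in aff) ll_new[j, cc] <- model$ll_pc(prow, j, cc)
              }
              # prior ratio c^-np (Z/Z')^np times Jacobian c^(np+1)
              lr <- sum(ll_new) - sum(LL[, aff]) + log(cs) -
                np * (log(Z_new) - log(Z_old))
              if (is.finite(lr) && log(runif(1)) < lr) {
                sg[f] <- sg_new
                P[, f] <- col_new
                LL[, aff] <- ll_new
                acc[b] <- acc[b] + 1L
              }
            }
          }
        }
      }
      # batch adaptation during burn-in only
      if (it <= burn && it %% 25 == 0) {
        batch <- batch + 1L
        d <- min(0.05, 1 / sqrt(batch))
        rate <- ifelse(int_n > 0, acc / int_n, 0.44)
        ls <- ls + ifelse(rate > 0.44, d, -d)
        acc[] <- 0L; int_n[] <- 0L
      }
      if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
        kept <- kept + 1L
        draws[ch, kept, ] <- c(mu, sg, as.vector(P))
        ll_keep[ch, kept] <- sum(LL)
      }
    }
    acc_all <- rbind(acc_all, ifelse(int_n > 0, acc / int_n, NA))
  }

  structure(list(draws = draws, loglik = ll_keep,
                 param_names = param_names,
                 group_names = model$group_names,
                 settings = list(n_iter = n_iter, burn = burn, thin = thin,
                                 chains = chains, seed = seed),
                 acceptance = acc_all),
            class = "posterior_samples")
}

# draw initial values from the priors, redrawing until the posterior is
# finite (bounded retries); participant rows are redrawn individually
init_chain <- function(model, init_retries) {
  fam <- model$fam
  nf <- model$n_fam
  np <- model$n_participants
  cues <- model$cues
  for (attempt in seq_len(init_retries)) {
    mu <- runif(nf, fam$mu_lo, fam$mu_hi)
    sg <- runif(nf, fam$sigma_lo, pmin(fam$sigma_hi,
                                       (fam$mu_hi - fam$mu_lo) / 2))
    P <- matrix(NA_real_, np, nf)
    LL <- matrix(NA_real_, np, length(cues),
                 dimnames = list(NULL, cues))
    ok <- TRUE
    for (j in seq_len(np)) {
      good <- FALSE
      for (r in seq_len(init_retries)) {
        prow <- pmin(fam$sup_hi, pmax(fam$sup_lo, rnorm(nf, mu, sg)))
        lls <- vapply(cues, function(cc) model$ll_pc(prow, j, cc), 0)
        if (all(is.finite(lls))) {
          P[j, ] <- prow
          LL[j, ] <- lls
          good <- TRUE
          break
        }
      }
      if (!good) { ok <- FALSE; break }
    }
    if (ok) return(list(mu = mu, sg = sg, P = P, LL = LL))
  }
  stop("chain initialisation failed: no finite posterior found after ",
       init_retries, " redraws (check that response times exceed ",
       "plausible non-decision times)")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "Posterior samples: %d chains x %d retained draws x %d parameters\n",
    d[1], d[2], d[3]))
  cat(sprintf("  sampler: %d iterations, %d burn-in, thin %d, seed %d\n",
              x$settings$n_iter, x$settings$burn, x$settings$thin,
              x$settings$seed))
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `posterior_samples`.
#' @param pars parameter names (default: group-level parameters).
#' @param prob credible-interval mass.
#' @param ... unused.
#' @return data.frame with posterior mean, SD and central credible interval.
#' @export
summary.posterior_samples <- function(object, pars = object$group_names,
                                      prob = 0.95, ...) {
  a <- (1 - prob) / 2
  out <- do.call(rbind, lapply(pars, function(p) {
    v <- as.vector(object$draws[, , p])
    data.frame(parameter = p, mean = mean(v), sd = sd(v),
               ci_lo = quantile(v, a, names = FALSE),
               ci_hi = quantile(v, 1 - a, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor: each chain is split in
#' half and the ratio of pooled to within-sequence variance is computed per
#' parameter.  Values near 1 indicate convergence; the package's working
#' criterion is a maximum below 1.03 over group-level parameters.
#'
#' @param samples a `posterior_samples`.
#' @param pars parameter names (default: group-level).
#' @return named vector of R-hat values (`NA` with a warning for
#'   zero-variance parameters).
#' @export
gelman_rubin <- function(samples, pars = samples$group_names) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- dim(samples$draws)
  if (d[1] < 2) stop("need at least 2 chains")
  if (d[2] < 10) stop("need at least 10 retained draws per chain")
  half <- floor(d[2] / 2)
  rhat <- vapply(pars, function(p) {
    segs <- list()
    for (ch in seq_len(d[1])) {
      v <- samples$draws[ch, , p]
      segs <- c(segs, list(v[seq_len(half)], v[(half + 1):(2 * half)]))
    }
    m <- length(segs)
    L <- half
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, var, 0)
    W <- mean(vars)
    B <- L * var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((L - 1) / L * W + B / L) / W)
  }, 0)
  if (any(is.na(rhat)))
    warning("zero within-chain variance for: ",
            paste(pars[is.na(rhat)], collapse = ", "))
  rhat
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `D(theta) = -2 log L(theta)`, `Dbar` the
#' posterior-mean deviance over the retained draws, and
#' `pD = Dbar - D(theta_bar)` evaluated at the posterior mean of all
#' parameters (the classic plug-in form).  Lower is better.
#'
#' @param samples a `posterior_samples` carrying per-draw log-likelihoods.
#' @param model the `ddm_model` the samples came from.
#' @return list with `dic`, `pd`, `dbar`.
#' @export
dic <- function(samples, model) {
  stopifnot(inherits(samples, "posterior_samples"),
            inherits(model, "ddm_model"))
  ll <- as.vector(samples$loglik)
  if (any(!is.finite(ll)))
    stop("non-finite deviance at retained draw(s) ",
         paste(head(which(!is.finite(ll)), 5), collapse = ", "))
  dbar <- mean(-2 * ll)
  theta_bar <- apply(samples$draws, 3, mean)
  # part_names have the participant index varying fastest
  P <- matrix(theta_bar[model$part_names], nrow = model$n_participants)
  ll_hat <- model_total_ll(model, P)
  if (!is.finite(ll_hat))
    stop("non-finite deviance at the posterior mean")
  d_hat <- -2 * ll_hat
  list(dic = dbar + (dbar - d_hat), pd = dbar - d_hat, dbar = dbar)
}

#' Posterior probability of a contrast
#'
#' Evaluates `Prob(lhs > rhs)` (or `<`) over the pooled retained draws,
#' where each side is a group-level parameter name or a numeric constant,
#' e.g. `"mu_gamma_late[70F] > mu_gamma_late[30F]"` or
#' `"mu_gamma_early[50F] > 0"`.  Draws are paired (same chain and index),
#' and the inequality is strict, so a parameter contrasted with itself has
#' probability 0.
#'
#' @param samples a `posterior_samples`.
#' @param contrast a string `"A > B"` or `"A < B"`.
#' @return the posterior probability of the inequality.
#' @export
posterior_prob <- function(samples, contrast) {
  stopifnot(inherits(samples, "posterior_samples"))
  op <- if (grepl(">", contrast, fixed = TRUE)) ">"
        else if (grepl("<", contrast, fixed = TRUE)) "<"
        else stop("contrast must contain '>' or '<'")
  sides <- trimws(strsplit(contrast, op, fixed = TRUE)[[1]])
  if (length(sides) != 2) stop("contrast must have exactly two sides")
  side_draws <- function(s) {
    if (grepl("^[-+0-9.eE]+$", s)) return(as.numeric(s))
    if (!s %in% samples$param_names) stop("unknown parameter: ", s)
    as.vector(samples$draws[, , s])
  }
  a <- side_draws(sides[1])
  b <- side_draws(sides[2])
  if (op == ">") mean(a > b) else mean(a < b)
}

#' Fit and rank a set of model variants by DIC
#'
#' Fits each specification to the same data with identical sampler
#' settings and seed policy, and returns the DIC table sorted ascending
#' (the winner is the minimum-DIC model), flagging convergence violations
#' (max group-level R-hat above the threshold) per model.  A failed fit
#' yields a row of `NA`s with the error message.
#'
#' @param specs list of [model_spec()] objects (>= 2).
#' @param data a [hierarchical_data()] or `trial_table`.
#' @param n_iter,burn,thin,chains,seed sampler settings (shared).
#' @param rhat_threshold convergence flag threshold.
#' @return list with `table` (data.frame: variant, dic, pd, dbar,
#'   max_rhat, converged, error), `winner` (variant id), `fits` (named
#'   list of `posterior_samples`).
#' @export
compare_models <- function(specs, data, n_iter = 11000, burn = 1000,
                           thin = 50, chains = 4, seed = 1L,
                           rhat_threshold = 1.1) {
  stopifnot(length(specs) >= 2)
  if (inherits(data, "trial_table")) data <- hierarchical_data(data)
  rows <- list()
  fits <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    vid <- sprintf("%s#%d", sp$variant, i)
    res <- tryCatch({
      model <- build_model(sp, data)
      samp <- sample_posterior(model, n_iter = n_iter, burn = burn,
                               thin = thin, chains = chains, seed = seed)
      ic <- dic(samp, model)
      rh <- suppressWarnings(gelman_rubin(samp))
      fits[[vid]] <- samp
      data.frame(variant = sp$variant, dic = ic$dic, pd = ic$pd,
                 dbar = ic$dbar, max_rhat = max(rh, na.rm = TRUE),
                 converged = max(rh, na.rm = TRUE) <= rhat_threshold,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(variant = sp$variant, dic = NA_real_, pd = NA_real_,
                 dbar = NA_real_, max_rhat = NA_real_, converged = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    rows[[vid]] <- res
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dic), ]
  winner <- tab$variant[which.min(tab$dic)]
  list(table = tab, winner = winner, fits = fits)
}
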