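#' Run configuration for a full simulate-decode-fit pipeline
#'
#' Builds (and validates) the configuration driving [run_pipeline()].  Can
#' be constructed from a YAML file with [read_run_config()].  Every
#' stochastic stage derives its own seed from the master seed and the
#' stage name, so a run is reproducible end to end from one integer.
#'
#' @param out_dir output directory for the run's artefacts.
#' @param seed master seed.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "preprocess", "decode", "fit", "compare")` (stages run
#'   in this order; later stages require the artefacts of earlier ones,
#'   either from this run or from `epochs_file`/`table_file`).
#' @param design list: `n_participants`, `n_sessions`,
#'   `n_trials_per_session`, `srate`, `with_epochs` (logical; epoch
#'   simulation is optional since behaviour-only fits need no EEG).
#' @param gt_args list of arguments passed to [ground_truth()].
#' @param decode list: `window`, `step`, `t_range`, `lambda`, `n_perm`
#'   (0 disables permutation testing).
#' @param fit list: `variant`, `n_iter`, `burn`, `thin`, `chains`.
#' @param compare character vector of variant ids for DIC comparison.
#' @param table_file,epochs_file optional paths to pre-existing inputs for
#'   runs that skip the simulate stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "decode", "fit"),
                       design = list(), gt_args = list(),
                       decode = list(), fit = list(),
                       compare = c("M3", "M1"),
                       table_file = NULL, epochs_file = NULL) {
  known <- c("simulate", "preprocess", "decode", "fit", "compare")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  design <- utils::modifyList(
    list(n_participants = 8, n_sessions = 1, n_trials_per_session = 360,
         srate = 250, with_epochs = FALSE), design)
  decode <- utils::modifyList(
    list(window = 0.050, step = 0.010, t_range = c(-0.100, 1.000),
         lambda = 1e-3, n_perm = 0), decode)
  fit <- utils::modifyList(
    list(variant = "M3", n_iter = 3000, burn = 500, thin = 10, chains = 4),
    fit)
  if (!("simulate" %in% stages)) {
    if (any(c("fit", "compare") %in% stages) && is.null(table_file))
      stop("config error: fitting without the simulate stage requires ",
           "table_file")
    if (any(c("preprocess", "decode") %in% stages) && is.null(epochs_file))
      stop("config error: decoding without the simulate stage requires ",
           "epochs_file")
    for (p in c(table_file, epochs_file))
      if (!is.null(p) && !file.exists(p))
        stop("config error: referenced input does not exist: ", p)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, design = design, gt_args = gt_args,
                 decode = decode, fit = fit, compare = compare,
                 table_file = table_file, epochs_file = epochs_file),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config` arguments.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Execute a pipeline run
#'
#' Runs the enabled stages in order (simulate -> preprocess -> decode ->
#' fit -> compare), writing each stage's artefacts under the run directory
#' (`tables/*.csv`, `epochs/*.rds`, `posterior/*.rds`, `ground_truth.json`,
#' `report.json`) and collecting provenance, decoding summaries, DIC
#' tables and posterior contrasts into a run report.  A failure in any
#' stage halts the run with an error naming the stage.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report` (also serialised to
#'   `report.json` in the run directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("tables", "epochs", "posterior"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  stamp <- function(stage, t0, ...) {
    report$stages[[stage]] <<- c(list(
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
      seed = derive_seed(config$seed, stage)), list(...))
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  gt <- do.call(ground_truth, utils::modifyList(
    list(seed = derive_seed(config$seed, "ground-truth")), config$gt_args))
  table <- NULL
  epochs <- NULL
  fit_samples <- NULL
  fit_model <- NULL

  if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    in_stage("simulate", {
      de <- config$design
      table <- generate_design(de$n_participants, de$n_sessions,
                               de$n_trials_per_session,
                               seed = derive_seed(config$seed, "design"))
      table <- simulate_amplitudes(table, gt,
                                   seed = derive_seed(config$seed, "amps"))
      table <- simulate_behaviour(table, gt,
                                  seed = derive_seed(config$seed, "behav"))
      write_trial_table(table, file.path(config$out_dir, "tables",
                                         "trials.csv"))
      write_ground_truth(gt, file.path(config$out_dir, "ground_truth.json"))
      if (isTRUE(de$with_epochs)) {
        epochs <- simulate_epochs(table, gt, srate = de$srate,
                                  seed = derive_seed(config$seed, "epochs"))
        saveRDS(epochs, file.path(config$out_dir, "epochs", "epochs.rds"))
      }
      pp <- attr(table, "participant_params")
      saveRDS(pp, file.path(config$out_dir, "tables",
                            "participant_params.rds"))
    })
    stamp("simulate", t0, n_trials = nrow(table),
          valid_fraction = mean(table$valid))
  } else if (!is.null(config$table_file)) {
    table <- read_trial_table(config$table_file)
  }

  if ("preprocess" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    in_stage("preprocess", {
      if (is.null(epochs)) {
        if (is.null(config$epochs_file))
          stop("no epochs available (enable with_epochs or give epochs_file)")
        epochs <- readRDS(config$epochs_file)
      }
      epochs <- average_reference(epochs)
      saveRDS(epochs, file.path(config$out_dir, "epochs",
                                "epochs_preprocessed.rds"))
    })
    stamp("preprocess", t0)
  }

  decode_summary <- NULL
  if ("decode" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    in_stage("decode", {
      if (is.null(epochs)) {
        if (is.null(config$epochs_file))
          stop("no epochs available for decoding")
        epochs <- readRDS(config$epochs_file)
      }
      dc <- config$decode
      # decode per participant, as classifiers are participant-specific
      per_p <- split(seq_len(nrow(table)), table$participant)
      comp_rows <- list()
      for (p in names(per_p)) {
        idx <- per_p[[p]]
        sub <- epoch_set(epochs$data[idx, , , drop = FALSE], epochs$srate,
                         epochs$times, epochs$channels)
        z <- as.numeric(table$stimulus[idx] == "face")
        ser <- sliding_discrimination(sub, z, window = dc$window,
                                      step = dc$step, t_range = dc$t_range,
                                      lambda = dc$lambda)
        comp <- pick_components(ser)
        table$y_early[idx] <- comp$y_early
        table$y_late[idx] <- comp$y_late
        comp_rows[[p]] <- data.frame(
          participant = as.integer(p), early_time = comp$early_time,
          late_time = comp$late_time, early_az = comp$early_az,
          late_az = comp$late_az)
        ser_df <- data.frame(centre = ser$centres, az = ser$az)
        write.csv(ser_df, file.path(config$out_dir, "tables",
                                    sprintf("az_participant%s.csv", p)),
                  row.names = FALSE)
      }
      decode_summary <- do.call(rbind, comp_rows)
      write.csv(decode_summary,
                file.path(config$out_dir, "tables", "components.csv"),
                row.names = FALSE)
      write_trial_table(table, file.path(config$out_dir, "tables",
                                         "trials_decoded.csv"))
    })
    stamp("decode", t0, mean_early_az = mean(decode_summary$early_az),
          mean_late_az = mean(decode_summary$late_az))
    report$az_summary <- decode_summary
  }

  if ("fit" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    in_stage("fit", {
      ft <- config$fit
      spec <- model_spec(ft$variant)
      fit_model <- build_model(spec, hierarchical_data(table))
      fit_samples <- sample_posterior(
        fit_model, n_iter = ft$n_iter, burn = ft$burn, thin = ft$thin,
        chains = ft$chains, seed = derive_seed(config$seed, "fit"))
      saveRDS(fit_samples, file.path(config$out_dir, "posterior",
                                     sprintf("fit_%s.rds", ft$variant)))
    })
    ic <- dic(fit_samples, fit_model)
    rh <- suppressWarnings(gelman_rubin(fit_samples))
    stamp("fit", t0, variant = config$fit$variant, dic = ic$dic,
          max_rhat = max(rh, na.rm = TRUE))
    report$fit_summary <- summary(fit_samples)
    report$max_rhat <- max(rh, na.rm = TRUE)
    report$dic <- ic
  }

  if ("compare" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    cmp <- NULL
    in_stage("compare", {
      specs <- lapply(config$compare, model_spec)
      ft <- config$fit
      cmp <- compare_models(specs, hierarchical_data(table),
                            n_iter = ft$n_iter, burn = ft$burn,
                            thin = ft$thin, chains = ft$chains,
                            seed = derive_seed(config$seed, "compare"))
      report$dic_table <- cmp$table
      report$winner <- cmp$winner
    })
    stamp("compare", t0, winner = report$winner)
  }

  report$gt_seed <- gt$seed
  class(report) <- "run_report"
  writeable <- report
  writeable$az_summary <- if (!is.null(report$az_summary))
    as.list(report$az_summary)
  jsonlite::write_json(
    lapply(unclass(writeable), function(x)
      if (is.data.frame(x)) as.list(x) else x),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed ", x$seed, ")\n", sep = "")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %6.1f s\n", s, x$stages[[s]]$wall_time_s))
  if (!is.null(x$dic))
    cat(sprintf("  DIC %.1f (pD %.1f), max R-hat %.3f\n",
                x$dic$dic, x$dic$pd, x$max_rhat))
  if (!is.null(x$winner)) cat("  DIC winner:", x$winner, "\n")
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares the generating group-level parameters of a synthetic run
#' against the fitted posterior: per group-level parameter the truth,
#' posterior mean, central 95% credible interval and an inside-interval
#' flag, plus the aggregate coverage fraction.  The fit must descend from
#' the same seed lineage as the ground truth (checked against the trial
#' table's recorded seed).
#'
#' @param gt the generating [ground_truth()].
#' @param samples the fitted `posterior_samples`.
#' @param table the trial table the fit used (carries the seed lineage).
#' @param prob credible-interval mass.
#' @return list with `table` (data.frame: parameter, truth, estimate,
#'   ci_lo, ci_hi, inside) and `coverage`.
#' @export
recovery_report <- function(gt, samples, table = NULL, prob = 0.95) {
  stopifnot(inherits(gt, "ground_truth"),
            inherits(samples, "posterior_samples"))
  if (!is.null(table)) {
    tseed <- attr(table, "seed")
    if (!is.null(tseed) && tseed != gt$seed)
      stop("lineage mismatch: trial table seed ", tseed,
           " does not match ground truth seed ", gt$seed)
  }
  truth <- ground_truth_group_values(gt)
  pars <- intersect(samples$group_names, names(truth))
  if (length(pars) == 0)
    stop("no fitted group-level parameter matches the ground truth")
  sm <- summary(samples, pars = pars, prob = prob)
  sm$truth <- truth[sm$parameter]
  sm$inside <- sm$truth >= sm$ci_lo & sm$truth <= sm$ci_hi
  out <- sm[, c("parameter", "truth", "mean", "ci_lo", "ci_hi", "inside")]
  names(out)[3] <- "estimate"
  list(table = out, coverage = mean(out$inside))
}

# named vector of true group-level values on the fitted parameter scale
ground_truth_group_values <- function(gt) {
  cues <- cue_levels()
  v <- c(mu_alpha = gt$alpha_mean, sigma_alpha = gt$alpha_sd)
  for (cc in cues) {
    v[sprintf("mu_tau[%s]", cc)] <- gt$tau_mean
    v[sprintf("sigma_tau[%s]", cc)] <- gt$tau_sd
    v[sprintf("mu_beta[%s]", cc)] <- gt$beta_mean[cc]
    v[sprintf("sigma_beta[%s]", cc)] <- gt$beta_sd
    v[sprintf("mu_gamma0[%s]", cc)] <- gt$gamma0[cc]
    v[sprintf("sigma_gamma0[%s]", cc)] <- gt$gamma0_sd
    v[sprintf("mu_gamma_early[%s]", cc)] <- gt$gamma_early[cc]
    v[sprintf("sigma_gamma_early[%s]", cc)] <- gt$gamma_early_sd
    v[sprintf("mu_gamma_late[%s]", cc)] <- gt$gamma_late[cc]
    v[sprintf("sigma_gamma_late[%s]", cc)] <- gt$gamma_late_sd
  }
  v
}
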