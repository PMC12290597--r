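#' Derive a stage- or chain-specific seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; individual
#' stages (and MCMC chains) get independent, reproducible streams by hashing
#' the master seed together with a label.  The result is always a positive
#' integer below 2^31.
#'
#' @param master integer master seed.
#' @param label character label of the stage or stream.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003L
  as.integer((abs(master) %% 2^20) * 2039 + h * 7 + 1) %% 2147483646L + 1L
}

cue_levels <- function() c("30F", "50F", "70F")

face_prob_by_cue <- function() c(`30F` = 0.3, `50F` = 0.5, `70F` = 0.7)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
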