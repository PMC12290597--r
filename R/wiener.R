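#' Wiener diffusion parameter set
#'
#' Bundle the four parameters of the two-boundary Wiener diffusion used
#' throughout the package: boundary separation `alpha` (evidence units),
#' relative starting point `beta` (unitless, in (0, 1); 0.5 is unbiased),
#' non-decision time `tau` (seconds) and drift rate `delta`
#' (evidence per second).  The diffusion coefficient is fixed at 1, so all
#' parameter scales are relative to unit within-trial noise; this matches
#' the convention of the Wiener likelihood used in hierarchical
#' drift-diffusion fitting (note that some DDM software fixes it at 0.1,
#' which rescales `alpha` and `delta` by a factor of 10).
#'
#' @param alpha boundary separation, > 0.
#' @param beta relative starting point, in (0, 1).
#' @param tau non-decision time in seconds, >= 0.
#' @param delta drift rate.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(alpha, beta, tau, delta) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(tau),
            is.finite(delta))
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(alpha = alpha, beta = beta, tau = tau, delta = delta),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "Wiener diffusion parameters: alpha = %.3f, beta = %.3f, tau = %.3f s, delta = %.3f\n",
    x$alpha, x$beta, x$tau, x$delta))
  invisible(x)
}

#' First-passage-time density of the Wiener diffusion
#'
#' Defective density (per second) of absorption at the upper or lower
#' boundary at decision time `t` (i.e. response time minus non-decision
#' time).  Evaluated with the standard small-time/large-time series pair,
#' switching to whichever expansion needs fewer terms for the requested
#' absolute truncation error.  The lower-boundary density is obtained from
#' the upper case by the reflection `beta -> 1 - beta`, `delta -> -delta`.
#'
#' @param t vector of decision times (s); non-positive times get density 0.
#' @param boundary `"upper"` or `"lower"`; by package convention the upper
#'   boundary corresponds to a face choice.
#' @param params a [ddm_params()] object.
#' @param tol absolute truncation error bound of the series.
#' @return numeric vector of densities.
#' @export
fpt_density <- function(t, boundary = c("upper", "lower"), params,
                        tol = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  wiener_fpt_density_cpp(as.numeric(t), boundary == "upper",
                         params$alpha, params$beta, params$tau,
                         params$delta, tol)
}

#' Joint log-likelihood of choices and response times under the Wiener model
#'
#' Sums `log fpt_density(rt - tau, boundary(choice))` over trials, with the
#' upper boundary mapped to face choices.  Parameters may vary per trial
#' (each of `alpha`, `beta`, `tau`, `delta` is recycled to the number of
#' trials).  Any response time at or below its trial's non-decision time
#' makes the data impossible and the function returns `-Inf`.
#'
#' @param rt numeric vector of response times (s).
#' @param face logical vector; `TRUE` when the face (upper) boundary was hit.
#' @param delta,beta,tau,alpha per-trial parameters (recycled).
#' @param tol series truncation error bound.
#' @return a single log-likelihood value (possibly `-Inf`).
#' @export
wiener_loglik <- function(rt, face, delta, beta, tau, alpha, tol = 1e-7) {
  n <- length(rt)
  stopifnot(length(face) == n)
  wiener_loglik_cpp(as.numeric(rt), as.integer(face),
                    rep_len(as.numeric(delta), n),
                    rep_len(as.numeric(beta), n),
                    rep_len(as.numeric(tau), n),
                    rep_len(as.numeric(alpha), n), tol)
}

#' Probability of absorption at the upper boundary
#'
#' Computed by adaptive quadrature of the upper-boundary first-passage
#' density over decision time.  (The closed form
#' `(1 - exp(-2 delta alpha beta)) / (1 - exp(-2 delta alpha))` exists and is
#' used as an independent cross-check in the package tests.)
#'
#' @param params a [ddm_params()] object.
#' @return probability of an upper-boundary (face) response.
#' @export
choice_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  f <- function(t) wiener_fpt_density_cpp(t, TRUE, params$alpha, params$beta,
                                          params$tau, params$delta, 1e-9)
  integrate(f, 0, Inf, rel.tol = 1e-8, abs.tol = 1e-10)$value
}

#' Simulate choices and response times from the Wiener diffusion
#'
#' Euler-Maruyama path simulation with Gaussian increments
#' `delta * dt + sqrt(dt) * eps` from starting position `alpha * beta`
#' between absorbing barriers 0 and `alpha`.  The returned response time is
#' the absorption time plus the non-decision time `tau`; paths still
#' unabsorbed at the deadline (on the response-time scale) return choice
#' `NA`.
#'
#' @param params a [ddm_params()] object; alternatively pass per-trial drift
#'   via `delta`.
#' @param n number of trials.
#' @param dt Euler step (s).
#' @param deadline response deadline in seconds (`Inf` for none).
#' @param seed optional integer seed (set before drawing).
#' @param delta optional per-trial drift vector overriding `params$delta`.
#' @return data.frame with columns `choice` (`"face"`, `"car"` or `NA`) and
#'   `rt` (s; `NA` for non-responses).
#' @export
wiener_sample <- function(params, n, dt = 1e-4, deadline = Inf, seed = NULL,
                          delta = NULL) {
  stopifnot(inherits(params, "ddm_params"), n >= 1, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  d <- if (is.null(delta)) params$delta else as.numeric(delta)
  res <- wiener_sample_cpp(as.integer(n), params$alpha, params$beta,
                           params$tau, d, dt, deadline)
  choice <- ifelse(is.na(res$choice), NA_character_,
                   ifelse(res$choice == 1L, "face", "car"))
  data.frame(choice = choice, rt = res$rt, stringsAsFactors = FALSE)
}
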