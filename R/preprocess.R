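#' Zero-phase band-pass filtering
#'
#' Applies 4th-order Butterworth high-pass and low-pass filters forward and
#' backward (zero net phase shift, squared magnitude response) to a
#' continuous multichannel record.  The record is demeaned per channel and
#' reflection-padded at both ends before filtering to suppress edge
#' transients.
#'
#' @param record samples x channels numeric matrix (a single channel may be
#'   passed as a vector), or an `epoch_set` (filtered per trial).
#' @param srate sampling rate (Hz); taken from the `epoch_set` if given.
#' @param hp_hz high-pass cutoff (Hz); `NULL` to skip.
#' @param lp_hz low-pass cutoff (Hz); `NULL` to skip. Must be below Nyquist.
#' @param order Butterworth order per pass.
#' @return filtered object of the same shape/class as the input.
#' @export
zero_phase_bandpass <- function(record, srate = NULL, hp_hz = 0.5,
                                lp_hz = 100, order = 4) {
  if (inherits(record, "epoch_set")) {
    out <- record
    for (i in seq_len(dim(record)[1]))
      out$data[i, , ] <- t(zero_phase_bandpass(t(record$data[i, , ]),
                                               record$srate, hp_hz, lp_hz,
                                               order))
    return(out)
  }
  if (is.null(srate)) stop("srate is required for matrix input")
  if (!is.null(lp_hz)) {
    if (lp_hz >= srate / 2)
      stop("low-pass cutoff must be below the Nyquist frequency")
  }
  x <- if (is.matrix(record)) record else matrix(record, ncol = 1)
  x <- sweep(x, 2, colMeans(x), `-`)
  filts <- list()
  if (!is.null(hp_hz) && hp_hz > 0)
    filts <- c(filts, list(signal::butter(order, hp_hz / (srate / 2),
                                          type = "high")))
  if (!is.null(lp_hz))
    filts <- c(filts, list(signal::butter(order, lp_hz / (srate / 2),
                                          type = "low")))
  N <- nrow(x)
  pad <- min(N - 1, max(32, round(srate)))
  for (flt in filts) {
    for (ch in seq_len(ncol(x))) {
      v <- x[, ch]
      ext <- c(2 * v[1] - v[(pad + 1):2],        # reflected head
               v,
               2 * v[N] - v[(N - 1):(N - pad)])  # reflected tail
      fwd <- signal::filter(flt, ext)
      bwd <- rev(signal::filter(flt, rev(fwd)))
      x[, ch] <- bwd[(pad + 1):(pad + N)]
    }
  }
  if (is.matrix(record)) x else x[, 1]
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean over all channels from every channel,
#' so the channel mean at each sample is exactly zero.  Idempotent.
#'
#' @param epochs an `epoch_set`, or a samples x channels matrix.
#' @return the re-referenced object, same class as the input.
#' @export
average_reference <- function(epochs) {
  if (inherits(epochs, "epoch_set")) {
    if (dim(epochs)[2] < 2) stop("need at least 2 channels")
    m <- apply(epochs$data, c(1, 3), mean)      # trials x samples
    for (k in seq_len(dim(epochs)[2]))
      epochs$data[, k, ] <- epochs$data[, k, ] - m
    return(epochs)
  }
  if (ncol(epochs) < 2) stop("need at least 2 channels")
  epochs - rowMeans(epochs)
}

#' Learn ocular-artifact spatial projections from a calibration recording
#'
#' For each artifact class (blink, horizontal saccade, vertical saccade),
#' extracts the recording segments around that class's events and takes the
#' first principal component of the channel covariance as the artifact's
#' spatial pattern.  Filters are returned with unit norm.  A warning is
#' raised when a class's leading component explains too small a share of
#' the segment variance to be a credible stereotyped artifact.
#'
#' @param calibration output of [make_calibration_recording()] (or any list
#'   with `record`, `srate`, `times`, `events`).
#' @param n_components number of artifact classes to learn (classes are
#'   taken in order of appearance in `events$type`).
#' @param segment_s segment length captured after each event (s).
#' @return an object of class `ocular_projection`: `filters`
#'   (components x channels, unit rows), `labels`, `explained` (variance
#'   share of the leading component per class).
#' @export
learn_ocular_projections <- function(calibration, n_components = 3,
                                     segment_s = 0.3) {
  ev <- calibration$events
  classes <- unique(ev$type)[seq_len(n_components)]
  if (any(is.na(classes))) stop("fewer artifact classes than components")
  K <- ncol(calibration$record)
  filters <- matrix(0, length(classes), K)
  explained <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    ev_t <- ev$time[ev$type == classes[ci]]
    if (length(ev_t) < 1)
      stop(sprintf("no events for class %s", classes[ci]))
    seg <- do.call(rbind, lapply(ev_t, function(t0) {
      idx <- which(calibration$times >= t0 &
                     calibration$times < t0 + segment_s)
      calibration$record[idx, , drop = FALSE]
    }))
    seg <- sweep(seg, 2, colMeans(seg), `-`)
    pc <- prcomp(seg, center = FALSE)
    filters[ci, ] <- pc$rotation[, 1] / sqrt(sum(pc$rotation[, 1]^2))
    explained[ci] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  if (any(explained < 0.25))
    warning("leading component explains <25% of segment variance for: ",
            paste(classes[explained < 0.25], collapse = ", "),
            "; artifact may be absent or too weak")
  structure(list(filters = filters, labels = classes,
                 explained = explained,
                 segment_s = segment_s, n_events = nrow(ev)),
            class = "ocular_projection")
}

#' Remove ocular artifacts by subspace projection
#'
#' Projects the data onto the orthogonal complement of the span of the
#' learned artifact spatial patterns: `x <- (I - U (U'U)^-1 U') x` per
#' sample.  Equivalent to estimating the artifact component time courses by
#' least squares and subtracting their re-projection through the spatial
#' patterns.  Idempotent; signals orthogonal to the artifact subspace pass
#' unchanged.
#'
#' @param epochs an `epoch_set`, or a samples x channels matrix.
#' @param proj an `ocular_projection`.
#' @return cleaned object, same class as the input.
#' @export
remove_ocular <- function(epochs, proj) {
  stopifnot(inherits(proj, "ocular_projection"))
  U <- t(proj$filters)                           # channels x components
  apply_proj <- function(M_ks) {                 # channels x samples
    M_ks - U %*% solve(crossprod(U), crossprod(U, M_ks))
  }
  if (inherits(epochs, "epoch_set")) {
    if (dim(epochs)[2] != ncol(proj$filters))
      stop("channel count of epochs does not match the projection")
    for (i in seq_len(dim(epochs)[1]))
      epochs$data[i, , ] <- apply_proj(epochs$data[i, , ])
    return(epochs)
  }
  if (ncol(epochs) != ncol(proj$filters))
    stop("channel count of record does not match the projection")
  t(apply_proj(t(epochs)))
}
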