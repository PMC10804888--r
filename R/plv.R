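#' Frequency band specifications
#'
#' @description
#' `band_spec()` builds a validated band; `eeg_bands()` returns the packaged
#' band set used for the functional-connectivity decomposition: the broadband
#' range plus the classical EEG rhythms —
#' `all` (1–51 Hz), `delta` (1–4), `theta` (4–8), `alpha` (8–12), `mu`
#' (8–13), `beta` (12–30), `mi` (8–30, the sensorimotor range most relevant
#' to motor imagery) and `gamma` (30–51).
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high <= fs/2`.
#' @return `band_spec()`: an object of class `band_spec`; `eeg_bands()`: a
#'   named list of them.
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1, length(high) == 1)
  if (!(low > 0 && high > low))
    stop("need 0 < low < high", call. = FALSE)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @rdname band_spec
#' @export
eeg_bands <- function() {
  list(
    all   = band_spec("all",   1, 51),
    delta = band_spec("delta", 1, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    mu    = band_spec("mu",    8, 13),
    beta  = band_spec("beta",  12, 30),
    mi    = band_spec("mi",    8, 30),
    gamma = band_spec("gamma", 30, 51)
  )
}

#' @export
print.band_spec <- function(x, ...) {
  cat("<band_spec> ", x$name, ": ", x$low, "-", x$high, " Hz\n", sep = "")
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1) {
    bands <- eeg_bands()
    if (!band %in% names(bands))
      stop("unknown band '", band, "'; packaged bands: ",
           paste(names(bands), collapse = ", "), call. = FALSE)
    return(bands[[band]])
  }
  stop("band must be a band_spec or a packaged band name", call. = FALSE)
}

# cached Butterworth design (order 4, band-pass), applied forward-backward
band_filter <- function(band, fs) {
  if (band$high >= fs / 2)
    stop("band edge ", band$high, " Hz is at or above Nyquist (fs = ", fs, ")",
         call. = FALSE)
  signal::butter(4, c(band$low, band$high) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filtering of a trial set
#'
#' @description
#' Applies a zero-phase (forward-backward) order-4 Butterworth band-pass to
#' every channel of every trial. Zero-phase filtering is essential here:
#' phase-locking analysis must not be confounded by filter group delay.
#'
#' @param trials a `trial_set`.
#' @param band a `band_spec` or packaged band name (see [eeg_bands()]).
#' @return A filtered `trial_set` (same shape), with the band recorded in
#'   the provenance.
#' @export
bandpass_filter <- function(trials, band) {
  stopifnot(inherits(trials, "trial_set"))
  band <- as_band(band)
  bf <- band_filter(band, trials$fs)
  x <- trials$signals
  d <- dim(x)
  for (t in seq_len(d[1])) {
    m <- matrix(x[t, , ], d[2], d[3])  # channels x samples, one copy per trial
    for (c in seq_len(d[2]))
      m[c, ] <- signal::filtfilt(bf, m[c, ])
    x[t, , ] <- m
  }
  out <- trials
  out$signals <- x
  out$provenance$band <- c(band$name, band$low, band$high)
  out
}

#' Instantaneous phase of a band-limited signal
#'
#' @description
#' Phase of the analytic signal, computed with the FFT construction of the
#' Hilbert transform: the negative-frequency half of the spectrum is zeroed
#' (positive half doubled) and the inverse transform's complex angle is
#' returned, wrapped to `(-pi, pi]`. Meaningful only for band-limited
#' input — run [bandpass_filter()] first; broadband phase is physically
#' ambiguous.
#'
#' @param x numeric vector, one channel of one trial (length >= 4).
#' @param fs sampling rate in Hz (kept for interface symmetry; the phase
#'   itself is rate-free).
#' @return Numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(x, fs = NULL) {
  n <- length(x)
  if (n < 4) stop("signal too short for phase extraction", call. = FALSE)
  if (all(x == 0)) stop("phase undefined for an all-zero signal", call. = FALSE)
  Arg(analytic_signal(x))
}

# analytic signal via FFT: zero negative frequencies, double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value matrix of one trial
#'
#' @description
#' For every channel pair \eqn{(i, j)} the phase-locking value is the
#' magnitude of the time-averaged unit phasor of their phase difference,
#' \deqn{PLV_{ij} = \frac{1}{M}\left|\sum_{t=1}^{M}
#'   e^{\,\mathrm{i}(\varphi_i(t) - \varphi_j(t))}\right|,}
#' with \eqn{\varphi} the instantaneous (analytic-signal) phase and \eqn{M}
#' the number of retained samples. The value is 1 for perfect phase
#' synchrony, near 0 for independent phases, is symmetric, has unit
#' diagonal, and is invariant to per-channel amplitude scaling and to any
#' common phase offset.
#'
#' By default `edge_trim` samples are dropped at each end of the epoch
#' before averaging, suppressing filter and Hilbert edge artifacts; set
#' `edge_trim = 0` for exact-arithmetic tests on synthetic phases.
#'
#' @param trial numeric matrix `channels x samples`, already band-passed.
#' @param fs sampling rate in Hz.
#' @param edge_trim samples discarded at each epoch edge (default 125,
#'   i.e. 0.5 s at 250 Hz).
#' @return A symmetric `channels x channels` matrix in `[0, 1]` with unit
#'   diagonal.
#' @export
plv_matrix <- function(trial, fs = 250, edge_trim = 125L) {
  stopifnot(is.matrix(trial), nrow(trial) >= 2)
  m <- ncol(trial)
  keep <- seq_len(m)
  if (edge_trim > 0) {
    if (2 * edge_trim >= m - 1)
      stop("edge_trim leaves no samples", call. = FALSE)
    keep <- (edge_trim + 1L):(m - edge_trim)
  }
  nch <- nrow(trial)
  Z <- matrix(complex(real = 0, imaginary = 0), nch, length(keep))
  for (c in seq_len(nch)) {
    if (all(trial[c, ] == trial[c, 1]))
      stop("constant channel ", c, ": phase undefined", call. = FALSE)
    a <- analytic_signal(trial[c, ])[keep]
    Z[c, ] <- a / Mod(a)
  }
  P <- Mod(Z %*% Conj(t(Z))) / length(keep)
  diag(P) <- 1
  P[P > 1] <- 1
  dimnames(P) <- list(rownames(trial), rownames(trial))
  P
}

#' Per-trial PLV connectivity tensor for a band
#'
#' @description
#' Runs [bandpass_filter()] then [plv_matrix()] on every trial, producing
#' the functional-connectivity representation consumed by the PLV
#' classifier: one dense `channels x channels` phase-locking matrix per
#' trial. No thresholding is applied — edge weights are the PLV strengths
#' themselves.
#'
#' @param trials a `trial_set`.
#' @param band a `band_spec` or packaged band name.
#' @param edge_trim see [plv_matrix()].
#' @return An object of class `plv_tensor`: list with `values` (array
#'   `trials x channels x channels`), `band`, `labels`, `channel_names`,
#'   `fs`, `provenance`.
#' @export
plv_dataset <- function(trials, band, edge_trim = 125L) {
  stopifnot(inherits(trials, "trial_set"))
  band <- as_band(band)
  filt <- bandpass_filter(trials, band)
  d <- dim(filt$signals)
  vals <- array(NA_real_, c(d[1], d[2], d[2]),
                dimnames = list(NULL, trials$channel_names, trials$channel_names))
  for (t in seq_len(d[1]))
    vals[t, , ] <- plv_matrix(filt$signals[t, , ], fs = trials$fs,
                              edge_trim = edge_trim)
  structure(
    list(values = vals, band = band, labels = trials$labels,
         channel_names = trials$channel_names, fs = trials$fs,
         provenance = c(trials$provenance,
                        list(plv_band = band$name, edge_trim = edge_trim))),
    class = "plv_tensor")
}

#' @export
print.plv_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<plv_tensor> ", d[1], " trials x ", d[2], "x", d[3], " channels, band ",
      x$band$name, " (", x$band$low, "-", x$band$high, " Hz)\n", sep = "")
  invisible(x)
}

#' Class-averaged PLV matrices
#'
#' Mean connectivity matrix per class — the standard per-class heat-map view
#' of a PLV tensor (exportable with [write_matrix_csv()]).
#'
#' @param plv a `plv_tensor`.
#' @return Named list of `channels x channels` matrices, one per class level.
#' @export
class_mean_plv <- function(plv) {
  stopifnot(inherits(plv, "plv_tensor"))
  lapply(stats::setNames(nm = levels(plv$labels)), function(cl) {
    idx <- which(plv$labels == cl)
    apply(plv$values[idx, , , drop = FALSE], c(2, 3), mean)
  })
}
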