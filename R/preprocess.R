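#' Digital filter specifications
#'
#' Filter designs used throughout the preprocessing pipeline. `design_semg_filters()`
#' returns the sEMG pair — a fourth-order Butterworth bandpass with -3 dB points
#' at 20 and 250 Hz and a narrow 50 Hz IIR notch (quality factor 30) for
#' powerline removal. `design_imu_filter()` returns the fourth-order Butterworth
#' 6 Hz low-pass used to stabilise the IMU baseline against soft-tissue
#' oscillation artifacts. All filters are applied forward-backward (zero phase),
#' and every design is checked for pole stability (all poles strictly inside the
#' unit circle).
#'
#' @param fs Sampling rate in Hz. The sEMG designs require `fs > 500` (so the
#'   250 Hz edge is below Nyquist); the IMU design requires `fs > 12`.
#' @return A list of `filter_spec` objects (`bandpass` and `notch` for
#'   [design_semg_filters()]); a single `filter_spec` for [design_imu_filter()].
#'   A `filter_spec` holds `kind`, `order`, `cutoffs`, `fs` and the transfer
#'   function coefficients `b` (numerator) and `a` (denominator).
#' @examples
#' flt <- design_semg_filters(1000)
#' max(Mod(filter_poles(flt$bandpass))) < 1
#' @export
design_semg_filters <- function(fs) {
  if (fs <= 500) abort("fs must exceed 500 Hz for a 250 Hz band edge")
  bf <- signal::butter(4, c(20, 250) / (fs / 2), type = "pass")
  bandpass <- new_filter_spec("bandpass", 4, c(20, 250), fs, bf$b, bf$a)

  # second-order IIR notch, Q = 30: narrow enough to spare the adjacent band
  w0 <- 2 * pi * 50 / fs
  alpha <- sin(w0) / (2 * 30)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  notch <- new_filter_spec("notch", 2, 50, fs, b, a)

  list(bandpass = bandpass, notch = notch)
}

#' @rdname design_semg_filters
#' @export
design_imu_filter <- function(fs) {
  if (fs <= 12) abort("fs must exceed 12 Hz for a 6 Hz cutoff")
  bf <- signal::butter(4, 6 / (fs / 2), type = "low")
  new_filter_spec("lowpass", 4, 6, fs, bf$b, bf$a)
}

new_filter_spec <- function(kind, order, cutoffs, fs, b, a) {
  spec <- structure(list(kind = kind, order = order, cutoffs = cutoffs,
                         fs = fs, b = as.numeric(b), a = as.numeric(a)),
                    class = "filter_spec")
  if (max(Mod(filter_poles(spec))) >= 1) {
    abort(paste0("unstable ", kind, " filter design at fs = ", fs))
  }
  spec
}

#' @rdname design_semg_filters
#' @param spec A `filter_spec`.
#' @export
filter_poles <- function(spec) {
  polyroot(rev(spec$a))
}

#' Frequency response of a filter design
#'
#' Evaluates the transfer function magnitude at the requested frequencies. With
#' `zero_phase = TRUE` the magnitude of a single pass is squared, matching the
#' effective response of forward-backward application.
#'
#' @param spec A `filter_spec`.
#' @param freqs_hz Frequencies (Hz) at which to evaluate.
#' @param zero_phase Report the forward-backward (squared-magnitude) response.
#' @return A tibble with `freq_hz`, `magnitude` and `db` columns.
#' @examples
#' flt <- design_semg_filters(1000)
#' filter_response(flt$bandpass, c(20, 135, 250))
#' @export
filter_response <- function(spec, freqs_hz, zero_phase = FALSE) {
  z <- exp(-1i * 2 * pi * freqs_hz / spec$fs)
  h <- vapply(z, function(zz) {
    num <- sum(spec$b * zz^(seq_along(spec$b) - 1))
    den <- sum(spec$a * zz^(seq_along(spec$a) - 1))
    Mod(num / den)
  }, numeric(1))
  if (zero_phase) h <- h^2
  tibble::tibble(freq_hz = freqs_hz, magnitude = h,
                 db = 20 * log10(pmax(h, .Machine$double.xmin)))
}

# single-pass IIR with steady-state initial conditions: the filter starts as
# if it had been fed x[1] forever, so step offsets cause no startup transient
apply_iir <- function(x, b, a) {
  stopifnot(abs(a[1] - 1) < 1e-12)
  nb <- length(b)
  x0 <- x[1]
  gain <- sum(b) / sum(a)
  xx <- if (nb > 1) c(rep(x0, nb - 1), x) else x
  u <- stats::filter(xx, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb:length(xx)]
  if (length(a) > 1) {
    as.numeric(stats::filter(u, -a[-1], method = "recursive",
                             init = rep(gain * x0, length(a) - 1)))
  } else {
    u
  }
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward then backward so the net phase response is zero:
#' an input symmetric about its midpoint yields an output symmetric about the
#' same midpoint. Edge transients are suppressed twice over: the signal is
#' extended by odd reflection — at least `3 * (order + 1)` samples, growing to
#' the slowest pole's settle length for high-Q designs — and each pass starts
#' from its steady state for the first padded sample.
#'
#' @param x Numeric signal (length must exceed `3 * (order + 1)` samples).
#' @param spec A `filter_spec`.
#' @return Filtered signal, same length as `x`.
#' @examples
#' flt <- design_imu_filter(200)
#' y <- zero_phase_filter(sin(2 * pi * 2 * (0:399) / 200), flt)
#' @export
zero_phase_filter <- function(x, spec) {
  n_ord <- max(length(spec$a), length(spec$b)) - 1
  min_pad <- 3 * (n_ord + 1)
  if (length(x) <= min_pad) {
    abort(paste0("signal too short for zero-phase filtering (need > ", min_pad,
                 " samples)"))
  }
  # pad until the slowest pole's transient has decayed to ~1e-4, so junction
  # artefacts from the reflected extension stay inside the padding (a high-Q
  # notch rings for hundreds of samples)
  r <- max(Mod(filter_poles(spec)))
  settle <- if (r < 1) ceiling(log(1e-4) / log(r)) else min_pad
  pad <- min(length(x) - 1, max(min_pad, settle))
  # odd reflection about the end samples
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
  xe <- c(left, x, right)
  y <- apply_iir(xe, spec$b, spec$a)
  y <- rev(apply_iir(rev(y), spec$b, spec$a))
  as.numeric(y[(pad + 1):(pad + length(x))])
}

#' Segment a signal into non-overlapping 100 ms windows
#'
#' Cuts each channel into consecutive non-overlapping windows of
#' `round(fs * window_ms / 1000)` samples, discarding any trailing partial
#' window. Windows are cut rectangular; the Hamming taper named in `taper` is
#' stored and applied only when power spectra are estimated (tapering would bias
#' the time-domain amplitude features).
#'
#' @param x Numeric vector (one channel) or samples-by-channels matrix.
#' @param fs Sampling rate in Hz.
#' @param labels Optional per-window labels; length must equal the number of
#'   complete windows.
#' @param window_ms Window length in milliseconds (default 100).
#' @param taper `"none"` or `"hamming"` — the taper used later for spectral
#'   features.
#' @return A `window_set`: list with `windows` (a list of n_windows x
#'   window_len matrices, one per channel), `window_len`, `fs`, `taper` and
#'   `labels`.
#' @examples
#' ws <- segment_windows(sin(1:1000), fs = 1000)
#' nrow(ws$windows[[1]])
#' @export
segment_windows <- function(x, fs, labels = NULL, window_ms = 100,
                            taper = c("hamming", "none")) {
  taper <- match.arg(taper)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) == 0) abort("cannot segment an empty signal")
  wl <- round(fs * window_ms / 1000)
  if (wl < 2) abort("window too short: fs * window_ms must cover >= 2 samples")
  n_win <- floor(nrow(x) / wl)
  if (n_win < 1) abort("signal shorter than one window")
  if (!is.null(labels) && length(labels) != n_win) {
    abort(paste0("expected ", n_win, " labels, got ", length(labels)))
  }
  windows <- lapply(seq_len(ncol(x)), function(ch) {
    matrix(x[seq_len(n_win * wl), ch], nrow = n_win, ncol = wl, byrow = TRUE)
  })
  names(windows) <- colnames(x)
  structure(list(windows = windows, window_len = wl, fs = fs,
                 taper = taper, labels = labels),
            class = "window_set")
}
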