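#' Time-domain window features
#'
#' Amplitude statistics computed per analysis window: `mav()` is the mean
#' absolute value (localized contraction intensity), `rms()` the root mean
#' square (neuromuscular energy), and `svar()` the unbiased sample variance
#' (dynamic force fluctuation, `N - 1` denominator, mean-subtracted). For every
#' window `rms(x) >= mav(x)` by the power-mean inequality.
#'
#' @param x Numeric window (non-empty; `svar()` needs at least 2 samples).
#' @return A single non-negative number.
#' @examples
#' mav(c(3, -4))   # 3.5
#' rms(c(3, 4))    # sqrt(12.5)
#' svar(c(1, 2, 3)) # 1
#' @export
mav <- function(x) {
  if (length(x) == 0) abort("empty window")
  mean(abs(x))
}

#' @rdname mav
#' @export
rms <- function(x) {
  if (length(x) == 0) abort("empty window")
  sqrt(mean(x^2))
}

#' @rdname mav
#' @export
svar <- function(x) {
  if (length(x) < 2) abort("variance needs at least 2 samples")
  stats::var(x)
}

#' One-sided periodogram power spectral density of a window
#'
#' Mean-removed, Hamming-tapered single-taper periodogram with density scaling:
#' the powers integrate (sum times bin width) to approximately the tapered
#' signal's variance.
#'
#' @param x Numeric window, at least 4 samples.
#' @param fs Sampling rate in Hz.
#' @param taper `"hamming"` (default) or `"none"`.
#' @return A tibble with `freq` (Hz, strictly increasing, excluding DC) and
#'   `power` (PSD, >= 0).
#' @examples
#' s <- psd_estimate(sin(2 * pi * 50 * (0:99) / 1000), fs = 1000)
#' s$freq[which.max(s$power)]
#' @export
psd_estimate <- function(x, fs, taper = c("hamming", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  if (n < 4) abort("window too short for spectral estimation")
  x <- x - mean(x)
  w <- if (taper == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  } else {
    rep(1, n)
  }
  xf <- fft(x * w)
  # one-sided density scaling over the taper's power
  nyq <- floor(n / 2)
  p <- Mod(xf[2:(nyq + 1)])^2 / (fs * sum(w^2))
  dbl <- rep(2, nyq)
  if (n %% 2 == 0) dbl[nyq] <- 1 # Nyquist bin not mirrored
  tibble::tibble(freq = (1:nyq) * fs / n, power = p * dbl)
}

#' Spectral summary frequencies
#'
#' `median_frequency()` returns the smallest frequency at which the cumulative
#' power reaches half of the total power (ties resolve to the first crossing).
#' `mean_power_frequency()` returns the power-weighted mean frequency
#' `sum(f * p) / sum(p)`.
#'
#' @param spectrum A tibble/data frame with `freq` and `power` columns (e.g.
#'   from [psd_estimate()]); total power must be positive.
#' @return Frequency in Hz.
#' @examples
#' s <- data.frame(freq = c(50, 150), power = c(1, 1))
#' median_frequency(s)      # 50
#' mean_power_frequency(s)  # 100
#' @export
median_frequency <- function(spectrum) {
  p <- spectrum$power
  tot <- sum(p)
  if (tot <= 0) abort("median frequency undefined for a zero spectrum")
  spectrum$freq[which(cumsum(p) >= tot / 2)[1]]
}

#' @rdname median_frequency
#' @export
mean_power_frequency <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (tot <= 0) abort("mean power frequency undefined for a zero spectrum")
  sum(spectrum$freq * spectrum$power) / tot
}

semg_window_features <- function(win, fs, taper) {
  sp <- psd_estimate(win, fs, taper = taper)
  mf <- if (sum(sp$power) > 0) median_frequency(sp) else 0
  mpf <- if (sum(sp$power) > 0) mean_power_frequency(sp) else 0
  c(mav = mav(win), rms = rms(win), var = svar(win), mf = mf, mpf = mpf)
}

#' Extract the bidomain feature matrix from a recording
#'
#' Runs the full per-trial feature pipeline: sEMG channels are zero-phase
#' filtered (20-250 Hz fourth-order Butterworth bandpass, then 50 Hz notch) and
#' cut into 100 ms non-overlapping windows; five features per channel are
#' computed — MAV, RMS, VAR in the time domain and median/mean power frequency
#' from the Hamming-tapered periodogram — giving 30 sEMG columns under the
#' default 6-channel montage. IMU axes are zero-phase low-pass filtered at 6 Hz
#' and windowed on the same 100 ms grid; MAV and VAR per axis give 12 features
#' per IMU, 36 columns for three units. `modality = "fusion"` concatenates both
#' blocks (66 columns).
#'
#' @param rec A `lir_recording`.
#' @param modality `"fusion"`, `"semg"` or `"imu"`.
#' @param taper Taper used for the spectral features (`"hamming"` default).
#' @return A tibble with `.label` (window mode code) followed by feature columns
#'   named `semg.<channel>.<feature>` / `imu.<unit>.<axis>.<feature>`, in a
#'   deterministic order. Use [feature_modalities()] to recover the per-column
#'   modality tag.
#' @examples
#' rec <- generate_trial(sim_config(), data.frame(mode = "LW", duration = 1), seed = 1)
#' ft <- extract_features(rec)
#' dim(ft)
#' @export
extract_features <- function(rec, modality = c("fusion", "semg", "imu"),
                             taper = c("hamming", "none")) {
  modality <- match.arg(modality)
  taper <- match.arg(taper)
  stopifnot(inherits(rec, "lir_recording"))

  n_win_semg <- floor(nrow(rec$semg) / round(rec$fs_semg * 0.1))
  n_win_imu <- floor(nrow(rec$imu) / round(rec$fs_imu * 0.1))
  n_win <- min(n_win_semg, n_win_imu)
  if (abs(n_win_semg - n_win_imu) > 1) {
    abort("sEMG and IMU window grids disagree by more than one window")
  }
  labels <- rec$window_labels[seq_len(n_win)]

  blocks <- list()
  if (modality %in% c("fusion", "semg")) {
    flt <- design_semg_filters(rec$fs_semg)
    filtered <- apply(rec$semg, 2, function(ch) {
      zero_phase_filter(zero_phase_filter(ch, flt$bandpass), flt$notch)
    })
    ws <- segment_windows(filtered, rec$fs_semg, taper = taper)
    cols <- lapply(colnames(rec$semg), function(ch) {
      f <- t(apply(ws$windows[[ch]][seq_len(n_win), , drop = FALSE], 1,
                   semg_window_features, fs = rec$fs_semg, taper = taper))
      colnames(f) <- paste("semg", ch, colnames(f), sep = ".")
      f
    })
    blocks$semg <- do.call(cbind, cols)
  }
  if (modality %in% c("fusion", "imu")) {
    flt <- design_imu_filter(rec$fs_imu)
    filtered <- apply(rec$imu, 2, function(ch) zero_phase_filter(ch, flt))
    ws <- segment_windows(filtered, rec$fs_imu, taper = taper)
    cols <- lapply(colnames(rec$imu), function(ax) {
      w <- ws$windows[[ax]][seq_len(n_win), , drop = FALSE]
      f <- cbind(mav = apply(w, 1, mav), var = apply(w, 1, svar))
      colnames(f) <- paste("imu", ax, colnames(f), sep = ".")
      f
    })
    blocks$imu <- do.call(cbind, cols)
  }

  vals <- do.call(cbind, blocks[intersect(c("semg", "imu"), names(blocks))])
  rownames(vals) <- NULL
  if (any(!is.finite(vals))) abort("non-finite feature values produced")
  dplyr::bind_cols(tibble::tibble(.label = labels), tibble::as_tibble(vals))
}

#' Per-column modality tags of a feature tibble
#'
#' @param features A feature tibble from [extract_features()] or
#'   [dataset_features()].
#' @return Named character vector (`"semg"`/`"imu"`) over the feature columns.
#' @export
feature_modalities <- function(features) {
  cols <- setdiff(names(features), c(".label", ".trial"))
  tags <- sub("\\..*$", "", cols)
  names(tags) <- cols
  tags
}

feature_columns <- function(features) {
  setdiff(names(features), c(".label", ".trial"))
}

#' Feature matrix for a whole dataset
#'
#' Applies [extract_features()] to every recording and row-binds the results,
#' adding a `.trial` identifier column (used for trial-level train/test
#' splitting).
#'
#' @param recordings List of `lir_recording`.
#' @inheritParams extract_features
#' @return A tibble with `.trial`, `.label` and the feature columns.
#' @export
dataset_features <- function(recordings, modality = c("fusion", "semg", "imu"),
                             taper = c("hamming", "none")) {
  modality <- match.arg(modality)
  taper <- match.arg(taper)
  purrr::map_dfr(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    id <- rec$meta$trial
    if (is.null(id)) id <- as.character(i)
    dplyr::bind_cols(
      tibble::tibble(.trial = as.character(id)),
      extract_features(rec, modality = modality, taper = taper)
    )
  })
}
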