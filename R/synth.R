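#' Simulation configuration for synthetic gait recordings
#'
#' Builds the full parameter set for the synthetic sEMG/IMU gait generator. Each
#' of the five steady-state modes carries (a) an activation template per muscle —
#' a terrain-specific tonic (co-contraction) level plus Gaussian bursts
#' parameterised by centre (fraction of the gait cycle), width (fraction) and
#' amplitude (mV) — and (b) a kinematic template per IMU axis — an offset plus
#' up to four cadence harmonics with mode-specific amplitudes and phases.
#' Transition modes reference their two steady phases and are synthesised by
#' linearly cross-fading the two templates over one gait cycle, plus a brief
#' anticipatory bilateral adjustment burst (dorsiflexors peaking before the
#' phase change, knee extensors after, scaled by the entered terrain's demand)
#' that marks the step adjustment itself.
#'
#' Muscles are bilateral rectus femoris, tibialis anterior and soleus; the right
#' leg's activation is the left leg's shifted by half a gait cycle. IMUs sit on
#' the thigh, shank and ankle, each providing triaxial acceleration (m/s^2) and
#' angular velocity (deg/s).
#'
#' @param cadence_hz Gait-cycle rate in Hz (cycles per second).
#' @param fs_semg,fs_imu Sampling rates in Hz for the sEMG and IMU streams.
#' @param powerline_amp Amplitude (mV) of the 50 Hz powerline interference added
#'   to every sEMG channel (random phase per trial).
#' @param drift_amp Scale (mV) of the slow random-walk baseline drift.
#' @param artifact_level Scale of high-frequency soft-tissue/sensor artifact
#'   noise added to the IMU axes (m/s^2 for accelerometer axes; gyroscope axes
#'   use a 20x scale to match their numeric range).
#' @param activation_scale Global multiplier on all activation-template
#'   amplitudes (tonic levels, bursts and the transition burst); `0` silences
#'   every muscle.
#' @param transition_burst Peak amplitude (mV, before demand scaling) of the
#'   anticipatory adjustment burst added during transition cross-fades; `0`
#'   reduces transitions to the pure cross-fade.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' names(cfg$modes)
#' @export
sim_config <- function(cadence_hz = 1, fs_semg = 1000, fs_imu = 200,
                       powerline_amp = 0.05, drift_amp = 0.08,
                       artifact_level = 0.5, activation_scale = 1,
                       transition_burst = 0.35, cadence_jitter = 0.05,
                       gain_cv = 0.05) {
  stopifnot(cadence_hz > 0, fs_semg > 500, fs_imu > 12,
            powerline_amp >= 0, drift_amp >= 0, artifact_level >= 0,
            activation_scale >= 0, cadence_jitter >= 0, cadence_jitter < 1,
            gain_cv >= 0)

  # per-muscle burst tables: centre / width (gait-cycle fraction), amplitude (mV)
  bursts <- list(
    LW = list(
      rf  = rbind(c(0.05, 0.06, 0.30)),
      ta  = rbind(c(0.02, 0.05, 0.55), c(0.65, 0.07, 0.45)),
      sol = rbind(c(0.42, 0.08, 0.65))
    ),
    SA = list(
      rf  = rbind(c(0.18, 0.10, 1.30)),
      ta  = rbind(c(0.55, 0.08, 0.39)),
      sol = rbind(c(0.52, 0.10, 1.24))
    ),
    SD = list(
      rf  = rbind(c(0.38, 0.10, 0.49)),
      ta  = rbind(c(0.05, 0.07, 0.60)),
      sol = rbind(c(0.15, 0.07, 0.18))
    ),
    RA = list(
      rf  = rbind(c(0.10, 0.08, 0.69), c(0.50, 0.08, 0.40)),
      ta  = rbind(c(0.62, 0.07, 0.58)),
      sol = rbind(c(0.45, 0.12, 1.21))
    ),
    RD = list(
      rf  = rbind(c(0.30, 0.12, 0.43)),
      ta  = rbind(c(0.12, 0.08, 0.55), c(0.75, 0.06, 0.30)),
      sol = rbind(c(0.25, 0.08, 0.38))
    )
  )
  # terrain-dependent co-contraction: each mode holds a distinct baseline
  # activation per muscle (mV), on top of which the phasic bursts ride
  tonic_base <- c(rf = 0.12, ta = 0.15, sol = 0.15)
  tonic_gain <- rbind(
    LW = c(1.0, 1.0, 1.0),
    SA = c(2.5, 1.2, 2.2),
    SD = c(1.8, 2.2, 0.8),
    RA = c(2.2, 1.5, 2.6),
    RD = c(1.5, 1.8, 1.4)
  )
  colnames(tonic_gain) <- names(tonic_base)

  # kinematic recipe: per-mode harmonic gains and phase offset, per-axis base
  # amplitudes, per-unit gains; distinct rows keep modes separable by design
  mode_gain <- rbind(
    LW = c(1.0, 0.50, 0.25, 0.10),
    SA = c(0.7, 0.90, 0.40, 0.20),
    SD = c(0.8, 0.30, 0.60, 0.30),
    RA = c(1.2, 0.60, 0.20, 0.05),
    RD = c(0.9, 0.20, 0.50, 0.40)
  )
  mode_phase <- c(LW = 0, SA = 0.8, SD = 1.6, RA = 2.4, RD = 3.2)
  axis_base <- c(ax = 2.0, ay = 1.5, az = 2.5, gx = 60, gy = 40, gz = 80)
  axis_offset <- c(ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0)
  unit_gain <- c(thigh = 0.8, shank = 1.0, ankle = 1.3)

  steady <- names(bursts)
  kin <- lapply(steady, function(m) {
    amp <- array(0, dim = c(3, 6, 4),
                 dimnames = list(names(unit_gain), names(axis_base), NULL))
    phase <- amp
    for (u in 1:3) for (a in 1:6) for (h in 1:4) {
      amp[u, a, h] <- axis_base[a] * mode_gain[m, h] * unit_gain[u] / h
      phase[u, a, h] <- mode_phase[m] + 0.7 * h + 0.9 * u + 0.5 * a
    }
    list(offset = matrix(rep(axis_offset, each = 3), nrow = 3,
                         dimnames = list(names(unit_gain), names(axis_base))),
         amp = amp, phase = phase)
  })
  names(kin) <- steady

  tax <- locomotion_modes()
  modes <- lapply(seq_len(nrow(tax)), function(i) {
    code <- tax$code[i]
    if (tax$is_transition[i]) {
      list(kind = "transition", from = tax$from[i], to = tax$to[i])
    } else {
      act <- lapply(names(tonic_base), function(mu) {
        b <- bursts[[code]][[mu]]
        b[, 3] <- b[, 3] * activation_scale
        list(tonic = tonic_base[[mu]] * tonic_gain[code, mu] * activation_scale,
             bursts = b)
      })
      names(act) <- names(tonic_base)
      list(kind = "steady", act = act, kin = kin[[code]])
    }
  })
  names(modes) <- tax$code

  structure(list(
    cadence_hz = cadence_hz, fs_semg = fs_semg, fs_imu = fs_imu,
    powerline_amp = powerline_amp, drift_amp = drift_amp,
    artifact_level = artifact_level,
    transition_burst = transition_burst * activation_scale,
    cadence_jitter = cadence_jitter, gain_cv = gain_cv, modes = modes,
    semg_channels = c("rf_l", "ta_l", "sol_l", "rf_r", "ta_r", "sol_r"),
    imu_units = names(unit_gain), imu_axes = names(axis_base)
  ), class = "sim_config")
}

# wrapped-Gaussian activation envelope at gait-cycle positions `pos` in [0, 1)
burst_envelope <- function(pos, tmpl) {
  env <- rep(tmpl$tonic, length(pos))
  b <- tmpl$bursts
  for (k in seq_len(nrow(b))) {
    ctr <- b[k, 1]; w <- b[k, 2]; a <- b[k, 3]
    for (shift in c(-1, 0, 1)) {
      env <- env + a * exp(-0.5 * ((pos - ctr + shift) / w)^2)
    }
  }
  env
}

# per-channel steady-mode envelope over absolute time; right leg in antiphase
steady_envelopes <- function(cfg, mode, t) {
  tmpl <- cfg$modes[[mode]]$act
  muscles <- c("rf", "ta", "sol")
  sapply(seq_along(cfg$semg_channels), function(ch) {
    mu <- muscles[(ch - 1) %% 3 + 1]
    off <- if (ch > 3) 0.5 else 0
    pos <- (t * cfg$cadence_hz + off) %% 1
    burst_envelope(pos, tmpl[[mu]])
  })
}

steady_kinematics <- function(cfg, mode, t) {
  k <- cfg$modes[[mode]]$kin
  out <- matrix(0, nrow = length(t), ncol = 18)
  idx <- 0
  for (u in 1:3) for (a in 1:6) {
    idx <- idx + 1
    x <- rep(k$offset[u, a], length(t))
    for (h in 1:4) {
      x <- x + k$amp[u, a, h] *
        cos(2 * pi * h * cfg$cadence_hz * t + k$phase[u, a, h])
    }
    out[, idx] <- x
  }
  out
}

# cross-fade weight: 0 -> 1 linearly over one gait cycle centred at tc
crossfade_weight <- function(t, tc, cadence_hz) {
  pmin(1, pmax(0, (t - tc) * cadence_hz + 0.5))
}

mode_envelopes <- function(cfg, mode, t, tc) {
  m <- cfg$modes[[mode]]
  if (m$kind == "steady") return(steady_envelopes(cfg, mode, t))
  w <- crossfade_weight(t, tc, cfg$cadence_hz)
  env <- (1 - w) * steady_envelopes(cfg, m$from, t) +
    w * steady_envelopes(cfg, m$to, t)
  # anticipatory step adjustment: brief bilateral rf/ta co-activation centred
  # on the phase change (breaks the left/right antiphase pattern, so the
  # adjustment itself is a distinctive transition signature)
  if (cfg$transition_burst > 0) {
    cad <- cfg$cadence_hz
    # anticipatory step adjustment, scaled by the demand of the terrain being
    # entered: dorsiflexors pre-position the foot before the change, knee
    # extensors stabilise after weight acceptance — the time skew encodes the
    # transition's direction, the scaling its target terrain
    g_ta <- cfg$modes[[m$to]]$act$ta$tonic / cfg$modes[["LW"]]$act$ta$tonic
    g_rf <- cfg$modes[[m$to]]$act$rf$tonic / cfg$modes[["LW"]]$act$rf$tonic
    bump_ta <- cfg$transition_burst * g_ta *
      exp(-0.5 * (((t - tc) * cad + 0.15) / 0.12)^2)
    bump_rf <- cfg$transition_burst * g_rf *
      exp(-0.5 * (((t - tc) * cad - 0.15) / 0.12)^2)
    env[, 2] <- env[, 2] + bump_ta
    env[, 5] <- env[, 5] + bump_ta
    env[, 1] <- env[, 1] + bump_rf
    env[, 4] <- env[, 4] + bump_rf
  }
  env
}

mode_kinematics <- function(cfg, mode, t, tc) {
  m <- cfg$modes[[mode]]
  if (m$kind == "steady") return(steady_kinematics(cfg, mode, t))
  w <- crossfade_weight(t, tc, cfg$cadence_hz)
  (1 - w) * steady_kinematics(cfg, m$from, t) + w * steady_kinematics(cfg, m$to, t)
}

#' Generate one synthetic gait trial
#'
#' Synthesises a synchronized sEMG + IMU recording for a sequence of locomotion
#' modes. Each sEMG channel is a mode- and muscle-specific activation envelope
#' multiplying a zero-mean Gaussian carrier band-shaped to 20-250 Hz, plus 50 Hz
#' powerline interference (random phase per trial) and a slow random-walk
#' baseline drift. Each IMU axis is a sum of up to four cadence harmonics with
#' mode-specific coefficients plus high-frequency artifact noise. Transition
#' modes cross-fade their two steady templates over one gait cycle centred in
#' the segment. The same `(cfg, mode_sequence, seed)` always reproduces the
#' recording bit for bit.
#'
#' @param cfg A [sim_config()].
#' @param mode_sequence Data frame with columns `mode` (codes from
#'   [mode_codes()]) and `duration` (seconds, > 0).
#' @param seed Integer seed controlling every random component.
#' @param subject,trial Identifiers stored in the recording metadata.
#' @return A `lir_recording`: list with `semg` (samples x 6 matrix, mV),
#'   `fs_semg`, `imu` (samples x 18 matrix), `fs_imu`, `window_labels` (one mode
#'   code per 100 ms window) and `meta`.
#' @examples
#' rec <- generate_trial(sim_config(), data.frame(mode = "LW", duration = 2), seed = 1)
#' dim(rec$semg)
#' table(rec$window_labels)
#' @export
generate_trial <- function(cfg, mode_sequence, seed, subject = 1L, trial = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  mode_sequence <- as.data.frame(mode_sequence)
  stopifnot(all(c("mode", "duration") %in% names(mode_sequence)))
  assert_mode(mode_sequence$mode)
  if (any(mode_sequence$duration <= 0)) abort("segment durations must be > 0")

  withr::with_seed(seed, {
    # trial-level variability: self-selected pace and day-to-day gain drifts
    # (electrode impedance, sensor placement, activation vigour)
    trial_cfg <- cfg
    trial_cfg$cadence_hz <- cfg$cadence_hz *
      runif(1, 1 - cfg$cadence_jitter, 1 + cfg$cadence_jitter)
    semg_gain <- pmax(exp(rnorm(6, 0, cfg$gain_cv)), 0.5)
    imu_gain <- pmax(exp(rnorm(18, 0, cfg$gain_cv)), 0.5)

    durs <- mode_sequence$duration
    ends <- cumsum(durs)
    starts <- c(0, head(ends, -1))
    total <- ends[length(ends)]

    n_semg <- round(total * cfg$fs_semg)
    n_imu <- round(total * cfg$fs_imu)
    t_semg <- (seq_len(n_semg) - 1) / cfg$fs_semg
    t_imu <- (seq_len(n_imu) - 1) / cfg$fs_imu
    seg_of <- function(t) pmin(findInterval(t, starts), length(durs))

    # piecewise envelopes / kinematics on each time grid
    env <- matrix(0, n_semg, 6)
    kin <- matrix(0, n_imu, 18)
    seg_semg <- seg_of(t_semg)
    seg_imu <- seg_of(t_imu)
    for (s in seq_along(durs)) {
      tc <- (starts[s] + ends[s]) / 2
      i1 <- which(seg_semg == s)
      if (length(i1)) {
        env[i1, ] <- mode_envelopes(trial_cfg, mode_sequence$mode[s],
                                    t_semg[i1], tc)
      }
      i2 <- which(seg_imu == s)
      if (length(i2)) {
        kin[i2, ] <- mode_kinematics(trial_cfg, mode_sequence$mode[s],
                                     t_imu[i2], tc)
      }
    }
    env <- env %*% diag(semg_gain)
    # gains scale the oscillatory kinematics, not the gravity offset
    off18 <- rep(c(0, 0, 9.81, 0, 0, 0), times = 3)
    kin <- sweep(sweep(kin, 2, off18, "-") %*% diag(imu_gain), 2, off18, "+")

    # band-shaped Gaussian carrier per channel, unit variance
    flt <- design_semg_filters(cfg$fs_semg)
    semg <- matrix(0, n_semg, 6)
    phase_pl <- runif(1, 0, 2 * pi)
    for (ch in 1:6) {
      carrier <- zero_phase_filter(rnorm(n_semg), flt$bandpass)
      carrier <- carrier / sd(carrier)
      x <- env[, ch] * carrier
      if (cfg$powerline_amp > 0) {
        x <- x + cfg$powerline_amp * sin(2 * pi * 50 * t_semg + phase_pl)
      }
      if (cfg$drift_amp > 0) {
        x <- x + cfg$drift_amp * cumsum(rnorm(n_semg)) / sqrt(n_semg)
      }
      semg[, ch] <- x
    }
    colnames(semg) <- cfg$semg_channels

    if (cfg$artifact_level > 0) {
      scale <- rep(c(1, 1, 1, 20, 20, 20), times = 3) * cfg$artifact_level
      kin <- kin + matrix(rnorm(n_imu * 18), n_imu, 18) %*% diag(scale)
    }
    colnames(kin) <- paste(rep(cfg$imu_units, each = 6),
                           rep(cfg$imu_axes, times = 3), sep = ".")

    wl <- round(cfg$fs_semg * 0.1)
    n_win <- floor(n_semg / wl)
    mid_t <- ((seq_len(n_win) - 1) * wl + wl / 2) / cfg$fs_semg
    labels <- mode_sequence$mode[seg_of(mid_t)]

    structure(list(
      semg = semg, fs_semg = cfg$fs_semg,
      imu = kin, fs_imu = cfg$fs_imu,
      window_labels = labels,
      meta = list(subject = subject, trial = trial, seed = seed,
                  cadence_hz = cfg$cadence_hz, mode_sequence = mode_sequence)
    ), class = "lir_recording")
  })
}

#' @export
print.lir_recording <- function(x, ...) {
  cat("<lir_recording> ", nrow(x$semg), " sEMG samples @ ", x$fs_semg, " Hz (",
      ncol(x$semg), " ch), ", nrow(x$imu), " IMU samples @ ", x$fs_imu,
      " Hz (", ncol(x$imu), " axes), ", length(x$window_labels),
      " windows\n", sep = "")
  cat("  modes:", paste(unique(x$window_labels), collapse = " "), "\n")
  invisible(x)
}

#' Inject additive white Gaussian noise into the sEMG channels
#'
#' Adds white Gaussian noise to every sEMG channel, scaled per channel so that
#' the empirical signal-to-noise ratio equals `snr_db`. IMU streams and window
#' labels are untouched. `snr_db = Inf` returns the input unchanged.
#'
#' @param rec A `lir_recording`.
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` for no noise.
#' @param seed Integer seed for the noise realisation.
#' @return A `lir_recording` with noisy sEMG.
#' @examples
#' rec <- generate_trial(sim_config(), data.frame(mode = "LW", duration = 1), seed = 1)
#' noisy <- inject_awgn(rec, snr_db = 10, seed = 2)
#' @export
inject_awgn <- function(rec, snr_db, seed) {
  stopifnot(inherits(rec, "lir_recording"))
  if (is.infinite(snr_db) && snr_db > 0) return(rec)
  p_sig <- colMeans(rec$semg^2)
  if (any(p_sig == 0)) abort("SNR undefined: an sEMG channel has zero power")
  withr::with_seed(seed, {
    n <- nrow(rec$semg)
    for (ch in seq_len(ncol(rec$semg))) {
      sd_n <- sqrt(p_sig[ch] * 10^(-snr_db / 10))
      rec$semg[, ch] <- rec$semg[, ch] + rnorm(n, sd = sd_n)
    }
  })
  rec
}

#' Generate a labelled synthetic gait dataset
#'
#' Produces `trials_per_mode` trials for each of the 13 locomotion modes.
#' Steady-mode trials hold the mode for `steady_duration` seconds; transition
#' trials embed the transition between its two steady phases —
#' `transition_pad` seconds of the departing mode, one gait cycle of labelled
#' transition (the cross-fade), then `transition_pad` seconds of the arriving
#' mode.
#'
#' @inheritParams generate_trial
#' @param trials_per_mode Number of trials per mode (>= 1).
#' @param steady_duration Duration (s) of a steady-mode trial.
#' @param transition_pad Duration (s) of each flanking steady phase in a
#'   transition trial.
#' @return A list of `lir_recording`, one per trial, with `meta$trial` of the
#'   form `"<MODE>-<k>"`.
#' @examples
#' ds <- generate_dataset(sim_config(), trials_per_mode = 1, seed = 7)
#' length(ds)
#' @export
generate_dataset <- function(cfg, trials_per_mode, seed,
                             steady_duration = 2, transition_pad = 1) {
  stopifnot(trials_per_mode >= 1)
  tax <- locomotion_modes()
  out <- list()
  counter <- 0L
  for (i in seq_len(nrow(tax))) {
    code <- tax$code[i]
    seqn <- if (tax$is_transition[i]) {
      data.frame(mode = c(tax$from[i], code, tax$to[i]),
                 duration = c(transition_pad, 1 / cfg$cadence_hz, transition_pad))
    } else {
      data.frame(mode = code, duration = steady_duration)
    }
    for (k in seq_len(trials_per_mode)) {
      counter <- counter + 1L
      out[[counter]] <- generate_trial(cfg, seqn, seed = seed + counter,
                                       trial = sprintf("%s-%02d", code, k))
    }
  }
  out
}
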