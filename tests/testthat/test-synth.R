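test_that("the taxonomy has 13 modes, 5 steady and 8 transitions", {
  tax <- locomotion_modes()
  expect_equal(nrow(tax), 13)
  expect_equal(length(unique(tax$code)), 13)
  expect_equal(sum(!tax$is_transition), 5)
  expect_true(all(tax$from[tax$is_transition] %in% tax$code))
  expect_true(all(tax$to[tax$is_transition] %in% tax$code))
})

test_that("generate_trial is deterministic and labels follow the sequence", {
  cfg <- small_cfg()
  seqn <- data.frame(mode = c("LW", "SA"), duration = c(1, 1))
  r1 <- generate_trial(cfg, seqn, seed = 3)
  r2 <- generate_trial(cfg, seqn, seed = 3)
  expect_identical(r1, r2)
  r3 <- generate_trial(cfg, seqn, seed = 4)
  expect_false(identical(r1$semg, r3$semg))

  # 10 s single-mode trial: 100 windows, all labelled with the mode
  r <- generate_trial(cfg, data.frame(mode = "LW", duration = 10), seed = 1)
  expect_equal(length(r$window_labels), 100)
  expect_true(all(r$window_labels == "LW"))
  expect_true(all(is.finite(r$semg)), all(is.finite(r$imu)))

  # durations implied by the two streams agree to within one window
  expect_lt(abs(nrow(r$semg) / r$fs_semg - nrow(r$imu) / r$fs_imu), 0.1)
  expect_equal(ncol(r$semg), 6)
  expect_equal(ncol(r$imu), 18)
})

test_that("silencing every amplitude yields identically zero sEMG", {
  cfg <- sim_config(powerline_amp = 0, drift_amp = 0, artifact_level = 0,
                    activation_scale = 0)
  r <- generate_trial(cfg, data.frame(mode = "RD", duration = 1), seed = 2)
  expect_true(all(r$semg == 0))
})

test_that("unknown modes and non-positive durations are rejected", {
  cfg <- small_cfg()
  expect_error(generate_trial(cfg, data.frame(mode = "FLY", duration = 1), 1),
               "unknown")
  expect_error(generate_trial(cfg, data.frame(mode = "LW", duration = 0), 1),
               "duration")
})

test_that("injected noise hits the requested empirical SNR", {
  cfg <- small_cfg()
  rec <- generate_trial(cfg, data.frame(mode = "LW", duration = 12), seed = 8)
  for (snr in c(0, 10)) {
    noisy <- inject_awgn(rec, snr_db = snr, seed = 21)
    p_sig <- colMeans(rec$semg^2)
    p_noise <- colMeans((noisy$semg - rec$semg)^2)
    measured <- 10 * log10(p_sig / p_noise)
    expect_true(all(abs(measured - snr) < 0.5))
    if (snr == 0) expect_true(all(abs(p_noise / p_sig - 1) < 0.05))
    expect_identical(noisy$window_labels, rec$window_labels)
    expect_identical(noisy$imu, rec$imu)
  }
  expect_identical(inject_awgn(rec, Inf, seed = 1), rec)
  silent <- rec
  silent$semg[] <- 0
  expect_error(inject_awgn(silent, 10, seed = 1), "zero power")
})

test_that("generate_dataset covers every mode and reproduces label histograms", {
  ds <- small_dataset()
  expect_equal(length(ds), 26)
  labs <- unlist(lapply(ds, `[[`, "window_labels"))
  expect_setequal(unique(labs), mode_codes())

  ds2 <- generate_dataset(small_cfg(), trials_per_mode = 2, seed = 101,
                          steady_duration = 2, transition_pad = 1)
  labs2 <- unlist(lapply(ds2, `[[`, "window_labels"))
  expect_equal(c(table(labs)), c(table(labs2)))

  ds3 <- generate_dataset(small_cfg(), trials_per_mode = 1, seed = 999,
                          steady_duration = 2, transition_pad = 1)
  labs3 <- unlist(lapply(ds3, `[[`, "window_labels"))
  # different seed: same label multiset per construction, different signals
  expect_false(identical(ds3[[1]]$semg, ds[[1]]$semg))
  expect_setequal(unique(labs3), mode_codes())
})

test_that("with artifacts disabled, >= 95% of sEMG power lies in 20-250 Hz", {
  cfg <- sim_config(powerline_amp = 0, drift_amp = 0, artifact_level = 0)
  for (mode in c("LW", "SA", "RD")) {
    rec <- generate_trial(cfg, data.frame(mode = mode, duration = 8), seed = 31)
    for (ch in c(1, 4)) {
      sp <- psd_estimate(rec$semg[, ch], rec$fs_semg, taper = "none")
      frac <- sum(sp$power[sp$freq >= 20 & sp$freq <= 250]) / sum(sp$power)
      expect_gt(frac, 0.95)
    }
  }
})

test_that("modes are separable by nearest-centroid on oracle envelope parameters", {
  cfg <- small_cfg()
  ds <- small_dataset()

  # oracle parameter vector per window: the true (noise-free) activation
  # envelopes and kinematics over the cycle-aligned gait cycle containing the
  # window, including cross-fade blending and the adjustment burst
  oracle_vecs <- function(rec) {
    seqn <- rec$meta$mode_sequence
    ends <- cumsum(seqn$duration)
    starts <- c(0, utils::head(ends, -1))
    t(vapply(seq_along(rec$window_labels), function(w) {
      mid <- (w - 0.5) * 0.1
      cyc0 <- floor(mid * cfg$cadence_hz) / cfg$cadence_hz
      tt <- cyc0 + seq(0, 0.95, by = 0.05) / cfg$cadence_hz
      s <- min(findInterval(mid, starts), nrow(seqn))
      tc <- (starts[s] + ends[s]) / 2
      c(locomode:::mode_envelopes(cfg, seqn$mode[s], tt, tc),
        locomode:::mode_kinematics(cfg, seqn$mode[s], tt, tc))
    }, numeric(20 * 24)))
  }

  V <- do.call(rbind, lapply(ds, oracle_vecs))
  y <- unlist(lapply(ds, `[[`, "window_labels"))
  centroids <- t(sapply(split(seq_along(y), y), function(i) colMeans(V[i, , drop = FALSE])))
  d2 <- outer(rowSums(V^2), rowSums(centroids^2), "+") - 2 * V %*% t(centroids)
  pred <- rownames(centroids)[max.col(-d2)]
  expect_gt(mean(pred == y), 0.9)
})

test_that("recordings round-trip through the delimited text format", {
  cfg <- small_cfg()
  rec <- generate_trial(cfg, data.frame(mode = "SD", duration = 1), seed = 17)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs_semg, rec$fs_semg)
  expect_equal(back$fs_imu, rec$fs_imu)
  expect_identical(back$window_labels, rec$window_labels)
  expect_equal(unname(back$semg), unname(rec$semg), tolerance = 1e-6)
  expect_equal(unname(back$imu), unname(rec$imu), tolerance = 1e-6)
})
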