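# Synthetic call and soundscape generation.

test_that("age pitch scale anchors, monotonicity and bounds", {
  expect_equal(age_pitch_scale(1), 1.0)
  expect_equal(age_pitch_scale(42), 0.6)
  sc <- age_pitch_scale(1:42)
  expect_true(all(diff(sc) < 0))
  expect_error(age_pitch_scale(-1), "age_days")
  expect_error(age_pitch_scale(50), "age_days")
})

test_that("synthesized ages shift measured fundamentals by the scale", {
  set.seed(4)
  ev1 <- sample_call_event("SP", 0, age_days = 1)
  ev42 <- ev1
  ev42[c("f0_start", "f0_end")] <- ev1[c("f0_start", "f0_end")] * 0.6
  f1 <- measure_f0(ev1)
  f42 <- measure_f0(ev42)
  expect_lt(abs(f42 / f1 - 0.6) / 0.6, 0.05)
})

test_that("call contours match their declared direction", {
  set.seed(7)
  fs <- 48000
  # ascending PN ridge rises monotonically (smoothed)
  pn <- sample_call_event("PN", 0, 7)
  pn$duration <- 0.15
  tr <- dominant_freq_track(synth_call(pn, fs), fs, nfft = 512, hop = 64)
  inner <- tr[3:(length(tr) - 2)]
  expect_gt(tail(inner, 1), head(inner, 1))
  expect_true(all(diff(inner) > -100))  # monotone up to bin resolution
  # descending SP
  sp <- sample_call_event("SP", 0, 7)
  sp$duration <- 0.2
  tr <- dominant_freq_track(synth_call(sp, fs), fs, nfft = 512, hop = 64)
  inner <- tr[3:(length(tr) - 2)]
  expect_lt(tail(inner, 1), head(inner, 1))
  # bow-shaped W: interior peak above both ends
  w <- sample_call_event("W", 0, 7)
  w$n_syllables <- 1
  w$duration <- 0.5
  tr <- dominant_freq_track(synth_call(w, fs), fs, nfft = 1024, hop = 128)
  inner <- tr[2:(length(tr) - 1)]
  expect_gt(max(inner), head(inner, 1) + 100)
  expect_gt(max(inner), tail(inner, 1) + 100)
  mid <- which.max(inner)
  expect_gt(mid, 1)
  expect_lt(mid, length(inner))
})

test_that("repetitive DC calls contain the requested number of bursts", {
  ev <- data.frame(type = "DC", onset = 0, duration = 4 * 0.3 + 3 * 0.08,
                   f0_start = 3800, f0_end = 2800, contour = "descending",
                   n_syllables = 4, level_db = 10, age_days = 7,
                   stringsAsFactors = FALSE)
  w <- synth_call(ev, 48000)
  # 2 ms moving-RMS envelope; bursts are separated by silent gaps much
  # longer than any within-syllable envelope dip
  e2 <- stats::filter(w^2, rep(1 / 96, 96), sides = 2)
  e2[is.na(e2)] <- 0
  on <- as.numeric(e2) > 0.01 * max(e2, na.rm = TRUE)
  runs <- rle(on)
  long_gaps <- sum(!runs$values & runs$lengths > 1920 &
                     seq_along(runs$values) != 1 &
                     seq_along(runs$values) != length(runs$values))
  expect_equal(long_gaps + 1, 4)
})

test_that("rendering is deterministic and rejects Nyquist violations", {
  set.seed(9)
  ev <- sample_call_event("DC", 0, 1)
  expect_identical(synth_call(ev, 48000), synth_call(ev, 48000))
  expect_error(synth_call(ev, 6000), "Nyquist")
})

test_that("level presets order call energies (DC loudest)", {
  set.seed(10)
  rms <- sapply(c("DC", "SP", "PN", "W"), function(ty) {
    ev <- sample_call_event(ty, 0, 7)
    w <- synth_call(ev, 48000)
    sqrt(mean(w^2))
  })
  expect_gt(rms["DC"], rms["SP"])
  expect_gt(rms["SP"], rms["PN"] * 0.99)
  expect_gt(rms["SP"], rms["W"] * 0.99)
})

test_that("zero-rate profiles give no events; seeds change events", {
  prof0 <- diurnal_profile(list(SP = 0, DC = 0))
  cfg <- soundscape_config(600, prof0, seed = 1)
  expect_equal(nrow(sample_events(cfg)), 0)
  prof <- diurnal_profile(list(SP = 6))
  e1 <- sample_events(soundscape_config(600, prof, seed = 1))
  e2 <- sample_events(soundscape_config(600, prof, seed = 2))
  expect_gt(nrow(e1), 0)
  expect_false(identical(e1$onset, e2$onset))
  # determinism
  e1b <- sample_events(soundscape_config(600, prof, seed = 1))
  expect_identical(e1, e1b)
})

test_that("event counts follow the configured Poisson rate", {
  # constant 6 s/min of SP with mean duration 0.125 s over 20 minutes:
  # expected count 20 * 6 / 0.125 = 960 per soundscape
  prof <- diurnal_profile(list(SP = 6))
  counts <- sapply(1:12, function(s) {
    cfg <- soundscape_config(1200, prof, seed = s)
    nrow(sample_events(cfg))
  })
  expected <- 20 * 6 / 0.125
  se <- sqrt(expected / 12)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("ground-truth minute durations agree with a brute-force oracle", {
  prof <- diurnal_profile(list(SP = 8, DC = 3, W = 1, PN = 2, OV = 1))
  cfg <- soundscape_config(300, prof, seed = 21)
  ev <- sample_events(cfg)
  md <- minute_durations_from_events(ev, 300)
  # oracle: per minute and type, sum interval intersections independently
  for (m in 0:4) {
    for (ty in CALL_TYPES) {
      sel <- ev[ev$type == ty, , drop = FALSE]
      ov <- 0
      if (nrow(sel)) for (i in seq_len(nrow(sel))) {
        lo <- max(sel$onset[i], m * 60)
        hi <- min(sel$onset[i] + sel$duration[i], (m + 1) * 60)
        ov <- ov + max(0, hi - lo)
      }
      expect_equal(unname(md[m + 1, ty]), ov, tolerance = 1e-12)
    }
  }
  expect_true(all(md >= 0 & md <= 60))
})

test_that("without overlap, per-minute durations sum to at most 60 s", {
  prof <- diurnal_profile(list(SP = 25, DC = 20, OV = 15))
  cfg <- soundscape_config(300, prof, seed = 3, allow_overlap = FALSE)
  ev <- sample_events(cfg)
  # events must be disjoint
  ends <- head(ev$onset + ev$duration, -1)
  expect_true(all(ev$onset[-1] >= ends - 1e-12))
  md <- minute_durations_from_events(ev, 300)
  expect_true(all(rowSums(md) <= 60 + 1e-9))
})

test_that("frame labels follow the frame-midpoint rule", {
  ev <- data.frame(type = "SP", onset = 0, duration = 0.48,
                   f0_start = 3500, f0_end = 2500, contour = "descending",
                   n_syllables = 1, level_db = 0, age_days = 7,
                   stringsAsFactors = FALSE)
  fl <- frame_labels_from_events(ev, 60)
  expect_equal(length(fl), ceiling(60 / 0.24))
  expect_equal(which(fl == "SP"), c(1, 2))
  # a call missing all midpoints labels nothing
  ev$onset <- 0.125; ev$duration <- 0.1  # covers no frame center
  expect_false(any(frame_labels_from_events(ev, 60) != "background"))
  # the louder of two overlapping calls wins the frame
  two <- rbind(
    data.frame(type = "DC", onset = 0.0, duration = 0.5, f0_start = 3800,
               f0_end = 2800, contour = "descending", n_syllables = 1,
               level_db = 10, age_days = 7, stringsAsFactors = FALSE),
    data.frame(type = "W", onset = 0.0, duration = 0.5, f0_start = 1200,
               f0_end = 1300, contour = "bow", n_syllables = 1,
               level_db = -6, age_days = 7, stringsAsFactors = FALSE))
  expect_equal(unique(frame_labels_from_events(two, 0.48)), "DC")
})

test_that("soundscapes are deterministic and respect the SNR definition", {
  prof <- diurnal_profile(list(SP = 10, DC = 4))
  cfg <- soundscape_config(60, prof, seed = 12, snr_db = 20)
  s1 <- synth_soundscape(cfg)
  s2 <- synth_soundscape(cfg)
  expect_identical(s1$wave, s2$wave)
  expect_identical(s1$truth, s2$truth)
  # empty profile: pure background, zero durations
  s0 <- synth_soundscape(soundscape_config(60, diurnal_profile(list(SP = 0)),
                                           seed = 2))
  expect_true(all(s0$truth$minute_durations == 0))
  expect_true(all(s0$truth$frame_labels == "background"))
  expect_gt(sd(s0$wave), 0)
})

test_that("fixtures round-trip losslessly at the label level", {
  dir <- tempfile("fix")
  prof <- diurnal_profile(list(SP = 15, DC = 5, PN = 3, W = 2, OV = 1))
  for (cfg in list(
    soundscape_config(60, diurnal_profile(list(SP = 0)), seed = 1),
    soundscape_config(60, diurnal_profile(list(SP = 0.8)), seed = 5),
    soundscape_config(120, prof, seed = 6))) {
    sc <- synth_soundscape(cfg)
    write_fixture(sc, dir)
    back <- read_fixture(dir)
    expect_equal(back$sample_rate, cfg$sample_rate)
    expect_equal(length(back$wave), length(sc$wave))
    expect_identical(back$frame_labels, sc$truth$frame_labels)
    expect_equal(back$minute_durations, sc$truth$minute_durations,
                 tolerance = 1e-12)
    expect_equal(back$events$onset_s, sc$truth$events$onset,
                 tolerance = 1e-12)
    expect_identical(back$events$type, sc$truth$events$type)
  }
})

test_that("WAV I/O preserves samples to 16-bit precision", {
  x <- sin(2 * pi * 440 * (0:999) / 8000) * 0.8
  f <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f)
  back <- read_wav(f)
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$wave, x, tolerance = 1 / 32000)
})
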