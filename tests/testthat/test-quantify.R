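# Threshold-based duration quantification and calendar binning.

make_raster_rows <- function(spec_rows) {
  # spec_rows: list of (class, prob); remaining mass spread over others
  t(sapply(spec_rows, function(s) {
    p <- rep((1 - s[[2]]) / 5, 6)
    names(p) <- MODEL_CLASSES
    p[s[[1]]] <- s[[2]]
    p
  }))
}

test_that("detected frames convert to seconds at 0.24 s per frame", {
  rows <- c(replicate(10, list(list("DC", 0.8)), simplify = FALSE),
            replicate(240, list(list("background", 0.9)),
                      simplify = FALSE))
  raster <- make_raster_rows(unlist(rows, recursive = FALSE))
  md <- threshold_durations(raster)
  expect_equal(md$DC, 10 * 0.24)
  expect_equal(md$SP + md$W + md$PN + md$OV, 0)
  # saturation: all 250 rows detected for SP gives the full minute
  sat <- make_raster_rows(replicate(250, list("SP", 0.95),
                                    simplify = FALSE))
  md2 <- threshold_durations(sat)
  expect_equal(md2$SP, 60)
  expect_equal(md2$DC + md2$W + md2$PN + md2$OV, 0)
})

test_that("the threshold is inclusive and normalization is enforced", {
  r <- make_raster_rows(list(list("W", 0.7), list("W", 0.699999)))
  md <- threshold_durations(r)
  expect_equal(md$W, 0.24)  # >= 0.7 counts, just below does not
  bad <- matrix(0.5, 4, 6)
  expect_error(threshold_durations(bad), "sum to 1")
})

test_that("quantification matches a brute-force row scan on random rasters", {
  for (s in 1:200) {
    raster <- random_raster(50, seed = s, sharp = TRUE)
    md <- threshold_durations(raster)
    for (ty in CALL_TYPES) {
      cnt <- 0
      for (i in seq_len(nrow(raster)))
        if (raster[i, ty] >= 0.7) cnt <- cnt + 1
      expect_identical(md[[ty]][1], cnt * 0.24)
    }
    # mutual exclusivity: normalized rows above 0.7 are unique, so the
    # five types can never sum past the minute
    expect_lte(sum(md[1, CALL_TYPES]), 60 + 1e-9)
  }
})

test_that("rasters spanning minutes split on wall-clock boundaries", {
  raster <- random_raster(500, seed = 1, sharp = TRUE)
  md <- threshold_durations(structure(
    list(scores = raster, frame_duration = 0.24, start_clock = 120),
    class = "prob_raster"))
  expect_equal(md$minute, c(2, 3))
  # totals agree with an unsplit scan
  all_md <- threshold_durations(raster)
  for (ty in CALL_TYPES)
    expect_equal(sum(md[[ty]]), sum(all_md[[ty]]))
})

test_that("hourly aggregation averages minutes and keeps gaps missing", {
  mins <- data.frame(minute = 0:59, clock_hour = 0)
  for (ty in CALL_TYPES) mins[[ty]] <- 5
  h <- aggregate_hourly(mins)
  expect_equal(h$SP, 5)
  expect_equal(h$n_minutes, 60)
  mins$SP <- rep(c(0, 10), 30)
  expect_equal(aggregate_hourly(mins)$SP, 5)
  # a missing hour yields no row rather than a zero
  mins2 <- mins[mins$minute < 30, ]
  mins2$minute <- mins2$minute + 120  # hour 2 only
  h2 <- aggregate_hourly(rbind(mins, mins2))
  expect_equal(h2$hour, c(0, 2))
  expect_equal(h2$n_minutes, c(60, 30))
  # random tables match the obvious mean
  set.seed(4)
  mins$DC <- runif(60, 0, 60)
  expect_equal(aggregate_hourly(mins)$DC, mean(mins$DC))
})

test_that("diurnal bins partition the clock as specified", {
  expect_equal(as.character(bin_time_of_day(23)), "night")
  expect_equal(as.character(bin_time_of_day(4)), "morning")
  expect_equal(as.character(bin_time_of_day(9.99)), "morning")
  expect_equal(as.character(bin_time_of_day(10)), "midday")
  expect_equal(as.character(bin_time_of_day(16)), "evening")
  expect_equal(as.character(bin_time_of_day(22)), "night")
  expect_equal(as.character(bin_time_of_day(0)), "night")
  tab <- table(bin_time_of_day(0:23))
  expect_true(all(tab == 6))
  expect_error(bin_time_of_day(24), "hour_of_day")
  expect_error(bin_time_of_day(-1), "hour_of_day")
})

test_that("rearing phases partition days 0-41", {
  expect_equal(as.character(assign_phase(0)), "starter")
  expect_equal(as.character(assign_phase(9)), "starter")
  expect_equal(as.character(assign_phase(10)), "grower")
  expect_equal(as.character(assign_phase(22)), "grower")
  expect_equal(as.character(assign_phase(23)), "finisher")
  expect_equal(as.character(assign_phase(41)), "finisher")
  expect_equal(sum(table(assign_phase(0:41))), 42)
  expect_error(assign_phase(42), "age_days")
  expect_error(assign_phase(-1), "age_days")
})

test_that("bin means weight hours by their recorded minutes", {
  h <- data.frame(hour = c(4, 5, 10), clock_hour = c(4, 5, 10),
                  n_minutes = c(60, 30, 60))
  for (ty in CALL_TYPES) h[[ty]] <- c(3, 6, 9)
  bm <- bin_means(h)
  expect_equal(bm$SP[bm$bin == "morning"], (3 * 60 + 6 * 30) / 90)
  expect_equal(bm$SP[bm$bin == "midday"], 9)
  expect_true(is.na(bm$SP[bm$bin == "night"]))
})
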