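test_that("detrending recovers a sinusoidal seasonal cycle under a linear trend", {
  sim <- make_station_record(1990:2005, trend = 2, amplitude = 6, noise_sd = 0)
  cyc <- seasonal_cycle(sim$record, epoch = c(1994, 2001))
  months <- 1:12
  expected <- 6 * sin(2 * pi * (months - 12) / 12)
  expect_equal(cyc$anomaly, expected, tolerance = 1e-6)
  expect_lt(abs(sum(cyc$anomaly)), 1e-6)
})

test_that("a trendless constant record has a flat seasonal cycle", {
  rec <- tidyr::expand_grid(year = 1990:1999, month = 1:12) |>
    dplyr::mutate(ppm = 350)
  cyc <- seasonal_cycle(rec, epoch = c(1992, 1997))
  expect_equal(cyc$anomaly, rep(0, 12))
})

test_that("an amplitude-growing record deepens its later-epoch minimum", {
  sim <- make_station_record(1974:2005, deepening = 0.1, noise_sd = 0)
  early <- seasonal_cycle(sim$record, epoch = c(1975, 1980))
  late <- seasonal_cycle(sim$record, epoch = c(2000, 2005))
  expect_lt(min(late$anomaly), min(early$anomaly))
})

test_that("seasonal cycle errors on short epochs and gappy records", {
  sim <- make_station_record(1990:2005)
  expect_error(seasonal_cycle(sim$record, epoch = c(1994, 1996)), "4 years")
  gappy <- sim$record
  gappy$ppm[gappy$year %in% 1994:1995] <- NA
  expect_error(seasonal_cycle(gappy, epoch = c(1993, 1996)), "missing")
})

test_that("drawdown change is near zero for a stationary seasonal cycle", {
  sim <- make_station_record(1974:2005, deepening = 0, noise_sd = 0)
  res <- drawdown_change(sim$record)
  expect_lt(abs(res$change), 1e-9)
  expect_true(all(tidy(res)$slope <= 0))
})

test_that("drawdown change recovers a prescribed deepening rate", {
  # noiseless record: only discretisation and smoothing-edge error remain
  clean <- make_station_record(1974:2005, deepening = 0.045, noise_sd = 0)
  truth <- clean$truth$drawdown_change()
  expect_lt(truth, 0)
  res0 <- drawdown_change(clean$record)
  expect_lt(abs(res0$change - truth) / abs(truth), 0.05)
  # noisy record: estimate consistent with truth within its own uncertainty
  noisy <- make_station_record(1974:2005, deepening = 0.045, noise_sd = 0.2,
                               seed = 4)
  res <- drawdown_change(noisy$record)
  expect_lt(abs(res$change - truth), 3 * res$change_sd)
  expect_true(res$change_sd >= 0 && is.finite(res$change))
})

test_that("the slope statistic ignores constants and linear trends", {
  sim <- make_station_record(1974:2005, deepening = 0.05, noise_sd = 0)
  base <- drawdown_change(sim$record)
  # add a constant and an extra pure linear trend
  shifted <- sim$record |>
    dplyr::mutate(t = (year - min(year)) + (month - 1) / 12,
                  ppm = ppm + 25 + 0.8 * t) |>
    dplyr::select(-t)
  res <- drawdown_change(shifted)
  expect_equal(res$change, base$change, tolerance = 1e-9)
  # and equals the result on a linearly detrended record
  detr <- sim$record |>
    dplyr::mutate(t = (year - min(year)) + (month - 1) / 12,
                  ppm = ppm - 1.7 * t) |>
    dplyr::select(-t)
  expect_equal(drawdown_change(detr)$change, base$change, tolerance = 1e-9)
})

test_that("the drawdown change is invariant under a seasonal phase shift", {
  a <- make_station_record(1974:2005, deepening = 0.05, phase = 12)
  b <- make_station_record(1974:2005, deepening = 0.05, phase = 3)
  ra <- drawdown_change(a$record)
  rb <- suppressWarnings(drawdown_change(b$record))
  expect_equal(rb$change, ra$change, tolerance = 0.02)
})

test_that("gap handling interpolates short gaps and rejects gappy windows", {
  sim <- make_station_record(1974:2005, deepening = 0.045, noise_sd = 0)
  base <- drawdown_change(sim$record)
  gappy <- sim$record
  gappy$ppm[gappy$year == 1990 & gappy$month == 2] <- NA  # winter gap, 1 month
  res <- drawdown_change(gappy)
  expect_equal(res$change, base$change, tolerance = 0.05)
  worse <- sim$record
  worse$ppm[worse$year %in% 1985:1990] <- NA
  expect_error(drawdown_change(worse), "missing")
})

test_that("the NOAA monthly text format round-trips through the reader", {
  sim <- make_station_record(1990:1995)
  path <- withr::local_tempfile(fileext = ".txt")
  lines <- c("# synthetic station record, NOAA/ESRL monthly surface format",
             "# site year month value",
             sprintf("SYN %d %d %.2f", sim$record$year, sim$record$month,
                     sim$record$ppm))
  lines[10] <- sub("[0-9.]+$", "-999.99", lines[10])  # one flagged-missing month
  writeLines(lines, path)
  rec <- read_noaa_monthly(path)
  expect_equal(nrow(rec), 6 * 12)
  expect_equal(unique(rec$site), "SYN")
  expect_true(is.na(rec$ppm[8]))  # line 10 is the 8th data row
  expect_equal(rec$ppm[-8], as.numeric(sprintf("%.2f", sim$record$ppm[-8])))
})

test_that("cycle amplitude grows with the deepening rate", {
  sim <- make_station_record(1974:2005, deepening = 0.1, noise_sd = 0)
  amp <- cycle_amplitude(sim$record) |> dplyr::filter(!is.na(amplitude))
  expect_gt(utils::tail(amp$amplitude, 1), utils::head(amp$amplitude, 1))
})
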