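# Preprocessing chain: filter response, epoching, bad-channel repair,
# artifact rejection, ocular regression, re-referencing, cropping.

make_sine_recording <- function(freqs, amps, dur_s = 30, fs = 512) {
  t <- seq_len(dur_s * fs) / fs
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  list(data = rbind(x, x), fs = fs,
       events = data.frame(sample = integer(0), kind = character(0),
                           velocity = numeric(0), score = numeric(0)),
       channel_names = c("A", "B"))
}

test_that("band-pass filter preserves the passband and removes drift", {
  rec <- make_sine_recording(25, 1)
  out <- bandpass_filter(rec)
  mid <- 5000:10000
  expect_equal(sd(out$data[1, mid]), sd(rec$data[1, mid]), tolerance = 0.05)

  # 0.05 Hz drift of amplitude 100 is suppressed below 10 (filter-response
  # oracle: |H| at 0.05 Hz for the order-4 high-pass cascade is ~1e-8)
  drift <- make_sine_recording(c(0.05, 10), c(100, 1), dur_s = 60)
  outd <- bandpass_filter(drift)
  resid <- outd$data[1, 10000:20000] -
    sin(2 * pi * 10 * (10000:20000) / 512)
  expect_lt(max(abs(resid)), 10)

  # stopband: 60 Hz attenuated by at least 20 dB
  hi <- make_sine_recording(60, 1)
  outh <- bandpass_filter(hi)
  expect_lt(sd(outh$data[1, mid]) / sd(hi$data[1, mid]), 0.1)

  # all-zero input stays zero
  z <- make_sine_recording(10, 0)
  expect_equal(max(abs(bandpass_filter(z)$data)), 0)

  expect_error(bandpass_filter(list(data = matrix(0, 2, 100), fs = 80)),
               "Nyquist")
})

test_that("epochs are aligned to wind onsets with metadata joined", {
  rec <- make_tiny_recording(seed = 31, trials = 8)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data), c(64, 11 * 512, 8))
  expect_equal(ep$meta$velocity, rec$schedule$velocity)
  # sample 513 of each epoch is the wind_on sample itself
  on <- rec$events$sample[rec$events$kind == "wind_on"]
  for (i in c(1, 5)) {
    expect_equal(ep$data[, 513, i], rec$data[, on[i]])
    expect_equal(ep$meta$onset_sample[i], on[i])
  }
  # an onset too close to the file start is skipped with a warning
  rec2 <- rec
  rec2$events$sample[rec2$events$kind == "wind_on"][1] <- 100L
  expect_warning(ep2 <- extract_epochs(rec2), "skipped")
  expect_equal(dim(ep2$data)[3], 7)
})

test_that("bad channels are detected and spherical-spline interpolated", {
  rec <- make_tiny_recording(seed = 32, trials = 4)
  ep <- extract_epochs(rec)
  # corrupt one channel with 100x amplitude noise
  bad <- 17L
  withr::with_seed(1, {
    ep_bad <- ep
    ep_bad$data[bad, , ] <- 100 * sd(ep$data) *
      rnorm(prod(dim(ep$data)[2:3]))
  })
  fixed <- detect_and_interpolate_bad_channels(ep_bad)
  expect_identical(fixed$bad_channels, ep$channel_names[bad])
  # interpolation must land near the true (uncorrupted) signal
  rel <- sd(fixed$data[bad, , ] - ep$data[bad, , ]) / sd(ep$data[bad, , ])
  expect_lt(rel, 0.6)
  # clean data pass through untouched
  expect_identical(detect_and_interpolate_bad_channels(ep), ep)
})

test_that("spherical-spline interpolation recovers a smooth field", {
  # closed-form oracle: a low-degree harmonic field sampled at the montage
  pos <- as.matrix(standard_montage()[, c("x", "y", "z")])
  u <- pos / sqrt(rowSums(pos^2))
  field <- 3 * u[, 3]^2 - 1 + u[, 2]          # P2(z) + y
  drop_ch <- 30L
  Tm <- windeeg:::spline_interpolation_matrix(pos, setdiff(1:64, drop_ch),
                                              drop_ch)
  est <- drop(Tm %*% field[-drop_ch])
  expect_lt(abs(est - field[drop_ch]) / max(abs(field)), 0.05)
})

test_that("peak-to-peak rejection flags exactly the spiked epochs", {
  rec <- make_tiny_recording(seed = 33, trials = 8)
  ep <- extract_epochs(rec)
  clean <- reject_artifact_epochs(ep)
  expect_equal(sum(clean$meta$rejected), 0)     # clean by construction
  ep$data[5, 100, 3] <- 500
  ep$data[5, 200, 3] <- -500
  flagged <- reject_artifact_epochs(ep)
  expect_equal(which(flagged$meta$rejected), 3L)
  # idempotence
  expect_identical(reject_artifact_epochs(flagged)$meta, flagged$meta)
  ep$data <- ep$data * 0 + 1000 * rnorm(length(ep$data))
  expect_error(reject_artifact_epochs(ep), "all epochs rejected")
})

test_that("ocular regression removes a known EOG admixture", {
  rec <- make_tiny_recording(seed = 34, trials = 4)
  ep <- extract_epochs(rec)
  d <- dim(ep$data)
  withr::with_seed(2, {
    eog <- matrix(rnorm(d[2] * d[3]), d[2], d[3])
    b <- runif(d[1], -2, 2)
    contaminated <- ep
    for (i in seq_len(d[3]))
      contaminated$data[, , i] <- contaminated$data[, , i] +
        b %o% eog[, i]
    cleaned <- remove_ocular_artifacts(contaminated, eog = eog)
    rel <- sd(cleaned$data - ep$data) / sd(ep$data)
    expect_lt(rel, 0.01)
    # zero EOG: identity
    expect_equal(remove_ocular_artifacts(ep, eog = eog * 0)$data, ep$data)
    # missing EOG: skipped with warning
    expect_warning(same <- remove_ocular_artifacts(ep), "skipped")
    expect_identical(same$data, ep$data)
  })
})

test_that("average re-reference zeroes the channel mean and keeps differences", {
  rec <- make_tiny_recording(seed = 35, trials = 4)
  ep <- extract_epochs(rec)
  rr <- rereference_average(ep)
  cm <- colMeans(matrix(rr$data, dim(rr$data)[1]))
  expect_lt(max(abs(cm)), 1e-10)
  # idempotence
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
  # bipolar differences unchanged
  expect_equal(rr$data[3, , 2] - rr$data[9, , 2],
               ep$data[3, , 2] - ep$data[9, , 2], tolerance = 1e-10)
})

test_that("crop splits epochs into 512-sample baseline and 4096-sample analysis", {
  rec <- make_tiny_recording(seed = 36, trials = 8)
  ep <- extract_epochs(rec)
  ep$meta$rejected[2] <- TRUE
  cr <- crop_analysis_window(ep)
  expect_equal(dim(cr$baseline$data), c(64, 512, 7))
  expect_equal(dim(cr$analysis$data), c(64, 4096, 7))
  # analysis starts exactly at t = 2 s (sample 1537 of the epoch)
  expect_equal(cr$analysis$data[, 1, 1], ep$data[, 3 * 512 + 1, 1])
  expect_equal(cr$baseline$data[, , 1], ep$data[, 1:512, 1])
  # rejected trials are gone from the metadata
  expect_false(2 %in% cr$analysis$meta$trial)
})

test_that("preprocessing metadata survives the full chain", {
  rec <- make_tiny_recording(seed = 37, trials = 8)
  pp <- preprocess_recording(rec)
  expect_equal(pp$analysis$meta$velocity,
               rec$schedule$velocity[!pp$epochs$meta$rejected])
  expect_equal(pp$analysis$meta$score,
               rec$events$score[rec$events$kind == "wind_on"][!pp$epochs$meta$rejected])
})
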