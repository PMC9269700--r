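test_that("time-domain features match direct arithmetic", {
  expect_equal(time_domain_feature(c(1, -1, 2, -2), "MAV"), 1.5)
  expect_equal(time_domain_feature(c(0, 1, 3), "MWL"), 1.5)
  # DRMS of a linear ramp with step k equals |k|
  expect_equal(time_domain_feature(seq(0, 10, by = 0.25), "DRMS"), 0.25)
  expect_equal(time_domain_feature(seq(8, 0, by = -2), "DRMS"), 2)
  expect_error(time_domain_feature(1, "MWL"), "too short")
})

test_that("STFT band feature picks the band containing the tone", {
  spec <- feature_spec("STFT", window_ms = 500)
  expect_equal(unname(stft_band_feature(rep(0, 250), spec)), c(0, 0, 0))
  t <- (0:249) / 500
  out80 <- stft_band_feature(sin(2 * pi * 80 * t), spec)
  expect_length(out80, 3)
  expect_true(out80["STFTmid"] > out80["STFTlow"])
  expect_true(out80["STFTmid"] > out80["STFThig"])
  out30 <- stft_band_feature(sin(2 * pi * 30 * t), spec)
  expect_true(out30["STFTlow"] > out30["STFThig"])
  out150 <- stft_band_feature(sin(2 * pi * 150 * t), spec)
  expect_true(out150["STFThig"] > out150["STFTlow"])
  expect_error(stft_band_feature(rep(0, 50), spec), "Hanning")
})

test_that("SWT cD3 feature is band-selective and absolutely homogeneous", {
  spec <- feature_spec("SWT", window_ms = 500)
  expect_equal(swt_feature(rep(0, 250), spec), 0)
  set.seed(9)
  x <- rnorm(250)
  expect_equal(swt_feature(-2.5 * x, spec), 2.5 * swt_feature(x, spec),
               tolerance = 1e-12)
  # level-3 detail band at fs 500 is ~31-62.5 Hz
  t <- (0:249) / 500
  expect_gt(swt_feature(sin(2 * pi * 45 * t), spec),
            swt_feature(sin(2 * pi * 150 * t), spec))
  expect_error(swt_feature(rep(0, 6), spec), "shorter than 8")
})

test_that("assembled features equal per-window single-feature evaluation", {
  set.seed(13)
  x <- matrix(rnorm(2300 * 2), ncol = 2)
  rec <- emg_recording(x, 500, stage = "preprocessed")
  spec <- feature_spec("ALL", window_ms = 300)
  fm <- assemble_features(rec, spec)
  kept <- attr(fm, "kept")
  L <- 150
  idx <- sample(seq_along(kept), 12)
  sspec <- feature_spec("ALL", window_ms = 300)
  for (i in idx) {
    for (ch in 1:2) {
      w <- x[(kept[i] - L + 1):kept[i], ch]
      base <- (ch - 1) * 7
      expect_equal(fm[i, base + 1], time_domain_feature(w, "MAV"),
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(fm[i, base + 2], time_domain_feature(w, "MWL"),
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(fm[i, base + 3], time_domain_feature(w, "DRMS"),
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(unname(fm[i, base + 4:6]),
                   unname(stft_band_feature(w, sspec)), tolerance = 1e-9)
      expect_equal(fm[i, base + 7], swt_feature(w, sspec),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("trimming and decimation arithmetic gives 82 rows for a 4.6 s trial", {
  rec <- emg_recording(matrix(rnorm(2300 * 12), ncol = 12), 500,
                       stage = "preprocessed")
  fm <- assemble_features(rec, feature_spec("ALL"))
  expect_equal(nrow(fm), 82)
  expect_equal(ncol(fm), 12 * 7)
  # index-enumeration oracle for the kept timesteps
  expect_equal(attr(fm, "kept"), seq.int(251L, 2300L, by = 25L))
  expect_error(assemble_features(
    emg_recording(matrix(rnorm(200), ncol = 1), 500, stage = "preprocessed"),
    feature_spec("MAV")), "shorter")
})

test_that("row count is invariant to the window lengths on the grid", {
  set.seed(2)
  x <- matrix(rnorm(2300), ncol = 1)
  pre <- emg_recording(x, 500, stage = "preprocessed")
  counts <- sapply(c(100, 200, 300, 400, 500), function(wf) {
    nrow(assemble_features(pre, feature_spec("MAV", window_ms = wf)))
  })
  expect_true(all(counts == counts[1]))
  # and to the normalization window
  counts2 <- sapply(c(100, 300, 500), function(wn) {
    rec <- sliding_window_normalize(pre, normalization_spec("swn", wn))
    nrow(assemble_features(rec, feature_spec("MAV", window_ms = 200)))
  })
  expect_true(all(counts2 == counts[1]))
})

test_that("features are finite and the nonnegative ones stay nonnegative", {
  set.seed(77)
  for (i in 1:5) {
    x <- matrix(rnorm(1500, sd = 10^runif(1, -3, 3)), ncol = 1)
    fm <- assemble_features(
      emg_recording(x, 500, stage = "preprocessed"), feature_spec("ALL"))
    expect_true(all(is.finite(fm)))
    nonneg <- grepl("MAV|DRMS|STFT|SWT", colnames(fm))
    expect_true(all(fm[, nonneg] >= 0))
  }
})

test_that("feature columns are channel-major with component names", {
  rec <- emg_recording(matrix(rnorm(1300 * 3), ncol = 3), 500,
                       stage = "preprocessed")
  fm <- assemble_features(rec, feature_spec("STFT"))
  expect_equal(ncol(fm), 9)
  expect_equal(colnames(fm)[1:3],
               c("ch01_STFTlow", "ch01_STFTmid", "ch01_STFThig"))
  fm2 <- assemble_features(rec, feature_spec("MWL"))
  expect_equal(colnames(fm2), c("ch01_MWL", "ch02_MWL", "ch03_MWL"))
})
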