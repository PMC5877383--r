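test_that("the per-channel feature bank has exactly 42 named dimensions", {
  nm <- semg_feature_names()
  expect_length(nm, 42)
  expect_false(anyDuplicated(nm) > 0)
  set.seed(31)
  win <- list(samples = matrix(rnorm(250), ncol = 1), label = "MF",
              trial = 1L, start = 0L)
  fm1 <- extract_features(list(win), fs = 1000)
  expect_equal(colnames(fm1$values), nm)
  win4 <- list(samples = matrix(rnorm(1000), ncol = 4,
                                dimnames = list(NULL, c("APL", "ECR", "ECU", "FCU"))),
               label = "MF", trial = 1L, start = 0L)
  expect_equal(ncol(extract_features(list(win4), 1000)$values), 168)
  win2 <- list(samples = win4$samples[, 1:2], label = "MF",
               trial = 1L, start = 0L)
  expect_equal(ncol(extract_features(list(win2), 1000)$values), 84)
})

test_that("a zero window gives zero amplitude features and zero counts", {
  f <- extract_time_features(numeric(100))
  expect_equal(unname(f[c("MAV", "RMS", "VAR", "WL", "SSI")]), rep(0, 5))
  expect_equal(unname(f[c("ZC1", "ZC2", "SSC")]), rep(0, 3))
  expect_equal(unname(f[paste0("WAMP", 1:5)]), rep(0, 5))
})

test_that("closed-form amplitude features are recovered on a unit sinusoid", {
  t <- seq(0, 0.999, by = 1e-3)   # 10 full cycles, 100 samples per cycle
  x <- sin(2 * pi * 10 * t)
  f <- extract_time_features(x)
  expect_equal(unname(f["RMS"]), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(unname(f["MAV"]), 2 / pi, tolerance = 1e-3)
  expect_equal(unname(f["SSI"]), 500, tolerance = 1)
})

test_that("zero crossings count sign changes with a zero deadband", {
  f <- extract_time_features(c(1, -1, 1, -1))
  expect_equal(unname(f["ZC1"]), 3)
})

test_that("amplitude features scale as expected with input gain", {
  set.seed(32)
  x <- rnorm(500)
  f1 <- extract_time_features(x)
  f3 <- extract_time_features(3 * x)
  for (nm in c("MAV", "MMAV1", "MMAV2", "RMS", "WL"))
    expect_equal(unname(f3[nm]), 3 * unname(f1[nm]), tolerance = 1e-10)
  for (nm in c("VAR", "SSI"))
    expect_equal(unname(f3[nm]), 9 * unname(f1[nm]), tolerance = 1e-10)
  # RMS-relative thresholds make the count features gain-invariant
  for (nm in c("ZC1", "ZC2", "SSC", paste0("WAMP", 1:5)))
    expect_equal(unname(f3[nm]), unname(f1[nm]))
})

test_that("median frequency locates a pure spectral line within one bin", {
  t <- seq(0, 0.999, by = 1e-3)
  f <- extract_frequency_features(sin(2 * pi * 100 * t), fs = 1000)
  expect_lt(abs(f[["MDF"]] - 100), 1000 / 256)   # one Welch bin
})

test_that("mean frequency of band-limited white noise sits mid-band", {
  set.seed(33)
  x <- signal::filtfilt(signal::butter(8, c(10, 450) / 500, "pass"),
                        rnorm(60000))
  f <- extract_frequency_features(x, fs = 1000,
                                  feature_spec(welch_seg_len = 1024))
  expect_lt(abs(f[["MNF"]] - 230), 10)
})

test_that("MDF of two equal spectral lines lies between them, MNF at their mean", {
  t <- seq(0, 1.999, by = 1e-3)
  x <- sin(2 * pi * 100 * t) + sin(2 * pi * 200 * t)
  f <- extract_frequency_features(x, fs = 1000,
                                  feature_spec(welch_seg_len = 1000))
  expect_gt(f[["MDF"]], 100)
  expect_lt(f[["MDF"]], 200)
  expect_equal(f[["MNF"]], 150, tolerance = 2)
})

test_that("Burg estimation recovers known AR(4) coefficients", {
  phi <- c(0.55, -0.35, 0.15, -0.1)
  set.seed(34)
  x <- as.numeric(arima.sim(list(ar = phi), n = 10000))
  f <- extract_frequency_features(x, fs = 1000)
  expect_equal(unname(f[paste0("AR", 1:4)]), phi, tolerance = 0.05)
})

test_that("constant windows make spectral features an error", {
  expect_error(extract_frequency_features(rep(2, 100), 1000), "degenerate")
})

test_that("six DWT levels yield seven power and seven spread sub-band features", {
  set.seed(35)
  f <- extract_timefreq_features(rnorm(250), fs = 1000)
  expect_length(grep("^APWC_", names(f)), 7)
  expect_length(grep("^SDWC_", names(f)), 7)
  expect_equal(names(f)[1], "STFT")
})

test_that("a constant window concentrates energy in the approximation band", {
  f <- extract_timefreq_features(rep(1, 256), fs = 1000)
  details <- f[paste0("APWC_D", 1:6)]
  expect_true(all(details < 1e-6 * f[["APWC_A6"]]))
})

test_that("sub-band powers conserve total energy (Parseval)", {
  set.seed(36)
  x <- rnorm(250)
  f <- extract_timefreq_features(x, fs = 1000)
  w <- dwt_db4(x, 6)
  counts <- c(vapply(w$details, length, numeric(1)), length(w$approx))
  bands <- c(paste0("APWC_D", 1:6), "APWC_A6")
  expect_equal(sum(counts * f[bands]), sum(x^2), tolerance = 1e-8)
})

test_that("windows too short for the extractors are errors", {
  expect_error(extract_time_features(c(1, 2)), "at least 3")
  expect_error(extract_frequency_features(rnorm(5), 1000), "too short")
})
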