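ctx1 <- threshold_ctx(1)

test_that("amplitude features match hand evaluation on a tiny window", {
  x <- c(1, -2, 2, -1)
  f <- amplitude_features(x, dt = 1e-3)
  expect_equal(f[["IEMG"]], 6)
  expect_equal(f[["MAV"]], 1.5)
  expect_equal(f[["SSI"]], 10)
  expect_equal(f[["VAR"]], 10 / 3)
  expect_equal(f[["RMS"]], sqrt(2.5))
  expect_equal(f[["TM3"]], 0)
  expect_equal(f[["Kurt"]], 1.36)
  expect_equal(f[["AUC"]], 0.005)        # trapezoid (1.5 + 2 + 1.5) * 1 ms
  expect_equal(f[["AFB"]], 2)
  expect_equal(f[["V3"]], mean(abs(x)^3)^(1 / 3))
  expect_error(amplitude_features(1), "at least 2")
  expect_error(amplitude_features(rep(0, 10)), "zero-variance")
})

test_that("V2 equals RMS and amplitude features scale linearly", {
  set.seed(1)
  x <- rnorm(1500)
  f <- amplitude_features(x)
  expect_equal(f[["V2"]], f[["RMS"]])
  f3 <- amplitude_features(3 * x)
  for (nm in c("IEMG", "MAV", "RMS", "AFB"))
    expect_equal(f3[[nm]], 3 * f[[nm]])
})

test_that("rate features match hand evaluation and scale with amplitude", {
  f <- rate_features(c(0, 1, 3))
  expect_equal(f[["WL"]], 3)
  expect_equal(f[["AAC"]], 1)
  expect_equal(f[["DASDV"]], sqrt(2.5))
  expect_equal(f[["MFL"]], log10(sqrt(5)))
  expect_error(rate_features(rep(2, 10)), "constant")
  set.seed(2)
  x <- rnorm(100)
  expect_equal(rate_features(5 * x)[["WL"]], 5 * rate_features(x)[["WL"]])
  expect_equal(rate_features(5 * x)[["DASDV"]], 5 * rate_features(x)[["DASDV"]])
})

test_that("threshold counts follow their definitions", {
  ctx <- threshold_ctx(0.5 / 0.3)              # makes the jump threshold 0.5
  f <- threshold_features(c(1, -1, 1, -1), ctx)
  expect_equal(f[["ZC"]], 3)
  expect_equal(f[["WAMP"]], 3)
  expect_equal(f[["MYOP"]], 0)                 # all magnitudes < 5.5 uV
  expect_equal(threshold_features(c(0, 1, 0, 1, 0), ctx1)[["SSC"]], 3)
  ramp <- threshold_features(1:10, ctx1)
  expect_equal(ramp[["SSC"]], 0)
  expect_equal(ramp[["ZC"]], 0)
  expect_equal(threshold_features(c(0, 6, 0, 6), ctx1)[["MYOP"]], 0.5)
  expect_error(threshold_ctx(0), "positive")
  # counts invariant when signal and noise SD scale together
  set.seed(3)
  x <- rnorm(500)
  a <- threshold_features(x, threshold_ctx(0.8, myop_threshold_uV = 1))
  b <- threshold_features(10 * x, threshold_ctx(8, myop_threshold_uV = 10))
  expect_equal(a, b)
})

test_that("sample and approximate entropy agree with the naive counting oracle", {
  set.seed(10)
  for (i in 1:6) {
    x <- rnorm(200)
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r), naive_sampen(x, 2, r),
                 tolerance = 1e-10)
    expect_equal(approx_entropy(x, 2, r), naive_apen(x, 2, r),
                 tolerance = 1e-10)
  }
})

test_that("entropies and Higuchi dimension behave at known limits", {
  line <- seq(0, 1, length.out = 1500)
  expect_equal(higuchi_fd(line), 1, tolerance = 0.05)
  set.seed(11)
  expect_gt(higuchi_fd(rnorm(1500)), 1.8)     # white noise is space-filling
  sq <- rep(c(1, 1, -1, -1), 100)             # strictly periodic sequence
  expect_lt(sample_entropy(sq, 2, 0.2 * sd(sq)), 0.05)
  expect_error(complexity_features(rep(1, 1500)), "positive")
  expect_error(higuchi_fd(rnorm(100), k_max = 128), "k_max")
})

test_that("the periodogram satisfies Parseval and finds pure tones", {
  set.seed(12)
  x <- rnorm(1500)
  sp <- compute_spectrum(x, 1000)
  expect_equal(sum(sp$p), mean((x - mean(x))^2), tolerance = 1e-9)
  t <- (0:1499) / 1000
  tone <- sin(2 * pi * 50 * t)
  sp50 <- compute_spectrum(tone, 1000)
  expect_equal(sp50$f[which.max(sp50$p)], 50)
})

test_that("spectral features collapse correctly on one- and two-line spectra", {
  t <- (0:1499) / 1000
  sp <- compute_spectrum(sin(2 * pi * 50 * t), 1000)
  f <- spectral_features(sp, NULL)
  expect_equal(f[["MNF"]], 50, tolerance = 1e-6)
  expect_equal(f[["MDF"]], 50)
  expect_equal(f[["PKF"]], 50)
  expect_equal(f[["VCF"]], 0, tolerance = 1e-6)
  expect_equal(f[["PSR"]], 1, tolerance = 1e-9)
  two <- sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t)
  f2 <- spectral_features(compute_spectrum(two, 1000), NULL)
  expect_equal(f2[["MNF"]], 200, tolerance = 1e-6)
  expect_equal(f2[["FR"]], 1, tolerance = 1e-9)
})

test_that("spectral-moment inequalities hold over random windows", {
  set.seed(13)
  for (i in 1:200) {
    sp <- compute_spectrum(rnorm(300), 1000)
    f <- spectral_features(sp, NULL)
    expect_gte(f[["VCF"]], -1e-9)
    expect_gte(f[["PSDd"]], 1 - 1e-12)
  }
})

test_that("the full vector has all 46 features, in order, deterministic", {
  set.seed(14)
  x <- rnorm(1500)
  v1 <- compute_features(x, 1000, ctx1)
  v2 <- compute_features(x, 1000, ctx1)
  expect_identical(names(v1), feature_names())
  expect_length(unique(names(v1)), 46)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  expect_true(v1[["MYOP"]] >= 0 && v1[["MYOP"]] <= 1)
  expect_equal(v1[["MMAV"]], v1[["MAV1"]])   # documented duplicate
  expect_true(v1[["MPD"]] != v1[["MNP"]])    # Welch vs periodogram estimators
})

test_that("channel combination modes behave as specified", {
  set.seed(15)
  x <- rnorm(1500)
  single <- compute_features(x, 1000, ctx1)
  mn <- build_feature_vector(x, x, ctx1, ctx1, 1000, mode = "mean")
  expect_equal(mn, single)
  cc <- build_feature_vector(x, rnorm(1500), ctx1, ctx1, 1000, mode = "concat")
  expect_length(cc, 92)
  expect_identical(names(cc)[1], "IEMG_L")
  expect_identical(names(cc)[47], "IEMG_R")
  expect_error(build_feature_vector(x, rnorm(100), ctx1, ctx1), "lengths")
  huge <- x; huge[1] <- 1e200               # overflow -> hard error, no NaN out
  expect_error(compute_features(huge, 1000, ctx1))
})
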