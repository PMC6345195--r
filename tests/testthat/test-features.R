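smallParams <- function() featureParams(sampenM = 1, higuchiKmax = 2,
                                        arOrder = 1, welchSegment = 8)

test_that("amplitude features follow their defining formulas on tiny inputs", {
  x <- c(1, -1, 2, -2)
  f <- suppressWarnings(temporalFeatures(ScalarSequence(x), smallParams()))
  expect_equal(unname(f["MAV"]), 1.5)
  expect_equal(unname(f["IEMG"]), 6)
  expect_equal(unname(f["SSI"]), 10)
  expect_equal(unname(f["RMS"]), sqrt(2.5))
  expect_equal(unname(f["VAR"]), var(x))

  y <- c(0, 1, 3, 0, 1, 3, 0, 1)
  g <- suppressWarnings(temporalFeatures(ScalarSequence(y), smallParams()))
  expect_equal(unname(g["WL"]), sum(abs(diff(y))))
  expect_equal(unname(g["MFL"]), log(sum(abs(diff(y)))))
})

test_that("ZC counts every crossing of an alternating zero-mean signal", {
  x <- rep(c(1, -1), 50)
  f <- suppressWarnings(temporalFeatures(ScalarSequence(x)))
  expect_equal(unname(f["ZC"]), 99)
  expect_equal(unname(f["SSC"]), 98)
})

test_that("Higuchi dimension separates smooth from noisy signals", {
  t <- (0:4095) / 100
  sine <- sin(2 * pi * 2 * t)
  fdSine <- higuchiFD(sine, 5)
  expect_gte(fdSine, 1.0)
  expect_lte(fdSine, 1.1)
  withr::with_seed(4, noise <- rnorm(4096))
  fdNoise <- higuchiFD(noise, 5)
  expect_gte(fdNoise, 1.8)
  expect_lte(fdNoise, 2.05)
  # matches the literal small-N implementation
  withr::with_seed(9, z <- cumsum(rnorm(300)))
  expect_equal(higuchiFD(z, 5), oracleHiguchi(z, 5), tolerance = 1e-9)
})

test_that("every feature matches the literal loop-based oracle on random sequences", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      n <- sample(400:700, 1)
      x <- switch(1 + rep %% 3,
                  rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3)),
                  cumsum(rnorm(n)) / 5,
                  sin(2 * pi * runif(1, 1, 10) * (0:(n - 1)) / 100) + rnorm(n, 0, .3))
      s <- ScalarSequence(x, fs = 100)
      got <- extractFeatures(s)
      want <- oracleFeatures(x, 100)
      expect_equal(got[names(want)], want, tolerance = 1e-9)
      # intra-vector identities hold on every extraction
      expect_equal(unname(got["VAR"]), unname(got["STD"])^2,
                   tolerance = 1e-9)
      expect_equal(unname(got["IEMG"]), n * unname(got["MAV"]),
                   tolerance = 1e-9)
      expect_equal(unname(got["SSI"]), n * unname(got["RMS"])^2,
                   tolerance = 1e-9)
      expect_equal(unname(got["MFL"]), log(unname(got["WL"])),
                   tolerance = 1e-9)
    }
  })
})

test_that("the full bank has exactly 35 named finite values in canonical order", {
  withr::with_seed(1, x <- rnorm(512))
  f <- extractFeatures(ScalarSequence(x, fs = 100))
  expect_identical(names(f), featureNamesCanonical())
  expect_length(f, 35)
  expect_true(all(is.finite(f)))
})

test_that("features scale and permute as their formulas dictate", {
  withr::with_seed(13, x <- rnorm(512) + 0.3)
  s1 <- extractFeatures(ScalarSequence(x, fs = 100))
  s2 <- extractFeatures(ScalarSequence(2 * x, fs = 100))
  for (nm in c("MAV", "RMS", "STD", "WL"))
    expect_equal(unname(s2[nm]), 2 * unname(s1[nm]), tolerance = 1e-9)
  expect_equal(unname(s2["ZC"]), unname(s1["ZC"]))

  withr::with_seed(14, perm <- sample(512))
  s3 <- suppressWarnings(
    temporalFeatures(ScalarSequence(x[perm], fs = 100)))
  t1 <- suppressWarnings(temporalFeatures(ScalarSequence(x, fs = 100)))
  for (nm in c("MAV", "VAR", "RMS", "IEMG", "SSI"))
    expect_equal(unname(s3[nm]), unname(t1[nm]), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(unname(s3["WL"]), unname(t1["WL"]))))
  expect_false(isTRUE(all.equal(unname(s3["AAC"]), unname(t1["AAC"]))))
})

test_that("sample entropy is non-increasing in the tolerance r", {
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- rnorm(300)
      r <- 0.2 * sd(x)
      e1 <- sampleEntropy(x, 2, r)
      e2 <- sampleEntropy(x, 2, 2 * r)
      expect_lte(e2, e1 + 1e-12)
    }
  })
})

test_that("sample entropy agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  withr::with_seed(3, x <- rnorm(400))
  r <- 0.2 * sd(x)
  ours <- sampleEntropy(x, 2, r)
  theirs <- pracma::sample_entropy(x, edim = 2, r = r, tau = 1)
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("spectral features locate known line spectra", {
  fs <- 100
  t <- (0:4095) / fs
  s8 <- ScalarSequence(sin(2 * pi * 8 * t), fs = fs)
  f8 <- spectralFeatures(s8)
  expect_lt(abs(f8[["Fmax"]] - 8), fs / 256 + 1e-9)
  expect_lt(abs(f8[["MNF"]] - 8), 0.5)
  expect_lt(abs(f8[["MDF"]] - 8), 0.5)

  two <- ScalarSequence(sin(2 * pi * 4 * t) + sin(2 * pi * 12 * t), fs = fs)
  f2 <- spectralFeatures(two)
  expect_lt(abs(f2[["MNF"]] - 8), 0.5)
})

test_that("degenerate sequences are guarded", {
  expect_error(temporalFeatures(ScalarSequence(rnorm(6)), featureParams()),
               "too short")
  const <- ScalarSequence(rep(2, 512), fs = 100)
  expect_warning(tf <- temporalFeatures(const), "constant")
  expect_equal(unname(tf["SENT"]), 0)
  expect_equal(unname(tf["FD"]), 0)
  expect_warning(sf <- spectralFeatures(const), "constant")
  expect_equal(unname(sf[c("Auto1", "Auto2", "Auto3")]), rep(0, 3))
  # spectrum of a constant is confined to the DC main lobe
  expect_equal(sf[["Fmax"]], 0)
  psd <- welchPsd(rep(2, 512), fs = 100)
  expect_gt(sum(psd$power[1:3]) / sum(psd$power), 0.99)
})

test_that("total Welch power approximates time-domain power for broadband noise", {
  withr::with_seed(77, x <- rnorm(4096, sd = 2))
  f <- spectralFeatures(ScalarSequence(x, fs = 100))
  df <- 100 / 256
  expect_lt(abs(f[["TP"]] * df - mean(x^2)) / mean(x^2), 0.1)
})

test_that("the effective sampling rate drives spectral features unless overridden", {
  t <- (0:4095)
  x <- sin(2 * pi * 80 * t / 4096)   # 80 cycles across the window
  fEff <- spectralFeatures(ScalarSequence(x, fs = 409.6))
  fNom <- spectralFeatures(ScalarSequence(x, fs = 409.6),
                           featureParams(fsOverride = 100))
  expect_equal(fEff[["Fmax"]], 4.096 * fNom[["Fmax"]], tolerance = 1e-9)
})
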