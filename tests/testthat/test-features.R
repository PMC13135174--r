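# Spectral energies, ratios, cohort aggregation, standardization.

test_that("spectral_energy follows the Parseval convention", {
  fs <- 2000
  x <- sin(2 * pi * 300 * (0:255) / fs)   # unit tone, 128 ms
  X <- stats::fft(c(x, rep(0, 1024 - 256)))
  total <- spectral_energy(X, fs, c(0, fs / 2))
  expect_equal(total, sum(x^2) / fs, tolerance = 1e-12)
  expect_equal(total, 0.064, tolerance = 0.02 * 0.064 / 0.064)  # A^2 T / 2
  expect_equal(spectral_energy(rep(0 + 0i, 1024), fs, c(150, 500)), 0)
  expect_error(spectral_energy(X, fs, c(500, 150)), "inverted")
  expect_error(spectral_energy(X, fs, c(0, 1500)), "outside")
})

test_that("mode energies sum to the segment energy", {
  bank <- test_bank()
  set.seed(21)
  for (rep in 1:5) {
    x <- stats::rnorm(256)
    f <- compute_features(ewt_decompose(x, bank))
    expect_equal(f$e1 + f$e2 + f$e3, sum(x^2) / 2000, tolerance = 1e-6)
  }
})

test_that("ratios follow their definitions", {
  bank <- test_bank()
  t <- (0:255) / 2000
  # equal-amplitude tones deep in bands 1 and 2 -> P1 = 1 (up to leakage)
  m <- ewt_decompose(sin(2 * pi * 60 * t) + sin(2 * pi * 300 * t), bank)
  f <- compute_features(m)
  expect_equal(f$P1, 1, tolerance = 0.02)
  # forcing mode 3 to zero gives P2 = 0 exactly
  m$spectra[, 3] <- 0 + 0i
  expect_identical(compute_features(m)$P2, 0)
  # zero segment: energies zero, ratios undefined with a warning
  z <- ewt_decompose(rep(0, 256), bank)
  expect_warning(fz <- compute_features(z), "undefined")
  expect_true(is.na(fz$P1))
})

test_that("the published worked example reproduces its mean row", {
  ref <- utils::read.csv(system.file("extdata", "reference_diastole_features.csv",
                                     package = "pcgewt"))
  agg <- aggregate_cohort(ref, "group", signif_digits = 2)
  cad <- agg[agg$group == "cad", ]
  nor <- agg[agg$group == "normal", ]
  expect_equal(cad$e1_mean, 8.6e-4)
  expect_equal(cad$e2_mean, 1.7e-6)
  expect_equal(cad$e3_mean, 1.4e-7)
  expect_equal(cad$P1_mean, 0.0023)
  expect_equal(cad$P2_mean, 1.8e-4)
  expect_equal(nor$e1_mean, 1.0e-3)
  expect_equal(nor$e2_mean, 2.0e-8)
  expect_equal(nor$e3_mean, 1.7e-10)
  expect_equal(nor$P1_mean, 3.4e-5)
  expect_equal(nor$P2_mean, 3.0e-7)

  one <- aggregate_cohort(ref[1, ], "group")
  expect_equal(one$e2_mean, ref$e2[1])
  expect_error(aggregate_cohort(ref[0, ], "group"), "no feature rows")
})

test_that("energies are shift-invariant (matched grid) and scale as a^2", {
  bank256 <- test_bank(nfft = 256L)
  set.seed(22)
  x <- stats::rnorm(256)
  f0 <- compute_features(ewt_decompose(x, bank256))
  xs <- c(x[101:256], x[1:100])                 # circular shift
  fs_ <- compute_features(ewt_decompose(xs, bank256))
  expect_equal(c(fs_$e1, fs_$e2, fs_$e3), c(f0$e1, f0$e2, f0$e3), tolerance = 1e-10)

  bank <- test_bank()
  a <- 2.5
  fa <- compute_features(ewt_decompose(a * x, bank))
  fb <- compute_features(ewt_decompose(x, bank))
  expect_equal(c(fa$e1, fa$e2, fa$e3), a^2 * c(fb$e1, fb$e2, fb$e3), tolerance = 1e-12)
  expect_equal(c(fa$P1, fa$P2), c(fb$P1, fb$P2), tolerance = 1e-12)
})

test_that("standardization learns from the training side only", {
  set.seed(23)
  tr <- data.frame(e1 = rnorm(50, 2), e2 = rnorm(50, -1, 3), e3 = runif(50),
                   P1 = rexp(50), P2 = rnorm(50))
  std <- fit_standardizer(tr)
  trs <- apply_standardizer(std, tr)
  for (f in std$features) {
    expect_lt(abs(mean(trs[[f]])), 1e-12)
    expect_equal(stats::sd(trs[[f]]), 1, tolerance = 1e-12)
  }
  # a test row equal to the training mean maps to all zeros
  mid <- as.data.frame(as.list(std$center))
  expect_equal(unlist(apply_standardizer(std, mid)), unlist(mid) * 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  # shifting one test feature by c shifts its standardized value by c / sd
  te <- tr[1:10, ]
  te2 <- te; te2$e2 <- te2$e2 + 5
  d <- apply_standardizer(std, te2)$e2 - apply_standardizer(std, te)$e2
  expect_equal(d, rep(5 / std$scale[["e2"]], 10), tolerance = 1e-12)

  bad <- tr; bad$e3 <- 1
  expect_error(fit_standardizer(bad), "e3")
  expect_error(fit_standardizer(tr[1, ]), "at least 2")
})
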