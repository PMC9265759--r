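test_that("angular-spectrum kernel: identity at z = 0, unimodular, composes over distance", {
  k0 <- angularSpectrumKernel(c(64, 64), pitch = 1.27, wavelength = 0.532, z = 0)
  prop <- Mod(k0) > 0
  expect_true(all(k0[prop] == 1 + 0i))

  k1 <- angularSpectrumKernel(c(64, 64), pitch = 1.27, wavelength = 0.532, z = 100)
  expect_equal(max(abs(Mod(k1[Mod(k1) > 0]) - 1)), 0, tolerance = 1e-12)

  # semigroup property pins the frequency-grid convention
  k2 <- angularSpectrumKernel(c(64, 64), pitch = 1.27, wavelength = 0.532, z = 250)
  k12 <- angularSpectrumKernel(c(64, 64), pitch = 1.27, wavelength = 0.532, z = 350)
  expect_lt(max(Mod(k1 * k2 - k12)), 1e-12)

  # evanescent band is zeroed once the grid resolves super-wavelength frequencies
  kf <- angularSpectrumKernel(c(32, 32), pitch = 0.2, wavelength = 0.532, z = 50)
  expect_true(any(Mod(kf) == 0))
  expect_true(all(Mod(kf) <= 1))

  expect_error(angularSpectrumKernel(c(8, 8), pitch = -1, wavelength = 0.5, z = 1),
               "positive")
  expect_error(angularSpectrumKernel(c(8, 8), pitch = 1, wavelength = 0, z = 1),
               "positive")
})

test_that("kernel matches its independent transcription on a small grid", {
  k <- angularSpectrumKernel(c(6, 5), pitch = 0.4, wavelength = 0.532, z = 35)
  expect_lt(max(Mod(k - oracleKernel(6, 5, 0.4, 0.532, 35))), 1e-12)
})

test_that("propagation: plane-wave invariance, round trip, non-expansive", {
  pw <- complexField(matrix(2 + 0i, 32, 32), pitch = 1.27, wavelength = 0.532)
  out <- propagateField(pw, 500)
  # constant field only excites DC: result is the same constant up to phase
  expect_lt(max(Mod(Mod(out@values) - 2)), 1e-12)
  expect_lt(max(Mod(out@values / out@values[1, 1] - 1)), 1e-12)

  x <- complexField(randomComplexMatrix(32, 32, 1), pitch = 1.27,
                    wavelength = 0.532)
  back <- propagateField(propagateField(x, 350), -350)
  expect_lt(max(Mod(back@values - x@values)), 1e-10)

  for (s in 1:5) {
    y <- complexField(randomComplexMatrix(16, 16, s), pitch = 0.3,
                      wavelength = 0.532)
    expect_lte(sum(Mod(propagateField(y, 120)@values)^2),
               sum(Mod(y@values)^2) * (1 + 1e-12))
  }
})

test_that("forward map A_k is linear, non-expansive and dense-equivalent", {
  sys <- tinySystem(n = 8L, K = 2L, sigma = c(2L, 2L), z = 40)
  syscrop <- tinySystem(n = 8L, K = 2L, crop = c(4L, 4L), z = 40, seed = 3)
  for (sy in list(sys, syscrop)) {
    A1 <- denseA(sy, 1)
    for (s in 1:3) {
      x <- randomComplexMatrix(8, 8, s + 10)
      z2 <- randomComplexMatrix(8, 8, s + 20)
      set.seed(s)
      al <- complex(real = rnorm(1), imaginary = rnorm(1))
      be <- complex(real = rnorm(1), imaginary = rnorm(1))
      fx <- complexField(x, pitch(sy), wavelength(sy))
      fz <- complexField(z2, pitch(sy), wavelength(sy))
      fl <- complexField(al * x + be * z2, pitch(sy), wavelength(sy))
      lin <- applyForward(fl, sy, 1)@values -
        al * applyForward(fx, sy, 1)@values -
        be * applyForward(fz, sy, 1)@values
      expect_lt(max(Mod(lin)), 1e-10)
      expect_lte(sum(Mod(applyForward(fx, sy, 1)@values)^2),
                 sum(Mod(x)^2) * (1 + 1e-12))
      dense <- matrix(A1 %*% as.vector(x), nrow(applyForward(fx, sy, 1)@values))
      expect_lt(max(Mod(applyForward(fx, sy, 1)@values - dense)), 1e-10)
    }
  }
  zf <- complexField(matrix(0 + 0i, 8, 8), pitch(sys), wavelength(sys))
  expect_true(all(applyForward(zf, sys, 1)@values == 0))
  expect_error(applyForward(zf, sys, 3), "out of range")
})

test_that("no-crop z = 0 system reduces A_k to the bare modulation", {
  sys0 <- tinySystem(n = 8L, K = 1L, z = 0)
  x <- randomComplexMatrix(8, 8, 5)
  fx <- complexField(x, pitch(sys0), wavelength(sys0))
  expect_lt(max(Mod(applyForward(fx, sys0, 1)@values -
                      exp(1i * modulations(sys0)[[1]]) * x)), 1e-12)
  r <- randomComplexMatrix(8, 8, 6)
  expect_lt(max(Mod(applyAdjoint(r, sys0, 1)@values -
                      Conj(exp(1i * modulations(sys0)[[1]])) * r)), 1e-12)
})

test_that("adjoint identity <A_k x, y> = <x, A_k^H y> holds to machine precision", {
  sys <- tinySystem(n = 8L, K = 2L, crop = c(4L, 4L), z = 75, seed = 9)
  for (s in 1:20) {
    x <- randomComplexMatrix(8, 8, s)
    y <- randomComplexMatrix(4, 4, s + 100)
    fx <- complexField(x, pitch(sys), wavelength(sys))
    lhs <- cdot(y, applyForward(fx, sys, 1 + s %% 2)@values)
    rhs <- cdot(applyAdjoint(y, sys, 1 + s %% 2)@values, x)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  }
  zf <- matrix(0 + 0i, 4, 4)
  expect_true(all(applyAdjoint(zf, sys, 1)@values == 0))
  expect_error(applyAdjoint(randomComplexMatrix(3, 3, 1), sys, 1),
               "sensor window")
})

test_that("sensor binning: identity at sigma 1, block sums, dense-equivalent", {
  s1 <- samplingOperator(c(5L, 7L))
  m <- matrix(runif(35), 5, 7)
  expect_identical(downsampleIntensity(m, s1), m)

  s2 <- samplingOperator(c(4L, 4L), sigma = 2L)
  cimg <- matrix(3.5, 4, 4)
  expect_equal(downsampleIntensity(cimg, s2), matrix(14, 2, 2))

  set.seed(8)
  w <- matrix(runif(36), 6, 6)
  s3 <- samplingOperator(c(6L, 6L), sigma = 3L, weights = w)
  img <- matrix(runif(36), 6, 6)
  Sm <- denseS(c(6L, 6L), c(3L, 3L), w)
  expect_equal(as.vector(downsampleIntensity(img, s3)),
               as.vector(Sm %*% as.vector(img)), tolerance = 1e-12)

  expect_error(samplingOperator(c(5L, 5L), sigma = 2L), "divisible")
  expect_error(downsampleIntensity(matrix(0, 3, 3), s2), "cropped grid")
})

test_that("binning adjoint realizes s = S^T 1 and passes the adjoint test", {
  s2 <- samplingOperator(c(4L, 6L), sigma = 2L)
  expect_equal(upsampleAdjoint(matrix(1, 2, 3), s2), matrix(1, 4, 6))

  set.seed(13)
  w <- matrix(runif(24), 4, 6)
  sw <- samplingOperator(c(4L, 6L), sigma = 2L, weights = w)
  expect_equal(upsampleAdjoint(matrix(1, 2, 3), sw), w)
  for (s in 1:5) {
    img <- matrix(runif(24), 4, 6)
    y <- matrix(runif(6), 2, 3)
    lhs <- sum(downsampleIntensity(img, sw) * y)
    rhs <- sum(img * upsampleAdjoint(y, sw))
    expect_lt(abs(lhs - rhs), 1e-12)
  }
  expect_true(all(upsampleAdjoint(matrix(0, 2, 3), sw) == 0))
  expect_error(upsampleAdjoint(matrix(1, 3, 3), sw), "sensor grid")
})

test_that("forward measurement S|A_k x|^2 matches the dense oracle", {
  sys <- tinySystem(n = 16L, K = 2L, sigma = c(2L, 2L), z = 60, seed = 17)
  x <- randomComplexMatrix(16, 16, 2)
  fx <- complexField(x, pitch(sys), wavelength(sys))
  A1 <- denseA(sys, 1)
  samp <- sampling(sys)
  Sm <- denseS(samp@cropSize, samp@sigma, samp@weights)
  oracle <- Sm %*% Mod(A1 %*% as.vector(x))^2
  expect_equal(as.vector(forwardMeasure(fx, sys, 1)), as.vector(oracle),
               tolerance = 1e-10)

  zf <- complexField(matrix(0 + 0i, 16, 16), pitch(sys), wavelength(sys))
  expect_true(all(forwardMeasure(zf, sys, 1) == 0))

  flat <- tinySystem(n = 8L, K = 1L, z = 0, seed = 1)
  flat@modulations[[1]] <- matrix(0, 8, 8)
  flat@phasors[[1]] <- matrix(1 + 0i, 8, 8)
  x8 <- randomComplexMatrix(8, 8, 3)
  expect_equal(forwardMeasure(complexField(x8, pitch(flat), wavelength(flat)),
                              flat, 1), Mod(x8)^2, tolerance = 1e-12)
})

test_that("spectral-radius estimate: bounded by 1, exact for unitary, dense-equivalent, monotone", {
  sys <- tinySystem(n = 8L, K = 3L, crop = c(4L, 4L), sigma = c(2L, 2L), z = 90)
  for (k in 1:3)
    expect_lte(spectralRadiusEstimate(sys, k, 60, seed = k), 1 + 1e-9)

  uni <- tinySystem(n = 8L, K = 1L, z = 55)   # no crop, sigma 1: unitary A_k
  expect_equal(spectralRadiusEstimate(uni, 1, 30), 1, tolerance = 1e-6)

  A1 <- denseA(sys, 1)
  samp <- sampling(sys)
  s <- as.vector(samp@weights)
  T1 <- Conj(t(A1)) %*% (s * A1)
  lamMax <- max(abs(eigen(T1, only.values = TRUE)$values))
  expect_equal(spectralRadiusEstimate(sys, 1, 300, seed = 2), lamMax,
               tolerance = 1e-6)

  ests <- vapply(c(1L, 3L, 10L, 30L), function(it)
    spectralRadiusEstimate(sys, 1, it, seed = 4), numeric(1))
  expect_true(all(diff(ests) >= -1e-12))
})
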