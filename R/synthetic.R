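# periodic Gaussian blur via the FFT (circular convolution, matching the
# circular boundary model of the forward operator)
.gaussianBlurFFT <- function(x, sigmaPx) {
  if (sigmaPx <= 0) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  f1 <- .fftFreq(n1, 1); f2 <- .fftFreq(n2, 1)
  h <- exp(-2 * pi^2 * sigmaPx^2 * outer(f1^2, f2^2, "+"))
  Re(.ifft2(h * .fft2(x + 0i)))
}

# rescale a matrix affinely onto [lo, hi]; constant input maps to midpoint
.rescaleRange <- function(x, lo, hi) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps)
    return(matrix((lo + hi) / 2, nrow(x), ncol(x)))
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Build a complex test sample
#'
#' Either maps a user-supplied grayscale image pair (amplitude, phase)
#' affinely onto the configured amplitude/phase ranges, or generates the
#' built-in procedural sample: textured smooth blobs, resolution-target-like
#' bar groups and a smooth phase ramp, so the package exercises the solver
#' with zero external assets. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param amplitudeImage,phaseImage optional single-channel numeric matrices
#'   of identical size; when NULL the procedural sample is used.
#' @return A \linkS4class{ComplexField} with amplitude in
#'   \code{amplitudeRange} and phase in \code{phaseRange}.
#' @export
makeSample <- function(config, amplitudeImage = NULL, phaseImage = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  n1 <- config@gridSize[1L]; n2 <- config@gridSize[2L]
  if (xor(is.null(amplitudeImage), is.null(phaseImage)))
    stop("supply both 'amplitudeImage' and 'phaseImage', or neither")
  if (!is.null(amplitudeImage)) {
    if (length(dim(amplitudeImage)) != 2L || length(dim(phaseImage)) != 2L)
      stop("images must be single-channel (2-D matrices)")
    if (!identical(dim(amplitudeImage), dim(phaseImage)))
      stop("amplitude and phase images must have identical size")
    ampImg <- amplitudeImage
    phImg <- phaseImage
  } else {
    imgs <- .withSeed(config@seed, .proceduralImages(n1, n2))
    ampImg <- imgs$amp
    phImg <- imgs$phase
  }
  amp <- .rescaleRange(ampImg, config@amplitudeRange[1L],
                       config@amplitudeRange[2L])
  ph <- .rescaleRange(phImg, config@phaseRange[1L], config@phaseRange[2L])
  complexField(amp * exp(1i * ph), config@pitch, config@wavelength)
}

# procedural amplitude/phase textures: blobs + bars + ramps (RNG-dependent)
.proceduralImages <- function(n1, n2) {
  ix <- matrix(rep(seq_len(n1), n2), n1, n2) / n1
  iy <- matrix(rep(seq_len(n2), each = n1), n1, n2) / n2
  blobs <- matrix(0, n1, n2)
  for (b in seq_len(12L)) {
    cx <- stats::runif(1); cy <- stats::runif(1)
    w <- stats::runif(1, 0.03, 0.15); a <- stats::runif(1, 0.3, 1)
    blobs <- blobs + a * exp(-((ix - cx)^2 + (iy - cy)^2) / (2 * w^2))
  }
  texture <- .gaussianBlurFFT(matrix(stats::runif(n1 * n2), n1, n2),
                              max(1, n1 / 64))
  bars <- matrix(0, n1, n2)
  for (g in 1:3) {                       # bar groups of decreasing period
    period <- max(2L, n1 %/% (8L * 2L^g))
    rows <- seq.int(round(n1 * 0.1), round(n1 * 0.3))
    cols <- seq.int(round(n2 * (0.15 + 0.25 * (g - 1))),
                    round(n2 * (0.15 + 0.25 * (g - 1)) + n2 * 0.18))
    cols <- cols[cols <= n2]
    stripe <- ((cols %/% period) %% 2L) == 0L
    bars[rows, cols[stripe]] <- 1
  }
  amp <- 0.55 * blobs / max(blobs) + 0.25 * texture + 0.4 * bars
  ramp <- 0.7 * ix + 0.3 * iy
  phase <- 0.6 * ramp + 0.5 * blobs / max(blobs) +
    0.25 * .gaussianBlurFFT(matrix(stats::runif(n1 * n2), n1, n2),
                            max(1, n1 / 32))
  list(amp = amp, phase = phase)
}

#' Generate random Gaussian-filtered phase modulation patterns
#'
#' K i.i.d. uniform random phase fields, low-pass filtered with a Gaussian
#' of width \code{modulationSigmaPx} pixels (circular convolution) and
#' rescaled to span [0, 2*pi): enough diversity across patterns while
#' keeping neighbouring modulator pixels correlated, emulating the
#' crosstalk-limited patterns a phase-only SLM can display. Deterministic
#' given \code{config@seed}; as the filter width grows the patterns tend to
#' a constant (zero diversity).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list of K real matrices (radians) on the full grid.
#' @export
makeModulationPatterns <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n1 <- config@gridSize[1L]; n2 <- config@gridSize[2L]
  .withSeed(config@seed + 1000L, lapply(seq_len(config@K), function(k) {
    raw <- matrix(stats::runif(n1 * n2), n1, n2)
    sm <- .gaussianBlurFFT(raw, config@modulationSigmaPx)
    .rescaleRange(sm, 0, 2 * pi * (1 - 1e-9))
  }))
}

#' Build the system operator for a simulation configuration
#'
#' Convenience constructor: random Gaussian-filtered modulation patterns
#' (unless supplied), angular-spectrum propagation over \code{config@z}, and
#' a sampling model with the configured binning; the sensor window defaults
#' to the full grid (no crop), the usual choice in simulation studies.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param patterns optional list of modulation phase matrices.
#' @param cropSize,cropOffset,weights optional sensor window and sub-pixel
#'   weights, passed to \code{\link{samplingOperator}}.
#' @return A \linkS4class{SystemOperator}.
#' @export
makeSystem <- function(config, patterns = NULL, cropSize = NULL,
                       cropOffset = NULL, weights = 1) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(patterns)) patterns <- makeModulationPatterns(config)
  if (is.null(cropSize)) cropSize <- config@gridSize
  samp <- samplingOperator(config@gridSize, sigma = config@sigma,
                           cropSize = cropSize, cropOffset = cropOffset,
                           weights = weights)
  systemOperator(patterns, pitch = config@pitch,
                 wavelength = config@wavelength, z = config@z,
                 sampling = samp)
}

#' Simulate a measurement stack
#'
#' Applies the forward model y_k^2 = S |A_k x|^2 for every k and adds the
#' configured sensor noise: \code{"gaussian"} adds intensity noise at the
#' stated SNR (dB), clipped at zero; \code{"poisson"} draws photon counts
#' scaled so the mean-intensity pixel receives \code{noiseParam} expected
#' photons, then rescales back to intensity units. Deterministic given
#' \code{seed}. The md5 digest of the ground truth is stored in the stack
#' for later identity checks.
#'
#' @param x the ground-truth \linkS4class{ComplexField}.
#' @param sys a \linkS4class{SystemOperator}.
#' @param noise "none", "gaussian" or "poisson".
#' @param noiseParam SNR in dB (gaussian) or photon level (poisson).
#' @param seed RNG seed for the noise draws.
#' @return A \linkS4class{MeasurementStack}.
#' @export
simulateStack <- function(x, sys, noise = c("none", "gaussian", "poisson"),
                          noiseParam = NA_real_, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(is(x, "ComplexField"), is(sys, "SystemOperator"))
  if (!identical(dim(x@values), as.integer(sys@gridSize)))
    stop("sample grid does not match the system grid")
  K <- length(sys@modulations)
  d <- sys@sampling@cropSize %/% sys@sampling@sigma
  ints <- array(0, c(d[1L], d[2L], K))
  for (k in seq_len(K)) ints[, , k] <- forwardMeasure(x, sys, k)
  if (noise != "none") {
    if (!is.finite(noiseParam))
      stop(sprintf("'noiseParam' required for %s noise", noise))
    ints <- .withSeed(seed, switch(noise,
      gaussian = {
        sd <- sqrt(mean(ints^2)) / 10^(noiseParam / 20)
        pmax(ints + array(stats::rnorm(length(ints), sd = sd), dim(ints)), 0)
      },
      poisson = {
        scale <- noiseParam / mean(ints)
        array(stats::rpois(length(ints), ints * scale) / scale, dim(ints))
      }))
  }
  measurementStack(ints, sys, truthHash = .objectDigest(x@values))
}
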