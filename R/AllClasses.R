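#' @import methods
NULL

#' ComplexField: a sampled complex wavefield
#'
#' Container for the complex transmittance of a sample (or any intermediate
#' wavefield) on a regular 2-D grid, together with the physical sampling pitch
#' and the illumination wavelength. All lengths are in micrometres.
#'
#' @slot values complex matrix, the field samples.
#' @slot pitch numeric(1), physical size of one grid sample in um.
#' @slot wavelength numeric(1), illumination wavelength in um.
#' @name ComplexField-class
#' @aliases ComplexField
#' @exportClass ComplexField
setClass("ComplexField",
  representation(values = "matrix", pitch = "numeric", wavelength = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.complex(object@values) && !is.numeric(object@values))
      msg <- c(msg, "'values' must be a numeric or complex matrix")
    if (any(!is.finite(Re(object@values))) || any(!is.finite(Im(object@values))))
      msg <- c(msg, "'values' must be finite everywhere (no NA/NaN/Inf)")
    if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
      msg <- c(msg, "'pitch' must be a single positive number")
    if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
        object@wavelength <= 0)
      msg <- c(msg, "'wavelength' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ComplexField
#'
#' @param values numeric or complex matrix of field samples.
#' @param pitch grid pitch in um.
#' @param wavelength illumination wavelength in um.
#' @return A \linkS4class{ComplexField}.
#' @examples
#' f <- complexField(matrix(1 + 0i, 8, 8), pitch = 1.0, wavelength = 0.532)
#' gridDim(f)
#' @export
complexField <- function(values, pitch, wavelength) {
  if (!is.complex(values)) values <- values + 0i
  new("ComplexField", values = values, pitch = as.numeric(pitch),
      wavelength = as.numeric(wavelength))
}

#' SamplingOperator: sensor crop and sub-pixel binning
#'
#' Describes the linear map from the reconstruction grid (n samples) to the
#' sensor pixel grid (d pixels): a crop to the sensor window (m samples,
#' m = sigma * d) followed by a weighted block sum over sigma1 x sigma2
#' sub-pixels per sensor pixel. With the default unit weights the weight
#' vector s = S^T 1 is identically one, which is the normalization under
#' which the composed measurement operators are non-expansive.
#'
#' @slot gridSize integer(2), full reconstruction grid (N1, N2).
#' @slot cropSize integer(2), sensor window size (M1, M2) in grid samples.
#' @slot cropOffset integer(2), 0-based offset of the window in the full grid.
#' @slot sigma integer(2), binning factors (sigma1, sigma2).
#' @slot weights numeric matrix (M1 x M2) of per-subpixel weights in [0, 1].
#' @name SamplingOperator-class
#' @aliases SamplingOperator
#' @exportClass SamplingOperator
setClass("SamplingOperator",
  representation(gridSize = "integer", cropSize = "integer",
                 cropOffset = "integer", sigma = "integer",
                 weights = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@gridSize) != 2L || any(object@gridSize < 1L))
      msg <- c(msg, "'gridSize' must be two positive integers")
    if (length(object@sigma) != 2L || any(object@sigma < 1L))
      msg <- c(msg, "'sigma' must be two positive integers")
    if (length(object@cropSize) != 2L || any(object@cropSize < 1L))
      msg <- c(msg, "'cropSize' must be two positive integers")
    if (any(object@cropSize %% object@sigma != 0L))
      msg <- c(msg, "'cropSize' must be divisible by 'sigma' (m = sigma * d)")
    if (any(object@cropOffset < 0L) ||
        any(object@cropOffset + object@cropSize > object@gridSize))
      msg <- c(msg, "crop window must lie inside the grid")
    if (!identical(dim(object@weights), as.integer(object@cropSize)))
      msg <- c(msg, "'weights' must be an M1 x M2 matrix on the cropped grid")
    if (any(object@weights < 0) || any(object@weights > 1))
      msg <- c(msg, "'weights' must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SamplingOperator
#'
#' @param gridSize integer(2), reconstruction grid size.
#' @param sigma integer(2) (or scalar) binning factors.
#' @param cropSize integer(2); defaults to the full grid (no crop).
#' @param cropOffset integer(2) 0-based; defaults to a centered window.
#' @param weights scalar or M1 x M2 matrix of sub-pixel weights in [0, 1].
#' @return A \linkS4class{SamplingOperator}.
#' @export
samplingOperator <- function(gridSize, sigma = c(1L, 1L), cropSize = gridSize,
                             cropOffset = NULL, weights = 1) {
  gridSize <- as.integer(rep(gridSize, length.out = 2L))
  sigma <- as.integer(rep(sigma, length.out = 2L))
  cropSize <- as.integer(rep(cropSize, length.out = 2L))
  if (is.null(cropOffset)) cropOffset <- (gridSize - cropSize) %/% 2L
  cropOffset <- as.integer(rep(cropOffset, length.out = 2L))
  if (length(weights) == 1L)
    weights <- matrix(as.numeric(weights), cropSize[1L], cropSize[2L])
  new("SamplingOperator", gridSize = gridSize, cropSize = cropSize,
      cropOffset = cropOffset, sigma = sigma, weights = weights)
}

#' SystemOperator: the per-measurement forward maps A_k = C H M_k
#'
#' Bundles the K phase-only modulation patterns M_k, the angular-spectrum
#' free-space propagation H over distance z, and the sensor sampling model
#' (crop C and binning S). The frequency-domain propagation kernel and the
#' modulation phasors exp(i phi_k) are precomputed at construction.
#'
#' @slot gridSize integer(2), reconstruction grid (N1, N2).
#' @slot pitch numeric(1), grid pitch in um.
#' @slot wavelength numeric(1), wavelength in um.
#' @slot z numeric(1), sample-to-sensor propagation distance in um.
#' @slot modulations list of K real matrices of modulation phase (radians).
#' @slot phasors list of K complex matrices exp(i * phase) (derived).
#' @slot kernel complex matrix, angular-spectrum transfer function (derived).
#' @slot sampling a \linkS4class{SamplingOperator}.
#' @name SystemOperator-class
#' @aliases SystemOperator
#' @exportClass SystemOperator
setClass("SystemOperator",
  representation(gridSize = "integer", pitch = "numeric",
                 wavelength = "numeric", z = "numeric",
                 modulations = "list", phasors = "list",
                 kernel = "matrix", sampling = "SamplingOperator"),
  validity = function(object) {
    msg <- NULL
    if (length(object@modulations) < 1L)
      msg <- c(msg, "at least one modulation pattern is required")
    okdim <- vapply(object@modulations, function(m)
      identical(dim(m), as.integer(object@gridSize)), logical(1))
    if (!all(okdim))
      msg <- c(msg, "all modulation patterns must match 'gridSize'")
    if (!identical(object@sampling@gridSize, object@gridSize))
      msg <- c(msg, "sampling operator grid must match 'gridSize'")
    if (length(object@z) != 1L || !is.finite(object@z))
      msg <- c(msg, "'z' must be a single finite number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SystemOperator
#'
#' @param modulations list of real matrices (radians) on the full grid, one
#'   per diversity measurement; phase-only modulation is assumed.
#' @param pitch grid pitch in um.
#' @param wavelength wavelength in um.
#' @param z propagation distance in um (0 or negative allowed).
#' @param sampling a \linkS4class{SamplingOperator}; defaults to identity
#'   sampling (no crop, sigma = 1).
#' @return A \linkS4class{SystemOperator}.
#' @export
systemOperator <- function(modulations, pitch, wavelength, z,
                           sampling = NULL) {
  if (is.matrix(modulations)) modulations <- list(modulations)
  gridSize <- as.integer(dim(modulations[[1L]]))
  if (is.null(sampling)) sampling <- samplingOperator(gridSize)
  kern <- angularSpectrumKernel(gridSize, pitch, wavelength, z)
  phas <- lapply(modulations, function(m) exp(1i * m))
  new("SystemOperator", gridSize = gridSize, pitch = as.numeric(pitch),
      wavelength = as.numeric(wavelength), z = as.numeric(z),
      modulations = modulations, phasors = phas, kernel = kern,
      sampling = sampling)
}

#' MeasurementStack: recorded low-resolution intensity images
#'
#' The K sensor intensity images y_k^2 together with the full description of
#' the system that produced them (so a stack is self-contained for
#' reconstruction and for serialization).
#'
#' @slot intensities numeric array d1 x d2 x K of recorded intensities.
#' @slot system the \linkS4class{SystemOperator} that generated/acquired them.
#' @slot truthHash character(1), md5 digest of the ground-truth field when the
#'   stack was simulated ("" for experimental stacks).
#' @name MeasurementStack-class
#' @aliases MeasurementStack
#' @exportClass MeasurementStack
setClass("MeasurementStack",
  representation(intensities = "array", system = "SystemOperator",
                 truthHash = "character"),
  validity = function(object) {
    msg <- NULL
    d <- object@system@sampling@cropSize %/% object@system@sampling@sigma
    K <- length(object@system@modulations)
    if (length(dim(object@intensities)) != 3L)
      msg <- c(msg, "'intensities' must be a 3-D array (d1 x d2 x K)")
    else if (!identical(dim(object@intensities), c(as.integer(d), K)))
      msg <- c(msg, sprintf("'intensities' must be %d x %d x %d to match the system",
                            d[1L], d[2L], K))
    if (any(object@intensities < 0))
      msg <- c(msg, "'intensities' must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a MeasurementStack
#'
#' @param intensities d1 x d2 x K array of recorded intensities y_k^2.
#' @param system the generating \linkS4class{SystemOperator}.
#' @param truthHash optional md5 digest of the ground truth (simulation only).
#' @return A \linkS4class{MeasurementStack}.
#' @export
measurementStack <- function(intensities, system, truthHash = "") {
  new("MeasurementStack", intensities = intensities, system = system,
      truthHash = truthHash)
}

#' Regularizer: the non-smooth penalty and its proximal solver settings
#'
#' Supported kinds: \code{"tv"} (anisotropic complex total variation,
#' lambda * ||Dx||_1 on horizontal/vertical first differences) and
#' \code{"none"} (identity proximal map).
#'
#' @slot kind character(1), "tv" or "none".
#' @slot lambda numeric(1) >= 0, regularization weight.
#' @slot innerIterations integer(1) >= 1, dual projected-gradient steps per
#'   proximal evaluation.
#' @slot warmStart logical(1), carry the dual variables across outer
#'   iterations of the solver.
#' @name Regularizer-class
#' @aliases Regularizer
#' @exportClass Regularizer
setClass("Regularizer",
  representation(kind = "character", lambda = "numeric",
                 innerIterations = "integer", warmStart = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("tv", "none"))
      msg <- c(msg, "'kind' must be \"tv\" or \"none\"")
    if (length(object@lambda) != 1L || object@lambda < 0)
      msg <- c(msg, "'lambda' must be a single non-negative number")
    if (object@innerIterations < 1L)
      msg <- c(msg, "'innerIterations' must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Regularizer
#'
#' @param kind "tv" or "none".
#' @param lambda non-negative regularization weight.
#' @param innerIterations dual iterations per proximal step (default 1; with
#'   warm starting a single inner step is typically sufficient at small
#'   lambda).
#' @param warmStart carry dual variables across solver iterations.
#' @return A \linkS4class{Regularizer}.
#' @export
regularizer <- function(kind = c("tv", "none"), lambda = 0,
                        innerIterations = 1L, warmStart = TRUE) {
  kind <- match.arg(kind)
  new("Regularizer", kind = kind, lambda = as.numeric(lambda),
      innerIterations = as.integer(innerIterations),
      warmStart = isTRUE(warmStart))
}

#' ReconResult: the output of a reconstruction run
#'
#' @slot estimate the final \linkS4class{ComplexField}.
#' @slot history data.frame with one row per iteration: iter, fidelity,
#'   objective, and (when ground truth was supplied) rmseAmp, rmsePhase,
#'   rmseComplex.
#' @slot gamma numeric(1), the step size actually used.
#' @slot config list, the full option set needed to re-run bit-identically.
#' @name ReconResult-class
#' @aliases ReconResult
#' @exportClass ReconResult
setClass("ReconResult",
  representation(estimate = "ComplexField", history = "data.frame",
                 gamma = "numeric", config = "list"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@history) > 0L &&
        any(diff(object@history$iter) <= 0))
      msg <- c(msg, "'history$iter' must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' SimulationConfig: study conditions for the synthetic-data generator
#'
#' Defaults emulate a modulation-diversity acquisition: K = 8 diversity
#' images, 4 x 4 binning (down-sampling ratio 16), 532 nm illumination,
#' 500 um sample-to-sensor distance, 0.95 um reconstruction pitch (a 3.8 um
#' sensor pixel split four ways), passive sample with amplitude in [0.2, 1]
#' and phase in [0, pi], and modulation patterns smoothed at the
#' modulator-pixel scale (4 reconstruction samples).
#'
#' @slot gridSize integer(2), reconstruction grid.
#' @slot sigma integer(2), binning factors.
#' @slot K integer(1), number of diversity measurements.
#' @slot wavelength numeric(1), um.
#' @slot z numeric(1), um.
#' @slot pitch numeric(1), um per high-resolution sample.
#' @slot amplitudeRange numeric(2) in (0, 1].
#' @slot phaseRange numeric(2), radians.
#' @slot modulationSigmaPx numeric(1), Gaussian filter width (pixels) applied
#'   to the random modulation patterns.
#' @slot noise character(1), "none", "gaussian" or "poisson".
#' @slot noiseParam numeric(1), SNR in dB (gaussian) or photon level
#'   (poisson).
#' @slot seed integer(1).
#' @name SimulationConfig-class
#' @aliases SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(gridSize = "integer", sigma = "integer", K = "integer",
                 wavelength = "numeric", z = "numeric", pitch = "numeric",
                 amplitudeRange = "numeric", phaseRange = "numeric",
                 modulationSigmaPx = "numeric", noise = "character",
                 noiseParam = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@K < 1L) msg <- c(msg, "'K' must be >= 1")
    if (any(object@sigma < 1L)) msg <- c(msg, "'sigma' must be >= 1")
    if (any(object@gridSize %% object@sigma != 0L))
      msg <- c(msg, "'gridSize' must be divisible by 'sigma'")
    if (object@amplitudeRange[1L] <= 0 || object@amplitudeRange[2L] > 1 ||
        diff(object@amplitudeRange) < 0)
      msg <- c(msg, "'amplitudeRange' must lie in (0, 1] (passive sample)")
    if (!object@noise %in% c("none", "gaussian", "poisson"))
      msg <- c(msg, "'noise' must be \"none\", \"gaussian\" or \"poisson\"")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SimulationConfig
#'
#' @param gridSize integer(2) or scalar, reconstruction grid size.
#' @param sigma integer(2) or scalar, binning factors.
#' @param K number of diversity measurements.
#' @param wavelength,z,pitch system geometry in um.
#' @param amplitudeRange,phaseRange affine target ranges for the sample
#'   amplitude (in (0, 1]) and phase (radians).
#' @param modulationSigmaPx Gaussian filter width (pixels) for the random
#'   modulation patterns.
#' @param noise "none", "gaussian" (additive on intensity at \code{noiseParam}
#'   dB SNR, clipped at zero) or "poisson" (\code{noiseParam} expected photons
#'   at the mean-intensity pixel).
#' @param noiseParam noise parameter, see \code{noise}.
#' @param seed RNG seed for all stochastic generator components.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(gridSize = c(256L, 256L), sigma = c(4L, 4L),
                             K = 8L, wavelength = 0.532, z = 500,
                             pitch = 0.95, amplitudeRange = c(0.2, 1),
                             phaseRange = c(0, pi), modulationSigmaPx = 4,
                             noise = "none", noiseParam = NA_real_,
                             seed = 1L) {
  new("SimulationConfig",
      gridSize = as.integer(rep(gridSize, length.out = 2L)),
      sigma = as.integer(rep(sigma, length.out = 2L)),
      K = as.integer(K), wavelength = as.numeric(wavelength),
      z = as.numeric(z), pitch = as.numeric(pitch),
      amplitudeRange = as.numeric(amplitudeRange),
      phaseRange = as.numeric(phaseRange),
      modulationSigmaPx = as.numeric(modulationSigmaPx),
      noise = noise, noiseParam = as.numeric(noiseParam),
      seed = as.integer(seed))
}
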