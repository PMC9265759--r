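#' @include AllClasses.R
NULL

#' Accessors for awflow objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{fieldValues} (complex sample matrix), \code{pitch} (um per sample),
#' \code{wavelength} (um), \code{gridDim} (grid dimensions),
#' \code{numPatterns} (number of diversity measurements K),
#' \code{modulations} (list of modulation phase matrices),
#' \code{sampling} (the crop/binning model), \code{intensities}
#' (the recorded y_k^2 array), \code{convergenceHistory} (per-iteration
#' records of a run), \code{finalField} (the reconstructed field) and
#' \code{stepSizeUsed} (the gamma a run actually used).
#'
#' @param x an awflow object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))
#' @rdname accessors
#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("numPatterns", function(x) standardGeneric("numPatterns"))
#' @rdname accessors
#' @export
setGeneric("modulations", function(x) standardGeneric("modulations"))
#' @rdname accessors
#' @export
setGeneric("sampling", function(x) standardGeneric("sampling"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("convergenceHistory", function(x) standardGeneric("convergenceHistory"))
#' @rdname accessors
#' @export
setGeneric("finalField", function(x) standardGeneric("finalField"))
#' @rdname accessors
#' @export
setGeneric("stepSizeUsed", function(x) standardGeneric("stepSizeUsed"))

#' @rdname accessors
setMethod("fieldValues", "ComplexField", function(x) x@values)
#' @rdname accessors
setMethod("pitch", "ComplexField", function(x) x@pitch)
#' @rdname accessors
setMethod("wavelength", "ComplexField", function(x) x@wavelength)
#' @rdname accessors
setMethod("gridDim", "ComplexField", function(x) dim(x@values))
#' @rdname accessors
setMethod("pitch", "SystemOperator", function(x) x@pitch)
#' @rdname accessors
setMethod("wavelength", "SystemOperator", function(x) x@wavelength)
#' @rdname accessors
setMethod("gridDim", "SystemOperator", function(x) x@gridSize)
#' @rdname accessors
setMethod("numPatterns", "SystemOperator", function(x) length(x@modulations))
#' @rdname accessors
setMethod("modulations", "SystemOperator", function(x) x@modulations)
#' @rdname accessors
setMethod("sampling", "SystemOperator", function(x) x@sampling)
#' @rdname accessors
setMethod("numPatterns", "MeasurementStack", function(x) dim(x@intensities)[3L])
#' @rdname accessors
setMethod("intensities", "MeasurementStack", function(x) x@intensities)
#' @rdname accessors
setMethod("sampling", "MeasurementStack", function(x) x@system@sampling)
#' @rdname accessors
setMethod("gridDim", "MeasurementStack", function(x) x@system@gridSize)
#' @rdname accessors
setMethod("convergenceHistory", "ReconResult", function(x) x@history)
#' @rdname accessors
setMethod("finalField", "ReconResult", function(x) x@estimate)
#' @rdname accessors
setMethod("stepSizeUsed", "ReconResult", function(x) x@gamma)

#' Extract the generating system of a measurement stack
#'
#' @param x a \linkS4class{MeasurementStack}.
#' @return The \linkS4class{SystemOperator} stored with the stack.
#' @export
setGeneric("systemOf", function(x) standardGeneric("systemOf"))
#' @rdname systemOf
setMethod("systemOf", "MeasurementStack", function(x) x@system)

setMethod("show", "ComplexField", function(object) {
  d <- dim(object@values)
  cat(sprintf("ComplexField: %d x %d samples, pitch %.4g um, wavelength %.4g um\n",
              d[1L], d[2L], object@pitch, object@wavelength))
  cat(sprintf("  amplitude range [%.4g, %.4g]\n",
              min(Mod(object@values)), max(Mod(object@values))))
})

setMethod("show", "SamplingOperator", function(object) {
  d <- object@cropSize %/% object@sigma
  cat(sprintf("SamplingOperator: grid %d x %d -> crop %d x %d (offset %d, %d) -> sensor %d x %d\n",
              object@gridSize[1L], object@gridSize[2L],
              object@cropSize[1L], object@cropSize[2L],
              object@cropOffset[1L], object@cropOffset[2L], d[1L], d[2L]))
  cat(sprintf("  binning sigma = %d x %d = %d, weights in [%.3g, %.3g]\n",
              object@sigma[1L], object@sigma[2L], prod(object@sigma),
              min(object@weights), max(object@weights)))
})

setMethod("show", "SystemOperator", function(object) {
  cat(sprintf("SystemOperator: A_k = C H M_k, K = %d measurements\n",
              length(object@modulations)))
  cat(sprintf("  grid %d x %d, pitch %.4g um, wavelength %.4g um, z = %.4g um\n",
              object@gridSize[1L], object@gridSize[2L], object@pitch,
              object@wavelength, object@z))
  show(object@sampling)
})

setMethod("show", "MeasurementStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("MeasurementStack: %d intensity images of %d x %d sensor pixels\n",
              d[3L], d[1L], d[2L]))
  if (nzchar(object@truthHash))
    cat(sprintf("  simulated (truth digest %s)\n", object@truthHash))
  show(object@system)
})

setMethod("show", "Regularizer", function(object) {
  cat(sprintf("Regularizer: kind = %s, lambda = %.4g, innerIterations = %d, warmStart = %s\n",
              object@kind, object@lambda, object@innerIterations,
              object@warmStart))
})

setMethod("show", "ReconResult", function(object) {
  h <- object@history
  cat(sprintf("ReconResult: %d iterations, gamma = %.4g\n", nrow(h), object@gamma))
  if (nrow(h) > 0L)
    cat(sprintf("  final fidelity %.6g%s\n", h$fidelity[nrow(h)],
                if (!is.null(h$rmseComplex) && !all(is.na(h$rmseComplex)))
                  sprintf(", final rmseComplex %.6g", h$rmseComplex[nrow(h)])
                else ""))
  show(object@estimate)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: grid %d x %d, sigma %d x %d, K = %d\n",
              object@gridSize[1L], object@gridSize[2L], object@sigma[1L],
              object@sigma[2L], object@K))
  cat(sprintf("  wavelength %.4g um, z %.4g um, pitch %.4g um, noise = %s\n",
              object@wavelength, object@z, object@pitch, object@noise))
})
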