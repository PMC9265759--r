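# container schema version written into every archive/sidecar
.STACK_SCHEMA <- 1L

#' Write / read a measurement stack archive
#'
#' The primary container is a single serialized archive (.rds) holding the
#' intensity images, modulation patterns and all system attributes; the
#' round trip is bitwise lossless. For interchange with other tools see
#' \code{\link{exportStackTIFF}} / \code{\link{importStackTIFF}}.
#'
#' @param stack a \linkS4class{MeasurementStack}.
#' @param path file path (conventionally ending in .rds).
#' @return \code{writeStack} returns \code{path} invisibly;
#'   \code{readStack} returns the \linkS4class{MeasurementStack}.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "MeasurementStack"))
  sys <- stack@system
  samp <- sys@sampling
  payload <- list(
    schema = .STACK_SCHEMA,
    intensities = stack@intensities,
    modulations = sys@modulations,
    wavelength_um = sys@wavelength, z_um = sys@z, pitch_um = sys@pitch,
    sigma = samp@sigma, gridSize = samp@gridSize,
    cropSize = samp@cropSize, cropOffset = samp@cropOffset,
    weights = samp@weights, truthHash = stack@truthHash)
  saveRDS(payload, path)
  invisible(path)
}

.requireFields <- function(x, fields, where) {
  miss <- setdiff(fields, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required attribute(s): %s", where,
                 paste(miss, collapse = ", ")))
}

.stackFromPayload <- function(p, where) {
  .requireFields(p, c("schema", "intensities", "modulations",
                      "wavelength_um", "z_um", "pitch_um", "sigma",
                      "gridSize", "cropSize", "cropOffset", "weights"),
                 where)
  d <- dim(p$intensities)
  expect <- as.integer(p$cropSize) %/% as.integer(p$sigma)
  if (!identical(d[1:2], expect))
    stop(sprintf("%s: intensity images are %d x %d but sigma/crop imply %d x %d",
                 where, d[1L], d[2L], expect[1L], expect[2L]))
  samp <- samplingOperator(p$gridSize, sigma = p$sigma,
                           cropSize = p$cropSize, cropOffset = p$cropOffset,
                           weights = p$weights)
  sys <- systemOperator(p$modulations, pitch = p$pitch_um,
                        wavelength = p$wavelength_um, z = p$z_um,
                        sampling = samp)
  measurementStack(p$intensities, sys,
                   truthHash = if (is.null(p$truthHash)) "" else p$truthHash)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  p <- readRDS(path)
  .stackFromPayload(p, where = path)
}

#' Export / import a stack as TIFF images plus a YAML sidecar
#'
#' Writes one 16-bit TIFF per intensity image (affinely rescaled to [0, 1];
#' the scale is recorded in the sidecar), one 32-bit float TIFF per
#' modulation pattern (phase / 2 pi), a weights TIFF, and a
#' \code{stack.yaml} sidecar carrying the system attributes. The import path
#' validates the sidecar schema and reassembles the stack; intensities are
#' recovered up to 16-bit quantization, modulation phases to float32
#' precision.
#'
#' @param stack a \linkS4class{MeasurementStack}.
#' @param dir directory to create/fill.
#' @return \code{exportStackTIFF} returns \code{dir} invisibly;
#'   \code{importStackTIFF} returns the \linkS4class{MeasurementStack}.
#' @export
exportStackTIFF <- function(stack, dir) {
  stopifnot(is(stack, "MeasurementStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sys <- stack@system
  samp <- sys@sampling
  K <- numPatterns(stack)
  imax <- max(stack@intensities)
  if (imax <= 0) imax <- 1
  for (k in seq_len(K))
    tiff::writeTIFF(stack@intensities[, , k] / imax,
                    file.path(dir, sprintf("meas_%03d.tif", k)),
                    bits.per.sample = 16L)
  for (k in seq_len(K))
    tiff::writeTIFF(sys@modulations[[k]] / (2 * pi),
                    file.path(dir, sprintf("mod_%03d.tif", k)),
                    bits.per.sample = 32L)
  tiff::writeTIFF(samp@weights, file.path(dir, "weights.tif"),
                  bits.per.sample = 32L)
  meta <- list(schema = .STACK_SCHEMA, K = K,
               wavelength_um = sys@wavelength, z_um = sys@z,
               pitch_um = sys@pitch, sigma = as.integer(samp@sigma),
               gridSize = as.integer(samp@gridSize),
               cropSize = as.integer(samp@cropSize),
               cropOffset = as.integer(samp@cropOffset),
               intensity_scale = imax, modulation_scale = 2 * pi,
               truthHash = stack@truthHash)
  yaml::write_yaml(meta, file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname exportStackTIFF
#' @export
importStackTIFF <- function(dir) {
  sidecar <- file.path(dir, "stack.yaml")
  if (!file.exists(sidecar))
    stop(sprintf("%s: missing stack.yaml sidecar", dir))
  meta <- yaml::read_yaml(sidecar)
  .requireFields(meta, c("schema", "K", "wavelength_um", "z_um", "pitch_um",
                         "sigma", "gridSize", "cropSize", "cropOffset",
                         "intensity_scale", "modulation_scale"), sidecar)
  K <- meta$K
  ints <- NULL
  for (k in seq_len(K)) {
    m <- tiff::readTIFF(file.path(dir, sprintf("meas_%03d.tif", k)))
    if (is.null(ints)) ints <- array(0, c(dim(m), K))
    ints[, , k] <- m * meta$intensity_scale
  }
  mods <- lapply(seq_len(K), function(k)
    tiff::readTIFF(file.path(dir, sprintf("mod_%03d.tif", k))) *
      meta$modulation_scale)
  wfile <- file.path(dir, "weights.tif")
  weights <- if (file.exists(wfile)) tiff::readTIFF(wfile) else 1
  p <- list(schema = meta$schema, intensities = ints, modulations = mods,
            wavelength_um = meta$wavelength_um, z_um = meta$z_um,
            pitch_um = meta$pitch_um, sigma = as.integer(meta$sigma),
            gridSize = as.integer(meta$gridSize),
            cropSize = as.integer(meta$cropSize),
            cropOffset = as.integer(meta$cropOffset), weights = weights,
            truthHash = if (is.null(meta$truthHash)) "" else meta$truthHash)
  .stackFromPayload(p, where = dir)
}

#' Write / read a convergence history as CSV
#'
#' Floats are written with 17 significant digits so the CSV re-parses to
#' bit-identical doubles.
#'
#' @param history a history data.frame (see \linkS4class{ReconResult}).
#' @param path CSV file path.
#' @return \code{writeHistory} returns \code{path} invisibly;
#'   \code{readHistory} returns the data.frame.
#' @export
writeHistory <- function(history, path) {
  out <- history
  for (nm in names(out))
    if (is.double(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHistory
#' @export
readHistory <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(h), "iter")) h[[nm]] <- as.numeric(h[[nm]])
  if ("iter" %in% names(h)) h$iter <- as.integer(h$iter)
  h
}

#' Write / read a reconstruction result archive
#'
#' Single-file serialized container for a \linkS4class{ReconResult};
#' bitwise-lossless round trip. For image interchange use
#' \code{\link{exportReconTIFF}}.
#'
#' @param result a \linkS4class{ReconResult}.
#' @param path file path (.rds).
#' @return \code{writeRecon} returns \code{path} invisibly;
#'   \code{readRecon} the \linkS4class{ReconResult}.
#' @export
writeRecon <- function(result, path) {
  stopifnot(is(result, "ReconResult"))
  est <- result@estimate
  saveRDS(list(schema = .STACK_SCHEMA, values = est@values,
               pitch_um = est@pitch, wavelength_um = est@wavelength,
               history = result@history, gamma = result@gamma,
               config = result@config), path)
  invisible(path)
}

#' @rdname writeRecon
#' @export
readRecon <- function(path) {
  p <- readRDS(path)
  .requireFields(p, c("schema", "values", "pitch_um", "wavelength_um",
                      "history", "gamma", "config"), path)
  new("ReconResult",
      estimate = complexField(p$values, p$pitch_um, p$wavelength_um),
      history = p$history, gamma = p$gamma, config = p$config)
}

#' Write / read a complex field archive
#'
#' Single-file serialized container for a \linkS4class{ComplexField} (e.g. a
#' simulation ground truth); bitwise-lossless round trip.
#'
#' @param field a \linkS4class{ComplexField}.
#' @param path file path (.rds).
#' @return \code{writeField} returns \code{path} invisibly; \code{readField}
#'   the \linkS4class{ComplexField}.
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "ComplexField"))
  saveRDS(list(schema = .STACK_SCHEMA, values = field@values,
               pitch_um = field@pitch, wavelength_um = field@wavelength),
          path)
  invisible(path)
}

#' @rdname writeField
#' @export
readField <- function(path) {
  p <- readRDS(path)
  .requireFields(p, c("schema", "values", "pitch_um", "wavelength_um"), path)
  complexField(p$values, p$pitch_um, p$wavelength_um)
}

#' Export a reconstruction as amplitude/phase TIFFs plus history CSV
#'
#' Writes \code{amplitude.tif} and \code{phase.tif} (32-bit float, affinely
#' rescaled to [0, 1] with scales recorded in \code{recon.yaml}) and the
#' convergence history as \code{history.csv}.
#'
#' @param result a \linkS4class{ReconResult}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
exportReconTIFF <- function(result, dir) {
  stopifnot(is(result, "ReconResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- result@estimate
  amp <- Mod(est@values)
  ph <- Arg(est@values)
  arange <- range(amp)
  if (diff(arange) == 0) arange[2L] <- arange[1L] + 1
  tiff::writeTIFF((amp - arange[1L]) / diff(arange),
                  file.path(dir, "amplitude.tif"), bits.per.sample = 32L)
  tiff::writeTIFF((ph + pi) / (2 * pi), file.path(dir, "phase.tif"),
                  bits.per.sample = 32L)
  writeHistory(result@history, file.path(dir, "history.csv"))
  yaml::write_yaml(list(schema = .STACK_SCHEMA,
                        amplitude_offset = arange[1L],
                        amplitude_scale = diff(arange),
                        phase_offset = -pi, phase_scale = 2 * pi,
                        pitch_um = est@pitch,
                        wavelength_um = est@wavelength,
                        gamma = result@gamma),
                   file.path(dir, "recon.yaml"))
  invisible(dir)
}
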