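#' Ambiguity-aligned reconstruction errors
#'
#' Intensity measurements are blind to a global phase, so the estimate is
#' first rotated by the closed-form optimal phasor e^{i phi*} with
#' phi* = Arg(<x_true, x_hat>) before any error is computed. Reported
#' metrics: \code{rmseComplex} = ||aligned - truth||_2 / sqrt(n),
#' \code{rmseAmp} on the moduli, \code{rmsePhase} on the wrapped phase
#' difference (mapped to (-pi, pi]), and \code{relError} =
#' ||aligned - truth|| / ||truth||. A border margin (default: the binning
#' factors) is excluded to keep circular-convolution wrap-around out of the
#' metric.
#'
#' @param xHat,xTrue \linkS4class{ComplexField}s on the same grid.
#' @param border integer(2) (or scalar) margin in pixels excluded on every
#'   side; NULL uses the default margin of \code{defaultBorder}.
#' @param defaultBorder fallback margin when \code{border} is NULL.
#' @return A list with rmseAmp, rmsePhase, rmseComplex, relError and the
#'   alignment phase \code{phi}.
#' @export
alignedRMSE <- function(xHat, xTrue, border = NULL, defaultBorder = 0L) {
  stopifnot(is(xHat, "ComplexField"), is(xTrue, "ComplexField"))
  a <- xHat@values; b <- xTrue@values
  if (!identical(dim(a), dim(b)))
    stop("fields must share the same grid")
  if (is.null(border)) border <- defaultBorder
  border <- as.integer(rep(border, length.out = 2L))
  if (any(border > 0L)) {
    rows <- seq.int(border[1L] + 1L, nrow(a) - border[1L])
    cols <- seq.int(border[2L] + 1L, ncol(a) - border[2L])
    a <- a[rows, cols, drop = FALSE]
    b <- b[rows, cols, drop = FALSE]
  }
  phi <- Arg(sum(b * Conj(a)))
  al <- a * exp(1i * phi)
  n <- length(al)
  dphi <- Arg(al) - Arg(b)
  dphi <- ((dphi + pi) %% (2 * pi)) - pi        # wrap to (-pi, pi]
  nb <- sqrt(sum(Mod(b)^2))
  list(rmseAmp = sqrt(sum((Mod(al) - Mod(b))^2) / n),
       rmsePhase = sqrt(sum(dphi^2) / n),
       rmseComplex = sqrt(sum(Mod(al - b)^2) / n),
       relError = if (nb > 0) sqrt(sum(Mod(al - b)^2)) / nb else NA_real_,
       phi = phi)
}

#' Ground-truth phase of a height structure
#'
#' phi = 2 * pi * h * (RI - 1) / w for a structure of height \code{h} and
#' refractive index \code{RI} in a medium of unit index, illuminated at
#' wavelength \code{w} (all lengths in the same unit).
#'
#' @param h structure height (um).
#' @param RI refractive index (> 1).
#' @param w illumination wavelength (um).
#' @return Phase in radians.
#' @examples
#' phaseFromHeight(h = 0.35, RI = 1.52, w = 0.532)
#' @export
phaseFromHeight <- function(h, RI, w) {
  if (any(h <= 0) || any(RI <= 1) || any(w <= 0))
    stop("'h' and 'w' must be positive and 'RI' > 1")
  2 * pi * h * (RI - 1) / w
}

#' First iteration at which a convergence metric reaches a threshold
#'
#' @param history a convergence history data.frame (see
#'   \linkS4class{ReconResult}).
#' @param metric column name, e.g. "fidelity" or "rmseComplex".
#' @param threshold the target value.
#' @param relative if TRUE, the threshold is multiplied by the metric's
#'   first recorded value.
#' @return The first \code{iter} with metric <= threshold, or
#'   \code{NA_integer_} when never reached.
#' @export
iterationsToThreshold <- function(history, metric = "fidelity", threshold,
                                  relative = FALSE) {
  if (!is.data.frame(history) || nrow(history) == 0L)
    stop("'history' must be a non-empty data.frame")
  if (!metric %in% names(history))
    stop(sprintf("metric column '%s' not found in history", metric))
  v <- history[[metric]]
  if (relative) threshold <- threshold * v[1L]
  hit <- which(v <= threshold)
  if (length(hit) == 0L) NA_integer_ else history$iter[hit[1L]]
}
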