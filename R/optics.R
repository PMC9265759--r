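#' Angular-spectrum transfer function
#'
#' Frequency-domain kernel for exact scalar free-space propagation over a
#' distance \code{z}: at spatial frequency (fx, fy) the kernel is
#' \code{exp(2i * pi * z * sqrt(1/lambda^2 - fx^2 - fy^2))} on propagating
#' frequencies (\code{fx^2 + fy^2 <= 1/lambda^2}) and 0 on evanescent ones.
#' Zeroing the evanescent band makes the kernel modulus at most 1 everywhere,
#' so propagation is non-expansive — the property the automatic step-size
#' rule of the solver relies on. Frequencies follow the unnormalized FFT
#' convention fx = j / (N * pitch) with DC at index (1, 1).
#'
#' @param gridSize integer(2) (or scalar), grid dimensions (N1, N2).
#' @param pitch sample pitch in um.
#' @param wavelength wavelength in um.
#' @param z propagation distance in um; 0 or negative (back-propagation)
#'   allowed.
#' @return An N1 x N2 complex matrix, unit modulus on propagating
#'   frequencies and 0 on evanescent ones.
#' @examples
#' k <- angularSpectrumKernel(c(32, 32), pitch = 1.27, wavelength = 0.532,
#'                            z = 100)
#' range(Mod(k))
#' @export
angularSpectrumKernel <- function(gridSize, pitch, wavelength, z) {
  gridSize <- as.integer(rep(gridSize, length.out = 2L))
  if (pitch <= 0 || wavelength <= 0)
    stop("'pitch' and 'wavelength' must be positive")
  fx <- .fftFreq(gridSize[1L], pitch)
  fy <- .fftFreq(gridSize[2L], pitch)
  arg <- outer(fx^2, fy^2, "+")
  radic <- 1 / wavelength^2 - arg
  kern <- matrix(0 + 0i, gridSize[1L], gridSize[2L])
  prop <- radic >= 0
  kern[prop] <- exp(2i * pi * z * sqrt(radic[prop]))
  kern
}

#' Free-space propagation of a wavefield
#'
#' Propagates a \linkS4class{ComplexField} over distance \code{z} via
#' circular convolution with the angular-spectrum kernel (multiplication in
#' the frequency domain). Energy is non-increasing, and conserved whenever no
#' energy sits on evanescent frequencies; propagating by \code{z} then
#' \code{-z} restores the propagating part of the input.
#'
#' @param field a \linkS4class{ComplexField}.
#' @param z propagation distance in um.
#' @param kernel optional precomputed kernel for this (grid, pitch,
#'   wavelength, z); passed by inner loops to avoid recomputation.
#' @return The propagated \linkS4class{ComplexField}.
#' @export
propagateField <- function(field, z, kernel = NULL) {
  stopifnot(is(field, "ComplexField"))
  if (is.null(kernel))
    kernel <- angularSpectrumKernel(dim(field@values), field@pitch,
                                    field@wavelength, z)
  if (!identical(dim(kernel), dim(field@values)))
    stop("kernel and field grids do not match")
  vals <- .ifft2(kernel * .fft2(field@values))
  complexField(vals, field@pitch, field@wavelength)
}

# crop window row/col indices (1-based) of a sampling operator
.cropRows <- function(samp) seq.int(samp@cropOffset[1L] + 1L,
                                    samp@cropOffset[1L] + samp@cropSize[1L])
.cropCols <- function(samp) seq.int(samp@cropOffset[2L] + 1L,
                                    samp@cropOffset[2L] + samp@cropSize[2L])

.cropMatrix <- function(x, samp) x[.cropRows(samp), .cropCols(samp), drop = FALSE]

.padMatrix <- function(x, samp) {
  out <- matrix(if (is.complex(x)) 0 + 0i else 0,
                samp@gridSize[1L], samp@gridSize[2L])
  out[.cropRows(samp), .cropCols(samp)] <- x
  out
}

# sum of sigma1 x sigma2 blocks of an M1 x M2 matrix
.blockSum <- function(x, s1, s2) {
  d1 <- nrow(x) %/% s1
  d2 <- ncol(x) %/% s2
  a <- array(x, c(s1, d1, s2, d2))
  colSums(aperm(array(colSums(a), c(d1, s2, d2)), c(2L, 1L, 3L)))
}

# replicate a d1 x d2 matrix into sigma blocks (adjoint of the block sum)
.blockExpand <- function(y, s1, s2) {
  y[rep(seq_len(nrow(y)), each = s1), rep(seq_len(ncol(y)), each = s2),
    drop = FALSE]
}

#' Sensor pixel binning (down-sampling operator S)
#'
#' Collapses the cropped high-resolution intensity grid onto the sensor
#' pixel grid: each sensor pixel is the weighted sum of its sigma1 x sigma2
#' sub-pixel intensities. With the default unit weights this is a plain
#' block sum, and with sigma = 1 it is the identity (the classical phase
#' retrieval limit).
#'
#' @param intensity non-negative real matrix on the cropped (M1 x M2) grid.
#' @param samp a \linkS4class{SamplingOperator}.
#' @return A d1 x d2 matrix of sensor-pixel values.
#' @export
downsampleIntensity <- function(intensity, samp) {
  stopifnot(is(samp, "SamplingOperator"))
  if (!identical(dim(intensity), as.integer(samp@cropSize)))
    stop("'intensity' must live on the cropped grid (M1 x M2)")
  .blockSum(samp@weights * intensity, samp@sigma[1L], samp@sigma[2L])
}

#' Adjoint of the sensor binning (S^T)
#'
#' Spreads each sensor-pixel value back over its sub-pixels, multiplied by
#' the sub-pixel weight. \code{upsampleAdjoint(1, samp)} realizes the weight
#' vector s = S^T 1 of the step-size rule, identically 1 under unit weights.
#'
#' @param y real matrix on the sensor (d1 x d2) grid.
#' @param samp a \linkS4class{SamplingOperator}.
#' @return An M1 x M2 matrix on the cropped grid.
#' @export
upsampleAdjoint <- function(y, samp) {
  stopifnot(is(samp, "SamplingOperator"))
  d <- samp@cropSize %/% samp@sigma
  if (length(y) == 1L) y <- matrix(y, d[1L], d[2L])
  if (!identical(dim(y), as.integer(d)))
    stop("'y' must live on the sensor grid (d1 x d2)")
  samp@weights * .blockExpand(y, samp@sigma[1L], samp@sigma[2L])
}

#' Apply the forward map A_k = C H M_k
#'
#' Phase modulation by pattern k, angular-spectrum propagation to the sensor
#' plane, and crop to the sensor window. The result lives on the cropped
#' grid; intensity formation and binning are applied separately by
#' \code{\link{forwardMeasure}}.
#'
#' @param x a \linkS4class{ComplexField} on the full grid.
#' @param sys a \linkS4class{SystemOperator}.
#' @param k measurement index in 1..K.
#' @return A \linkS4class{ComplexField} on the cropped (M1 x M2) grid.
#' @export
applyForward <- function(x, sys, k) {
  stopifnot(is(x, "ComplexField"), is(sys, "SystemOperator"))
  if (k < 1L || k > length(sys@modulations))
    stop(sprintf("measurement index k = %d out of range 1..%d", k,
                 length(sys@modulations)))
  if (!identical(dim(x@values), as.integer(sys@gridSize)))
    stop("field grid does not match the system grid")
  mod <- sys@phasors[[k]] * x@values
  prop <- .ifft2(sys@kernel * .fft2(mod))
  complexField(.cropMatrix(prop, sys@sampling), x@pitch, x@wavelength)
}

#' Apply the adjoint map A_k^H = M_k^H H^H C^T
#'
#' Zero-pads a residual field from the sensor window back to the full grid,
#' back-propagates with the conjugated kernel, and removes the phase
#' modulation. Satisfies the adjoint identity
#' \code{<A_k x, y> == <x, A_k^H y>} to machine precision.
#'
#' @param r a \linkS4class{ComplexField} (or complex matrix) on the cropped
#'   grid.
#' @param sys a \linkS4class{SystemOperator}.
#' @param k measurement index in 1..K.
#' @return A \linkS4class{ComplexField} on the full grid.
#' @export
applyAdjoint <- function(r, sys, k) {
  stopifnot(is(sys, "SystemOperator"))
  if (k < 1L || k > length(sys@modulations))
    stop(sprintf("measurement index k = %d out of range 1..%d", k,
                 length(sys@modulations)))
  vals <- if (is(r, "ComplexField")) r@values else r
  if (!identical(dim(vals), as.integer(sys@sampling@cropSize)))
    stop("residual grid does not match the sensor window")
  padded <- .padMatrix(vals, sys@sampling)
  back <- .ifft2(Conj(sys@kernel) * .fft2(padded))
  complexField(Conj(sys@phasors[[k]]) * back, sys@pitch, sys@wavelength)
}

#' Forward intensity measurement y_k^2 = S |A_k x|^2
#'
#' @param x a \linkS4class{ComplexField} on the full grid.
#' @param sys a \linkS4class{SystemOperator}.
#' @param k measurement index in 1..K.
#' @return A non-negative d1 x d2 matrix of simulated sensor intensities.
#' @export
forwardMeasure <- function(x, sys, k) {
  a <- applyForward(x, sys, k)
  downsampleIntensity(Mod(a@values)^2, sys@sampling)
}

#' Power-iteration estimate of the spectral radius of A_k^H diag(s) A_k
#'
#' Runs power iteration on the Hermitian positive semi-definite composition
#' x -> A_k^H (s * (A_k x)) where s = S^T 1 is the per-subpixel weight
#' vector. The estimate is deterministic given \code{seed}, non-decreasing
#' in the iteration count (up to round-off), and never exceeds the true
#' spectral radius; under the default unit weights that radius is at most 1.
#'
#' @param sys a \linkS4class{SystemOperator}.
#' @param k measurement index in 1..K.
#' @param iterations number of power iterations (>= 1).
#' @param seed RNG seed for the start vector.
#' @return The spectral-radius estimate (non-negative scalar).
#' @export
spectralRadiusEstimate <- function(sys, k, iterations = 100L, seed = 1L) {
  stopifnot(is(sys, "SystemOperator"), iterations >= 1L)
  n <- sys@gridSize
  v <- .withSeed(seed, .complexRandn(n[1L], n[2L]))
  v <- v / sqrt(sum(Mod(v)^2))
  s <- sys@sampling@weights
  rho <- 0
  for (i in seq_len(iterations)) {
    a <- applyForward(complexField(v, sys@pitch, sys@wavelength), sys, k)
    w <- applyAdjoint(s * a@values, sys, k)@values
    nw <- sqrt(sum(Mod(w)^2))
    if (nw == 0) return(0)
    rho <- nw            # ||T v|| with ||v|| = 1, T Hermitian PSD
    v <- w / nw
  }
  rho
}
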