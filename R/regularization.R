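#' Forward finite differences (the TV analysis operator D)
#'
#' First differences along rows (vertical) and columns (horizontal) with a
#' Neumann boundary: the last difference in each direction is zero, the
#' standard convention in the proximal TV literature. Operates on complex
#' fields; the adjoint is \code{\link{finiteDifferenceAdjoint}} (a negative
#' divergence).
#'
#' @param x a \linkS4class{ComplexField} or a (complex) matrix.
#' @return A list with components \code{dh} (differences along columns,
#'   x[i, j+1] - x[i, j]) and \code{dv} (differences along rows), each the
#'   size of \code{x}.
#' @export
finiteDifference <- function(x) {
  v <- if (is(x, "ComplexField")) x@values else x
  dh <- v
  dh[, -ncol(v)] <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  dh[, ncol(v)] <- 0
  dv <- v
  dv[-nrow(v), ] <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  dv[nrow(v), ] <- 0
  list(dh = dh, dv = dv)
}

#' Adjoint of the finite-difference operator (negative divergence)
#'
#' @param dh,dv difference fields as returned by
#'   \code{\link{finiteDifference}}.
#' @return A matrix the size of the original field with
#'   \code{<Dx, p> == <x, D^H p>} holding to machine precision.
#' @export
finiteDifferenceAdjoint <- function(dh, dv) {
  nr <- nrow(dh); nc <- ncol(dh)
  dh[, nc] <- 0   # the last difference in each direction is structurally
  dv[nr, ] <- 0   # zero, so these dual components never act
  out <- matrix(0 + 0i, nr, nc)
  # horizontal: column j receives -dh[, j] + dh[, j - 1] (dh[, nc] is 0)
  out[, 1L] <- -dh[, 1L]
  if (nc > 1L)
    out[, -1L] <- dh[, -nc, drop = FALSE] - dh[, -1L, drop = FALSE]
  out2 <- matrix(0 + 0i, nr, nc)
  out2[1L, ] <- -dv[1L, ]
  if (nr > 1L)
    out2[-1L, ] <- dv[-nr, , drop = FALSE] - dv[-1L, , drop = FALSE]
  out + out2
}

#' Anisotropic complex total variation
#'
#' \code{sum(|dh|) + sum(|dv|)} with the complex modulus, the regularization
#' functional R(x) = ||Dx||_1 used by the solver (scaled by lambda there).
#'
#' @param x a \linkS4class{ComplexField} or matrix.
#' @return Non-negative scalar.
#' @export
tvNorm <- function(x) {
  d <- finiteDifference(x)
  sum(Mod(d$dh)) + sum(Mod(d$dv))
}

# project complex dual pair onto the unit disk, componentwise
.projDisk <- function(p) {
  m <- pmax(1, Mod(p))
  p / m
}

#' Proximity operator of the regularizer
#'
#' Evaluates prox_{gamma R}(v) = argmin_x (1/(2 gamma)) ||x - v||^2 + R(x).
#' For \code{kind = "none"} (or lambda = 0) this is the identity. For the
#' anisotropic complex TV it runs projected-gradient ascent on the dual
#' problem (FGP-style): the two dual fields are clipped componentwise to the
#' complex unit disk, which shrinks each complex difference by its modulus.
#' A warm-started dual state can be supplied so that single inner iterations
#' accumulate accuracy across outer solver iterations.
#'
#' @param v a \linkS4class{ComplexField} or complex matrix.
#' @param gamma positive step size of the outer solver.
#' @param reg a \linkS4class{Regularizer}.
#' @param dual optional dual state (list \code{ph}, \code{pv}) from a
#'   previous call; \code{NULL} starts from zero.
#' @return A list with \code{x} (same type as \code{v}) and \code{dual} (the
#'   dual state, for warm starting).
#' @export
proxOperator <- function(v, gamma, reg, dual = NULL) {
  stopifnot(is(reg, "Regularizer"))
  if (gamma <= 0) stop("'gamma' must be positive")
  isField <- is(v, "ComplexField")
  vals <- if (isField) v@values else v
  if (reg@kind == "none" || reg@lambda == 0)
    return(list(x = v, dual = dual))
  tau <- gamma * reg@lambda
  nr <- nrow(vals); nc <- ncol(vals)
  if (is.null(dual))
    dual <- list(ph = matrix(0 + 0i, nr, nc), pv = matrix(0 + 0i, nr, nc))
  ph <- dual$ph; pv <- dual$pv
  # dual objective gradient step 1/(8 tau) (Lipschitz bound of D D^H is 8)
  step <- 1 / (8 * tau)
  x <- vals
  for (it in seq_len(reg@innerIterations)) {
    x <- vals - tau * finiteDifferenceAdjoint(ph, pv)
    g <- finiteDifference(x)
    ph <- .projDisk(ph + step * g$dh)
    pv <- .projDisk(pv + step * g$dv)
  }
  x <- vals - tau * finiteDifferenceAdjoint(ph, pv)
  out <- if (isField) complexField(x, v@pitch, v@wavelength) else x
  list(x = out, dual = list(ph = ph, pv = pv))
}
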