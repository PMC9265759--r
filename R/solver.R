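#' Amplitude-based data fidelity
#'
#' F(x) = (1/(2K)) sum_k || sqrt(S |A_k x|^2) - y_k ||^2, the lower-order
#' (amplitude) residual between the binned model intensities and the
#' recorded amplitudes y_k = sqrt of the measured intensities. Minimizing
#' the amplitude residual rather than the intensity residual is what gives
#' Wirtinger flow its favourable convergence behaviour on this problem.
#'
#' @param x a \linkS4class{ComplexField} on the reconstruction grid.
#' @param stack a \linkS4class{MeasurementStack}.
#' @param sys optional \linkS4class{SystemOperator}; defaults to the one
#'   stored in the stack.
#' @return Non-negative scalar.
#' @export
fidelity <- function(x, stack, sys = systemOf(stack)) {
  K <- numPatterns(stack)
  total <- 0
  for (k in seq_len(K)) {
    b <- sqrt(forwardMeasure(x, sys, k))
    y <- sqrt(stack@intensities[, , k])
    total <- total + sum((b - y)^2)
  }
  total / (2 * K)
}

# gradient and (free) fidelity at the same point, shared by the solver loop
.gradientAndFidelity <- function(xvals, sys, amps) {
  K <- length(amps)
  samp <- sys@sampling
  grad <- matrix(0 + 0i, sys@gridSize[1L], sys@gridSize[2L])
  fid <- 0
  fld <- complexField(xvals, sys@pitch, sys@wavelength)
  for (k in seq_len(K)) {
    a <- applyForward(fld, sys, k)@values
    b <- sqrt(downsampleIntensity(Mod(a)^2, samp))
    y <- amps[[k]]
    fid <- fid + sum((b - y)^2)
    ratio <- matrix(0, nrow(b), ncol(b))
    pos <- b > 0
    ratio[pos] <- y[pos] / b[pos]      # zero-intensity entries: ratio := 0
    resid <- upsampleAdjoint(1 - ratio, samp)
    grad <- grad + applyAdjoint(a * resid, sys, k)@values
  }
  list(gradient = grad / (2 * K), fidelity = fid / (2 * K))
}

#' Wirtinger gradient of the fidelity
#'
#' The conjugate-coordinate (Wirtinger) gradient
#' (1/(2K)) sum_k A_k^H [ (A_k x) * S^T (1 - y_k / sqrt(S |A_k x|^2)) ].
#' Where a binned model intensity is exactly zero the ratio is set to zero
#' (a bounded subgradient choice at the non-smooth points). The real-calculus
#' directional derivative along a direction e equals 2 Re <grad, e>, which
#' is why the admissible step size carries a factor of two.
#'
#' @inheritParams fidelity
#' @return A \linkS4class{ComplexField} holding the gradient.
#' @export
wirtingerGradient <- function(x, stack, sys = systemOf(stack)) {
  amps <- lapply(seq_len(numPatterns(stack)),
                 function(k) sqrt(stack@intensities[, , k]))
  g <- .gradientAndFidelity(x@values, sys, amps)
  complexField(g$gradient, x@pitch, x@wavelength)
}

#' Automatic step-size bound from spectral radii
#'
#' gamma <= 2K / sum_k rho(A_k^H diag(s) A_k), with each spectral radius
#' estimated by power iteration. Under the default unit sensor weights each
#' radius is at most 1 (modulations are unitary, the propagation kernel has
#' modulus at most 1, the crop is a restriction), so the bound is at least
#' 2; the solver default uses min(bound, 2), which reproduces the canonical
#' step gamma = 2 for this system class.
#'
#' @param sys a \linkS4class{SystemOperator}.
#' @param iterations power iterations per measurement index.
#' @param seed RNG seed for the power-iteration start vectors.
#' @return Positive scalar step-size bound.
#' @export
stepSizeBound <- function(sys, iterations = 100L, seed = 1L) {
  K <- length(sys@modulations)
  rhos <- vapply(seq_len(K), function(k)
    max(spectralRadiusEstimate(sys, k, iterations = iterations, seed = seed),
        .Machine$double.eps), numeric(1))
  2 * K / sum(rhos)
}

#' Momentum coefficient schedule
#'
#' \code{"nesterov"}: beta_t = t / (t + 3), the extrapolation weight of the
#' accelerated iterates; \code{"none"}: 0, recovering plain (non-accelerated)
#' Wirtinger flow.
#'
#' @param t iteration counter (>= 1).
#' @param schedule "nesterov" or "none".
#' @return A value in [0, 1).
#' @export
momentumCoefficient <- function(t, schedule = c("nesterov", "none")) {
  schedule <- match.arg(schedule)
  stopifnot(t >= 1)
  if (schedule == "none") 0 else t / (t + 3)
}

#' Initialize the solver state
#'
#' @param stack a \linkS4class{MeasurementStack}.
#' @param sys the \linkS4class{SystemOperator}.
#' @param gamma step size.
#' @param init "flat" (constant field whose intensity matches the mean
#'   per-subpixel measured intensity, zero phase), "random" (seeded complex
#'   Gaussian at the same scale) or "backprop" (average back-propagated
#'   measured amplitude).
#' @param seed RNG seed (used by \code{init = "random"}).
#' @return A solver-state list with elements x, xPrev, u (complex matrices),
#'   t = 0, gamma, dual (NULL until the first proximal step).
#' @export
initializeState <- function(stack, sys = systemOf(stack), gamma = 2,
                            init = c("flat", "random", "backprop"),
                            seed = 1L) {
  init <- match.arg(init)
  n <- sys@gridSize
  sig <- prod(sys@sampling@sigma)
  amp0 <- sqrt(mean(stack@intensities) / sig)
  x0 <- switch(init,
    flat = matrix(amp0 + 0i, n[1L], n[2L]),
    random = amp0 * .withSeed(seed, .complexRandn(n[1L], n[2L])),
    backprop = {
      K <- numPatterns(stack)
      acc <- matrix(0 + 0i, n[1L], n[2L])
      for (k in seq_len(K)) {
        up <- upsampleAdjoint(sqrt(stack@intensities[, , k]), sys@sampling) / sig
        acc <- acc + applyAdjoint(up + 0i, sys, k)@values
      }
      acc / K
    })
  list(x = x0, xPrev = x0, u = x0, t = 0L, gamma = gamma, dual = NULL)
}

#' One accelerated Wirtinger flow iteration
#'
#' Performs the iterate triplet: a Wirtinger gradient step on the
#' extrapolated point u, a proximal step on the regularizer (identity when
#' lambda = 0), and a Nesterov extrapolation with beta_t = t/(t+3) (or 0 for
#' plain Wirtinger flow). The returned state carries a \code{record} entry
#' with the per-iteration log row.
#'
#' @param state a solver-state list from \code{\link{initializeState}} or a
#'   previous \code{awfStep}.
#' @param stack a \linkS4class{MeasurementStack}.
#' @param reg a \linkS4class{Regularizer}.
#' @param sys the \linkS4class{SystemOperator} (defaults to the stack's).
#' @param schedule momentum schedule, "nesterov" or "none".
#' @param logObjective if TRUE, evaluate the fidelity and objective at the
#'   new iterate x (one extra forward pass); if FALSE, log the fidelity at
#'   the gradient point u, which is free.
#' @param amps optional precomputed list of measured amplitude matrices.
#' @return The updated state list.
#' @export
awfStep <- function(state, stack, reg, sys = systemOf(stack),
                    schedule = "nesterov", logObjective = TRUE,
                    amps = NULL) {
  if (is.null(amps))
    amps <- lapply(seq_len(numPatterns(stack)),
                   function(k) sqrt(stack@intensities[, , k]))
  t <- state$t + 1L
  g <- .gradientAndFidelity(state$u, sys, amps)
  v <- state$u - state$gamma * g$gradient
  pr <- proxOperator(v, state$gamma, reg,
                     dual = if (reg@warmStart) state$dual else NULL)
  x <- pr$x
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    stop(sprintf("solver diverged at iteration %d (non-finite iterate)", t))
  beta <- momentumCoefficient(t, schedule)
  u <- x + beta * (x - state$x)
  if (logObjective) {
    fid <- .fidelityOnly(x, sys, amps)
    obj <- fid + reg@lambda * tvNorm(x)
  } else {
    fid <- g$fidelity   # at u^(t-1); exact for plain WF where u = x
    obj <- NA_real_
  }
  list(x = x, xPrev = state$x, u = u, t = t, gamma = state$gamma,
       dual = pr$dual,
       record = list(iter = t, fidelity = fid, objective = obj))
}

.fidelityOnly <- function(xvals, sys, amps) {
  K <- length(amps)
  fld <- complexField(xvals, sys@pitch, sys@wavelength)
  fid <- 0
  for (k in seq_len(K)) {
    a <- applyForward(fld, sys, k)@values
    b <- sqrt(downsampleIntensity(Mod(a)^2, sys@sampling))
    fid <- fid + sum((b - amps[[k]])^2)
  }
  fid / (2 * K)
}

#' Accelerated Wirtinger flow reconstruction
#'
#' Recovers the complex sample transmittance from a stack of low-resolution
#' intensity measurements by proximal-gradient iterations on the
#' amplitude-based fidelity plus an optional anisotropic complex TV penalty,
#' with Nesterov momentum. The step size defaults to
#' min(\code{\link{stepSizeBound}}, 2); for the modulation-diversity system
#' with unit sensor weights this is 2.
#'
#' @param stack a \linkS4class{MeasurementStack}.
#' @param sys the \linkS4class{SystemOperator}; defaults to the stack's own.
#' @param lambda TV regularization weight (0 disables the proximal step).
#' @param schedule "nesterov" (accelerated) or "none" (plain Wirtinger
#'   flow).
#' @param iterations number of iterations T (fixed budget).
#' @param gamma step size, or "auto" for min(stepSizeBound, 2).
#' @param init initialization rule, see \code{\link{initializeState}}.
#' @param seed RNG seed for every stochastic component (random init, power
#'   iteration starts).
#' @param truth optional ground-truth \linkS4class{ComplexField}; when
#'   given, ambiguity-aligned RMSEs are logged each iteration.
#' @param innerIterations,warmStart TV proximal solver settings, see
#'   \code{\link{regularizer}}.
#' @param logObjective log fidelity/objective at each iterate x (costs one
#'   extra forward pass per iteration); when FALSE the fidelity at the
#'   gradient point is logged instead and the objective column is NA.
#' @param rmseBorder border margin (pixels) excluded from RMSE computation;
#'   defaults to the binning factors.
#' @return A \linkS4class{ReconResult}.
#' @examples
#' cfg <- simulationConfig(gridSize = 32, sigma = 2, K = 4,
#'                         modulationSigmaPx = 1, seed = 7)
#' truth <- makeSample(cfg)
#' sys <- makeSystem(cfg)
#' stack <- simulateStack(truth, sys, seed = 7)
#' res <- awfReconstruct(stack, iterations = 50, seed = 7, truth = truth)
#' tail(convergenceHistory(res), 3)
#' @export
awfReconstruct <- function(stack, sys = systemOf(stack), lambda = 0,
                           schedule = c("nesterov", "none"),
                           iterations = 100L, gamma = "auto",
                           init = "flat", seed = 1L, truth = NULL,
                           innerIterations = 1L, warmStart = TRUE,
                           logObjective = TRUE, rmseBorder = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(iterations >= 1L)
  if (identical(gamma, "auto"))
    gamma <- min(stepSizeBound(sys, seed = seed), 2)
  reg <- regularizer(kind = if (lambda > 0) "tv" else "none",
                     lambda = lambda, innerIterations = innerIterations,
                     warmStart = warmStart)
  state <- initializeState(stack, sys, gamma = gamma, init = init,
                           seed = seed)
  amps <- lapply(seq_len(numPatterns(stack)),
                 function(k) sqrt(stack@intensities[, , k]))
  T <- as.integer(iterations)
  fid <- numeric(T); obj <- numeric(T)
  withTruth <- !is.null(truth)
  if (withTruth) {
    rmA <- numeric(T); rmP <- numeric(T); rmC <- numeric(T)
  }
  for (t in seq_len(T)) {
    state <- awfStep(state, stack, reg, sys, schedule = schedule,
                     logObjective = logObjective, amps = amps)
    fid[t] <- state$record$fidelity
    obj[t] <- state$record$objective
    if (withTruth) {
      est <- complexField(state$x, sys@pitch, sys@wavelength)
      m <- alignedRMSE(est, truth, border = rmseBorder)
      rmA[t] <- m$rmseAmp; rmP[t] <- m$rmsePhase; rmC[t] <- m$rmseComplex
    }
  }
  hist <- data.frame(iter = seq_len(T), fidelity = fid, objective = obj)
  if (withTruth) {
    hist$rmseAmp <- rmA; hist$rmsePhase <- rmP; hist$rmseComplex <- rmC
  }
  cfg <- list(lambda = lambda, schedule = schedule, iterations = T,
              gamma = gamma, init = init, seed = seed,
              innerIterations = innerIterations, warmStart = warmStart,
              logObjective = logObjective, rmseBorder = rmseBorder)
  new("ReconResult",
      estimate = complexField(state$x, sys@pitch, sys@wavelength),
      history = hist, gamma = gamma, config = cfg)
}
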