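# Dense-matrix oracles built from first principles (DFT matrix, explicit
# selection and binning rows), independent of the package's FFT code paths.
# All operate on column-major vectorized fields.

denseDFT1 <- function(n) {
  j <- 0:(n - 1)
  exp(-2i * pi * outer(j, j) / n)
}

# 2-D DFT on vec(X) (column-major): F2 kron F1
denseDFT2 <- function(n1, n2) {
  kronecker(denseDFT1(n2), denseDFT1(n1))
}

# angular-spectrum kernel values, written out independently of the package
oracleKernel <- function(n1, n2, pitch, wavelength, z) {
  freq <- function(n) {
    f <- 0:(n - 1)
    f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
    f / (n * pitch)
  }
  fx <- freq(n1); fy <- freq(n2)
  k <- matrix(0 + 0i, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    r <- 1 / wavelength^2 - fx[i]^2 - fy[j]^2
    if (r >= 0) k[i, j] <- exp(2i * pi * z * sqrt(r))
  }
  k
}

# H = F^{-1} diag(kernel) F as a dense matrix
denseH <- function(n1, n2, pitch, wavelength, z) {
  F <- denseDFT2(n1, n2)
  Finv <- Conj(F) / (n1 * n2)
  kern <- oracleKernel(n1, n2, pitch, wavelength, z)
  Finv %*% (as.vector(kern) * F)
}

denseM <- function(phase) diag(as.complex(exp(1i * as.vector(phase))))

# crop selection matrix C (m x n) from first principles
denseC <- function(gridSize, cropSize, cropOffset) {
  n <- prod(gridSize); m <- prod(cropSize)
  C <- matrix(0, m, n)
  r <- 0L
  for (j in seq_len(cropSize[2])) for (i in seq_len(cropSize[1])) {
    r <- r + 1L
    full <- (cropOffset[2] + j - 1L) * gridSize[1] + cropOffset[1] + i
    C[r, full] <- 1
  }
  C
}

# weighted binning matrix S (d x m) from first principles
denseS <- function(cropSize, sigma, weights) {
  d <- cropSize %/% sigma
  S <- matrix(0, prod(d), prod(cropSize))
  r <- 0L
  for (bj in seq_len(d[2])) for (bi in seq_len(d[1])) {
    r <- r + 1L
    for (aj in seq_len(sigma[2])) for (ai in seq_len(sigma[1])) {
      i <- (bi - 1L) * sigma[1] + ai
      j <- (bj - 1L) * sigma[2] + aj
      col <- (j - 1L) * cropSize[1] + i
      S[r, col] <- weights[i, j]
    }
  }
  S
}

denseA <- function(sys, k) {
  samp <- awflow::sampling(sys)
  Cm <- denseC(samp@gridSize, samp@cropSize, samp@cropOffset)
  Hm <- denseH(sys@gridSize[1], sys@gridSize[2], pitch(sys), wavelength(sys),
               sys@z)
  Mm <- denseM(modulations(sys)[[k]])
  Cm %*% Hm %*% Mm
}

# finite-difference analysis matrix D (2n x n), Neumann boundary
denseD <- function(n1, n2) {
  n <- n1 * n2
  idx <- function(i, j) (j - 1L) * n1 + i
  D <- matrix(0, 2L * n, n)
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    r <- idx(i, j)
    if (j < n2) { D[r, idx(i, j + 1L)] <- 1; D[r, idx(i, j)] <- -1 }
    if (i < n1) { D[n + r, idx(i + 1L, j)] <- 1; D[n + r, idx(i, j)] <- -1 }
  }
  D
}

# standalone classical amplitude-based Wirtinger flow on dense matrices
# (sigma = 1, identity S): the reduction oracle for the solver
classicWF <- function(Alist, ys, x0, gamma, iters) {
  K <- length(Alist)
  x <- x0
  for (t in seq_len(iters)) {
    g <- 0
    for (k in seq_len(K)) {
      a <- Alist[[k]] %*% x
      mod <- Mod(a)
      ratio <- ifelse(mod > 0, ys[[k]] / mod, 0)
      g <- g + Conj(t(Alist[[k]])) %*% (a * (1 - ratio))
    }
    x <- x - gamma * g / (2 * K)
  }
  x
}

randomComplexMatrix <- function(n1, n2, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n1 * n2), imaginary = rnorm(n1 * n2)), n1, n2)
}

# small ready-made test system: 8x8 grid, K patterns, optional crop/binning
tinySystem <- function(n = 8L, K = 2L, sigma = c(1L, 1L), crop = NULL,
                       z = 40, pitch = 1.27, wavelength = 0.532,
                       weights = 1, seed = 42) {
  set.seed(seed)
  mods <- lapply(seq_len(K), function(k) matrix(runif(n * n, 0, 2 * pi), n, n))
  if (is.null(crop)) crop <- c(n, n)
  samp <- samplingOperator(c(n, n), sigma = sigma, cropSize = crop,
                           weights = weights)
  systemOperator(mods, pitch = pitch, wavelength = wavelength, z = z,
                 sampling = samp)
}

cdot <- function(a, b) sum(Conj(a) * b)  # <a, b>, conjugate-linear in a
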