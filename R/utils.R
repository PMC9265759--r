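# internal helpers shared across modules

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT sample frequencies (cycles per um): DC at index 1, wrap at ceiling(n/2)
.fftFreq <- function(n, pitch) {
  f <- seq_len(n) - 1L
  f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
  f / (n * pitch)
}

# md5 digest of an arbitrary R object (via a serialized temp file)
.objectDigest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2L, compress = FALSE)
  unname(tools::md5sum(tf))
}

.complexRandn <- function(n1, n2) {
  matrix(complex(real = stats::rnorm(n1 * n2),
                 imaginary = stats::rnorm(n1 * n2)) / sqrt(2), n1, n2)
}
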