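# Spectral helpers shared across the simulator and the analysis code.
# All grids follow the stats::fft layout (DC at [1, 1]); fftshift2() moves
# DC to the centre for display and radial profiling.

# unshifted FFT sample frequencies, cycles per unit of d
fft_freq <- function(n, d = 1) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, -rev(seq_len(floor(n / 2))))
  k / (n * d)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c(seq(floor(n1 / 2) + 1L, n1), seq_len(floor(n1 / 2))),
    c(seq(floor(n2 / 2) + 1L, n2), seq_len(floor(n2 / 2)))]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c(seq(ceiling(n1 / 2) + 1L, n1), seq_len(ceiling(n1 / 2))),
    c(seq(ceiling(n2 / 2) + 1L, n2), seq_len(ceiling(n2 / 2)))]
}

# outer-product style frequency grids (matrices dim n1 x n2), unshifted
fft_freq_grids <- function(n1, n2, d = 1) {
  kx <- fft_freq(n1, d)
  ky <- fft_freq(n2, d)
  list(
    kx = matrix(kx, n1, n2),
    ky = matrix(ky, n1, n2, byrow = TRUE)
  )
}

# Run `code` under a fixed RNG seed and restore the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
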