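# Decimated Daubechies-4 (8-tap) wavelet transform with periodized
# boundaries. Periodization keeps the transform orthogonal, so coefficient
# energy equals signal energy (Parseval) and full reconstruction is exact.
# Signals whose length is not a multiple of 2^levels are zero-padded up to
# the next multiple before analysis (padding is energy-neutral).

# Daubechies-4 decomposition low-pass filter (standard published values)
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- rev(DB4_LO) * c(-1, 1, -1, 1, -1, 1, -1, 1)

# Circular convolution of x with filter h, then downsample by 2:
# a[k] = sum_j h[j] x[(2k + 4 - j) mod n] (0-based). The phase offset of
# L/2 = 4 samples matches the PyWavelets "periodization" convention.
dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  idx <- outer(seq(0L, n - 2L, by = 2L) + 4L, seq_len(L) - 1L, "-") %% n + 1L
  as.numeric(matrix(x[idx], ncol = L) %*% h)
}

# exact transpose of dwt_step (orthogonal transform => synthesis = adjoint)
idwt_step <- function(a, d, lo, hi) {
  n <- 2L * length(a)
  L <- length(lo)
  pos <- (seq(0L, n - 2L, by = 2L) + 4L) %% n + 1L
  up_a <- numeric(n); up_a[pos] <- a
  up_d <- numeric(n); up_d[pos] <- d
  y <- numeric(n)
  for (j in seq_len(L)) {
    sel <- (seq_len(n) - 1L + j - 1L) %% n + 1L
    y <- y + lo[j] * up_a[sel] + hi[j] * up_d[sel]
  }
  y
}

#' Multilevel DB4 discrete wavelet transform
#'
#' Decomposes a signal into `levels` detail bands `D1..Dlevels` plus the
#' final approximation band. Periodized boundaries keep the transform
#' orthogonal; input is zero-padded to the next multiple of `2^levels`.
#'
#' @param x numeric vector.
#' @param levels decomposition depth, default 6.
#' @return list with `approx` (final approximation coefficients), `details`
#'   (list `D1`..`Dlevels`), `levels`, `n` (original length), `n_padded`.
#' @export
dwt_db4 <- function(x, levels = 6) {
  if (levels < 1) stop("levels must be >= 1")
  n <- length(x)
  block <- 2^levels
  if (n < block)
    stop("signal of ", n, " samples too short for ", levels,
         "-level decomposition (needs >= ", block, ")")
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) x <- c(x, numeric(n_pad - n))
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    details[[lev]] <- dwt_step(a, DB4_HI)
    a <- dwt_step(a, DB4_LO)
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(list(approx = a, details = details, levels = levels,
                 n = n, n_padded = n_pad),
            class = "dwt_db4")
}

#' Inverse multilevel DB4 wavelet transform
#'
#' @param w a [dwt_db4()] decomposition (coefficients may be modified).
#' @return numeric vector of the original length.
#' @export
idwt_db4 <- function(w) {
  stopifnot(inherits(w, "dwt_db4"))
  a <- w$approx
  for (lev in rev(seq_len(w$levels)))
    a <- idwt_step(a, w$details[[lev]], DB4_LO, DB4_HI)
  a[seq_len(w$n)]
}
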