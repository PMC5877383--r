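#' ICA-based artifact removal
#'
#' Unmixes the channels into statistically independent components with a
#' symmetric fixed-point ICA (tanh contrast, whitened input), rejects
#' components flagged as artifacts, and reconstructs the recording from the
#' remaining components. The linear model is `x = A s`; the estimated
#' unmixing `W` recovers sources `u = W x`, and rejecting a component zeroes
#' its column of `A` in the reconstruction.
#'
#' The default rejection rule targets baseline drift and motion artifacts:
#' a component is rejected when more than `low_freq_frac` of its spectral
#' power lies below `low_freq_hz`.
#'
#' @param rec a [recording()] with at least 2 channels.
#' @param reject_rule either a function `(sources_matrix, fs) -> integer
#'   indices to reject`, or a list `list(low_freq_hz =, low_freq_frac =)`
#'   for the built-in low-frequency-power rule, or `NULL` to reject nothing.
#' @param seed RNG seed for the random orthogonal start, default 1.
#' @param maxit,tol fixed-point iteration limit and convergence tolerance.
#' @return list with `recording` (cleaned) and `model` (class `ica_model`:
#'   `mixing`, `unmixing`, `sources`, `rejected`, `iterations`).
#' @export
ica_denoise <- function(rec, reject_rule = list(low_freq_hz = 10,
                                                low_freq_frac = 0.6),
                        seed = 1, maxit = 500, tol = 1e-7) {
  stopifnot(inherits(rec, "semg_recording"))
  X <- t(rec$samples)                       # channels x time
  n <- nrow(X)
  if (n < 2) stop("ICA requires at least 2 channels")
  if (!all(is.finite(X))) stop("non-finite samples")
  m <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  # whitening
  C <- tcrossprod(Xc) / m
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values <= 1e-12 * eg$values[1]))
    stop("channels are linearly dependent; ICA whitening failed")
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitening matrix
  Z <- K %*% Xc
  # symmetric fixed-point iteration, tanh contrast
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  W <- sym_decor(W)
  it <- 0L
  repeat {
    it <- it + 1L
    U <- W %*% Z
    G <- tanh(U)
    W1 <- G %*% t(Z) / m - diag(rowMeans(1 - G^2)) %*% W
    W1 <- sym_decor(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
    if (it >= maxit)
      stop("ICA did not converge after ", it, " iterations (delta = ",
           signif(delta, 3), ")")
  }
  W_full <- W %*% K                          # unmixing in channel space
  A <- solve(W_full)                         # mixing (square, invertible)
  U <- W_full %*% Xc                         # sources
  rejected <- integer(0)
  if (is.function(reject_rule)) {
    rejected <- as.integer(reject_rule(U, rec$fs))
  } else if (is.list(reject_rule)) {
    rejected <- which(vapply(seq_len(n), function(i) {
      p <- Mod(stats::fft(U[i, ]))^2
      half <- p[seq_len(floor(m / 2) + 1)]
      freqs <- (seq_along(half) - 1) * rec$fs / m
      sum(half[freqs < reject_rule$low_freq_hz]) / sum(half) >
        reject_rule$low_freq_frac
    }, logical(1)))
  }
  keep <- setdiff(seq_len(n), rejected)
  Xr <- A[, keep, drop = FALSE] %*% U[keep, , drop = FALSE] + mu
  out <- rec
  out$samples <- t(Xr)
  colnames(out$samples) <- rec$channel_names
  list(recording = out,
       model = structure(list(mixing = A, unmixing = W_full, sources = U,
                              rejected = rejected, iterations = it),
                         class = "ica_model"))
}

#' @export
print.ica_model <- function(x, ...) {
  cat("<ica_model> ", nrow(x$sources), " components, ",
      x$iterations, " iterations; rejected: ",
      if (length(x$rejected)) paste(x$rejected, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
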