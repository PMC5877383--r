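#' Multiscale PCA denoising
#'
#' Denoises a multichannel recording by combining the wavelet transform
#' with per-scale principal component analysis: each channel is decomposed
#' into wavelet sub-bands, the coefficient covariance of every scale is
#' analyzed separately, only the leading principal components of each scale
#' are retained, and the signal is rebuilt by the inverse transform.
#' Cross-channel structure is captured by the PCA; within-channel
#' autocorrelation is largely removed by the wavelet decomposition, which
#' is what makes scale-wise PCA effective.
#'
#' @param rec a [recording()] with at least 2 channels.
#' @param wavelet currently only `"db4"`.
#' @param levels decomposition depth, default 5.
#' @param pc_rule `"kaiser"` (retain components with eigenvalue above the
#'   mean eigenvalue of that scale), `"all"` (retain everything: identity
#'   round trip), or an integer number of components per scale.
#' @return the denoised recording (same shape, annotations preserved).
#' @export
mspca_denoise <- function(rec, wavelet = "db4", levels = 5,
                          pc_rule = "kaiser") {
  stopifnot(inherits(rec, "semg_recording"))
  if (!identical(wavelet, "db4")) stop("only the db4 wavelet is supported")
  X <- rec$samples
  nch <- ncol(X)
  if (nch < 2) stop("MSPCA requires at least 2 channels")
  if (nrow(X) < 2^levels)
    stop("signal of ", nrow(X), " samples too short for ", levels,
         "-level decomposition")
  dec <- lapply(seq_len(nch), function(j) dwt_db4(X[, j], levels))
  scale_names <- c(paste0("D", seq_len(levels)), "approx")
  get_band <- function(d, s) if (s == "approx") d$approx else d$details[[s]]
  set_band <- function(d, s, v) {
    if (s == "approx") d$approx <- v else d$details[[s]] <- v
    d
  }
  for (s in scale_names) {
    M <- vapply(dec, get_band, numeric(length(get_band(dec[[1]], s))), s = s)
    mu <- colMeans(M)
    Mc <- sweep(M, 2, mu)
    eg <- eigen(stats::cov(Mc), symmetric = TRUE)
    keep <- if (identical(pc_rule, "all")) {
      nch
    } else if (identical(pc_rule, "kaiser")) {
      max(1L, sum(eg$values > mean(eg$values)))
    } else {
      k <- as.integer(pc_rule)
      if (is.na(k) || k < 1 || k > nch) stop("invalid pc_rule")
      k
    }
    V <- eg$vectors[, seq_len(keep), drop = FALSE]
    Mr <- sweep(Mc %*% V %*% t(V), 2, mu, "+")
    for (j in seq_len(nch)) dec[[j]] <- set_band(dec[[j]], s, Mr[, j])
  }
  Y <- vapply(dec, idwt_db4, numeric(nrow(X)))
  colnames(Y) <- rec$channel_names
  rec$samples <- Y
  rec
}
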