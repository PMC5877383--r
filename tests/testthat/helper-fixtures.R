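# shared fixtures, all generated in code

# two clearly separated classes in 2 informative dims + noise dims
toy_separable_fm <- function(n_per_class = 20, n_noise = 3, seed = 42,
                             gap = 6) {
  with_seed_local(seed, {
    a <- cbind(matrix(rnorm(n_per_class * 2), ncol = 2),
               matrix(rnorm(n_per_class * n_noise), ncol = n_noise))
    b <- cbind(matrix(rnorm(n_per_class * 2) + gap, ncol = 2),
               matrix(rnorm(n_per_class * n_noise), ncol = n_noise))
    vals <- rbind(a, b)
    colnames(vals) <- paste0("F", seq_len(ncol(vals)))
    feature_matrix(vals, rep(c("MF", "WE"), each = n_per_class))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# independent linear-SVM weight vector via the dual QP (kernlab::ipop),
# used as the RFE oracle; completely separate from the e1071 code path
svm_weights_qp <- function(X, y, C = 1) {
  y <- ifelse(y == sort(unique(y))[1], -1, 1)
  n <- nrow(X)
  H <- (y %o% y) * tcrossprod(X) + diag(1e-8, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H,
                       A = matrix(y, 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n))
  alpha <- kernlab::primal(sol)
  as.numeric(t(X) %*% (alpha * y))
}

# brute-force recursive elimination using the dual-QP weights and the
# margin-criterion definition (drop the i-th component of w)
rfe_oracle_order <- function(fm, C = 1) {
  X <- scale(fm$values)
  y <- fm$labels
  remaining <- seq_len(ncol(X))
  elim <- integer(0)
  while (length(remaining) > 1) {
    w <- svm_weights_qp(X[, remaining, drop = FALSE], y, C)
    J <- abs(sum(w^2) - vapply(seq_along(w),
                               function(i) sum(w[-i]^2), numeric(1)))
    drop_i <- which.min(J)
    elim <- c(elim, remaining[drop_i])
    remaining <- remaining[-drop_i]
  }
  elim <- c(elim, remaining)
  colnames(fm$values)[rev(elim)]
}
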