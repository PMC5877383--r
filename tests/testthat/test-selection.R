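fm_from_cols <- function(values, labels) {
  colnames(values) <- paste0("F", seq_len(ncol(values)))
  feature_matrix(values, labels)
}

test_that("variance entropy hits its closed forms", {
  # equal class variances -> maximum entropy ln 2
  v <- c(0, 2, 0, -2, 0, 2, 0, -2)          # same spread in both classes
  fm <- fm_from_cols(cbind(v), rep(c("a", "b"), each = 4))
  expect_equal(unname(ec_score(fm)$sv), log(2), tolerance = 1e-12)

  # one class constant -> entropy 0 (most separable)
  v2 <- c(1, 1, 1, 1, 0, 3, 1, 2)
  fm2 <- fm_from_cols(cbind(v2), rep(c("a", "b"), each = 4))
  expect_equal(unname(ec_score(fm2)$sv), 0)

  # variances (2, 6): J = -(0.25 ln 0.25 + 0.75 ln 0.75)
  a <- c(-2, 0, 2); b <- c(-sqrt(3) * 2, 0, sqrt(3) * 2)  # var 4 and 12
  fm3 <- fm_from_cols(cbind(c(a, b)), rep(c("a", "b"), each = 3))
  expect_equal(unname(ec_score(fm3)$sv),
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-12)
})

test_that("variance entropy is bounded by ln(n_classes) and ranks ascending", {
  set.seed(41)
  fm <- generate_planted_features(80, 10, planted = 1:3, effect_size = 2,
                                  seed = 7)
  rep <- ec_score(fm)
  expect_true(all(rep$sv >= 0 & rep$sv <= log(4) + 1e-12))
  expect_equal(rep$order, names(sort(rep$sv)))
})

test_that("Fisher discrimination reproduces the hand-enumerated examples", {
  fm <- fm_from_cols(cbind(c(0, 1, 3, 4)), rep(c("a", "b"), each = 2))
  expect_equal(unname(fd_score(fm)$sv), 4.75)   # 9.5 / (1 + 1)

  # identical classes {0,1,2}: cross 4/3 over within 2 + 2
  fm2 <- fm_from_cols(cbind(c(0, 1, 2, 0, 1, 2)), rep(c("a", "b"), each = 3))
  expect_equal(unname(fd_score(fm2)$sv), 1 / 3, tolerance = 1e-12)

  # degenerate constant classes flag infinite separability
  fm3 <- fm_from_cols(cbind(c(5, 5, 5, 5)), rep(c("a", "b"), each = 2))
  expect_warning(rep3 <- fd_score(fm3), "zero within-class")
  expect_true(is.infinite(rep3$sv[[1]]))
})

test_that("Fisher discrimination is translation- and scale-invariant", {
  set.seed(42)
  fm <- generate_planted_features(60, 6, planted = 1:2, effect_size = 1.5,
                                  seed = 3)
  J0 <- fd_score(fm)$sv
  fm$values <- fm$values * 7 + 100
  expect_equal(fd_score(fm)$sv, J0, tolerance = 1e-10)
})

test_that("RFE eliminates a label-independent noise feature first", {
  set.seed(43)
  n <- 30
  sig <- c(rnorm(n, -3), rnorm(n, 3))
  noise <- rnorm(2 * n)
  fm <- fm_from_cols(cbind(sig, noise), rep(c("a", "b"), each = n))
  rep <- rfe_rank(fm)
  expect_equal(rep$order, c("F1", "F2"))
})

test_that("RFE output is a permutation ranking of all features", {
  set.seed(44)
  fm <- generate_planted_features(40, 8, planted = 1:2, effect_size = 2,
                                  seed = 5)
  rep <- rfe_rank(fm)
  expect_setequal(rep$order, colnames(fm$values))
  expect_equal(sort(unname(rep$sv)), 1:8)
})

test_that("RFE elimination order matches the exhaustive dual-QP oracle", {
  set.seed(45)
  for (d in 3:4) {
    n <- 24
    gaps <- c(4, 2, 1, 0)[seq_len(d)]
    vals <- sapply(gaps, function(g) c(rnorm(n, -g / 2), rnorm(n, g / 2)))
    fm <- fm_from_cols(vals, rep(c("a", "b"), each = n))
    expect_equal(rfe_rank(fm)$order, rfe_oracle_order(fm),
                 info = paste("d =", d))
  }
})

test_that("the OFN sweep recovers a small planted subset and covers all sizes", {
  fm <- generate_planted_features(120, 12, planted = 1:3, effect_size = 2.5,
                                  seed = 9)
  rep <- fd_score(fm)
  res <- ofn_sweep(fm, rep, classifier_config("svm"), k_folds = 5, seed = 1)
  expect_length(res$accuracy_curve, 12)
  expect_lte(res$ofn, 5)
  expect_gte(max(res$accuracy_curve), res$accuracy_curve[1])
})

test_that("OFN ties resolve to the smallest subset size", {
  # all-noise features: flat accuracy curve -> smallest size wins
  fm <- generate_planted_features(40, 4, planted = integer(0), effect_size = 0,
                                  seed = 11)
  rep <- fd_score(fm)
  res <- ofn_sweep(fm, rep, classifier_config("knn"), k_folds = 4, seed = 2)
  flat <- which(res$accuracy_curve == max(res$accuracy_curve))
  expect_equal(res$ofn, as.integer(names(flat)[1]))
})

test_that("aggregation of a single report returns its own top-k", {
  fm <- generate_planted_features(60, 8, planted = 1:2, effect_size = 2,
                                  seed = 13)
  rep <- fd_score(fm, subject = "S1", channel = "ECU")
  res <- aggregate_selection(list(rep), subset_size = 3)
  expect_equal(res$selected, rep$order[1:3])
})

test_that("RFE frequency counting saturates at subjects x channels", {
  fm <- generate_planted_features(48, 6, planted = 1:2, effect_size = 2,
                                  seed = 14)
  reports <- list()
  for (s in 1:9) for (ch in c("ECU", "ECR"))
    reports[[length(reports) + 1]] <-
      rfe_rank(fm, subject = paste0("S", s), channel = ch)
  res <- aggregate_selection(reports, subset_size = 3)
  expect_equal(max(res$frequency), 18)
  expect_equal(unname(res$frequency[res$selected[1]]), 18)
})

test_that("symmetric reversed ranks tie and break by canonical feature order", {
  sv1 <- setNames(c(0.1, 0.5, 0.9), paste0("F", 1:3))
  sv2 <- setNames(c(0.9, 0.5, 0.1), paste0("F", 1:3))
  r1 <- semgopt:::new_separability_report("EC", sv1, names(sort(sv1)), 2,
                                          "S1", "ch1")
  r2 <- semgopt:::new_separability_report("EC", sv2, names(sort(sv2)), 2,
                                          "S1", "ch2")
  res <- aggregate_selection(list(r1, r2), subset_size = 2)
  expect_equal(res$selected, c("F1", "F2"))  # all tie at 1.0; canonical order
})

test_that("channel ranking puts an informative channel above pure noise", {
  set.seed(46)
  informative <- generate_planted_features(80, 10, planted = 1:4,
                                           effect_size = 2.5, seed = 17)
  noise <- generate_planted_features(80, 10, planted = integer(0),
                                     effect_size = 0, seed = 18)
  res <- rank_channels(list(good = informative, bad = noise),
                       classifier_config("knn"), k_folds = 5, seed = 1)
  expect_equal(res$top[1], "good")
  expect_equal(ncol(res$ranking), 8)   # channel + 6 pairwise + mean
  expect_gt(res$ranking$mean[1], res$ranking$mean[2])
})

test_that("channel ranking requires every class in every channel", {
  fm <- generate_planted_features(40, 5, 1, 1, seed = 19)
  partial <- fm[fm$labels != "WF", ]
  expect_error(rank_channels(list(a = fm, b = partial)), "missing a class")
})
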