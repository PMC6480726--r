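# Transforms, univariate testing, PCA, OPLS-DA, MCCV-SVM, random forest.

sep_data <- function(n1 = 10, n2 = 14, p = 12, shift = 3, seed = 1,
                     informative = 1:3) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  g <- rep(c("a", "b"), c(n1, n2))
  x[g == "b", informative] <- x[g == "b", informative] + shift
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, g = g)
}

test_that("the generalised log transform has its closed-form limits", {
  expect_equal(glog_transform(matrix(2), lambda = 0)[1, 1], log(2))
  expect_equal(glog_transform(matrix(0), lambda = 1)[1, 1], log(1 / 2))
  # strictly increasing in x for several lambdas
  grid <- seq(-5, 5, by = 0.01)
  for (lam in c(0.1, 1, 100)) {
    gl <- glog_transform(matrix(grid, ncol = 1), lambda = lam)
    expect_true(all(diff(gl[, 1]) > 0))
  }
})

test_that("Pareto scaling centres and divides by sqrt(sd)", {
  m <- matrix(c(0, 2, 5, 5.5), 2)
  out <- pareto_scale(m)
  expect_equal(out[, 1], c(-0.840896, 0.840896), tolerance = 1e-6)
  expect_equal(colMeans(out), c(0, 0))
  # scaled variance equals the original standard deviation
  expect_equal(apply(out, 2, var), apply(m, 2, sd))
  expect_error(pareto_scale(matrix(c(1, 1, 2, 3), 2)),
               class = "lfnmr_validation_error")
})

test_that("t tests with FDR control behave at the boundaries", {
  # identical groups: t = 0, p = 1
  m_eq <- matrix(c(1, 2, 1, 2, 5, 6, 5, 6), 4, 2)
  res_eq <- ttest_fdr(m_eq, c("a", "a", "b", "b"))
  expect_equal(res_eq$t, c(0, 0))
  expect_equal(res_eq$p, c(1, 1))
  # single bucket: adjusted equals raw
  one <- ttest_fdr(matrix(c(1, 2, 3, 7, 8, 9), 6, 1),
                   rep(c("a", "b"), each = 3))
  expect_equal(one$p_adj, one$p)
  expect_true(all(ttest_fdr(m_eq, c("a", "a", "b", "b"),
                            "holm")$p_adj >= res_eq$p))
})

test_that("a large single effect survives FDR correction with high power", {
  hits <- vapply(1:40, function(s) {
    d <- sep_data(10, 14, p = 27, shift = 3, seed = s, informative = 5)
    res <- ttest_fdr(d$x, d$g)
    res$p_adj[5] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("PCA retains components by explained variance and rotates safely", {
  # exactly collinear columns: one component carries all variance
  set.seed(3)
  a <- rnorm(20)
  res <- nmr_pca(cbind(a, 2 * a), variance_criterion = 0.8,
                 rotate = "none")
  expect_equal(res$n_components, 1)
  expect_equal(res$explained_variance, 1, tolerance = 1e-12)
  # orthogonal rotation preserves total explained variance
  d <- sep_data(10, 10, p = 6, seed = 4)
  plain <- nmr_pca(d$x, 0.999, rotate = "none")
  rot <- nmr_pca(d$x, 0.999, rotate = "varimax")
  expect_equal(rot$total_explained, plain$total_explained,
               tolerance = 1e-9)
  expect_true(all(diff(rot$explained_variance) <= 1e-12))
  # duplicated samples have identical scores
  x2 <- rbind(d$x, d$x[1, ])
  sc <- nmr_pca(x2, 0.9, rotate = "none")$scores
  expect_equal(sc[nrow(x2), ], sc[1, ])
  expect_error(nmr_pca(d$x, 1.2), class = "lfnmr_validation_error")
})

test_that("OPLS-DA isolates the class-predictive direction", {
  set.seed(5)
  n <- 20
  g <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 8, sd = 0.3), n, 8)
  x[, 4] <- x[, 4] + ifelse(g == "b", 4, 0)   # dominant class variable
  colnames(x) <- paste0("v", 1:8)
  m <- oplsda_fit(x, g)
  expect_equal(which.max(abs(m$weights)), 4L, ignore_attr = TRUE)
  expect_equal(names(which.max(m$vip)), "v4")
  expect_gt(m$R2Y, 0.8)
  # orthogonal scores are uncorrelated with class membership
  expect_lt(abs(cor(m$orthogonal_scores[, 1], m$y)), 1e-8)
  # permuted labels give near-chance R2Y
  perm_r2y <- vapply(1:20, function(s) {
    set.seed(100 + s)
    oplsda_fit(x, sample(g))$R2Y
  }, numeric(1))
  expect_lt(mean(perm_r2y), 0.5 * m$R2Y)
  expect_error(oplsda_fit(x, rep(c("a", "b", "c"), length.out = n)),
               class = "lfnmr_validation_error")
})

test_that("cross-validated Q2 separates real structure from noise", {
  d <- sep_data(10, 14, shift = 4, seed = 6)
  q2 <- cv_q2(d$x, d$g, seed = 1)
  r2y <- oplsda_fit(d$x, d$g)$R2Y
  expect_gt(q2, 0.4)
  expect_lte(q2, r2y + 1e-9)
  # labels independent of the data: Q2 near or below zero on average
  nulls <- vapply(1:10, function(s) {
    set.seed(200 + s)
    x <- matrix(rnorm(24 * 12), 24, 12)
    cv_q2(x, rep(c("a", "b"), 12), seed = s)
  }, numeric(1))
  expect_lte(mean(nulls), 0.1)
  # Q2 <= R2Y across several datasets
  for (s in 1:5) {
    d2 <- sep_data(8, 8, shift = 2, seed = 300 + s)
    expect_lte(cv_q2(d2$x, d2$g, seed = s),
               oplsda_fit(d2$x, d2$g)$R2Y + 1e-9)
  }
})

test_that("permutation p-values respect their attainable bounds", {
  d <- sep_data(8, 8, shift = 5, seed = 7)
  res <- permutation_test(d$x, d$g, B = 99, k_folds = 4, seed = 2)
  expect_equal(res$p_q2, 1 / 100)   # nothing beats clear separation
  expect_gte(res$p_r2y, 1 / 100)
  # null data: p near 0.5
  set.seed(8)
  xn <- matrix(rnorm(16 * 6), 16, 6)
  resn <- permutation_test(xn, rep(c("a", "b"), 8), B = 199, k_folds = 4,
                           seed = 3)
  expect_gt(resn$p_q2, 0.15)
  expect_lt(resn$p_q2, 0.85)
  expect_gte(resn$p_q2, 1 / 200)
})

test_that("MCCV-SVM AUROC spans separable to chance regimes", {
  d <- sep_data(10, 14, shift = 6, seed = 9)
  res <- mccv_svm_roc(d$x, d$g, n_features = 3, n_splits = 25, seed = 1)
  expect_equal(res$auroc, 1.0)
  expect_true(all(res$splits >= 0 & res$splits <= 1))
  # labels unrelated to the data: no separation (large n keeps the
  # finite-sample optimism of per-labelling chance structure small)
  set.seed(10)
  xn <- matrix(rnorm(120 * 12), 120, 12)
  gn <- rep(c("a", "b"), 60)
  res0 <- mccv_svm_roc(xn, gn, n_features = 3, n_splits = 50, seed = 2)
  expect_lt(abs(res0$auroc - 0.5), 0.1)
  # mean AUROC is insensitive to sample order
  perm <- sample(nrow(d$x))
  resp <- mccv_svm_roc(d$x[perm, ], d$g[perm], n_features = 3,
                       n_splits = 50, seed = 3)
  res1 <- mccv_svm_roc(d$x, d$g, n_features = 3, n_splits = 50, seed = 3)
  expect_equal(resp$auroc, res1$auroc, tolerance = 0.05)
  expect_error(mccv_svm_roc(d$x, d$g, n_splits = 5),
               class = "lfnmr_validation_error")
})

test_that("the internal AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  score <- rnorm(40)
  lab <- score + rnorm(40) > 0.3
  ours <- lfnmr:::rank_auroc(score, lab)
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("random forests classify separable data and flag tiny ensembles", {
  set.seed(12)
  g <- rep(c("a", "b"), each = 12)
  x <- cbind(ifelse(g == "b", 1, 0) + rnorm(24, sd = 0.05),
             ifelse(g == "b", 1, 0) + rnorm(24, sd = 0.05),
             matrix(rnorm(24 * 4), 24))
  res <- random_forest_classify(x, g, n_trees = 200, m_try = 2, seed = 4)
  expect_gte(res$oob_accuracy, 0.95)
  expect_equal(dim(res$confusion), c(2L, 2L))
  one_tree <- random_forest_classify(x, g, n_trees = 1, m_try = 2,
                                     seed = 5)
  expect_true(one_tree$unstable)
  expect_error(random_forest_classify(x, g, m_try = 99),
               class = "lfnmr_validation_error")
})

test_that("exclusion filtering drops intersecting buckets with a log", {
  b <- bucket_table(data.frame(low_ppm = c(1.0, 4.5, 6.0),
                               high_ppm = c(1.5, 4.6, 6.5),
                               label = c("keep1", "water", "keep2")),
                    exclusions = data.frame(low_ppm = numeric(),
                                            high_ppm = numeric()))
  fm <- structure(matrix(1, 2, 3, dimnames = list(NULL, b$buckets$label)),
                  class = c("feature_matrix", "matrix", "array"),
                  bucket_table = b, state = c("raw", "tsp"))
  same <- exclusion_filter(fm, data.frame(low_ppm = numeric(),
                                          high_ppm = numeric()))
  expect_equal(colnames(same), colnames(fm))
  out <- exclusion_filter(fm, data.frame(low_ppm = 4.41, high_ppm = 5.16))
  expect_equal(attr(out, "dropped"), "water")
  expect_equal(colnames(out), c("keep1", "keep2"))
})

test_that("the transform pipeline enforces its order contract", {
  spec <- fix_small_cohort_spec()
  co <- generate_cohort(spec, fix_config(), seed = 3)
  fm <- build_feature_matrix(co$spectra)
  expect_error(glog_transform(fm), class = "lfnmr_state_error")
  fm_tsp <- normalize_features(fm, "tsp")
  expect_error(pareto_scale(fm_tsp), class = "lfnmr_state_error")
  out <- pareto_scale(glog_transform(fm_tsp))
  expect_equal(attr(out, "state"), c("raw", "tsp", "glog", "pareto"))
})
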