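# Multivariate statistics pipeline: variance-stabilising transforms,
# univariate testing with multiplicity control, PCA, OPLS-DA with
# cross-validation and permutation testing, MCCV-SVM ROC analysis and
# random-forest classification.

state_of <- function(x) attr(x, "state") %||% character(0)

require_state <- function(x, needed, op) {
  if (!inherits(x, "feature_matrix")) return(invisible(TRUE))
  st <- state_of(x)
  if (!any(needed %in% st))
    stop_lfnmr(op, " requires a matrix in state {",
               paste(needed, collapse = " or "), "}; current state: ",
               paste(c("raw", setdiff(st, "raw")), collapse = " > "),
               class = "lfnmr_state_error")
  invisible(TRUE)
}

push_state <- function(out, x, tag) {
  if (inherits(x, "feature_matrix")) {
    attributes(out) <- attributes(x)
    attr(out, "state") <- c(state_of(x), tag)
  }
  out
}

#' Generalised logarithm transform
#'
#' Variance-stabilising transform
#' \deqn{g(x) = \ln\{(x + \sqrt{x^2 + \lambda})/2\},}
#' defined for all reals; with `lambda = 0` it reduces to `log(x)` for
#' positive `x`. Strictly increasing in `x` for every `lambda >= 0`.
#'
#' @param x Numeric matrix (or `feature_matrix` in a normalised state).
#' @param lambda Transform parameter (>= 0). The default, `NULL`, uses the
#'   squared median absolute intensity of the matrix (a noise-scale proxy).
#' @return Transformed matrix; state tags gain `"glog"`.
#' @export
glog_transform <- function(x, lambda = NULL) {
  require_state(x, c("tsp", "csn"), "glog_transform")
  if (is.null(lambda)) lambda <- stats::median(abs(x))^2
  check_number(lambda, "lambda", nonnegative = TRUE)
  out <- log((x + sqrt(x^2 + lambda)) / 2)
  push_state(out, x, "glog")
}

#' Pareto scaling
#'
#' Mean-centres each column and divides by the square root of its standard
#' deviation, leaving each variable with mean zero and a variance equal to
#' its original standard deviation (similar, but not equal, to unity).
#'
#' @param x Numeric matrix with >= 2 rows; constant columns raise an error.
#' @return Scaled matrix; state tags gain `"pareto"`.
#' @export
pareto_scale <- function(x) {
  require_state(x, "glog", "pareto_scale")
  if (nrow(x) < 2L)
    stop_lfnmr("need >= 2 samples", class = "lfnmr_validation_error")
  sds <- apply(x, 2, stats::sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop_lfnmr("constant column(s): ",
               paste(colnames(x)[zero] %||% zero, collapse = ", "),
               class = "lfnmr_validation_error")
  out <- sweep(sweep(x, 2, colMeans(x)), 2, sqrt(sds), "/")
  push_state(out, x, "pareto")
}

#' Per-bucket two-sample t tests with multiplicity control
#'
#' Two-sample t statistics per column with Benjamini-Hochberg false
#' discovery rate (default) or step-down Holm adjustment.
#'
#' @param x Numeric matrix, samples x buckets.
#' @param groups Two-level grouping vector.
#' @param method `"BH"` or `"holm"`.
#' @param var_equal Use the pooled-variance (Student) statistic (default),
#'   as opposed to Welch.
#' @return Data frame with columns `bucket`, `t`, `p`, `p_adj`.
#' @export
ttest_fdr <- function(x, groups, method = c("BH", "holm"),
                      var_equal = TRUE) {
  method <- match.arg(method)
  g <- factor(groups)
  if (nlevels(g) != 2L)
    stop_lfnmr("exactly two groups required",
               class = "lfnmr_validation_error")
  if (any(table(g) < 2L))
    stop_lfnmr("each group needs n >= 2", class = "lfnmr_validation_error")
  res <- apply(x, 2, function(col) {
    a <- col[g == levels(g)[1]]; b <- col[g == levels(g)[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(c(t = 0, p = 1))
    tt <- stats::t.test(a, b, var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  data.frame(bucket = colnames(x) %||% seq_len(ncol(x)),
             t = res["t", ], p = res["p", ],
             p_adj = stats::p.adjust(res["p", ], method = method),
             row.names = NULL)
}

#' Principal component analysis with variance criterion and varimax
#'
#' PCA on the (column-centred) matrix, retaining components until the
#' cumulative explained variance reaches `variance_criterion`, optionally
#' followed by varimax rotation with Kaiser normalisation of the loadings.
#'
#' @param x Numeric matrix.
#' @param variance_criterion Minimum cumulative explained-variance fraction
#'   in `(0, 1]` (default 0.8).
#' @param rotate `"varimax"` or `"none"`.
#' @return List of class `nmr_pca`: `scores`, `loadings`,
#'   `explained_variance` (fractions of total variance, non-increasing),
#'   `n_components`, `rotation`.
#' @export
nmr_pca <- function(x, variance_criterion = 0.8,
                    rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  if (nrow(x) < 2L)
    stop_lfnmr("need more than one sample",
               class = "lfnmr_validation_error")
  if (variance_criterion <= 0 || variance_criterion > 1)
    stop_lfnmr("variance_criterion must lie in (0, 1]",
               class = "lfnmr_validation_error")
  pc <- stats::prcomp(unclass(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_criterion - 1e-12)[1]
  k <- max(k, 1L)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  expl <- frac[seq_len(k)]
  if (rotate == "varimax" && k >= 2L) {
    vm <- stats::varimax(loadings, normalize = TRUE, eps = 1e-8)
    loadings <- loadings %*% vm$rotmat
    scores <- scores %*% vm$rotmat
    expl <- apply(scores, 2, stats::var) / sum(ev)
    o <- order(expl, decreasing = TRUE)
    scores <- scores[, o, drop = FALSE]
    loadings <- loadings[, o, drop = FALSE]
    expl <- expl[o]
    colnames(scores) <- colnames(loadings) <- paste0("RC", seq_len(k))
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = unname(expl), n_components = k,
                 rotation = rotate,
                 total_explained = sum(expl)),
            class = "nmr_pca")
}

#' @export
print.nmr_pca <- function(x, ...) {
  cat(sprintf("<nmr_pca> %d component(s) (%s), %.1f%% of variance\n",
              x$n_components, x$rotation, 100 * x$total_explained))
  invisible(x)
}

# Core O-PLS fit for a single centred response. Returns the model pieces
# needed for prediction and variance bookkeeping.
opls_core <- function(X, y, n_orthogonal) {
  ssx0 <- sum(X^2)
  W_o <- P_o <- NULL
  r2x_comp <- numeric(0)
  Xf <- X
  for (j in seq_len(n_orthogonal)) {
    w <- crossprod(Xf, y); w <- w / sqrt(sum(w^2))
    t_ <- Xf %*% w
    p <- crossprod(Xf, t_) / sum(t_^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / n_wo
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
    r2x_comp <- c(r2x_comp, sum(t_o^2) * sum(p_o^2) / ssx0)
  }
  w <- crossprod(Xf, y); w <- w / sqrt(sum(w^2))
  t_ <- Xf %*% w
  p <- crossprod(Xf, t_) / sum(t_^2)
  q <- as.numeric(crossprod(y, t_) / sum(t_^2))
  list(w = w, p = p, q = q, t = t_, W_o = W_o, P_o = P_o,
       t_o = if (is.null(W_o)) NULL else X %*% W_o,
       r2x_pred = sum(t_^2) * sum(p^2) / ssx0,
       r2x_orth = r2x_comp, ssx0 = ssx0)
}

opls_predict_scores <- function(core, Xnew) {
  Xf <- Xnew
  if (!is.null(core$W_o)) {
    for (j in seq_len(ncol(core$W_o))) {
      t_o <- Xf %*% core$W_o[, j]
      Xf <- Xf - tcrossprod(t_o, core$P_o[, j])
    }
  }
  Xf %*% core$w
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' Fits an OPLS-DA model for a binary class vector: `n_orthogonal`
#' components orthogonal to class membership are stripped from the data
#' (orthogonal signal correction) before a single predictive partial
#' least squares component is extracted. Orthogonal score vectors are
#' uncorrelated with the class by construction.
#'
#' @param x Numeric matrix (samples x variables), typically normalised,
#'   glog-transformed and Pareto-scaled.
#' @param groups Binary grouping vector.
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @return Object of class `oplsda`: predictive/orthogonal scores and
#'   loadings, `R2X`, `R2Y`, VIP scores, and the fitted centring
#'   information. `Q2` is `NA` until filled by [cv_q2()].
#' @export
oplsda_fit <- function(x, groups, n_orthogonal = 1) {
  g <- factor(groups)
  if (nlevels(g) != 2L)
    stop_lfnmr("OPLS-DA requires exactly two classes",
               class = "lfnmr_validation_error")
  if (nrow(x) < 4L)
    stop_lfnmr("need n >= 4 samples", class = "lfnmr_validation_error")
  y <- ifelse(g == levels(g)[1], -1, 1)
  ybar <- mean(y); yc <- y - ybar
  xbar <- colMeans(x); Xc <- sweep(unclass(x), 2, xbar)
  core <- opls_core(Xc, yc, n_orthogonal)
  yhat <- core$t * core$q
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  K <- ncol(x)
  vip <- sqrt(K * core$w^2 / sum(core$w^2))
  structure(list(core = core, scores = core$t,
                 orthogonal_scores = core$t_o,
                 loadings = core$p, weights = core$w,
                 R2X = core$r2x_pred + sum(core$r2x_orth),
                 R2X_predictive = core$r2x_pred,
                 R2Y = r2y, Q2 = NA_real_,
                 vip = stats::setNames(as.numeric(vip),
                                       colnames(x) %||% seq_len(K)),
                 levels = levels(g), y = y, ybar = ybar, xbar = xbar,
                 n_orthogonal = n_orthogonal),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "<oplsda> 1 predictive + %d orthogonal; R2X %.3f, R2Y %.3f, Q2 %s\n",
    x$n_orthogonal, x$R2X, x$R2Y,
    if (is.na(x$Q2)) "NA (run cv_q2)" else sprintf("%.3f", x$Q2)))
  invisible(x)
}

#' @export
predict.oplsda <- function(object, newdata, type = c("response", "class"),
                           ...) {
  type <- match.arg(type)
  Xc <- sweep(as.matrix(newdata), 2, object$xbar)
  t_ <- opls_predict_scores(object$core, Xc)
  yhat <- as.numeric(t_ * object$core$q) + object$ybar
  if (type == "response") return(yhat)
  object$levels[ifelse(yhat < 0, 1L, 2L)]
}

# Stratified k-fold assignment; every fold keeps both classes.
stratified_folds <- function(g, k) {
  g <- factor(g)
  if (any(table(g) < k) && k > 2L) k <- min(table(g))
  idx <- integer(length(g))
  for (lev in levels(g)) {
    who <- which(g == lev)
    idx[who] <- sample(rep_len(seq_len(k), length(who)))
  }
  idx
}

#' Cross-validated predictive ability (Q2)
#'
#' Stratified k-fold cross-validation of the OPLS-DA class prediction:
#' \eqn{Q^2 = 1 - PRESS/TSS} over held-out class values. Values of 0.40
#' and above are the routine cut-off for a meaningful model.
#'
#' @param x Numeric matrix.
#' @param groups Binary grouping vector.
#' @param k_folds Number of folds (default 10; reduced if a class is
#'   smaller than `k_folds`).
#' @param n_orthogonal Orthogonal components per fold model.
#' @param seed Optional seed for the fold assignment.
#' @return Q2 (scalar).
#' @export
cv_q2 <- function(x, groups, k_folds = 10, n_orthogonal = 1, seed = NULL) {
  g <- factor(groups)
  if (nlevels(g) != 2L)
    stop_lfnmr("two classes required", class = "lfnmr_validation_error")
  if (k_folds < 2)
    stop_lfnmr("k_folds must be >= 2", class = "lfnmr_validation_error")
  k_folds <- min(k_folds, min(table(g)))
  y <- ifelse(g == levels(g)[1], -1, 1)
  x <- unclass(x)
  with_seed(seed, {
    fold <- stratified_folds(g, k_folds)
    press <- 0
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      m <- oplsda_fit(x[tr, , drop = FALSE], g[tr], n_orthogonal)
      yhat <- predict(m, x[!tr, , drop = FALSE])
      press <- press + sum((y[!tr] - yhat)^2)
    }
    1 - press / sum((y - mean(y))^2)
  })
}

#' Permutation test for OPLS-DA model statistics
#'
#' Recomputes R2Y and Q2 under `B` random permutations of the class labels
#' and reports one-sided permutation p values
#' \eqn{p = (1 + \#\{permuted \ge observed\})/(1 + B)}; the smallest
#' attainable p is `1/(B + 1)`.
#'
#' @param x Numeric matrix.
#' @param groups Binary grouping vector.
#' @param B Number of permutations (>= 1).
#' @param k_folds,n_orthogonal Passed to the per-permutation model fits.
#' @param seed Optional seed.
#' @return List with observed statistics, permutation distributions and
#'   `p_r2y`, `p_q2`.
#' @export
permutation_test <- function(x, groups, B = 2000, k_folds = 10,
                             n_orthogonal = 1, seed = NULL) {
  if (B < 1)
    stop_lfnmr("B must be >= 1", class = "lfnmr_validation_error")
  x <- unclass(x)
  with_seed(seed, {
    obs_r2y <- oplsda_fit(x, groups, n_orthogonal)$R2Y
    obs_q2 <- cv_q2(x, groups, k_folds, n_orthogonal)
    perm <- vapply(seq_len(B), function(b) {
      gp <- sample(groups)
      c(r2y = oplsda_fit(x, gp, n_orthogonal)$R2Y,
        q2 = cv_q2(x, gp, k_folds, n_orthogonal))
    }, c(r2y = 0, q2 = 0))
    list(R2Y = obs_r2y, Q2 = obs_q2,
         perm_r2y = perm["r2y", ], perm_q2 = perm["q2", ],
         p_r2y = (1 + sum(perm["r2y", ] >= obs_r2y)) / (1 + B),
         p_q2 = (1 + sum(perm["q2", ] >= obs_q2)) / (1 + B),
         B = B)
  })
}

# Rank-based (Mann-Whitney) AUROC; ties get half weight.
rank_auroc <- function(score, is_positive) {
  pos <- score[is_positive]; neg <- score[!is_positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

#' Monte Carlo cross-validated SVM ROC analysis
#'
#' Repeated balanced subsampling: each split draws an equal number of
#' training samples per class (a `train_fraction` of the minority class
#' size), ranks features by absolute two-sample t statistic on the training
#' data only, fits a linear-kernel maximum-margin classifier on the top
#' `n_features`, and scores the held-out samples. AUROC is averaged over
#' splits with a 95% percentile interval.
#'
#' @param x Numeric matrix.
#' @param groups Binary grouping vector.
#' @param n_features Number(s) of top-ranked features per split.
#' @param n_splits Number of Monte Carlo splits (>= 10).
#' @param train_fraction Fraction of the minority class used for training
#'   per class (default 2/3).
#' @param seed Optional seed.
#' @return Object of class `mccv_roc`: per-feature-count mean AUROC with
#'   95% intervals, per-split AUROCs, and a mean ROC curve on a common
#'   false-positive grid for the first feature count.
#' @export
mccv_svm_roc <- function(x, groups, n_features = 10, n_splits = 100,
                         train_fraction = 2 / 3, seed = NULL) {
  g <- factor(groups)
  if (nlevels(g) != 2L)
    stop_lfnmr("two classes required", class = "lfnmr_validation_error")
  if (n_splits < 10)
    stop_lfnmr("n_splits must be >= 10", class = "lfnmr_validation_error")
  n_min <- min(table(g))
  n_train <- floor(n_min * train_fraction)
  if (n_train < 2L)
    stop_lfnmr("classes too small for balanced subsampling",
               class = "lfnmr_validation_error")
  x <- unclass(x)
  n_features <- pmin(n_features, ncol(x))
  pos_level <- levels(g)[2]
  fpr_grid <- seq(0, 1, by = 0.02)
  with_seed(seed, {
    auc <- matrix(NA_real_, n_splits, length(n_features))
    tpr_sum <- numeric(length(fpr_grid))
    for (s in seq_len(n_splits)) {
      tr_idx <- unlist(lapply(levels(g), function(lev)
        sample(which(g == lev), n_train)))
      te_idx <- setdiff(seq_len(nrow(x)), tr_idx)
      tt <- ttest_fdr(x[tr_idx, , drop = FALSE], g[tr_idx])
      rank <- order(abs(tt$t), decreasing = TRUE)
      for (j in seq_along(n_features)) {
        feats <- rank[seq_len(n_features[j])]
        fit <- e1071::svm(x[tr_idx, feats, drop = FALSE],
                          g[tr_idx], kernel = "linear", scale = FALSE)
        dv <- attr(stats::predict(fit, x[te_idx, feats, drop = FALSE],
                                  decision.values = TRUE),
                   "decision.values")[, 1]
        # orient decision values towards the positive class
        if (rank_auroc(dv, g[te_idx] == pos_level) < 0.5) dv <- -dv
        a <- rank_auroc(dv, g[te_idx] == pos_level)
        auc[s, j] <- a
        if (j == 1L) {
          ro <- roc_points(dv, g[te_idx] == pos_level)
          tpr_sum <- tpr_sum + stats::approx(ro$fpr, ro$tpr, fpr_grid,
                                             ties = max, rule = 2)$y
        }
      }
    }
    summary_df <- data.frame(
      n_features = n_features,
      auroc = colMeans(auc),
      lower95 = apply(auc, 2, stats::quantile, 0.025),
      upper95 = apply(auc, 2, stats::quantile, 0.975))
    structure(list(summary = summary_df, auroc = summary_df$auroc[1],
                   splits = auc,
                   mean_roc = data.frame(fpr = fpr_grid,
                                         tpr = tpr_sum / n_splits),
                   positive = pos_level, n_splits = n_splits),
              class = "mccv_roc")
  })
}

roc_points <- function(score, is_positive) {
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(is_positive[o]); fp <- cumsum(!is_positive[o])
  data.frame(fpr = c(0, fp / max(fp[length(fp)], 1)),
             tpr = c(0, tp / max(tp[length(tp)], 1)))
}

#' @export
print.mccv_roc <- function(x, ...) {
  cat(sprintf("<mccv_roc> %d balanced splits, positive class '%s'\n",
              x$n_splits, x$positive))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Random-forest classification with out-of-bag accuracy
#'
#' Bootstrap-aggregated decision trees via the randomForest package; the
#' case-study defaults are 500 trees with seven candidate variables per
#' node.
#'
#' @param x Numeric matrix.
#' @param groups Grouping vector.
#' @param n_trees Number of trees (default 500).
#' @param m_try Variables tried per split (default 7; must not exceed the
#'   number of features).
#' @param seed Optional seed.
#' @return List with `oob_accuracy`, `confusion`, and the fitted forest.
#'   A single-tree forest is flagged `unstable`.
#' @export
random_forest_classify <- function(x, groups, n_trees = 500, m_try = 7,
                                   seed = NULL) {
  if (m_try > ncol(x))
    stop_lfnmr("m_try exceeds the number of features",
               class = "lfnmr_validation_error")
  g <- factor(groups)
  with_seed(seed, {
    fit <- randomForest::randomForest(unclass(x), g, ntree = n_trees,
                                      mtry = m_try)
    conf <- fit$confusion[, levels(g), drop = FALSE]
    list(oob_accuracy = sum(diag(conf)) / sum(conf), confusion = conf,
         unstable = n_trees < 50, forest = fit)
  })
}

#' Drop buckets intersecting exclusion regions
#'
#' Removes feature-matrix columns whose bucket bounds intersect any of the
#' given ppm regions (for example the two glucose buckets, to test their
#' contribution to a discriminant model).
#'
#' @param fm A `feature_matrix` (or any matrix with a `bucket_table`
#'   attribute).
#' @param regions Data frame with columns `low_ppm`, `high_ppm`.
#' @return The filtered matrix; the attribute `dropped` lists removed
#'   bucket labels.
#' @export
exclusion_filter <- function(fm, regions) {
  if (is.null(regions) || nrow(regions) == 0L) {
    attr(fm, "dropped") <- character(0)
    return(fm)
  }
  bt <- attr(fm, "bucket_table")
  if (is.null(bt))
    stop_lfnmr("matrix carries no bucket table",
               class = "lfnmr_validation_error")
  b <- bt$buckets
  drop <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(regions)))
    drop <- drop | (b$low_ppm < regions$high_ppm[i] &
                      b$high_ppm > regions$low_ppm[i])
  keep_labels <- b$label[!drop]
  out <- fm[, colnames(fm) %in% keep_labels, drop = FALSE]
  attributes(out)$bucket_table <- bucket_table(b[!drop, , drop = FALSE],
                                               bt$exclusions)
  for (a in c("state", "tsp_area", "field_MHz"))
    attr(out, a) <- attr(fm, a)
  class(out) <- class(fm)
  attr(out, "dropped") <- b$label[drop]
  out
}
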