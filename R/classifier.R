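#' Default six-parameter feature set for PD classification
#'
#' The fixation saccadic intrusion rate; for short-eccentricity
#' pro-saccades the first gain, mean velocity, mean latency and average
#' number of saccades; and the first gain error for large-eccentricity
#' pro-saccades.
#'
#' @return Character vector of six canonical parameter names.
#' @export
default_features <- function() {
  c("fix_intrusion_rate", "pro_short_first_gain", "pro_short_mean_velocity",
    "pro_short_latency", "pro_short_n_saccades", "pro_large_first_gain_error")
}

#' Ridge-regularised logistic regression
#'
#' Minimises the mean negative log-likelihood plus
#' `ridge_strength * ||w||^2 / 2` (intercept unpenalised) by damped
#' Newton iterations to a gradient-norm tolerance of 1e-8. The penalty
#' keeps the solution finite even on separable data.
#'
#' @param features Numeric matrix (rows = samples), ideally standardised.
#' @param labels 0/1 vector (or logical / two-level factor).
#' @param ridge_strength Penalty weight (default 1).
#' @param max_iter Newton iteration cap.
#' @param tol Gradient-norm convergence tolerance.
#' @return List with `weights`, `intercept`, `converged`, `n_iter`.
#' @export
fit_ridge_logistic <- function(features, labels, ridge_strength = 1,
                               max_iter = 200, tol = 1e-8) {
  X <- as.matrix(features)
  y <- if (is.factor(labels)) as.numeric(labels) - 1 else as.numeric(labels)
  if (length(unique(y)) < 2) {
    stop("fit_ridge_logistic: labels contain a single class", call. = FALSE)
  }
  if (any(table(y) < 2)) {
    stop("fit_ridge_logistic: need at least 2 samples per class",
         call. = FALSE)
  }
  n <- nrow(X)
  d <- ncol(X)
  Xa <- cbind(1, X)
  beta <- numeric(d + 1)
  pen <- c(0, rep(ridge_strength, d))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(Xa, p - y)) / n + pen * beta
    if (sqrt(sum(grad^2)) < tol) {
      return(list(weights = beta[-1], intercept = beta[1], converged = TRUE,
                  n_iter = it - 1L))
    }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa, Xa * w) / n + diag(pen, d + 1)
    step <- solve(H, grad)
    # backtracking on the penalised objective
    obj <- function(b) {
      e <- drop(Xa %*% b)
      mean(log1p(exp(-abs(e))) + pmax(e, 0) - y * e) +
        sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    alpha <- 1
    while (obj(beta - alpha * step) > f0 && alpha > 1e-8) alpha <- alpha / 2
    beta <- beta - alpha * step
  }
  list(weights = beta[-1], intercept = beta[1], converged = FALSE,
       n_iter = max_iter)
}

#' Area under the ROC curve
#'
#' Mann-Whitney pair statistic: the fraction of (positive, negative)
#' score pairs ranked correctly, ties counting one half.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels 0/1 (or logical / two-level factor) true labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.numeric(labels) - 1 else as.numeric(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve (FPR, TPR) points for scores/labels, for vertical averaging.
.roc_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  list(fpr = fpr, tpr = tpr)
}

#' Subsampled evaluation of the ridge-logistic classifier
#'
#' Repeats `n_subsamples` stratified random train/test splits: features
#' are standardised with training-fold means/SDs only, the ridge-logistic
#' model is fitted on the training fold and scored on the test fold. The
#' mean ROC curve is obtained by vertical averaging of per-subsample
#' curves over a fixed FPR grid; AUC, sensitivity and specificity 95% CIs
#' are the 2.5/97.5 percentiles over subsamples; the point sensitivity
#' and specificity come from the pooled test confusion counts at the 0.5
#' probability threshold.
#'
#' @param table Parameter table with `group` (`"PD"` positive, `"HC"`
#'   negative) and the feature columns.
#' @param features Character vector of feature column names.
#' @param n_subsamples Number of random subsamples (default 1,000).
#' @param split_fraction Training fraction (default 0.7, stratified).
#' @param seed Integer seed.
#' @param ridge_strength Ridge penalty (default 1 on standardised
#'   features).
#' @param threshold Probability threshold for the confusion matrix.
#' @param add_age Append age as an extra feature.
#' @return List of class `classifier_report`: `fpr_grid`, `tpr_mean`,
#'   `tpr_lo`, `tpr_hi`, `auc_mean`, `auc_ci`, `sensitivity`,
#'   `sensitivity_ci`, `specificity`, `specificity_ci`, `confusion`
#'   (TP/FN/TN/FP pooled counts), `n_subsamples`, `n`.
#' @export
subsample_evaluate <- function(table, features = default_features(),
                               n_subsamples = 1000, split_fraction = 0.7,
                               seed = 1, ridge_strength = 1, threshold = 0.5,
                               add_age = FALSE) {
  if (add_age) features <- c(features, "age")
  missing_cols <- setdiff(c(features, "group"), names(table))
  if (length(missing_cols)) {
    stop("subsample_evaluate: table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(table[, features])
  X <- as.matrix(table[ok, features])
  y <- as.numeric(table$group[ok] == "PD")
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  if (length(i1) < 4 || length(i0) < 4) {
    stop("subsample_evaluate: need at least 4 subjects per class",
         call. = FALSE)
  }
  n_tr1 <- max(2L, floor(length(i1) * split_fraction))
  n_tr0 <- max(2L, floor(length(i0) * split_fraction))
  if (n_tr1 >= length(i1) || n_tr0 >= length(i0)) {
    stop("subsample_evaluate: split leaves an empty test class",
         call. = FALSE)
  }
  restore <- local_rng(seed)
  on.exit(restore())

  grid <- seq(0, 1, by = 0.01)
  tpr_mat <- matrix(NA_real_, n_subsamples, length(grid))
  auc <- sens <- spec <- numeric(n_subsamples)
  conf <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
  for (b in seq_len(n_subsamples)) {
    tr <- c(sample(i1, n_tr1), sample(i0, n_tr0))
    te <- setdiff(seq_along(y), tr)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- fit_ridge_logistic(Ztr, y[tr], ridge_strength)
    p <- stats::plogis(drop(Zte %*% fit$weights) + fit$intercept)
    yt <- y[te]
    auc[b] <- roc_auc(p, yt)
    rc <- .roc_points(p, yt)
    tpr_mat[b, ] <- stats::approx(rc$fpr, rc$tpr, xout = grid,
                                  ties = max, rule = 2)$y
    pred <- as.numeric(p >= threshold)
    tp <- sum(pred == 1 & yt == 1); fn <- sum(pred == 0 & yt == 1)
    tn <- sum(pred == 0 & yt == 0); fp <- sum(pred == 1 & yt == 0)
    conf <- conf + c(TP = tp, FN = fn, TN = tn, FP = fp)
    sens[b] <- tp / (tp + fn)
    spec[b] <- tn / (tn + fp)
  }
  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975)))
  structure(list(
    fpr_grid = grid, tpr_mean = colMeans(tpr_mat),
    tpr_lo = apply(tpr_mat, 2, stats::quantile, 0.025),
    tpr_hi = apply(tpr_mat, 2, stats::quantile, 0.975),
    auc_mean = mean(auc), auc_ci = ci(auc),
    sensitivity = unname(conf["TP"] / (conf["TP"] + conf["FN"])),
    sensitivity_ci = ci(sens),
    specificity = unname(conf["TN"] / (conf["TN"] + conf["FP"])),
    specificity_ci = ci(spec),
    confusion = conf, n_subsamples = n_subsamples, n = length(y),
    features = features),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    paste0("<classifier_report> %d subjects, %d subsamples\n",
           "  AUC %.3f (95%% CI [%.3f, %.3f])\n",
           "  sensitivity %.3f (95%% CI [%.3f, %.3f])\n",
           "  specificity %.3f (95%% CI [%.3f, %.3f])\n",
           "  pooled confusion: TP %d  FN %d  TN %d  FP %d\n"),
    x$n, x$n_subsamples, x$auc_mean, x$auc_ci[1], x$auc_ci[2],
    x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
    x$specificity, x$specificity_ci[1], x$specificity_ci[2],
    x$confusion["TP"], x$confusion["FN"], x$confusion["TN"],
    x$confusion["FP"]))
  invisible(x)
}
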