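#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom,
#' computed from group means, SDs and sizes (as reported in demographics
#' tables).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' welch_t(63.76, 8.23, 59, 56.64, 8.56, 62)$t  # 4.66
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("welch_t: need n >= 2 per group", call. = FALSE)
  if (sd1 <= 0 && sd2 <= 0) {
    stop("welch_t: zero variance in both groups", call. = FALSE)
  }
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Without continuity correction (matching the convention used for the
#' glasses-wearing comparison).
#'
#' @param counts 2x2 matrix of counts.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0)) {
    stop("chi2_2x2: counts must be a non-negative 2x2 table", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi2_2x2: zero marginal makes the test undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Severity correlation with a normality gate
#'
#' Shapiro-Wilk tests both variables at `alpha_normality`; if both pass,
#' Pearson's r is used, otherwise Spearman's rho (average ranks for ties).
#' Complete cases only.
#'
#' @param values Parameter values.
#' @param severity Severity scores (e.g. UPDRS-III).
#' @param alpha_normality Normality alpha (default 0.05).
#' @param parameter Optional parameter name carried into the result.
#' @return List of class `correlation_result`: `parameter`, `method`
#'   (`"pearson"`/`"spearman"`), `coefficient`, `p_raw`, `n`
#'   (`p_adjusted` is filled in by [bh_adjust()] at the family level).
#' @export
correlate_with_severity <- function(values, severity, alpha_normality = 0.05,
                                    parameter = NA_character_) {
  ok <- is.finite(values) & is.finite(severity)
  x <- values[ok]
  y <- severity[ok]
  if (length(x) < 4) {
    stop("correlate_with_severity: need at least 4 complete pairs",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate_with_severity: constant input, coefficient undefined",
         call. = FALSE)
  }
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha_normality
  }
  method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(parameter = parameter, method = method,
                 coefficient = unname(ct$estimate), p_raw = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values (sort ascending, multiply by m/i, enforce
#' monotonicity from the largest, cap at 1), returned in the original
#' order.
#'
#' @param p Vector of p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("bh_adjust: p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

.design_frame <- function(group, covariates) {
  df <- data.frame(.group = factor(group))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1  # binary indicator
      df[[nm]] <- v
    }
  }
  df
}

#' MANCOVA: multivariate group test with covariates
#'
#' Fits the multivariate linear model `responses ~ group + covariates`
#' (complete cases) and reports, per model term, Pillai's trace with its
#' standard F approximation from type-III hypothesis/error cross-product
#' matrices.
#'
#' @param responses Numeric matrix or data frame, one column per
#'   parameter.
#' @param group Group labels (two or more levels).
#' @param covariates Data frame of covariates (e.g. age, sex); non-numeric
#'   columns are encoded as binary indicators.
#' @return Data frame with one row per term: `term`, `pillai`,
#'   `approx_f`, `df1`, `df2`, `p`.
#' @export
mancova <- function(responses, group, covariates = NULL) {
  responses <- as.matrix(responses)
  df <- .design_frame(group, covariates)
  ok <- stats::complete.cases(responses) & stats::complete.cases(df)
  responses <- responses[ok, , drop = FALSE]
  df <- df[ok, , drop = FALSE]
  preds <- paste(c(".group", setdiff(names(df), ".group")), collapse = " + ")
  n_pred <- ncol(df)
  if (nrow(df) <= n_pred + ncol(responses) + 1) {
    stop("mancova: too few complete cases for the design and responses",
         call. = FALSE)
  }
  mod <- stats::lm(stats::as.formula(paste("responses ~", preds)), data = df)
  qrm <- qr(stats::model.matrix(mod))
  if (qrm$rank < ncol(stats::model.matrix(mod))) {
    bad <- colnames(stats::model.matrix(mod))[qrm$pivot[-seq_len(qrm$rank)]]
    stop("mancova: rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (ncol(responses) == 1) {
    # dimensional reduction: one response collapses Pillai's trace to the
    # univariate type-III F (pillai = df1 F / (df1 F + df2))
    an <- car::Anova(mod, type = "III")
    terms <- setdiff(rownames(an), c("(Intercept)", "Residuals"))
    df2 <- an["Residuals", "Df"]
    out <- do.call(rbind, lapply(terms, function(tm) {
      f <- an[tm, "F value"]
      df1 <- an[tm, "Df"]
      data.frame(term = sub("^\\.group$", "group", tm),
                 pillai = df1 * f / (df1 * f + df2), approx_f = f,
                 df1 = df1, df2 = df2, p = an[tm, "Pr(>F)"])
    }))
    rownames(out) <- NULL
    return(out)
  }
  man <- car::Manova(mod, type = "III", test.statistic = "Pillai")
  sm <- summary(man, multivariate = TRUE)$multivariate.tests
  terms <- setdiff(names(sm), "(Intercept)")
  out <- do.call(rbind, lapply(terms, function(tm) {
    st <- sm[[tm]]
    # Pillai trace + standard F approximation from the H and E matrices
    eig <- Re(eigen(st$SSPH %*% solve(st$SSPE), only.values = TRUE)$values)
    pillai <- sum(eig / (1 + eig))
    p_dim <- nrow(st$SSPH)
    q <- unname(st$df)
    v <- st$df.residual
    s <- min(p_dim, q)
    m1 <- (abs(p_dim - q) - 1) / 2
    n1 <- (v - p_dim - 1) / 2
    f <- ((2 * n1 + s + 1) / (2 * m1 + s + 1)) * (pillai / (s - pillai))
    df1 <- s * (2 * m1 + s + 1)
    df2 <- s * (2 * n1 + s + 1)
    data.frame(term = sub("^\\.group$", "group", tm), pillai = pillai,
               approx_f = f, df1 = df1, df2 = df2,
               p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Post-hoc ANCOVA for one parameter
#'
#' Type-III F for the group term of `response ~ group + covariates`, with
#' covariate-adjusted group means (predictions at the covariate averages)
#' and the percent difference of the first non-reference group relative
#' to the reference (alphabetical first level, typically HC).
#'
#' @param response Numeric response vector.
#' @param group Group labels.
#' @param covariates Data frame of covariates, or `NULL`.
#' @return List of class `group_comparison_result`: `f_statistic`, `df`,
#'   `p_raw`, `adjusted_means` (named), `percent_difference`.
#' @export
ancova_posthoc <- function(response, group, covariates = NULL) {
  df <- .design_frame(group, covariates)
  df$.y <- as.numeric(response)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  preds <- paste(setdiff(names(df), ".y"), collapse = " + ")
  mod <- stats::lm(stats::as.formula(paste(".y ~", preds)), data = df)
  if (any(is.na(stats::coef(mod)))) {
    stop("ancova_posthoc: rank-deficient design; offending column(s): ",
         paste(names(stats::coef(mod))[is.na(stats::coef(mod))],
               collapse = ", "), call. = FALSE)
  }
  # partial (type-III) F for the group term by model comparison; with no
  # interactions this equals the classical type-III test and stays
  # defined even for an exact (zero-residual) fit
  red_preds <- setdiff(names(df), c(".y", ".group"))
  red <- if (length(red_preds)) {
    stats::lm(stats::as.formula(paste(".y ~", paste(red_preds,
                                                    collapse = " + "))),
              data = df)
  } else stats::lm(.y ~ 1, data = df)
  rss1 <- sum(stats::residuals(mod)^2)
  rss0 <- sum(stats::residuals(red)^2)
  q <- stats::df.residual(red) - stats::df.residual(mod)
  df2 <- stats::df.residual(mod)
  f <- if (rss1 > 0) ((rss0 - rss1) / q) / (rss1 / df2) else Inf
  row <- list(`F value` = f, Df = q,
              `Pr(>F)` = stats::pf(f, q, df2, lower.tail = FALSE))
  lv <- levels(df$.group)
  newd <- df[rep(1, length(lv)), , drop = FALSE]
  newd$.group <- factor(lv, levels = lv)
  for (nm in setdiff(names(df), c(".group", ".y"))) {
    newd[[nm]] <- mean(df[[nm]])
  }
  adj <- stats::predict(mod, newdata = newd)
  names(adj) <- lv
  pct <- if (length(lv) == 2 && adj[1] != 0) {
    100 * (adj[2] - adj[1]) / abs(adj[1])
  } else NA_real_
  structure(list(
    f_statistic = row[["F value"]],
    df = c(row[["Df"]], stats::df.residual(mod)),
    p_raw = row[["Pr(>F)"]],
    adjusted_means = adj, percent_difference = unname(pct)),
    class = "group_comparison_result")
}

#' Run the full statistical layer over a parameter table
#'
#' For each parameter: the severity correlation (PD subjects with a
#' UPDRS-III score, normality-gated) and the covariate-adjusted group
#' comparison (MANCOVA per task family, then per-parameter post-hoc
#' ANCOVA). BH correction is applied separately within each task family
#' (fixation / pro-saccade / anti-saccade), matching the per-table
#' presentation of the parameters.
#'
#' @param table Parameter table ([read_parameter_table()] /
#'   [extract_cohort()]).
#' @param alpha_normality Normality-gate alpha.
#' @return List with `correlations`, `comparisons` (data frames including
#'   BH-adjusted p values) and `mancova` (per-family multivariate tests).
#' @export
analyze_parameter_table <- function(table, alpha_normality = 0.05) {
  params <- intersect(canonical_parameter_names(), names(table))
  family <- function(nm) {
    if (startsWith(nm, "fix_")) "fixation"
    else if (startsWith(nm, "pro_")) "prosaccade" else "antisaccade"
  }
  covs <- table[, c("age", "sex")]
  pd <- table$group == "PD" & is.finite(table$updrs3)

  cors <- lapply(params, function(nm) {
    res <- tryCatch(
      correlate_with_severity(table[[nm]][pd], table$updrs3[pd],
                              alpha_normality, parameter = nm),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(parameter = nm, family = family(nm), method = res$method,
               coefficient = res$coefficient, p_raw = res$p_raw, n = res$n)
  })
  cors <- do.call(rbind, cors)

  cmps <- lapply(params, function(nm) {
    res <- tryCatch(ancova_posthoc(table[[nm]], table$group, covs),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(parameter = nm, family = family(nm),
               f_statistic = res$f_statistic, df1 = res$df[1],
               df2 = res$df[2], p_raw = res$p_raw,
               percent_difference = res$percent_difference)
  })
  cmps <- do.call(rbind, cmps)

  adjust_by_family <- function(df) {
    df$p_adjusted <- NA_real_
    for (fam in unique(df$family)) {
      i <- df$family == fam
      df$p_adjusted[i] <- bh_adjust(df$p_raw[i])
    }
    df
  }
  if (!is.null(cors)) cors <- adjust_by_family(cors)
  if (!is.null(cmps)) cmps <- adjust_by_family(cmps)

  mans <- lapply(unique(vapply(params, family, character(1))), function(fam) {
    nm <- params[vapply(params, family, character(1)) == fam]
    keep <- nm[vapply(nm, function(x) {
      v <- table[[x]][stats::complete.cases(table[, c(x, "age", "sex")])]
      stats::sd(v, na.rm = TRUE) > 0
    }, logical(1))]
    if (!length(keep)) return(NULL)
    res <- tryCatch(mancova(table[, keep, drop = FALSE], table$group, covs),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$family <- fam
    res
  })
  list(correlations = cors, comparisons = cmps,
       mancova = do.call(rbind, mans))
}
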