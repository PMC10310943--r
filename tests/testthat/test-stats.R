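test_that("welch_t matches direct formula evaluation on random summaries", {
  set.seed(1)
  for (i in 1:200) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    res <- welch_t(m1, s1, n1, m2, s2, n2)
    tt <- (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
    df <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    expect_equal(res$t, tt, tolerance = 1e-12)
    expect_equal(res$df, df, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(tt), df), tolerance = 1e-12)
  }
  # identical summaries -> t = 0; larger n -> larger |t|
  expect_equal(welch_t(1, 1, 10, 1, 1, 10)$t, 0)
  expect_gt(abs(welch_t(1, 1, 40, 0.5, 1, 40)$t),
            abs(welch_t(1, 1, 20, 0.5, 1, 20)$t))
  expect_error(welch_t(1, 0, 10, 1, 0, 10), "zero variance")
})

test_that("welch_t agrees with t.test on raw data", {
  set.seed(2)
  x <- rnorm(30, 1); y <- rnorm(40, 0.4, 1.5)
  res <- welch_t(mean(x), sd(x), 30, mean(y), sd(y), 40)
  ref <- t.test(x, y)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("chi2_2x2 equals the direct O/E sum", {
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    res <- chi2_2x2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(res$df, 1)
  }
  expect_equal(chi2_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("severity correlation gates on normality", {
  x <- 1:10
  res <- correlate_with_severity(2 * x + 1, x)
  expect_equal(res$method, "pearson")
  expect_equal(res$coefficient, 1)

  y <- exp(seq(1, 20))
  res2 <- correlate_with_severity(y, seq(1, 20))
  expect_equal(res2$method, "spearman")
  expect_equal(res2$coefficient, 1)

  # heavy-tailed pair with known population Spearman correlation
  set.seed(4)
  n <- 500
  z <- rnorm(n)
  a <- exp(2 * (0.45 * z + sqrt(1 - 0.45^2) * rnorm(n)))
  b <- rt(n, df = 3) + 1.2 * z
  rho_pop <- cor(rank(a), rank(b))  # large-n rank oracle on this draw
  res3 <- correlate_with_severity(a, b)
  expect_equal(res3$method, "spearman")
  expect_equal(res3$coefficient, rho_pop, tolerance = 1e-10)

  expect_error(correlate_with_severity(rep(1, 10), 1:10), "constant")
  expect_error(correlate_with_severity(1:3, 1:3), "4 complete")
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  # worked step-up example with distinct outcomes: sorted raw p are
  # {.005,.03,.04,.9} -> m/i-scaled {.02,.06,.0533,.9} -> monotone step
  # from the largest gives {.02,.0533,.0533,.9}
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03, 0.9)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.9))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust is order-equivariant and never decreases p", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("single-response MANCOVA equals univariate ANCOVA", {
  set.seed(6)
  n <- 60
  df <- data.frame(g = rep(c("HC", "PD"), each = n / 2),
                   age = rnorm(n, 60, 8),
                   sex = sample(c("F", "M"), n, TRUE))
  y <- 0.4 * (df$g == "PD") + 0.02 * df$age + rnorm(n)
  man <- mancova(matrix(y, ncol = 1), df$g,
                 covariates = df[, c("age", "sex")])
  anc <- ancova_posthoc(y, df$g, df[, c("age", "sex")])
  f_man <- man$approx_f[man$term == "group"]
  expect_equal(f_man, anc$f_statistic, tolerance = 1e-9)
  expect_equal(man$p[man$term == "group"], anc$p_raw, tolerance = 1e-9)
})

test_that("mancova detects a strong multivariate group shift", {
  set.seed(7)
  n <- 100
  g <- rep(c("HC", "PD"), each = n / 2)
  covs <- data.frame(age = rnorm(n, 60, 8), sex = sample(c("F", "M"), n, TRUE))
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[g == "PD", 1] <- Y[g == "PD", 1] + 3
  res <- mancova(Y, g, covs)
  expect_lt(res$p[res$term == "group"], 0.001)
  expect_gte(min(res$pillai), 0)
  # and a pure-covariate response absorbs into the covariate
  y2 <- covs$age + rnorm(n, 0, 0.01)
  anc <- ancova_posthoc(y2, g, covs)
  expect_lt(anc$f_statistic, 4)
})

test_that("permuted group labels give a uniform MANCOVA p value", {
  set.seed(8)
  n <- 40
  covs <- data.frame(age = rnorm(n, 60, 8), sex = sample(c("F", "M"), n, TRUE))
  Y <- matrix(rnorm(n * 3), n, 3)
  g0 <- rep(c("HC", "PD"), each = n / 2)
  ps <- vapply(1:200, function(i) {
    g <- sample(g0)
    res <- mancova(Y, g, covs)
    res$p[res$term == "group"]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ancova adjusted means and percent difference are exact on clean data", {
  df <- data.frame(g = rep(c("HC", "PD"), each = 10),
                   age = rep(seq(50, 70, length.out = 10), 2))
  y <- 2 * (df$g == "PD") + 1   # HC mean 1, PD mean 3, no noise
  res <- ancova_posthoc(y, df$g, df["age"])
  expect_equal(unname(res$adjusted_means["PD"] - res$adjusted_means["HC"]), 2,
               tolerance = 1e-10)
  expect_equal(res$percent_difference, 200, tolerance = 1e-8)
  expect_error(ancova_posthoc(y, df$g, data.frame(dup = df$age,
                                                  dup2 = df$age)),
               "rank-deficient")
})

test_that("the full statistical layer runs on an extracted-style table", {
  tab <- make_separable_table(n_per_group = 25, gap = 1, seed = 9)
  tab$updrs3[tab$group == "PD"] <- round(runif(25, 5, 60))
  res <- analyze_parameter_table(tab)
  expect_true(all(c("fixation", "prosaccade", "antisaccade") %in%
                    res$comparisons$family))
  expect_true(all(res$comparisons$p_adjusted >= res$comparisons$p_raw - 1e-12))
  expect_true(all(res$correlations$method %in% c("pearson", "spearman")))
  expect_equal(nrow(res$comparisons), 24)
  # the separable feature should be flagged
  expect_lt(res$comparisons$p_adjusted[
    res$comparisons$parameter == "fix_intrusion_rate"], 0.01)
  expect_true("group" %in% res$mancova$term)
})
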