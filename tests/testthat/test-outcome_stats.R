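test_that("paired_t matches the classical t-test", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    pre <- rnorm(n, 10, 3)
    post <- pre - rnorm(n, 1, 2)
    ours <- paired_t(pre, post)
    ref <- t.test(pre, post, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$ci, as.numeric(ref$conf.int), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("paired_t handles degenerate inputs explicitly", {
  x <- c(3, 5, 7)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$cohen_d, 0)
  expect_error(paired_t(x, x - 2), "constant nonzero")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("the |t| = |d| sqrt(n) identity holds exactly", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    res <- paired_t(rnorm(n), rnorm(n))
    expect_equal(abs(res$t), abs(res$cohen_d) * sqrt(n), tolerance = 1e-12)
  }
  sm <- paired_t_stats(1.06, 1.87, 27)
  expect_equal(abs(sm$t), abs(sm$cohen_d) * sqrt(27), tolerance = 1e-12)
})

test_that("correlation matrix uses pairwise complete pairs", {
  d <- data.frame(
    a = c(1, 2, 3, 4, 5, NA),
    b = c(2, 4, 6, 8, 10, 12),
    c = c(5, 3, 4, 1, NA, 2)
  )
  cm <- correlation_matrix(d)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], 1) # exactly linear
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$n["a", "c"], 4)
  expect_equal(cm$n["b", "c"], 5)
  expect_equal(cm$r["a", "c"], cor(d$a, d$c, use = "pairwise"))

  const <- data.frame(a = rep(2, 5), b = 1:5)
  cm2 <- correlation_matrix(const)
  expect_true("a" %in% cm2$degenerate)
  expect_true(is.na(cm2$r["a", "b"]))
})

test_that("a planted correlation is recovered within its sampling band", {
  set.seed(33)
  n <- 500
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  cm <- correlation_matrix(data.frame(x = x, y = y))
  expect_lt(abs(cm$r["x", "y"] - 0.5), 0.08) # Fisher-z 95% width at n = 500
})

test_that("single-predictor regression reduces to the zero-order correlation", {
  set.seed(34)
  d <- data.frame(x = rnorm(40))
  d$y <- 0.6 * d$x + rnorm(40)
  hr <- hierarchical_regression(d, "y", list("x"))
  r <- cor(d$x, d$y)
  expect_equal(hr$steps[[1]]$coefficients$beta, r, tolerance = 1e-12)
  expect_equal(hr$steps[[1]]$r2, r^2, tolerance = 1e-12)
})

test_that("hierarchical steps report non-negative R2 change and valid dF", {
  set.seed(35)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 0.5 * d$x1 - 0.3 * d$x2 + rnorm(n)
  hr <- hierarchical_regression(d, "y", list("x1", c("x2", "x3")))
  expect_equal(length(hr$steps), 2)
  expect_gte(hr$steps[[2]]$dr2, 0)
  expect_equal(hr$steps[[2]]$r2,
    hr$steps[[1]]$r2 + hr$steps[[2]]$dr2,
    tolerance = 1e-12)
  # dF identity: (dR2/q) / ((1 - R2_full)/(n - k - 1))
  st <- hr$steps[[2]]
  dF_manual <- (st$dr2 / 2) / ((1 - st$r2) / (n - 3 - 1))
  expect_equal(st$dF, dF_manual, tolerance = 1e-10)

  d$x4 <- d$x1 * 2 # exact collinearity
  expect_error(hierarchical_regression(d, "y", list("x1", "x4")), "singular")
})

test_that("adding pure-noise predictors rejects at about the nominal rate", {
  set.seed(36)
  reps <- 1000
  n <- 40
  p <- replicate(reps, {
    d <- data.frame(x = rnorm(n), z1 = rnorm(n), z2 = rnorm(n))
    d$y <- 0.4 * d$x + rnorm(n)
    hierarchical_regression(d, "y", list("x", c("z1", "z2")))$steps[[2]]$p_dF
  })
  rate <- mean(p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 2.5 * mc_se)
})

test_that("regression and correlation-bridge solutions agree on the same data", {
  set.seed(37)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$x3 <- 0.5 * d$x1 + rnorm(n)
  d$y <- 0.3 * d$x1 + 0.2 * d$x2 - 0.4 * d$x3 + rnorm(n)
  preds <- c("x1", "x2", "x3")
  hr <- hierarchical_regression(d, "y", list("x1", c("x2", "x3")))
  R <- cor(d[preds])
  r <- sapply(preds, function(v) cor(d[[v]], d$y))
  sr <- regression_from_correlations(R, r, list("x1", c("x2", "x3")))
  for (s in 1:2) {
    expect_equal(
      setNames(hr$steps[[s]]$coefficients$beta,
        hr$steps[[s]]$coefficients$predictor),
      sr$steps[[s]]$beta,
      tolerance = 1e-8
    )
    expect_equal(hr$steps[[s]]$r2, sr$steps[[s]]$r2, tolerance = 1e-8)
  }
})

test_that("the correlation bridge handles canonical cases", {
  one <- regression_from_correlations(
    matrix(1, dimnames = list("x", "x")), c(x = 0.5), list("x"))
  expect_equal(one$steps[[1]]$beta, c(x = 0.5))
  expect_equal(one$steps[[1]]$r2, 0.25)

  # orthogonal predictors: R2 adds up
  R <- diag(2)
  dimnames(R) <- list(c("a", "b"), c("a", "b"))
  two <- regression_from_correlations(R, c(a = 0.3, b = 0.4),
    list(c("a", "b")))
  expect_equal(two$steps[[1]]$r2, 0.09 + 0.16)

  bad <- matrix(c(1, 0.99, 0.99, 0.97), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(
    regression_from_correlations(bad, c(a = 0.1, b = 0.1), list(c("a", "b"))),
    "positive definite")
})

test_that("icc_agreement implements single-rater absolute agreement", {
  x <- c(0, 1, 2, 3, 1, 2, 0, 3, 2, 1)
  expect_equal(icc_agreement(x, x)$value, 1)

  set.seed(38)
  r1 <- sample(0:3, 600, replace = TRUE)
  r2 <- sample(0:3, 600, replace = TRUE)
  expect_lt(abs(icc_agreement(r1, r2)$value), 0.1)

  same <- icc_agreement(rep(2, 10), rep(2, 10))
  expect_true(same$degenerate)

  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("icc_agreement matches a variance-component fit", {
  skip_if_not_installed("lme4")
  set.seed(39)
  n <- 300
  truth <- rnorm(n, 1.5, 0.8)
  bias <- c(0, 0.25) # coder 2 rates systematically higher
  r1 <- truth + bias[1] + rnorm(n, 0, 0.4)
  r2 <- truth + bias[2] + rnorm(n, 0, 0.4)
  ours <- icc_agreement(r1, r2)$value

  long <- data.frame(
    y = c(r1, r2),
    target = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  fit <- lme4::lmer(y ~ 1 + (1 | target) + (1 | rater), data = long)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  ref <- v[["target"]] / (v[["target"]] + v[["rater"]] + v[["Residual"]])
  expect_equal(ours, unname(ref), tolerance = 0.02)
})
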