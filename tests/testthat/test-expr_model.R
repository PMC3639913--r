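make_xy <- function(n = 200, seed = 1) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  d$y <- 2 * d$x1 + rnorm(n)
  d
}

test_that("stepwise selection finds a planted single predictor", {
  d <- make_xy()
  fit <- stepwise_select(d, "y", c("x1", "x2", "x3", "x4"))
  expect_equal(fit$selected, "x1")
  expect_s3_class(fit, "expr_model")
  expect_gt(fit$r_squared, 0.7)
})

test_that("penalty zero keeps the full model and larger penalties never grow it", {
  d <- make_xy(seed = 2)
  full <- stepwise_select(d, "y", c("x1", "x2", "x3", "x4"), k = 0)
  expect_setequal(full$selected, c("x1", "x2", "x3", "x4"))
  sizes <- vapply(c(0, 2, log(200), 8, 20), function(k) {
    length(stepwise_select(d, "y", c("x1", "x2", "x3", "x4"), k = k)$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("all-noise candidates yield the intercept-only model in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    y = rnorm(n))
    fit <- stepwise_select(d, "y", c("x1", "x2", "x3"), k = log(n))
    hits <- hits + (length(fit$selected) == 0L)
  }
  expect_gte(hits, 18L)
})

test_that("collinear candidates are dropped with a warning before selection", {
  d <- make_xy(seed = 3)
  d$x5 <- d$x1 + d$x2        # exactly collinear
  expect_warning(
    fit <- stepwise_select(d, "y", c("x1", "x2", "x3", "x4", "x5")),
    "collinear"
  )
  expect_equal(fit$dropped, "x5")
  expect_true("x1" %in% fit$selected)
  expect_false("x5" %in% fit$selected)
})

test_that("LMG shares are exact for planted designs and match enumeration", {
  d <- make_xy(seed = 4)
  fit <- stepwise_select(d, "y", c("x1", "x2", "x3", "x4"))
  expect_equal(fit$contributions$share, 1)   # single selected predictor

  # two orthonormal predictors with equal signal split the share evenly
  n <- 100
  x1 <- rep(c(1, -1), n / 2) / sqrt(n)
  x2 <- rep(c(1, 1, -1, -1), n / 4) / sqrt(n)
  y <- x1 + x2                                # exact symmetric case
  sh <- contribution_decomposition(cbind(x1 = x1, x2 = x2), y = y)
  expect_equal(sh$share, c(0.5, 0.5), tolerance = 1e-9)

  set.seed(5)
  for (p in 2:4) {
    X <- matrix(rnorm(50 * p), 50, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    yy <- X %*% runif(p, 0.5, 1.5) + rnorm(50)
    got <- contribution_decomposition(X, y = as.numeric(yy))
    expect_equal(got$share, oracle_lmg(X, as.numeric(yy)), tolerance = 1e-9)
    expect_equal(sum(got$share), 1, tolerance = 1e-9)
  }
})

test_that("contribution bootstrap CIs are seeded and bracket the shares", {
  set.seed(6)
  X <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, 0.5, 0.25) + rnorm(120))
  ci1 <- contribution_decomposition(X, y = y, boot = 200, seed = 7)
  ci2 <- contribution_decomposition(X, y = y, boot = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_lower <= ci1$share + 1e-9))
  expect_true(all(ci1$ci_upper >= ci1$share - 1e-9))
})

test_that("the ratio covariate model reports R-squared faithfully", {
  set.seed(8)
  n <- 300
  d <- data.frame(tai = runif(n, 0.25, 0.5),
                  log_cds_len = log(runif(n, 300, 3000)))
  d$y <- 3 * d$tai / d$log_cds_len          # exact linear in the ratio
  fit <- suppressWarnings(ratio_model(d, "y"))  # lm warns on a perfect fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$selected, "tai_over_logLcds")

  # response independent of the ratio: R-squared stays near zero
  small <- 0L
  for (s in 1:5) {
    set.seed(s + 100)
    d$y <- rnorm(n)
    small <- small + (ratio_model(d, "y")$r_squared < 0.03)
  }
  expect_gte(small, 4L)
})

test_that("expr_model methods behave like a classic fitted model", {
  d <- make_xy(seed = 9)
  fit <- stepwise_select(d, "y", c("x1", "x2", "x3", "x4"), boot = 50, seed = 1)
  expect_output(print(fit), "Stepwise expression model")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.expr_model")
  expect_true(all(c("coefficient", "ci_lower", "p_value", "contribution")
                  %in% names(sm$table)))
  expect_output(print(sm), "R-squared")
  expect_named(coef(fit)[2], "x1")
  expect_equal(length(predict(fit, newdata = d[1:5, ])), 5L)
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(fitted(fit) + residuals(fit), fitted(fit$fit) + residuals(fit$fit))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2L))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
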