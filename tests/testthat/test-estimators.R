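# The five direct-mapping estimators against independent oracles and
# parameter-recovery experiments.

test_that("OLS matches the normal-equations oracle and handles edge cases", {
  X <- random_design(50, 3, seed = 1)
  beta_true <- c(0.9, 0.03, -0.02, 0.01)
  set.seed(2)
  y <- drop(X %*% beta_true) + rnorm(50, 0, 0.05)
  fit <- fit_ols(X, y)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% y  # brute-force normal equations
  expect_equal(unname(fit$coefficients), unname(drop(oracle)),
               tolerance = 1e-8)

  # exact linear data: zero residuals
  y0 <- drop(X %*% beta_true)
  fit0 <- fit_ols(X, y0)
  expect_equal(unname(fit0$coefficients), beta_true, tolerance = 1e-10)
  expect_lt(max(abs(y0 - predict(fit0, X))), 1e-10)

  # constant outcome: intercept c, slopes 0
  fitc <- fit_ols(X, rep(0.7, 50))
  expect_equal(unname(fitc$coefficients), c(0.7, 0, 0, 0), tolerance = 1e-12)

  # rank deficiency names the collinear column
  X2 <- cbind(X, x1_copy = X[, "x1"])
  expect_error(fit_ols(X2, y), "x1_copy")
})

test_that("OLS predictions pass through the training centroid", {
  X <- random_design(80, 2, seed = 3)
  set.seed(4)
  y <- 0.8 + 0.05 * X[, 2] + rnorm(80, 0, 0.03)
  fit <- fit_ols(X, y)
  centroid <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_equal(predict(fit, centroid), mean(y), tolerance = 1e-10)
})

test_that("GLM with logit link recovers an inverse-logit mean model", {
  X <- random_design(2000, 2, seed = 5)
  beta_true <- c(1.8, 0.4, -0.3)
  set.seed(6)
  y <- plogis(drop(X %*% beta_true)) + rnorm(2000, 0, 0.01)
  y <- pmin(pmax(y, 0), 1)
  fit <- fit_glm_logit(X, y)
  expect_true(all(abs(fit$coefficients - beta_true) < 2 * fit$se))
  pr <- predict(fit, X)
  expect_true(all(pr > 0 & pr < 1))

  # constant y = 0.5: zero intercept and slope
  fit5 <- fit_glm_logit(random_design(500, 1, seed = 7), rep(0.5, 500))
  expect_lt(max(abs(fit5$coefficients)), 0.02)
})

test_that("Tobit without censored observations reduces to OLS", {
  X <- random_design(300, 2, seed = 8)
  set.seed(9)
  y <- 0.6 + 0.05 * X[, 2] - 0.03 * X[, 3] + rnorm(300, 0, 0.05)
  y <- pmin(y, 0.95)  # keep everything strictly below the bound
  ols <- fit_ols(X, y)
  tob <- fit_tobit(X, y, upper = 1)
  expect_equal(tob$coefficients, ols$coefficients, tolerance = 1e-4)
  # censoring bound at infinity: exact Gaussian likelihood, OLS solution
  tob_inf <- fit_tobit(X, y, upper = Inf, lower = -Inf)
  expect_equal(tob_inf$coefficients, ols$coefficients, tolerance = 1e-6)
})

test_that("Tobit MLE recovers the generating parameters under censoring", {
  X <- random_design(5000, 2, seed = 10)
  beta_true <- c(0.92, 0.06, -0.04)
  sigma_true <- 0.08
  set.seed(11)
  ystar <- drop(X %*% beta_true) + rnorm(5000, 0, sigma_true)
  y <- pmin(ystar, 1)
  expect_gt(mean(y == 1), 0.05)  # censoring actually binds
  fit <- fit_tobit(X, y, upper = 1)
  expect_true(all(abs(fit$coefficients - beta_true) < 3 * fit$se))
  expect_lt(abs(fit$sigma - sigma_true) / sigma_true, 0.10)
  expect_lt(fit$grad_max, 1e-5)  # score vanishes at the optimum
  expect_true(all(predict(fit, X) <= 1))
})

test_that("Tobit agrees with the survreg censored-regression oracle", {
  skip_if_not_installed("survival")
  X <- random_design(1000, 2, seed = 12)
  set.seed(13)
  y <- pmin(drop(X %*% c(0.9, 0.05, -0.05)) + rnorm(1000, 0, 0.07), 1)
  fit <- fit_tobit(X, y, upper = 1)
  sv <- survival::survreg(survival::Surv(y, y < 1, type = "right") ~ X[, -1],
                          dist = "gaussian")
  expect_equal(unname(fit$coefficients), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-6)
})

test_that("Tobit rejects degenerate censoring patterns", {
  X <- random_design(50, 1, seed = 14)
  expect_error(fit_tobit(X, rep(1, 50), upper = 1), "all observations")
})

test_that("Beta regression recovers the generating parameters", {
  X <- random_design(5000, 2, seed = 15)
  beta_true <- c(2.0, 0.35, -0.25)
  phi_true <- 60
  set.seed(16)
  mu <- plogis(drop(X %*% beta_true))
  y <- rbeta(5000, mu * phi_true, (1 - mu) * phi_true)
  fit <- fit_beta(X, y, adjust = FALSE)
  expect_true(all(abs(fit$coefficients - beta_true) < 3 * fit$se))
  expect_lt(abs(fit$phi - phi_true) / phi_true, 0.15)
  expect_lt(fit$grad_max, 1e-5)
  expect_true(all(predict(fit, X) > 0 & predict(fit, X) < 1))
})

test_that("Beta regression limits behave correctly", {
  # intercept-only: fitted mean matches the sample mean
  X1 <- matrix(1, 400, 1, dimnames = list(NULL, "(Intercept)"))
  set.seed(17)
  y <- rbeta(400, 8, 2)
  fit <- fit_beta(X1, y, adjust = FALSE)
  expect_equal(plogis(fit$coefficients[[1]]), mean(y), tolerance = 0.01)

  # near-noiseless inverse-logit data: coefficients recovered to 1e-3
  X <- random_design(3000, 2, seed = 18)
  beta_true <- c(1.5, 0.3, -0.2)
  set.seed(19)
  mu <- plogis(drop(X %*% beta_true))
  y2 <- rbeta(3000, mu * 5000, (1 - mu) * 5000)
  fit2 <- fit_beta(X, y2, adjust = FALSE)
  expect_lt(max(abs(fit2$coefficients - beta_true)), 1e-3)

  expect_error(fit_beta(X, runif(3000, -1, 2)), "\\[0, 1\\]")
})

test_that("the boundary adjustment maps [0,1] into the open interval", {
  y <- c(0, 0.5, 1)
  y2 <- adjust_boundary(y, n = 100)
  expect_true(all(y2 > 0 & y2 < 1))
  expect_equal(y2[2], 0.5, tolerance = 1e-12)
  expect_error(adjust_boundary(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("MM matches OLS on clean data but resists gross outliers", {
  X <- random_design(500, 1, seed = 20)
  beta_true <- c(0.85, 0.06)
  set.seed(21)
  y <- drop(X %*% beta_true) + rnorm(500, 0, 0.05)
  mm <- fit_mm(X, y)
  ols <- fit_ols(X, y)
  expect_equal(mm$coefficients, ols$coefficients, tolerance = 1e-3)

  # 10% gross contamination at +10
  y_bad <- y
  set.seed(22)
  bad <- sample(500, 50)
  y_bad[bad] <- y_bad[bad] + 10
  mm_c <- fit_mm(X, y_bad)
  ols_c <- fit_ols(X, y_bad)
  err_mm <- abs(mm_c$coefficients[["x1"]] - beta_true[2])
  err_ols <- abs(ols_c$coefficients[["x1"]] - beta_true[2])
  expect_lt(err_mm / abs(beta_true[2]), 0.05)
  expect_lt(err_mm, err_ols)

  # constant outcome degenerates to an exact fit
  mm0 <- fit_mm(X, rep(0.9, 500))
  expect_equal(unname(mm0$coefficients), c(0.9, 0), tolerance = 1e-12)
})

test_that("prediction rules follow each family's published form", {
  X <- random_design(100, 1, seed = 23)
  set.seed(24)
  y <- pmin(0.9 + 0.05 * X[, 2] + rnorm(100, 0, 0.05), 1)
  tob <- fit_tobit(X, y)
  # a row whose linear predictor exceeds 1 is capped at exactly 1
  x_hi <- matrix(c(1, (1.5 - tob$coefficients[1]) / tob$coefficients[2]),
                 1, dimnames = list(NULL, colnames(X)))
  expect_identical(predict(tob, x_hi), 1)

  bet <- fit_beta(X, y)
  x_mid <- matrix(c(1, -bet$coefficients[1] / bet$coefficients[2]),
                  1, dimnames = list(NULL, colnames(X)))
  expect_equal(predict(bet, x_mid), 0.5, tolerance = 1e-12)

  expect_error(predict(tob, X[, 2, drop = FALSE]), "do not match")
})

test_that("design matrices implement the six variable combinations", {
  prep <- test_prep()
  expect_equal(colnames(design_matrix(prep, 1)), c("(Intercept)", "total"))
  expect_equal(colnames(design_matrix(prep, 4)),
               c("(Intercept)", "PF", "EF", "SF", "ScF", "female", "age"))
  X6 <- design_matrix(prep, 6)
  expect_equal(ncol(X6), 16)  # intercept + 13 items + female + age
  expect_true(all(X6[, "pf2"] %in% c(0, .25, .5, .75, 1)))
  # all score regressors divided by 100, so bounded by 1
  expect_true(all(X6[, setdiff(colnames(X6), c("(Intercept)", "age"))] <= 1))
  expect_equal(design_matrix(prep, 1)[, "total"] * 100,
               prep$total[attr(design_matrix(prep, 1), "rows")],
               ignore_attr = TRUE)
})
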