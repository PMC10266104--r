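# Metrics, cross-validation, ranking, screening, stepwise selection.

test_that("metrics behave on identity and constant-shift predictions", {
  set.seed(51)
  y <- runif(50, 0.6, 1)
  m_id <- compute_metrics(y, y, p = 1)
  expect_equal(m_id$mae, 0)
  expect_equal(m_id$rmse, 0)
  expect_equal(m_id$ccc, 1)
  expect_equal(m_id$adj_r2, 1)

  m_sh <- compute_metrics(y, y + 0.1, p = 1)
  expect_equal(m_sh$mae, 0.1, tolerance = 1e-12)
  expect_equal(m_sh$rmse, 0.1, tolerance = 1e-12)
  expect_lt(m_sh$ccc, 1)  # CCC penalises the shift; Pearson r stays 1
  expect_equal(cor(y, y + 0.1), 1)

  expect_error(compute_metrics(rep(0.5, 20), runif(20), p = 1),
               "zero variance")
})

test_that("CCC matches an independently coded textbook oracle", {
  ccc_oracle <- function(y, x) {
    # Lin's CCC via the correlation-and-scale decomposition
    n <- length(y)
    sy <- sqrt(mean((y - mean(y))^2)); sx <- sqrt(mean((x - mean(x))^2))
    r <- cor(y, x)
    (2 * r * sy * sx) / (sy^2 + sx^2 + (mean(y) - mean(x))^2)
  }
  set.seed(52)
  for (i in 1:5) {
    y <- rnorm(20); x <- 0.8 * y + rnorm(20, 0, 0.5)
    got <- compute_metrics(y, x, p = 1)$ccc
    expect_equal(got, ccc_oracle(y, x), tolerance = 1e-12)
    expect_lte(abs(got), abs(cor(y, x)))  # |CCC| <= |Pearson r|
  }
})

test_that("MAE never exceeds RMSE", {
  set.seed(53)
  for (i in 1:10) {
    y <- rnorm(30); x <- y + rnorm(30, 0, runif(1, 0.01, 1))
    m <- compute_metrics(y, x, p = 1)
    expect_lte(m$mae, m$rmse + 1e-15)
  }
})

test_that("Spearman screen reproduces the printed strength bands", {
  set.seed(54)
  n <- 60
  u <- runif(n)
  x <- data.frame(mono = u^3, noise = rnorm(n), flat = rep(1, n))
  scr <- spearman_screen(x, u)
  expect_equal(scr$rho[scr$variable == "mono"], 1)
  expect_equal(scr$band[scr$variable == "mono"], "very strong")
  expect_equal(scr$band[scr$variable == "flat"], "undefined")
  expect_true(is.na(scr$rho[scr$variable == "flat"]))
  expect_equal(spearman_screen(data.frame(v = 1:10), 1:10)$band, "very strong")
})

test_that("strength bands cut at the printed edges", {
  # a rho in the 0.60-0.79 band must read "strong"
  set.seed(63)
  repeat {
    x <- rnorm(40); y <- 0.8 * x + rnorm(40, 0, 0.75)
    rho <- cor(x, y, method = "spearman")
    if (rho > 0.60 && rho < 0.79) break
  }
  expect_equal(spearman_screen(data.frame(x = x), y)$band, "strong")
})

test_that("Spearman with ties equals the rank-then-Pearson oracle", {
  set.seed(55)
  for (i in 1:5) {
    x <- sample(1:4, 10, replace = TRUE)  # heavy ties
    y <- sample(1:3, 10, replace = TRUE)
    got <- spearman_screen(data.frame(x = x), y)$rho
    oracle <- cor(rank(x), rank(y), method = "pearson")
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("fold sizes differ by at most one", {
  vs <- test_valueset()
  for (n in c(100, 103)) {
    coh <- generate_cohort(n, seed = 56)
    cvr <- kfold_cv(coh, "ols", 1, vs, k = 10, seed = 1)
    sizes <- tabulate(cvr$fold_of, 10)
    if (n == 100) expect_true(all(sizes == 10))
    else expect_equal(sort(sizes, decreasing = TRUE),
                      c(11, 11, 11, rep(10, 7)))
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("cross-validated error is more pessimistic than in-sample error", {
  vs <- test_valueset()
  coh <- generate_cohort(2000, seed = 57)
  prep <- prepare_mapping_data(coh, vs)
  X <- design_matrix(prep, 2)
  y <- prep$utility[attr(X, "rows")]
  fit <- fit_ols(X, y)
  in_mae <- mean(abs(predict(fit, X) - y))
  hits <- 0
  for (s in 1:10) {
    cv_mae <- kfold_cv(coh, "ols", 2, vs, k = 10, seed = s)$summary$mae
    hits <- hits + (cv_mae >= in_mae)
  }
  expect_gte(hits, 9)
})

test_that("leave-one-out cross-validation matches the brute-force oracle", {
  vs <- test_valueset()
  coh <- generate_cohort(20, seed = 58)
  prep <- prepare_mapping_data(coh, vs)
  X <- design_matrix(prep, 1)
  y <- prep$utility[attr(X, "rows")]
  n <- length(y)
  cvr <- kfold_cv(coh, "ols", 1, vs, k = n, seed = 2, aggregate = "pooled")
  # brute-force LOO: refit lm dropping each observation in turn
  loo <- vapply(seq_len(n), function(i) {
    b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
    drop(X[i, ] %*% b)
  }, numeric(1))
  expect_equal(unname(cvr$predictions), loo, tolerance = 1e-12)
  expect_equal(cvr$summary$mae, mean(abs(loo - y)), tolerance = 1e-12)
  expect_equal(cvr$summary$rmse, sqrt(mean((loo - y)^2)), tolerance = 1e-12)
})

test_that("comprehensive ranking uses mean rank with MAE tiebreak", {
  # dominance: A beats B on all four metrics
  tab <- data.frame(model = c("A", "B"),
                    mae = c(0.05, 0.06), rmse = c(0.06, 0.07),
                    adj_r2 = c(0.5, 0.4), ccc = c(0.7, 0.6))
  rk <- rank_models(tab, exclude = character(0))
  expect_equal(rk$model[1], "A")

  # the published combination-6 pattern: response mapping best on
  # MAE/RMSE/adj R2, Beta best only on CCC -> response mapping first
  tab <- data.frame(model = c("mlogit", "beta"),
                    mae = c(0.0501, 0.0525), rmse = c(0.0630, 0.0670),
                    adj_r2 = c(0.5745, 0.5188), ccc = c(0.7271, 0.7318))
  rk <- rank_models(tab, exclude = character(0))
  expect_equal(rk$model[1], "mlogit")
  # but mlogit is excluded from the recommendation by default
  rk2 <- rank_models(tab)
  expect_equal(attr(rk2, "recommended"), "beta")

  # identical metrics: tied mean rank, input order kept, flagged
  tab <- data.frame(model = c("A", "B"),
                    mae = 0.05, rmse = 0.06, adj_r2 = 0.5, ccc = 0.7)
  rk <- rank_models(tab, exclude = character(0))
  expect_equal(rk$model, c("A", "B"))
  expect_true(all(rk$tied))
})

test_that("stepwise selection recovers strong item effects", {
  coh <- generate_cohort(2000, seed = 59)
  prep <- prepare_mapping_data(coh, NULL)
  items <- prep[pedsql_items()] / 100
  set.seed(60)
  y <- 0.9 + 0.15 * items$pf2 + 0.12 * items$sf3 + rnorm(2000, 0, 0.05)
  sel <- stepwise_select(items, y)
  expect_true(all(c("pf2", "sf3") %in% sel$selected))
  expect_equal(sel$trace$action[1], "add")
})

test_that("stepwise selection stays near-empty under the null", {
  coh <- generate_cohort(300, seed = 61)
  prep <- prepare_mapping_data(coh, NULL)
  items <- prep[pedsql_items()] / 100
  false_in <- integer(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    y0 <- rnorm(300)  # independent of every item
    sel <- suppressWarnings(stepwise_select(items, y0))
    false_in[s] <- length(sel$selected)
  }
  # with 23 candidates at alpha = 0.05 the minimum p-value enters often,
  # but selections under the null stay very small
  expect_lte(mean(false_in), 2)
  expect_lte(max(false_in), 5)
})

test_that("single significant candidate is selected", {
  set.seed(62)
  x <- data.frame(a = rnorm(100))
  y <- 0.5 + 0.8 * x$a + rnorm(100, 0, 0.3)
  sel <- stepwise_select(x, y)
  expect_equal(sel$selected, "a")
})
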