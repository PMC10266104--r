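# Goodness-of-fit metrics, k-fold cross-validation, Spearman screening,
# stepwise item selection, and the comprehensive model ranking.

#' Goodness-of-fit metrics for predicted utilities
#'
#' Computes the prediction summary (mean, SD, min, max of the predicted
#' values) and the four comparison metrics used to rank mapping models:
#' mean absolute error, root mean squared error, adjusted R-squared, and
#' Lin's concordance correlation coefficient. The CCC uses n-denominator
#' (population) moments: `ccc = 2 cov(y, yhat) / (var(y) + var(yhat) +
#' (mean(y) - mean(yhat))^2)`.
#'
#' @param y Observed utilities.
#' @param yhat Predicted utilities.
#' @param p Number of regressors (excluding the intercept), for the
#'   adjusted R-squared.
#' @return An object of class `metrics_report` (a list with `mean_p`,
#'   `sd_p`, `min_p`, `max_p`, `mae`, `rmse`, `adj_r2`, `ccc`, `n`, `p`).
#' @export
#' @examples
#' compute_metrics(c(.8, .9, 1), c(.82, .88, .97), p = 1)
compute_metrics <- function(y, yhat, p) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  n <- length(y)
  if (n <= p + 1) stop("need n > p + 1 observations for adjusted R-squared")
  err <- yhat - y
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("observed y has zero variance; adj R2 and CCC undefined")
  r2 <- 1 - sum(err^2) / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  my <- mean(y); mp <- mean(yhat)
  vy <- mean((y - my)^2); vp <- mean((yhat - mp)^2)
  cyp <- mean((y - my) * (yhat - mp))
  ccc <- 2 * cyp / (vy + vp + (my - mp)^2)
  structure(list(mean_p = mean(yhat), sd_p = sd(yhat),
                 min_p = min(yhat), max_p = max(yhat),
                 mae = mae, rmse = rmse, adj_r2 = adj_r2, ccc = ccc,
                 n = n, p = p),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d, p = %d | mean P %.4f (SD %.4f), range [%.4f, %.4f]\n",
    x$n, x$p, x$mean_p, x$sd_p, x$min_p, x$max_p))
  cat(sprintf("MAE %.4f  RMSE %.4f  adj R2 %.4f  CCC %.4f\n",
              x$mae, x$rmse, x$adj_r2, x$ccc))
  invisible(x)
}

#' Mapping model families
#'
#' @return The six estimator family names understood by [kfold_cv()] and
#'   [run_tournament()].
#' @export
mapping_families <- function() {
  c("ols", "glm_logit", "mm", "tobit", "beta", "mlogit")
}

# Dispatch one family on prepared training data.
fit_family <- function(family, X, y, states = NULL) {
  switch(family,
         ols = fit_ols(X, y),
         glm_logit = fit_glm_logit(X, y),
         mm = fit_mm(X, y),
         tobit = fit_tobit(X, y),
         beta = fit_beta(X, y),
         mlogit = fit_mlogit(X, states),
         stop("unknown family: ", family))
}

predict_family <- function(fit, X, valueset = NULL) {
  if (inherits(fit, "response_fit")) predict(fit, X, valueset = valueset)
  else predict(fit, X)
}

#' k-fold cross-validation of one mapping model
#'
#' Splits the sample into `k` folds of sizes differing by at most one
#' (after a seeded shuffle), holds each fold out once, fits the model on
#' the remaining folds, predicts the held-out utilities, and computes
#' [compute_metrics()] per fold. With `aggregate = "fold"` (default) the
#' four metrics are averaged across folds, the reported `sd_p` is the SD
#' of fold mean predictions, and the adjusted R-squared uses each fold's
#' own n. With `aggregate = "pooled"` the metrics are computed once on the
#' pooled held-out predictions (required when folds are too small for
#' fold-level metrics, e.g. leave-one-out).
#'
#' @param data Respondent data frame with CHU-9D levels.
#' @param family One of [mapping_families()].
#' @param combination Variable combination 1--6.
#' @param valueset A [chu9d_valueset()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param aggregate `"fold"` or `"pooled"` (see above).
#' @return A list of class `cv_report`: `summary` (a `metrics_report`),
#'   `folds` (per-fold reports, for `"fold"` aggregation), `predictions`
#'   (held-out predictions aligned to the modelled rows), `rows` (modelled
#'   row indices), `skipped` (folds skipped for lost design variation).
#' @export
kfold_cv <- function(data, family, combination, valueset, k = 10,
                     seed = NULL, aggregate = c("fold", "pooled")) {
  aggregate <- match.arg(aggregate)
  family <- match.arg(family, mapping_families())
  prep <- prepare_mapping_data(data, valueset)
  if (is.null(prep$utility))
    stop("data must contain chu9d_1..chu9d_9 so observed utilities exist")
  X <- design_matrix(prep, combination)
  rows <- attr(X, "rows")
  y <- prep$utility[rows]
  states <- if (family == "mlogit")
    as.matrix(prep[rows, paste0("chu9d_", 1:9)]) else NULL
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must lie between 2 and n")
  if (aggregate == "fold" && n < 2 * k)
    stop("need n >= 2k observations for per-fold metrics; ",
         "use aggregate = \"pooled\" for small folds")
  p <- ncol(X) - 1L
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(n)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  fold_of <- integer(n)
  fold_of[idx] <- rep(seq_len(k), sizes)

  preds <- rep(NA_real_, n)
  fold_reports <- vector("list", k)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    test <- fold_of == f
    fit <- tryCatch(
      fit_family(family, X[!test, , drop = FALSE], y[!test],
                 states = states[!test, , drop = FALSE]),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("fold %d skipped: %s", f, conditionMessage(fit)),
              call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    yhat <- predict_family(fit, X[test, , drop = FALSE], valueset)
    preds[test] <- yhat
    if (aggregate == "fold")
      fold_reports[[f]] <- compute_metrics(y[test], yhat, p = p)
  }
  used <- setdiff(seq_len(k), skipped)
  if (!length(used)) stop("all folds were skipped")
  if (aggregate == "fold") {
    reps <- fold_reports[used]
    avg <- function(field) mean(vapply(reps, `[[`, numeric(1), field))
    summary <- structure(list(
      mean_p = avg("mean_p"),
      sd_p = sd(vapply(reps, `[[`, numeric(1), "mean_p")),
      min_p = min(vapply(reps, `[[`, numeric(1), "min_p")),
      max_p = max(vapply(reps, `[[`, numeric(1), "max_p")),
      mae = avg("mae"), rmse = avg("rmse"),
      adj_r2 = avg("adj_r2"), ccc = avg("ccc"),
      n = n, p = p), class = "metrics_report")
  } else {
    ok <- !is.na(preds)
    summary <- compute_metrics(y[ok], preds[ok], p = p)
    fold_reports <- NULL
  }
  structure(list(summary = summary, folds = fold_reports,
                 predictions = preds, y = y, rows = rows,
                 fold_of = fold_of, skipped = skipped,
                 family = family, combination = combination, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: family %s, combination %d%s\n", x$k, x$family,
              x$combination,
              if (length(x$skipped))
                paste0(" (skipped folds: ", paste(x$skipped, collapse = ","), ")")
              else ""))
  print(x$summary)
  invisible(x)
}

#' Comprehensive ranking of mapping models
#'
#' Ranks each model on the four metrics (MAE and RMSE ascending, adjusted
#' R-squared and CCC descending; ties get average ranks), averages the
#' four ranks into the comprehensive score, and orders models by that
#' score with MAE as the tiebreak (MAE is preferred over RMSE when models
#' disagree, being less sensitive to outliers). Models with identical
#' metrics keep their input order and are flagged as tied.
#'
#' @param metrics A data frame with a `model` column and columns `mae`,
#'   `rmse`, `adj_r2`, `ccc` (one row per model).
#' @param exclude Model names excluded from the recommendation (but kept
#'   in the table). Defaults to `"mlogit"`: response mapping is reported
#'   but not recommended, because sparse level coverage can bias its fits.
#' @return A `rank_table` data frame sorted by final rank, with per-metric
#'   ranks, `mean_rank`, `final_rank`, and `tied`; the recommended model
#'   name is in `attr(, "recommended")`.
#' @export
rank_models <- function(metrics, exclude = "mlogit") {
  metrics <- as.data.frame(metrics)
  need <- c("model", "mae", "rmse", "adj_r2", "ccc")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics lacks column(s): ", paste(miss, collapse = ", "))
  m <- nrow(metrics)
  if (m < 2) stop("need at least two models to rank")
  rk <- data.frame(
    rank_mae = rank(metrics$mae, ties.method = "average"),
    rank_rmse = rank(metrics$rmse, ties.method = "average"),
    rank_adj_r2 = rank(-metrics$adj_r2, ties.method = "average"),
    rank_ccc = rank(-metrics$ccc, ties.method = "average"))
  mean_rank <- rowMeans(rk)
  ord <- order(mean_rank, metrics$mae, seq_len(m))
  out <- cbind(metrics, rk, mean_rank = mean_rank)[ord, ]
  out$final_rank <- seq_len(m)
  key <- paste(out$mean_rank, out$mae)
  out$tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  rownames(out) <- NULL
  rec <- out$model[!(out$model %in% exclude)]
  attr(out, "recommended") <- if (length(rec)) rec[1] else NA_character_
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Spearman correlation screen with strength bands
#'
#' Screens candidate regressors for conceptual overlap with the utility
#' score using Spearman rank correlations, labelled with the conventional
#' strength bands: very weak (|rho| < 0.20), weak (0.20--0.39), moderate
#' (0.40--0.59), strong (0.60--0.79), very strong (0.80--1.00).
#'
#' @param x Data frame (or matrix) of candidate variables.
#' @param utility Observed utilities.
#' @return Data frame with `variable`, `rho`, `band` (`NA` rho and band
#'   `"undefined"` for constant variables).
#' @export
spearman_screen <- function(x, utility) {
  x <- as.data.frame(x)
  if (length(utility) < 3) stop("need at least 3 observations")
  band_of <- function(r) {
    if (is.na(r)) return("undefined")
    a <- abs(r)
    if (a < 0.20) "very weak"
    else if (a < 0.40) "weak"
    else if (a < 0.60) "moderate"
    else if (a < 0.80) "strong"
    else "very strong"
  }
  rho <- vapply(x, function(v) {
    ok <- !is.na(v) & !is.na(utility)
    if (length(unique(v[ok])) < 2 || length(unique(utility[ok])) < 2)
      return(NA_real_)
    cor(v[ok], utility[ok], method = "spearman")
  }, numeric(1))
  data.frame(variable = names(x), rho = unname(rho),
             band = vapply(rho, band_of, character(1)),
             row.names = NULL)
}

#' Stepwise selection of PedsQL item regressors
#'
#' Forward-backward stepwise OLS on the candidate item scores with
#' p-to-enter = p-to-remove = `alpha` (partial t-tests): at each step the
#' candidate with the smallest entry p-value below `alpha` is added, then
#' any included item whose p-value rises above `alpha` is removed, until
#' the selection is stable. Deterministic given the data; ties break by
#' column order.
#'
#' @param x Data frame of candidate regressors (e.g. the 23 item scores).
#' @param y Observed utilities.
#' @param alpha Significance level for entry and removal (default 0.05).
#' @param max_steps Safety cap on add/remove steps.
#' @return A list of class `stepwise_selection`: `selected` (in order of
#'   entry) and `trace` (a data frame of step, action, variable, p-value).
#' @export
stepwise_select <- function(x, y, alpha = 0.05, max_steps = 200) {
  x <- as.data.frame(x)
  n <- length(y)
  if (n <= 30) stop("need n > 30 observations for stepwise selection")
  pval_of <- function(vars, v) {
    fit <- lm(y ~ ., data = x[c(vars, v)])
    cf <- summary(fit)$coefficients
    if (!v %in% rownames(cf)) return(NA_real_)  # aliased
    cf[v, 4]
  }
  selected <- character(0)
  trace <- list()
  step_i <- 0L
  repeat {
    changed <- FALSE
    # forward
    cands <- setdiff(names(x), selected)
    if (length(cands)) {
      pv <- vapply(cands, function(v) pval_of(selected, v), numeric(1))
      ok <- which(!is.na(pv) & pv < alpha)
      if (length(ok)) {
        best <- ok[order(pv[ok], ok)][1]
        v <- cands[best]
        selected <- c(selected, v)
        step_i <- step_i + 1L
        trace[[step_i]] <- data.frame(step = step_i, action = "add",
                                      variable = v, p_value = pv[best])
        changed <- TRUE
      }
    }
    # backward
    repeat {
      if (length(selected) == 0L) break
      fit <- lm(y ~ ., data = x[selected])
      cf <- summary(fit)$coefficients
      pv <- cf[intersect(selected, rownames(cf)), 4]
      worst <- which.max(pv)
      if (length(pv) && pv[worst] > alpha) {
        v <- names(pv)[worst]
        selected <- setdiff(selected, v)
        step_i <- step_i + 1L
        trace[[step_i]] <- data.frame(step = step_i, action = "remove",
                                      variable = v, p_value = pv[[worst]])
        changed <- TRUE
      } else break
      if (step_i >= max_steps) break
    }
    if (!changed || step_i >= max_steps) break
  }
  if (!length(selected))
    warning("no item met the significance level; empty selection",
            call. = FALSE)
  structure(list(selected = selected,
                 trace = if (length(trace)) do.call(rbind, trace)
                 else data.frame(step = integer(), action = character(),
                                 variable = character(), p_value = numeric()),
                 alpha = alpha),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("Stepwise selection (alpha = %.2f): %d item(s)\n",
              x$alpha, length(x$selected)))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full family-by-combination mapping tournament
#'
#' Fits every requested estimator family on every variable combination,
#' scores each with [compute_metrics()] (in-sample by default, or by
#' [kfold_cv()]), and ranks the families within each combination with
#' [rank_models()].
#'
#' @param data Respondent data frame with CHU-9D levels.
#' @param valueset A [chu9d_valueset()].
#' @param families Subset of [mapping_families()].
#' @param combinations Subset of 1--6.
#' @param cv Use k-fold cross-validated metrics instead of full-sample
#'   metrics.
#' @param k,seed Cross-validation folds and shuffle seed (also seeds
#'   nothing when `cv = FALSE`).
#' @param exclude Families excluded from per-combination recommendations
#'   (default `"mlogit"`).
#' @return A list of class `tournament`: `metrics` (one row per family x
#'   combination), `ranks` (per-combination `rank_table`s), and `best`
#'   (the recommended family per combination).
#' @export
run_tournament <- function(data, valueset, families = mapping_families(),
                           combinations = 1:6, cv = FALSE, k = 10,
                           seed = NULL, exclude = "mlogit") {
  families <- match.arg(families, mapping_families(), several.ok = TRUE)
  prep <- prepare_mapping_data(data, valueset)
  if (is.null(prep$utility))
    stop("data must contain chu9d_1..chu9d_9 so observed utilities exist")
  rows_list <- list()
  out <- list()
  for (combo in combinations) {
    X <- design_matrix(prep, combo)
    rows <- attr(X, "rows")
    y <- prep$utility[rows]
    states <- as.matrix(prep[rows, paste0("chu9d_", 1:9)])
    for (fam in families) {
      rep_i <- if (cv) {
        kfold_cv(data, fam, combo, valueset, k = k, seed = seed)$summary
      } else {
        fit <- fit_family(fam, X, y, states = states)
        compute_metrics(y, predict_family(fit, X, valueset),
                        p = ncol(X) - 1L)
      }
      out[[length(out) + 1L]] <- data.frame(
        combination = combo, model = fam,
        mean_p = rep_i$mean_p, sd_p = rep_i$sd_p,
        min_p = rep_i$min_p, max_p = rep_i$max_p,
        mae = rep_i$mae, rmse = rep_i$rmse,
        adj_r2 = rep_i$adj_r2, ccc = rep_i$ccc)
    }
  }
  metrics <- do.call(rbind, out)
  ranks <- lapply(split(metrics, metrics$combination), rank_models,
                  exclude = exclude)
  best <- vapply(ranks, attr, character(1), "recommended")
  structure(list(metrics = metrics, ranks = ranks, best = best,
                 cv = cv, k = if (cv) k else NA_integer_),
            class = "tournament")
}

#' @export
print.tournament <- function(x, ...) {
  cat(sprintf("Mapping tournament (%s metrics)\n",
              if (x$cv) sprintf("%d-fold CV", x$k) else "full-sample"))
  for (nm in names(x$ranks)) {
    cat(sprintf("Combination %s (recommended: %s)\n", nm, x$best[[nm]]))
    tab <- x$ranks[[nm]]
    print(cbind(model = tab$model,
                round(tab[c("mae", "rmse", "adj_r2", "ccc", "mean_rank")], 4)))
  }
  invisible(x)
}
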