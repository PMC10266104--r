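# Response mapping: one multinomial logit per CHU-9D dimension predicting
# level membership from the combination regressors, aggregated to a
# predicted utility by the expected-utility method.

#' Fit the multinomial-logit response-mapping model
#'
#' Fits nine independent multinomial logistic regressions, one per CHU-9D
#' dimension, each predicting the probability of the dimension's levels
#' from the design columns. The reference level is the lowest level
#' observed in the training data; levels never observed receive
#' probability zero (a coverage warning is emitted, since sparse level
#' coverage is the known weakness of response mapping). A dimension with a
#' single observed level is kept as a degenerate point-mass model.
#'
#' @param X Design matrix including the intercept (see [design_matrix()]).
#' @param states n x 9 matrix or data frame of CHU-9D levels
#'   (`chu9d_1`...`chu9d_9` or dimension-named columns).
#' @param maxit,reltol Optimiser control passed to [nnet::multinom()].
#' @return An object of class `response_fit`: per dimension, the observed
#'   levels and the fitted [nnet::multinom()] model (or the degenerate
#'   level).
#' @export
fit_mlogit <- function(X, states, maxit = 1000, reltol = 1e-14) {
  X <- as.matrix(X)
  dims <- chu9d_dimensions()
  states <- as.data.frame(states)
  std <- paste0("chu9d_", 1:9)
  if (all(std %in% names(states))) states <- states[std]
  else if (all(dims %in% names(states))) states <- states[dims]
  else if (ncol(states) != 9L) stop("states must have 9 dimension columns")
  S <- as.matrix(states)
  if (nrow(S) != nrow(X)) stop("states and X must have the same rows")
  xn <- setdiff(colnames(X), "(Intercept)")
  df <- as.data.frame(X[, xn, drop = FALSE])
  models <- vector("list", 9L)
  for (d in 1:9) {
    lev <- S[, d]
    obs <- sort(unique(lev))
    if (length(obs) < 5L)
      warning(sprintf(
        "dimension '%s': level(s) %s never observed; they receive probability 0",
        dims[d], paste(setdiff(1:5, obs), collapse = ", ")), call. = FALSE)
    if (length(obs) == 1L) {
      warning(sprintf("dimension '%s' is degenerate at level %d", dims[d], obs),
              call. = FALSE)
      models[[d]] <- list(type = "degenerate", dimension = dims[d],
                          observed_levels = obs, reference_level = obs)
      next
    }
    f <- factor(lev, levels = obs)
    m <- nnet::multinom(f ~ ., data = cbind(f = f, df), trace = FALSE,
                        maxit = maxit, reltol = reltol, MaxNWts = 10000)
    cf <- coef(m)
    if (max(abs(cf)) > 100)
      stop(sprintf(
        "possible perfect separation in dimension '%s' (|coef| up to %.1f)",
        dims[d], max(abs(cf))))
    models[[d]] <- list(type = "multinom", dimension = dims[d],
                        observed_levels = obs, reference_level = obs[1],
                        model = m)
  }
  structure(list(models = models, xnames = xn, dimensions = dims),
            class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  cat("CHU-9D response-mapping fit (9 multinomial logits)\n")
  for (m in x$models) {
    cat(sprintf("  %-14s levels observed: %s%s\n", m$dimension,
                paste(m$observed_levels, collapse = ","),
                if (m$type == "degenerate") " [degenerate]" else ""))
  }
  invisible(x)
}

#' Predicted level probabilities per dimension
#'
#' @param fit A `response_fit`.
#' @param X Design matrix with the columns the model was fitted on.
#' @return A list of nine n x 5 probability matrices (columns = levels
#'   1--5; unobserved levels carry probability 0).
#' @export
predict_level_probs <- function(fit, X) {
  X <- as.matrix(X)
  xn <- setdiff(colnames(X), "(Intercept)")
  if (!identical(xn, fit$xnames))
    stop("design columns do not match the fit: expected ",
         paste(fit$xnames, collapse = ", "))
  newdf <- as.data.frame(X[, xn, drop = FALSE])
  n <- nrow(X)
  lapply(fit$models, function(m) {
    P <- matrix(0, n, 5, dimnames = list(NULL, paste0("level", 1:5)))
    if (m$type == "degenerate") {
      P[, m$observed_levels] <- 1
    } else {
      pr <- predict(m$model, newdata = newdf, type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two observed levels
      P[, m$observed_levels] <- as.matrix(pr)
    }
    P
  })
}

#' Expected utility from predicted level probabilities
#'
#' The expected-utility aggregation of response mapping: with an additive
#' tariff, `E[U] = 1 - sum_d sum_k P_d(k) * decrement(d, k)`, computed
#' dimension by dimension.
#'
#' @param probs A list of nine n x 5 level-probability matrices, e.g. from
#'   [predict_level_probs()].
#' @param valueset A [chu9d_valueset()].
#' @return Numeric vector of expected utilities.
#' @export
expected_utility <- function(probs, valueset) {
  if (!inherits(valueset, "chu9d_valueset"))
    stop("valueset must be a chu9d_valueset")
  if (length(probs) != 9L) stop("probs must be a list of 9 matrices")
  dec <- valueset$decrements
  n <- nrow(probs[[1]])
  u <- rep(1, n)
  for (d in 1:9) {
    P <- probs[[d]]
    if (any(abs(rowSums(P) - 1) > 1e-9))
      stop("internal error: level probabilities for dimension ", d,
           " do not sum to 1")
    u <- u - drop(P %*% dec[d, ])
  }
  u
}

#' Predict utilities from a response-mapping fit
#'
#' @param object A `response_fit`.
#' @param X Design matrix with the columns the model was fitted on.
#' @param valueset A [chu9d_valueset()] used for the expected-utility
#'   aggregation.
#' @param type `"utility"` (default) or `"probs"` for the per-dimension
#'   level probabilities.
#' @param ... Unused.
#' @return Numeric vector of predicted utilities, or a list of probability
#'   matrices.
#' @export
predict.response_fit <- function(object, X, valueset,
                                 type = c("utility", "probs"), ...) {
  type <- match.arg(type)
  probs <- predict_level_probs(object, X)
  if (type == "probs") return(probs)
  expected_utility(probs, valueset)
}
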