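# Direct-mapping estimators: OLS, GLM (gaussian errors, logit link),
# robust MM, upper-censored Tobit (hand-written MLE), Beta regression
# (hand-written MLE). All take a design matrix that already contains the
# intercept column (see design_matrix()) and the observed utilities y.

new_map_fit <- function(family, coefficients, se, n,
                        sigma = NA_real_, phi = NA_real_,
                        loglik = NA_real_, converged = TRUE,
                        upper = NA_real_, lower = NA_real_,
                        boundary_adjusted = FALSE, grad_max = NA_real_) {
  structure(list(family = family, coefficients = coefficients, se = se,
                 sigma = sigma, phi = phi, loglik = loglik,
                 converged = converged, upper = upper, lower = lower,
                 boundary_adjusted = boundary_adjusted,
                 grad_max = grad_max, n = n,
                 xnames = names(coefficients)),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("Mapping fit [%s], n = %d%s\n", x$family, x$n,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  if (!is.na(x$sigma)) cat(sprintf("sigma = %.4f\n", x$sigma))
  if (!is.na(x$phi)) cat(sprintf("phi = %.4f\n", x$phi))
  invisible(x)
}

check_design <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete (no NA)")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Boundary adjustment for unit-interval outcomes
#'
#' Shrinks utilities that sit exactly on 0 or 1 into the open interval
#' using the conventional compression `(y * (n - 1) + 0.5) / n`, so that
#' logit-mean models (GLM-logit, Beta) are estimable. Applied by default
#' inside [fit_glm_logit()] and [fit_beta()].
#'
#' @param y Numeric vector in `[0, 1]`.
#' @param n Sample size used for the compression (default `length(y)`).
#' @return Adjusted vector strictly inside (0, 1) for n > 1.
#' @export
adjust_boundary <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1] before adjustment")
  (y * (n - 1) + 0.5) / n
}

# --- OLS -------------------------------------------------------------------

#' Ordinary least squares mapping fit
#'
#' @param X Design matrix including the intercept column (see
#'   [design_matrix()]).
#' @param y Observed utilities.
#' @return A `map_fit` with coefficients, classical standard errors,
#'   residual scale `sigma`, and Gaussian log-likelihood.
#' @export
fit_ols <- function(X, y) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  q <- qr(X)
  beta <- qr.coef(q, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(q))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- names(beta) <- colnames(X)
  ll <- sum(dnorm(res, 0, sqrt(rss / n), log = TRUE))
  new_map_fit("ols", beta, se, n, sigma = sqrt(sigma2), loglik = ll)
}

# --- GLM, gaussian errors with logit link ---------------------------------

#' GLM mapping fit with a logit link
#'
#' Fits `E[y] = plogis(X beta)` with Gaussian working errors by iteratively
#' reweighted least squares (`stats::glm.fit` with
#' `gaussian(link = "logit")`). Predictions are inverse-logit and therefore
#' lie strictly inside (0, 1).
#'
#' @inheritParams fit_ols
#' @param adjust Apply [adjust_boundary()] first (the data contain exact
#'   1.0 utilities, which the logit mean cannot reach). Default `TRUE`.
#' @param maxit IRLS iteration cap.
#' @return A `map_fit`.
#' @export
fit_glm_logit <- function(X, y, adjust = TRUE, maxit = 100) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  y2 <- if (adjust) adjust_boundary(y) else y
  if (any(y2 <= 0 | y2 > 1))
    stop("y must lie in (0, 1] after the boundary adjustment")
  mustart <- pmin(pmax(y2, 1e-4), 1 - 1e-4)
  fit <- glm.fit(X, y2, family = stats::gaussian(link = "logit"),
                 mustart = mustart,
                 control = glm.control(maxit = maxit, epsilon = 1e-10))
  if (!fit$converged)
    stop(sprintf(
      "GLM (logit link) did not converge after %d IRLS iterations (deviance %.6g)",
      fit$iter, fit$deviance))
  beta <- coef(fit)
  dispersion <- sum(fit$residuals[fit$weights > 0]^2 *
                      fit$weights[fit$weights > 0]) / fit$df.residual
  covmat <- chol2inv(fit$qr$qr[1:p, 1:p, drop = FALSE]) * dispersion
  se <- sqrt(diag(covmat))
  names(se) <- names(beta)
  res <- y2 - fit$fitted.values
  ll <- sum(dnorm(res, 0, sqrt(mean(res^2)), log = TRUE))
  new_map_fit("glm_logit", beta, se, n, sigma = sqrt(dispersion),
              loglik = ll, converged = fit$converged,
              boundary_adjusted = adjust)
}

# A few damped Newton steps to drive the score to machine precision after
# BFGS (whose stopping rule is on the objective, not the gradient).
newton_polish <- function(par, negll, neggr, max_iter = 25, gtol = 1e-10) {
  g0 <- max(abs(neggr(par)))
  for (i in seq_len(max_iter)) {
    if (g0 < gtol) break
    H <- optimHess(par, negll, neggr)
    step <- tryCatch(solve(H, neggr(par)), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # near the optimum the objective change sits below summation noise, so
    # accept on gradient-norm decrease instead of function decrease
    lambda <- 1
    accepted <- FALSE
    while (lambda >= 1e-6) {
      cand <- par - lambda * step
      gc <- max(abs(neggr(cand)))
      if (is.finite(gc) && gc < g0) {
        par <- cand; g0 <- gc; accepted <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!accepted) break
  }
  par
}

# --- Tobit -----------------------------------------------------------------

#' Upper-censored Tobit mapping fit (maximum likelihood)
#'
#' Fits the latent-Gaussian model `y* = X beta + e`, `e ~ N(0, sigma^2)`,
#' observing `y = min(y*, upper)` (and `max(y*, lower)` if a lower bound is
#' given). Utilities pile up at the 1.0 ceiling, which the censored
#' likelihood accounts for: uncensored observations contribute the normal
#' density, ceiling observations the upper-tail probability. Estimated by
#' BFGS on the exact log-likelihood with analytic gradient, started at the
#' OLS solution.
#'
#' @inheritParams fit_ols
#' @param upper Upper censoring bound (default 1, the full-health utility).
#'   `Inf` disables upper censoring, in which case the fit reduces to OLS.
#' @param lower Optional lower censoring bound (default `-Inf`, disabled:
#'   observed utility minima sit well above any floor).
#' @param maxit,reltol BFGS control passed to [stats::optim()].
#' @return A `map_fit` with latent-scale coefficients, `sigma`, standard
#'   errors from the inverse observed information, the maximized
#'   log-likelihood, and `grad_max`, the largest absolute score component
#'   at the optimum (a convergence self-check).
#' @export
fit_tobit <- function(X, y, upper = 1, lower = -Inf,
                      maxit = 500, reltol = 1e-12) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  cu <- is.finite(upper) & y >= upper - 1e-12
  cl <- is.finite(lower) & y <= lower + 1e-12
  if (all(cu | cl)) stop("all observations are censored; Tobit is not identified")
  obs <- !(cu | cl)
  # start at OLS
  ols <- qr.coef(qr(X), y)
  s0 <- sd(y - drop(X %*% ols))
  if (!is.finite(s0) || s0 <= 0) s0 <- 0.05
  par0 <- c(unname(ols), log(s0))

  negll <- function(par) {
    beta <- par[1:p]; s <- exp(par[p + 1])
    mu <- drop(X %*% beta)
    ll <- 0
    if (any(obs)) ll <- ll + sum(dnorm(y[obs], mu[obs], s, log = TRUE))
    if (any(cu)) ll <- ll + sum(pnorm((upper - mu[cu]) / s,
                                      lower.tail = FALSE, log.p = TRUE))
    if (any(cl)) ll <- ll + sum(pnorm((lower - mu[cl]) / s, log.p = TRUE))
    -ll
  }
  neggr <- function(par) {
    beta <- par[1:p]; s <- exp(par[p + 1])
    mu <- drop(X %*% beta)
    dmu <- numeric(n)   # d ll / d mu
    dls <- 0            # d ll / d log sigma
    if (any(obs)) {
      r <- (y[obs] - mu[obs]) / s
      dmu[obs] <- r / s
      dls <- dls + sum(r^2 - 1)
    }
    if (any(cu)) {
      z <- (upper - mu[cu]) / s
      lam <- exp(dnorm(z, log = TRUE) -
                   pnorm(z, lower.tail = FALSE, log.p = TRUE))
      dmu[cu] <- lam / s
      dls <- dls + sum(z * lam)
    }
    if (any(cl)) {
      z <- (lower - mu[cl]) / s
      lam <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
      dmu[cl] <- -lam / s
      dls <- dls - sum(z * lam)
    }
    -c(drop(crossprod(X, dmu)), dls)
  }
  opt <- optim(par0, negll, neggr, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  opt$par <- newton_polish(opt$par, negll, neggr)
  s <- exp(opt$par[p + 1])
  if (s < 1e-6) stop("Tobit scale collapsed toward zero; model degenerate")
  g <- neggr(opt$par)
  H <- optimHess(opt$par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  beta <- opt$par[1:p]
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(V)[1:p], 0))
  names(se) <- colnames(X)
  new_map_fit("tobit", beta, se, n, sigma = s, loglik = -opt$value,
              converged = opt$convergence == 0, upper = upper,
              lower = lower, grad_max = max(abs(g)))
}

# --- Beta regression -------------------------------------------------------

#' Beta-regression mapping fit (maximum likelihood)
#'
#' Models the (boundary-adjusted) utility as Beta-distributed with mean
#' `mu = plogis(X beta)` and precision `phi` (shape1 = mu*phi, shape2 =
#' (1-mu)*phi), the standard parameterisation for unit-interval outcomes
#' with heteroscedastic, skewed noise. Estimated by BFGS on the exact
#' log-likelihood with analytic gradient; starting values come from OLS on
#' the logit of the adjusted outcome and a method-of-moments precision.
#'
#' @inheritParams fit_glm_logit
#' @param maxit,reltol BFGS control passed to [stats::optim()].
#' @return A `map_fit` with coefficients on the logit-mean scale, precision
#'   `phi`, standard errors, log-likelihood, and `grad_max` (largest
#'   absolute score component at the optimum).
#' @export
fit_beta <- function(X, y, adjust = TRUE, maxit = 500, reltol = 1e-12) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1] before adjustment")
  y2 <- if (adjust) adjust_boundary(y) else y
  if (any(y2 <= 0 | y2 >= 1))
    stop("y must lie strictly inside (0, 1) after the boundary adjustment")
  ly <- qlogis(y2)
  beta0 <- qr.coef(qr(X), ly)
  mu0 <- plogis(drop(X %*% beta0))
  s2 <- var(y2 - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 2)
  par0 <- c(unname(beta0), log(phi0))

  logy <- log(y2); log1y <- log1p(-y2)
  negll <- function(par) {
    eta <- drop(X %*% par[1:p]); phi <- exp(par[p + 1])
    mu <- plogis(eta)
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * logy + ((1 - mu) * phi - 1) * log1y)
  }
  neggr <- function(par) {
    eta <- drop(X %*% par[1:p]); phi <- exp(par[p + 1])
    mu <- plogis(eta)
    ystar <- logy - log1y
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    deta <- phi * mu * (1 - mu) * (ystar - mustar)
    dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                  (1 - mu) * digamma((1 - mu) * phi) +
                  mu * logy + (1 - mu) * log1y)
    -c(drop(crossprod(X, deta)), dphi * phi)
  }
  opt <- optim(par0, negll, neggr, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0)
    stop("Beta regression did not converge (optim code ", opt$convergence, ")")
  opt$par <- newton_polish(opt$par, negll, neggr)
  phi <- exp(opt$par[p + 1])
  g <- neggr(opt$par)
  H <- optimHess(opt$par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  beta <- opt$par[1:p]
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(V)[1:p], 0))
  names(se) <- colnames(X)
  new_map_fit("beta", beta, se, n, phi = phi, loglik = -opt$value,
              converged = TRUE, boundary_adjusted = adjust,
              grad_max = max(abs(g)))
}

# --- MM robust regression --------------------------------------------------

#' Robust MM mapping fit
#'
#' High-breakdown robust regression: an S-estimate of scale followed by an
#' M-step with Tukey's bisquare at 95% Gaussian efficiency, via
#' [MASS::rlm()] with `method = "MM"`. Less sensitive than OLS to outlying
#' utilities.
#'
#' @inheritParams fit_ols
#' @param maxit Iteration cap for the M-step.
#' @return A `map_fit` with robust coefficients, standard errors, and the
#'   robust scale estimate `sigma`.
#' @export
fit_mm <- function(X, y, maxit = 200) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  if (n <= 2 * p) stop("need n > 2p observations for the MM estimator")
  # degenerate exact fit (e.g. constant y): the S-scale is 0; return the
  # exact least-squares solution, which every robust fit agrees with
  ols_beta <- qr.coef(qr(X), y)
  res0 <- y - drop(X %*% ols_beta)
  if (max(abs(res0)) < 1e-10) {
    se <- rep(0, p); names(se) <- names(ols_beta) <- colnames(X)
    return(new_map_fit("mm", ols_beta, se, n, sigma = 0))
  }
  fit <- MASS::rlm(x = X, y = y, method = "MM", maxit = maxit)
  if (!fit$converged)
    stop("MM estimator did not converge after ", maxit, " iterations")
  beta <- coef(fit)
  se <- summary(fit, method = "XtX")$coefficients[, "Std. Error"]
  names(se) <- names(beta) <- colnames(X)
  new_map_fit("mm", beta, se, n, sigma = fit$s,
              converged = fit$converged)
}

# --- Prediction ------------------------------------------------------------

#' Predict utilities from a direct-mapping fit
#'
#' Applies each family's published prediction rule: OLS and MM return the
#' unclipped linear predictor (they can exceed 1, the documented behaviour
#' of linear direct mapping); GLM-logit and Beta return the inverse-logit
#' of the linear predictor (always inside (0, 1)); Tobit returns the
#' linear predictor capped at the censoring bound(s), i.e. predictions at
#' or above 1 map to exactly 1.
#'
#' @param object A `map_fit`.
#' @param X Design matrix with the same columns the model was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predicted utilities.
#' @export
predict.map_fit <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!identical(colnames(X), object$xnames))
    stop("design columns do not match the fit: expected ",
         paste(object$xnames, collapse = ", "))
  eta <- drop(X %*% object$coefficients)
  switch(object$family,
         ols = , mm = eta,
         glm_logit = , beta = plogis(eta),
         tobit = {
           out <- eta
           if (is.finite(object$upper)) out <- pmin(out, object$upper)
           if (is.finite(object$lower)) out <- pmax(out, object$lower)
           out
         },
         stop("unknown family: ", object$family))
}
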