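# Seeded synthetic paired-instrument cohorts.
#
# Both instruments are driven by one latent health trait theta per subject
# (higher = healthier). Each PedsQL item and each CHU-9D dimension responds
# through a cumulative-logistic (graded-response) ordinal model: for item j
# with loading a_j and ordered thresholds tau_j1 < ... < tau_j4,
#   P(raw <= k | theta) = plogis(tau_j(k+1) + a_j * theta),
# so larger theta pushes responses toward "never a problem" (raw 0) and
# CHU-9D levels toward 1. Shared theta induces the cross-instrument
# correlation the mapping estimators rely on.

#' Default synthetic-cohort parameters
#'
#' Returns the shipped calibration of the cohort generator. Thresholds are
#' set from target marginal category probabilities per PedsQL dimension and
#' per CHU-9D dimension (scaled for the latent-trait dispersion), so that a
#' large seeded cohort has: mean age about 7.2 years concentrated on ages
#' 6--8, about 45% girls, PedsQL total score near 61, mean utility near
#' 0.88 with a ceiling mass at 1.0 and left skew, and a strong Spearman
#' correlation (about 0.6--0.7) between total score and utility.
#'
#' @return A list of class `cohort_params` with elements `item_loadings`
#'   (23), `item_thresholds` (23 x 4), `chu9d_loadings` (9),
#'   `chu9d_thresholds` (9 x 4), `pct_female`, `age_weights` (named
#'   probabilities over ages 6--17), `age_effect`, `gender_effect`, and
#'   `missing_rate`.
#' @export
default_cohort_params <- function() {
  items <- pedsql_items()
  dims <- pedsql_dimensions()
  a <- 0.5
  lat <- sqrt(1 + a^2 * 3 / pi^2)  # marginal latent scale adjustment
  # target marginal cumulative probabilities P(raw <= 0..3) per dimension
  cum <- list(PF  = c(0.15, 0.60, 0.95, 0.99),
              EF  = c(0.07, 0.40, 0.85, 0.97),
              SF  = c(0.07, 0.40, 0.85, 0.97),
              ScF = c(0.10, 0.50, 0.90, 0.98))
  item_thresholds <- matrix(NA_real_, length(items), 4,
                            dimnames = list(items, NULL))
  for (d in names(dims)) {
    item_thresholds[dims[[d]], ] <- matrix(lat * qlogis(cum[[d]]),
                                           length(dims[[d]]), 4, byrow = TRUE)
  }
  b <- 1.0
  lat9 <- sqrt(1 + b^2 * 3 / pi^2)
  chu_cum <- c(0.48, 0.75, 0.89, 0.97)  # P(level <= 1..4)
  chu9d_thresholds <- matrix(lat9 * qlogis(chu_cum), 9, 4, byrow = TRUE,
                             dimnames = list(chu9d_dimensions(), NULL))
  structure(list(
    item_loadings = stats::setNames(rep(a, length(items)), items),
    item_thresholds = item_thresholds,
    chu9d_loadings = stats::setNames(rep(b, 9), chu9d_dimensions()),
    chu9d_thresholds = chu9d_thresholds,
    pct_female = 0.4531,
    age_weights = stats::setNames(
      c(0.50, 0.22, 0.12, 0.07, 0.04, 0.02,
        0.012, 0.008, 0.004, 0.003, 0.002, 0.001), 6:17),
    age_effect = 0.05,
    gender_effect = -0.05,
    missing_rate = 0
  ), class = "cohort_params")
}

validate_cohort_params <- function(params) {
  stopifnot(is.list(params))
  need <- c("item_loadings", "item_thresholds", "chu9d_loadings",
            "chu9d_thresholds", "pct_female", "age_weights",
            "age_effect", "gender_effect", "missing_rate")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("cohort params missing: ", paste(miss, collapse = ", "))
  if (length(params$item_loadings) != 23L || any(params$item_loadings < 0))
    stop("item_loadings must be 23 nonnegative values")
  if (length(params$chu9d_loadings) != 9L || any(params$chu9d_loadings < 0))
    stop("chu9d_loadings must be 9 nonnegative values")
  if (!all(dim(params$item_thresholds) == c(23L, 4L)))
    stop("item_thresholds must be 23 x 4")
  if (!all(dim(params$chu9d_thresholds) == c(9L, 4L)))
    stop("chu9d_thresholds must be 9 x 4")
  if (any(apply(params$item_thresholds, 1, function(t) any(diff(t) <= 0))))
    stop("item thresholds must be strictly increasing")
  if (any(apply(params$chu9d_thresholds, 1, function(t) any(diff(t) <= 0))))
    stop("chu9d thresholds must be strictly increasing")
  if (abs(sum(params$age_weights) - 1) > 1e-9)
    stop("age_weights must sum to 1")
  if (params$pct_female < 0 || params$pct_female > 1)
    stop("pct_female must be in [0, 1]")
  if (params$missing_rate < 0 || params$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  invisible(params)
}

# One ordinal draw per subject: number of cumulative thresholds exceeded.
# u ~ U(0,1); P(response <= k) = plogis(tau_k + loading * theta).
ordinal_draw <- function(u, theta, loading, thresholds) {
  cum <- plogis(outer(loading * theta, thresholds, `+`))
  rowSums(u > cum)
}

#' Generate a synthetic paired-instrument cohort
#'
#' Draws `n` subjects with age, gender, the 23 raw PedsQL 4.0 item
#' responses and the 9 CHU-9D dimension levels from the latent-trait
#' graded-response model described in [default_cohort_params()]. The same
#' seed always reproduces the identical cohort.
#'
#' @param n Number of subjects (>= 2).
#' @param params A `cohort_params` list; see [default_cohort_params()].
#' @param seed Integer RNG seed; required for reproducibility.
#' @return A data frame with columns `id`, `age`, `gender` (0 = boy,
#'   1 = girl), `pf1`...`scf5` (raw responses 0--4, `NA` where deleted by
#'   `missing_rate`), and `chu9d_1`...`chu9d_9` (levels 1--5).
#' @export
#' @examples
#' coh <- generate_cohort(100, seed = 1)
#' head(coh[, 1:6])
generate_cohort <- function(n, params = default_cohort_params(), seed) {
  if (n < 2) stop("n must be at least 2")
  validate_cohort_params(params)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  ages <- as.integer(names(params$age_weights))
  age <- sample(ages, n, replace = TRUE, prob = params$age_weights)
  female <- rbinom(n, 1, params$pct_female)
  theta <- rnorm(n) + params$age_effect * (age - 7) +
    params$gender_effect * female
  items <- pedsql_items()
  out <- data.frame(id = seq_len(n), age = age, gender = female)
  for (j in items) {
    out[[j]] <- ordinal_draw(runif(n), theta, params$item_loadings[[j]],
                             params$item_thresholds[j, ])
  }
  for (d in 1:9) {
    out[[paste0("chu9d_", d)]] <-
      1L + ordinal_draw(runif(n), theta, params$chu9d_loadings[[d]],
                        params$chu9d_thresholds[d, ])
  }
  if (params$missing_rate > 0) {
    for (j in items) {
      drop <- runif(n) < params$missing_rate
      out[[j]][drop] <- NA_integer_
    }
  }
  out
}

#' Read and write respondent-level CSV files
#'
#' The respondent CSV dialect has columns `id`, `age`, `gender` (0 = boy,
#' 1 = girl), the 23 raw PedsQL items `pf1`...`scf5` (0--4, empty =
#' missing), and optionally the CHU-9D levels `chu9d_1`...`chu9d_9`
#' (1--5).
#'
#' @param path File path.
#' @param data A respondent data frame, e.g. from [generate_cohort()].
#' @return `read_respondents()` returns a data frame;
#'   `write_respondents()` returns `path` invisibly.
#' @export
read_respondents <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("age", "gender", pedsql_items()), names(dat))
  if (length(miss))
    stop("respondent file lacks column(s): ", paste(miss, collapse = ", "))
  dat
}

#' @rdname read_respondents
#' @export
write_respondents <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
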