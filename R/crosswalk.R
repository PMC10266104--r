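# The published crosswalk: packaged coefficient sets for the six variable
# combinations and their prediction rules (Beta inverse-logit for
# combinations 1-3, Tobit cap-at-1 for combinations 4-6).

#' Load the packaged published crosswalk table
#'
#' Reads the versioned YAML coefficient file shipped with the package (or
#' a user-supplied file with the same layout) and validates its structure:
#' six combinations, combinations 1--3 under the Beta inverse-logit rule
#' and 4--6 under the Tobit censoring rule, with the regressor names each
#' combination requires.
#'
#' @param path Optional path to an alternative crosswalk YAML file.
#' @return An object of class `crosswalk_table`.
#' @export
load_crosswalk <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "crosswalk.yaml", package = "chumap")
  if (!nzchar(path) || !file.exists(path))
    stop("crosswalk file not found: ", path)
  cw <- yaml::read_yaml(path)
  combos <- cw$combinations
  if (is.null(combos) || length(combos) != 6L)
    stop("corrupted crosswalk file: expected 6 combinations")
  for (i in 1:6) {
    cb <- combos[[paste0("combination", i)]]
    if (is.null(cb)) stop("corrupted crosswalk file: combination ", i, " missing")
    expected_rule <- if (i <= 3) "beta_inverse_logit" else "tobit_censor"
    if (!identical(cb$rule, expected_rule))
      stop(sprintf("corrupted crosswalk file: combination %d must use rule %s",
                   i, expected_rule))
    need <- c("intercept", crosswalk_regressors(i))
    have <- names(cb$coefficients)
    if (!setequal(need, have))
      stop(sprintf("corrupted crosswalk file: combination %d needs coefficients %s",
                   i, paste(need, collapse = ", ")))
    if (!all(vapply(cb$coefficients, is.numeric, logical(1))))
      stop("corrupted crosswalk file: non-numeric coefficient")
  }
  structure(list(version = cw$version, combinations = combos),
            class = "crosswalk_table")
}

# Regressor names (score columns on the 0-100 scale, plus female/age) each
# published combination requires.
crosswalk_regressors <- function(combination) {
  demo <- c("female", "age")
  switch(as.integer(combination),
         "total",
         c("total", demo),
         c("PF", "EF", "SF", "ScF"),
         c("PF", "EF", "SF", "ScF", demo),
         pedsql_selected_items(),
         c(pedsql_selected_items(), demo),
         stop("combination must be 1-6"))
}

#' @export
print.crosswalk_table <- function(x, ...) {
  cat("Published PedsQL 4.0 -> CHU-9D crosswalk, version", x$version, "\n")
  for (i in 1:6) {
    cb <- x$combinations[[paste0("combination", i)]]
    cat(sprintf("  combination %d [%s]: %s\n", i, cb$rule,
                paste(setdiff(names(cb$coefficients), "intercept"),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Pick the richest variable combination supported by the available data
#'
#' Prefers item-level over dimension-level over total-score crosswalks,
#' and includes demographics when both gender and age are present:
#' items + age + gender -> 6; items -> 5; dimensions + demographics -> 4;
#' dimensions -> 3; total + demographics -> 2; total -> 1. Partial
#' demographics (one of age/gender) trigger a warning and fall back to the
#' score-only combination.
#'
#' @param fields Character vector of available variable names: any of
#'   `"total"`, the dimension scores `PF`/`EF`/`SF`/`ScF`, the 13 selected
#'   item names ([pedsql_selected_items()]), `"female"` (or `"gender"`),
#'   `"age"`.
#' @return The selected combination id (integer 1--6).
#' @export
#' @examples
#' auto_select_combination(c("total", "age", "female"))  # 2
auto_select_combination <- function(fields) {
  fields <- tolower(fields)
  fields[fields == "gender"] <- "female"
  has_items <- all(pedsql_selected_items() %in% fields)
  has_dims <- all(tolower(c("PF", "EF", "SF", "ScF")) %in% fields)
  has_total <- "total" %in% fields
  has_age <- "age" %in% fields
  has_female <- "female" %in% fields
  demo <- has_age && has_female
  if (has_age != has_female) {
    lacking <- if (has_age) "gender" else "age"
    warning("demographic combinations need both age and gender; ", lacking,
            " is missing, falling back to the score-only combination",
            call. = FALSE)
  }
  if (has_items) return(if (demo) 6L else 5L)
  if (has_dims) return(if (demo) 4L else 3L)
  if (has_total) return(if (demo) 2L else 1L)
  stop("no usable PedsQL scores: need at least a total score")
}

#' Apply a published crosswalk to new PedsQL data
#'
#' Evaluates the packaged coefficient set for the chosen combination:
#' linear predictor = intercept + sum of coefficient x regressor, with
#' every PedsQL score divided by 100; combinations 1--3 then apply the
#' inverse logit (predictions strictly inside (0, 1)), combinations 4--6
#' cap the predictor at the censoring bound 1.
#'
#' Input is either a respondent data frame with the 23 raw item columns
#' (scores are computed internally) or a data frame that already carries
#' the needed 0--100 score columns (`total`, `PF`...`ScF`, item scores)
#' plus `age` and `female`/`gender` (1 = girl). Missing required
#' regressors are never imputed: selection with `combination = "auto"`
#' downgrades to the richest supported combination instead.
#'
#' @param data Data frame of new respondents.
#' @param combination `"auto"` (default) or an integer 1--6.
#' @param crosswalk A `crosswalk_table`, by default the packaged one.
#' @return A data frame with `id`, `combination`, and `predicted_utility`.
#' @export
#' @examples
#' predict_published(data.frame(total = 61.52), combination = 1)
predict_published <- function(data, combination = "auto",
                              crosswalk = load_crosswalk()) {
  data <- as.data.frame(data)
  if ("gender" %in% names(data) && !"female" %in% names(data))
    data$female <- data$gender
  if (all(pedsql_items() %in% names(data))) {
    sc <- pedsql_score(data[pedsql_items()])
    for (v in names(sc)) if (!v %in% names(data)) data[[v]] <- sc[[v]]
  }
  if (identical(combination, "auto")) {
    avail <- names(data)[!vapply(data, anyNA, logical(1))]
    combination <- auto_select_combination(avail)
  }
  combination <- as.integer(combination)
  if (!combination %in% 1:6) stop("combination must be 'auto' or 1-6")
  vars <- crosswalk_regressors(combination)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop(sprintf("combination %d needs regressor(s): %s",
                 combination, paste(miss, collapse = ", ")))
  cb <- crosswalk$combinations[[paste0("combination", combination)]]
  score_vars <- setdiff(vars, c("female", "age"))
  for (v in score_vars) {
    bad <- !is.na(data[[v]]) & (data[[v]] < 0 | data[[v]] > 100)
    if (any(bad))
      stop("score '", v, "' outside [0, 100] at row(s): ",
           paste(which(bad), collapse = ", "))
  }
  if ("female" %in% vars && !all(data$female %in% c(0, 1, NA)))
    stop("female must be coded 0/1 (1 = girl)")
  lp <- rep(cb$coefficients$intercept, nrow(data))
  for (v in vars) {
    x <- data[[v]]
    if (v %in% score_vars) x <- x / 100
    lp <- lp + cb$coefficients[[v]] * x
  }
  pred <- if (cb$rule == "beta_inverse_logit") plogis(lp) else pmin(lp, 1)
  data.frame(
    id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
    combination = combination,
    predicted_utility = pred)
}

#' Map a respondent file onto CHU-9D utilities
#'
#' Convenience wrapper: scores PedsQL, picks (or takes) a combination, and
#' returns predicted utilities for every respondent — the programmatic
#' equivalent of the `map` command-line subcommand.
#'
#' @inheritParams predict_published
#' @export
map_utilities <- function(data, combination = "auto",
                          crosswalk = load_crosswalk()) {
  predict_published(data, combination = combination, crosswalk = crosswalk)
}
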