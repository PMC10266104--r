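# Variable combinations and design matrices for the mapping models.

#' Prepare respondent data for mapping
#'
#' Scores the PedsQL items and, when CHU-9D levels and a value set are
#' available, attaches observed utilities. This is the common input to the
#' fitting, cross-validation and crosswalk-application functions.
#'
#' @param data Respondent data frame (see [read_respondents()]).
#' @param valueset Optional [chu9d_valueset()]; required to compute the
#'   `utility` column from `chu9d_1`...`chu9d_9`.
#' @return A data frame with `id`, `age`, `female`, the 23 item scores
#'   (0--100), `PF`, `EF`, `SF`, `ScF`, `total`, the CHU-9D level columns
#'   if present, and `utility` when computable.
#' @export
prepare_mapping_data <- function(data, valueset = NULL) {
  data <- as.data.frame(data)
  sc <- pedsql_score(data[pedsql_items()])
  out <- data.frame(
    id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
    age = data$age,
    female = data$gender)
  out <- cbind(out, sc)
  chu_cols <- paste0("chu9d_", 1:9)
  if (all(chu_cols %in% names(data))) {
    out[chu_cols] <- data[chu_cols]
    if (!is.null(valueset))
      out$utility <- chu9d_utility(data[chu_cols], valueset)
  }
  out
}

#' Regressor names for a variable combination
#'
#' The six combinations of independent variables used by the mapping
#' models: (1) total score; (2) total score, gender, age; (3) the four
#' dimension scores; (4) dimension scores, gender, age; (5) the 13
#' stepwise-selected item scores; (6) those item scores, gender, age.
#' All score regressors enter divided by 100.
#'
#' @param combination Integer 1--6.
#' @return Character vector of regressor names (excluding the intercept).
#' @export
combination_regressors <- function(combination) {
  combination <- as.integer(combination)
  if (!combination %in% 1:6) stop("combination must be 1-6")
  demo <- c("female", "age")
  switch(combination,
         "total",
         c("total", demo),
         c("PF", "EF", "SF", "ScF"),
         c("PF", "EF", "SF", "ScF", demo),
         pedsql_selected_items(),
         c(pedsql_selected_items(), demo))
}

#' Build the design matrix for a variable combination
#'
#' @param prep Prepared data from [prepare_mapping_data()].
#' @param combination Integer 1--6; see [combination_regressors()].
#' @return A numeric matrix with an `(Intercept)` column followed by the
#'   combination's regressors; score columns are divided by 100. Rows with
#'   missing regressors are dropped; the retained row indices are stored in
#'   `attr(, "rows")` and the combination in `attr(, "combination")`.
#' @export
design_matrix <- function(prep, combination) {
  vars <- combination_regressors(combination)
  miss <- setdiff(vars, names(prep))
  if (length(miss))
    stop("prepared data lacks regressor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(prep[vars])
  storage.mode(X) <- "numeric"
  score_vars <- setdiff(vars, c("female", "age"))
  X[, score_vars] <- X[, score_vars, drop = FALSE] / 100
  if ("female" %in% vars && !all(X[, "female"] %in% c(0, 1, NA)))
    stop("female must be coded 0/1 (1 = girl)")
  keep <- which(stats::complete.cases(X))
  X <- X[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X)
  const <- vapply(seq_len(ncol(X))[-1],
                  function(j) length(unique(X[, j])) == 1L, logical(1))
  if (any(const))
    stop("constant non-intercept column(s): ",
         paste(colnames(X)[-1][const], collapse = ", "))
  attr(X, "rows") <- keep
  attr(X, "combination") <- combination
  X
}
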