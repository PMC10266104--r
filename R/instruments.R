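# PedsQL 4.0 and CHU-9D instrument scoring.

#' PedsQL 4.0 item identifiers
#'
#' The 23 items of the PedsQL 4.0 generic core scales in their fixed order:
#' eight physical functioning items (`pf1`--`pf8`) followed by five items
#' each for emotional (`ef`), social (`sf`) and school (`scf`) functioning.
#'
#' @return Character vector of length 23.
#' @export
#' @examples
#' pedsql_items()
pedsql_items <- function() {
  c(sprintf("pf%d", 1:8), sprintf("ef%d", 1:5),
    sprintf("sf%d", 1:5), sprintf("scf%d", 1:5))
}

#' PedsQL 4.0 dimension membership
#'
#' @return Named list mapping the four dimensions (`PF`, `EF`, `SF`, `ScF`)
#'   to their item identifiers.
#' @export
pedsql_dimensions <- function() {
  list(PF = sprintf("pf%d", 1:8), EF = sprintf("ef%d", 1:5),
       SF = sprintf("sf%d", 1:5), ScF = sprintf("scf%d", 1:5))
}

#' CHU-9D dimension names
#'
#' @return Character vector of the nine CHU-9D dimensions, in instrument
#'   order.
#' @export
chu9d_dimensions <- function() {
  c("worried", "sad", "pain", "tired", "annoyed",
    "schoolwork", "sleep", "daily_routine", "activities")
}

#' Stepwise-selected PedsQL items used by the item-level crosswalks
#'
#' The 13 PedsQL 4.0 items retained by stepwise selection (p-to-enter =
#' p-to-remove = 0.05) in the source crosswalk, used as regressors by
#' variable combinations 5 and 6.
#'
#' @return Character vector of 13 item identifiers.
#' @export
pedsql_selected_items <- function() {
  c("pf2", "pf5", "pf8", "ef1", "ef4", "ef5",
    "sf1", "sf3", "sf4", "scf1", "scf2", "scf3", "scf4")
}

#' Transform a raw PedsQL item response to the 0--100 score scale
#'
#' Items are answered on a five-point scale (0 = never a problem ... 4 =
#' almost always a problem) and reverse-scored linearly so that higher
#' scores mean better health: 0 -> 100, 1 -> 75, 2 -> 50, 3 -> 25, 4 -> 0.
#'
#' @param raw Numeric vector of raw responses in \{0,...,4\}; `NA` allowed
#'   and propagated.
#' @param item Item label used in error messages.
#' @return Numeric vector of item scores in \{0, 25, 50, 75, 100\}.
#' @export
#' @examples
#' pedsql_item_score(c(0, 1, 2, 3, 4))
pedsql_item_score <- function(raw, item = "item") {
  raw <- as.numeric(raw)
  bad <- !is.na(raw) & !(raw %in% 0:4)
  if (any(bad)) {
    stop(sprintf("invalid raw response(s) for %s: %s (must be 0-4 or NA)",
                 item, paste(unique(raw[bad]), collapse = ", ")),
         call. = FALSE)
  }
  100 - 25 * raw
}

#' Score PedsQL 4.0 records
#'
#' Transforms raw item responses to the 0--100 scale and computes the four
#' dimension scores and the total score. A dimension score is the mean of
#' the answered items in that dimension (missing if all its items are
#' missing); the total score is the mean over all answered items, i.e.
#' item-weighted rather than dimension-weighted. No imputation or
#' half-scale rule is applied.
#'
#' @param responses A data frame or matrix containing the 23 raw item
#'   columns named as in [pedsql_items()] (values 0--4, `NA` = missing).
#' @return A data frame with the 23 transformed item scores (same column
#'   names, now 0--100), the dimension scores `PF`, `EF`, `SF`, `ScF`, and
#'   `total`.
#' @export
#' @examples
#' rec <- as.data.frame(as.list(setNames(rep(2, 23), pedsql_items())))
#' pedsql_score(rec)[, c("PF", "EF", "SF", "ScF", "total")]
pedsql_score <- function(responses) {
  items <- pedsql_items()
  if (is.vector(responses) && !is.list(responses)) {
    if (length(responses) != 23L)
      stop("a single PedsQL record must have exactly 23 responses")
    responses <- as.data.frame(as.list(stats::setNames(responses, items)))
  }
  responses <- as.data.frame(responses)
  missing_cols <- setdiff(items, names(responses))
  if (length(missing_cols))
    stop("missing PedsQL item column(s): ", paste(missing_cols, collapse = ", "))
  raw <- as.matrix(responses[items])
  storage.mode(raw) <- "numeric"
  for (j in items) pedsql_item_score(raw[, j], item = j)
  scores <- 100 - 25 * raw
  n_answered <- rowSums(!is.na(scores))
  if (any(n_answered == 0L)) {
    stop("record(s) with all 23 items missing at row(s): ",
         paste(which(n_answered == 0L), collapse = ", "))
  }
  dims <- pedsql_dimensions()
  out <- as.data.frame(scores)
  for (d in names(dims)) {
    m <- scores[, dims[[d]], drop = FALSE]
    ans <- rowSums(!is.na(m))
    ds <- rowSums(m, na.rm = TRUE) / ans
    ds[ans == 0L] <- NA_real_
    out[[d]] <- ds
  }
  out$total <- rowSums(scores, na.rm = TRUE) / n_answered
  out
}

# --- CHU-9D value set ------------------------------------------------------

#' Construct a CHU-9D value set (tariff)
#'
#' A value set maps each of the 5^9 CHU-9D health states to a utility in
#' additive multi-attribute form: utility = 1 - sum of per-dimension
#' decrements at the state's levels. Level 1 of every dimension carries a
#' zero decrement so the best state scores exactly 1; decrements must be
#' non-decreasing in level within a dimension so worse levels never raise
#' utility.
#'
#' @param decrements A 9 x 5 numeric matrix (rows = dimensions in
#'   [chu9d_dimensions()] order) or a named list of length-5 decrement
#'   vectors, one per dimension. First entry of each row must be 0.
#' @param floor Lowest admissible worst-state utility (default 0). The
#'   worst state scores `1 - sum(decrements[, 5])`, which must be >= floor.
#' @return An object of class `chu9d_valueset`.
#' @seealso [read_valueset()], [synthetic_valueset()], [chu9d_utility()]
#' @export
chu9d_valueset <- function(decrements, floor = 0) {
  dims <- chu9d_dimensions()
  if (is.list(decrements) && !is.data.frame(decrements)) {
    missing_d <- setdiff(dims, names(decrements))
    if (length(missing_d))
      stop("value set is missing dimension(s): ", paste(missing_d, collapse = ", "))
    decrements <- do.call(rbind, lapply(dims, function(d) {
      v <- as.numeric(decrements[[d]])
      if (length(v) != 5L) stop("dimension '", d, "' must have 5 decrements")
      v
    }))
  }
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(9L, 5L)))
    stop("decrements must be a 9 x 5 matrix")
  rownames(decrements) <- dims
  colnames(decrements) <- paste0("level", 1:5)
  if (any(abs(decrements[, 1]) > 1e-12))
    stop("level-1 decrements must all be 0")
  if (any(decrements < 0))
    stop("decrements must be nonnegative")
  if (any(apply(decrements, 1, diff) < -1e-12))
    stop("decrements must be non-decreasing in level within each dimension")
  worst <- 1 - sum(decrements[, 5])
  if (worst < floor - 1e-12)
    stop(sprintf("worst-state utility %.4f is below the configured floor %.4f",
                 worst, floor))
  structure(list(decrements = decrements, floor = floor, worst = worst),
            class = "chu9d_valueset")
}

#' @export
print.chu9d_valueset <- function(x, ...) {
  cat("CHU-9D value set (additive): worst-state utility",
      sprintf("%.4f\n", x$worst))
  print(round(x$decrements, 4))
  invisible(x)
}

#' Read a CHU-9D value set from a YAML or JSON file
#'
#' The file must contain one key per dimension (see [chu9d_dimensions()]),
#' each holding the five utility decrements for levels 1--5 (level 1 must
#' be 0). Entries other than the nine dimensions (e.g. `version`,
#' `description`) are ignored.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param floor Passed to [chu9d_valueset()].
#' @return A `chu9d_valueset`.
#' @export
read_valueset <- function(path, floor = 0) {
  if (!file.exists(path)) stop("value-set file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported value-set format '", ext, "' (use yaml or json)"))
  chu9d_valueset(raw[chu9d_dimensions()], floor = floor)
}

#' The synthetic CHU-9D tariff shipped with the package
#'
#' A synthetic additive value set used for examples and tests. It is not a
#' country value set: real analyses must supply their own tariff via
#' [read_valueset()]. Its worst-state utility is 0.315.
#'
#' @return A `chu9d_valueset`.
#' @export
synthetic_valueset <- function() {
  read_valueset(system.file("extdata", "chu9d_valueset_synthetic.yaml",
                            package = "chumap"))
}

#' Compute CHU-9D utilities from health states
#'
#' @param state A length-9 vector of dimension levels (1--5, in
#'   [chu9d_dimensions()] order), or an n x 9 matrix / data frame of
#'   states. Columns named `chu9d_1`...`chu9d_9` or by dimension name are
#'   recognised; otherwise the first nine columns are used positionally.
#' @param valueset A [chu9d_valueset()].
#' @return Numeric vector of utilities; 1 for the all-level-1 state.
#' @export
#' @examples
#' vs <- synthetic_valueset()
#' chu9d_utility(rep(1, 9), vs)  # best health -> 1
chu9d_utility <- function(state, valueset) {
  if (!inherits(valueset, "chu9d_valueset"))
    stop("valueset must be a chu9d_valueset")
  dims <- chu9d_dimensions()
  if (is.vector(state) && !is.list(state)) state <- matrix(state, nrow = 1)
  state <- as.data.frame(state)
  std <- paste0("chu9d_", 1:9)
  if (all(std %in% names(state))) {
    state <- state[std]
  } else if (all(dims %in% names(state))) {
    state <- state[dims]
  } else if (ncol(state) != 9L) {
    stop("state must have 9 dimension levels")
  }
  m <- as.matrix(state)
  storage.mode(m) <- "numeric"
  ok <- is.na(m) | (m %in% 1:5 & m == round(m))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop(sprintf("CHU-9D level out of range 1-5 at row %d, dimension %s",
                 bad[1, 1], dims[bad[1, 2]]))
  }
  dec <- unname(valueset$decrements)
  u <- rep(1, nrow(m))
  for (d in 1:9) u <- u - dec[d, ][m[, d]]
  u
}

#' Size of the CHU-9D health-state space
#'
#' With nine dimensions of five levels each the instrument defines
#' 5^9 = 1,953,125 distinct health states.
#'
#' @param dimensions,levels Dimension and level counts; defaults describe
#'   the CHU-9D.
#' @return Number of distinct states, `levels ^ dimensions`.
#' @export
#' @examples
#' chu9d_state_count()  # 1953125
chu9d_state_count <- function(dimensions = 9, levels = 5) {
  stopifnot(dimensions >= 1, levels >= 1,
            dimensions == round(dimensions), levels == round(levels))
  levels ^ dimensions
}
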