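# Shared fixtures, built in code.

test_valueset <- function() synthetic_valueset()

# A small complete PedsQL record data frame with every response equal to
# `value`.
constant_record <- function(value, n = 1) {
  as.data.frame(matrix(value, n, 23, dimnames = list(NULL, pedsql_items())))
}

# Seeded prepared cohort reused across estimator tests.
test_prep <- local({
  cache <- NULL
  function(n = 2000, seed = 7) {
    if (is.null(cache)) {
      coh <- generate_cohort(n, seed = seed)
      cache <<- prepare_mapping_data(coh, test_valueset())
    }
    cache
  }
})

# Random design matrix (intercept + k standard-normal regressors).
random_design <- function(n, k, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * k), n, k))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k)))
  X
}
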