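`%||%` <- function(x, y) if (is.null(x)) y else x

# All randomness in the package flows through this: one explicit integer seed
# per call, global RNG state untouched.
with_seed <- function(seed, code) {
  gbn_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "invalid_seed", "seed must be a single finite integer")
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seeds for staged computations (kept well below 2^31).
derive_seed <- function(seed, k) {
  (as.integer(seed) * 10007L + as.integer(k) * 7919L) %% 2100000000L
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

# states of every variable as a named list from a data frame
states_from_data <- function(data) {
  lapply(data, function(col) {
    if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
  })
}

# data frame of character columns (canonical survey representation)
as_character_df <- function(data) {
  out <- as.data.frame(lapply(data, as.character),
                       stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(data)
  out
}
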