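# Condition helpers: the CLI maps these classes onto exit codes
# (config -> 2, data -> 3, numeric -> 4).

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "gostrat_config_error")
}

abort_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "gostrat_data_error")
}

abort_numeric <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "gostrat_numeric_error")
}

# match.arg with a data-error condition instead of a base error
match_enum <- function(value, choices, what) {
  if (length(value) != 1L || !value %in% choices) {
    abort_config("%s must be one of: %s (got '%s')",
                 what, paste(choices, collapse = ", "),
                 paste(value, collapse = ","))
  }
  value
}

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# deterministic seed derivation for sub-tasks; stays well below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483L
}

# 17 significant digits: enough for an IEEE double to round-trip exactly
num17 <- function(x) sprintf("%.17g", x)
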