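# Internal helpers shared across modules.

# stop with a classed condition so tests can assert on error class
stop_metfa <- function(msg, class = "metfa_error", ...) {
  rlang::abort(msg, class = c(class, "metfa_error"), ...)
}

assert_that <- function(ok, msg, class = "metfa_error") {
  if (!isTRUE(ok)) stop_metfa(msg, class = class)
  invisible(TRUE)
}

# deterministic integer seed derived from a base seed and a stream label,
# kept below .Machine$integer.max
derive_seed <- function(seed, stream) {
  base <- as.integer(seed)
  off <- sum(utf8ToInt(as.character(stream))) %% 10000L
  (abs(base) %% 200000000L) * 10L + off %% 10L + off
}

# symmetric eigen floor check
min_eigenvalue <- function(X) {
  min(eigen((X + t(X)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

is_square_numeric <- function(X) {
  is.matrix(X) && is.numeric(X) && nrow(X) == ncol(X)
}

# column centring that errors on NA
centre_columns <- function(M) {
  if (anyNA(M)) stop_metfa("marker matrix contains missing values; impute before centring")
  sweep(M, 2L, colMeans(M), `-`)
}
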