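#' @keywords internal
"_PACKAGE"

# Deterministic small-integer seed stream derived from a master seed and a
# string key; stays below 2^31 so it is always a valid set.seed() input.
derive_seed <- function(seed, key) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

assert_prob_mix <- function(x, what) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-8) {
    stop_invalid(what, " must be non-negative and sum to 1")
  }
  invisible(x)
}

# geometric-mean rescaling used for TMM factors
rescale_geomean <- function(f) {
  f / exp(mean(log(f)))
}
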