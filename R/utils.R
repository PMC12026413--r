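# Internal validation and seeding utilities.

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single number, got ", deparse(substitute(x)))
  }
  if (finite && !allow_inf && !is.finite(x)) {
    stop("`", name, "` must be finite, got ", x)
  }
  if (positive && !(x > 0)) stop("`", name, "` must be > 0, got ", x)
  if (nonneg && x < 0) stop("`", name, "` must be >= 0, got ", x)
  invisible(x)
}

# Deterministic sub-seed derivation; keeps everything inside a 32-bit range
# so set.seed() never overflows. `master` < 2^31, k small.
sub_seed <- function(master, k) {
  as.integer(((as.numeric(master) %% 2147483587) * 69069 + k * 7919 + 1) %% 2147483587)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG stream alone (caller-managed randomness).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
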