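# Internal helpers: seeding, validation, small numerics.

# All randomness in the package flows from one integer master seed.  Distinct
# components draw sub-seeds from a counter-based mix so that, e.g., stimulus 7
# of a bank always sees the same stream regardless of how many draws other
# components consumed.  Kept below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (c in as.numeric(counter)) {
    s <- (s * 48271 + c * 16807 + 12345) %% m
  }
  as.integer(max(1, floor(s)))
}

with_local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_audenc <- function(msg, class) {
  rlang::abort(msg, class = c(class, "audenc_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop_audenc(
      sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
      "audenc_config_error"
    )
  }
  invisible(x)
}

# moving-average smoother used by the synthetic stimulus generator
smooth_ma <- function(x, width) {
  width <- min(width, length(x))
  if (width <= 1) return(x)
  kern <- rep(1 / width, width)
  as.numeric(stats::filter(x, kern, sides = 2, circular = TRUE))
}

# safe Pearson correlation: returns 0 when either series is constant
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

clip1 <- function(x) pmin(1, pmax(-1, x))
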