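#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd rnorm rlnorm fft aov rchisq pt qnorm plnorm median quantile setNames
NULL

# Deterministic sub-seed derivation: fold integer indices into a master seed
# with a fixed LCG-style hash (mod 2^31 - 1, exact in double arithmetic).
# Appending an index never changes seeds derived from shorter prefixes, so
# adding a subject or burst never perturbs earlier ones.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (x in c(...)) {
    s <- (s * 48271 + (as.numeric(x) + 1) * 16807) %% m
  }
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed_ <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Multiplier -> band label ("0.5f", "1f", ..., "4f"); broadband kept verbatim.
band_label <- function(multiplier) {
  ifelse(multiplier == round(multiplier),
         sprintf("%df", as.integer(round(multiplier))),
         sprintf("%gf", multiplier))
}
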