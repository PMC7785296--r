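# Internal helpers shared across modules.

#' Derive a deterministic RNG seed from a sample id and a base seed
#'
#' Random-number streams throughout the package are keyed by
#' `(sample_id, seed)` so that panel-level runs are reproducible
#' sample-by-sample: adding or reordering samples never perturbs another
#' sample's draws. The derived seed is a 31-bit integer, computed from a
#' polynomial rolling hash of the id combined with a Lehmer-style scramble
#' of the base seed (all arithmetic stays below 2^53 so it is exact in
#' doubles).
#'
#' @param sample_id Character scalar naming the sample.
#' @param seed Integer base seed.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
derive_seed <- function(sample_id, seed) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            !is.na(sample_id))
  seed <- check_seed(seed)
  mod <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(sample_id)) h <- (h * 31 + k) %% mod
  s <- ((seed %% mod) * 16807) %% mod
  as.integer((h + s) %% mod)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != trunc(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  as.numeric(seed)
}

# Positive finite scalar check with a readable error.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  if (bad_low || x > upper) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  as.numeric(x)
}

# Canonical channel order used everywhere.
CHANNELS <- c("fsc_a", "ssc_a", "gfp", "mcherry")

# Default mapping from canonical channel keys to file parameter names.
default_channel_map <- function() {
  c(fsc_a = "FSC-A", ssc_a = "SSC-A", gfp = "GFP-A", mcherry = "mCherry-A")
}
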