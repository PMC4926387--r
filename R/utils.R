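# Internal numeric helpers shared across modules.

# Squared Euclidean cross-distance matrix between two coordinate matrices
# (rows are points). Clamps tiny negatives from catastrophic cancellation.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

cross_dist <- function(a, b) sqrt(cross_dist2(a, b))

# Round half away from zero at `digits` decimals (reporting convention for
# mean binding affinities). base::round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Wrap angles (degrees) into [-180, 180).
wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mod <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched. All stochastic operations in the package go through this.
with_private_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
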