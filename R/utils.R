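# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a secondary seed below 2^31 from a base seed and stream labels.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  s <- 0
  for (p in parts) s <- (s * 7919 + abs(p) + 1) %% 2147483629
  as.integer(s)
}

# Population (biased) central moments; the cluster-profile statistics use the
# population convention so that e.g. sd(c(1,2,3,4)) = 1.118.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Fisher moment skewness; 0 for degenerate (zero-variance or n < 2) samples.
pop_skewness <- function(x) {
  if (length(x) < 2L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Excess kurtosis (normal -> 0); 0 for degenerate samples.
pop_kurtosis <- function(x) {
  if (length(x) < 2L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

# Min-max normalization to [0, 1]; an all-equal vector maps to all zeros so
# that "no spread" never manufactures a high-scoring node.
minmax <- function(x) {
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_triple <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x)) {
    stopf("`%s` must be a numeric triple", name)
  }
  if (positive && any(x <= 0)) stopf("`%s` must be strictly positive", name)
  as.numeric(x)
}
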