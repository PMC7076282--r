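`%||%` <- function(a, b) if (is.null(a)) b else a

# population (divide-by-n) standard deviation
popSd <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

assertCount <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || (positive && x <= 0) || (!positive && x < 0))
    stop(sprintf("'%s' must be a single %sinteger", name,
                 if (positive) "positive " else "non-negative "), call. = FALSE)
  as.integer(x)
}

assertScalar <- function(x, name, lower = -Inf, allowInf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allowInf && !is.finite(x)) || x < lower)
    stop(sprintf("'%s' must be a single numeric >= %g", name, lower),
         call. = FALSE)
  as.numeric(x)
}

# recycle a per-cell parameter (scalar or length-n vector) to length n
perCell <- function(x, n, name) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n)
    stop(sprintf("'%s' must be a scalar or have one value per cell", name),
         call. = FALSE)
  as.numeric(x)
}

# deterministic per-cell seed streams derived from one master seed
cellSeeds <- function(seed, n) {
  seed <- assertCount(seed, "seed", positive = FALSE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# format numerics at full (round-trippable) precision for table output
fullPrecision <- function(x) {
  if (is.double(x)) sprintf("%.17g", x)
  else if (is.numeric(x)) format(x)
  else as.character(x)
}
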