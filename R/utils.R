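# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Add-one Monte Carlo p-value: never exactly 0, always in (0, 1].
addOneP <- function(nExtreme, nRep) (nExtreme + 1) / (nRep + 1)

# Stage sub-seed scheme used by the pipeline: documented, collision-free for
# stage indices 1..99 and |seed| < 2^31 / 100.
stageSeed <- function(seed, stage) {
  s <- as.double(seed) * 100 + stage
  as.integer(s %% .Machine$integer.max)
}

lowerTri <- function(m) m[lower.tri(m)]

# Symmetric matrix from a vector of lower-triangle values (column-major).
symFromLower <- function(x, n, labels = NULL, diagVal = 0) {
  m <- matrix(diagVal, n, n)
  m[lower.tri(m)] <- x
  m <- m + t(m)
  diag(m) <- diagVal
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
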