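# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# unit-normalize a 3-vector
unit3 <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (n < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

is_unit3 <- function(v, tol = 1e-9) {
  length(v) == 3L && abs(sqrt(sum(v^2)) - 1) <= tol
}

# deterministic orthonormal complement of a unit vector u: returns 3x2 matrix
orthonormal_complement <- function(u) {
  pivot <- which.min(abs(u))
  t <- c(0, 0, 0)
  t[pivot] <- 1
  e1 <- unit3(cross3(u, t))
  e2 <- cross3(u, e1)
  cbind(e1, e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# normalize the sign of an axis so its z-component (first coordinate of a
# (z, y, x) vector) is nonnegative; ties broken on y, then x
canonical_axis_sign <- function(axis) {
  for (k in 1:3) {
    if (axis[k] > 0) return(axis)
    if (axis[k] < 0) return(-axis)
  }
  axis
}

`%||%` <- function(a, b) if (is.null(a)) b else a
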