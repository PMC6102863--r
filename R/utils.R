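# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generator calls never perturb user code.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Dirichlet draws via normalised gamma variates; n x length(alpha).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# rows x cols x channels array -> (rows*cols) x channels matrix, column-major
# pixel order; inverse of pixelArray().
pixelMatrix <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1] * d[2], ncol = d[3])
}

pixelArray <- function(m, nrow, ncol) {
  array(m, dim = c(nrow, ncol, ncol(m)))
}

# Row/col index vectors (1-based) for a 0-based half-open rectangle.
roiRows <- function(roi) seq.int(roi$y0 + 1L, roi$y1)
roiCols <- function(roi) seq.int(roi$x0 + 1L, roi$x1)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
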