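#' @useDynLib hpstwin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif approx sd cor
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## wrap angle(s) to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

## circular distance between two angles
circ_dist <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  pmin(d, 2 * pi - d)
}

row_norms <- function(m) sqrt(rowSums(m * m))

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Deterministic 31-bit sub-seed derived from a master seed and a label,
## so every pipeline stage / fascicle gets an independent reproducible stream.
sub_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- master %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h %% 2147483562 + 1)
}

## Evaluate `expr` under a local RNG stream seeded from (master, label),
## restoring the caller's RNG state afterwards.
with_substream <- function(master, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(master, label))
  expr
}
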