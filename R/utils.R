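## Shared helpers.

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# uniform random proper rotation matrix (det +1) from quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  R <- matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a - b*b + c*c - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a - b*b - c*c + d*d
  ), 3, 3, byrow = TRUE)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.pairwise_dist <- function(x) {
  as.matrix(stats::dist(x))
}
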