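# Internal geometry / numeric helpers shared across modules.

row_norms <- function(m) sqrt(rowSums(m * m))

unit_rows <- function(m) {
  n <- row_norms(m)
  keep <- n > 0
  m[keep, , drop = FALSE] / n[keep]
}

# Uniform random unit vectors in 3D (Marsaglia via normal deviates).
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / row_norms(m)
}

# Rotate unit vector `dir` by polar angle `theta` (radians) with a uniform
# azimuth, i.e. draw a new direction at fixed angular deviation from `dir`.
deflect_direction <- function(dir, theta, phi = stats::runif(1, 0, 2 * pi)) {
  # orthonormal basis (e1, e2) perpendicular to dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    dir[2] * e1[3] - dir[3] * e1[2],
    dir[3] * e1[1] - dir[1] * e1[3],
    dir[1] * e1[2] - dir[2] * e1[1]
  )
  cos(theta) * dir + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
}

# Minimum distances from each point (rows of `p`) to the segment a--b.
point_segment_distance <- function(p, a, b) {
  d <- b - a
  len2 <- sum(d * d)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(p, 2, a)^2)))
  }
  rel <- sweep(p, 2, a)
  tt <- pmin(pmax(as.vector(rel %*% d) / len2, 0), 1)
  proj <- rel - outer(tt, d)
  sqrt(rowSums(proj * proj))
}

# Method-of-moments central moments; skew m3/m2^1.5, non-excess kurtosis
# m4/m2^2 (population denominators, matching direct summation).
moment_stats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  list(
    n = n, mean = mu, m2 = m2,
    skew = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
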