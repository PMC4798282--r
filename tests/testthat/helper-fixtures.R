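# Fixtures and independent brute-force oracles used across test files.

# Track from an n x 3 coordinate matrix at a fixed frame interval.
make_track <- function(coords, dt = 15, id = "t1") {
  coords <- as.matrix(coords)
  track(id,
    t = (seq_len(nrow(coords)) - 1) * dt,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    frame_dt = dt
  )
}

straight_track <- function(n = 5, step = 2, dt = 15, dir = c(1, 0, 0),
                           origin = c(0, 0, 0), id = "straight") {
  coords <- t(sapply(seq_len(n) - 1, function(i) origin + i * step * dir))
  make_track(coords, dt, id)
}

# A jittery random track (small per-frame displacements, no structure).
random_track <- function(n = 10, scale = 3, dt = 15, id = "rnd") {
  make_track(apply(matrix(rnorm(n * 3, sd = scale), ncol = 3), 2, cumsum),
    dt, id
  )
}

# ---- oracles -------------------------------------------------------------

# Step segmentation by direct recomputation: walks the displacement
# vectors, testing each angle with a scalar acos, against the first
# direction of the step.
oracle_steps <- function(tr, theta_max = 15) {
  disp <- diff(tr$pos)
  ang_between <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
  }
  groups <- integer(nrow(disp))
  g <- 1L
  ref <- NULL
  for (i in seq_len(nrow(disp))) {
    v <- disp[i, ]
    if (sqrt(sum(v^2)) == 0) {
      groups[i] <- g
      next
    }
    if (is.null(ref)) {
      ref <- v
    } else if (ang_between(v, ref) > theta_max + 1e-9) {
      g <- g + 1L
      ref <- v
    }
    groups[i] <- g
  }
  t(sapply(split(seq_len(nrow(disp)), groups), function(idx) {
    res <- colSums(disp[idx, , drop = FALSE])
    c(
      start = min(idx), end = max(idx) + 1,
      length = sqrt(sum(res^2)),
      duration = tr$t[max(idx) + 1] - tr$t[min(idx)]
    )
  }))
}

# Explicit-sum moment statistics.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(skew = m3 / m2^(3 / 2), kurtosis = m4 / m2^2)
}

# Grid visits by triple loop over tracks, positions and cubes.
oracle_grid_visits <- function(fl, cube_edge = 20) {
  origin <- fl$bbox["min", ]
  counts <- list()
  for (tr in fl$tracks) {
    seen <- character(0)
    for (i in seq_len(nrow(tr$pos))) {
      key <- paste(floor((tr$pos[i, ] - origin) / cube_edge),
        collapse = "_"
      )
      if (!(key %in% seen)) seen <- c(seen, key)
    }
    for (key in seen) counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar point-to-segment distance via calculus-free case analysis.
oracle_point_seg <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt(sum((p - a)^2)))
  }
  tt <- sum((p - a) * ab) / len2
  tt <- min(1, max(0, tt))
  sqrt(sum((p - (a + tt * ab))^2))
}

# Exhaustive nearest-neighbour Hopkins for fixed probes and sample.
oracle_hopkins <- function(points, probes, idx, power = 1) {
  nn <- function(p, pts) {
    min(apply(pts, 1, function(q) sqrt(sum((p - q)^2))))
  }
  u <- apply(probes, 1, nn, pts = points)
  w <- sapply(idx, function(j) nn(points[j, ], points[-j, , drop = FALSE]))
  sum(w^power) / (sum(u^power) + sum(w^power))
}
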