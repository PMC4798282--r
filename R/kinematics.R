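#' Frame-to-frame velocities
#'
#' Position vectors joining adjacent cell locations divided by the elapsed
#' time, i.e. v_i = (p_{i+1} - p_i) / (t_{i+1} - t_i).
#'
#' @param tr an [track()] object.
#' @return An (n-1) x 3 matrix of velocity vectors in um/s.
#' @export
velocities <- function(tr) {
  dt <- diff(tr$t)
  if (any(dt == 0)) stop("duplicate timestamps in track", call. = FALSE)
  diff(tr$pos) / dt
}

#' Frame-to-frame speeds
#'
#' Norms of the [velocities()]; the per-frame displacement divided by the
#' frame interval.
#'
#' @param tr an [track()] object.
#' @param unit `"um_s"` (default) or `"um_min"` (values multiplied by 60,
#'   the unit used for reporting cell speeds).
#' @return Numeric vector of n-1 speeds.
#' @export
speeds <- function(tr, unit = c("um_s", "um_min")) {
  unit <- match.arg(unit)
  s <- row_norms(velocities(tr))
  if (unit == "um_min") s * 60 else s
}

#' Turning angles along a track
#'
#' The angle between consecutive velocity vectors, via the arccos of the
#' normalized dot product (clamped to [-1, 1] against roundoff). Pairs
#' involving a zero-length velocity (repeated positions) contribute no
#' angle; the number skipped is attached as attribute `"n_skipped"`.
#'
#' @param tr an [track()] object with at least 3 positions.
#' @return Data frame with columns `angle` (degrees in [0, 180]) and
#'   `at_index` (frame index of the vertex, 2-based on positions).
#' @export
turning_angles <- function(tr) {
  if (n_positions(tr) < 3) {
    stop("turning angles need at least 3 positions", call. = FALSE)
  }
  v <- velocities(tr)
  nv <- row_norms(v)
  i <- seq_len(nrow(v) - 1)
  ok <- nv[i] > 0 & nv[i + 1] > 0
  dots <- rowSums(v[i, , drop = FALSE] * v[i + 1, , drop = FALSE])
  cosang <- pmin(pmax(dots / (nv[i] * nv[i + 1]), -1), 1)
  out <- data.frame(
    angle = acos(cosang[ok]) * 180 / pi,
    at_index = (i + 1L)[ok]
  )
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Angle-threshold step segmentation
#'
#' A *step* is the resultant of a maximal run of consecutive velocity
#' vectors that stays within `theta_max` degrees of the run's reference
#' direction; its length is the norm of the resultant displacement. The
#' greedy left-to-right segmentation accumulates vectors while the
#' deviation criterion holds and opens a new step at the first violation.
#'
#' By default the deviation is measured against the direction of the FIRST
#' velocity vector of the current step, which bounds total within-step
#' curvature; `reference = "previous"` instead compares each vector with its
#' immediate predecessor. Zero-length velocity vectors contribute no angle
#' and are absorbed into the current step.
#'
#' @param tr an [track()] object.
#' @param theta_max deviation threshold in degrees, in (0, 180]. At 180
#'   every track yields exactly one step.
#' @param reference `"first"` (default) or `"previous"`.
#' @return Data frame with one row per step: `start_index`, `end_index`
#'   (position indices), `vx`, `vy`, `vz` (resultant displacement, um),
#'   `length` (um) and `duration` (s). Steps partition the track's frame
#'   intervals: durations sum to the track duration and resultants sum to
#'   the net displacement.
#' @export
segment_steps <- function(tr, theta_max = 15,
                          reference = c("first", "previous")) {
  reference <- match.arg(reference)
  if (!is.finite(theta_max) || theta_max <= 0 || theta_max > 180) {
    stop("theta_max must be in (0, 180]", call. = FALSE)
  }
  disp <- diff(tr$pos) # per-frame displacement vectors
  nd <- row_norms(disp)
  cos_max <- cos(theta_max * pi / 180)
  nseg <- nrow(disp)

  starts <- integer(0)
  start <- 1L
  ref_dir <- NULL # unit reference direction of current step
  for (i in seq_len(nseg)) {
    if (nd[i] == 0) next # absorbed, no direction information
    u <- disp[i, ] / nd[i]
    if (is.null(ref_dir)) {
      ref_dir <- u # first non-zero vector of this step
    } else if (sum(u * ref_dir) < cos_max - 1e-12) {
      starts <- c(starts, start)
      start <- i
      ref_dir <- u
    } else if (reference == "previous") {
      ref_dir <- u
    }
  }
  starts <- c(starts, start)
  ends <- c(starts[-1] - 1L, nseg)

  res <- t(vapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    colSums(disp[idx, , drop = FALSE])
  }, numeric(3)))
  data.frame(
    start_index = starts,
    end_index = ends + 1L,
    vx = res[, 1], vy = res[, 2], vz = res[, 3],
    length = sqrt(rowSums(res^2)),
    duration = tr$t[ends + 1L] - tr$t[starts]
  )
}

#' Pool step lengths over the tracks of a field
#'
#' @param fl an [field()] object.
#' @inheritParams segment_steps
#' @return Numeric vector of step lengths (um) pooled across tracks.
#' @export
step_lengths <- function(fl, theta_max = 15,
                         reference = c("first", "previous")) {
  reference <- match.arg(reference)
  unlist(lapply(fl$tracks, function(tr) {
    segment_steps(tr, theta_max, reference)$length
  }), use.names = FALSE)
}

#' Pool per-frame speeds over the tracks of a field
#'
#' @param fl an [field()] object.
#' @inheritParams speeds
#' @return Numeric vector of pooled speeds.
#' @export
pooled_speeds <- function(fl, unit = c("um_s", "um_min")) {
  unit <- match.arg(unit)
  unlist(lapply(fl$tracks, speeds, unit = unit), use.names = FALSE)
}

#' Normalize per-track values by their own track mean
#'
#' Used to ask whether heavy tails survive when between-track mean
#' differences are removed: each speed (or step length) drawn from a track
#' is divided by that track's mean, so every track's normalized values have
#' unit mean.
#'
#' @param values list of numeric vectors, one per track.
#' @return List of normalized vectors; tracks with zero (or non-finite)
#'   mean are dropped with a warning.
#' @export
normalize_by_track_mean <- function(values) {
  stopifnot(is.list(values))
  means <- vapply(values, function(v) mean(v), numeric(1))
  bad <- !is.finite(means) | means <= 0
  if (any(bad)) {
    warning(sum(bad), " track(s) with non-positive mean excluded")
  }
  mapply(function(v, m) v / m, values[!bad], means[!bad], SIMPLIFY = FALSE)
}
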