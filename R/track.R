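#' Track and field containers
#'
#' A `track` is the atomic observation unit: one cell followed through time
#' as an ordered sequence of 3D positions (micrometres) with timestamps
#' (seconds). A `field` is a set of tracks imaged together: they share a
#' bounding box and a nominal frame interval, the unit at which simulations
#' and null models are matched to observation.
#'
#' @param track_id identifier (coerced to character).
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y,z numeric coordinate vectors in micrometres.
#' @param frame_dt nominal frame interval in seconds. Consecutive time
#'   differences must lie within 10\% of `frame_dt`: real acquisitions
#'   jitter, but larger gaps indicate broken tracks.
#' @return `track()` returns an object of class `"lw_track"`; `field()`
#'   an object of class `"lw_field"`.
#' @examples
#' tr <- track("a", t = c(0, 15, 30), x = c(0, 1, 2), y = 0, z = 0)
#' fl <- field(list(tr), frame_dt = 15)
#' n_positions(tr)
#' @export
track <- function(track_id, t, x, y, z, frame_dt = NULL) {
  n <- length(t)
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  if (n < 2) stop("a track needs at least 2 positions", call. = FALSE)
  if (!all(is.finite(c(t, x, y, z)))) {
    stop("track coordinates and times must be finite", call. = FALSE)
  }
  if (any(t < 0)) stop("timestamps must be non-negative", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing within a track",
      call. = FALSE
    )
  }
  if (is.null(frame_dt)) frame_dt <- stats::median(dt)
  if (any(abs(dt - frame_dt) > 0.1 * frame_dt)) {
    stop("frame intervals deviate more than 10% from frame_dt",
      call. = FALSE
    )
  }
  structure(
    list(
      track_id = as.character(track_id),
      t = as.numeric(t),
      pos = cbind(x = x, y = y, z = z),
      frame_dt = frame_dt
    ),
    class = "lw_track"
  )
}

#' @param tracks list of `lw_track` objects.
#' @param field_id identifier for the field.
#' @param bbox 2x3 matrix (rows: min, max; cols: x, y, z) in micrometres, or
#'   `NULL` for the tight bounds of the tracks.
#' @param dataset_id grouping key for fields imaged at frame rates within
#'   one second of each other.
#' @rdname track
#' @export
field <- function(tracks, field_id = "field", bbox = NULL, frame_dt = NULL,
                  dataset_id = field_id) {
  stopifnot(is.list(tracks))
  if (length(tracks) > 0) {
    dts <- vapply(tracks, function(tr) tr$frame_dt, numeric(1))
    if (is.null(frame_dt)) frame_dt <- stats::median(dts)
    if (any(abs(dts - frame_dt) > 1)) {
      stop("all tracks in a field must share frame_dt within 1 s",
        call. = FALSE
      )
    }
    allpos <- do.call(rbind, lapply(tracks, function(tr) tr$pos))
    tight <- rbind(
      min = apply(allpos, 2, min),
      max = apply(allpos, 2, max)
    )
    if (is.null(bbox)) {
      bbox <- tight
    } else {
      bbox <- as.matrix(bbox)
      dimnames(bbox) <- list(c("min", "max"), c("x", "y", "z"))
      if (any(tight["min", ] < bbox["min", ] - 1e-9) ||
        any(tight["max", ] > bbox["max", ] + 1e-9)) {
        stop("track positions fall outside the field bounding box",
          call. = FALSE
        )
      }
    }
  } else {
    if (is.null(frame_dt)) frame_dt <- NA_real_
    if (is.null(bbox)) {
      bbox <- matrix(NA_real_, 2, 3,
        dimnames = list(c("min", "max"), c("x", "y", "z"))
      )
    }
  }
  structure(
    list(
      field_id = as.character(field_id),
      tracks = tracks,
      bbox = bbox,
      frame_dt = frame_dt,
      dataset_id = as.character(dataset_id)
    ),
    class = "lw_field"
  )
}

#' @param tr an `lw_track`.
#' @rdname track
#' @export
n_positions <- function(tr) nrow(tr$pos)

#' Total path length of a track in micrometres.
#' @param tr an `lw_track`.
#' @export
path_length <- function(tr) sum(row_norms(diff(tr$pos)))

#' Net start-to-end displacement of a track in micrometres.
#' @param tr an `lw_track`.
#' @export
net_displacement <- function(tr) {
  sqrt(sum((tr$pos[nrow(tr$pos), ] - tr$pos[1, ])^2))
}

#' Track duration in seconds.
#' @param tr an `lw_track`.
#' @export
track_duration <- function(tr) tr$t[length(tr$t)] - tr$t[1]

#' @export
print.lw_track <- function(x, ...) {
  cat(sprintf(
    "<lw_track %s: %d positions, %.1f s, path %.1f um>\n",
    x$track_id, n_positions(x), track_duration(x), path_length(x)
  ))
  invisible(x)
}

#' @export
print.lw_field <- function(x, ...) {
  cat(sprintf(
    "<lw_field %s: %d tracks, frame_dt %.1f s>\n",
    x$field_id, length(x$tracks), x$frame_dt
  ))
  invisible(x)
}
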