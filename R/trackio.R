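#' Read a track table into a field
#'
#' The on-disk dialect is a plain CSV with header
#' `track_id,frame,t,x,y,z`: one row per observed position, `t` in seconds,
#' coordinates in micrometres, `frame` a 0-based frame index. This matches
#' what common tracking software (e.g. Imaris spot exports) can be trivially
#' mapped onto.
#'
#' @param path path to a CSV track table.
#' @param field_id,dataset_id identifiers for the resulting field.
#' @param bbox optional bounding-box override (2x3 matrix); default is the
#'   tight bounds of the read positions.
#' @param frame_dt optional nominal frame interval in seconds; default is
#'   the median observed interval.
#' @return An [field()] object.
#' @export
read_tracks <- function(path, field_id = basename(path), bbox = NULL,
                        frame_dt = NULL, dataset_id = field_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("track_id", "frame", "t", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(
      "track table is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(df) == 0) stop("track table is empty", call. = FALSE)
  tracks <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (any(diff(d$t) <= 0)) {
      stop(
        "non-monotone time in track ", d$track_id[1],
        call. = FALSE
      )
    }
    track(d$track_id[1], d$t, d$x, d$y, d$z, frame_dt = frame_dt)
  })
  field(unname(tracks),
    field_id = field_id, bbox = bbox,
    frame_dt = frame_dt, dataset_id = dataset_id
  )
}

#' Write a field back to the CSV track-table dialect
#'
#' Inverse of [read_tracks()]: positions are written with enough digits that
#' a read/write round trip reproduces coordinates to at least 6 decimal
#' places.
#'
#' @param fl an [field()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fl, path) {
  rows <- lapply(fl$tracks, function(tr) {
    data.frame(
      track_id = tr$track_id,
      frame = seq_len(nrow(tr$pos)) - 1L,
      t = tr$t,
      x = tr$pos[, 1], y = tr$pos[, 2], z = tr$pos[, 3]
    )
  })
  df <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(
      track_id = character(), frame = integer(), t = numeric(),
      x = numeric(), y = numeric(), z = numeric()
    )
  }
  if (nrow(df) > 0 && !all(is.finite(as.matrix(df[c("t", "x", "y", "z")])))) {
    stop("refusing to write non-finite coordinates", call. = FALSE)
  }
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Motility filter
#'
#' Discards tracks of non-motile cells using three Imaris-style track
#' statistics: total path length below `min_path` (17 um, three cell
#' diameters), net start-to-end squared displacement below `min_sq_disp`
#' (300 um^2 = 17 um x 17 um, the Imaris Displacement^2 statistic), or
#' fewer than `min_steps` recorded time steps.
#'
#' @param fl an [field()] object.
#' @param min_path minimum total path length, um.
#' @param min_sq_disp minimum net squared displacement, um^2.
#' @param min_steps minimum number of time steps (frame intervals).
#' @return A new field containing only the motile tracks; the input is not
#'   modified. Filtering is idempotent.
#' @export
filter_motile <- function(fl, min_path = 17, min_sq_disp = 300,
                          min_steps = 3) {
  keep <- vapply(fl$tracks, function(tr) {
    path_length(tr) >= min_path &&
      net_displacement(tr)^2 >= min_sq_disp &&
      (n_positions(tr) - 1L) >= min_steps
  }, logical(1))
  field(fl$tracks[keep],
    field_id = fl$field_id,
    bbox = if (any(keep)) fl$bbox else NULL,
    frame_dt = fl$frame_dt, dataset_id = fl$dataset_id
  )
}
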