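#' Unique-track visit counts on a 20 um grid
#'
#' Discretizes the field into cubes of `cube_edge` per side (default 20
#' um, about twice a naive T-cell diameter; 8000 um^3) anchored at the
#' bounding-box minimum corner, with half-open intervals
#' [k * e, (k + 1) * e). A track visits a cube if any of its positions
#' falls inside; each track is counted once per cube regardless of how
#' often it returns.
#'
#' @param fl an [field()] object.
#' @param cube_edge cube side length, um.
#' @return Named integer vector of unique-track visit counts; names are
#'   `"ix_iy_iz"` cube indices. Attributes `"cube_edge"` and `"origin"`
#'   record the grid geometry.
#' @export
grid_visits <- function(fl, cube_edge = 20) {
  stopifnot(length(fl$tracks) >= 1)
  origin <- fl$bbox["min", ]
  keys_per_track <- lapply(fl$tracks, function(tr) {
    idx <- floor(sweep(tr$pos, 2, origin) / cube_edge)
    unique(paste(idx[, 1], idx[, 2], idx[, 3], sep = "_"))
  })
  counts <- table(unlist(keys_per_track, use.names = FALSE))
  out <- as.integer(counts)
  names(out) <- names(counts)
  attr(out, "cube_edge") <- cube_edge
  attr(out, "origin") <- origin
  out
}

#' Null-model hotspot threshold from LogMCRW simulation
#'
#' Simulates the lognormal-modulated correlated random walk null model
#' matched to the field — same start positions, frame interval and track
#' durations — `reps` times, pools the per-location unique-track visit
#' counts over all visited locations and repetitions, and returns
#' mean + 2 SD of the pooled counts: a single threshold per field.
#'
#' @param fl an [field()] object.
#' @param params walker parameters for the null model; fitted from the
#'   field via [fit_walker_params()] when NULL.
#' @param reps number of null simulations pooled (>= 2).
#' @param cube_edge grid edge, um.
#' @param model null walker model (default `"logmcrw"`).
#' @return Threshold (numeric scalar) with attributes `"null_counts"`
#'   (the pooled counts) and `"mean"`/`"sd"`.
#' @export
null_threshold <- function(fl, params = NULL, reps = 10, cube_edge = 20,
                           model = "logmcrw") {
  if (reps < 2) stop("need at least 2 null repetitions", call. = FALSE)
  if (is.null(params)) params <- fit_walker_params(fl)
  counts <- unlist(lapply(seq_len(reps), function(r) {
    sim <- simulate_null_field(fl, params, model)
    as.vector(grid_visits(sim, cube_edge))
  }), use.names = FALSE)
  mu <- mean(counts)
  sdev <- stats::sd(counts)
  thr <- mu + 2 * sdev
  attr(thr, "null_counts") <- counts
  attr(thr, "mean") <- mu
  attr(thr, "sd") <- sdev
  thr
}

#' Simulate a null replicate matched to a field
#'
#' One walker per observed track with the same start position, frame
#' interval and duration, confined to the same bounding box.
#'
#' @inheritParams null_threshold
#' @return An [field()] of simulated tracks.
#' @export
simulate_null_field <- function(fl, params = NULL, model = "logmcrw") {
  if (is.null(params)) params <- fit_walker_params(fl)
  box <- sim_box(lo = fl$bbox["min", ], hi = fl$bbox["max", ])
  tracks <- lapply(fl$tracks, function(tr) {
    generate_walker_track(model, params, box,
      frame_dt = fl$frame_dt, duration = track_duration(tr),
      start = tr$pos[1, ], track_id = paste0("null_", tr$track_id),
      semantics = "frame"
    )
  })
  field(tracks,
    field_id = paste0(fl$field_id, "_null"),
    bbox = fl$bbox, frame_dt = fl$frame_dt, dataset_id = fl$dataset_id
  )
}

#' Flag hotspots against a null threshold
#'
#' A visited cube is a hotspot when its observed unique-track visit count
#' strictly exceeds the null threshold (ties are not hotspots).
#'
#' @param observed_counts counts from [grid_visits()].
#' @param threshold from [null_threshold()].
#' @return A `HotspotGrid`: list with `counts`, `threshold`,
#'   `hotspot_keys`, `hotspot_fraction` (fraction of visited cubes
#'   flagged), `cube_edge`, `origin`; class `"lw_hotspots"`.
#' @export
find_hotspots <- function(observed_counts, threshold) {
  flags <- observed_counts > as.numeric(threshold)
  structure(
    list(
      counts = observed_counts,
      threshold = as.numeric(threshold),
      hotspot_keys = names(observed_counts)[flags],
      hotspot_fraction = if (length(observed_counts) > 0) {
        mean(flags)
      } else {
        0
      },
      cube_edge = attr(observed_counts, "cube_edge"),
      origin = attr(observed_counts, "origin")
    ),
    class = "lw_hotspots"
  )
}

#' Classify tracks as hot or cold and compare their motility
#'
#' Hot tracks intersect at least one hotspot cube; cold tracks do not.
#' Reports per-track labels with visit and dwell accounting, and a group
#' comparison: median speed (um/min) of hot vs cold tracks with a
#' Mann-Whitney p-value, and skew/kurtosis of the step-length
#' distributions per group. Dwell time is the length (in time steps) of a
#' maximal run of consecutive frames inside one cube, split by whether
#' the cube is a hotspot.
#'
#' @param fl an [field()] object.
#' @param grid an `lw_hotspots` from [find_hotspots()] computed on `fl`.
#' @param theta_max step-segmentation threshold for the step-length
#'   statistics, degrees.
#' @return List with `labels` (data frame: `track_id`, `label`,
#'   `hotspot_visits`, `coldspot_visits`, `timesteps_in_hotspots`,
#'   `timesteps_in_coldspots`), `summary` (median speeds, Mann-Whitney p,
#'   per-group step-length skew/kurtosis) and `dwell` (data frame of
#'   per-visit dwell lengths for hot tracks, by spot type).
#' @export
classify_hot_cold <- function(fl, grid, theta_max = 15) {
  hot_keys <- grid$hotspot_keys
  origin <- grid$origin
  edge <- grid$cube_edge
  rows <- vector("list", length(fl$tracks))
  dwell_rows <- vector("list", 0)
  for (k in seq_along(fl$tracks)) {
    tr <- fl$tracks[[k]]
    idx <- floor(sweep(tr$pos, 2, origin) / edge)
    keys <- paste(idx[, 1], idx[, 2], idx[, 3], sep = "_")
    in_hot <- keys %in% hot_keys
    runs <- rle(keys)
    run_hot <- runs$values %in% hot_keys
    hot <- any(in_hot)
    rows[[k]] <- data.frame(
      track_id = tr$track_id,
      label = if (hot) "hot" else "cold",
      hotspot_visits = sum(run_hot),
      coldspot_visits = sum(!run_hot),
      timesteps_in_hotspots = sum(in_hot),
      timesteps_in_coldspots = sum(!in_hot)
    )
    if (hot) {
      dwell_rows[[length(dwell_rows) + 1]] <- data.frame(
        track_id = tr$track_id,
        spot = ifelse(run_hot, "hot", "cold"),
        dwell = runs$lengths
      )
    }
  }
  labels <- do.call(rbind, rows)
  dwell <- if (length(dwell_rows) > 0) {
    do.call(rbind, dwell_rows)
  } else {
    data.frame(
      track_id = character(), spot = character(), dwell = integer()
    )
  }
  hot_tracks <- fl$tracks[labels$label == "hot"]
  cold_tracks <- fl$tracks[labels$label == "cold"]
  summary <- NULL
  if (length(hot_tracks) > 0 && length(cold_tracks) > 0) {
    hot_speeds <- unlist(lapply(hot_tracks, speeds, unit = "um_min"))
    cold_speeds <- unlist(lapply(cold_tracks, speeds, unit = "um_min"))
    hot_steps <- unlist(lapply(hot_tracks, function(tr) {
      segment_steps(tr, theta_max)$length
    }))
    cold_steps <- unlist(lapply(cold_tracks, function(tr) {
      segment_steps(tr, theta_max)$length
    }))
    hs <- moment_stats(hot_steps)
    cs <- moment_stats(cold_steps)
    summary <- list(
      median_speed_hot = stats::median(hot_speeds),
      median_speed_cold = stats::median(cold_speeds),
      p_speed = stats::wilcox.test(hot_speeds, cold_speeds,
        exact = FALSE
      )$p.value,
      skew_hot = hs$skew, kurtosis_hot = hs$kurtosis,
      skew_cold = cs$skew, kurtosis_cold = cs$kurtosis
    )
  } else {
    warning("all tracks are ", labels$label[1],
      "; hot/cold group comparison skipped"
    )
  }
  list(labels = labels, summary = summary, dwell = dwell)
}

#' Null self-consistency rate of the hotspot detector
#'
#' The detector's false-positive rate under its own null: a threshold is
#' built from `reps` LogMCRW replicates of a field, then an independent
#' LogMCRW replicate is scored against it. Because the threshold is
#' mean + 2 SD of the pooled null counts, a few percent of visited
#' locations in an independent replicate exceed it by chance.
#'
#' @param fl an [field()] (typically synthetic).
#' @param params walker parameters for the null model.
#' @param reps null repetitions used to pool the threshold.
#' @param cube_edge grid edge, um.
#' @return Fraction (in [0, 1]) of visited locations in the independent
#'   replicate that exceed the threshold.
#' @export
null_hotspot_rate <- function(fl, params = NULL, reps = 10,
                              cube_edge = 20) {
  if (is.null(params)) params <- fit_walker_params(fl)
  thr <- null_threshold(fl, params, reps = reps, cube_edge = cube_edge)
  indep <- simulate_null_field(fl, params)
  counts <- grid_visits(indep, cube_edge)
  find_hotspots(counts, thr)$hotspot_fraction
}
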