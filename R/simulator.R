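#' Simulation box
#'
#' Axis-aligned box for the agent-based search simulation. The default is
#' a 355 x 355 x 50 um slab (6.3e6 um^3): two-photon observation fields
#' average that volume and are thin in z (40-60 um of imaging depth), and
#' the slab geometry matters — quasi-2D confinement changes how much a
#' diffusive searcher re-covers its own ground. Pass `hi` (or a cube via
#' `hi = lo + volume^(1/3)`) to override.
#'
#' @param volume box volume in um^3 (used when `hi` is NULL, realised as
#'   a 355 x 355 x thickness slab with 50 um at the default volume).
#' @param lo,hi numeric length-3 corners in um.
#' @return List with `lo`, `hi` and `volume`, class `"lw_box"`.
#' @export
sim_box <- function(volume = 6.3e6, lo = c(0, 0, 0), hi = NULL) {
  if (is.null(hi)) {
    hi <- lo + c(355, 355, volume / 355^2)
  }
  lo <- as.numeric(lo)
  hi <- as.numeric(hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
  structure(
    list(lo = lo, hi = hi, volume = prod(hi - lo)),
    class = "lw_box"
  )
}

runif_box <- function(n, box) {
  m <- matrix(stats::runif(3 * n), ncol = 3)
  sweep(sweep(m, 2, box$hi - box$lo, `*`), 2, box$lo, `+`)
}

#' Place clustered dendritic-cell targets
#'
#' Targets at the estimated dendritic-cell density are grouped into
#' clusters: cluster centres are uniform in the box and the members of a
#' cluster are uniform within a sphere of `cluster_radius` about the
#' centre (resampled until inside the box). Small radii give compact
#' clusters (Hopkins statistic near 0.2); `cluster_radius = NULL` places
#' all targets uniformly (Hopkins near 0.5).
#'
#' @param box an [sim_box()].
#' @param density targets per um^3; the default 3.17e-5 corresponds to a
#'   2-5\% dendritic-cell volume fraction.
#' @param cluster_size targets per cluster.
#' @param cluster_radius cluster sphere radius in um, or `NULL` for
#'   uniform placement.
#' @return A `TargetSet`: list with `points` (n x 3 matrix), `cluster_id`,
#'   `cluster_radius`, `density`, class `"lw_targets"`.
#' @export
place_targets <- function(box, density = 3.17e-5, cluster_size = 10,
                          cluster_radius = NULL) {
  n <- round(density * box$volume)
  if (n == 0) stop("box too small: zero targets at this density",
      call. = FALSE
    )
  if (is.null(cluster_radius) || !is.finite(cluster_radius)) {
    pts <- runif_box(n, box)
    cid <- seq_len(n)
  } else {
    stopifnot(cluster_radius > 0)
    ncl <- ceiling(n / cluster_size)
    centres <- runif_box(ncl, box)
    cid <- rep(seq_len(ncl), each = cluster_size)[seq_len(n)]
    pts <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      repeat {
        dir <- runif_sphere(1)
        r <- cluster_radius * stats::runif(1)^(1 / 3)
        p <- centres[cid[i], ] + r * dir[1, ]
        if (all(p >= box$lo) && all(p <= box$hi)) break
      }
      pts[i, ] <- p
    }
  }
  structure(
    list(
      points = pts, cluster_id = cid,
      cluster_radius = cluster_radius, density = density, box = box
    ),
    class = "lw_targets"
  )
}

#' 3D Hopkins aggregation statistic
#'
#' Measures spatial non-uniformity of a point set. Per repetition, `m`
#' uniform probe points are sampled in the box (nearest-data distances
#' u_j) together with `m` data points without replacement (nearest-other-
#' data distances w_j); the statistic is sum(w) / (sum(u) + sum(w)),
#' averaged over repetitions. Under this convention uniform point sets
#' score about 0.5 and increasingly clustered sets approach 0 (w shrinks
#' inside clusters while u does not).
#'
#' @param points n x 3 matrix of coordinates.
#' @param box an [sim_box()] bounding the points.
#' @param m probes per repetition (>= 5); default max(10, n/10).
#' @param reps repetitions averaged over.
#' @param power exponent applied to the nearest-neighbour distances; 1
#'   (raw distances, default) or 3 (volume-element variant).
#' @return Scalar in [0, 1].
#' @export
hopkins_3d <- function(points, box, m = max(10L, floor(0.1 * nrow(points))),
                       reps = 100, power = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (m < 5) stop("m must be at least 5", call. = FALSE)
  if (m > n - 1) stop("m must be below the number of points", call. = FALSE)
  vals <- vapply(seq_len(reps), function(r) {
    hopkins_once(points, runif_box(m, box), sample.int(n, m), power)
  }, numeric(1))
  mean(vals)
}

# One Hopkins evaluation for a fixed probe set and data-point sample.
hopkins_once <- function(points, probes, idx, power = 1) {
  n <- nrow(points)
  m <- nrow(probes)
  sq <- rowSums(points^2)
  cross <- outer(rowSums(probes^2), rep(1, n)) +
    outer(rep(1, m), sq) - 2 * probes %*% t(points)
  u <- sqrt(pmax(apply(cross, 1, min), 0))
  self <- outer(sq[idx], rep(1, n)) +
    outer(rep(1, length(idx)), sq) -
    2 * points[idx, , drop = FALSE] %*% t(points)
  self[cbind(seq_along(idx), idx)] <- Inf
  w <- sqrt(pmax(apply(self, 1, min), 0))
  sum(w^power) / (sum(u^power) + sum(w^power))
}

# Reflect a proposed position into the box; returns the folded position
# and the per-axis sign flip to apply to the direction of motion.
reflect_box <- function(p, box) {
  flip <- c(1, 1, 1)
  for (ax in 1:3) {
    span <- box$hi[ax] - box$lo[ax]
    # fold into [lo, lo + 2 span) then mirror the upper half
    y <- (p[ax] - box$lo[ax]) %% (2 * span)
    if (y > span) {
      y <- 2 * span - y
      flip[ax] <- -1
    }
    p[ax] <- box$lo[ax] + y
  }
  list(p = p, flip = flip)
}

#' Walker-model parameters fitted from a field
#'
#' Parameterizes the idealized search models by the speeds and turning
#' angles estimated from observation: lognormal, Gaussian and Maxwell MLE
#' fits to the pooled per-frame speeds, a gamma MLE fit to the pooled
#' turning angles, a lognormal fit to the pooled step lengths (the
#' LogMCRW step-length law), both power-law fits to the step lengths —
#' the full-sample MLE (`powerlaw_walk`, the Levy-walker
#' parameterization) and the Clauset tail fit (`powerlaw_tail`, the tail
#' analysis) — the pooled mean speed (used to traverse steps at finite
#' speed), and the pooled empirical (speed, angle) pairs for the
#' bootstrap walker.
#'
#' @param fl an [field()] object.
#' @param theta_max step-segmentation threshold, degrees.
#' @return List of class `"lw_walker_params"`.
#' @export
fit_walker_params <- function(fl, theta_max = 15) {
  sp <- pooled_speeds(fl)
  ang <- unlist(
    lapply(fl$tracks, function(tr) turning_angles(tr)$angle),
    use.names = FALSE
  )
  steps <- step_lengths(fl, theta_max)
  pairs <- do.call(rbind, lapply(fl$tracks, function(tr) {
    s <- speeds(tr)
    a <- turning_angles(tr)
    # angle at vertex i pairs with the speed of the outgoing velocity
    data.frame(speed = s[a$at_index], angle = a$angle)
  }))
  structure(
    list(
      lognormal = fit_mle(sp, "lognormal"),
      gaussian = fit_mle(sp, "gaussian"),
      maxwell = fit_mle(sp, "maxwell"),
      angle_gamma = fit_mle(ang[ang > 0], "gamma"),
      step_lognormal = fit_mle(steps, "lognormal"),
      powerlaw_walk = fit_mle(steps, "powerlaw")$params,
      powerlaw_tail = fit_powerlaw_tail(steps),
      mean_speed = mean(sp),
      pairs = pairs
    ),
    class = "lw_walker_params"
  )
}

walker_models <- c(
  "brownian", "crw", "lognormal", "logmcrw", "powerlaw", "bootstrap"
)

draw_angle_gamma <- function(fit) {
  repeat {
    a <- stats::rgamma(1,
      shape = fit$params["shape"], scale = fit$params["scale"]
    )
    if (a <= 180) {
      return(a * pi / 180)
    }
  }
}

# Gaussian speed truncated at zero: negative draws become pauses
# (speed 0) rather than being resampled — resampling would inflate the
# walker's mean speed well above the fitted value on skewed speed data.
draw_speed_truncnorm <- function(fit) {
  max(0, stats::rnorm(1, fit$params["mean"], fit$params["sd"]))
}

#' Generate one simulated walker track
#'
#' Continuous-3D generation, one of six models:
#' \describe{
#'   \item{brownian}{new direction uniform on the sphere every frame;
#'     per-frame speed from the Maxwell fit (the 3D Brownian reference).}
#'   \item{lognormal}{uniform direction each frame with a fresh speed
#'     from the lognormal fit to observed per-frame speeds: heavy-tailed
#'     but isotropic, hence diffusive (ensemble MSD slope near 1).}
#'   \item{crw}{correlated random walk: polar turning angle from the gamma
#'     fit to observed turning angles every frame, azimuth uniform; speed
#'     from the Gaussian fit truncated at zero (negative draws are
#'     pauses).}
#'   \item{logmcrw}{the lognormal-modulated CRW: a CRW whose straight
#'     steps have lognormally distributed lengths — gamma turning angle
#'     per step, step length from the lognormal step-length fit,
#'     traversed at the pooled mean speed.}
#'   \item{powerlaw}{the Levy walker: step lengths from the power-law fit
#'     to observed step lengths (`powerlaw_walk`), uniform direction per
#'     step, traversed at the pooled mean observed speed (a walk, not a
#'     flight — speeds stay finite).}
#'   \item{bootstrap}{per frame, one (speed, turning angle) pair drawn
#'     uniformly from the pooled empirical values.}
#' }
#'
#' With `semantics = "frame"` the logmcrw model instead draws a fresh
#' speed from the lognormal per-frame speed fit every frame with a gamma
#' turning angle per frame. This is the kinematic reading used by the
#' synthetic-data generator, whose per-frame speeds must follow the speed
#' fit; the step-length reading above is the search-model semantics.
#'
#' Walkers are confined to the box by specular reflection. A walker whose
#' distance budget is exhausted halts in place for the remainder of its
#' duration: searcher time keeps accruing, so the population's average
#' velocity stays within the observed range rather than being inflated by
#' fast models finishing their budget early.
#'
#' @param model one of the six model names.
#' @param params an [fit_walker_params()] or [synthetic_params()] object.
#' @param box an [sim_box()].
#' @param frame_dt frame interval, seconds.
#' @param duration maximum simulated time, seconds.
#' @param start length-3 start position (default: uniform in the box).
#' @param distance_budget maximum path length in um (default unlimited).
#' @param track_id identifier for the generated track.
#' @param semantics `"step"` (search-model reading, default) or
#'   `"frame"` (kinematic reading); only affects logmcrw.
#' @return An [track()] object.
#' @export
generate_walker_track <- function(model, params, box, frame_dt = 15,
                                  duration = 600, start = NULL,
                                  distance_budget = Inf,
                                  track_id = model,
                                  semantics = c("step", "frame")) {
  model <- match.arg(model, walker_models)
  semantics <- match.arg(semantics)
  if (is.null(start)) start <- runif_box(1, box)[1, ]
  n_frames <- max(1L, floor(round(duration / frame_dt, 6)))
  step_based <- model == "powerlaw" ||
    (model == "logmcrw" && semantics == "step")
  pos <- matrix(NA_real_, n_frames + 1, 3)
  pos[1, ] <- start
  dir <- runif_sphere(1)[1, ]
  travelled <- 0
  i <- 1L
  exhausted <- FALSE
  step_left <- 0 # remaining length of the current multi-frame step
  while (i <= n_frames) {
    if (exhausted) { # budget spent: idle in place, time still accrues
      pos[i + 1, ] <- pos[i, ]
      i <- i + 1L
      next
    }
    if (step_based) {
      if (step_left <= 0) { # new straight step
        step_left <- switch(model,
          powerlaw = rpowerlaw(
            1, params$powerlaw_walk["mu"], params$powerlaw_walk["xmin"]
          ),
          stats::rlnorm(
            1, params$step_lognormal$params["meanlog"],
            params$step_lognormal$params["sdlog"]
          )
        )
        dir <- if (model == "logmcrw") {
          deflect_direction(dir, draw_angle_gamma(params$angle_gamma))
        } else {
          runif_sphere(1)[1, ]
        }
      }
      speed <- params$mean_speed
    } else if (model %in% c("brownian", "lognormal")) {
      dir <- runif_sphere(1)[1, ]
      speed <- if (model == "brownian") {
        rmaxwell(1, params$maxwell$params["a"])
      } else {
        stats::rlnorm(
          1, params$lognormal$params["meanlog"],
          params$lognormal$params["sdlog"]
        )
      }
    } else if (model %in% c("crw", "logmcrw")) {
      dir <- deflect_direction(dir, draw_angle_gamma(params$angle_gamma))
      speed <- if (model == "crw") {
        draw_speed_truncnorm(params$gaussian)
      } else {
        stats::rlnorm(
          1, params$lognormal$params["meanlog"],
          params$lognormal$params["sdlog"]
        )
      }
    } else { # bootstrap
      j <- sample.int(nrow(params$pairs), 1)
      dir <- deflect_direction(dir, params$pairs$angle[j] * pi / 180)
      speed <- params$pairs$speed[j]
    }
    d <- speed * frame_dt
    if (travelled + d > distance_budget) {
      exhausted <- TRUE
      pos[i + 1, ] <- pos[i, ]
      i <- i + 1L
      next
    }
    travelled <- travelled + d
    if (step_based) step_left <- step_left - d
    ref <- reflect_box(pos[i, ] + dir * d, box)
    pos[i + 1, ] <- ref$p
    dir <- dir * ref$flip
    i <- i + 1L
  }
  track(track_id,
    t = (seq_len(n_frames + 1) - 1) * frame_dt,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    frame_dt = frame_dt
  )
}

#' Run the target-search contact analysis
#'
#' A target is contacted when a searcher track passes within
#' `detection_radius` of the target point; contact is tested with the
#' exact point-to-segment distance on every inter-frame segment, so
#' detection is frame-rate-robust. The 10 um default encodes assumed radii
#' of 5 um each for T cells and dendritic cells.
#'
#' Unique contacts count each (searcher, target) pair at most once. Total
#' contacts count repeated interaction with the same target; two counting
#' conventions are provided. `"reentry"` (default) increments only when a
#' target transitions from outside to inside a searcher's detection
#' sphere (a contiguous run of in-contact segments is one event);
#' `"presence"` increments for every frame interval a searcher spends in
#' contact with a target, weighting thorough searchers that linger near
#' targets.
#'
#' @param tracks list of [track()] searcher tracks.
#' @param targets an [place_targets()] result.
#' @param detection_radius contact distance, um.
#' @param total_mode `"presence"` or `"reentry"` (see above).
#' @return An `EfficiencyResult`: list with `unique_contacts`,
#'   `total_contacts`, `searcher_time` (minutes), `efficiency_unique` and
#'   `efficiency_total` (contacts per searcher-minute).
#' @export
run_search <- function(tracks, targets, detection_radius = 10,
                       total_mode = c("reentry", "presence")) {
  total_mode <- match.arg(total_mode)
  pts <- targets$points
  total_time <- sum(vapply(tracks, track_duration, numeric(1))) / 60
  if (total_time <= 0) stop("zero total searcher time", call. = FALSE)
  uniq <- 0L
  tot <- 0L
  for (tr in tracks) {
    ns <- nrow(tr$pos) - 1L
    contact <- matrix(FALSE, ns, nrow(pts))
    for (s in seq_len(ns)) {
      d <- point_segment_distance(pts, tr$pos[s, ], tr$pos[s + 1, ])
      contact[s, ] <- d <= detection_radius
    }
    hit <- colSums(contact) > 0
    uniq <- uniq + sum(hit)
    if (total_mode == "presence") {
      tot <- tot + sum(contact)
    } else {
      prev <- rbind(FALSE, contact[-ns, , drop = FALSE])
      tot <- tot + sum(contact & !prev)
    }
  }
  list(
    unique_contacts = uniq, total_contacts = tot,
    searcher_time = total_time,
    efficiency_unique = uniq / total_time,
    efficiency_total = tot / total_time
  )
}

#' Compare a model's efficiency distribution with a reference
#'
#' Reports the percent change in median search efficiency relative to the
#' reference, a 95\% confidence interval over independent repetitions, and
#' two Mann-Whitney U p-values: one comparing the per-repetition medians
#' (N = number of repetitions per side) and one comparing all pooled raw
#' efficiency values. Mann-Whitney is used because efficiency
#' distributions are non-Gaussian.
#'
#' @param model_eff,ref_eff numeric efficiency samples.
#' @param model_rep,ref_rep optional repetition labels (same lengths);
#'   without them no CI or median-level p-value is computed.
#' @return List with `pct_change_median`, `ci95` (half-width, or NA),
#'   `p_median`, `p_all`.
#' @export
compare_models <- function(model_eff, ref_eff,
                           model_rep = NULL, ref_rep = NULL) {
  if (length(model_eff) < 2 || length(ref_eff) < 2) {
    stop("need at least 2 efficiency samples on each side", call. = FALSE)
  }
  pct <- 100 * (stats::median(model_eff) - stats::median(ref_eff)) /
    stats::median(ref_eff)
  p_all <- stats::wilcox.test(model_eff, ref_eff, exact = FALSE)$p.value
  ci95 <- NA_real_
  p_median <- NA_real_
  if (!is.null(model_rep) && !is.null(ref_rep)) {
    mm <- tapply(model_eff, model_rep, stats::median)
    rm_ <- tapply(ref_eff, ref_rep, stats::median)
    if (length(mm) >= 2 && length(rm_) >= 2) {
      per_rep <- 100 * (mm - rm_[names(mm)]) / rm_[names(mm)]
      per_rep <- per_rep[is.finite(per_rep)]
      ci95 <- stats::qt(0.975, length(per_rep) - 1) *
        stats::sd(per_rep) / sqrt(length(per_rep))
      p_median <- stats::wilcox.test(mm, rm_, exact = FALSE)$p.value
    }
  }
  list(
    pct_change_median = pct, ci95 = ci95,
    p_median = p_median, p_all = p_all
  )
}

#' Search-efficiency experiment over models and target clusterings
#'
#' For each cluster radius and each replicate: targets are placed afresh,
#' one simulated searcher is generated per observed track (same start,
#' frame interval and duration, with the per-searcher distance budget set
#' to that observed track's path length, so the summed simulated distance
#' is limited by the total observed distance), and both the simulated and
#' the observed searchers are scored with [run_search()]. The observed
#' tracks themselves are entered as model `"observed"`.
#'
#' @param fl an [field()] with the observed (or synthetic stand-in)
#'   tracks.
#' @param models character vector of walker models to compare.
#' @param cluster_radii numeric vector of target cluster radii (um; `NA`
#'   entries mean uniform placement).
#' @param replicates replicates per repetition.
#' @param reps independent repetitions (for confidence intervals).
#' @param detection_radius contact distance, um.
#' @param density,cluster_size target placement parameters.
#' @param params optional pre-fitted [fit_walker_params()]; fitted from
#'   `fl` when NULL.
#' @param total_mode total-contact counting convention (see
#'   [run_search()]).
#' @return Tidy data frame: `field`, `model`, `radius`, `rep`,
#'   `replicate`, `efficiency_unique`, `efficiency_total`.
#' @export
efficiency_experiment <- function(fl, models = walker_models,
                                  cluster_radii = c(10, 20, 40),
                                  replicates = 100, reps = 1,
                                  detection_radius = 10,
                                  density = 3.17e-5, cluster_size = 10,
                                  params = NULL,
                                  total_mode = c("reentry", "presence")) {
  total_mode <- match.arg(total_mode)
  if (is.null(params)) params <- fit_walker_params(fl)
  box <- sim_box(lo = fl$bbox["min", ], hi = fl$bbox["max", ])
  obs <- fl$tracks
  budgets <- vapply(obs, path_length, numeric(1))
  durations <- vapply(obs, track_duration, numeric(1))
  starts <- lapply(obs, function(tr) tr$pos[1, ])
  out <- vector("list", 0)
  for (radius in cluster_radii) {
    cr <- if (is.na(radius)) NULL else radius
    for (rep_i in seq_len(reps)) {
      for (repl in seq_len(replicates)) {
        targets <- place_targets(box,
          density = density,
          cluster_size = cluster_size, cluster_radius = cr
        )
        for (model in c("observed", models)) {
          searchers <- if (model == "observed") {
            obs
          } else {
            lapply(seq_along(obs), function(k) {
              generate_walker_track(model, params, box,
                frame_dt = fl$frame_dt, duration = durations[k],
                start = starts[[k]], distance_budget = budgets[k],
                track_id = paste0(model, "_", k)
              )
            })
          }
          eff <- run_search(searchers, targets, detection_radius,
            total_mode = total_mode
          )
          out[[length(out) + 1]] <- data.frame(
            field = fl$field_id, model = model, radius = radius,
            rep = rep_i, replicate = repl,
            efficiency_unique = eff$efficiency_unique,
            efficiency_total = eff$efficiency_total
          )
        }
      }
    }
  }
  do.call(rbind, out)
}
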