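#' Squared displacement from the track origin
#'
#' The displacement-from-origin convention: squared distance from the
#' track's first position at each elapsed time up to `max_window`. Only the
#' first 10 minutes are kept by default — beyond that few tracks persist
#' and the ensemble curve is dominated by noise.
#'
#' @param tr an [track()] object with at least 3 positions.
#' @param max_window longest elapsed time retained, seconds.
#' @return An `MSDCurve`: data frame with `lag` (s), `msd` (um^2) and
#'   `count` (always 1 for a single track); `msd[lag == 0]` is 0.
#' @export
track_msd <- function(tr, max_window = 600) {
  lag <- tr$t - tr$t[1]
  keep <- lag <= max_window
  sq <- rowSums(sweep(tr$pos, 2, tr$pos[1, ])^2)
  data.frame(lag = lag[keep], msd = sq[keep], count = 1L)
}

#' Ensemble mean squared displacement
#'
#' Per-lag mean of the squared displacement from origin over the tracks
#' still alive at that lag, with the number of contributing tracks
#' reported. Lags are aligned across tracks by rounding to the shared frame
#' interval, so all tracks must come from one dataset (frame intervals
#' within 1 s).
#'
#' @param tracks list of [track()] objects sharing a frame interval.
#' @param max_window longest elapsed time retained, seconds.
#' @return Data frame with `lag`, `msd` and `count` columns.
#' @export
ensemble_msd <- function(tracks, max_window = 600) {
  stopifnot(length(tracks) >= 1)
  dts <- vapply(tracks, function(tr) tr$frame_dt, numeric(1))
  if (diff(range(dts)) > 1) {
    stop("tracks span frame intervals differing by more than 1 s; ",
      "group fields into datasets first",
      call. = FALSE
    )
  }
  dt <- stats::median(dts)
  per <- lapply(tracks, function(tr) {
    m <- track_msd(tr, max_window)
    m$lag <- round(m$lag / dt) * dt
    m
  })
  all <- do.call(rbind, per)
  agg <- stats::aggregate(msd ~ lag, all, mean)
  cnt <- stats::aggregate(msd ~ lag, all, length)
  data.frame(lag = agg$lag, msd = agg$msd, count = cnt$msd)
}

#' Anomalous-diffusion exponent from an MSD curve
#'
#' Degree-1 least-squares fit to (log lag, log msd): the slope is the
#' displacement exponent alpha (1 = diffusive, 2 = ballistic, in between =
#' superdiffusive Levy window) and the r^2 of the linear fit measures how
#' well any single exponent describes the curve. Zero lags and zero MSD
#' values are excluded from the logs.
#'
#' @param curve data frame with `lag` and `msd` columns.
#' @return List with `alpha`, `r2`, `intercept` (log-space), `n_points`.
#' @export
fit_alpha <- function(curve) {
  ok <- curve$lag > 0 & curve$msd > 0
  if (sum(ok) < 3) {
    stop("need at least 3 positive (lag, msd) points", call. = FALSE)
  }
  lx <- log(curve$lag[ok])
  ly <- log(curve$msd[ok])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  ssr <- sum(fit$residuals^2)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(
    alpha = alpha, r2 = r2,
    intercept = unname(fit$coefficients[1]), n_points = sum(ok)
  )
}

#' Motion class from the displacement exponent
#'
#' @param alpha displacement exponent.
#' @return `"subdiffusive"` (alpha < 1), `"levy_window"` (1 <= alpha <= 2,
#'   the range a Levy walk can produce), or `"ballistic_plus"` (alpha > 2,
#'   accelerating motion).
#' @export
classify_alpha <- function(alpha) {
  stopifnot(all(is.finite(alpha)))
  ifelse(alpha < 1, "subdiffusive",
    ifelse(alpha <= 2, "levy_window", "ballistic_plus")
  )
}

#' Motility coefficient of a track
#'
#' Unweighted-average method: a plain linear model is fit to the
#' (untransformed) squared-displacement curve over the first 25\% of lags,
#' with positions not exceeding the 10-minute track window; the motility
#' coefficient is slope / 6 (3D), reported in um^2/min.
#'
#' @param tr an [track()] object.
#' @param max_window longest elapsed time used, seconds.
#' @param early_fraction fraction of the curve used for the linear fit.
#' @return List with `D` (um^2/min), `r2` of the linear fit, `n_points`.
#' @export
motility_coefficient <- function(tr, max_window = 600,
                                 early_fraction = 0.25) {
  m <- track_msd(tr, max_window)
  cutoff <- early_fraction * max(m$lag)
  m <- m[m$lag <= cutoff, , drop = FALSE]
  if (nrow(m) < 3) {
    stop("fewer than 3 points in the early-time window", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, m$lag), m$msd)
  slope <- unname(fit$coefficients[2]) # um^2/s
  ssr <- sum(fit$residuals^2)
  sst <- sum((m$msd - mean(m$msd))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(D = slope * 60 / 6, r2 = r2, n_points = nrow(m))
}

#' Population motility coefficient
#'
#' Unweighted mean of per-track motility coefficients over tracks whose
#' early-time linear fit has r^2 above `min_r2`.
#'
#' @param fl an [field()] object.
#' @param min_r2 fit-quality filter (default 0.8).
#' @inheritParams motility_coefficient
#' @return List with `D` (um^2/min), `n_used`, `n_total`.
#' @export
population_motility <- function(fl, min_r2 = 0.8, max_window = 600,
                                early_fraction = 0.25) {
  per <- lapply(fl$tracks, function(tr) {
    tryCatch(motility_coefficient(tr, max_window, early_fraction),
      error = function(e) NULL
    )
  })
  per <- per[!vapply(per, is.null, logical(1))]
  d <- vapply(per, `[[`, numeric(1), "D")
  r2 <- vapply(per, `[[`, numeric(1), "r2")
  keep <- r2 > min_r2
  list(
    D = mean(d[keep]), n_used = sum(keep), n_total = length(fl$tracks)
  )
}

#' Per-track displacement exponents for a field
#'
#' Fits [fit_alpha()] to every track's displacement curve and tabulates the
#' motion-class fractions at a given r^2 filter.
#'
#' @param fl an [field()] object.
#' @param min_r2 keep tracks with fit r^2 above this (0 keeps all).
#' @param max_window longest elapsed time used, seconds.
#' @return List with `per_track` data frame (`track_id`, `alpha`, `r2`,
#'   `class`) and `fractions` (named proportions over the retained tracks).
#' @export
alpha_census <- function(fl, min_r2 = 0, max_window = 600) {
  rows <- lapply(fl$tracks, function(tr) {
    af <- tryCatch(fit_alpha(track_msd(tr, max_window)),
      error = function(e) NULL
    )
    if (is.null(af)) {
      return(NULL)
    }
    data.frame(
      track_id = tr$track_id, alpha = af$alpha, r2 = af$r2,
      class = classify_alpha(af$alpha)
    )
  })
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  kept <- per[per$r2 > min_r2 | min_r2 <= 0, , drop = FALSE]
  fr <- prop.table(table(factor(kept$class,
    levels = c("subdiffusive", "levy_window", "ballistic_plus")
  )))
  list(per_track = per, fractions = fr, n_kept = nrow(kept))
}
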