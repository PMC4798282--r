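#' Velocity (turning-angle) autocorrelation
#'
#' Directional persistence: the ensemble mean over tracks and start times
#' of the dot product of unit velocity vectors separated by a delay,
#' C(tau) = < u(t) . u(t + tau) >. C(0) = 1 by construction; for a
#' persistent (correlated) walk C decays toward zero over the persistence
#' time, while an isotropic walker gives C(tau) ~ 0 for all tau > 0.
#' Zero-length velocity vectors are skipped.
#'
#' @param tracks list of [track()] objects sharing a frame interval
#'   (within 1 s).
#' @param max_delay largest delay evaluated, seconds.
#' @return A `CorrelationCurve`: data frame with `delay` (s), `corr` and
#'   `n_pairs`; delays with no valid pairs are dropped with a warning.
#' @export
velocity_autocorrelation <- function(tracks, max_delay = 300) {
  stopifnot(length(tracks) >= 1)
  dts <- vapply(tracks, function(tr) tr$frame_dt, numeric(1))
  if (diff(range(dts)) > 1) {
    stop("tracks span frame intervals differing by more than 1 s",
      call. = FALSE
    )
  }
  dt <- stats::median(dts)
  max_j <- floor(max_delay / dt)
  sums <- numeric(max_j + 1)
  counts <- integer(max_j + 1)
  for (tr in tracks) {
    v <- velocities(tr)
    nv <- row_norms(v)
    ok <- nv > 0
    u <- v / ifelse(nv > 0, nv, 1)
    m <- nrow(u)
    for (j in 0:min(max_j, m - 1)) {
      i <- seq_len(m - j)
      valid <- ok[i] & ok[i + j]
      if (!any(valid)) next
      dots <- rowSums(u[i, , drop = FALSE] * u[i + j, , drop = FALSE])
      sums[j + 1] <- sums[j + 1] + sum(dots[valid])
      counts[j + 1] <- counts[j + 1] + sum(valid)
    }
  }
  keep <- counts > 0
  if (!all(keep)) {
    warning(sum(!keep), " delay(s) had no valid velocity pairs; dropped")
  }
  data.frame(
    delay = (which(keep) - 1) * dt,
    corr = sums[keep] / counts[keep],
    n_pairs = counts[keep]
  )
}

#' Cross-correlation between tracks: field drift check
#'
#' C_cross = < u_k(t) . u_m(t) > over all distinct track pairs k != m at
#' matched absolute times — a measure of drift due to global effects on the
#' observation field (flow, stage movement). Independent isotropic walkers
#' give a value within sampling noise of zero; a shared drift direction
#' pushes it strictly positive.
#'
#' @param fl an [field()] object with at least 2 temporally overlapping
#'   tracks.
#' @return List with `corr` (overall mean), `se` (standard error over
#'   pairs of matched unit-velocity dot products), `n_pairs` (number of
#'   matched vector pairs), and `by_time` (data frame of the per-time
#'   means).
#' @export
cross_correlation <- function(fl) {
  tracks <- fl$tracks
  if (length(tracks) < 2) {
    stop("cross-correlation needs at least 2 tracks", call. = FALSE)
  }
  dt <- fl$frame_dt
  # unit velocities indexed by absolute frame slot round(t / dt)
  tab <- lapply(tracks, function(tr) {
    v <- velocities(tr)
    nv <- row_norms(v)
    slot <- round(tr$t[-length(tr$t)] / dt)
    keep <- nv > 0
    list(slot = slot[keep], u = v[keep, , drop = FALSE] / nv[keep])
  })
  dots <- numeric(0)
  times <- numeric(0)
  nt <- length(tab)
  for (k in seq_len(nt - 1)) {
    for (m in (k + 1):nt) {
      common <- intersect(tab[[k]]$slot, tab[[m]]$slot)
      if (length(common) == 0) next
      ik <- match(common, tab[[k]]$slot)
      im <- match(common, tab[[m]]$slot)
      d <- rowSums(
        tab[[k]]$u[ik, , drop = FALSE] * tab[[m]]$u[im, , drop = FALSE]
      )
      dots <- c(dots, d)
      times <- c(times, common * dt)
    }
  }
  if (length(dots) == 0) {
    stop("no temporal overlap between any pair of tracks", call. = FALSE)
  }
  by_time <- stats::aggregate(
    list(corr = dots),
    by = list(t = times), FUN = mean
  )
  list(
    corr = mean(dots),
    se = stats::sd(dots) / sqrt(length(dots)),
    n_pairs = length(dots),
    by_time = by_time
  )
}
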