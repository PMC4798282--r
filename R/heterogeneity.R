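#' Sliding-window shape statistics over track mean speed
#'
#' Stratifies cells by how fast they move on average and asks how the
#' shape of the within-stratum speed distribution changes: for each mean-
#' speed window (width 0.125 um/s, advancing in 0.1 um/s increments) the
#' per-frame speeds of all member tracks are pooled and the method-of-
#' moments skew and (non-excess) kurtosis computed. Windows with fewer
#' than `min_n` pooled speeds are omitted. A decline of skew with window
#' mean speed is the signature of heterogeneous motility: slow cells
#' heavy-tailed, fast cells closer to Gaussian.
#'
#' @param tracks list of [track()] objects.
#' @param window_width window width in um/s.
#' @param step window increment in um/s.
#' @param min_n minimum pooled sample size per reported window.
#' @return Data frame with `window_center` (um/s), `window_lo`,
#'   `window_hi`, `n`, `n_tracks`, `skew`, `kurtosis`; empty (with a
#'   warning) if no window qualifies.
#' @export
sliding_skew <- function(tracks, window_width = 0.125, step = 0.1,
                         min_n = 10) {
  mean_speeds <- vapply(
    tracks, function(tr) mean(speeds(tr)), numeric(1)
  )
  speed_list <- lapply(tracks, speeds)
  lo <- seq(0, max(mean_speeds), by = step)
  rows <- lapply(lo, function(l) {
    member <- mean_speeds >= l & mean_speeds < l + window_width
    if (!any(member)) {
      return(NULL)
    }
    pooled <- unlist(speed_list[member], use.names = FALSE)
    if (length(pooled) < min_n) {
      return(NULL)
    }
    ms <- moment_stats(pooled)
    data.frame(
      window_center = l + window_width / 2, window_lo = l,
      window_hi = l + window_width, n = ms$n, n_tracks = sum(member),
      skew = ms$skew, kurtosis = ms$kurtosis
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no mean-speed window had enough data")
    return(data.frame(
      window_center = numeric(), window_lo = numeric(),
      window_hi = numeric(), n = integer(), n_tracks = integer(),
      skew = numeric(), kurtosis = numeric()
    ))
  }
  do.call(rbind, rows)
}

#' Distribution competition for slow and fast subpopulations
#'
#' Splits tracks by mean speed — slow below `slow_cut`, fast above
#' `fast_cut` (both in um/min) — pools the per-frame speeds within each
#' class and runs the full distribution competition ([rank_models()]).
#' Slow cells keeping a lognormal winner while fast cells flip to a
#' Gaussian/Maxwell winner is the heterogeneity signature.
#'
#' @param tracks list of [track()] objects.
#' @param slow_cut,fast_cut mean-speed cuts in um/min (`slow_cut <
#'   fast_cut`).
#' @param families candidate families passed to [rank_models()].
#' @return List with elements `slow` and `fast`, each a list with the
#'   ranked `fits` table, the `winner` family, `moments`
#'   ([moment_stats()]-style skew/kurtosis) and `n_tracks`; a class with
#'   no tracks is `NULL` with a warning.
#' @export
subpopulation_fits <- function(tracks, slow_cut = 5, fast_cut = 15,
                               families = c(
                                 "lognormal", "gaussian", "maxwell",
                                 "powerlaw"
                               )) {
  if (slow_cut >= fast_cut) {
    stop("slow_cut must be below fast_cut", call. = FALSE)
  }
  mean_speeds <- vapply(
    tracks, function(tr) mean(speeds(tr, unit = "um_min")), numeric(1)
  )
  one_class <- function(member, name) {
    if (!any(member)) {
      warning("no tracks in the ", name, " class; skipped")
      return(NULL)
    }
    pooled <- unlist(lapply(tracks[member], speeds), use.names = FALSE)
    tab <- rank_models(pooled, families)
    ms <- moment_stats(pooled)
    list(
      fits = tab, winner = tab$family[1],
      moments = list(skew = ms$skew, kurtosis = ms$kurtosis, n = ms$n),
      n_tracks = sum(member)
    )
  }
  list(
    slow = one_class(mean_speeds < slow_cut, "slow"),
    fast = one_class(mean_speeds > fast_cut, "fast")
  )
}
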