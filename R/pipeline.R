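#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages in dependency order — track input (or
#' synthetic generation), motility filtering, kinematics and distribution
#' competition, MSD/alpha, correlation, search-efficiency simulation,
#' hotspot detection and heterogeneity — writing one tidy CSV per stage
#' plus a JSON summary stamped with the seed. Every stochastic stage is
#' driven by the single `seed`.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{input}{path to a track CSV, or NULL to generate
#'       synthetically.}
#'     \item{generator}{an [generator_spec()] (used when `input` is
#'       NULL).}
#'     \item{stages}{character vector among `"filter"`, `"fit"`, `"msd"`,
#'       `"correlate"`, `"simulate"`, `"hotspots"`, `"heterogeneity"`;
#'       default all.}
#'     \item{seed}{integer seed (required).}
#'     \item{out_dir}{output directory.}
#'     \item{theta_max, cluster_radii, replicates, reps, detection_radius,
#'       cube_edge}{stage parameters with their standard defaults.}
#'   }
#' @return Named list of stage results (also written under `out_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  stages <- config$stages %||% c(
    "filter", "fit", "msd", "correlate", "simulate", "hotspots",
    "heterogeneity"
  )
  out_dir <- config$out_dir %||% "results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  theta_max <- config$theta_max %||% 15
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  fl <- stage("input", {
    if (!is.null(config$input)) {
      read_tracks(config$input)
    } else {
      gen_field(config$generator %||% generator_spec(seed = config$seed))
    }
  })
  results <- list(seed = config$seed, field_id = fl$field_id,
    n_tracks_in = length(fl$tracks))

  if ("filter" %in% stages) {
    fl <- stage("filter", filter_motile(fl))
    results$n_tracks_motile <- length(fl$tracks)
  }

  if ("fit" %in% stages) {
    results$fits <- stage("fit", {
      sp <- pooled_speeds(fl)
      st <- step_lengths(fl, theta_max)
      speed_tab <- rank_models(sp)
      step_tab <- rank_models(st)
      utils::write.csv(speed_tab,
        file.path(out_dir, "fits_speeds.csv"),
        row.names = FALSE
      )
      utils::write.csv(step_tab,
        file.path(out_dir, "fits_steps.csv"),
        row.names = FALSE
      )
      tail <- fit_powerlaw_tail(st)
      list(
        speed_winner = speed_tab$family[1],
        step_winner = step_tab$family[1],
        tail_mu = tail$mu, tail_fraction = tail$tail_fraction
      )
    })
  }

  if ("msd" %in% stages) {
    results$msd <- stage("msd", {
      curve <- ensemble_msd(fl$tracks)
      utils::write.csv(curve, file.path(out_dir, "msd.csv"),
        row.names = FALSE
      )
      af <- fit_alpha(curve)
      census <- alpha_census(fl, min_r2 = 0.8)
      pm <- population_motility(fl)
      list(
        alpha = af$alpha, r2 = af$r2,
        fractions = as.list(census$fractions), D = pm$D
      )
    })
  }

  if ("correlate" %in% stages) {
    results$correlation <- stage("correlate", {
      ac <- velocity_autocorrelation(fl$tracks)
      utils::write.csv(ac, file.path(out_dir, "autocorrelation.csv"),
        row.names = FALSE
      )
      cc <- cross_correlation(fl)
      list(cross_corr = cc$corr, cross_se = cc$se)
    })
  }

  if ("simulate" %in% stages) {
    results$efficiency <- stage("simulate", {
      tab <- efficiency_experiment(fl,
        models = config$models %||% walker_models,
        cluster_radii = config$cluster_radii %||% 10,
        replicates = config$replicates %||% 20,
        reps = config$reps %||% 1
      )
      utils::write.csv(tab, file.path(out_dir, "efficiency.csv"),
        row.names = FALSE
      )
      obs <- tab[tab$model == "observed", ]
      comps <- lapply(
        setdiff(unique(tab$model), "observed"),
        function(mdl) {
          m <- tab[tab$model == mdl, ]
          cm <- compare_models(
            m$efficiency_unique, obs$efficiency_unique
          )
          data.frame(model = mdl,
            pct_change_unique = cm$pct_change_median,
            p_all = cm$p_all)
        }
      )
      do.call(rbind, comps)
    })
  }

  if ("hotspots" %in% stages) {
    results$hotspots <- stage("hotspots", {
      counts <- grid_visits(fl, config$cube_edge %||% 20)
      thr <- null_threshold(fl,
        reps = config$reps %||% 10,
        cube_edge = config$cube_edge %||% 20
      )
      hs <- find_hotspots(counts, thr)
      hc <- classify_hot_cold(fl, hs)
      utils::write.csv(hc$labels,
        file.path(out_dir, "track_heat_labels.csv"),
        row.names = FALSE
      )
      list(
        threshold = as.numeric(thr),
        hotspot_fraction = hs$hotspot_fraction,
        n_hot_tracks = sum(hc$labels$label == "hot")
      )
    })
  }

  if ("heterogeneity" %in% stages) {
    results$heterogeneity <- stage("heterogeneity", {
      sk <- sliding_skew(fl$tracks)
      utils::write.csv(sk, file.path(out_dir, "sliding_skew.csv"),
        row.names = FALSE
      )
      sub <- subpopulation_fits(fl$tracks)
      list(
        n_windows = nrow(sk),
        slow_winner = if (!is.null(sub$slow)) sub$slow$winner else NA,
        fast_winner = if (!is.null(sub$fast)) sub$fast$winner else NA
      )
    })
  }

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(results,
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
  }
  invisible(results)
}
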