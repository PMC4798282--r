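#!/usr/bin/env Rscript
# Step-based statistical characterization of the reference field:
# distribution competition for speeds and step lengths (raw and
# track-normalized), the Clauset power-law tail diagnostic, the
# anomalous-diffusion exponent, the motility coefficient, and the
# directional persistence / drift correlations.

library(lymphwalk)

fl <- filter_motile(read_tracks("results/reference_tracks.csv",
  field_id = "reference"
))
message(length(fl$tracks), " motile tracks")

# -- speeds and step lengths ----------------------------------------------
sp <- pooled_speeds(fl)
steps <- step_lengths(fl, theta_max = 15)
message(sprintf(
  "mean speed %.2f um/min (median %.2f), %d per-frame speeds, %d steps",
  mean(sp) * 60, stats::median(sp) * 60, length(sp), length(steps)
))

speed_tab <- rank_models(sp)
step_tab <- rank_models(steps)
write.csv(speed_tab, "results/fits_speeds.csv", row.names = FALSE)
write.csv(step_tab, "results/fits_steps.csv", row.names = FALSE)
message(
  "best fit - speeds: ", speed_tab$family[1],
  "; step lengths: ", step_tab$family[1]
)

# normalized versions remove between-track mean differences
norm_sp <- unlist(normalize_by_track_mean(lapply(fl$tracks, speeds)))
norm_tab <- rank_models(norm_sp)
write.csv(norm_tab, "results/fits_speeds_normalized.csv", row.names = FALSE)
message("best fit - normalized speeds: ", norm_tab$family[1])

# -- is it a Levy walk? the power-law tail diagnostic ---------------------
tail <- fit_powerlaw_tail(steps)
message(sprintf(
  "power-law tail: mu = %.2f at xmin = %.2f um, keeping %.1f%% of steps",
  tail$mu, tail$xmin, 100 * tail$tail_fraction
))

# -- displacement analysis ------------------------------------------------
curve <- ensemble_msd(fl$tracks)
write.csv(curve, "results/msd.csv", row.names = FALSE)
af <- fit_alpha(curve)
message(sprintf(
  "ensemble MSD exponent alpha = %.2f (r^2 = %.3f)", af$alpha, af$r2
))
census <- alpha_census(fl, min_r2 = 0.8)
print(round(100 * census$fractions, 1))
pm <- population_motility(fl)
message(sprintf(
  "motility coefficient D = %.1f um^2/min (from %d of %d tracks with r^2 > 0.8)",
  pm$D, pm$n_used, pm$n_total
))

# -- persistence and drift ------------------------------------------------
ac <- velocity_autocorrelation(fl$tracks, max_delay = 300)
write.csv(ac, "results/autocorrelation.csv", row.names = FALSE)
decay <- ac$delay[which(ac$corr < 0.05)[1]]
message(sprintf(
  "velocity autocorrelation decays below 0.05 at ~%.0f s", decay
))
cc <- cross_correlation(fl)
message(sprintf(
  "cross-correlation (field drift check): %.4f +- %.4f (n = %d pairs)",
  cc$corr, cc$se, cc$n_pairs
))
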