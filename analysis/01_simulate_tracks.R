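#!/usr/bin/env Rscript
# Generate the synthetic reference field that stands in for a two-photon
# imaging field: 100 lognormal-modulated correlated-random-walk (LogMCRW)
# walkers in a 355 x 355 x 50 um field, 15 s frames, track durations
# 2-10 min, speeds lognormal(-2.5027, 0.9329) ln-um/s and gamma(2, 30 deg)
# turning angles. Writes the track table used by the downstream steps.

library(lymphwalk)

dir.create("results", showWarnings = FALSE)

spec <- generator_spec(model = "logmcrw", n_tracks = 100, seed = 20260928)
fl <- gen_field(spec, field_id = "reference")

message(sprintf(
  "generated %d tracks, frame_dt %.0f s, box %.0f x %.0f x %.0f um",
  length(fl$tracks), fl$frame_dt,
  fl$bbox["max", 1], fl$bbox["max", 2], fl$bbox["max", 3]
))

motile <- filter_motile(fl)
message(sprintf(
  "motility filter (path >= 17 um, disp^2 >= 300 um^2, >= 3 steps): %d of %d tracks retained",
  length(motile$tracks), length(fl$tracks)
))

write_tracks(fl, "results/reference_tracks.csv")
message("wrote results/reference_tracks.csv")
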