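test_that("grid visits count unique tracks per cube", {
  box <- rbind(min = c(0, 0, 0), max = c(100, 100, 100))
  # straight track through three cubes along x
  tr <- make_track(rbind(
    c(5, 5, 5), c(25, 5, 5), c(45, 5, 5)
  ), dt = 15, id = "a")
  # a looping track that stays inside one cube
  loop <- make_track(rbind(
    c(65, 65, 65), c(70, 70, 70), c(65, 65, 65), c(70, 70, 70)
  ), dt = 15, id = "b")
  # a second track crossing the first cube
  cross <- make_track(rbind(c(10, 10, 10), c(12, 10, 10)),
    dt = 15, id = "c"
  )
  fl <- field(list(tr, loop, cross), field_id = "g", bbox = box)
  counts <- grid_visits(fl)
  expect_equal(unname(counts[["0_0_0"]]), 2) # tr and cross
  expect_equal(unname(counts[["1_0_0"]]), 1)
  expect_equal(unname(counts[["2_0_0"]]), 1)
  expect_equal(unname(counts[["3_3_3"]]), 1) # loop counted once
  expect_equal(sum(counts), 5)
})

test_that("grid visits match the brute-force oracle and are stable", {
  set.seed(61)
  for (i in 1:10) {
    tracks <- lapply(1:6, function(k) {
      make_track(matrix(runif(8 * 3, 0, 120), ncol = 3), id = k)
    })
    fl <- field(tracks,
      field_id = "o",
      bbox = rbind(min = c(0, 0, 0), max = c(120, 120, 120))
    )
    got <- grid_visits(fl)
    want <- oracle_grid_visits(fl)
    expect_mapequal(as.list(got[order(names(got))]),
      as.list(want[order(names(want))]))
    # invariant to track ordering
    fl_rev <- field(rev(tracks),
      field_id = "o",
      bbox = fl$bbox
    )
    got_rev <- grid_visits(fl_rev)
    expect_mapequal(as.list(got_rev), as.list(got))
  }
})

test_that("grid visits are invariant to sub-cube jitter of inner points", {
  # positions well inside cubes stay in the same cube under small jitter
  set.seed(62)
  base <- matrix(c(
    10, 10, 10,
    30, 10, 10,
    30, 30, 10,
    50, 30, 10
  ), ncol = 3, byrow = TRUE)
  fl <- field(list(make_track(base, id = "j")),
    field_id = "jit",
    bbox = rbind(min = c(0, 0, 0), max = c(100, 100, 100))
  )
  ref <- grid_visits(fl)
  for (i in 1:5) {
    jit <- base + matrix(runif(length(base), -4, 4), ncol = 3)
    flj <- field(list(make_track(jit, id = "j")),
      field_id = "jit", bbox = fl$bbox
    )
    expect_mapequal(as.list(grid_visits(flj)), as.list(ref))
  }
})

test_that("null threshold is mean plus two standard deviations", {
  set.seed(63)
  fl <- gen_field(generator_spec(model = "logmcrw", n_tracks = 25, seed = 5))
  pars <- synthetic_params()
  thr <- null_threshold(fl, params = pars, reps = 3)
  counts <- attr(thr, "null_counts")
  expect_equal(
    as.numeric(thr), mean(counts) + 2 * sd(counts),
    tolerance = 1e-12
  )
  expect_error(null_threshold(fl, params = pars, reps = 1), "at least 2")
})

test_that("hotspot flagging uses a strict threshold", {
  counts <- c(a = 1L, b = 2L, c = 3L, d = 3L)
  hs <- find_hotspots(counts, 2)
  expect_setequal(hs$hotspot_keys, c("c", "d"))
  expect_equal(hs$hotspot_fraction, 0.5)
  # ties are not hotspots: threshold equal to every count flags nothing
  expect_equal(
    find_hotspots(c(a = 2L, b = 2L), 2)$hotspot_fraction, 0
  )
  expect_equal(
    find_hotspots(setNames(integer(0), character(0)), 2)$hotspot_fraction,
    0
  )
})

test_that("hot and cold labels partition tracks and compare groups", {
  set.seed(64)
  box <- rbind(min = c(0, 0, 0), max = c(200, 200, 40))
  # slow tracks confined to one corner cube region; fast tracks elsewhere
  slow <- lapply(1:6, function(i) {
    make_track(
      matrix(rep(c(10, 10, 10), 8), ncol = 3, byrow = TRUE) +
        matrix(rnorm(24, sd = 1), ncol = 3),
      id = paste0("s", i)
    )
  })
  fast <- lapply(1:6, function(i) {
    straight_track(
      n = 8, step = 6, origin = c(100, 50 + 10 * i, 20),
      id = paste0("f", i)
    )
  })
  fl <- field(c(slow, fast), field_id = "hc", bbox = box)
  counts <- grid_visits(fl)
  hs <- find_hotspots(counts, 2) # corner cube visited by all six slow
  labels <- classify_hot_cold(fl, hs)
  expect_equal(nrow(labels$labels), 12)
  expect_setequal(labels$labels$label, c("hot", "cold"))
  hot_ids <- labels$labels$track_id[labels$labels$label == "hot"]
  expect_true(all(grepl("^s", hot_ids)))
  # group comparison: slow hot tracks vs fast cold tracks
  expect_lt(
    labels$summary$median_speed_hot, labels$summary$median_speed_cold
  )
  expect_lt(labels$summary$p_speed, 0.05)
  # dwell accounting exists only for hot tracks
  expect_true(all(grepl("^s", labels$dwell$track_id)))

  # all-cold field warns and skips the comparison
  flc <- field(fast, field_id = "cold", bbox = box)
  hsc <- find_hotspots(grid_visits(flc), 99)
  expect_warning(out <- classify_hot_cold(flc, hsc), "skipped")
  expect_null(out$summary)
})

test_that("embedded attractive slow regions are recovered as hotspots", {
  set.seed(65)
  slow_pars <- synthetic_params(
    speed_meanlog = -3.2, angle_shape = 2, angle_scale = 60
  )
  region <- list(
    center = c(150, 150, 25), radius = 18,
    params = slow_pars, dwell_bias = 0.9,
    attract_weight = 0.8, attract_radius = 120
  )
  spec <- generator_spec(
    model = "logmcrw", n_tracks = 80, seed = 9, regions = list(region)
  )
  fl <- gen_hotspot_field(spec, start_bias = 0.3)
  mask <- attr(fl, "region_mask")
  expect_gt(length(mask), 0)
  thr <- null_threshold(fl, params = synthetic_params(), reps = 5)
  hs <- find_hotspots(grid_visits(fl), thr)
  sens <- mean(mask %in% hs$hotspot_keys)
  expect_gte(sens, 0.8)
  # hot tracks (region dwellers) are slower than cold tracks
  hc <- classify_hot_cold(fl, hs)
  expect_lt(
    hc$summary$median_speed_hot, hc$summary$median_speed_cold
  )
  expect_lt(hc$summary$p_speed, 0.05)
})
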