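test_that("target placement respects density and cluster structure", {
  box <- sim_box() # 6.3e6 um^3 -> 200 targets in 20 clusters
  set.seed(51)
  ts <- place_targets(box, cluster_radius = 10)
  expect_equal(nrow(ts$points), 200)
  expect_equal(length(unique(ts$cluster_id)), 20)
  # members stay inside the box and within the sphere of their centre
  expect_true(all(sweep(ts$points, 2, box$lo, `>=`)))
  expect_true(all(sweep(ts$points, 2, box$hi, `<=`)))
  for (cl in unique(ts$cluster_id)) {
    pts <- ts$points[ts$cluster_id == cl, , drop = FALSE]
    centre <- colMeans(pts)
    expect_lt(max(sqrt(rowSums(sweep(pts, 2, centre)^2))), 2 * 10)
  }
  expect_error(
    place_targets(sim_box(hi = c(10, 10, 10))), "zero targets"
  )
})

test_that("hopkins statistic matches the exhaustive oracle", {
  set.seed(52)
  box <- sim_box(hi = c(100, 100, 100))
  for (i in 1:10) {
    pts <- runif(20 * 3) * 100
    pts <- matrix(pts, ncol = 3)
    probes <- matrix(runif(8 * 3) * 100, ncol = 3)
    idx <- sample.int(20, 8)
    for (p in c(1, 3)) {
      expect_equal(
        lymphwalk:::hopkins_once(pts, probes, idx, power = p),
        oracle_hopkins(pts, probes, idx, power = p),
        tolerance = 1e-12
      )
    }
  }
})

test_that("hopkins separates coincident, clustered and uniform points", {
  set.seed(53)
  box <- sim_box()
  # all points coincident: w = 0 -> statistic 0
  same <- matrix(rep(c(100, 100, 25), each = 30), ncol = 3)
  expect_equal(hopkins_3d(same, box, m = 10, reps = 5), 0)
  # uniform: about one half
  unif <- place_targets(box, cluster_radius = NULL)
  expect_equal(
    hopkins_3d(unif$points, box, m = 20, reps = 50), 0.5,
    tolerance = 0.07
  )
  # clustering is monotone in sphere radius (10 < 20 < 40 < uniform)
  hops <- vapply(list(10, 20, 40, NULL), function(r) {
    mean(vapply(1:5, function(i) {
      ts <- place_targets(box, cluster_radius = r)
      hopkins_3d(ts$points, box, m = 20, reps = 40)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(hops) > 0))
  expect_error(hopkins_3d(unif$points, box, m = 4), "at least 5")
})

test_that("walker tracks respect box, budget and model definitions", {
  pars <- synthetic_params()
  box <- sim_box()
  set.seed(54)
  for (m in c("brownian", "crw", "lognormal", "logmcrw", "powerlaw")) {
    tr <- generate_walker_track(m, pars, box, duration = 600)
    expect_true(all(sweep(tr$pos, 2, box$lo, `>=`)))
    expect_true(all(sweep(tr$pos, 2, box$hi, `<=`)))
    expect_equal(n_positions(tr), 41) # 600 s at 15 s frames
  }
  # distance budget caps the path length (walker then idles in place)
  tr <- generate_walker_track("brownian", pars, box,
    duration = 600, distance_budget = 20
  )
  expect_lte(path_length(tr), 20)
  expect_equal(track_duration(tr), 600)

  # bootstrap on a single-pair pool reproduces that speed exactly
  # (big box: a wall reflection would shorten the recorded chord)
  single <- synthetic_params(
    pairs = data.frame(speed = 0.1, angle = 30)
  )
  tr <- generate_walker_track("bootstrap", single,
    sim_box(hi = c(5000, 5000, 5000)),
    start = c(2500, 2500, 2500), duration = 300
  )
  expect_equal(speeds(tr), rep(0.1, n_positions(tr) - 1), tolerance = 1e-10)

  expect_error(
    generate_walker_track("wiener", pars, box), "arg"
  )
})

test_that("contact detection matches the scalar point-segment oracle", {
  set.seed(55)
  for (i in 1:20) {
    pts <- matrix(runif(15 * 3, 0, 50), ncol = 3)
    a <- runif(3, 0, 50)
    b <- runif(3, 0, 50)
    got <- lymphwalk:::point_segment_distance(pts, a, b)
    want <- apply(pts, 1, oracle_point_seg, a = a, b = b)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # degenerate zero-length segment
  p <- matrix(c(1, 1, 1), 1)
  expect_equal(
    lymphwalk:::point_segment_distance(p, c(0, 0, 0), c(0, 0, 0)),
    sqrt(3)
  )
})

test_that("search counts unique and total contacts per the contract", {
  box <- sim_box(hi = c(400, 400, 50))
  # a 10-minute straight track passing 5 um from a single target
  tr <- straight_track(n = 41, step = 2, dt = 15, origin = c(10, 10, 25))
  targets <- list(
    points = matrix(c(50, 15, 25), 1), cluster_id = 1L,
    cluster_radius = NULL, density = NA, box = box
  )
  res <- run_search(list(tr), targets)
  expect_equal(res$unique_contacts, 1)
  expect_equal(res$total_contacts, 1)
  expect_equal(res$efficiency_unique, 0.1)

  # no target within reach
  far <- targets
  far$points <- matrix(c(50, 200, 25), 1)
  expect_equal(run_search(list(tr), far)$unique_contacts, 0)

  # a path that leaves and re-enters the detection sphere:
  # unique 1, total 2 under re-entry counting
  zig <- make_track(rbind(
    c(0, 0, 0), c(20, 0, 0), c(40, 0, 0), c(20, 0, 0), c(0, 0, 0)
  ), dt = 15)
  one <- list(
    points = matrix(c(0, 5, 0), 1), cluster_id = 1L,
    cluster_radius = NULL, density = NA, box = box
  )
  res2 <- run_search(list(zig), one)
  expect_equal(res2$unique_contacts, 1)
  expect_equal(res2$total_contacts, 2)
  # presence counting instead counts in-contact frame intervals
  res3 <- run_search(list(zig), one, total_mode = "presence")
  expect_equal(res3$total_contacts, 2)
})

test_that("contacts are monotone in detection radius and unique <= total", {
  set.seed(56)
  box <- sim_box()
  ts <- place_targets(box, cluster_radius = 20)
  pars <- synthetic_params()
  tracks <- lapply(1:10, function(i) {
    generate_walker_track("logmcrw", pars, box, duration = 450)
  })
  prev_u <- 0
  prev_t <- 0
  for (r in c(5, 10, 20)) {
    res <- run_search(tracks, ts, detection_radius = r)
    expect_gte(res$total_contacts, res$unique_contacts)
    expect_gte(res$unique_contacts, prev_u)
    expect_gte(res$total_contacts, prev_t)
    prev_u <- res$unique_contacts
    prev_t <- res$total_contacts
  }
})

test_that("model comparison reports percent change and both p-values", {
  set.seed(57)
  ref <- rlnorm(1000, 0, 0.5)
  same <- rlnorm(1000, 0, 0.5)
  cm <- compare_models(same, ref)
  expect_lt(abs(cm$pct_change_median), 10)
  expect_gt(cm$p_all, 0.05)

  shifted <- ref * 1.5
  cm2 <- compare_models(shifted, ref,
    model_rep = rep(1:10, each = 100), ref_rep = rep(1:10, each = 100)
  )
  expect_equal(cm2$pct_change_median, 50, tolerance = 5)
  expect_lt(cm2$p_all, 1e-3)
  expect_lt(cm2$p_median, 0.05)
  expect_true(is.finite(cm2$ci95))

  expect_error(compare_models(numeric(0), ref), "at least 2")
})

test_that("efficiency experiment returns a tidy self-consistent table", {
  set.seed(58)
  fl <- gen_field(generator_spec(model = "logmcrw", n_tracks = 12, seed = 7))
  tab <- efficiency_experiment(fl,
    models = c("brownian", "logmcrw"),
    cluster_radii = 10, replicates = 4, reps = 2
  )
  expect_setequal(
    unique(tab$model), c("observed", "brownian", "logmcrw")
  )
  expect_equal(nrow(tab), 3 * 4 * 2)
  expect_true(all(tab$efficiency_total >= tab$efficiency_unique - 1e-12))
  # observed vs observed is exactly zero change
  obs <- tab$efficiency_unique[tab$model == "observed"]
  expect_equal(
    compare_models(obs, obs)$pct_change_median, 0
  )
})
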