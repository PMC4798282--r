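test_that("closed-form MLEs are exact where closed forms exist", {
  # gaussian on {1, 2, 3}: mean 2, MLE sd sqrt(2/3)
  fit <- fit_mle(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 2), "gaussian")
  expect_equal(unname(fit$params["mean"]), 2)
  expect_equal(unname(fit$params["sd"]), sqrt(mean((c(
    1, 2, 3, 1, 2, 3, 1, 2, 3, 2
  ) - 2)^2)))

  # maxwell closed form a^2 = sum(x^2) / (3n), checked against the sum
  set.seed(2)
  x <- rmaxwell(500, a = 2)
  fit <- fit_mle(x, "maxwell")
  expect_equal(unname(fit$params["a"]), sqrt(sum(x^2) / (3 * length(x))))
  expect_equal(unname(fit$params["a"]), 2, tolerance = 0.05)

  # exponential: rate = 1 / mean
  x <- rexp(200, rate = 3)
  expect_equal(
    unname(fit_mle(x, "exponential")$params["rate"]), 1 / mean(x)
  )
})

test_that("lognormal and gamma parameters are recovered from big samples", {
  set.seed(3)
  x <- exp(rnorm(1e5)) # lognormal meanlog 0, sdlog 1
  fit <- fit_mle(x, "lognormal")
  expect_equal(unname(fit$params["meanlog"]), 0, tolerance = 0.01)
  expect_equal(unname(fit$params["sdlog"]), 1, tolerance = 0.01)

  g <- rgamma(2e4, shape = 2.5, scale = 30)
  fit <- fit_mle(g, "gamma")
  expect_equal(unname(fit$params["shape"]), 2.5, tolerance = 0.05)
  expect_equal(unname(fit$params["scale"]), 30, tolerance = 1)
})

test_that("fit_mle validates its inputs", {
  expect_error(fit_mle(1:5, "lognormal"), "at least 10")
  expect_error(fit_mle(c(-1, 1:10), "lognormal"), "positive")
  expect_error(fit_mle(rep(2, 20), "powerlaw"), "degenerate")
  # gaussian accepts negatives (it is the untruncated reference)
  expect_silent(fit_mle(rnorm(20), "gaussian"))
})

test_that("fitted parameters maximize the likelihood", {
  set.seed(11)
  samples <- list(
    lognormal = rlnorm(400, -2.5, 0.9),
    gaussian = rnorm(400, 5, 2),
    maxwell = rmaxwell(400, 1.5),
    gamma = rgamma(400, 2, scale = 3)
  )
  for (fam in names(samples)) {
    x <- samples[[fam]]
    fit <- fit_mle(x, fam)
    for (j in seq_along(fit$params)) {
      for (eps in c(-0.01, 0.01)) {
        pert <- fit
        pert$params[j] <- pert$params[j] * (1 + eps)
        nlogl_pert <- -sum(log(pmax(
          dist_pdf(pert, x), .Machine$double.xmin
        )))
        expect_gte(nlogl_pert, fit$nlogl - 1e-8)
      }
    }
  }
})

test_that("power-law tail fitting recovers Pareto ground truth", {
  set.seed(13)
  x <- rpowerlaw(1e4, mu = 2.5, xmin = 1)
  tail <- fit_powerlaw_tail(x)
  expect_equal(tail$mu, 2.5, tolerance = 0.125) # within 5%
  expect_lte(tail$xmin, quantile(x, 0.1)) # within one sample decile
  expect_gte(tail$tail_fraction, 0.9)
})

test_that("power-law tail fitting rejects most of a lognormal body", {
  set.seed(14)
  x <- rlnorm(5e3, 0.48, 0.92)
  tail <- fit_powerlaw_tail(x)
  expect_lt(tail$tail_fraction, 0.7)
  expect_error(fit_powerlaw_tail(rep(1, 100)), "identical")
})

test_that("goodness-of-fit panel is coherent", {
  set.seed(15)
  x <- rlnorm(500, 0, 1)
  fit <- fit_mle(x, "lognormal")
  panel <- gof(fit, x)
  expect_equal(panel$k, 2)
  # AICc exceeds plain AIC by the positive correction
  expect_gt(panel$aicc, 2 * panel$k + 2 * panel$nlogl)
  expect_true(panel$ks >= 0 && panel$ks <= 1)
  expect_true(is.finite(panel$ad) && is.finite(panel$chi2))

  # KS distance of a well-specified fit shrinks with sample size
  ks_at <- function(n) {
    xx <- rlnorm(n, 0, 1)
    gof(fit_mle(xx, "lognormal"), xx)$ks
  }
  expect_gt(ks_at(100), ks_at(5e4))

  expect_error(gof(fit, rlnorm(3)), "AICc")
})

test_that("model ranking identifies the generating family", {
  set.seed(16)
  # lognormal data: lognormal must rank first of the standard four
  x <- rlnorm(5e3, -2.5, 0.93)
  tab <- rank_models(x)
  expect_equal(tab$family[1], "lognormal")
  expect_equal(tab$rank, 1:4)
  # nlogl ordering is respected
  expect_true(!is.unsorted(tab$nlogl))

  # near-symmetric positive gaussian data (mean >> sd): gaussian beats
  # lognormal, the fast-cell signature
  y <- rnorm(5e3, mean = 20, sd = 2)
  y <- y[y > 0]
  tab2 <- rank_models(y, c("lognormal", "gaussian", "maxwell"))
  expect_lt(
    which(tab2$family == "gaussian"), which(tab2$family == "lognormal")
  )

  expect_error(rank_models(x, "lognormal"), "at least two")
})

test_that("maxwell and powerlaw distribution helpers are self-consistent", {
  a <- 1.7
  xs <- seq(0.01, 8, length.out = 200)
  # pmaxwell is the integral of dmaxwell
  num <- cumsum(dmaxwell(xs, a)) * diff(xs)[1]
  expect_equal(pmaxwell(xs, a), num, tolerance = 0.01)
  expect_equal(qmaxwell(pmaxwell(2.2, a), a), 2.2, tolerance = 1e-8)
  expect_equal(qpowerlaw(ppowerlaw(3, 2.5, 1), 2.5, 1), 3, tolerance = 1e-10)
})
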