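#' Maxwell (Maxwell-Boltzmann) distribution
#'
#' Speed distribution of 3D Brownian motion: f(x) = sqrt(2/pi) x^2
#' exp(-x^2 / (2 a^2)) / a^3 for x >= 0 and scale `a > 0`. X^2/(2a^2) is
#' Gamma(3/2, 1), which gives the CDF and quantiles.
#'
#' @param x,q,p numeric vectors.
#' @param n number of draws.
#' @param a scale parameter (> 0).
#' @name maxwell
NULL

#' @rdname maxwell
#' @export
dmaxwell <- function(x, a) {
  out <- numeric(length(x))
  ok <- x >= 0
  out[ok] <- sqrt(2 / pi) * x[ok]^2 * exp(-x[ok]^2 / (2 * a^2)) / a^3
  out
}

#' @rdname maxwell
#' @export
pmaxwell <- function(q, a) {
  out <- numeric(length(q))
  ok <- q > 0
  out[ok] <- stats::pgamma(q[ok]^2 / (2 * a^2), shape = 1.5)
  out
}

#' @rdname maxwell
#' @export
qmaxwell <- function(p, a) {
  a * sqrt(2 * stats::qgamma(p, shape = 1.5))
}

#' @rdname maxwell
#' @export
rmaxwell <- function(n, a) {
  a * sqrt(2 * stats::rgamma(n, shape = 1.5))
}

#' Continuous power-law (Pareto) distribution
#'
#' P(x) = ((mu - 1) / x_min) (x / x_min)^(-mu) for x >= x_min, the
#' step-length law of an ideal Levy walk (1 < mu <= 3 gives the
#' superdiffusive regime).
#'
#' @param x,q,p numeric vectors.
#' @param n number of draws.
#' @param mu exponent (> 1).
#' @param xmin lower support bound (> 0).
#' @name powerlaw
NULL

#' @rdname powerlaw
#' @export
dpowerlaw <- function(x, mu, xmin) {
  out <- numeric(length(x))
  ok <- x >= xmin
  out[ok] <- (mu - 1) / xmin * (x[ok] / xmin)^(-mu)
  out
}

#' @rdname powerlaw
#' @export
ppowerlaw <- function(q, mu, xmin) {
  out <- numeric(length(q))
  ok <- q >= xmin
  out[ok] <- 1 - (q[ok] / xmin)^(1 - mu)
  out
}

#' @rdname powerlaw
#' @export
qpowerlaw <- function(p, mu, xmin) {
  xmin * (1 - p)^(-1 / (mu - 1))
}

#' @rdname powerlaw
#' @export
rpowerlaw <- function(n, mu, xmin) {
  qpowerlaw(stats::runif(n), mu, xmin)
}

lw_families <- c(
  "lognormal", "gaussian", "maxwell", "exponential", "gamma", "powerlaw"
)

n_params <- c(
  lognormal = 2L, gaussian = 2L, maxwell = 1L, exponential = 1L,
  gamma = 2L, powerlaw = 1L
)

#' Maximum-likelihood fit of a candidate distribution
#'
#' Fits one of the candidate speed / step-length families by maximum
#' likelihood. Closed forms are used where they exist: lognormal (mean and
#' SD of logs), Gaussian (sample mean, MLE SD), Maxwell (a^2 =
#' sum(x^2)/(3n)), exponential (1/mean); the gamma shape is found by
#' one-dimensional optimization of the profile log-likelihood; the
#' power-law exponent uses the Hill estimator with `xmin` fixed at the
#' smallest observed value (for a free tail cutoff see
#' [fit_powerlaw_tail()]).
#'
#' Gaussian fits to positive data are deliberately plain (untruncated)
#' Gaussians — the Brownian-speed reference model — so their likelihoods
#' are comparable across tables.
#'
#' @param samples numeric vector, n >= 10; strictly positive for families
#'   with positive support.
#' @param family one of `"lognormal"`, `"gaussian"`, `"maxwell"`,
#'   `"exponential"`, `"gamma"`, `"powerlaw"`.
#' @return A `DistributionFit`: list with `family`, `params` (named),
#'   `n`, `nlogl` (negative log-likelihood), class `"lw_fit"`.
#' @export
fit_mle <- function(samples, family = lw_families) {
  family <- match.arg(family)
  x <- as.numeric(samples)
  if (length(x) < 10) stop("need at least 10 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)
  if (family != "gaussian" && any(x <= 0)) {
    stop("samples must be positive for family ", family, call. = FALSE)
  }
  n <- length(x)
  params <- switch(family,
    lognormal = {
      lx <- log(x)
      c(meanlog = mean(lx), sdlog = sqrt(mean((lx - mean(lx))^2)))
    },
    gaussian = c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2))),
    maxwell = c(a = sqrt(sum(x^2) / (3 * n))),
    exponential = c(rate = 1 / mean(x)),
    gamma = fit_gamma_mle(x),
    powerlaw = {
      xmin <- min(x)
      s <- sum(log(x / xmin))
      if (s <= 0) stop("degenerate sample for power-law fit", call. = FALSE)
      c(mu = 1 + n / s, xmin = xmin)
    }
  )
  if (any(!is.finite(params))) {
    stop("MLE did not produce finite parameters", call. = FALSE)
  }
  fit <- structure(
    list(family = family, params = params, n = n, nlogl = NA_real_),
    class = "lw_fit"
  )
  fit$nlogl <- -sum(log(pmax(dist_pdf(fit, x), .Machine$double.xmin)))
  fit
}

# profile-likelihood gamma MLE: scale = mean/shape for fixed shape
fit_gamma_mle <- function(x) {
  mx <- mean(x)
  mlx <- mean(log(x))
  nll <- function(shape) {
    scale <- mx / shape
    -sum(stats::dgamma(x, shape = shape, scale = scale, log = TRUE))
  }
  # moment estimator as bracket centre
  s0 <- mx^2 / stats::var(x)
  opt <- stats::optimize(nll, c(s0 / 50, s0 * 50))
  c(shape = opt$minimum, scale = mx / opt$minimum)
}

#' Density, CDF and quantiles of a fitted distribution
#'
#' @param fit an `lw_fit` from [fit_mle()].
#' @param x,q,p numeric vectors.
#' @export
dist_pdf <- function(fit, x) {
  p <- fit$params
  switch(fit$family,
    lognormal = stats::dlnorm(x, p["meanlog"], p["sdlog"]),
    gaussian = stats::dnorm(x, p["mean"], p["sd"]),
    maxwell = dmaxwell(x, p["a"]),
    exponential = stats::dexp(x, p["rate"]),
    gamma = stats::dgamma(x, shape = p["shape"], scale = p["scale"]),
    powerlaw = dpowerlaw(x, p["mu"], p["xmin"])
  )
}

#' @rdname dist_pdf
#' @export
dist_cdf <- function(fit, q) {
  p <- fit$params
  switch(fit$family,
    lognormal = stats::plnorm(q, p["meanlog"], p["sdlog"]),
    gaussian = stats::pnorm(q, p["mean"], p["sd"]),
    maxwell = pmaxwell(q, p["a"]),
    exponential = stats::pexp(q, p["rate"]),
    gamma = stats::pgamma(q, shape = p["shape"], scale = p["scale"]),
    powerlaw = ppowerlaw(q, p["mu"], p["xmin"])
  )
}

#' @rdname dist_pdf
#' @export
dist_quantile <- function(fit, p) {
  pp <- fit$params
  switch(fit$family,
    lognormal = stats::qlnorm(p, pp["meanlog"], pp["sdlog"]),
    gaussian = stats::qnorm(p, pp["mean"], pp["sd"]),
    maxwell = qmaxwell(p, pp["a"]),
    exponential = stats::qexp(p, pp["rate"]),
    gamma = stats::qgamma(p, shape = pp["shape"], scale = pp["scale"]),
    powerlaw = qpowerlaw(p, pp["mu"], pp["xmin"])
  )
}

#' @export
print.lw_fit <- function(x, ...) {
  cat(sprintf(
    "<lw_fit %s: %s; n = %d, nlogl = %.4g>\n",
    x$family,
    paste(names(x$params), signif(x$params, 5), sep = " = ", collapse = ", "),
    x$n, x$nlogl
  ))
  invisible(x)
}

#' Clauset-style power-law tail fit
#'
#' Estimates where a power-law tail begins by scanning candidate lower
#' cutoffs x_min: for each candidate the tail exponent is the continuous
#' MLE mu = 1 + m / sum(log(x_i / x_min)) over the m samples >= x_min, and
#' the Kolmogorov-Smirnov distance between the tail's empirical CDF and the
#' fitted power-law CDF is recorded. The x_min with the best (smallest) KS
#' distance wins; the fraction of samples retained in the tail measures how
#' much of the data a power law can actually describe.
#'
#' Candidate cutoffs are the unique sample values, thinned to at most
#' `max_candidates` quantile-spaced values for large samples (exhaustive
#' search is quadratic).
#'
#' @param samples positive numeric vector, n >= 50.
#' @param max_candidates cap on the number of candidate cutoffs.
#' @return A `PowerLawTail`: list with `mu`, `xmin`, `tail_fraction`,
#'   `ks_at_xmin`, `n_tail`, `n`, class `"lw_pltail"`.
#' @export
fit_powerlaw_tail <- function(samples, max_candidates = 1000) {
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 50) stop("need at least 50 samples", call. = FALSE)
  if (any(x <= 0)) stop("samples must be positive", call. = FALSE)
  cand <- unique(x)
  cand <- cand[-length(cand)] # at least 2 distinct tail values needed
  if (length(cand) == 0) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  if (length(cand) > max_candidates) {
    cand <- unique(stats::quantile(cand,
      probs = seq(0, 1, length.out = max_candidates),
      names = FALSE, type = 1
    ))
  }
  lx <- log(x)
  best <- NULL
  for (xm in cand) {
    i0 <- which(x >= xm)[1]
    m <- n - i0 + 1L
    if (m < 10) next
    tail_lx <- lx[i0:n]
    s <- sum(tail_lx - log(xm))
    if (s <= 0) next
    mu <- 1 + m / s
    fitted_cdf <- 1 - exp((1 - mu) * (tail_lx - log(xm)))
    emp_hi <- seq_len(m) / m
    ks <- max(pmax(emp_hi - fitted_cdf, fitted_cdf - (emp_hi - 1 / m)))
    if (is.null(best) || ks < best$ks_at_xmin) {
      best <- list(
        mu = mu, xmin = xm, tail_fraction = m / n,
        ks_at_xmin = ks, n_tail = m, n = n
      )
    }
  }
  if (is.null(best)) {
    stop("no candidate cutoff leaves a usable tail (>= 10 samples)",
      call. = FALSE
    )
  }
  structure(best, class = "lw_pltail")
}

#' @export
print.lw_pltail <- function(x, ...) {
  cat(sprintf(
    "<power-law tail: mu = %.2f, xmin = %.2f um, %.1f%% of steps in tail>\n",
    x$mu, x$xmin, 100 * x$tail_fraction
  ))
  invisible(x)
}

#' Goodness-of-fit panel for a fitted distribution
#'
#' Computes the panel used to compare candidate models on the same sample:
#' negative log-likelihood, corrected AIC, BIC, Kolmogorov-Smirnov and
#' Anderson-Darling statistics against the fitted CDF (no binning), and a
#' chi-squared statistic from equal-probability bins (ceiling(sqrt(n))
#' bins, the one place binning is unavoidable).
#'
#' @param fit an `lw_fit` produced from `samples`.
#' @param samples the sample the fit was produced from.
#' @return List with `nlogl`, `aicc`, `bic`, `ks`, `ad`, `chi2`, `k`, `n`.
#' @export
gof <- function(fit, samples) {
  x <- sort(as.numeric(samples))
  n <- length(x)
  k <- n_params[[fit$family]]
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  nlogl <- -sum(log(pmax(dist_pdf(fit, x), .Machine$double.xmin)))
  aicc <- 2 * k + 2 * nlogl + 2 * k * (k + 1) / (n - k - 1)
  bic <- k * log(n) + 2 * nlogl
  cdf <- dist_cdf(fit, x)
  i <- seq_len(n)
  ks <- max(pmax(i / n - cdf, cdf - (i - 1) / n))
  cc <- pmin(pmax(cdf, 1e-12), 1 - 1e-12)
  ad <- -n - mean((2 * i - 1) * (log(cc) + log(1 - rev(cc))))
  nb <- ceiling(sqrt(n))
  brk <- dist_quantile(fit, seq(0, 1, length.out = nb + 1))
  brk[1] <- -Inf
  brk[nb + 1] <- Inf
  obs <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = nb)
  expd <- n / nb
  chi2 <- sum((obs - expd)^2 / expd)
  list(
    nlogl = nlogl, aicc = aicc, bic = bic, ks = ks, ad = ad,
    chi2 = chi2, k = k, n = n
  )
}

#' Rank candidate distributions on one sample
#'
#' Fits every requested family by MLE and orders them by negative
#' log-likelihood (most negative first, i.e. best fit first); the full
#' goodness-of-fit panel is attached so that AICc/BIC can confirm the
#' ranking is not an artefact of parameter count.
#'
#' @param samples numeric vector.
#' @param families character vector of at least two family names.
#' @return Data frame, one row per family in rank order, with parameter
#'   columns and the panel statistics; the fits themselves are attached as
#'   attribute `"fits"`.
#' @export
rank_models <- function(samples,
                        families = c(
                          "lognormal", "gaussian", "maxwell", "powerlaw"
                        )) {
  families <- match.arg(families, lw_families, several.ok = TRUE)
  if (length(families) < 2) {
    stop("need at least two families to rank", call. = FALSE)
  }
  fits <- lapply(families, function(f) fit_mle(samples, f))
  panels <- lapply(fits, gof, samples = samples)
  ord <- order(vapply(panels, `[[`, numeric(1), "nlogl"))
  fits <- fits[ord]
  panels <- panels[ord]
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    params = vapply(fits, function(f) {
      paste(names(f$params), signif(f$params, 5),
        sep = "=", collapse = ", "
      )
    }, character(1)),
    nlogl = vapply(panels, `[[`, numeric(1), "nlogl"),
    aicc = vapply(panels, `[[`, numeric(1), "aicc"),
    bic = vapply(panels, `[[`, numeric(1), "bic"),
    ks = vapply(panels, `[[`, numeric(1), "ks"),
    ad = vapply(panels, `[[`, numeric(1), "ad"),
    chi2 = vapply(panels, `[[`, numeric(1), "chi2"),
    rank = seq_along(fits)
  )
  attr(tab, "fits") <- fits
  tab
}
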