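#' Gamma prior on fitness
#'
#' Prior on the fitness of the focal allele, \eqn{\varphi = 1 + \sigma}
#' (support \eqn{\varphi > 0}, i.e. \eqn{\sigma > -1}). The default
#' shape and rate of 0.001 give a prior that is essentially flat over
#' the range of selection coefficients seen in experimental evolution,
#' so it contributes almost nothing to the posterior relative to the
#' likelihood.
#'
#' @param a0 Shape (> 0); default 0.001.
#' @param b0 Rate (> 0); default 0.001.
#' @return An object of class `gamma_prior`.
#' @export
gamma_prior <- function(a0 = 0.001, b0 = 0.001) {
  if (!is.finite(a0) || !is.finite(b0) || a0 <= 0 || b0 <= 0)
    stop("prior shape and rate must be positive")
  structure(list(a0 = a0, b0 = b0), class = "gamma_prior")
}

#' Unnormalised log posterior of the selection coefficient
#'
#' Log-likelihood of the locus at `sigma` plus the log gamma-prior
#' density evaluated at the fitness \eqn{1 + \sigma}. Normalisation is
#' dropped; only differences across a grid matter downstream.
#'
#' @inheritParams locus_loglik
#' @param prior A [gamma_prior()].
#' @return Unnormalised log posterior density (real scalar).
#' @export
log_posterior_at <- function(sigma, counts, N, emission = emission_model(),
                             prior = gamma_prior(),
                             method = c("forward", "plugin"), cache = NULL) {
  if (sigma <= -1) stop("'sigma' must exceed -1")
  locus_loglik(counts, sigma, N, emission, method, cache) +
    stats::dgamma(1 + sigma, shape = prior$a0, rate = prior$b0, log = TRUE)
}

#' Grid of selection-coefficient values for the surface fit
#'
#' Two-stage placement: a coarse scan of the log-likelihood over
#' `coarse_points` equally spaced values on `coarse_range` (per
#' generation), then five final points centred on the interpolated peak
#' (parabola through the three scan values around the argmax) and
#' spanning three posterior standard deviations as judged by the
#' local curvature, never more than two coarse steps each side. The
#' continuous placement matters when the posterior is much narrower
#' than the coarse step (large N): snapping the window to the lattice
#' would make the fitted tail mass, and hence the Bayes factor, jump
#' erratically between neighbouring loci. An argmax at the edge of the
#' coarse range keeps the lattice window ending at the boundary, never
#' beyond it; a completely flat scan (e.g. no data) falls back to the
#' symmetric default window around 0.
#'
#' @inheritParams locus_loglik
#' @param coarse_range Numeric length-2 range of the coarse scan;
#'   default `c(-0.5, 0.5)`.
#' @param coarse_points Number of coarse points; default 21.
#' @return Numeric vector of 5 strictly increasing sigma values
#'   (> -1).
#' @export
choose_grid <- function(counts, N, emission = emission_model(),
                        coarse_range = c(-0.5, 0.5), coarse_points = 21L,
                        method = c("forward", "plugin"), cache = NULL) {
  .coarse_scan(counts, N, emission, coarse_range, coarse_points,
               method, cache)$fine_points
}

.coarse_scan <- function(counts, N, emission, coarse_range, coarse_points,
                         method, cache) {
  if (coarse_points < 5L) stop("need at least 5 coarse points")
  if (coarse_range[1] <= -1) stop("coarse range must stay above sigma = -1")
  pts <- seq(coarse_range[1], coarse_range[2], length.out = coarse_points)
  h <- pts[2L] - pts[1L]
  ll <- vapply(pts, function(s) locus_loglik(counts, s, N, emission, method, cache),
               numeric(1))
  lattice_window <- function(i) {
    i <- min(max(i, 3L), coarse_points - 2L)
    pts[(i - 2L):(i + 2L)]
  }
  if (diff(range(ll)) < 1e-9)                    # flat: default window around 0
    return(list(points = pts, loglik = ll,
                fine_points = lattice_window(which.min(abs(pts)))))
  imax <- which.max(ll)
  if (imax == 1L || imax == coarse_points)       # edge max: window ends at the
    return(list(points = pts, loglik = ll,       # boundary, never beyond
                fine_points = lattice_window(imax)))
  # continuous placement: parabola through the three points around the
  # argmax gives the interpolated peak and local curvature; the window
  # spans three posterior standard deviations, capped at the default
  # two coarse steps and floored to keep the design well conditioned
  d1 <- (ll[imax + 1L] - ll[imax - 1L]) / (2 * h)
  d2 <- (ll[imax + 1L] - 2 * ll[imax] + ll[imax - 1L]) / h^2
  if (d2 >= 0)
    return(list(points = pts, loglik = ll, fine_points = lattice_window(imax)))
  s_star <- min(max(pts[imax] - d1 / d2, pts[1L]), pts[coarse_points])
  # +-3 posterior sd: wide enough that the true coefficient falls inside
  # the window with high probability despite estimation noise
  w <- min(2 * h, max(3 / sqrt(-d2), h / 10))
  lo <- s_star - w; hi <- s_star + w
  if (hi > pts[coarse_points]) { lo <- lo - (hi - pts[coarse_points]); hi <- pts[coarse_points] }
  if (lo < pts[1L]) { hi <- min(hi + (pts[1L] - lo), pts[coarse_points]); lo <- pts[1L] }
  list(points = pts, loglik = ll, fine_points = seq(lo, hi, length.out = 5L))
}

#' Evaluated posterior grid
#'
#' Pairs sigma values with their unnormalised log posterior densities.
#'
#' @param points Strictly increasing sigma values (>= 5 for the
#'   standard pipeline, >= 3 to be fittable), all > -1.
#' @param log_post Log posterior densities at `points`.
#' @return An object of class `sigma_grid`.
#' @export
sigma_grid <- function(points, log_post) {
  if (length(points) != length(log_post))
    stop("'points' and 'log_post' lengths differ")
  if (any(points <= -1)) stop("all grid points must exceed -1")
  if (any(diff(points) <= 0)) stop("'points' must be strictly increasing")
  structure(list(points = as.numeric(points), log_post = as.numeric(log_post)),
            class = "sigma_grid")
}

#' Least-squares gamma-surface fit to a log-posterior grid
#'
#' Fits the three-parameter surface
#' \deqn{\log p(\sigma \mid c, C) = c + (\alpha - 1)\log x - \beta x}
#' to the grid by ordinary least squares, where \eqn{x = 1 + \sigma} is
#' the fitness (the gamma density has support \eqn{x > 0}, so fitting
#' in fitness space admits negative selection coefficients down to
#' -1). The estimates are the closed-form minimisers in terms of the
#' grid moments
#' \eqn{s_1 = \sum x_i/n, s_2 = \sum y_i/n, s_3 = \sum x_i y_i/n,
#' s_4 = \sum \log x_i/n, s_5 = \sum x_i \log x_i/n,
#' s_6 = \sum y_i \log x_i/n, s_7 = \sum \log^2 x_i/n,
#' s_8 = \sum x_i^2/n}, and agree with a generic linear least-squares
#' solve on the design matrix \eqn{[1, \log x_i, -x_i]} to numerical
#' precision.
#'
#' A fit with \eqn{\hat\alpha \le 0} or \eqn{\hat\beta \le 0} is not a
#' valid gamma density; it is flagged `degenerate` and reported rather
#' than raised as an error.
#'
#' @param grid A [sigma_grid()] with at least 3 distinct points.
#' @return An object of class `gamma_posterior`: list with `alpha`,
#'   `beta`, `c`, logical `degenerate`, and (for valid fits) the
#'   summaries `mean_sigma`, `var_sigma`, `log_bf`, `bf_saturated` from
#'   [summarize_posterior()].
#' @export
fit_gamma_surface <- function(grid) {
  x <- 1 + grid$points
  y <- grid$log_post
  n <- length(x)
  if (n < 3L) stop("need at least 3 grid points")
  lx <- log(x)
  s1 <- sum(x) / n;      s2 <- sum(y) / n
  s3 <- sum(x * y) / n;  s4 <- sum(lx) / n
  s5 <- sum(x * lx) / n; s6 <- sum(y * lx) / n
  s7 <- sum(lx^2) / n;   s8 <- sum(x^2) / n
  den <- s1^2 * s7 - 2 * s1 * s4 * s5 + s4^2 * s8 + s5^2 - s7 * s8
  alpha <- (s1^2 * s6 + s1^2 * s7 - s1 * s2 * s5 - s1 * s3 * s4 -
              2 * s1 * s4 * s5 + s2 * s4 * s8 + s3 * s5 + s4^2 * s8 +
              s5^2 - s6 * s8 - s7 * s8) / den
  beta <- (-s1 * s2 * s7 + s1 * s4 * s6 + s2 * s4 * s5 - s3 * s4^2 +
             s3 * s7 - s5 * s6) / den
  cc <- (s1 * s3 * s7 - s1 * s5 * s6 + s2 * s5^2 - s2 * s7 * s8 -
           s3 * s4 * s5 + s4 * s6 * s8) / den
  gp <- list(alpha = alpha, beta = beta, c = cc,
             degenerate = !is.finite(alpha) || !is.finite(beta) ||
               alpha <= 0 || beta <= 0)
  if (!gp$degenerate) gp <- c(gp, summarize_posterior(alpha, beta))
  structure(gp, class = "gamma_posterior")
}

#' Posterior summaries from a fitted gamma surface
#'
#' The surface is a gamma density over fitness \eqn{\varphi = 1+\sigma}
#' with shape `alpha` and rate `beta`, so the posterior mean and
#' variance of the selection coefficient are
#' \eqn{\alpha/\beta - 1} and \eqn{\alpha/\beta^2}. The log Bayes
#' factor is the log posterior odds that the allele is selected versus
#' counter-selected, i.e. the odds across \eqn{\varphi = 1}:
#' \deqn{\log BF = \log\frac{1 - F(1)}{F(1)}}
#' with \eqn{F} the fitted gamma CDF. A CDF value of exactly 0 or 1 to
#' machine precision clamps the log BF to \eqn{\pm 709} and sets
#' `bf_saturated`. The conventional "very strong evidence" threshold is
#' \eqn{\log(0.99/0.01) \approx 4.6}.
#'
#' @param alpha,beta Positive shape and rate of the fitted gamma.
#' @return List with `mean_sigma`, `var_sigma`, `log_bf`,
#'   `bf_saturated`.
#' @export
summarize_posterior <- function(alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be positive")
  F1 <- stats::pgamma(1, shape = alpha, rate = beta)
  saturated <- FALSE
  if (F1 <= 0 || F1 >= 1) {
    log_bf <- if (F1 <= 0) 709 else -709
    saturated <- TRUE
  } else {
    log_bf <- log1p(-F1) - log(F1)
    if (!is.finite(log_bf) || abs(log_bf) > 709) {
      log_bf <- sign(log_bf) * 709
      saturated <- TRUE
    }
  }
  list(mean_sigma = alpha / beta - 1, var_sigma = alpha / beta^2,
       log_bf = log_bf, bf_saturated = saturated)
}

#' Full per-locus analysis
#'
#' Runs the pipeline for one locus: variance pre-filter; coarse
#' likelihood scan and 5-point grid placement; log posterior at the
#' grid; gamma-surface fit; posterior summaries. Filtered loci yield a
#' flagged result with no statistics; degenerate fits keep their
#' invalid shape/rate for diagnosis but `NA` summaries.
#'
#' @inheritParams choose_grid
#' @param prior A [gamma_prior()].
#' @param filter_threshold Variance threshold of the pre-filter.
#' @param filter_mode Variance statistic, see [frequency_variance()].
#' @return An object of class `locus_result`.
#' @export
analyse_locus <- function(counts, N, emission = emission_model(),
                          prior = gamma_prior(), filter_threshold = 0.01,
                          filter_mode = c("frequencies", "increments"),
                          coarse_range = c(-0.5, 0.5), coarse_points = 21L,
                          method = c("forward", "plugin"), cache = NULL) {
  verdict <- apply_filter(counts, filter_threshold, filter_mode)
  res <- list(chrom = counts$chrom, pos = counts$pos,
              mean_sigma = NA_real_, log_bf = NA_real_,
              alpha = NA_real_, beta = NA_real_,
              filtered = !verdict$passed, degenerate = FALSE,
              variance = verdict$variance)
  if (!verdict$passed) return(structure(res, class = "locus_result"))
  scan <- .coarse_scan(counts, N, emission, coarse_range, coarse_points,
                       method, cache)
  pts <- scan$fine_points
  # fine points are locus-specific: evaluate without memoising the models
  lp <- vapply(pts, function(s) locus_loglik(counts, s, N, emission, method,
                                             NULL), numeric(1)) +
    stats::dgamma(1 + pts, shape = prior$a0, rate = prior$b0, log = TRUE)
  gp <- fit_gamma_surface(sigma_grid(pts, lp))
  res$alpha <- gp$alpha
  res$beta <- gp$beta
  res$degenerate <- gp$degenerate
  if (!gp$degenerate) {
    res$mean_sigma <- gp$mean_sigma
    res$log_bf <- gp$log_bf
    res$var_sigma <- gp$var_sigma
    res$bf_saturated <- gp$bf_saturated
  }
  structure(res, class = "locus_result")
}
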