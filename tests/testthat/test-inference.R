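test_that("gamma surface fit recovers exact gamma log-densities with zero residual", {
  x <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  y <- 2.0 + (2 - 1) * log(x) - 3 * x
  gp <- fit_gamma_surface(sigma_grid(x - 1, y))
  expect_equal(gp$alpha, 2, tolerance = 1e-10)
  expect_equal(gp$beta, 3, tolerance = 1e-10)
  expect_equal(gp$c, 2, tolerance = 1e-10)
  fitted <- gp$c + (gp$alpha - 1) * log(x) - gp$beta * x
  expect_lt(max(abs(fitted - y)), 1e-10)

  # no log term -> exponential special case alpha = 1
  y2 <- 0.7 - 2.2 * x
  gp2 <- fit_gamma_surface(sigma_grid(x - 1, y2))
  expect_equal(gp2$alpha, 1, tolerance = 1e-10)
  expect_equal(gp2$beta, 2.2, tolerance = 1e-10)
})

test_that("closed-form moment estimator equals generic least squares", {
  set.seed(21)
  for (i in 1:25) {
    x <- sort(stats::runif(sample(5:9, 1), 0.3, 3))
    y <- stats::rnorm(length(x), sd = 3)
    gp <- fit_gamma_surface(sigma_grid(x - 1, y))
    co <- stats::coef(stats::lm(y ~ log(x) + I(-x)))
    expect_equal(gp$c, unname(co[1]), tolerance = 1e-8)
    expect_equal(gp$alpha, unname(co[2]) + 1, tolerance = 1e-8)
    expect_equal(gp$beta, unname(co[3]), tolerance = 1e-8)
  }
})

test_that("degenerate fits are flagged, not raised", {
  x <- c(0.5, 1, 1.5, 2, 2.5)
  gp <- fit_gamma_surface(sigma_grid(x - 1, 1 - 2 * log(x) - 0.5 * x))
  expect_true(gp$degenerate)   # alpha-hat = -1
  expect_null(gp$mean_sigma)
})

test_that("posterior summaries follow gamma moments and tail odds", {
  s <- summarize_posterior(2, 3)
  expect_equal(s$mean_sigma, 2 / 3 - 1)
  expect_equal(s$var_sigma, 2 / 9)
  # even odds at the median
  med_beta <- stats::qgamma(0.5, 2, 1)  # rate so that F(1) = 0.5
  expect_equal(summarize_posterior(2, med_beta)$log_bf, 0, tolerance = 1e-12)
  # saturation clamps
  sat <- summarize_posterior(200, 2)    # F(1) ~ 0 -> all mass above fitness 1
  expect_equal(sat$log_bf, 709)
  expect_true(sat$bf_saturated)
  expect_error(summarize_posterior(-1, 2), "positive")
})

test_that("default gamma prior is numerically inert", {
  # the prior's log-density variation across a fitted 5-point window is
  # negligible against the likelihood, so estimates barely move if the
  # prior is flattened to (near) improper
  scn <- sim_scenario(Ne = 100, p0 = 0.5, sigma = 0.05, seed = 22)
  panel <- generate_panel(scn, 3)
  cache <- model_cache()
  for (cts in panel$counts) {
    a <- analyse_locus(cts, 100, prior = gamma_prior(), cache = cache)
    b <- analyse_locus(cts, 100, prior = gamma_prior(1e-9, 1e-9), cache = cache)
    if (a$filtered || a$degenerate) next
    expect_equal(a$mean_sigma, b$mean_sigma, tolerance = 1e-4)
    expect_equal(a$log_bf, b$log_bf, tolerance = 1e-2)
  }
})

test_that("with zero-information data the posterior is the prior", {
  lc <- locus_counts("x", 1, matrix(0, 2, 3), matrix(0, 2, 3), c(0, 5, 10))
  pr <- gamma_prior(2, 1)
  for (s in c(-0.3, 0, 0.4))
    expect_equal(log_posterior_at(s, lc, 10, prior = pr),
                 stats::dgamma(1 + s, 2, 1, log = TRUE))
})

test_that("grid selection falls back, clamps, and stays on the coarse lattice", {
  # flat likelihood -> symmetric default window around 0
  flat <- locus_counts("x", 1, matrix(0, 1, 2), matrix(0, 1, 2), c(0, 10))
  expect_equal(choose_grid(flat, 8), seq(-0.1, 0.1, by = 0.05))
  # extreme rise -> argmax clamped at the top of the coarse range
  steep <- make_counts(rbind(c(0.05, 0.95)), coverage = 100,
                       generations = c(0, 2))
  g <- choose_grid(steep, 20)
  expect_equal(g, seq(0.3, 0.5, by = 0.05))
  expect_lte(max(g), 0.5)
})

test_that("final grid brackets the true coefficient for selected loci", {
  # strong-selection base-experiment loci; statistical property at n = 60
  scn <- sim_scenario(Ne = 300, p0 = 0.5, sigma = 10 / 300, seed = 31)
  panel <- generate_panel(scn, 60)
  cache <- model_cache()
  hit <- vapply(panel$counts, function(cts) {
    g <- choose_grid(cts, 300, cache = cache)
    g[1] <= 10 / 300 && 10 / 300 <= g[5]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("analyse_locus wires filter, grid, fit and summaries together", {
  const <- make_counts(matrix(0.3, 2, 4), coverage = 50,
                       generations = c(0, 5, 10, 15))
  res <- analyse_locus(const, 30)
  expect_true(res$filtered)
  expect_true(is.na(res$mean_sigma) && is.na(res$log_bf) &&
                is.na(res$alpha) && is.na(res$beta))

  scn <- sim_scenario(Ne = 100, p0 = 0.5, sigma = 0.05, seed = 32)
  panel <- generate_panel(scn, 1)
  res2 <- analyse_locus(panel$counts[[1]], 100)
  expect_false(res2$filtered)
  expect_true(is.finite(res2$log_bf))
  expect_gt(res2$alpha, 0)
  expect_gt(res2$beta, 0)
})

test_that("an extra concordant replicate rarely weakens the evidence", {
  # information monotonicity as a statistical property: duplicating the
  # replicate that behaves most clearly selected (largest frequency
  # rise) should not decrease the log BF in >= 90% of loci. Duplicating
  # an arbitrary replicate can legitimately lower the BF when that
  # replicate happens to be flat or falling: it doubles evidence for
  # neutrality, not for selection.
  scn <- sim_scenario(Ne = 300, p0 = 0.5, sigma = 10 / 300, seed = 33)
  panel <- generate_panel(scn, 100)
  cache <- model_cache()
  delta <- vapply(panel$counts, function(cts) {
    r1 <- analyse_locus(cts, 300, cache = cache)
    p <- cts$focal / cts$coverage
    best <- which.max(p[, ncol(p)] - p[, 1])
    aug <- locus_counts(cts$chrom, cts$pos,
                        rbind(cts$focal, cts$focal[best, ]),
                        rbind(cts$coverage, cts$coverage[best, ]),
                        cts$generations)
    r2 <- analyse_locus(aug, 300, cache = cache)
    if (r1$filtered || r2$filtered || r1$degenerate || r2$degenerate)
      return(NA_real_)
    r2$log_bf - r1$log_bf
  }, numeric(1))
  expect_lt(mean(delta < 0, na.rm = TRUE), 0.10)
})
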