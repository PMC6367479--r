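test_that("beta weighting vanishes at its support edges and peaks at the closed-form mode", {
  p <- weighting_params()  # alpha1 4.5, alpha2 1.5, 3.5-12 kHz
  dense <- make_frequency_grid(3, 13, 4096)
  w <- weighting_function(p, dense)
  expect_equal(w[which.min(abs(dense - 3.5))], 0, tolerance = 1e-6)
  expect_equal(w[which.min(abs(dense - 12))], 0, tolerance = 1e-6)
  expect_true(all(w[dense <= 3.5 | dense >= 12] == 0))
  mode_closed <- (4.5 * 12 + 1.5 * 3.5) / (4.5 + 1.5)  # 9.875
  expect_equal(mode_closed, 9.875)
  expect_equal(dense[which.max(w)], mode_closed, tolerance = 1e-3)
  expect_equal(max(w), 1)
})

test_that("symmetric exponents put the weighting peak at the band midpoint", {
  p <- weighting_params(alpha1 = 2, alpha2 = 2, f_min = 4, f_max = 10)
  dense <- make_frequency_grid(3.8, 10.5, 4096)
  expect_equal(dense[which.max(weighting_function(p, dense))], 7,
               tolerance = 1e-3)
  expect_error(weighting_params(alpha1 = -1), "positive")
})

test_that("weighted sensory spectrum follows w * (H + X) elementwise", {
  h <- fx_hrtfs$gains[1, ]
  flat0 <- make_stimulus(0, 0, fx_grid)
  expect_equal(sensory_spectrum(h, flat0, rep(1, length(h))), h)
  expect_equal(sensory_spectrum(-10, 47, 0.5), 18.5)
  expect_equal(sensory_spectrum(c(-10, 0), c(47, 47), c(0, 0)), c(0, 0))
  expect_error(sensory_spectrum(h, flat0, 1:3), "grid")
})

test_that("a template matches itself perfectly inside the band", {
  s <- fx_hrtfs$gains[10, ]
  cf <- cross_correlate(s, fx_hrtfs, band = c(3, 12))
  expect_equal(cf$values[10], 1)
  expect_true(all(cf$values >= -1 & cf$values <= 1))
  expect_error(cross_correlate(s, fx_hrtfs, band = c(3, 3.001)))
})

test_that("flat stimuli are localized veridically for every elevation (uniform weights)", {
  flat <- make_stimulus(47, 47, fx_grid)
  for (i in seq_along(fx_elev)) {
    s <- fx_hrtfs$gains[i, ] + flat$levels_db
    cf <- cross_correlate(s, fx_hrtfs, band = c(3, 12))
    expect_equal(fx_elev[which.max(cf$values)], fx_elev[i])
  }
})

test_that("high positive contrast drags low sources into the upper hemifield", {
  x <- make_stimulus(65, 29, fx_grid)
  low <- fx_elev[fx_elev <= -30]
  resp <- vapply(low, function(e) localize(x, e, fx_hrtfs, fx_cfg), 0)
  expect_true(all(resp > 0))
})

test_that("rectification clips negatives and keeps positives", {
  cf <- structure(list(elevations = c(-10, 0, 10),
                       values = c(-0.5, 0.3, -1)),
                  class = "correlation_function")
  lf <- rectify_to_likelihood(cf)
  expect_equal(lf$values, c(0, 0.3, 0))
  expect_true(all(lf$values >= 0))
})

test_that("posterior is normalized and falls back to the prior without evidence", {
  lf <- structure(list(elevations = fx_elev, values = rep(0, length(fx_elev))),
                  class = "likelihood_function")
  post <- apply_prior(lf, spatial_prior("gaussian", mean = 0, sigma = 20))
  expect_equal(sum(post$mass), 1, tolerance = 1e-9)
  expect_equal(post$elevations[which.max(post$mass)], 0)
  # near-uniform prior leaves the posterior proportional to the likelihood
  lf2 <- structure(list(elevations = fx_elev,
                        values = abs(sin(fx_elev / 11)) + 0.01),
                   class = "likelihood_function")
  post2 <- apply_prior(lf2, spatial_prior("near-uniform"))
  expect_equal(post2$mass, lf2$values / sum(lf2$values), tolerance = 1e-12)
})

test_that("a Gaussian prior pulls a two-peak likelihood toward the central peak", {
  peaks <- exp(-0.5 * ((fx_elev + 50) / 6)^2) + exp(-0.5 * ((fx_elev - 20) / 6)^2)
  lf <- structure(list(elevations = fx_elev, values = peaks),
                  class = "likelihood_function")
  broad <- apply_prior(lf, spatial_prior("near-uniform"))
  narrow <- apply_prior(lf, spatial_prior("gaussian", mean = 0, sigma = 15))
  # with the sharp prior the mode is the peak nearer straight ahead
  expect_equal(narrow$elevations[which.max(narrow$mass)], 20, tolerance = 3)
  expect_lt(abs(narrow$elevations[which.max(narrow$mass)]),
            50)
  expect_equal(sum(broad$mass), 1, tolerance = 1e-9)
})

test_that("MAP decision matches brute-force argmax and breaks ties centrally", {
  set.seed(42)
  for (k in 1:1000) {
    m <- stats::runif(length(fx_elev))
    post <- structure(list(elevations = fx_elev, mass = m / sum(m)),
                      class = "posterior_distribution")
    expect_identical(decide(post, fx_cfg),
                     fx_elev[which.max(post$mass)])
  }
  mass <- rep(0, length(fx_elev))
  mass[match(c(-20, 20), fx_elev)] <- 0.5
  tied <- structure(list(elevations = fx_elev, mass = mass),
                    class = "posterior_distribution")
  expect_equal(decide(tied, fx_cfg), -20)
})

test_that("sampling decision reproduces the posterior mass", {
  mass <- c(0.1, 0.2, 0.3, 0.4)
  post <- structure(list(elevations = c(-30, -10, 10, 30), mass = mass),
                    class = "posterior_distribution")
  set.seed(7)
  cfg <- model_config(decision = "sample")
  draws <- replicate(10000, decide(post, cfg))
  counts <- table(factor(draws, levels = post$elevations))
  gof <- suppressWarnings(chisq.test(counts, p = mass))
  expect_gt(gof$p.value, 0.001)
})

test_that("localize is veridical for zero contrast and identity overall", {
  flat <- make_stimulus(56, 56, fx_grid)
  resp <- vapply(fx_elev, function(e) localize(flat, e, fx_hrtfs, fx_cfg), 0)
  expect_equal(resp, fx_elev)
  expect_error(localize(flat, 1.23, fx_hrtfs, fx_cfg), "grid")
})

test_that("a sharper prior never pushes the percept away from the prior mean", {
  x <- make_stimulus(47, 38, fx_grid)
  sigmas <- c(100, 50, 25, 12, 6)
  for (e in c(-50, -20, 30, 70)) {
    eps <- vapply(sigmas, function(s) {
      cfg <- model_config(prior = spatial_prior("gaussian", mean = 0, sigma = s))
      localize(x, e, fx_hrtfs, cfg)
    }, 0)
    expect_true(all(diff(abs(eps)) <= 1e-9))
  }
})

test_that("premultiplied correlation variant runs and exposes template weighting", {
  x <- make_stimulus(47, 47, fx_grid)
  cfg1 <- model_config(correlation = "premultiply")
  cfg2 <- model_config(correlation = "premultiply", weight_templates = TRUE)
  e1 <- localize(x, 0, fx_hrtfs, cfg1)
  e2 <- localize(x, 0, fx_hrtfs, cfg2)
  expect_true(is.finite(e1) && is.finite(e2))
  expect_error(cross_correlate(x$levels_db, fx_hrtfs, weight_templates = TRUE),
               "requires")
})
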