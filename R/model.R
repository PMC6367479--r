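#' Spectral weighting function parameters
#'
#' The observer does not treat all frequency bands as equally informative:
#' bands whose elevation cues are strong and reliable receive more weight.
#' The weighting is a negatively skewed beta-shaped bump in frequency,
#' `w(f) = a * (f - f_min)^alpha1 * (f_max - f)^alpha2` for
#' `f_min < f < f_max` and 0 outside. With the default parameters
#' (`alpha1 = 4.5`, `alpha2 = 1.5`, support 3.5-12 kHz) the peak falls at
#' `(alpha1 * f_max + alpha2 * f_min) / (alpha1 + alpha2) = 9.875` kHz and
#' the 3-6 kHz and above-12 kHz regions get little or no weight.
#'
#' The scale `a` is chosen so that `max(w) = 1` on the evaluation grid;
#' only relative weights matter downstream.
#'
#' @param alpha1,alpha2 positive shape exponents; `alpha2 < alpha1` skews
#'   the peak toward the upper band edge.
#' @param f_min,f_max support edges in kHz.
#' @return List of class `"weighting_params"`.
#' @export
weighting_params <- function(alpha1 = 4.5, alpha2 = 1.5,
                             f_min = 3.5, f_max = 12) {
  if (alpha1 <= 0 || alpha2 <= 0) stop("shape exponents must be positive")
  if (f_min >= f_max) stop("'f_min' must be below 'f_max'")
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 f_min = f_min, f_max = f_max),
            class = "weighting_params")
}

#' Evaluate the spectral weighting function on a grid
#'
#' @param p a [weighting_params()] object.
#' @param grid frequency grid in kHz.
#' @return Numeric vector of weights in `[0, 1]`, zero outside
#'   `(f_min, f_max)`, scaled so the maximum over the grid is 1.
#' @examples
#' g <- make_frequency_grid()
#' w <- weighting_function(weighting_params(), g)
#' g[which.max(w)]  # ~9.875
#' @export
weighting_function <- function(p, grid) {
  if (!inherits(p, "weighting_params")) stop("'p' must be weighting_params()")
  w <- numeric(length(grid))
  inside <- grid > p$f_min & grid < p$f_max
  w[inside] <- (grid[inside] - p$f_min)^p$alpha1 * (p$f_max - grid[inside])^p$alpha2
  m <- max(w)
  if (m == 0) stop("weighting support contains no grid bins")
  w / m
}

#' Spatial prior over source elevation
#'
#' Expected source locations, learned from the environment. Either a
#' Gaussian centered near straight ahead, or a near-uniform broad prior
#' (constant over the elevation grid), under which the posterior is
#' proportional to the likelihood.
#'
#' @param kind `"gaussian"` or `"near-uniform"`.
#' @param mean prior mean in degrees.
#' @param sigma prior SD in degrees (ignored for `"near-uniform"`).
#' @return List of class `"spatial_prior"`.
#' @export
spatial_prior <- function(kind = c("near-uniform", "gaussian"),
                          mean = 0, sigma = 30) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(kind = kind, mean = mean, sigma = sigma),
            class = "spatial_prior")
}

# Internal: prior density (unnormalized) on an elevation grid.
prior_density <- function(p, elevations) {
  if (p$kind == "near-uniform") {
    rep(1, length(elevations))
  } else {
    stats::dnorm(elevations, p$mean, p$sigma)
  }
}

#' Model configuration
#'
#' Bundles the pipeline parameters: spectral weighting, spatial prior,
#' analysis band, how the weighting enters the template comparison, and
#' the decision rule.
#'
#' `correlation = "weighted"` (default) applies the weighting as a
#' weighted Pearson correlation metric between the raw sensory spectrum
#' and each stored template; this is invariant to overall sound level, so
#' a flat spectrum at any level is localized veridically. `"premultiply"`
#' multiplies the sensory spectrum (and, with `weight_templates = TRUE`,
#' the templates) by `w(f)` before a plain Pearson correlation; this
#' variant is level-dependent and is provided for comparison.
#'
#' @param weighting a [weighting_params()] object.
#' @param prior a [spatial_prior()] object.
#' @param analysis_band correlation band in kHz (default `c(3, 12)`; an
#'   alternative wide band is `c(3.5, 15)`).
#' @param decision `"map"` (posterior maximum, deterministic) or
#'   `"sample"` (random draw from the posterior).
#' @param correlation `"weighted"` or `"premultiply"`.
#' @param weight_templates with `correlation = "premultiply"`, also
#'   multiply the stored templates by the weighting.
#' @param rng_seed optional integer seed used by the sampling decision.
#' @return List of class `"model_config"`.
#' @export
model_config <- function(weighting = weighting_params(),
                         prior = spatial_prior(),
                         analysis_band = c(3, 12),
                         decision = c("map", "sample"),
                         correlation = c("weighted", "premultiply"),
                         weight_templates = FALSE,
                         rng_seed = NULL) {
  decision <- match.arg(decision)
  correlation <- match.arg(correlation)
  structure(list(weighting = weighting, prior = prior,
                 analysis_band = analysis_band, decision = decision,
                 correlation = correlation,
                 weight_templates = isTRUE(weight_templates),
                 rng_seed = rng_seed),
            class = "model_config")
}

#' Weighted sensory spectrum
#'
#' The eardrum spectrum is the sum, in dB, of the source spectrum and the
#' HRTF at the true elevation (time-domain convolution becomes spectral
#' summation on the logarithmic cochlear scale). The weighting multiplies
#' this sum bin by bin: `S_w(f) = w(f) * (H(f) + X(f))`.
#'
#' @param h HRTF gain row in dB (numeric vector).
#' @param x a [stimulus_spectrum][make_stimulus] or numeric dB vector on
#'   the same grid.
#' @param w per-bin weights.
#' @return Numeric vector `w * (h + x)`.
#' @export
sensory_spectrum <- function(h, x, w) {
  xl <- if (inherits(x, "stimulus_spectrum")) x$levels_db else x
  if (length(h) != length(xl) || length(h) != length(w)) {
    stop("'h', 'x' and 'w' must share one frequency grid")
  }
  out <- w * (h + xl)
  if (any(!is.finite(out))) stop("non-finite sensory spectrum")
  out
}

# Internal: weighted Pearson correlation of vector s against each row of M.
# Weights are normalized to sum 1; zero-variance rows or input give 0.
weighted_row_cor <- function(s, M, w) {
  w <- w / sum(w)
  ms <- sum(w * s)
  ds <- s - ms
  vs <- sum(w * ds^2)
  mh <- as.vector(M %*% w)
  D <- M - mh
  num <- as.vector(D %*% (w * ds))
  vh <- as.vector((D * D) %*% w)
  den <- sqrt(vs * vh)
  out <- ifelse(den == 0, 0, num / den)
  pmin(1, pmax(-1, out))
}

#' Cross-correlate a sensory spectrum with the stored templates
#'
#' For every candidate elevation, computes the correlation between the
#' sensory spectrum and the stored HRTF template over the analysis band.
#' With `weights` supplied (the default model path), a weighted Pearson
#' correlation is used, so bands with higher weight dominate the match
#' while constant level shifts cancel. Without weights, plain Pearson; a
#' zero-variance input correlates 0 with everything (see [safe_cor()]).
#'
#' @param s sensory spectrum in dB over the full grid (numeric vector).
#' @param templates an [hrtf_set][make_canonical_hrtfs].
#' @param band analysis band in kHz.
#' @param weights optional per-bin weights over the full grid.
#' @param weight_templates multiply template rows by `weights` before a
#'   plain Pearson correlation (the premultiplied variant); requires
#'   `weights`.
#' @return List of class `"correlation_function"`: `elevations`, `values`
#'   in `[-1, 1]`.
#' @export
cross_correlate <- function(s, templates, band = c(3, 12), weights = NULL,
                            weight_templates = FALSE) {
  idx <- band_bins(templates$grid, band)
  if (length(idx) < 3) stop("analysis band contains fewer than 3 bins")
  if (length(s) != length(templates$grid)) {
    stop("'s' must live on the template frequency grid")
  }
  sb <- s[idx]
  Tb <- templates$gains[, idx, drop = FALSE]
  if (isTRUE(weight_templates)) {
    if (is.null(weights)) stop("'weight_templates' requires 'weights'")
    wb <- weights[idx]
    Tb <- sweep(Tb, 2, wb, `*`)
    vals <- apply(Tb, 1, function(h) safe_cor(sb, h))
  } else if (!is.null(weights)) {
    vals <- weighted_row_cor(sb, Tb, weights[idx])
  } else {
    vals <- apply(Tb, 1, function(h) safe_cor(sb, h))
  }
  structure(list(elevations = templates$elevations, values = vals),
            class = "correlation_function")
}

#' Rectify a correlation function into a likelihood
#'
#' Only positive correlations can signal the source location; negative
#' values are clipped to zero.
#'
#' @param c_fun a [correlation_function][cross_correlate].
#' @return List of class `"likelihood_function"`: `elevations`, `values`
#'   (nonnegative).
#' @export
rectify_to_likelihood <- function(c_fun) {
  structure(list(elevations = c_fun$elevations,
                 values = pmax(c_fun$values, 0)),
            class = "likelihood_function")
}

#' Combine likelihood and spatial prior into a posterior
#'
#' `R(eps) proportional to L(eps) * P(eps)`, normalized to unit mass over
#' the elevation grid. With an all-zero likelihood (no positive evidence)
#' the posterior falls back to the normalized prior — the Bayesian limit
#' of no evidence.
#'
#' @param l a [likelihood_function][rectify_to_likelihood].
#' @param p a [spatial_prior()].
#' @return List of class `"posterior_distribution"`: `elevations`, `mass`
#'   (nonnegative, sums to 1).
#' @export
apply_prior <- function(l, p) {
  pr <- prior_density(p, l$elevations)
  m <- l$values * pr
  if (sum(m) == 0) m <- pr
  structure(list(elevations = l$elevations, mass = m / sum(m)),
            class = "posterior_distribution")
}

#' Decision stage: perceived elevation from the posterior
#'
#' The optimal (MAP) rule returns the posterior mode; ties (within 1e-12
#' relative tolerance) are broken deterministically toward the smallest
#' `|elevation|`, then the smallest elevation — a centrality preference
#' consistent with a prior around straight ahead. The `"sample"` rule
#' draws one elevation from the posterior mass.
#'
#' @param r a [posterior_distribution][apply_prior].
#' @param cfg a [model_config()] (supplies the rule and, for sampling, an
#'   optional seed).
#' @return Perceived elevation in degrees.
#' @export
decide <- function(r, cfg = model_config()) {
  if (cfg$decision == "sample") {
    if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
    return(sample(r$elevations, 1L, prob = r$mass))
  }
  m <- max(r$mass)
  cand <- which(r$mass >= m - 1e-12 * max(1, abs(m)))
  e <- r$elevations[cand]
  e[order(abs(e), e)][1]
}

#' Localize a stimulus: full model pipeline
#'
#' Composes the stages of the generative observer: eardrum spectrum
#' (HRTF at the true elevation plus the source spectrum, in dB, plus any
#' sensory perturbation), weighted template correlation over the analysis
#' band, rectification into a likelihood, multiplication with the spatial
#' prior, and the decision rule. Deterministic when `noise` is absent and
#' the decision is MAP.
#'
#' @param x a [stimulus_spectrum][make_stimulus].
#' @param true_elevation true source elevation in degrees; must be on the
#'   template elevation grid.
#' @param hrtfs stored templates ([make_canonical_hrtfs()]).
#' @param cfg a [model_config()].
#' @param noise optional per-bin dB perturbation added to the eardrum
#'   spectrum (numeric vector on the stimulus grid).
#' @param details return the intermediate stages too.
#' @return Perceived elevation in degrees, or (with `details = TRUE`) a
#'   list with `epsilon_p`, `correlation`, `likelihood`, `posterior`.
#' @export
localize <- function(x, true_elevation, hrtfs, cfg = model_config(),
                     noise = NULL, details = FALSE) {
  i <- match(TRUE, abs(hrtfs$elevations - true_elevation) < 1e-9)
  if (is.na(i)) stop("'true_elevation' is not on the template elevation grid")
  if (!identical(length(x$levels_db), length(hrtfs$grid))) {
    stop("stimulus and templates must share one frequency grid")
  }
  s <- hrtfs$gains[i, ] + x$levels_db
  if (!is.null(noise)) {
    if (length(noise) != length(s)) stop("'noise' must match the grid length")
    s <- s + noise
  }
  w <- weighting_function(cfg$weighting, hrtfs$grid)
  cf <- if (cfg$correlation == "weighted") {
    cross_correlate(s, hrtfs, cfg$analysis_band, weights = w)
  } else {
    sw <- sensory_spectrum(hrtfs$gains[i, ], x$levels_db +
                             (if (is.null(noise)) 0 else noise), w)
    cross_correlate(sw, hrtfs, cfg$analysis_band,
                    weights = if (cfg$weight_templates) w else NULL,
                    weight_templates = cfg$weight_templates)
  }
  lf <- rectify_to_likelihood(cf)
  post <- apply_prior(lf, cfg$prior)
  eps <- decide(post, cfg)
  if (!details) return(eps)
  list(epsilon_p = eps, correlation = cf, likelihood = lf, posterior = post)
}
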