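#' Parameters of the canonical HRTF generator
#'
#' The canonical set emulates the structure of measured human HRTFs on the
#' midsagittal plane: a direction-independent ear-canal resonance near
#' 2.5 kHz, a prominent elevation-dependent spectral notch that sweeps
#' upward through the 6-9 kHz band as the source rises (deepest at low
#' elevations), weak monotonic cues between 4-6 kHz, and erratic
#' (non-monotonic) rippled structure above 9 kHz where human hearing is
#' less sensitive.
#'
#' @param notch_center_low notch center (kHz) at the lowest elevation.
#' @param notch_center_slope notch center drift in kHz per degree of
#'   elevation. The trajectory must stay within 5-11 kHz over the grid.
#' @param notch_depth maximum notch depth in dB (at the lowest elevation).
#' @param notch_depth_taper fractional reduction of the depth from the
#'   lowest to the highest elevation.
#' @param notch_width notch width (Gaussian SD) in octaves.
#' @param lowband_ramp_gain slope of the 4-6 kHz monotonic cue in dB per
#'   degree of elevation.
#' @param lowband_ramp_center,lowband_ramp_width center (kHz) and SD
#'   (octaves) of the window confining the low-band ramp.
#' @param highband_ripple_amp ripple amplitude above 9 kHz in dB.
#' @param highband_ripple_rate ripple rate in cycles per octave.
#' @param highband_ripple_period elevation period (deg) of the ripple phase
#'   drift; smaller values make the high-band cues vary faster (and less
#'   monotonically) with elevation.
#' @param highband_ripple_jitter SD (radians) of the seeded per-elevation
#'   phase jitter that makes the high band erratic.
#' @param highband_onset frequency (kHz) above which the ripple engages.
#' @param resonance_center,resonance_gain,resonance_width ear-canal
#'   resonance: center (kHz, direction-independent), gain (dB), SD (octaves).
#' @param rng_seed integer seed for the ripple phase jitter; the generator
#'   is fully deterministic given the seed.
#' @return A list of class `"hrtf_params"`.
#' @seealso [make_canonical_hrtfs()]
#' @export
hrtf_params <- function(notch_center_low = 5.8,
                        notch_center_slope = 4.0 / 145,
                        notch_depth = 10,
                        notch_depth_taper = 0.45,
                        notch_width = 0.25,
                        lowband_ramp_gain = 0.06,
                        lowband_ramp_center = 4.7,
                        lowband_ramp_width = 0.18,
                        highband_ripple_amp = 6,
                        highband_ripple_rate = 1.8,
                        highband_ripple_period = 200,
                        highband_ripple_jitter = 0.1,
                        highband_onset = 10.2,
                        resonance_center = 2.5,
                        resonance_gain = 12,
                        resonance_width = 0.35,
                        rng_seed = 73L) {
  p <- list(notch_center_low = notch_center_low,
            notch_center_slope = notch_center_slope,
            notch_depth = notch_depth,
            notch_depth_taper = notch_depth_taper,
            notch_width = notch_width,
            lowband_ramp_gain = lowband_ramp_gain,
            lowband_ramp_center = lowband_ramp_center,
            lowband_ramp_width = lowband_ramp_width,
            highband_ripple_amp = highband_ripple_amp,
            highband_ripple_rate = highband_ripple_rate,
            highband_ripple_period = highband_ripple_period,
            highband_ripple_jitter = highband_ripple_jitter,
            highband_onset = highband_onset,
            resonance_center = resonance_center,
            resonance_gain = resonance_gain,
            resonance_width = resonance_width,
            rng_seed = as.integer(rng_seed))
  stopifnot(p$notch_depth >= 0, p$notch_width > 0,
            p$highband_ripple_amp >= 0, p$resonance_width > 0)
  class(p) <- "hrtf_params"
  p
}

#' Generate a canonical HRTF set
#'
#' Builds the stored elevation templates `H(f; eps)`: one dB gain spectrum
#' per elevation, composed of a fixed ear-canal resonance, a moving
#' Gaussian notch (in log-frequency) whose center rises linearly with
#' elevation and whose depth is maximal at low elevations, a weak monotonic
#' gain ramp in the 4-6 kHz region, and an elevation-dependent sinusoidal
#' ripple above 9 kHz.
#'
#' @param params an [hrtf_params()] object.
#' @param grid frequency grid in kHz, from [make_frequency_grid()].
#' @param elevations elevation grid in degrees, from
#'   [make_elevation_grid()].
#' @return Object of class `"hrtf_set"`: a list with `grid`, `elevations`
#'   and `gains` (matrix, one row per elevation, dB).
#' @examples
#' h <- make_canonical_hrtfs()
#' dim(h$gains)  # 59 x 342
#' @export
make_canonical_hrtfs <- function(params = hrtf_params(),
                                 grid = make_frequency_grid(),
                                 elevations = make_elevation_grid()) {
  if (!inherits(params, "hrtf_params")) stop("'params' must be hrtf_params()")
  if (length(grid) == 0 || length(elevations) == 0) {
    stop("frequency and elevation grids must be non-empty")
  }
  e_lo <- min(elevations)
  ctr <- params$notch_center_low + params$notch_center_slope * (elevations - e_lo)
  if (any(ctr < 5 | ctr > 11)) {
    stop("notch center trajectory leaves the 5-11 kHz band")
  }
  e_span <- diff(range(elevations))
  if (e_span == 0) e_span <- 1
  lg <- log2(grid)
  resonance <- params$resonance_gain *
    exp(-0.5 * ((lg - log2(params$resonance_center)) / params$resonance_width)^2)
  ramp_win <- exp(-0.5 * ((lg - log2(params$lowband_ramp_center)) /
                            params$lowband_ramp_width)^2)
  onset <- 1 / (1 + exp(-(lg - log2(params$highband_onset)) / 0.05))

  jit <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(params$rng_seed)
    stats::rnorm(length(elevations), 0, params$highband_ripple_jitter)
  })

  gains <- matrix(NA_real_, nrow = length(elevations), ncol = length(grid))
  for (i in seq_along(elevations)) {
    e <- elevations[i]
    frac <- (e - e_lo) / e_span
    depth <- params$notch_depth * (1 - params$notch_depth_taper * frac)
    notch <- -depth * exp(-0.5 * ((lg - log2(ctr[i])) / params$notch_width)^2)
    ramp <- params$lowband_ramp_gain * e * ramp_win
    phase <- 2 * pi * (params$highband_ripple_rate * (lg - log2(params$highband_onset)) +
                         e / params$highband_ripple_period) + jit[i]
    ripple <- params$highband_ripple_amp * onset * sin(phase)
    gains[i, ] <- resonance + notch + ramp + ripple
  }
  structure(list(grid = grid, elevations = elevations, gains = gains,
                 params = params),
            class = "hrtf_set")
}

#' @export
print.hrtf_set <- function(x, ...) {
  cat(sprintf("HRTF set: %d elevations (%g to %g deg) x %d frequencies (%g to %g kHz)\n",
              length(x$elevations), min(x$elevations), max(x$elevations),
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("gain range: %.2f to %.2f dB\n", min(x$gains), max(x$gains)))
  invisible(x)
}

#' @export
plot.hrtf_set <- function(x, ...) {
  graphics::image(log2(x$grid), x$elevations, t(x$gains),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "frequency (kHz, log2 axis)", ylab = "elevation (deg)",
                  axes = FALSE, ...)
  at <- c(0.5, 1, 2, 4, 8, 16)
  graphics::axis(1, at = log2(at), labels = at)
  graphics::axis(2)
  graphics::box()
  invisible(x)
}

#' Pearson correlation with a zero-variance convention
#'
#' Plain Pearson correlation, except that any zero-variance argument yields
#' a correlation of exactly 0: a flat spectrum carries no shape information
#' to match against a template, and the convention avoids 0/0.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or 0 if either input has zero variance.
#' @export
safe_cor <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Template-uniqueness and source-decorrelation report
#'
#' Validates the two structural assumptions behind template-matching
#' elevation decoding: (i) every stored HRTF is unique over the analysis
#' band (its self-correlation exceeds its correlation with every other
#' template), and (ii) source spectra do not correlate appreciably with any
#' stored template. When both hold, the correlation maximum falls at the
#' veridical elevation.
#'
#' @param hrtfs an [hrtf_set][make_canonical_hrtfs] object.
#' @param stimuli optional list of stimulus spectra ([make_stimulus()]) to
#'   check assumption (ii) against.
#' @param band analysis band in kHz (default `c(3, 12)`).
#' @return List of class `"uniqueness_report"`: `correlation_matrix`
#'   (elevation x elevation), `min_diagonal_margin` (smallest
#'   diagonal-minus-max-off-diagonal over rows; positive certifies (i)),
#'   and `source_decorrelation` (data frame of max |correlation| per
#'   stimulus, or NULL).
#' @export
uniqueness_report <- function(hrtfs, stimuli = NULL, band = c(3, 12)) {
  idx <- band_bins(hrtfs$grid, band)
  if (length(idx) < 3) stop("analysis band contains fewer than 3 bins")
  g <- hrtfs$gains[, idx, drop = FALSE]
  n <- nrow(g)
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      cm[i, j] <- cm[j, i] <- safe_cor(g[i, ], g[j, ])
    }
  }
  margins <- vapply(seq_len(n), function(i) cm[i, i] - max(cm[i, -i]), 0)
  src <- NULL
  if (!is.null(stimuli)) {
    src <- do.call(rbind, lapply(seq_along(stimuli), function(k) {
      s <- stimuli[[k]]
      x <- s$levels_db[band_bins(s$grid, band)]
      cc <- apply(g, 1, function(h) safe_cor(x, h))
      data.frame(stimulus = k,
                 nri_db = s$nri, ori_db = s$ori,
                 max_abs_correlation = max(abs(cc)))
    }))
  }
  structure(list(correlation_matrix = cm,
                 min_diagonal_margin = min(margins),
                 margins = margins,
                 source_decorrelation = src,
                 band = band),
            class = "uniqueness_report")
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf("Template uniqueness over %g-%g kHz\n", x$band[1], x$band[2]))
  cat(sprintf("  min diagonal margin: %.3g (%s)\n", x$min_diagonal_margin,
              if (x$min_diagonal_margin > 0) "templates unique" else "degenerate"))
  if (!is.null(x$source_decorrelation)) {
    cat(sprintf("  max |stimulus-template correlation|: %.3g\n",
                max(x$source_decorrelation$max_abs_correlation)))
  }
  invisible(x)
}

#' Read / write an HRTF gain table
#'
#' Plain-text tabular exchange format for gain tables: first column holds
#' elevations in degrees, remaining column names are frequencies in kHz,
#' cells are gains in dB. Comma- or tab-separated (chosen from the file
#' extension: `.tsv`/`.txt` means tab). User-measured HRTFs in the same
#' layout import through the same reader.
#'
#' @param hrtfs an `hrtf_set` object.
#' @param path file path.
#' @return `read_hrtf_table()` returns an `hrtf_set`;
#'   `write_hrtf_table()` returns `path` invisibly.
#' @examples
#' # a small synthetic example table ships with the package
#' h <- read_hrtf_table(system.file("extdata", "example_hrtf_synthetic.csv",
#'                                  package = "specloc"))
#' length(h$elevations)  # 8
#' @export
write_hrtf_table <- function(hrtfs, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tab <- data.frame(elevation_deg = hrtfs$elevations, hrtfs$gains,
                    check.names = FALSE)
  names(tab)[-1] <- format(hrtfs$grid, digits = 10, trim = TRUE,
                           scientific = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hrtf_table
#' @export
read_hrtf_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  elevations <- tab[[1]]
  grid <- as.numeric(names(tab)[-1])
  if (anyNA(grid)) stop("header must hold numeric frequencies in kHz")
  if (any(diff(grid) <= 0)) stop("frequency axis must be strictly increasing")
  if (any(diff(elevations) <= 0)) stop("elevation axis must be strictly increasing")
  gains <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(gains) <- NULL
  if (anyNA(gains) || any(!is.finite(gains))) stop("gains must be finite")
  structure(list(grid = grid, elevations = elevations, gains = gains,
                 params = NULL),
            class = "hrtf_set")
}
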