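#' Logarithmic frequency grid
#'
#' Builds a log-spaced frequency axis (in kHz) with a fixed number of bins
#' per octave, including both endpoints. A logarithmic axis mirrors the
#' cochlear tonotopic representation; all spectra in this package live on
#' such a grid.
#'
#' @param f_lo,f_hi band edges in kHz, `0 < f_lo < f_hi`.
#' @param bins_per_octave grid density; the default 64 makes a 120
#'   dB/octave stimulus edge span roughly 20 bins.
#' @return Numeric vector of strictly increasing frequencies in kHz with
#'   `ceiling(bins_per_octave * log2(f_hi/f_lo)) + 1` points; first element
#'   `f_lo`, last `f_hi`.
#' @examples
#' f <- make_frequency_grid(0.5, 20, 64)
#' length(f)   # 342
#' range(f)    # 0.5 20
#' @export
make_frequency_grid <- function(f_lo = 0.5, f_hi = 20, bins_per_octave = 64) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || length(f_lo) != 1L ||
      length(f_hi) != 1L || !is.finite(f_lo) || !is.finite(f_hi)) {
    stop("'f_lo' and 'f_hi' must be single finite numbers")
  }
  if (f_lo <= 0) stop("frequencies must be positive")
  if (f_lo >= f_hi) stop("'f_lo' must be strictly below 'f_hi'")
  if (bins_per_octave < 1) stop("'bins_per_octave' must be at least 1")
  n_oct <- log2(f_hi / f_lo)
  k <- ceiling(bins_per_octave * n_oct)
  f_lo * 2^(seq(0, n_oct, length.out = k + 1))
}

#' Elevation grid for the midsagittal plane
#'
#' Candidate (and true) source elevations in degrees. The default matches a
#' speaker hoop with 2.5 degree resolution between -60 and +85 deg
#' elevation, giving 59 positions.
#'
#' @param lo,hi range in degrees.
#' @param step uniform step in degrees.
#' @return Strictly increasing numeric vector of elevations in degrees.
#' @examples
#' length(make_elevation_grid())  # 59
#' @export
make_elevation_grid <- function(lo = -60, hi = 85, step = 2.5) {
  if (lo >= hi) stop("'lo' must be strictly below 'hi'")
  if (step <= 0) stop("'step' must be positive")
  seq(lo, hi, by = step)
}

# Internal: index of grid bins falling inside a [lo, hi] kHz band.
band_bins <- function(grid, band) {
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("'band' must be c(lo, hi) in kHz with lo < hi")
  }
  if (band[1] < min(grid) || band[2] > max(grid)) {
    stop(sprintf("band [%g, %g] kHz lies outside the grid range [%g, %g]",
                 band[1], band[2], min(grid), max(grid)))
  }
  which(grid >= band[1] & grid <= band[2])
}
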