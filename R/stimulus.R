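#' Construct a spectral-contrast stimulus
#'
#' Builds one of the band-level stimuli used to probe elevation cues: a
#' broadband spectrum whose notch band (6-9 kHz) sits at level `nri` (notch
#' region intensity) and whose outer bands (0.5-6 and 9-20 kHz) sit at
#' level `ori` (outer region intensity), with linear-in-log-frequency
#' transition edges of fixed steepness at the 6 and 9 kHz band boundaries.
#' Spectral contrast is `nri - ori`; `nri == ori` gives the flat
#' white-noise control spectrum.
#'
#' Stimuli are specified directly as amplitude spectra in dB (the model's
#' input domain); the per-bin level inside each flat portion equals the
#' band's nominal level.
#'
#' @param nri notch-band level in dB.
#' @param ori outer-band level in dB.
#' @param grid frequency grid in kHz; must cover the outer band.
#' @param edge_slope transition steepness in dB/octave (default 120).
#' @param notch_band notch band edges in kHz.
#' @param outer_lo lower edge of the outer region in kHz (the spectrum is
#'   defined over `[outer_lo, max(grid)]`).
#' @return Object of class `"stimulus_spectrum"`: list with `grid`,
#'   `levels_db`, `nri`, `ori`.
#' @examples
#' s <- make_stimulus(65, 29)
#' spectral_contrast(s)  # 36
#' @export
make_stimulus <- function(nri, ori, grid = make_frequency_grid(),
                          edge_slope = 120, notch_band = c(6, 9),
                          outer_lo = 0.5) {
  if (edge_slope <= 0) stop("'edge_slope' must be positive")
  if (min(grid) > outer_lo || max(grid) < notch_band[2]) {
    stop("grid does not cover the stimulus bands")
  }
  lo <- notch_band[1]; hi <- notch_band[2]
  d <- ori - nri
  lv <- numeric(length(grid))
  inb <- grid >= lo & grid <= hi
  below <- grid < lo
  above <- grid > hi
  lv[inb] <- nri
  lv[below] <- nri + sign(d) * pmin(abs(d), edge_slope * log2(lo / grid[below]))
  lv[above] <- nri + sign(d) * pmin(abs(d), edge_slope * log2(grid[above] / hi))
  structure(list(grid = grid, levels_db = lv, nri = nri, ori = ori,
                 edge_slope = edge_slope, notch_band = notch_band),
            class = "stimulus_spectrum")
}

#' Spectral contrast of a stimulus
#'
#' @param s a [stimulus_spectrum][make_stimulus].
#' @return `nri - ori` in dB.
#' @export
spectral_contrast <- function(s) {
  if (!inherits(s, "stimulus_spectrum")) stop("'s' must be a stimulus_spectrum")
  s$nri - s$ori
}

#' The full 5 x 5 stimulus matrix
#'
#' All combinations of notch-band and outer-band levels over
#' `levels` (default 29, 38, 47, 56, 65 dB): 25 stimuli spanning contrasts
#' from -36 to +36 dB, with the 5 flat (zero-contrast) spectra on the main
#' diagonal.
#'
#' @param grid frequency grid in kHz.
#' @param levels band levels in dB.
#' @param ... passed to [make_stimulus()].
#' @return Object of class `"stimulus_matrix"`: list with `stimuli` (list
#'   of 25 stimulus spectra) and `conditions` (data frame with `nri_db`,
#'   `ori_db`, `contrast_db`).
#' @export
make_stimulus_matrix <- function(grid = make_frequency_grid(),
                                 levels = c(29, 38, 47, 56, 65), ...) {
  cond <- expand.grid(ori_db = levels, nri_db = levels,
                      KEEP.OUT.ATTRS = FALSE)[, c("nri_db", "ori_db")]
  cond$contrast_db <- cond$nri_db - cond$ori_db
  stimuli <- lapply(seq_len(nrow(cond)), function(i) {
    make_stimulus(cond$nri_db[i], cond$ori_db[i], grid = grid, ...)
  })
  structure(list(stimuli = stimuli, conditions = cond, levels = levels),
            class = "stimulus_matrix")
}

#' @export
print.stimulus_matrix <- function(x, ...) {
  cat(sprintf("Stimulus matrix: %d conditions, levels {%s} dB, contrast %g to %g dB\n",
              length(x$stimuli), paste(x$levels, collapse = ", "),
              min(x$conditions$contrast_db), max(x$conditions$contrast_db)))
  invisible(x)
}

#' @export
plot.stimulus_spectrum <- function(x, ...) {
  graphics::plot(log2(x$grid), x$levels_db, type = "l",
                 xlab = "frequency (kHz, log2 axis)", ylab = "level (dB)",
                 axes = FALSE, ...)
  at <- c(0.5, 1, 2, 4, 8, 16)
  graphics::axis(1, at = log2(at), labels = at)
  graphics::axis(2); graphics::box()
  invisible(x)
}

#' Export / import a stimulus matrix as long-form CSV
#'
#' One row per (condition, frequency bin): columns `nri_db`, `ori_db`,
#' `contrast_db`, `freq_khz`, `level_db`.
#'
#' @param sm a [stimulus_matrix][make_stimulus_matrix].
#' @param path file path.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns the long-form data frame.
#' @export
write_stimulus_csv <- function(sm, path) {
  long <- do.call(rbind, lapply(seq_along(sm$stimuli), function(i) {
    s <- sm$stimuli[[i]]
    data.frame(nri_db = s$nri, ori_db = s$ori, contrast_db = s$nri - s$ori,
               freq_khz = s$grid, level_db = s$levels_db)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("nri_db", "ori_db", "contrast_db", "freq_khz", "level_db")
  if (!all(need %in% names(tab))) {
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab
}
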