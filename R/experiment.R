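#' Sensory noise model
#'
#' Two sources of trial-to-trial variability at the model's front end: an
#' independent Gaussian dB perturbation per frequency bin (spectral jitter
#' in the sensory processing chain), and a room noise floor that is
#' superposed with the stimulus in the power domain, so that stimuli near
#' the floor lose spectral contrast (the signal-to-noise effect along the
#' level diagonal of the stimulus matrix).
#'
#' @param spectral_sigma per-bin dB jitter SD (default 3).
#' @param noise_floor floor level in dB SPL (default 30, a quiet room);
#'   use `-Inf` to disable.
#' @param rng_seed optional integer seed.
#' @return List of class `"noise_model"`.
#' @export
noise_model <- function(spectral_sigma = 3, noise_floor = 30,
                        rng_seed = NULL) {
  if (spectral_sigma < 0) stop("'spectral_sigma' must be nonnegative")
  structure(list(spectral_sigma = spectral_sigma, noise_floor = noise_floor,
                 rng_seed = rng_seed),
            class = "noise_model")
}

#' Perturb a spectrum with sensory noise and the room floor
#'
#' Adds the Gaussian per-bin jitter, then superposes the noise floor in
#' the power domain: `10*log10(10^(L/10) + 10^(floor/10))`. Levels far
#' above the floor are essentially unchanged; levels at or below the
#' floor are lifted toward it. Draws from the current RNG state (seed the
#' stream with [set.seed()] or via [run_experiment()]).
#'
#' @param x a [stimulus_spectrum][make_stimulus] or numeric dB vector.
#' @param nm a [noise_model()].
#' @return Numeric vector of perturbed dB levels.
#' @export
add_sensory_noise <- function(x, nm) {
  lv <- if (inherits(x, "stimulus_spectrum")) x$levels_db else x
  if (nm$spectral_sigma > 0) {
    lv <- lv + stats::rnorm(length(lv), 0, nm$spectral_sigma)
  }
  if (is.finite(nm$noise_floor)) {
    lv <- 10 * log10(10^(lv / 10) + 10^(nm$noise_floor / 10))
  }
  lv
}

#' Build a virtual experiment design
#'
#' Full crossing of the stimulus conditions with target directions and
#' repeats, shuffled reproducibly and split into blocks. The default
#' (25 stimuli x 48 random frontal directions x 1 repeat) gives 1200
#' trials in 8 blocks of 150. Target elevations are drawn from the
#' elevation grid; azimuths are drawn uniformly inside the double-pole
#' constraint `|azimuth| + |elevation| <= 90` and carried through as
#' metadata (the model is elevation-only).
#'
#' @param levels band levels in dB for the stimulus matrix.
#' @param targets either a count of random target directions or an
#'   explicit vector of target elevations in degrees (on the grid).
#' @param repeats repetitions of the full crossing.
#' @param n_blocks number of blocks.
#' @param seed integer seed for target draws and trial shuffling.
#' @param elevations elevation grid targets are drawn from.
#' @return List of class `"experiment_design"`: `conditions` (stimulus
#'   condition table), `trials` (data frame: `block`, `nri_db`, `ori_db`,
#'   `contrast_db`, `azimuth_t_deg`, `elevation_t_deg`), `levels`,
#'   `seed`.
#' @export
build_design <- function(levels = c(29, 38, 47, 56, 65), targets = 48,
                         repeats = 1, n_blocks = 8, seed = 1L,
                         elevations = make_elevation_grid()) {
  if (length(levels) == 0) stop("'levels' must be nonempty")
  if (repeats < 1) stop("'repeats' must be at least 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # A single positive whole number is a count of random targets; anything
  # else is an explicit list of target elevations. A single explicit
  # target therefore has to be a value that is not a valid count (all
  # negative or non-integer grid elevations qualify).
  if (length(targets) == 1L && targets >= 1 && targets == round(targets)) {
    n_t <- as.integer(targets)
    elev_t <- sample(elevations, n_t, replace = TRUE)
  } else {
    if (!all(targets %in% elevations)) {
      stop("explicit target elevations must lie on the elevation grid")
    }
    elev_t <- as.numeric(targets)
    n_t <- length(elev_t)
  }
  azi_t <- vapply(elev_t, function(e) stats::runif(1, -(90 - abs(e)), 90 - abs(e)), 0)

  cond <- expand.grid(ori_db = levels, nri_db = levels,
                      KEEP.OUT.ATTRS = FALSE)[, c("nri_db", "ori_db")]
  cond$contrast_db <- cond$nri_db - cond$ori_db

  base <- expand.grid(target = seq_len(n_t), condition = seq_len(nrow(cond)),
                      rep = seq_len(repeats), KEEP.OUT.ATTRS = FALSE)
  base <- base[sample.int(nrow(base)), , drop = FALSE]
  n <- nrow(base)
  trials <- data.frame(
    block = ceiling(seq_len(n) / (n / n_blocks)),
    nri_db = cond$nri_db[base$condition],
    ori_db = cond$ori_db[base$condition],
    contrast_db = cond$contrast_db[base$condition],
    azimuth_t_deg = azi_t[base$target],
    elevation_t_deg = elev_t[base$target]
  )
  structure(list(conditions = cond, trials = trials, levels = levels,
                 n_blocks = n_blocks, repeats = repeats, seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Virtual design: %d trials (%d conditions x %d targets x %d repeats), %d blocks\n",
              nrow(x$trials), nrow(x$conditions),
              nrow(x$trials) / nrow(x$conditions) / x$repeats,
              x$repeats, x$n_blocks))
  invisible(x)
}

#' Run the virtual experiment through the model
#'
#' Simulates every trial of the design: build the trial's stimulus
#' spectrum, optionally perturb it with the sensory noise model, localize
#' it with the Bayesian observer, and record the perceived elevation.
#' Azimuth responses are pass-through (`azimuth_t` plus optional Gaussian
#' error) — the model carries no binaural stage. Deterministic given the
#' design seed and the noise seed.
#'
#' @param design an [build_design()] object.
#' @param hrtfs stored templates.
#' @param cfg a [model_config()].
#' @param nm optional [noise_model()]; `NULL` for noise-free runs.
#' @param azimuth_sigma SD (deg) of the pass-through azimuth error.
#' @return Trial table (data frame): design columns plus
#'   `azimuth_r_deg`, `elevation_r_deg`.
#' @export
run_experiment <- function(design, hrtfs, cfg = model_config(), nm = NULL,
                           azimuth_sigma = 0) {
  trials <- design$trials
  sm <- make_stimulus_matrix(grid = hrtfs$grid, levels = design$levels)
  key <- paste(sm$conditions$nri_db, sm$conditions$ori_db)
  stim_of <- match(paste(trials$nri_db, trials$ori_db), key)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  nseed <- if (!is.null(nm) && !is.null(nm$rng_seed)) nm$rng_seed else design$seed + 1L
  set.seed(as.integer(nseed))

  n <- nrow(trials)
  resp <- numeric(n)
  for (k in seq_len(n)) {
    x <- sm$stimuli[[stim_of[k]]]
    if (!is.null(nm)) {
      xp <- x
      xp$levels_db <- add_sensory_noise(x, nm)
      x <- xp
    }
    resp[k] <- localize(x, trials$elevation_t_deg[k], hrtfs, cfg)
  }
  trials$azimuth_r_deg <- trials$azimuth_t_deg +
    if (azimuth_sigma > 0) stats::rnorm(n, 0, azimuth_sigma) else 0
  trials$elevation_r_deg <- resp
  trials
}

#' Read / write a trial table CSV
#'
#' Header: `block, nri_db, ori_db, contrast_db, azimuth_t_deg,
#' elevation_t_deg, azimuth_r_deg, elevation_r_deg`.
#'
#' @param trials trial table data frame.
#' @param path file path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` returns the data frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("block", "nri_db", "ori_db", "contrast_db",
            "elevation_t_deg", "elevation_r_deg")
  if (!all(need %in% names(tab))) {
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab
}
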