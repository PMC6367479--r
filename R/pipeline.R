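# Internal: derive a stage seed from the global seed and a stage name, so
# that stages get distinct, reproducible streams without seed collisions.
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' One object holding every knob of the end-to-end simulation: the HRTF
#' generator parameters, the stimulus levels, the model configuration,
#' the virtual design, the sensory noise model, and a single global seed
#' from which every stage derives its own stream.
#'
#' @param hrtf an [hrtf_params()] object.
#' @param levels stimulus band levels in dB.
#' @param model a [model_config()] object.
#' @param targets target count or explicit elevations for the design.
#' @param repeats design repeats.
#' @param n_blocks design blocks.
#' @param noise a [noise_model()] or `NULL` for noise-free runs.
#' @param seed global integer seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(hrtf = hrtf_params(),
                            levels = c(29, 38, 47, 56, 65),
                            model = model_config(),
                            targets = 48, repeats = 1, n_blocks = 8,
                            noise = noise_model(),
                            seed = 1L) {
  structure(list(hrtf = hrtf, levels = levels, model = model,
                 targets = targets, repeats = repeats, n_blocks = n_blocks,
                 noise = noise, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (flat YAML)
#'
#' Round-trips [pipeline_config()] through a flat key-value file; writing
#' then reading then writing again is idempotent.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  flat <- list(
    seed = cfg$seed,
    levels = cfg$levels,
    targets = cfg$targets,
    repeats = cfg$repeats,
    n_blocks = cfg$n_blocks,
    hrtf = unclass(cfg$hrtf),
    model = list(
      alpha1 = cfg$model$weighting$alpha1,
      alpha2 = cfg$model$weighting$alpha2,
      f_min_khz = cfg$model$weighting$f_min,
      f_max_khz = cfg$model$weighting$f_max,
      prior_kind = cfg$model$prior$kind,
      prior_mean_deg = cfg$model$prior$mean,
      prior_sigma_deg = cfg$model$prior$sigma,
      band_khz = cfg$model$analysis_band,
      decision = cfg$model$decision,
      correlation = cfg$model$correlation,
      weight_templates = cfg$model$weight_templates
    ),
    noise = if (is.null(cfg$noise)) NULL else list(
      spectral_sigma = cfg$noise$spectral_sigma,
      noise_floor = cfg$noise$noise_floor
    )
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("seed", "levels", "hrtf", "model")) {
    if (is.null(y[[k]])) stop("config is missing key '", k, "'")
  }
  hp <- do.call(hrtf_params, y$hrtf)
  m <- y$model
  mc <- model_config(
    weighting = weighting_params(m$alpha1, m$alpha2, m$f_min_khz, m$f_max_khz),
    prior = spatial_prior(m$prior_kind, m$prior_mean_deg, m$prior_sigma_deg),
    analysis_band = as.numeric(m$band_khz),
    decision = m$decision,
    correlation = m$correlation,
    weight_templates = isTRUE(m$weight_templates)
  )
  nm <- if (is.null(y$noise)) NULL else {
    noise_model(y$noise$spectral_sigma, y$noise$noise_floor)
  }
  pipeline_config(hrtf = hp, levels = as.numeric(y$levels), model = mc,
                  targets = y$targets, repeats = y$repeats,
                  n_blocks = y$n_blocks, noise = nm, seed = y$seed)
}

#' Run the full pipeline: HRTFs, stimuli, simulation, analysis
#'
#' Generates the canonical HRTF set, builds the stimulus matrix, simulates
#' the virtual experiment through the observer model, runs the
#' per-condition regression analysis, and writes every artifact as CSV
#' (plus a YAML manifest recording the configuration and per-stage
#' seeds). A rerun with the same configuration reproduces the tables
#' bit-identically.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts (`hrtfs`,
#'   `stimuli`, `design`, `trials`, `summary`) and `files` (paths).
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (!inherits(cfg, "pipeline_config")) stop("'cfg' must be pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  hrtfs <- make_canonical_hrtfs(cfg$hrtf)
  say("hrtf: %d elevations x %d frequencies", length(hrtfs$elevations),
      length(hrtfs$grid))
  sm <- make_stimulus_matrix(grid = hrtfs$grid, levels = cfg$levels)
  say("stimuli: %d conditions", length(sm$stimuli))

  design_seed <- derive_seed(cfg$seed, "design")
  design <- build_design(levels = cfg$levels, targets = cfg$targets,
                         repeats = cfg$repeats, n_blocks = cfg$n_blocks,
                         seed = design_seed, elevations = hrtfs$elevations)
  nm <- cfg$noise
  if (!is.null(nm)) nm$rng_seed <- derive_seed(cfg$seed, "noise")
  trials <- run_experiment(design, hrtfs, cfg$model, nm)
  say("trials: %d rows in %d blocks", nrow(trials), max(trials$block))
  summ <- summarize_conditions(trials)
  say("summary: %d condition fits", nrow(summ$conditions))

  files <- list(
    hrtf = file.path(out_dir, "hrtf.csv"),
    stimuli = file.path(out_dir, "stimuli.csv"),
    trials = file.path(out_dir, "trials.csv"),
    summary = file.path(out_dir, "summary.csv"),
    profiles = file.path(out_dir, "profiles.csv"),
    manifest = file.path(out_dir, "manifest.yaml"),
    config = file.path(out_dir, "config.yaml")
  )
  write_hrtf_table(hrtfs, files$hrtf)
  write_stimulus_csv(sm, files$stimuli)
  write_trials_csv(trials, files$trials)
  write_summary_csv(summ, files$summary, files$profiles)
  write_pipeline_config(cfg, files$config)
  yaml::write_yaml(list(
    seed = cfg$seed,
    stage_seeds = list(design = design_seed,
                       noise = if (is.null(nm)) NULL else nm$rng_seed),
    n_trials = nrow(trials),
    n_conditions = nrow(summ$conditions)
  ), files$manifest)
  invisible(list(hrtfs = hrtfs, stimuli = sm, design = design,
                 trials = trials, summary = summ, files = files))
}

#' Deterministic miniature fixtures for tests and examples
#'
#' A tiny bundle — 5-elevation HRTF set on a coarse grid, 3 stimuli, and
#' a small design — loadable through the same readers as full-size data.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, the fixtures are also
#'   written as CSV through the standard writers.
#' @return List with `hrtfs`, `stimuli` (list of 3), `design`, and (if
#'   `dir` is given) `files`.
#' @export
make_fixtures <- function(seed = 0L, dir = NULL) {
  grid <- make_frequency_grid(0.5, 20, 16)
  elevations <- make_elevation_grid(-40, 60, 25)
  hrtfs <- make_canonical_hrtfs(hrtf_params(rng_seed = seed + 7L),
                                grid, elevations)
  stimuli <- list(flat = make_stimulus(47, 47, grid),
                  pos = make_stimulus(65, 29, grid),
                  neg = make_stimulus(29, 65, grid))
  design <- build_design(levels = c(29, 47, 65), targets = elevations,
                         repeats = 1, n_blocks = 3, seed = seed,
                         elevations = elevations)
  out <- list(hrtfs = hrtfs, stimuli = stimuli, design = design)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(hrtf = file.path(dir, "fixture_hrtf.csv"),
                  trials = file.path(dir, "fixture_trials.csv"))
    write_hrtf_table(hrtfs, files$hrtf)
    write_trials_csv(run_experiment(design, hrtfs, model_config()),
                     files$trials)
    out$files <- files
  }
  out
}
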