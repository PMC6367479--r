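#' Linear stimulus-response regression minimizing mean absolute error
#'
#' Fits `response = g * target + b` by minimizing the mean absolute
#' residual, which is less sensitive to outliers (such as up-down
#' confusions) than least squares. The gain `g` is the response slope
#' (1 = accurate), the bias `b` the offset in degrees. The fit also
#' reports Pearson's `r`, the coefficient of determination `r2 = r^2` (a
#' precision measure), the residual SD around the fitted line, and the
#' mean absolute error.
#'
#' The objective is convex and piecewise linear. The optimizer runs a
#' Nelder-Mead simplex from the least-squares start, then refines with a
#' profiled line search over `g` (for fixed gain the optimal intercept is
#' the median residual), keeping the better of the two; parameter
#' tolerance 1e-6.
#'
#' Degenerate input (zero-variance targets) leaves the gain undefined:
#' the fit is flagged and returns `g = NA`, `b = median(responses)`.
#'
#' @param targets,responses numeric vectors (degrees), length >= 3.
#' @return List of class `"mae_fit"`: `g`, `b`, `r`, `r2`,
#'   `residual_sd`, `mae`, `n`, `degenerate`.
#' @examples
#' f <- fit_linear_mae(c(-30, 0, 30, 60), c(-5, 10, 25, 40))
#' c(f$g, f$b)  # 0.5 10
#' @export
fit_linear_mae <- function(targets, responses) {
  if (length(targets) != length(responses)) stop("lengths differ")
  if (length(targets) < 3) stop("need at least 3 points")
  if (any(!is.finite(targets)) || any(!is.finite(responses))) {
    stop("inputs must be finite")
  }
  n <- length(targets)
  if (stats::sd(targets) == 0) {
    b <- stats::median(responses)
    res <- responses - b
    return(structure(list(g = NA_real_, b = b, r = NA_real_, r2 = NA_real_,
                          residual_sd = stats::sd(res),
                          mae = mean(abs(res)), n = n, degenerate = TRUE),
                     class = "mae_fit"))
  }
  obj <- function(par) mean(abs(responses - par[1] * targets - par[2]))
  ols <- stats::coef(stats::lm.fit(cbind(targets, 1), responses))
  start <- c(ols[[1]], ols[[2]])
  nm <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 5000))
  # profiled refinement: b*(g) = median(responses - g * targets)
  prof <- function(g) {
    b <- stats::median(responses - g * targets)
    mean(abs(responses - g * targets - b))
  }
  lo <- min(nm$par[1], start[1]) - 2
  hi <- max(nm$par[1], start[1]) + 2
  op <- stats::optimize(prof, c(lo, hi), tol = 1e-7)
  g2 <- op$minimum
  cand2 <- c(g2, stats::median(responses - g2 * targets))
  best <- if (op$objective < nm$value) cand2 else nm$par
  g <- best[1]; b <- best[2]
  res <- responses - g * targets - b
  r <- safe_cor(targets, responses)
  structure(list(g = g, b = b, r = r, r2 = r * r,
                 residual_sd = stats::sd(res), mae = mean(abs(res)),
                 n = n, degenerate = FALSE),
            class = "mae_fit")
}

#' @export
print.mae_fit <- function(x, ...) {
  cat(sprintf("MAE regression (n = %d): g = %.3f, b = %.2f deg, r2 = %.3f, MAE = %.2f deg\n",
              x$n, x$g, x$b, x$r2, x$mae))
  invisible(x)
}

#' Per-condition regression summary and contrast/level profiles
#'
#' Fits the stimulus-response regression separately for each of the
#' stimulus conditions in a trial table, then aggregates two profiles:
#' the contrast profile (mean fit parameters over conditions sharing
#' `contrast_db` — the anti-diagonals of the stimulus matrix) and the
#' level profile (the zero-contrast main diagonal against band level).
#' With `pool = TRUE` the profiles instead refit pooled trials per
#' contrast (and per diagonal level).
#'
#' @param trials trial table with columns `nri_db`, `ori_db`,
#'   `contrast_db`, `elevation_t_deg`, `elevation_r_deg`.
#' @param pool refit pooled trials for the profiles instead of averaging
#'   per-condition fit parameters.
#' @return List of class `"condition_summary"`: `conditions` (one row per
#'   condition: `nri_db`, `ori_db`, `contrast_db`, `g`, `b`, `r`, `r2`,
#'   `residual_sd_deg`, `mae_deg`, `n`), `by_contrast`, `by_level`.
#' @export
summarize_conditions <- function(trials, pool = FALSE) {
  need <- c("nri_db", "ori_db", "contrast_db",
            "elevation_t_deg", "elevation_r_deg")
  if (!all(need %in% names(trials))) {
    stop("missing columns: ", paste(setdiff(need, names(trials)), collapse = ", "))
  }
  fit_row <- function(d) {
    if (nrow(d) < 3) {
      return(data.frame(g = NA_real_, b = NA_real_, r = NA_real_,
                        r2 = NA_real_, residual_sd_deg = NA_real_,
                        mae_deg = NA_real_, n = nrow(d), flagged = TRUE))
    }
    f <- fit_linear_mae(d$elevation_t_deg, d$elevation_r_deg)
    data.frame(g = f$g, b = f$b, r = f$r, r2 = f$r2,
               residual_sd_deg = f$residual_sd, mae_deg = f$mae, n = f$n,
               flagged = f$degenerate)
  }
  keys <- unique(trials[, c("nri_db", "ori_db", "contrast_db")])
  keys <- keys[order(keys$nri_db, keys$ori_db), ]
  conditions <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- trials[trials$nri_db == keys$nri_db[i] & trials$ori_db == keys$ori_db[i], ]
    cbind(keys[i, ], fit_row(d), row.names = NULL)
  }))
  ok <- !conditions$flagged
  agg <- function(d, by) {
    out <- stats::aggregate(d[, c("g", "b", "r", "r2", "residual_sd_deg",
                                  "mae_deg")],
                            by = by, FUN = mean)
    out$n <- stats::aggregate(d$n, by = by, FUN = sum)$x
    out
  }
  if (pool) {
    by_contrast <- do.call(rbind, lapply(sort(unique(trials$contrast_db)),
                                         function(cc) {
      d <- trials[trials$contrast_db == cc, ]
      cbind(data.frame(contrast_db = cc), fit_row(d), row.names = NULL)
    }))
    diagt <- trials[trials$nri_db == trials$ori_db, ]
    by_level <- do.call(rbind, lapply(sort(unique(diagt$nri_db)), function(lv) {
      d <- diagt[diagt$nri_db == lv, ]
      cbind(data.frame(level_db = lv), fit_row(d), row.names = NULL)
    }))
  } else {
    by_contrast <- agg(conditions[ok, ],
                       list(contrast_db = conditions$contrast_db[ok]))
    diag_ok <- ok & conditions$nri_db == conditions$ori_db
    by_level <- agg(conditions[diag_ok, ],
                    list(level_db = conditions$nri_db[diag_ok]))
  }
  structure(list(conditions = conditions, by_contrast = by_contrast,
                 by_level = by_level, pooled = pool),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition summary: %d conditions (%d flagged)\n",
              nrow(x$conditions), sum(x$conditions$flagged)))
  cat("contrast profile:\n")
  print(x$by_contrast[, c("contrast_db", "g", "b", "r2")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' Export a condition summary as CSV
#'
#' @param summary a [condition_summary][summarize_conditions].
#' @param path file path for the per-condition table.
#' @param profile_path optional path for the contrast/level profiles
#'   (written as one CSV with a `profile` column).
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, profile_path = NULL) {
  utils::write.csv(summary$conditions, path, row.names = FALSE)
  if (!is.null(profile_path)) {
    a <- summary$by_contrast
    a$profile <- "contrast"
    names(a)[names(a) == "contrast_db"] <- "value"
    b <- summary$by_level
    b$profile <- "level"
    names(b)[names(b) == "level_db"] <- "value"
    cols <- c("profile", "value", "g", "b", "r", "r2", "residual_sd_deg",
              "mae_deg", "n")
    utils::write.csv(rbind(a[, cols], b[, cols]), profile_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Double-pole coordinates from a Cartesian direction
#'
#' Azimuth is the angle between the direction and the midsagittal plane,
#' elevation the angle to the horizontal plane; in this system
#' `|azimuth| + |elevation| <= 90` for any direction, with equality on
#' the interaural axis. The frame is (forward, right, up); only frontal
#' directions (forward component >= 0) are admitted.
#'
#' @param direction numeric length-3 vector (or n x 3 matrix) in the
#'   (forward, right, up) frame; need not be unit length.
#' @return Data frame with `azimuth_deg`, `elevation_deg`.
#' @examples
#' double_pole_from_cartesian(c(1, 0, 0))  # 0, 0
#' double_pole_from_cartesian(c(0, 0, 1))  # 0, 90
#' @export
double_pole_from_cartesian <- function(direction) {
  m <- if (is.matrix(direction)) direction else matrix(direction, nrow = 1)
  if (ncol(m) != 3) stop("'direction' must have 3 components")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero direction vector")
  m <- m / nrm
  if (any(m[, 1] < -1e-9)) stop("direction must lie in the frontal hemisphere")
  data.frame(azimuth_deg = asin(pmin(1, pmax(-1, m[, 2]))) * 180 / pi,
             elevation_deg = asin(pmin(1, pmax(-1, m[, 3]))) * 180 / pi)
}

#' Unfold a frontal elevation to its rear mirror
#'
#' A percept reported at the mirror-imaged frontal position corresponds
#' to the rear elevation `180 - elevation_front`. The map is an
#' involution: applying it twice returns the input.
#'
#' @param elevation_front elevation in degrees, within `[-90, 90]` (or
#'   the rear image within `[90, 270]`, which maps back).
#' @return `180 - elevation_front`.
#' @examples
#' rear_unfold(60)  # 120
#' @export
rear_unfold <- function(elevation_front) {
  if (any(elevation_front < -90 | elevation_front > 270)) {
    stop("'elevation_front' out of range")
  }
  180 - elevation_front
}

#' Two-cluster gap test for bimodal (up-down confused) responses
#'
#' Splits the sorted responses at the largest inter-point gap and calls
#' the distribution bimodal when that gap is at least `gap_deg` and both
#' clusters hold at least a fraction `min_frac` of the responses. Used to
#' detect up-down confusions: bistable percepts produce one cluster near
#' the veridical (often downward) elevation and one far upward.
#'
#' @param x numeric responses in degrees.
#' @param gap_deg minimum gap between the clusters (default 40).
#' @param min_frac minimum fraction of responses per cluster.
#' @return List: `bimodal` (logical), `gap` (deg), `split` (boundary
#'   value), `fractions` (cluster fractions).
#' @export
two_cluster_gap <- function(x, gap_deg = 40, min_frac = 0.1) {
  s <- sort(x)
  if (length(s) < 4 || length(unique(s)) < 2) {
    return(list(bimodal = FALSE, gap = 0, split = NA_real_,
                fractions = c(1, 0)))
  }
  gp <- diff(s)
  k <- which.max(gp)
  fr <- c(k, length(s) - k) / length(s)
  list(bimodal = gp[k] >= gap_deg && min(fr) >= min_frac,
       gap = gp[k], split = mean(s[k + 0:1]), fractions = fr)
}
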