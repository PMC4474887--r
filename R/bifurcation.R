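# Dose scans and the quantitative analyses built on them: phase diagram,
# collapse-time curve, saturating-law fit, saturation point, time-resolved
# bifurcation and maxima-versus-dose summaries.

#' The saturating collapse-time law
#'
#' \eqn{\Delta t = A/(B + e^{-IR})}: exponential-like growth at low dose,
#' saturating at \eqn{A/B} once \eqn{e^{-IR} \ll B}.
#'
#' @param dose_gy Dose values (Gy).
#' @param A,B Law parameters.
#' @return Predicted collapse times.
#' @export
collapse_law <- function(dose_gy, A, B) A / (B + exp(-dose_gy))

#' Run a deterministic irradiation-dose scan
#'
#' Integrates the model once per dose with identical settings.  The dose
#' grid is sorted increasing and de-duplicated; a failed integration is
#' recorded per dose (with a warning) without aborting the scan.  To bound
#' memory only the series of \code{keep_species} are retained.
#'
#' @param doses Non-empty vector of doses (Gy), \code{>= 0}.
#' @param params,control,dsb_per_gy,init_overrides Passed to
#'   [make_initial_state()] / [integrate_model()].
#' @param horizon_h Integration horizon (hours).
#' @param keep_species Species whose sampled series are stored.
#' @param cache_dir Optional directory: each trajectory is also written as
#'   CSV (+JSON sidecar) named by its dose.
#' @return A \code{ccm_scan}: list with \code{doses}, \code{runs} (one
#'   element per dose: \code{dose_gy}, \code{time_h}, \code{series} (named
#'   list of value vectors), \code{error}), and the shared settings.
#' @export
run_dose_scan <- function(doses, params = default_parameters(),
                          horizon_h = 250,
                          control = integration_control(),
                          dsb_per_gy = 40,
                          keep_species = c("cyclin", "mpf", "p53", "mdm2"),
                          init_overrides = NULL, cache_dir = NULL) {
  stopifnot(length(doses) >= 1L, all(doses >= 0))
  doses <- sort(unique(as.numeric(doses)))
  runs <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    d <- doses[i]
    runs[[i]] <- tryCatch({
      init <- make_initial_state(d, overrides = init_overrides,
                                 dsb_per_gy = dsb_per_gy,
                                 params = params, control = control)
      tr <- integrate_model(params, init, t_end_h = horizon_h,
                            control = control)
      if (!is.null(cache_dir))
        write_trajectory(tr, file.path(cache_dir,
                                       sprintf("trajectory_ir_%g.csv", d)))
      ser <- lapply(stats::setNames(keep_species, keep_species),
                    function(sp) species_series(tr, sp)$value)
      list(dose_gy = d, time_h = tr$time_h, series = ser, error = NULL)
    }, error = function(e) {
      warning(sprintf("dose %g Gy failed: %s", d, conditionMessage(e)),
              call. = FALSE)
      list(dose_gy = d, time_h = NULL, series = NULL,
           error = conditionMessage(e))
    })
  }
  structure(list(doses = doses, runs = runs, params = params,
                 control = control, horizon_h = horizon_h,
                 dsb_per_gy = dsb_per_gy, keep_species = keep_species,
                 init_overrides = init_overrides),
            class = "ccm_scan")
}

#' @export
print.ccm_scan <- function(x, ...) {
  cat(sprintf(
    "ccm_scan: %d doses in [%g, %g] Gy, horizon %g h, %d failed\n",
    length(x$doses), min(x$doses), max(x$doses), x$horizon_h,
    sum(!vapply(x$runs, function(r) is.null(r$error), logical(1L)))))
  invisible(x)
}

# Scan-wide amplitude range of one species: the largest peak-to-trough
# range over all successful runs.  Detection thresholds derived from it
# are shared across doses, as the scan contract requires.
scan_species_range <- function(scan, species) {
  rng <- 0
  for (i in seq_along(scan$doses)) {
    if (!is.null(scan$runs[[i]]$error)) next
    v <- scan_series(scan, i, species)$value
    rng <- max(rng, max(v) - min(v))
  }
  rng
}

# Series of one species from one scan run, as a time_h/value data.frame.
scan_series <- function(scan, i, species) {
  run <- scan$runs[[i]]
  if (!is.null(run$error))
    stop("dose ", run$dose_gy, " Gy failed: ", run$error, call. = FALSE)
  sp <- species_table()$species[species_index(species)]
  if (!sp %in% names(run$series))
    stop("species ", sp, " was not kept in the scan", call. = FALSE)
  data.frame(time_h = run$time_h, value = run$series[[sp]])
}

# Oscillation test used by the phase diagram: does the series show at
# least min_peaks maxima of prominence >= eps inside the window?
late_window_oscillating <- function(s, window, eps, min_peaks) {
  w <- s[s$time_h >= window[1L] & s$time_h <= window[2L], ]
  mx <- find_maxima(w, transient_h = 0)
  prom <- mx$value - min(w$value)
  mx <- mx[prom >= eps, , drop = FALSE]
  list(oscillating = nrow(mx) >= min_peaks, maxima = mx,
       n = nrow(mx), max_value = if (nrow(mx)) max(mx$value) else NA_real_)
}

#' Oscillation/oscillation-death phase diagram over dose
#'
#' Classifies each scanned dose by whether the species still oscillates in
#' a fixed late-time window, and locates the boundary dose between the
#' low-dose oscillation-death phase (the ringing has died before the
#' window) and the high-dose oscillating phase, refining by bisection with
#' fresh integrations.
#'
#' The default window [70, 120] h starts beyond the relaxation time of
#' moderately dosed runs and before the longest collapse time the model
#' produces, so both phases are observable; the boundary location is
#' sensitive to this choice (see the methods vignette).
#'
#' @param scan A \code{ccm_scan} whose horizon covers \code{window}.
#' @param species Species classified (default p53).
#' @param window Absolute late-time window (hours).
#' @param eps_frac Peak-prominence threshold, as a fraction of the
#'   species' scan-wide amplitude range (one shared threshold for every
#'   dose, per the scan's shared-tolerance contract).
#' @param min_peaks Minimum qualifying maxima to call the window
#'   oscillating.  The default 1 mirrors the maxima-scatter construction
#'   of the phase diagram: a dose is in the oscillating phase exactly when
#'   it still contributes an above-threshold maximum to the late window.
#' @param refine Bisection-refine the boundary by integrating midpoint
#'   doses (horizon = \code{window[2]}).
#' @param dose_tol Bisection dose tolerance (Gy).
#' @return A \code{ccm_phase_diagram}: list with \code{table} (data.frame
#'   dose_gy, phase, n_peaks, max_value), \code{maxima} (all late-window
#'   maxima, data.frame dose_gy/time_h/value: the phase-diagram ordinate),
#'   \code{boundary_gy} (NA when the grid is single-phase), settings.
#' @export
phase_boundary <- function(scan, species = "p53", window = c(70, 120),
                           eps_frac = 0.01, min_peaks = 1L, refine = TRUE,
                           dose_tol = 0.02) {
  stopifnot(inherits(scan, "ccm_scan"), length(window) == 2L,
            window[2L] > window[1L])
  if (scan$horizon_h < window[2L])
    stop("scan horizon is shorter than the classification window",
         call. = FALSE)
  n <- length(scan$doses)
  eps <- eps_frac * scan_species_range(scan, species)
  osc <- logical(n)
  npk <- integer(n)
  mval <- numeric(n)
  mx_all <- list()
  for (i in seq_len(n)) {
    s <- scan_series(scan, i, species)
    lw <- late_window_oscillating(s, window, eps, min_peaks)
    osc[i] <- lw$oscillating
    npk[i] <- lw$n
    mval[i] <- lw$max_value
    if (nrow(lw$maxima))
      mx_all[[length(mx_all) + 1L]] <-
        data.frame(dose_gy = scan$doses[i], lw$maxima)
  }
  tab <- data.frame(dose_gy = scan$doses,
                    phase = ifelse(osc, "oscillating", "oscillation_death"),
                    n_peaks = npk, max_value = mval)
  boundary <- NA_real_
  if (any(osc) && any(!osc)) {
    lo <- max(scan$doses[!osc & scan$doses < min(scan$doses[osc])])
    hi <- min(scan$doses[osc])
    if (refine) {
      check <- function(d) {
        init <- make_initial_state(d, overrides = scan$init_overrides,
                                   dsb_per_gy = scan$dsb_per_gy,
                                   params = scan$params,
                                   control = scan$control)
        tr <- integrate_model(scan$params, init, t_end_h = window[2L],
                              control = scan$control)
        s <- species_series(tr, species)
        late_window_oscillating(s, window, eps, min_peaks)$oscillating
      }
      while (hi - lo > dose_tol) {
        mid <- (lo + hi) / 2
        if (check(mid)) hi <- mid else lo <- mid
      }
    }
    boundary <- (lo + hi) / 2
  }
  structure(list(table = tab,
                 maxima = if (length(mx_all)) do.call(rbind, mx_all)
                          else data.frame(dose_gy = numeric(),
                                          time_h = numeric(),
                                          value = numeric()),
                 boundary_gy = boundary, species = species,
                 window = window, eps_frac = eps_frac, eps = eps,
                 min_peaks = min_peaks, dose_tol = dose_tol),
            class = "ccm_phase_diagram")
}

#' @export
print.ccm_phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram (%s, window [%g, %g] h): boundary %s Gy\n",
              x$species, x$window[1L], x$window[2L],
              if (is.na(x$boundary_gy)) "none"
              else format(signif(x$boundary_gy, 4))))
  invisible(x)
}

#' Collapse time as a function of dose
#'
#' For each scanned dose, measures the collapse time of the species'
#' oscillation.  With \code{statistic = "onset"} (default) the collapse
#' time is the time at which the oscillation dies out — the start of the
#' terminal quiescent interval; a dose whose signal never establishes an
#' oscillation (fewer than \code{min_peaks} maxima of prominence
#' \code{eps}) reports 0, and a dose still oscillating at the horizon is
#' flagged censored.  With \code{statistic = "duration"} the collapse time
#' is the length of the longest quiescent interval
#' (see [collapse_interval()]), censored when that interval reaches the
#' horizon.
#'
#' @param scan A \code{ccm_scan}.
#' @param species Species measured (default p53).
#' @param statistic \code{"onset"} or \code{"duration"}; see Details.
#' @param eps_frac Quiescence threshold, as a fraction of the species'
#'   scan-wide amplitude range (shared across doses).
#' @param min_peaks Maxima needed to count as an established oscillation.
#' @return A \code{ccm_collapse_curve}: data.frame with \code{dose_gy},
#'   \code{dt_h}, \code{censored}; settings as attributes
#'   (\code{time_unit = "h"}).
#' @export
collapse_curve <- function(scan, species = "p53",
                           statistic = c("onset", "duration"),
                           eps_frac = 0.01, min_peaks = 5L) {
  stopifnot(inherits(scan, "ccm_scan"))
  statistic <- match.arg(statistic)
  n <- length(scan$doses)
  eps <- eps_frac * scan_species_range(scan, species)
  dt <- numeric(n)
  cens <- logical(n)
  for (i in seq_len(n)) {
    s <- scan_series(scan, i, species)
    per <- dominant_period(s$time_h, s$value)
    win <- if (is.na(per)) 5 else 1.5 * per
    if (statistic == "onset") {
      co <- collapse_onset(s, eps, win, min_peaks)
      if (!co$oscillated) {
        dt[i] <- 0
      } else if (co$censored) {
        dt[i] <- NA_real_
        cens[i] <- TRUE
      } else dt[i] <- co$onset_h
    } else {
      ci <- collapse_interval(s, eps = eps, window_h = win)
      dt[i] <- ci$dt_h
      cens[i] <- ci$censored
    }
  }
  structure(data.frame(dose_gy = scan$doses, dt_h = dt, censored = cens),
            species = species, statistic = statistic, eps_frac = eps_frac,
            eps = eps, min_peaks = min_peaks, time_unit = "h",
            class = c("ccm_collapse_curve", "data.frame"))
}

#' Fit the saturating collapse-time law
#'
#' Least-squares fit of \eqn{\Delta t = A/(B + e^{-IR})} to an uncensored
#' collapse curve.  For fixed \eqn{B} the optimal \eqn{A} is linear
#' (\eqn{A = \sum y g / \sum g^2}, \eqn{g = 1/(B+e^{-IR})}), so the fit
#' profiles the 1-D sum of squares over \eqn{\log_{10} B} (coarse
#' multi-start grid spanning 11 orders of magnitude, then golden-section
#' refinement), which is deterministic and insensitive to starting values.
#'
#' The fit's native time unit is seconds (the model's integration unit);
#' \code{time_unit = "h"} fits the same data in hours, scaling \eqn{A} by
#' 3600 and leaving \eqn{B} unchanged.
#'
#' @param curve A \code{ccm_collapse_curve} (censored points are dropped).
#' @param time_unit \code{"s"} (default, native) or \code{"h"}.
#' @return A \code{ccm_collapse_fit}: list with \code{A}, \code{B},
#'   \code{residual_norm} (same unit as \eqn{\Delta t}), \code{n},
#'   \code{time_unit}, \code{method}, \code{note}.
#' @export
fit_collapse_model <- function(curve, time_unit = c("s", "h")) {
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(curve, "ccm_collapse_curve"))
  use <- !curve$censored & !is.na(curve$dt_h)
  d <- curve$dose_gy[use]
  y <- curve$dt_h[use]
  if (length(y) < 4L)
    stop("at least 4 uncensored points are required", call. = FALSE)
  if (all(y == 0)) stop("nothing to fit: all collapse times are zero",
                        call. = FALSE)
  if (time_unit == "s") y <- y * HOURS
  e <- exp(-d)
  sse <- function(lb) {
    g <- 1 / (10^lb + e)
    A <- sum(y * g) / sum(g * g)
    sum((y - A * g)^2)
  }
  grid <- seq(-8, 3, by = 0.05)
  vals <- vapply(grid, sse, numeric(1L))
  j <- which.min(vals)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  B <- 10^opt$minimum
  g <- 1 / (B + e)
  A <- sum(y * g) / sum(g * g)
  structure(list(A = A, B = B, residual_norm = sqrt(opt$objective),
                 n = length(y), time_unit = time_unit,
                 method = "profiled 1-D least squares over log10(B)",
                 note = paste("saturation level A/B and low-dose level",
                              "A/(B+1) are reported in the fit's time",
                              "unit; compare like with like")),
            class = "ccm_collapse_fit")
}

#' @export
print.ccm_collapse_fit <- function(x, ...) {
  cat(sprintf(
    "collapse-law fit (dt in %s): A = %.6g, B = %.6g (A/B = %.6g %s)\n",
    x$time_unit, x$A, x$B, x$A / x$B, x$time_unit))
  cat(sprintf("  n = %d, residual norm = %.4g\n", x$n, x$residual_norm))
  invisible(x)
}

#' Detect saturation (plateau) of the collapse-time curve
#'
#' \eqn{R_c} is the smallest dose from which every subsequent collapse
#' time lies within \code{plateau_tol} (relative) of the terminal value;
#' \eqn{\Delta t_c} is the mean collapse time over the plateau.  A plateau
#' needs at least \code{min_points} points and must start strictly inside
#' the grid, otherwise the result is "not saturated".
#'
#' @param curve A \code{ccm_collapse_curve} (censored points dropped).
#' @param plateau_tol Relative plateau tolerance.
#' @param min_points Minimum points in the plateau.
#' @return A \code{ccm_saturation}: list with \code{saturated},
#'   \code{r_c_gy}, \code{dt_c_h} (NA when not saturated),
#'   \code{n_plateau}, \code{plateau_tol}.
#' @export
saturation <- function(curve, plateau_tol = 0.02, min_points = 3L) {
  stopifnot(inherits(curve, "ccm_collapse_curve"), plateau_tol > 0)
  use <- !curve$censored & !is.na(curve$dt_h)
  d <- curve$dose_gy[use]
  y <- curve$dt_h[use]
  o <- order(d)
  d <- d[o]; y <- y[o]
  n <- length(y)
  not_sat <- structure(list(saturated = FALSE, r_c_gy = NA_real_,
                            dt_c_h = NA_real_, n_plateau = 0L,
                            plateau_tol = plateau_tol),
                       class = "ccm_saturation")
  if (n < min_points + 1L) return(not_sat)
  terminal <- y[n]
  within <- abs(y - terminal) <= plateau_tol * abs(terminal)
  # smallest index from which all subsequent points are within tolerance
  ok_from <- rev(cumprod(rev(within))) > 0
  i <- which(ok_from)[1L]
  if (is.na(i) || i == 1L || (n - i + 1L) < min_points) return(not_sat)
  structure(list(saturated = TRUE, r_c_gy = d[i],
                 dt_c_h = mean(y[i:n]), n_plateau = n - i + 1L,
                 plateau_tol = plateau_tol),
            class = "ccm_saturation")
}

#' @export
print.ccm_saturation <- function(x, ...) {
  if (!x$saturated) cat("collapse curve not saturated within the grid\n")
  else cat(sprintf(
    "saturation: R_c = %.4g Gy, dt_c = %.4g h (%d plateau points)\n",
    x$r_c_gy, x$dt_c_h, x$n_plateau))
  invisible(x)
}

#' Time-resolved bifurcation diagram at one dose
#'
#' Integrates the model at the given dose and returns the (time, value)
#' maxima scatter of the species — the time-resolved bifurcation panel —
#' together with its sliding-window regime segmentation.
#'
#' @param ir_gy Dose (Gy).
#' @param species Species analyzed.
#' @param params,control,dsb_per_gy,init_overrides Model settings.
#' @param horizon_h Integration horizon.
#' @param window_h,hop_h Segmentation windows.
#' @param ... Further tolerances for [classify_regime()].
#' @return A \code{ccm_bifurcation}: list with \code{ir_gy},
#'   \code{species}, \code{maxima} (data.frame time_h/value, transient
#'   kept: the full scatter), \code{segments} (a \code{ccm_segments}) and
#'   \code{series} (the sampled species series).
#' @export
time_resolved_bifurcation <- function(ir_gy, species = "cyclin",
                                      params = default_parameters(),
                                      horizon_h = 250,
                                      control = integration_control(),
                                      dsb_per_gy = 40,
                                      init_overrides = NULL,
                                      window_h = 25, hop_h = 5, ...) {
  init <- make_initial_state(ir_gy, overrides = init_overrides,
                             dsb_per_gy = dsb_per_gy, params = params,
                             control = control)
  tr <- integrate_model(params, init, t_end_h = horizon_h,
                        control = control)
  s <- species_series(tr, species)
  structure(list(ir_gy = ir_gy, species = species,
                 maxima = as.data.frame(find_maxima(s, transient_h = 0)),
                 segments = segment_regimes(s, window_h = window_h,
                                            hop_h = hop_h, ...),
                 series = s),
            class = "ccm_bifurcation")
}

#' Maxima values per dose inside a fixed time window
#'
#' The dose-axis bifurcation summary: all maxima of the species inside
#' \code{t_window} at each scanned dose.
#'
#' @param scan A \code{ccm_scan}.
#' @param species Species summarized.
#' @param t_window Time window (hours), default [0, 50].
#' @return Data.frame with \code{dose_gy}, \code{time_h}, \code{value}.
#' @export
maxima_vs_dose <- function(scan, species, t_window = c(0, 50)) {
  stopifnot(inherits(scan, "ccm_scan"), length(t_window) == 2L)
  if (t_window[2L] > scan$horizon_h)
    stop("t_window extends beyond the scan horizon", call. = FALSE)
  out <- list()
  for (i in seq_along(scan$doses)) {
    s <- scan_series(scan, i, species)
    w <- s[s$time_h >= t_window[1L] & s$time_h <= t_window[2L], ]
    mx <- find_maxima(w, transient_h = 0)
    if (nrow(mx))
      out[[length(out) + 1L]] <- data.frame(dose_gy = scan$doses[i],
                                            time_h = mx$time_h,
                                            value = mx$value)
  }
  if (!length(out))
    return(data.frame(dose_gy = numeric(), time_h = numeric(),
                      value = numeric()))
  do.call(rbind, out)
}
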