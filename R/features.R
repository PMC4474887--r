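# Oscillation features: maxima extraction, collapse detection, regime
# classification and sliding-window segmentation.

# Coerce the various series inputs (ccm_trajectory + species, or a
# data.frame with time_h/value) to a two-column data.frame.
as_series <- function(x, species = NULL) {
  if (inherits(x, "ccm_trajectory")) {
    if (is.null(species))
      stop("a species must be named when passing a trajectory",
           call. = FALSE)
    return(species_series(x, species))
  }
  if (is.data.frame(x) && all(c("time_h", "value") %in% names(x)))
    return(x[, c("time_h", "value")])
  stop("cannot interpret input as a time series", call. = FALSE)
}

# Median peak spacing of the raw sampled series (no refinement); NA when
# fewer than two strict maxima exist.
dominant_period <- function(time_h, value) {
  i <- which(diff(sign(diff(value))) == -2) + 1L
  if (length(i) < 2L) return(NA_real_)
  stats::median(diff(time_h[i]))
}

#' Local maxima of a species series after transient removal
#'
#' Strict local maxima of the sampled series, with parabolic sub-sample
#' refinement of peak time and height; plateaus (runs of tied values higher
#' than both neighbours) are reported once at their midpoint, unrefined.
#'
#' @param x A \code{ccm_trajectory} (give \code{species}) or a data.frame
#'   with columns \code{time_h}, \code{value}.
#' @param species Species name, state name or index (trajectory input only).
#' @param transient_h Initial interval to discard (hours).  The default
#'   \code{NULL} uses the larger of 10\% of the series span and 5 dominant
#'   periods (0 when the series has no two peaks to estimate a period
#'   from).
#' @return A \code{ccm_maxima}: data.frame with columns \code{time_h},
#'   \code{value} (one row per maximum, times strictly increasing), with
#'   attributes \code{species}, \code{transient_h}, \code{signal_range}
#'   (post-transient peak-to-trough of the raw signal), \code{signal_min},
#'   \code{window} (analyzed time window) and \code{period_h} (median peak
#'   spacing, NA if < 2 peaks).
#' @export
#' @examples
#' s <- synth_signal("sustained", period_h = 2, horizon_h = 20)
#' nrow(find_maxima(s, transient_h = 0))   # 10 peaks
find_maxima <- function(x, species = NULL, transient_h = NULL) {
  s <- as_series(x, species)
  if (nrow(s) < 3L) stop("series too short", call. = FALSE)
  span <- s$time_h[nrow(s)] - s$time_h[1L]
  if (is.null(transient_h)) {
    per <- dominant_period(s$time_h, s$value)
    transient_h <- max(0.1 * span, if (is.na(per)) 0 else 5 * per)
  }
  keep <- s$time_h >= s$time_h[1L] + transient_h
  if (sum(keep) < 3L)
    stop("window after transient removal is shorter than one sample",
         call. = FALSE)
  tt <- s$time_h[keep]
  v <- s$value[keep]
  n <- length(v)

  # collapse tied runs so plateaus become single candidates
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rv <- r$values
  m <- length(rv)
  pk_t <- numeric(0)
  pk_v <- numeric(0)
  if (m >= 3L) {
    for (j in 2:(m - 1L)) {
      if (rv[j] > rv[j - 1L] && rv[j] > rv[j + 1L]) {
        if (r$lengths[j] > 1L) {              # plateau: midpoint, unrefined
          pk_t <- c(pk_t, (tt[starts[j]] + tt[ends[j]]) / 2)
          pk_v <- c(pk_v, rv[j])
        } else {
          i <- starts[j]
          t0 <- tt[i]; y0 <- v[i]
          if (i > 1L && i < n) {              # parabolic refinement
            ym <- v[i - 1L]; yp <- v[i + 1L]
            den <- ym - 2 * y0 + yp
            if (den < 0) {
              off <- 0.5 * (ym - yp) / den
              dt <- (tt[i + 1L] - tt[i - 1L]) / 2
              t0 <- tt[i] + off * dt
              y0 <- y0 - 0.25 * (ym - yp) * off
            }
          }
          pk_t <- c(pk_t, t0)
          pk_v <- c(pk_v, y0)
        }
      }
    }
  }
  out <- data.frame(time_h = pk_t, value = pk_v)
  structure(out,
            species = if (is.null(species)) NA_character_
                      else as.character(species),
            transient_h = transient_h,
            window = c(tt[1L], tt[n]),
            signal_range = max(v) - min(v),
            signal_min = min(v),
            period_h = if (length(pk_t) >= 2L) stats::median(diff(pk_t))
                       else NA_real_,
            class = c("ccm_maxima", "data.frame"))
}

# Rolling peak-to-trough excursion over a centred window of k samples.
rolling_excursion <- function(v, k) {
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(v)) return(rep(max(v) - min(v), length(v)))
  ex <- zoo::rollmax(v, k, fill = NA) + zoo::rollmax(-v, k, fill = NA)
  # extend edge values outward
  first <- which(!is.na(ex))[1L]
  last <- max(which(!is.na(ex)))
  ex[seq_len(first - 1L)] <- ex[first]
  ex[seq((last + 1L), length.out = length(v) - last)] <- ex[last]
  ex
}

# Quiescence mask and its runs; shared by collapse_interval/collapse_onset.
# A window centred at t sees [t - w/2, t + w/2], so a quiescent run of
# window centres understates the true quiet interval by half a window on
# every side that abuts an active epoch; those sides are extended back.
quiescent_runs <- function(s, eps, window_h) {
  dt <- stats::median(diff(s$time_h))
  k <- round(window_h / dt)
  ex <- rolling_excursion(s$value, k)
  q <- ex < eps
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start_h = s$time_h[starts[r$values]],
                    end_h = s$time_h[ends[r$values]],
                    at_start = starts[r$values] == 1L,
                    at_end = ends[r$values] == length(q))
  half <- window_h / 2
  t0 <- s$time_h[1L]
  t1 <- s$time_h[length(s$time_h)]
  out$start_h <- ifelse(out$at_start, t0, pmax(t0, out$start_h - half))
  out$end_h <- ifelse(out$at_end, t1, pmin(t1, out$end_h + half))
  out
}

#' Measure an oscillation-collapse interval
#'
#' Finds the longest contiguous interval in which the signal's rolling
#' peak-to-trough excursion stays below \code{eps}; the interval counts as
#' a collapse only when it exceeds \code{min_duration_h}.  Detection runs
#' on the full sampled trajectory (not only on maxima), so a quiescent
#' plateau without peaks is still measurable.  An interval that reaches the
#' end of the series is flagged \code{censored} (the collapse has not ended
#' within the horizon).
#'
#' @param x A \code{ccm_trajectory} (give \code{species}) or data.frame
#'   with \code{time_h}, \code{value}.
#' @param species Species, for trajectory input.
#' @param eps Excursion threshold in signal units; default 1\% of the
#'   series' global peak-to-trough range.
#' @param min_duration_h Minimum collapse length (hours); default twice the
#'   dominant period (5 h when no period is measurable).
#' @param window_h Width of the rolling excursion window (hours); default
#'   1.5 dominant periods (5 h fallback), wide enough that one full
#'   oscillation period registers its true amplitude.
#' @return A \code{ccm_collapse} list: \code{dt_h} (0 when no collapse),
#'   \code{start_h}, \code{end_h} (NA when no collapse), \code{censored},
#'   \code{eps}, \code{min_duration_h}, \code{note}.
#' @export
collapse_interval <- function(x, species = NULL, eps = NULL,
                              min_duration_h = NULL, window_h = NULL) {
  s <- as_series(x, species)
  rng <- max(s$value) - min(s$value)
  if (is.null(eps)) eps <- 0.01 * rng
  stopifnot(eps > 0)
  per <- dominant_period(s$time_h, s$value)
  if (is.null(window_h)) window_h <- if (is.na(per)) 5 else 1.5 * per
  if (is.null(min_duration_h))
    min_duration_h <- if (is.na(per)) 5 else 2 * per
  stopifnot(min_duration_h > 0)
  no_collapse <- function(note) {
    structure(list(dt_h = 0, start_h = NA_real_, end_h = NA_real_,
                   censored = FALSE, eps = eps,
                   min_duration_h = min_duration_h, note = note),
              class = "ccm_collapse")
  }
  if (rng < .Machine$double.eps)
    return(no_collapse("degenerate constant signal"))
  runs <- quiescent_runs(s, eps, window_h)
  if (!nrow(runs)) return(no_collapse("no quiescent interval"))
  len <- runs$end_h - runs$start_h
  ok <- len > min_duration_h
  if (!any(ok)) return(no_collapse("quiescence shorter than min_duration_h"))
  i <- which(ok)[which.max(len[ok])]
  structure(list(dt_h = len[i], start_h = runs$start_h[i],
                 end_h = runs$end_h[i], censored = runs$at_end[i],
                 eps = eps, min_duration_h = min_duration_h, note = ""),
            class = "ccm_collapse")
}

#' @export
print.ccm_collapse <- function(x, ...) {
  if (x$dt_h == 0) cat("no collapse detected", x$note, "\n")
  else cat(sprintf("collapse: dt = %.3g h over [%.3g, %.3g] h%s\n", x$dt_h,
                   x$start_h, x$end_h,
                   if (x$censored) " (censored at horizon)" else ""))
  invisible(x)
}

# Onset of terminal quiescence: the time at which a ringing/oscillating
# signal dies out for good.  Returns list(onset_h, censored, oscillated).
collapse_onset <- function(s, eps, window_h, min_peaks = 5L) {
  rng <- max(s$value) - min(s$value)
  runs <- quiescent_runs(s, eps, window_h)
  terminal <- nrow(runs) && runs$at_end[nrow(runs)]
  onset <- if (terminal) runs$start_h[nrow(runs)] else NA_real_
  # did the signal genuinely oscillate before dying?  count strict maxima
  # with prominence >= eps before the terminal quiescence
  i <- which(diff(sign(diff(s$value))) == -2) + 1L
  if (terminal) i <- i[s$time_h[i] <= onset]
  prom <- s$value[i] - min(s$value)
  n_osc <- sum(prom >= eps)
  list(onset_h = onset, censored = !terminal,
       oscillated = n_osc >= min_peaks)
}

# Split sorted heights at the k-1 largest gaps; returns cluster id per
# element of h (in original order).
gap_clusters <- function(h, k) {
  n <- length(h)
  if (k <= 1L || n <= k) {
    if (k >= n) return(seq_along(h))
    return(rep(1L, n))
  }
  o <- order(h)
  gaps <- diff(h[o])
  cut_after <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1L)])
  grp_sorted <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% cut_after)))
  grp <- integer(n)
  grp[o] <- grp_sorted
  grp
}

# Smallest k <= k_max whose gap-split clusters all have width <= delta
# times the height scale; NA when none fits.
select_k <- function(h, delta, k_max) {
  scale <- max(abs(h), .Machine$double.eps)
  for (k in seq_len(min(k_max, length(h)))) {
    grp <- gap_clusters(h, k)
    w <- vapply(split(h, grp), function(g) max(g) - min(g), numeric(1L))
    if (all(w <= delta * scale)) return(k)
  }
  NA_integer_
}

# Is the label sequence exactly k-cyclic (and not cyclic at any divisor)?
is_cyclic <- function(grp, k) {
  n <- length(grp)
  if (n <= k) return(FALSE)
  if (!all(grp[seq_len(n - k)] == grp[seq_len(n - k) + k])) return(FALSE)
  divs <- setdiff(which(k %% seq_len(k) == 0L), k)
  for (d in divs)
    if (all(grp[seq_len(n - d)] == grp[seq_len(n - d) + d])) return(FALSE)
  length(unique(grp)) == k
}

#' Dispersion of the successive-maxima return map
#'
#' Scale-free evidence of aperiodicity: successive-maxima pairs
#' \eqn{(h_n, h_{n+1})} are grouped by clustering \eqn{h_n} into k states
#' (k = 1..\code{k_max}); within each state the successor is predicted by
#' the state's mean successor, and the dispersion is the smallest (over k)
#' standard deviation of the prediction residuals, divided by the height
#' range.  An exact period-k sequence gives 0 (at the true k the successor
#' is a constant per state); a chaotic maxima map leaves residual spread at
#' every k.
#'
#' @param x A \code{ccm_maxima} or a numeric vector of peak heights
#'   (>= 10 values required).
#' @param k_max Largest state count tried.
#' @return A single non-negative number.
#' @export
maxima_dispersion <- function(x, k_max = 6L) {
  h <- if (is.data.frame(x)) x$value else as.numeric(x)
  if (length(h) < 10L)
    stop("at least 10 maxima are required for a dispersion estimate",
         call. = FALSE)
  rng <- max(h) - min(h)
  if (rng < .Machine$double.eps) return(0)
  a <- h[-length(h)]
  b <- h[-1L]
  best <- Inf
  for (k in seq_len(min(k_max, length(a)))) {
    grp <- gap_clusters(a, k)
    resid <- unlist(lapply(split(seq_along(a), grp), function(i) {
      b[i] - mean(b[i])
    }), use.names = FALSE)
    v <- sqrt(mean(resid^2)) / rng
    if (v < best) best <- v
  }
  best
}

#' Classify the dynamical regime of a maxima series
#'
#' Pure function of the maxima series and the stated tolerances.  Labels:
#' \describe{
#'   \item{oscillation_death}{post-transient signal excursion below
#'     \code{eps = eps_frac * scale}.}
#'   \item{damped}{peak heights decrease monotonically and the envelope has
#'     decayed below \code{eps} by the window end.}
#'   \item{period_1 ... period_k}{peak heights fall into exactly k height
#'     clusters under relative tolerance \code{delta} and the cluster
#'     sequence is k-cyclic ("period_1" is the sustained-oscillation
#'     label).}
#'   \item{chaotic}{more than \code{k_max} height clusters would be needed
#'     \emph{and} the return-map dispersion exceeds
#'     \code{disp_threshold} (both conditions, so slow amplitude modulation
#'     is not mislabelled).}
#'   \item{insufficient_evidence}{fewer than \code{min_peaks} maxima and no
#'     death/damped call possible.}
#' }
#' A non-cyclic or over-fragmented height sequence with dispersion below
#' threshold is treated as a slowly modulated sustained oscillation
#' (\code{period_1}).
#'
#' @param mx A \code{ccm_maxima} (from [find_maxima()]).
#' @param eps_frac Oscillation-death excursion threshold, as a fraction of
#'   \code{scale}.
#' @param delta Relative height-clustering tolerance.
#' @param k_max Largest period called.
#' @param min_peaks Minimum maxima for a period-k call.
#' @param disp_threshold Return-map dispersion above which aperiodicity
#'   counts as chaotic.
#' @param scale Amplitude scale for the death threshold; default the
#'   series' own post-transient excursion, but pass the species' global
#'   range when classifying windows of a longer trajectory.
#' @return A \code{ccm_regime} list: \code{label}, \code{k} (period count,
#'   NA unless period_k), \code{evidence} (n_peaks, n_clusters, excursion,
#'   dispersion, cyclic).
#' @export
classify_regime <- function(mx, eps_frac = 0.01, delta = 0.02, k_max = 6L,
                            min_peaks = 6L, disp_threshold = 0.01,
                            scale = NULL) {
  stopifnot(inherits(mx, "ccm_maxima"))
  if (is.null(scale)) scale <- attr(mx, "signal_range")
  eps <- eps_frac * scale
  exc <- attr(mx, "signal_range")
  h <- mx$value
  n <- length(h)
  ev <- list(n_peaks = n, n_clusters = NA_integer_, excursion = exc,
             dispersion = NA_real_, cyclic = NA)
  lab <- function(label, k = NA_integer_)
    structure(list(label = label, k = k, evidence = ev),
              class = "ccm_regime")
  if (exc == 0 || exc < eps) return(lab("oscillation_death"))
  if (n >= 2L) {
    decreasing <- all(diff(h) <= delta / 2 * abs(h[-n]))
    died_down <- (h[n] - attr(mx, "signal_min")) < eps
    if (decreasing && died_down) return(lab("damped"))
  }
  if (n < min_peaks) return(lab("insufficient_evidence"))
  k <- select_k(h, delta, k_max)
  ev$n_clusters <- if (is.na(k)) k_max + 1L else k
  disp <- if (n >= 10L) maxima_dispersion(mx, k_max) else NA_real_
  ev$dispersion <- disp
  if (!is.na(k)) {
    if (k == 1L) return(lab("period_1", 1L))
    grp <- gap_clusters(h, k)
    ev$cyclic <- is_cyclic(grp, k)
    if (ev$cyclic)
      return(lab(if (k <= 3L) paste0("period_", k) else "period_k", k))
    # non-cyclic height wandering: chaotic only with dispersion evidence
    if (!is.na(disp) && disp > disp_threshold) return(lab("chaotic"))
    return(lab("period_1", 1L))
  }
  if (!is.na(disp) && disp > disp_threshold) return(lab("chaotic"))
  lab("period_1", 1L)
}

#' @export
print.ccm_regime <- function(x, ...) {
  cat(sprintf("regime: %s (peaks=%d clusters=%s dispersion=%s)\n", x$label,
              x$evidence$n_peaks, format(x$evidence$n_clusters),
              format(signif(x$evidence$dispersion, 3))))
  invisible(x)
}

#' Sliding-window regime segmentation
#'
#' Classifies overlapping windows of one species' trajectory and merges
#' consecutive windows with the same label into maximal contiguous
#' segments.  Segment boundaries are reported midway between the centers of
#' the adjacent windows; the segments tile the analysis window exactly.
#'
#' @param x A \code{ccm_trajectory} (give \code{species}) or a data.frame
#'   with \code{time_h}, \code{value}.
#' @param species Species, for trajectory input.
#' @param window_h,hop_h Window width and hop (hours).  The 25 h default
#'   covers >= 5 periods of every oscillation the model produces.
#' @param ... Tolerances passed to [classify_regime()].
#' @return A \code{ccm_segments}: data.frame with \code{t_start},
#'   \code{t_end}, \code{label}, \code{k}; per-window labels in attribute
#'   \code{windows}; \code{window_h}, \code{hop_h} attached.
#' @export
segment_regimes <- function(x, species = NULL, window_h = 25, hop_h = 5,
                            ...) {
  s <- as_series(x, species)
  t0 <- s$time_h[1L]
  t1 <- s$time_h[nrow(s)]
  if (t1 - t0 < window_h)
    stop("series shorter than one classification window", call. = FALSE)
  scale <- max(s$value) - min(s$value)
  starts <- seq(t0, t1 - window_h, by = hop_h)
  centers <- starts + window_h / 2
  labels <- character(length(starts))
  ks <- rep(NA_integer_, length(starts))
  for (j in seq_along(starts)) {
    w <- s[s$time_h >= starts[j] & s$time_h <= starts[j] + window_h, ]
    mx <- find_maxima(w, transient_h = 0)
    r <- classify_regime(mx, scale = scale, ...)
    labels[j] <- r$label
    ks[j] <- r$k
  }
  # merge runs of identical labels; boundaries midway between window centers
  r <- rle(labels)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  nseg <- length(r$values)
  seg_start <- seg_end <- numeric(nseg)
  for (j in seq_len(nseg)) {
    seg_start[j] <- if (j == 1L) t0
      else (centers[starts_i[j]] + centers[ends_i[j - 1L]]) / 2
    seg_end[j] <- if (j == nseg) t1
      else (centers[ends_i[j]] + centers[starts_i[j + 1L]]) / 2
  }
  out <- data.frame(t_start = seg_start, t_end = seg_end, label = r$values,
                    k = ks[starts_i], stringsAsFactors = FALSE)
  structure(out,
            windows = data.frame(center = centers, label = labels, k = ks),
            window_h = window_h, hop_h = hop_h,
            class = c("ccm_segments", "data.frame"))
}

#' Write segmentation or maxima tables as tidy CSV
#'
#' @param x A \code{ccm_segments} or \code{ccm_maxima}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_features_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
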