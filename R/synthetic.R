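# Synthetic waveforms and curves with known ground truth: the fixture
# generator that makes every detector, classifier and fitter testable
# without running the full model.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# One bump per period: height h_cycle * (1 - cos(2 pi t / T)) / 2, so each
# cycle contributes exactly one strict maximum of height h_cycle.
bump_train <- function(tt, period_h, heights, t0 = 0) {
  cyc <- pmax(1L, pmin(length(heights),
                       floor((tt - t0) / period_h) + 1L))
  heights[cyc] * (1 - cos(2 * pi * (tt - t0) / period_h)) / 2
}

#' Generate a synthetic signal with known ground truth
#'
#' Waveform classes mirroring the regimes the analysis detects.  Every
#' signal carries a machine-readable truth record (attribute
#' \code{truth}): the regime label, the constructed maxima, the collapse
#' interval (if any) and the generating spec, so detector output can be
#' checked against construction.
#'
#' Kinds:
#' \describe{
#'   \item{sustained}{sinusoid, one maximum of height \code{amplitude} per
#'     period.}
#'   \item{damped}{exponentially damped sinusoid with decay time
#'     \code{tau_h}; truth records the envelope.}
#'   \item{period_2, period_3}{one-bump-per-period train whose peak heights
#'     cycle through \code{amplitudes} (length 2 or 3).}
#'   \item{chaotic_logistic}{bump train with heights driven by the logistic
#'     map \eqn{z_{n+1} = r z_n (1-z_n)} (default r = 3.9), rescaled to
#'     \code{amplitude * [0.5, 1]}: a standard construction with provably
#'     aperiodic maxima.}
#'   \item{collapse}{sustained oscillation, flat at baseline over
#'     \code{[collapse_start_h, collapse_start_h + collapse_len_h]}, then
#'     oscillation again.}
#'   \item{piecewise}{concatenation of segments; pass a list of specs in
#'     \code{segments}, each a list with \code{kind}, \code{length_h} and
#'     kind-specific fields.}
#' }
#'
#' @param kind Signal class; see Details.
#' @param period_h Oscillation period (hours).
#' @param amplitude Peak height (sustained/damped/chaotic/collapse).
#' @param amplitudes Height cycle for period_2/period_3.
#' @param tau_h Envelope decay time for \code{damped}.
#' @param r Logistic-map parameter for \code{chaotic_logistic}.
#' @param collapse_start_h,collapse_len_h Collapse placement (hours).
#' @param segments List of segment specs for \code{piecewise}.
#' @param horizon_h,dt_h Signal span and sampling interval (hours).
#' @param baseline Additive offset.
#' @param noise_sd Additive Gaussian noise standard deviation (signal
#'   units), seeded.
#' @param seed Integer seed fixing the realization exactly (noise and
#'   logistic initial condition).
#' @return A data.frame with \code{time_h}, \code{value}; attribute
#'   \code{truth} is a list with fields \code{kind}, \code{label},
#'   \code{period_h}, \code{maxima} (data.frame time_h/value of constructed
#'   peaks, noise-free), \code{collapse} (start/end/dt_h or NULL),
#'   \code{segments} (piecewise truth) and \code{spec}.
#' @export
#' @examples
#' s <- synth_signal("period_2", period_h = 2, amplitudes = c(1, 1.6),
#'                   horizon_h = 40)
#' attr(s, "truth")$label
synth_signal <- function(kind = c("sustained", "damped", "period_2",
                                  "period_3", "chaotic_logistic",
                                  "collapse", "piecewise"),
                         period_h = 2, amplitude = 1, amplitudes = NULL,
                         tau_h = NULL, r = 3.9, collapse_start_h = NULL,
                         collapse_len_h = NULL, segments = NULL,
                         horizon_h = 50, dt_h = 0.01, baseline = 0,
                         noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(horizon_h > 0, dt_h > 0, period_h > 0)
  tt <- seq(0, horizon_h, by = dt_h)
  spec <- as.list(environment())[c("kind", "period_h", "amplitude",
                                   "amplitudes", "tau_h", "r",
                                   "collapse_start_h", "collapse_len_h",
                                   "horizon_h", "dt_h", "baseline",
                                   "noise_sd", "seed")]
  truth <- list(kind = kind, period_h = period_h, collapse = NULL,
                segments = NULL, spec = spec)
  ncyc <- ceiling(horizon_h / period_h)
  peak_times <- (seq_len(ncyc) - 0.5) * period_h
  peak_times <- peak_times[peak_times <= horizon_h]

  v <- switch(kind,
    sustained = {
      truth$label <- "period_1"
      truth$maxima <- data.frame(time_h = peak_times, value = amplitude)
      amplitude * (1 - cos(2 * pi * tt / period_h)) / 2
    },
    damped = {
      if (is.null(tau_h)) tau_h <- horizon_h / 5
      truth$label <- "damped"
      truth$tau_h <- tau_h
      truth$maxima <- data.frame(time_h = peak_times,
                                 value = amplitude * exp(-peak_times / tau_h))
      amplitude * exp(-tt / tau_h) * (1 - cos(2 * pi * tt / period_h)) / 2
    },
    period_2 = ,
    period_3 = {
      kk <- if (kind == "period_2") 2L else 3L
      if (is.null(amplitudes))
        amplitudes <- amplitude * (1 + (seq_len(kk) - 1) / 2)
      stopifnot(length(amplitudes) == kk)
      truth$label <- paste0("period_", kk)
      h <- rep_len(amplitudes, ncyc)
      truth$maxima <- data.frame(time_h = peak_times,
                                 value = h[seq_along(peak_times)])
      bump_train(tt, period_h, h)
    },
    chaotic_logistic = {
      truth$label <- "chaotic"
      z <- with_seed(seed, stats::runif(1L, 0.2, 0.8))
      zz <- numeric(ncyc)
      for (i in seq_len(ncyc)) {
        z <- r * z * (1 - z)
        zz[i] <- z
      }
      h <- amplitude * (0.5 + 0.5 * zz)
      truth$maxima <- data.frame(time_h = peak_times,
                                 value = h[seq_along(peak_times)])
      bump_train(tt, period_h, h)
    },
    collapse = {
      if (is.null(collapse_start_h)) collapse_start_h <- horizon_h / 3
      if (is.null(collapse_len_h)) collapse_len_h <- horizon_h / 3
      if (collapse_start_h + collapse_len_h >= horizon_h)
        stop("collapse extends beyond the horizon", call. = FALSE)
      truth$label <- "collapse"
      truth$collapse <- list(start_h = collapse_start_h,
                             end_h = collapse_start_h + collapse_len_h,
                             dt_h = collapse_len_h)
      base <- amplitude * (1 - cos(2 * pi * tt / period_h)) / 2
      base[tt > collapse_start_h &
             tt < collapse_start_h + collapse_len_h] <- 0
      keep <- !(peak_times > collapse_start_h &
                  peak_times < collapse_start_h + collapse_len_h)
      truth$maxima <- data.frame(time_h = peak_times[keep],
                                 value = amplitude)
      base
    },
    piecewise = {
      if (is.null(segments) || !length(segments))
        stop("piecewise signals need a non-empty 'segments' list",
             call. = FALSE)
      truth$label <- "piecewise"
      segs <- list()
      vv <- numeric(length(tt))
      t_off <- 0
      for (sg in segments) {
        len <- sg$length_h
        if (is.null(len)) stop("each segment needs length_h", call. = FALSE)
        sub <- do.call(synth_signal, c(
          sg[setdiff(names(sg), "length_h")],
          list(horizon_h = len, dt_h = dt_h, noise_sd = 0, seed = seed)))
        idx <- tt >= t_off & tt <= t_off + len
        vv[idx] <- sub$value[seq_len(sum(idx))]
        segs[[length(segs) + 1L]] <-
          list(t_start = t_off, t_end = t_off + len,
               label = attr(sub, "truth")$label)
        t_off <- t_off + len
      }
      if (t_off < horizon_h - dt_h / 2)
        stop("segments do not cover the horizon", call. = FALSE)
      truth$segments <- segs
      truth$maxima <- NULL
      vv
    })

  v <- v + baseline
  if (!is.null(truth$maxima))
    truth$maxima$value <- truth$maxima$value + baseline
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, noise_sd))
  structure(data.frame(time_h = tt, value = v), truth = truth)
}

#' Generate a collapse-time-versus-dose fixture
#'
#' Collapse times drawn from the saturating law
#' \eqn{\Delta t = A/(B + e^{-IR})} with optional multiplicative
#' log-normal noise; the truth record holds (A, B).  Exercises
#' [fit_collapse_model()] and [saturation()].
#'
#' @param doses Dose grid (Gy).
#' @param A,B Law parameters; \code{B > 0}.
#' @param noise_cv Relative (coefficient-of-variation) noise on each point.
#' @param seed Integer seed.
#' @return A \code{ccm_collapse_curve} (see [collapse_curve()]) with
#'   attribute \code{truth = list(A, B)}.
#' @export
generate_collapse_family <- function(doses, A, B, noise_cv = 0,
                                     seed = NULL) {
  stopifnot(B > 0, noise_cv >= 0)
  dt <- A / (B + exp(-doses))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- with_seed(seed,
                     exp(stats::rnorm(length(doses), -sdlog^2 / 2, sdlog)))
    dt <- dt * fac
  }
  structure(data.frame(dose_gy = doses, dt_h = dt, censored = FALSE),
            truth = list(A = A, B = B), time_unit = "h",
            class = c("ccm_collapse_curve", "data.frame"))
}

#' Randomly perturb a parameter set
#'
#' Multiplies every rate constant by an independent log-normal factor with
#' coefficient of variation \code{cv} (mean 1), preserving positivity;
#' \code{cv = 0} is the identity.  Robustness harness for the model's
#' qualitative behaviour.
#'
#' @param base A \code{ccm_params}.
#' @param cv Coefficient of variation of the multiplicative factors.
#' @param seed Integer seed; fixes the draw exactly.
#' @return A perturbed \code{ccm_params}.
#' @export
perturb_parameters <- function(base, cv, seed = NULL) {
  stopifnot(inherits(base, "ccm_params"), cv >= 0)
  if (cv == 0) return(base)
  kn <- setdiff(.k_names, .k_composite)
  sdlog <- sqrt(log(1 + cv^2))
  fac <- with_seed(seed,
                   exp(stats::rnorm(length(kn), -sdlog^2 / 2, sdlog)))
  for (i in seq_along(kn)) base[[kn[i]]] <- base[[kn[i]]] * fac[i]
  base
}

#' Write a synthetic fixture as a CSV + JSON truth pair
#'
#' @param signal Output of [synth_signal()].
#' @param stem File stem; writes \code{<stem>.csv} and
#'   \code{<stem>.truth.json}.
#' @return \code{stem}, invisibly.
#' @export
write_fixture <- function(signal, stem) {
  utils::write.csv(as.data.frame(signal), paste0(stem, ".csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- attr(signal, "truth")
  jsonlite::write_json(tr, paste0(stem, ".truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(stem)
}
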