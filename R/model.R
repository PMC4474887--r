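# Species, right-hand side and state validation of the 13-ODE system.

#' Molecular species of the model
#'
#' @return A data.frame with columns \code{index}, \code{state} (the
#'   state-vector name \code{x1}...\code{x13}), \code{species} (short
#'   lower-case name accepted everywhere a species argument is taken) and
#'   \code{description}.
#' @export
species_table <- function() {
  data.frame(
    index = 1:13,
    state = paste0("x", 1:13),
    species = c("cyclin", "mpf", "protease", "p53", "mdm2", "mdm2_p53",
                "mdm2_mrna", "arf", "arf_mdm2", "ir", "damdna", "p21",
                "p21_mpf"),
    description = c(
      "unbound cyclin", "active MPF fraction M (inactive M* = 1 - x2)",
      "active cyclin-protease fraction X (inactive X* = 1 - x3)",
      "unbound p53", "unbound Mdm2", "Mdm2-p53 complex", "Mdm2 mRNA",
      "unbound ARF", "ARF-Mdm2 complex", "irradiation signal (Gy)",
      "damaged DNA", "p21", "p21-MPF complex"),
    stringsAsFactors = FALSE
  )
}

# Resolve a species argument ("p53", "x4" or 4) to a state index.
species_index <- function(species) {
  tab <- species_table()
  if (is.numeric(species)) {
    i <- as.integer(species)
  } else {
    species <- tolower(as.character(species))
    i <- match(species, tab$species)
    if (is.na(i)) i <- match(species, tab$state)
  }
  if (is.na(i) || i < 1L || i > 13L)
    stop("unknown species: ", species, call. = FALSE)
  i
}

.baseline_cache <- new.env(parent = emptyenv())

#' Equilibrated unirradiated state
#'
#' Integrates the unirradiated model (\code{x10 = 0}) from a cold start
#' (cyclin, MPF and protease at 0.01, everything else 0) for
#' \code{runin_h} hours and returns the final state: the p53 subsystem at
#' its stable fixed point and the cell-cycle subsystem on its limit cycle.
#' This is the "normal condition" from which irradiation runs are
#' launched, so that everything a dosed trajectory shows is a response to
#' the dose rather than to an arbitrary cold start.  Results are cached
#' per (parameters, run-in, step) so repeated calls are free.
#'
#' @param params A \code{ccm_params}.
#' @param runin_h Run-in length (hours); the cell-cycle limit cycle is
#'   converged to well under 1\% by 300 h.
#' @param control An [integration_control()].
#' @return Named numeric length-13 state vector.
#' @export
baseline_state <- function(params = default_parameters(), runin_h = 300,
                           control = integration_control()) {
  cold <- stats::setNames(numeric(13), paste0("x", 1:13))
  cold[c("x1", "x2", "x3")] <- 0.01
  key <- config_hash(list(k = params[setdiff(.k_names, .k_composite)],
                          runin_h = runin_h, dt_s = control$dt_s))
  hit <- .baseline_cache[[key]]
  if (!is.null(hit)) return(hit)
  tr <- integrate_model(params, cold, t_end_h = runin_h, control = control)
  out <- stats::setNames(as.numeric(tr[nrow(tr), -1L]), paste0("x", 1:13))
  .baseline_cache[[key]] <- out
  out
}

#' Initial state for a given irradiation dose
#'
#' The irradiation dose enters the model as the initial value of the
#' irradiation species \code{x10}.  Species concentrations are
#' dimensionless molecule-count-like activities, so a physical dose in Gy
#' is converted to damage units as \code{x10 = dsb_per_gy * ir_dose}; the
#' default 40 is the standard yield of DNA double-strand breaks per Gy per
#' cell used by p53-network models (with \code{dsb_per_gy = 1} the dose
#' has essentially no effect on the network at clinically meaningful
#' doses; see the methods vignette).  By default the remaining species
#' start from the equilibrated unirradiated state
#' (see [baseline_state()]), matching the flat p53 baseline the model
#' shows at zero dose; \code{equilibrate = FALSE} gives the documented
#' cold start instead (cyclin, MPF, protease at 0.01, zero elsewhere).
#'
#' @param ir_dose Irradiation dose in Gy, \code{>= 0}.
#' @param overrides Named numeric vector or list; names are species names
#'   (\code{"p53"}) or state names (\code{"x4"}).  Replaces exactly the
#'   named fields (applied last, so an \code{x10} override wins over the
#'   dose conversion).
#' @param dsb_per_gy Damage units created per Gy.
#' @param params,runin_h,control Settings for the baseline equilibration.
#' @param equilibrate Start from the unirradiated attractor (default) or
#'   from the cold start.
#' @return Named numeric vector of length 13 (\code{x1}...\code{x13}).
#' @export
#' @examples
#' make_initial_state(5, dsb_per_gy = 1)[["x10"]]   # 5
#' make_initial_state(0, overrides = c(p53 = 1))[["x4"]]
make_initial_state <- function(ir_dose = 0, overrides = NULL,
                               dsb_per_gy = 40,
                               params = default_parameters(),
                               equilibrate = TRUE, runin_h = 300,
                               control = integration_control()) {
  stopifnot(is.numeric(ir_dose), length(ir_dose) == 1L, dsb_per_gy > 0)
  if (is.na(ir_dose) || ir_dose < 0)
    stop("ir_dose must be a non-negative dose in Gy", call. = FALSE)
  if (equilibrate) {
    x <- baseline_state(params, runin_h, control)
  } else {
    x <- stats::setNames(numeric(13), paste0("x", 1:13))
    x[c("x1", "x2", "x3")] <- 0.01
  }
  x["x10"] <- dsb_per_gy * ir_dose
  if (!is.null(overrides)) {
    for (nm in names(overrides))
      x[species_index(nm)] <- as.numeric(overrides[[nm]])
  }
  x
}

#' Right-hand side of the 13-ODE model
#'
#' Time derivative of the state under mass-action/Michaelis kinetics, with
#' the printed-equation ambiguities resolved as recorded in
#' \code{params$typo_policy}.  The composite rates are
#' \deqn{k^* = k_2 x_1 x_3/(k_3 + x_1),\quad
#'       k^{**} = k_5 (1-x_2)/(k_6 + (1-x_2)),\ k_5 = k_{14} x_1/(k_{13}+x_1),}
#' \deqn{k^{***} = k_7 x_2/(k_8 + x_2),\quad
#'       k^{****} = k_9 (1-x_3)/(k_{10} + (1-x_3)),\ k_9 = k_{15} x_2,}
#' \deqn{k^{*****} = k_{11} x_3/(k_{12} + x_3).}
#' The irradiation species always decays as \eqn{dx_{10}/dt = -k_{24} x_{10}}
#' while creating damaged DNA.
#'
#' This is the plain-R reference implementation; the integrator uses an
#' identical compiled version.
#'
#' @param state Named or unnamed non-negative numeric vector of length 13.
#' @param params A \code{ccm_params} object.
#' @return Numeric vector of length 13: \code{d state / d t} (per second).
#' @export
ccm_rhs <- function(state, params) {
  stopifnot(length(state) == 13L)
  x <- as.numeric(state)
  if (anyNA(x)) stop("state contains NA", call. = FALSE)
  neg <- which(x < 0)
  if (length(neg))
    stop("negative state component: ", species_table()$species[neg[1L]],
         " = ", x[neg[1L]], call. = FALSE)
  k <- param_vector(params)
  k5 <- k["k14"] * x[1] / (k["k13"] + x[1])
  k9 <- k["k15"] * x[2]
  d <- numeric(13)
  d[1] <- k["k1"] - k["k2"] * x[1] * x[3] / (k["k3"] + x[1]) - k["k4"] * x[1]
  d[2] <- k5 * (1 - x[2]) / (k["k6"] + (1 - x[2])) -
    k["k7"] * x[2] / (k["k8"] + x[2]) - k["k31"] * x[12] * x[2]
  d[3] <- k9 * (1 - x[3]) / (k["k10"] + (1 - x[3])) -
    k["k11"] * x[3] / (k["k12"] + x[3])
  d[4] <- k["k16"] + k["k18"] * x[6] - k["k17"] * x[4] * x[5]
  d[5] <- k["k22"] * x[7] + k["k19"] * x[6] + k["k18"] * x[6] -
    k["k23"] * x[5] - k["k17"] * x[4] * x[5] - k["k27"] * x[5] * x[8]
  d[6] <- k["k17"] * x[4] * x[5] - k["k18"] * x[6] - k["k19"] * x[6]
  d[7] <- k["k20"] * x[4] - k["k21"] * x[7]
  d[8] <- k["k26"] * x[11] + k["k29"] * x[9] - k["k27"] * x[5] * x[8] -
    k["k28"] * x[8]
  d[9] <- k["k27"] * x[5] * x[8] - k["k29"] * x[9]
  d[10] <- -k["k24"] * x[10]
  d[11] <- k["k24"] * x[10] - k["k25"] * x[11]
  d[12] <- k["k30"] * x[4] - k["k31"] * x[2] * x[12] + k["k32"] * x[13] -
    k["k33"] * x[12]
  d[13] <- k["k31"] * x[12] * x[2] - k["k32"] * x[13]
  names(d) <- paste0("x", 1:13)
  d
}

#' Diagnose state-vector invariant violations
#'
#' Pure report: flags negative components and the activation fractions
#' \code{x2} (MPF) and \code{x3} (protease) outside \code{[0, 1]}.
#'
#' @param state Numeric vector of length 13, or a matrix/data.frame of
#'   states (one row per time point, 13 state columns).
#' @param tol Violations smaller than \code{tol} are ignored.
#' @return A data.frame with columns \code{species}, \code{rule},
#'   \code{value}, \code{magnitude}; zero rows when the state is valid.
#' @export
validate_state <- function(state, tol = 0) {
  tab <- species_table()
  if (is.data.frame(state)) state <- as.matrix(state[, tab$state])
  if (!is.matrix(state)) state <- matrix(as.numeric(state), nrow = 1L)
  stopifnot(ncol(state) == 13L)
  out <- list()
  lo <- apply(state, 2L, min)
  bad <- which(lo < -tol)
  for (i in bad)
    out[[length(out) + 1L]] <- data.frame(
      species = tab$species[i], rule = "non-negative", value = lo[i],
      magnitude = -lo[i], stringsAsFactors = FALSE)
  hi <- apply(state[, 2:3, drop = FALSE], 2L, max)
  for (j in which(hi > 1 + tol)) {
    i <- j + 1L
    out[[length(out) + 1L]] <- data.frame(
      species = tab$species[i], rule = "fraction <= 1", value = hi[j],
      magnitude = hi[j] - 1, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(species = character(), rule = character(),
                      value = numeric(), magnitude = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
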