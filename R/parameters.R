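# Rate constants, typo-resolution policy and parameter I/O.

# Names of the true rate constants.  k5 and k9 are *state-dependent*
# composite rates (k5 = k14*x1/(k13+x1), k9 = k15*x2) and are therefore not
# parameters; their slots exist only so that kN can be addressed as k[N]
# inside the compiled right-hand side.
.k_names <- paste0("k", 1:33)
.k_composite <- c("k5", "k9")

#' Default parameter set of the coupled p53--cell-cycle model
#'
#' Returns the published rate constants of the 25-reaction network, with the
#' documented resolutions of printed ambiguities applied.  All rates are in
#' per-second (or concentration-per-second) units; concentrations are
#' treated as dimensionless activity levels.
#'
#' Two printed values need a policy beyond a straight transcription:
#' \describe{
#'   \item{\code{k14}}{the maximal MPF-activation rate is printed as
#'     \code{0.00 s^-1}, which would freeze MPF activation permanently and
#'     contradicts the sustained cyclin/MPF oscillation reported at
#'     \code{IR = 0}.  It is treated as a free calibration constant; the
#'     default is the smallest round value for which the unirradiated
#'     cyclin/MPF dynamics is a sustained limit cycle under the default
#'     initial conditions (see the methods vignette).}
#'   \item{\code{k1}}{the cyclin synthesis rate is printed as
#'     \code{0.000416667e-2 s^-1}; the \code{e-2} factor is inconsistent
#'     with the minimal-cascade constants this block of parameters
#'     transcribes (0.025 per minute = 4.16667e-4 per second).  The default
#'     drops the factor; set \code{k1_literal_exponent = TRUE} to use the
#'     literal printed value.}
#' }
#'
#' @param k14 Maximal MPF activation rate (s^-1).  See Details.
#' @param k1_literal_exponent Logical; if \code{TRUE} use the literal
#'   printed \code{k1 = 4.16667e-6}, otherwise the corrected
#'   \code{4.16667e-4}.
#' @return An object of class \code{ccm_params}: a list with one element per
#'   rate constant (\code{k1}...\code{k33}, excluding the composite
#'   \code{k5}, \code{k9}), plus \code{typo_policy} (named logical/character
#'   flags recording how each printed ambiguity was resolved) and
#'   \code{time_unit = "s"}.
#' @seealso [parameter_profile()], [write_model_config()], [ccm_rhs()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$k17            # p53-Mdm2 association rate
#' p$typo_policy$mpf_decay_michaelis
default_parameters <- function(k14 = 0.005, k1_literal_exponent = FALSE) {
  stopifnot(is.numeric(k14), length(k14) == 1L, k14 > 0)
  k <- list(
    k1  = if (k1_literal_exponent) 0.000416667e-2 else 0.000416667,
    k2  = 0.004166667,  # maximal protease-mediated cyclin decay
    k3  = 0.02,         # Michaelis constant, cyclin decay
    k4  = 0.0000167,    # protease-independent cyclin decay
    k6  = 0.01,         # Michaelis constant, MPF activation
    k7  = 0.0025,       # maximal MPF inactivation
    k8  = 0.01,         # Michaelis constant, MPF inactivation
    k10 = 0.01,         # Michaelis constant, protease activation
    k11 = 0.0008333,    # maximal protease inactivation
    k12 = 0.01,         # Michaelis constant, protease inactivation
    k13 = 0.5,          # Michaelis constant of cyclin in MPF activation
    k14 = k14,          # maximal MPF activation (calibrated; see Details)
    k15 = 0.001667,     # MPF-driven protease activation scale
    k16 = 0.078,        # p53 synthesis
    k17 = 1.155e-3,     # p53 + Mdm2 association (mol^-1 s^-1)
    k18 = 1.155e-5,     # p53-Mdm2 dissociation
    k19 = 8.25e-4,      # Mdm2-mediated p53 ubiquitination
    k20 = 1.0e-4,       # Mdm2 gene transcription (per p53)
    k21 = 1.0e-4,       # Mdm2 mRNA decay
    k22 = 4.95e-4,      # Mdm2 translation
    k23 = 4.33e-4,      # Mdm2 decay
    k24 = 1.0,          # DNA damage creation from irradiation
    k25 = 2.0e-5,       # damaged-DNA repair
    k26 = 3.3e-5,       # ARF activation by damaged DNA
    k27 = 0.01,         # ARF + Mdm2 association (mol^-1 s^-1)
    k28 = 0.001,        # ARF decay
    k29 = 0.001,        # Mdm2 degradation out of the ARF complex
    k30 = 0.001,        # p53-driven p21 synthesis
    k31 = 0.0001,       # p21 + MPF association (mol^-1 s^-1)
    k32 = 0.002,        # p21-MPF complex dissociation (releases p21)
    k33 = 0.005         # p21 decay
  )
  structure(
    c(k, list(
      typo_policy = list(
        # dx2/dt activation denominator printed "x6 + (1-x2)": read as the
        # Michaelis constant k6 (the constants table lists k6 for this rate).
        mpf_activation_denominator_k6 = TRUE,
        # MPF decay printed "k7*x2*k8*x2": read as Michaelis form
        # k7*x2/(k8 + x2), matching the minimal-cascade structure.
        mpf_decay_michaelis = TRUE,
        # ARF decay printed "k28<x9><x8>" in the reaction table: the ODE
        # block's linear -k28*x8 is authoritative.
        arf_decay_linear = TRUE,
        # p21 + MPF complex formation: the garbled duplicate reaction row is
        # dropped; the ODE terms k31*x2*x12 define a single channel.
        p21_mpf_mass_action = TRUE,
        # inactive fractions are 1 - x2 (MPF) and 1 - x3 (protease); the
        # stray "1 - x10 / 1 - x11" sentence is recorded as an erratum.
        inactive_fractions_from_x2_x3 = TRUE,
        k1_literal_exponent = k1_literal_exponent,
        k14_policy = "calibrated"
      ),
      time_unit = "s"
    )),
    class = "ccm_params"
  )
}

#' Alternative parameter profiles
#'
#' \code{"default"} is [default_parameters()].  \code{"minimal-cascade"}
#' replaces the cell-cycle block (k1--k15) with a direct per-second
#' transcription of the classic minimal mitotic-oscillator constants
#' (vi = 0.025, vd = 0.25, kd = 0.01, VM1 = 3, V2 = 1.5, VM3 = 1,
#' V4 = 0.5 per minute; Kc = 0.5, sharpness constants 0.005), useful as an
#' independent cross-check that the cyclin/MPF/protease subsystem supports
#' a limit cycle.
#'
#' @param profile Character, one of \code{"default"},
#'   \code{"minimal-cascade"}.
#' @param ... Passed to [default_parameters()].
#' @return A \code{ccm_params} object.
#' @export
parameter_profile <- function(profile = c("default", "minimal-cascade"), ...) {
  profile <- match.arg(profile)
  p <- default_parameters(...)
  if (profile == "minimal-cascade") {
    p$k1  <- 0.025 / 60
    p$k2  <- 0.25 / 60
    p$k3  <- 0.02
    p$k4  <- 0.01 / 60
    p$k6  <- 0.005
    p$k7  <- 1.5 / 60
    p$k8  <- 0.005
    p$k10 <- 0.005
    p$k11 <- 0.5 / 60
    p$k12 <- 0.005
    p$k13 <- 0.5
    p$k14 <- 3 / 60
    p$k15 <- 1 / 60
    p$typo_policy$k14_policy <- "minimal-cascade"
  }
  p
}

# Flat numeric vector of length 33 indexed k[N]; composite slots are 0.
param_vector <- function(params) {
  stopifnot(inherits(params, "ccm_params"))
  k <- numeric(33)
  names(k) <- .k_names
  for (nm in setdiff(.k_names, .k_composite)) k[nm] <- params[[nm]]
  k
}

#' @export
print.ccm_params <- function(x, ...) {
  cat("Coupled p53-cell-cycle model parameters (per-second units)\n")
  k <- param_vector(x)
  k <- k[setdiff(.k_names, .k_composite)]
  print(k)
  cat("typo policy:",
      paste(names(x$typo_policy), unlist(lapply(x$typo_policy, format)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a model configuration file
#'
#' A flat JSON document holding every rate constant (\code{k1}...\code{k33}),
#' the initial condition (\code{x1_0}...\code{x13_0}), the irradiation dose
#' \code{ir_dose} and the typo-policy flags.  A round trip reproduces every
#' numeric field bit-identically (numbers are serialized at full precision).
#'
#' @param params A \code{ccm_params} object.
#' @param init Numeric length-13 initial state (see [make_initial_state()]).
#' @param path File path to write to / read from.
#' @param ir_dose Irradiation dose (Gy) recorded alongside the state.
#' @return \code{write_model_config} returns \code{path} invisibly;
#'   \code{read_model_config} returns a list with elements \code{params},
#'   \code{init}, \code{ir_dose}.
#' @export
write_model_config <- function(params, path, init = make_initial_state(0),
                               ir_dose = init[["x10"]]) {
  stopifnot(inherits(params, "ccm_params"), length(init) == 13L)
  kn <- setdiff(.k_names, .k_composite)
  doc <- c(
    params[kn],
    as.list(stats::setNames(as.numeric(init), paste0("x", 1:13, "_0"))),
    list(ir_dose = as.numeric(ir_dose), typo_policy = params$typo_policy,
         time_unit = params$time_unit)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- default_parameters()
  for (nm in setdiff(.k_names, .k_composite)) p[[nm]] <- as.numeric(doc[[nm]])
  tp <- doc$typo_policy
  p$typo_policy[names(tp)] <- tp
  init <- as.numeric(doc[paste0("x", 1:13, "_0")])
  names(init) <- paste0("x", 1:13)
  list(params = p, init = init, ir_dose = as.numeric(doc$ir_dose))
}
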