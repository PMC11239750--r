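#' Pipeline configuration
#'
#' Collects every tunable parameter of the prediction pipeline in one
#' validated list. Unknown keys are rejected by name, so typos fail loudly.
#' Defaults encode the study conditions: baseline coronary flow as 4.5% of
#' cardiac output, Murray exponent 3, hyperemic factor TCRI = 3, Windkessel
#' resistance split 0.01/0.84/0.15 and compliance split 0.025/0.975, total
#' systemic arterial compliance 1.7 mL/mmHg with a coronary fraction of
#' 0.045, a 0.036 cm guidewire, and a 1 ms time step.
#'
#' @param ... named overrides of the defaults listed below.
#' @return An object of class `ffr_config` (a named list).
#' @section Keys:
#' \describe{
#'   \item{n_generations, root_radius_cm, length_ratio_range, asymmetry_range}{
#'     synthetic tree generator: depth, inlet radius (cm), segment
#'     length-to-radius ratio range, bifurcation radius asymmetry range.}
#'   \item{q_cor_fraction}{baseline coronary flow as a fraction of CO (0.045).}
#'   \item{murray_exponent}{diameter exponent for Murray flow splitting (3).}
#'   \item{density, viscosity, venous_pressure_mmHg}{blood/venous constants.}
#'   \item{kt}{turbulent-loss coefficient of the stenosis model (1.52).}
#'   \item{tcri}{total coronary resistance index dividing baseline
#'     peripheral resistance under hyperemia (3).}
#'   \item{arterial_compliance_ml_mmhg, compliance_fraction}{systemic arterial
#'     compliance and the coronary portion of it.}
#'   \item{r_fractions, c_fractions}{Windkessel splits of R_hyp among
#'     (Ra, Ra_micro, Rd) and of C_out among (Ca, Cmyo).}
#'   \item{wire_diameter_cm, wire_path}{guidewire diameter and default
#'     extent, `"stenotic_branch"` or `"inlet_to_measurement"`.}
#'   \item{dt_s, max_cycles, periodicity_tol}{transient solver controls.}
#'   \item{cycle_duration_s, pulse_pressure_mmHg}{cardiac cycle defaults used
#'     when a patient record does not carry them.}
#'   \item{measurement_distance_cm}{distance distal to the lesion at which
#'     the distal pressure is sampled (2.5 cm, clipped to branch end).}
#'   \item{stenosis_length_cm, stenosis_position}{default stenosis throat
#'     length and fractional position along its segment.}
#'   \item{cutoff}{FFR positivity cutoff for diagnostic statistics (0.8).}
#'   \item{calibration_tol, calibration_flow_method}{cohort calibration
#'     tolerance on predicted FFR and the flow setup used to calibrate.}
#' }
#' @examples
#' cfg <- ffr_config(tcri = 2.5)
#' cfg$tcri
#' @export
ffr_config <- function(...) {
  defaults <- list(
    n_generations = 3L,
    root_radius_cm = 0.15,
    length_ratio_range = c(4, 8),
    asymmetry_range = c(0.5, 0.8),
    q_cor_fraction = 0.045,
    murray_exponent = 3,
    density = 1.05,
    viscosity = 0.035,
    venous_pressure_mmHg = 5,
    kt = 1.52,
    tcri = 3,
    arterial_compliance_ml_mmhg = 1.7,
    compliance_fraction = 0.045,
    r_fractions = c(0.01, 0.84, 0.15),
    c_fractions = c(0.025, 0.975),
    wire_diameter_cm = 0.036,
    wire_path = "stenotic_branch",
    dt_s = 0.001,
    max_cycles = 10L,
    periodicity_tol = 1e-3,
    cycle_duration_s = 0.8,
    pulse_pressure_mmHg = 40,
    measurement_distance_cm = 2.5,
    stenosis_length_cm = 0.3,
    stenosis_position = 0.5,
    cutoff = 0.8,
    calibration_tol = 0.01,
    calibration_flow_method = "murray"
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults[nm] <- overrides
  }
  structure(defaults, class = "ffr_config")
}

#' @export
print.ffr_config <- function(x, ...) {
  cat("FFR pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# fluid_params view of a config
config_fluid <- function(config) {
  fluid_params(density = config$density, viscosity = config$viscosity,
               venous_pressure = config$venous_pressure_mmHg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through YAML unchanged (numeric precision
#' permitting); unknown keys in the file are rejected just as in
#' [ffr_config()].
#'
#' @param path file path.
#' @param config an `ffr_config` object.
#' @return `read_config` returns an `ffr_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(ffr_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ffr_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
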