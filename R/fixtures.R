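#' Clinical parameter tables of the study population
#'
#' The packaged fixtures describe the 18-patient population and its 24
#' invasively measured lesions: mean aortic pressure (MAP, mmHg), cardiac
#' output (CO, L/min) and coronary arterial dominance per patient, and
#' lesion location plus invasive FFR per measurement. `load_patients()`
#' returns one row per patient, `load_lesions()` one row per FFR
#' measurement (FFR IDs 1-24, each referencing a patient).
#'
#' @param path optional path to an alternative CSV with the same schema
#'   (`patient_id,map_mmHg,co_l_min,dominance` respectively
#'   `ffr_id,patient_id,location,ffr_invasive`).
#' @return A data.frame.
#' @examples
#' p <- load_patients()
#' nrow(p)          # 18
#' l <- load_lesions()
#' range(l$ffr_invasive)
#' @export
load_patients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "patients.csv", package = "ffrwire",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "map_mmHg", "co_l_min", "dominance")
  if (!identical(names(df), need))
    stop("corrupted patient fixture file '", path, "': expected columns ",
         paste(need, collapse = ","))
  if (any(df$map_mmHg <= 0) || any(df$co_l_min <= 0))
    stop("corrupted patient fixture file '", path, "': non-positive MAP or CO")
  if (!all(df$dominance %in% c("right", "left")))
    stop("corrupted patient fixture file '", path, "': bad dominance value")
  df
}

#' @rdname load_patients
#' @export
load_lesions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lesions.csv", package = "ffrwire",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ffr_id", "patient_id", "location", "ffr_invasive")
  if (!identical(names(df), need))
    stop("corrupted lesion fixture file '", path, "': expected columns ",
         paste(need, collapse = ","))
  if (any(df$ffr_invasive <= 0) || any(df$ffr_invasive > 1))
    stop("corrupted lesion fixture file '", path,
         "': invasive FFR outside (0, 1]")
  df
}

#' Normalise a patient description
#'
#' Accepts a row of [load_patients()] output, or any named list with at
#' least `map` (or `map_mmHg`) and `co` (or `co_l_min`), and fills in the
#' cycle duration and pulse pressure defaults (0.8 s and 40 mmHg) when the
#' record does not carry them -- the population table reports only MAP, CO
#' and dominance.
#'
#' @param x patient description (list, data.frame row).
#' @param config an [ffr_config()] supplying the defaults.
#' @return A list of class `ffr_patient` with fields `patient_id`, `map`,
#'   `co`, `dominance`, `cycle_duration`, `pulse_pressure`.
#' @export
as_patient <- function(x, config = ffr_config()) {
  if (inherits(x, "ffr_patient")) return(x)
  x <- as.list(x)
  map <- x$map %||% x$map_mmHg
  co <- x$co %||% x$co_l_min
  if (is.null(map) || is.null(co))
    stop("patient record must provide MAP (mmHg) and CO (L/min)")
  out <- list(
    patient_id = x$patient_id %||% NA_integer_,
    map = as.numeric(map),
    co = as.numeric(co),
    dominance = x$dominance %||% NA_character_,
    cycle_duration = as.numeric(x$cycle_duration %||% config$cycle_duration_s),
    pulse_pressure = as.numeric(x$pulse_pressure %||% config$pulse_pressure_mmHg)
  )
  if (out$map <= 0 || out$co <= 0 || out$cycle_duration <= 0 ||
      out$pulse_pressure <= 0)
    stop("patient parameters must be positive")
  structure(out, class = "ffr_patient")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
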