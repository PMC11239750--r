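# Unit conversion: 1 mmHg = 1333.22 dyn/cm^2. Fixed here, used everywhere.
.DYN_PER_MMHG <- 1333.22

#' Blood and venous reference properties
#'
#' Container for the fluid constants used by every resistance and
#' pressure-drop computation: blood density and dynamic viscosity (CGS
#' units) and the reference venous pressure closing the coronary beds.
#'
#' @param density blood density, g/cm^3.
#' @param viscosity dynamic viscosity, g/(cm s) (poise).
#' @param venous_pressure reference venous pressure, mmHg.
#' @return An object of class `fluid_params`.
#' @examples
#' fluid_params()
#' @export
fluid_params <- function(density = 1.05, viscosity = 0.035, venous_pressure = 5) {
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  if (!is.numeric(viscosity) || viscosity <= 0) stop("viscosity must be positive")
  if (!is.numeric(venous_pressure) || venous_pressure <= 0)
    stop("venous_pressure must be positive")
  structure(list(density = density, viscosity = viscosity,
                 venous_pressure = venous_pressure),
            class = "fluid_params")
}

# Evaluate `expr` with the global RNG seeded at `seed`, restoring the
# previous RNG state afterwards.  Gives every generator an explicit,
# reproducible stream without leaking state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Trapezoidal integral of y(x) on a grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
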