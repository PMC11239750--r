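#' Total baseline coronary flow
#'
#' The baseline flow entering the coronary tree is taken as a fixed portion
#' of cardiac output, `q_cor = 0.045 * CO`, converted from L/min to mL/s.
#'
#' @param co cardiac output, L/min (non-negative).
#' @param fraction coronary portion of CO (default 0.045).
#' @return Flow in mL/s.
#' @examples
#' total_coronary_flow(6)   # 4.5 mL/s
#' @export
total_coronary_flow <- function(co, fraction = 0.045) {
  if (!is.numeric(co) || any(co < 0)) stop("CO must be non-negative")
  fraction * co * 1000 / 60
}

#' Outlet flow fractions by Murray's law
#'
#' Splits flow among outlets in proportion to outlet diameter raised to the
#' Murray exponent: `fraction_k = d_k^m / sum_j d_j^m`. The classical
#' exponent is 3; values in `[2, 3]` are customary for coronary arteries
#' (2.66 has been proposed) and anything outside that range triggers a
#' warning.
#'
#' @param diameters outlet diameters, cm (all positive, non-empty).
#' @param exponent Murray exponent.
#' @return Weights summing to 1.
#' @examples
#' murray_fractions(c(0.2, 0.1))          # 8/9, 1/9
#' murray_fractions(c(0.2, 0.1), 2.66)
#' @export
murray_fractions <- function(diameters, exponent = 3) {
  if (length(diameters) == 0L) stop("at least one outlet diameter is required")
  if (any(diameters <= 0)) stop("outlet diameters must be positive")
  if (exponent < 2 || exponent > 3)
    warning("Murray exponent outside the customary [2, 3] range")
  w <- diameters^exponent
  w / sum(w)
}

#' Outlet flow fractions by crown length
#'
#' The vessel-length (stem-and-crown) criterion allocates flow to each
#' outlet in proportion to the length of its crown: the summed length of
#' all segments distal to and including the outlet's terminal segment. For
#' a tree whose outlets are leaves this is the terminal segment length.
#'
#' @param tree a `coronary_tree`.
#' @return Weights summing to 1, ordered as [tree_outlets()].
#' @export
crown_length_fractions <- function(tree) {
  stopifnot(inherits(tree, "coronary_tree"))
  outs <- tree_outlets(tree)
  w <- vapply(outs, function(o) crown_length(tree, o), numeric(1))
  if (sum(w) <= 0) stop("total crown length must be positive")
  w / sum(w)
}

#' Allocate total flow among outlets
#'
#' @param q_cor total baseline coronary flow, mL/s.
#' @param weights per-outlet fractions; must sum to 1 (tiny rounding is
#'   renormalized silently).
#' @return An object of class `flow_allocation` with fields `q_cor`,
#'   `fractions` and `outlet_flows` (mL/s).
#' @examples
#' allocate_flow(4.5, c(0.5, 0.5))
#' @export
allocate_flow <- function(q_cor, weights) {
  if (!is.numeric(q_cor) || q_cor < 0) stop("q_cor must be non-negative")
  if (any(weights <= 0)) stop("weights must be positive")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8)
    stop("weights must sum to 1 (got ", format(s, digits = 12), ")")
  w <- weights / s
  structure(list(q_cor = q_cor, fractions = w, outlet_flows = q_cor * w),
            class = "flow_allocation")
}

#' @export
print.flow_allocation <- function(x, ...) {
  cat(sprintf("Flow allocation: q_cor = %.4g mL/s over %d outlets\n",
              x$q_cor, length(x$fractions)))
  cat("  fractions:", paste(sprintf("%.4f", x$fractions), collapse = " "), "\n")
  invisible(x)
}
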