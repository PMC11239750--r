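# Internal reduced-order network machinery shared by the baseline solve,
# the steady hyperemic solve and the transient kernel setup.

# Precompute everything the solvers need from a tree.
build_network <- function(tree, fluid = fluid_params(), kt = 1.52) {
  validate_tree(tree)
  s <- tree$segments
  n <- nrow(s)
  outs <- tree_outlets(tree)
  N <- length(outs)
  out_idx <- match(outs, s$id)
  parent_idx <- match(s$parent, s$id)          # NA for root
  inc <- matrix(0, n, N)                       # segment-on-path-of-outlet
  for (k in seq_len(N)) inc[match(tree_path(tree, outs[k]), s$id), k] <- 1
  co <- segment_coefficients(tree, fluid, kt)

  mi <- match(tree$measurement$segment_id, s$id)
  mf <- tree$measurement$offset_cm / s$length_cm[mi]
  mc <- partial_drop_coefficients(co, mi, mf)

  sten <- which(!is.na(s$sten_degree))
  lesion_idx <- if (length(sten)) sten[1] else mi

  list(tree = tree, seg = s, n = n, outlets = outs, out_idx = out_idx,
       parent_idx = parent_idx, inc = inc, co = co, fluid = fluid, kt = kt,
       meas_idx = mi, meas_R = mc$R, meas_K2 = mc$K2,
       lesion_idx = lesion_idx)
}

# Given outlet flows, march pressures from the inlet. Exact for trees.
eval_network <- function(net, q_out, p_in) {
  q_seg <- as.numeric(net$inc %*% q_out)
  drop <- (net$co$R_dist + net$co$R_lump) * q_seg +
    net$co$K2 * q_seg * abs(q_seg)
  p_dist <- numeric(net$n)
  for (i in seq_len(net$n)) {
    p_prox <- if (is.na(net$parent_idx[i])) p_in else p_dist[net$parent_idx[i]]
    p_dist[i] <- p_prox - drop[i]
  }
  qm <- q_seg[net$meas_idx]
  p_prox_meas <- if (is.na(net$parent_idx[net$meas_idx])) p_in
                 else p_dist[net$parent_idx[net$meas_idx]]
  p_d <- p_prox_meas - net$meas_R * qm - net$meas_K2 * qm * abs(qm)
  p_les <- if (is.na(net$parent_idx[net$lesion_idx])) p_in
           else p_dist[net$parent_idx[net$lesion_idx]]
  list(q_seg = q_seg, p_dist = p_dist, p_out = p_dist[net$out_idx],
       p_d = p_d, p_lesion_prox = p_les)
}

# Damped Newton on outlet flows for the loaded steady network:
#   p_out_k(q) - p_load - R_load_k * q_k = 0.
# R_load closes each outlet onto the load pressure (venous pressure for the
# hyperemic steady solve). Returns flows and the evaluated state.
solve_tree_steady <- function(net, p_in, R_load, p_load,
                              tol = 1e-10, max_iter = 100) {
  N <- length(net$outlets)
  stopifnot(length(R_load) == N)
  Rlin <- net$co$R_dist + net$co$R_lump
  A <- crossprod(net$inc * Rlin, net$inc)      # A[k,j] = sum over common path
  q <- solve(A + diag(R_load, N), rep(p_in - p_load, N))
  resid <- function(q) {
    ev <- eval_network(net, q, p_in)
    list(F = ev$p_out - p_load - R_load * q, ev = ev)
  }
  r <- resid(q)
  for (it in seq_len(max_iter)) {
    if (max(abs(r$F)) < tol) break
    w <- Rlin + 2 * net$co$K2 * abs(r$ev$q_seg)
    J <- -crossprod(net$inc * w, net$inc) - diag(R_load, N)
    step <- solve(J, -r$F)
    lambda <- 1
    repeat {
      qn <- q + lambda * step
      rn <- resid(qn)
      if (max(abs(rn$F)) < max(abs(r$F)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    q <- qn; r <- rn
  }
  if (max(abs(r$F)) >= 1e-6)
    stop("steady network solve did not converge; max residual ",
         format(max(abs(r$F))), " mmHg")
  list(q_out = q, ev = r$ev)
}

#' Baseline steady solve with prescribed inlet pressure and outlet flows
#'
#' Scenario I of the pipeline: the inlet is held at the patient's mean
#' aortic pressure and each outlet discharges its allocated baseline flow.
#' On a tree the segment flows are then fully determined (each segment
#' carries the sum of its distal outlet flows) and nodal pressures follow
#' by marching from the inlet, subtracting each segment's viscous plus
#' stenotic pressure drop.
#'
#' @param tree a `coronary_tree`.
#' @param map inlet (mean aortic) pressure, mmHg.
#' @param allocation a [allocate_flow()] result whose outlets match the
#'   tree's terminal segments.
#' @param fluid a [fluid_params()] object.
#' @param kt stenosis turbulent-loss coefficient.
#' @return An object of class `network_state`: inlet pressure, per-segment
#'   flows (mL/s) and distal-node pressures (mmHg), per-outlet pressure and
#'   flow, the distal measurement pressure `p_d` and the pressure just
#'   proximal to the lesion.
#' @examples
#' tr <- generate_tree(2, seed = 1)
#' al <- allocate_flow(4.5, murray_fractions(2 * tr$segments$radius_cm[2:3]))
#' solve_baseline(tr, 93.33, al)
#' @export
solve_baseline <- function(tree, map, allocation, fluid = fluid_params(),
                           kt = 1.52) {
  stopifnot(inherits(tree, "coronary_tree"))
  if (!inherits(allocation, "flow_allocation"))
    stop("allocation must come from allocate_flow()")
  net <- build_network(tree, fluid, kt)
  N <- length(net$outlets)
  if (length(allocation$outlet_flows) != N)
    stop("allocation has ", length(allocation$outlet_flows),
         " outlets but the tree has ", N)
  ev <- eval_network(net, allocation$outlet_flows, map)
  structure(list(
    inlet_pressure = map,
    segment_id = net$seg$id,
    segment_flow = ev$q_seg,
    node_pressure = ev$p_dist,
    outlets = net$outlets,
    outlet_pressure = ev$p_out,
    outlet_flow = allocation$outlet_flows,
    p_d = ev$p_d,
    p_lesion_prox = ev$p_lesion_prox,
    fluid = fluid
  ), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("Network state: inlet %.2f mmHg, %d outlets\n",
              x$inlet_pressure, length(x$outlets)))
  cat(sprintf("  outlet pressures: %s mmHg\n",
              paste(sprintf("%.2f", x$outlet_pressure), collapse = ", ")))
  cat(sprintf("  distal measurement pressure: %.2f mmHg\n", x$p_d))
  invisible(x)
}

#' Peripheral resistance calibration
#'
#' `baseline_outlet_resistances` computes the baseline peripheral
#' resistance of each coronary bed from the resting solve,
#' `R_out_k = (p_out_k - p_v) / q_out_k`; a baseline outlet pressure at or
#' below venous pressure is unphysiological (it signals an excessive
#' stenosis or bad inputs) and is rejected. `hyperemic_resistances`
#' applies the hyperemic factor, dividing every baseline resistance by the
#' total coronary resistance index (TCRI, default 3).
#'
#' @param state a `network_state` from [solve_baseline()].
#' @param fluid a [fluid_params()] object (venous pressure).
#' @param r_bln numeric vector of baseline resistances, mmHg s/mL. Passing
#'   an already-built `outlet_resistances` object is an error: the
#'   hyperemic division must not be applied twice.
#' @param tcri total coronary resistance index, > 0.
#' @return `baseline_outlet_resistances` returns a numeric vector;
#'   `hyperemic_resistances` an object of class `outlet_resistances` with
#'   fields `r_bln`, `r_hyp` (= `r_bln / tcri`) and `tcri`.
#' @examples
#' hyperemic_resistances(c(40, 60))$r_hyp
#' @export
baseline_outlet_resistances <- function(state, fluid = state$fluid) {
  stopifnot(inherits(state, "network_state"))
  p_v <- fluid$venous_pressure
  if (any(state$outlet_flow <= 0))
    stop("baseline outlet flows must be positive")
  if (any(state$outlet_pressure <= p_v))
    stop("baseline outlet pressure at or below venous pressure (",
         format(p_v), " mmHg): unphysiological baseline")
  (state$outlet_pressure - p_v) / state$outlet_flow
}

#' @rdname baseline_outlet_resistances
#' @export
hyperemic_resistances <- function(r_bln, tcri = 3) {
  if (inherits(r_bln, "outlet_resistances"))
    stop("input already holds hyperemic resistances; ",
         "the TCRI division must be applied exactly once")
  if (!is.numeric(r_bln) || any(r_bln <= 0))
    stop("baseline resistances must be positive")
  if (!is.numeric(tcri) || tcri <= 0) stop("tcri must be positive")
  structure(list(r_bln = r_bln, r_hyp = r_bln / tcri, tcri = tcri),
            class = "outlet_resistances")
}

#' @export
print.outlet_resistances <- function(x, ...) {
  cat(sprintf("Outlet resistances (TCRI = %g):\n", x$tcri))
  cat("  baseline :", paste(sprintf("%.3f", x$r_bln), collapse = ", "), "mmHg s/mL\n")
  cat("  hyperemic:", paste(sprintf("%.3f", x$r_hyp), collapse = ", "), "mmHg s/mL\n")
  invisible(x)
}
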