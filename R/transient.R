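#' Hyperemic simulations and FFR extraction
#'
#' `run_hyperemic_transient` integrates the pulsatile Windkessel-coupled
#' problem (the engine behind [simulate.ffr_model()]); at every 1 ms step a
#' damped Newton solve couples the nonlinear tree network to the frozen
#' Windkessel proximal pressures, after which the two bed states per outlet
#' are advanced by an unconditionally stable backward-Euler update.
#' `run_hyperemic_steady` solves the steady analogue: every outlet loaded
#' by its total hyperemic resistance `Ra + Ra_micro + Rd` discharging to
#' venous pressure, with the inlet at MAP. `compute_ffr` extracts FFR from
#' a simulation as the ratio of the means of distal and aortic pressure
#' over the final cardiac cycle.
#'
#' @param model an [ffr_model()].
#' @param dt time step, s.
#' @param max_cycles maximum number of cardiac cycles (default 10).
#' @param tol relative periodicity tolerance on cycle-mean distal pressure;
#'   non-convergence returns a result flagged `converged = FALSE` with a
#'   warning.
#' @return `run_hyperemic_transient`: an `ffr_sim` (see
#'   [simulate.ffr_model()]). `run_hyperemic_steady`: a list with `p_a`,
#'   `p_d`, `p_lesion_prox`, `outlet_flow`, `q_in`, `ffr`. `compute_ffr`:
#'   a single number.
#' @export
run_hyperemic_transient <- function(model, dt = model$config$dt_s,
                                    max_cycles = model$config$max_cycles,
                                    tol = model$config$periodicity_tol) {
  stopifnot(inherits(model, "ffr_model"))
  if (dt <= 0) stop("dt must be positive")
  period <- model$patient$cycle_duration
  spc <- max(2L, as.integer(round(period / dt)))
  net <- build_network(model$tree, model$fluid, model$config$kt)
  N <- length(net$outlets)
  wk <- model$windkessel

  # waveform samples at step ends: step k covers ((k-1)dt, k dt]
  ph <- (seq_len(spc) %% spc) / spc
  pa_cycle <- waveform_at(model$aortic, ph)
  plv_cycle <- waveform_at(model$lv, ph)

  # initialise states from the steady hyperemic solution
  st <- steady_core(model, net)
  p1 <- st$p_out - wk$Ra * st$q_out
  p2 <- p1 - wk$Ra_micro * st$q_out

  res <- transient_kernel(
    parent = ifelse(is.na(net$parent_idx), 0L, net$parent_idx),
    R_lin = net$co$R_dist + net$co$R_lump,
    K2 = net$co$K2,
    outlet_seg = net$out_idx,
    inc = matrix(as.integer(net$inc), nrow(net$inc), ncol(net$inc)),
    Ra = wk$Ra, Ram = wk$Ra_micro, Rd = wk$Rd, Ca = wk$Ca, Cmyo = wk$Cmyo,
    p_v = model$fluid$venous_pressure, dt = dt,
    pa_cycle = pa_cycle, plv_cycle = plv_cycle,
    max_cycles = as.integer(max_cycles), tol = tol,
    meas_seg = net$meas_idx, meas_R = net$meas_R, meas_K2 = net$meas_K2,
    lesion_seg = net$lesion_idx,
    p1_init = p1, p2_init = p2, q_init = st$q_out)

  n_steps <- length(res$p_a)
  sim <- data.frame(
    time_s = dt * seq_len(n_steps),
    p_a_mmHg = res$p_a,
    p_d_mmHg = res$p_d,
    p_lesion_prox_mmHg = res$p_lesion_prox,
    q_in_ml_s = res$q_in
  )
  if (!res$converged)
    warning("transient simulation did not reach periodicity within ",
            max_cycles, " cycles")
  structure(sim,
            outlet_flows = res$q_out, outlets = net$outlets,
            n_cycles = res$n_cycles, steps_per_cycle = spc,
            converged = res$converged, dt = dt, period = period,
            class = c("ffr_sim", "data.frame"))
}

# steady hyperemic core shared by run_hyperemic_steady and the transient
# initialisation; outlets loaded by the total hyperemic resistance to p_v.
steady_core <- function(model, net = NULL) {
  if (is.null(net)) net <- build_network(model$tree, model$fluid, model$config$kt)
  wk <- model$windkessel
  R_tot <- wk$Ra + wk$Ra_micro + wk$Rd
  sol <- solve_tree_steady(net, model$patient$map, R_tot,
                           model$fluid$venous_pressure)
  list(q_out = sol$q_out, p_out = sol$ev$p_out, ev = sol$ev)
}

#' @rdname run_hyperemic_transient
#' @export
run_hyperemic_steady <- function(model) {
  stopifnot(inherits(model, "ffr_model"))
  st <- steady_core(model)
  list(p_a = model$patient$map,
       p_d = st$ev$p_d,
       p_lesion_prox = st$ev$p_lesion_prox,
       outlet_flow = st$q_out,
       q_in = sum(st$q_out),
       ffr = st$ev$p_d / model$patient$map)
}

#' @rdname run_hyperemic_transient
#' @param sim an `ffr_sim` object.
#' @export
compute_ffr <- function(sim) {
  m <- final_cycle_means(sim)
  if (m["p_a"] == 0) stop("zero mean aortic pressure")
  unname(m["p_d"] / m["p_a"])
}

# Means of the recorded series over the final cycle.
final_cycle_means <- function(sim) {
  stopifnot(inherits(sim, "ffr_sim"))
  if (!isTRUE(attr(sim, "converged")))
    warning("simulation did not converge; FFR/means may be unreliable")
  spc <- attr(sim, "steps_per_cycle")
  idx <- seq.int(nrow(sim) - spc + 1, nrow(sim))
  c(p_a = mean(sim$p_a_mmHg[idx]),
    p_d = mean(sim$p_d_mmHg[idx]),
    p_lesion_prox = mean(sim$p_lesion_prox_mmHg[idx]),
    q_in = mean(sim$q_in_ml_s[idx]))
}

# FFR, trans-stenotic cycle-mean pressure drop and cycle-mean inflow.
sim_metrics <- function(sim) {
  m <- final_cycle_means(sim)
  list(ffr = unname(m["p_d"] / m["p_a"]),
       delta_p = unname(m["p_lesion_prox"] - m["p_d"]),
       inflow = unname(m["q_in"]))
}

#' Export a simulation as tidy CSV
#'
#' @param sim an `ffr_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.ffr_sim <- function(x, ...) {
  cat(sprintf(
    "Hyperemic transient: %d cycles of %d steps (dt = %g s), converged: %s\n",
    attr(x, "n_cycles"), attr(x, "steps_per_cycle"), attr(x, "dt"),
    attr(x, "converged")))
  m <- suppressWarnings(final_cycle_means(x))
  cat(sprintf("  cycle means: p_a %.2f mmHg, p_d %.2f mmHg, q_in %.3f mL/s\n",
              m["p_a"], m["p_d"], m["q_in"]))
  cat(sprintf("  FFR = %.4f\n", m["p_d"] / m["p_a"]))
  invisible(x)
}
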