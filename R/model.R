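#' Fit the FFR prediction model for one tree and patient
#'
#' Runs the calibration half of the prediction pipeline and returns a
#' fitted model object from which FFR is predicted:
#' \enumerate{
#'   \item total baseline coronary flow `q_cor = 0.045 * CO`;
#'   \item flow split among the tree outlets by the chosen criterion
#'     (Murray diameter weights or vessel-length / stem-and-crown weights);
#'   \item baseline steady solve with inlet at MAP and prescribed outlet
#'     flows (Scenario I);
#'   \item baseline peripheral resistances
#'     `R_out_k = (p_out_k - p_v) / q_out_k`;
#'   \item hyperemic resistances `R_out_k / TCRI` and their Windkessel
#'     split, plus the Murray-distributed coronary compliances;
#'   \item aortic and left-ventricular waveforms scaled to the patient's
#'     MAP, pulse pressure and cycle duration.
#' }
#' The hyperemic simulation itself (Scenario II) is run by
#' [simulate.ffr_model()] / [predict.ffr_model()].
#'
#' @param tree a `coronary_tree` (optionally stenosed / wired).
#' @param patient a patient description accepted by [as_patient()].
#' @param flow_method `"murray"` or `"length_based"`.
#' @param config an [ffr_config()].
#' @return An object of class `ffr_model`.
#' @examples
#' tr <- add_stenosis(generate_tree(3, seed = 1), 2, 0.6)
#' m <- ffr_model(tr, list(map = 93.33, co = 6))
#' m
#' @seealso [predict.ffr_model()], [simulate.ffr_model()],
#'   [paired_wire_study()]
#' @export
ffr_model <- function(tree, patient, flow_method = c("murray", "length_based"),
                      config = ffr_config()) {
  stopifnot(inherits(tree, "coronary_tree"))
  flow_method <- match.arg(flow_method)
  patient <- as_patient(patient, config)
  fluid <- config_fluid(config)

  outs <- tree_outlets(tree)
  diameters <- 2 * tree$segments$radius_cm[match(outs, tree$segments$id)]
  weights <- switch(flow_method,
    murray = murray_fractions(diameters, config$murray_exponent),
    length_based = crown_length_fractions(tree))

  q_cor <- total_coronary_flow(patient$co, config$q_cor_fraction)
  allocation <- allocate_flow(q_cor, weights)
  baseline <- solve_baseline(tree, patient$map, allocation, fluid, config$kt)
  r_bln <- baseline_outlet_resistances(baseline, fluid)
  resistances <- hyperemic_resistances(r_bln, config$tcri)

  murray_w <- murray_fractions(diameters, config$murray_exponent)
  c_out <- distribute_compliance(murray_w, config$arterial_compliance_ml_mmhg,
                                 config$compliance_fraction)
  wk <- split_windkessel(resistances$r_hyp, c_out,
                         config$r_fractions, config$c_fractions)

  aortic <- scale_waveform(aortic_waveform(), patient$map,
                           patient$pulse_pressure, patient$cycle_duration)
  lv <- scale_lv_waveform(lv_waveform(),
                          peak = patient$map + patient$pulse_pressure / 2,
                          period = patient$cycle_duration)

  structure(list(
    tree = tree, patient = patient, flow_method = flow_method,
    config = config, fluid = fluid,
    weights = weights, allocation = allocation, baseline = baseline,
    resistances = resistances, compliance = c_out, windkessel = wk,
    aortic = aortic, lv = lv
  ), class = "ffr_model")
}

#' @export
print.ffr_model <- function(x, ...) {
  s <- x$tree$segments
  sten <- which(!is.na(s$sten_degree))
  cat("Reduced-order FFR prediction model\n")
  cat(sprintf("  tree: %d segments, %d outlets; flow split: %s\n",
              nrow(s), length(tree_outlets(x$tree)), x$flow_method))
  if (length(sten))
    cat(sprintf("  lesion: segment %d, %.0f%% area reduction%s\n",
                s$id[sten[1]], 100 * s$sten_degree[sten[1]],
                if (any(s$wire)) ", guidewire included" else ""))
  cat(sprintf("  patient: MAP %.2f mmHg, CO %.2f L/min (q_cor %.3f mL/s)\n",
              x$patient$map, x$patient$co, x$allocation$q_cor))
  cat(sprintf("  TCRI %g; total hyperemic peripheral resistance %.2f mmHg s/mL\n",
              x$resistances$tcri, 1 / sum(1 / x$resistances$r_hyp)))
  invisible(x)
}

#' Windkessel coefficients of a fitted model
#'
#' Returns the calibrated per-outlet coronary-bed parameters: the
#' five Windkessel elements plus the baseline and hyperemic peripheral
#' resistances they were derived from.
#'
#' @param object an `ffr_model`.
#' @param ... unused.
#' @return A numeric matrix, one row per outlet.
#' @export
coef.ffr_model <- function(object, ...) {
  m <- cbind(R_bln = object$resistances$r_bln,
             R_hyp = object$resistances$r_hyp,
             as.matrix(object$windkessel))
  rownames(m) <- paste0("outlet_", tree_outlets(object$tree))
  m
}

#' @export
summary.ffr_model <- function(object, ...) {
  outs <- tree_outlets(object$tree)
  tab <- data.frame(
    outlet = outs,
    radius_cm = object$tree$segments$radius_cm[match(outs, object$tree$segments$id)],
    fraction = object$weights,
    q_bln_ml_s = object$baseline$outlet_flow,
    p_bln_mmHg = object$baseline$outlet_pressure,
    R_bln = object$resistances$r_bln,
    R_hyp = object$resistances$r_hyp,
    C_out = object$compliance
  )
  structure(list(model = object, outlet_table = tab), class = "summary.ffr_model")
}

#' @export
print.summary.ffr_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-outlet calibration:\n")
  print(x$outlet_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict FFR from a fitted model
#'
#' Runs the hyperemic simulation and returns the predicted fractional flow
#' reserve, the ratio of cycle-averaged distal to aortic pressure. The
#' default pulsatile prediction simulates the Windkessel-coupled transient
#' ([simulate.ffr_model()]); `type = "steady"` solves the equivalent
#' steady problem (each outlet loaded by its total hyperemic resistance to
#' venous pressure), a fast path that reproduces the transient prediction
#' closely.
#'
#' @param object an `ffr_model`.
#' @param type `"transient"` (default) or `"steady"`.
#' @param ... passed to [simulate.ffr_model()] (`dt`, `max_cycles`, ...).
#' @return FFR as a single number in (0, 1] for antegrade flow.
#' @examples
#' tr <- add_stenosis(generate_tree(2, seed = 1), 2, 0.6)
#' m <- ffr_model(tr, list(map = 93.33, co = 6))
#' predict(m, type = "steady")
#' @export
predict.ffr_model <- function(object, type = c("transient", "steady"), ...) {
  type <- match.arg(type)
  if (type == "steady") {
    run_hyperemic_steady(object)$ffr
  } else {
    compute_ffr(simulate(object, ...))
  }
}

#' Simulate the hyperemic pulsatile state of a fitted model
#'
#' Scenario II: the scaled aortic pressure waveform drives the tree inlet
#' while every outlet is coupled to its calibrated coronary-bed Windkessel
#' model; the left-ventricular waveform compresses the myocardial
#' compliances, reproducing systolic impediment of coronary flow. Cycles
#' are repeated until the cycle-mean distal pressure is periodic.
#' The solver is deterministic: `nsim` and `seed` are accepted for
#' compatibility with the generic but ignored beyond a warning.
#'
#' @param object an `ffr_model`.
#' @param nsim,seed ignored (deterministic simulation).
#' @param dt time step, s.
#' @param max_cycles maximum number of cardiac cycles.
#' @param tol relative periodicity tolerance on cycle-mean distal pressure.
#' @param ... unused.
#' @return An object of class `ffr_sim`: data.frame with columns `time_s`,
#'   `p_a_mmHg`, `p_d_mmHg`, `p_lesion_prox_mmHg`, `q_in_ml_s`, plus
#'   attributes `outlet_flows` (matrix), `n_cycles`, `steps_per_cycle`,
#'   `converged`, `dt`, `period`.
#' @export
simulate.ffr_model <- function(object, nsim = 1, seed = NULL,
                               dt = object$config$dt_s,
                               max_cycles = object$config$max_cycles,
                               tol = object$config$periodicity_tol, ...) {
  if (nsim != 1 || !is.null(seed))
    warning("the hyperemic simulation is deterministic; nsim/seed ignored")
  run_hyperemic_transient(object, dt = dt, max_cycles = max_cycles, tol = tol)
}

#' @export
plot.ffr_model <- function(x, y, ...) {
  sim <- simulate(x)
  spc <- attr(sim, "steps_per_cycle")
  last <- sim[seq.int(nrow(sim) - spc + 1, nrow(sim)), ]
  t0 <- last$time_s - last$time_s[1]
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(t0, last$p_a_mmHg, type = "l", xlab = "time in cycle (s)",
                 ylab = "pressure (mmHg)",
                 ylim = range(c(last$p_a_mmHg, last$p_d_mmHg)),
                 main = sprintf("FFR = %.3f", compute_ffr(sim)), ...)
  graphics::lines(t0, last$p_d_mmHg, lty = 2)
  graphics::legend("topright", legend = c("aortic p_a", "distal p_d"),
                   lty = c(1, 2), bty = "n")
  graphics::plot(t0, last$q_in_ml_s, type = "l", xlab = "time in cycle (s)",
                 ylab = "inlet flow (mL/s)")
  invisible(x)
}
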