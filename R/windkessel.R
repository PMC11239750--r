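#' Split hyperemic resistance and compliance among Windkessel elements
#'
#' Each outlet is closed by a five-element coronary-bed model: an arterial
#' path (proximal resistance `Ra`, arterial compliance `Ca`,
#' micro-circulation resistance `Ra_micro`), a venous path reduced to a
#' distal resistance `Rd`, and the myocardial compliance `Cmyo` joining the
#' two paths, loaded by the time-varying left-ventricular pressure. The
#' per-outlet hyperemic resistance is split among `(Ra, Ra_micro, Rd)` with
#' fractions 0.01/0.84/0.15 and the per-outlet compliance among
#' `(Ca, Cmyo)` with fractions 0.025/0.975. The last element of each split
#' is computed by difference so the totals are conserved exactly.
#'
#' @param r_hyp per-outlet hyperemic resistance(s), mmHg s/mL.
#' @param c_out per-outlet compliance(s), mL/mmHg.
#' @param r_fractions fractions for `(Ra, Ra_micro, Rd)`; must sum to 1.
#' @param c_fractions fractions for `(Ca, Cmyo)`; must sum to 1.
#' @return A data.frame with columns `Ra`, `Ra_micro`, `Rd`, `Ca`, `Cmyo`,
#'   one row per outlet, of class `windkessel_params`.
#' @examples
#' split_windkessel(100, 0.04)
#' @export
split_windkessel <- function(r_hyp, c_out,
                             r_fractions = c(0.01, 0.84, 0.15),
                             c_fractions = c(0.025, 0.975)) {
  if (length(r_fractions) != 3 || abs(sum(r_fractions) - 1) > 1e-12)
    stop("r_fractions must be 3 fractions summing to 1")
  if (length(c_fractions) != 2 || abs(sum(c_fractions) - 1) > 1e-12)
    stop("c_fractions must be 2 fractions summing to 1")
  if (any(r_fractions <= 0) || any(c_fractions <= 0))
    stop("fractions must be positive")
  if (any(r_hyp <= 0) || any(c_out <= 0))
    stop("resistances and compliances must be positive")
  if (length(r_hyp) != length(c_out))
    stop("r_hyp and c_out must have one value per outlet")
  Ra <- r_fractions[1] * r_hyp
  Ra_micro <- r_fractions[2] * r_hyp
  Rd <- r_hyp - Ra - Ra_micro         # exact conservation
  Ca <- c_fractions[1] * c_out
  Cmyo <- c_out - Ca
  structure(data.frame(Ra = Ra, Ra_micro = Ra_micro, Rd = Rd,
                       Ca = Ca, Cmyo = Cmyo),
            class = c("windkessel_params", "data.frame"))
}

#' Distribute coronary compliance among outlets
#'
#' Total peripheral coronary compliance is taken as a portion of the
#' systemic arterial compliance (1.7 mL/mmHg) and split among outlets in
#' proportion to their Murray flow weights, mirroring the assumption that
#' peripheral compliance follows flow.
#'
#' @param weights per-outlet Murray weights (sum to 1).
#' @param arterial_compliance systemic arterial compliance, mL/mmHg.
#' @param coronary_fraction coronary portion of it (default 0.045; the
#'   flow-fraction analogy).
#' @return Per-outlet compliances, mL/mmHg.
#' @examples
#' distribute_compliance(c(0.5, 0.5))
#' @export
distribute_compliance <- function(weights, arterial_compliance = 1.7,
                                  coronary_fraction = 0.045) {
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be positive and sum to 1")
  coronary_fraction * arterial_compliance * (weights / sum(weights))
}

# ---- waveforms --------------------------------------------------------------

#' Characteristic pressure waveforms
#'
#' Normalized periodic waveforms on phase `[0, 1]` used to drive the
#' hyperemic transient: an aortic pressure shape (low-order harmonic
#' stand-in with a systolic peak and a dicrotic-notch-like secondary
#' deflection) and a left-ventricular pressure shape (smooth systolic
#' pulse rising from ~0, zero in diastole). Both are exactly periodic
#' (first and last samples equal) and are only templates: simulations use
#' them after affine scaling to the patient's mean pressure and pulse
#' pressure ([scale_waveform()]) or to the systolic peak
#' ([scale_lv_waveform()]). FFR depends on cycle-averaged pressures, so
#' the precise shapes are secondary.
#'
#' @param n number of samples on the closed phase grid (odd alignment with
#'   a 1 ms step over a 0.8 s cycle is convenient but not required).
#' @param systole fraction of the cycle occupied by ventricular systole.
#' @return An object of class `waveform`: data.frame with columns `phase`
#'   and `value`.
#' @examples
#' wf <- aortic_waveform()
#' range(wf$value)
#' @export
aortic_waveform <- function(n = 801) {
  phase <- seq(0, 1, length.out = n)
  value <- 1 +
    0.35 * sin(2 * pi * (phase - 0.02)) +
    0.12 * sin(4 * pi * (phase - 0.02) + 0.9) +
    0.04 * sin(6 * pi * (phase - 0.02) + 1.8)
  value[n] <- value[1]   # guard periodicity against rounding
  new_waveform(phase, value)
}

#' @rdname aortic_waveform
#' @export
lv_waveform <- function(n = 801, systole = 0.35) {
  phase <- seq(0, 1, length.out = n)
  value <- ifelse(phase < systole, sin(pi * phase / systole)^2, 0)
  value[n] <- value[1]
  new_waveform(phase, value)
}

new_waveform <- function(phase, value, period = NA_real_) {
  stopifnot(length(phase) == length(value), length(phase) >= 3)
  if (abs(value[1] - value[length(value)]) > 1e-9)
    stop("waveform must be periodic (equal first and last samples)")
  structure(data.frame(phase = phase, value = value),
            period = period, class = c("waveform", "data.frame"))
}

# Time-average over one period (trapezoid on the closed phase grid).
waveform_mean <- function(wf) trapz(wf$phase, wf$value)

#' Scale a normalized waveform to patient targets
#'
#' Affine transform `a * w + b` with `a`, `b` solved so that the cycle
#' (trapezoidal) mean equals `mean_target` and the peak-to-trough range
#' equals `pulse`. Scaling an already-scaled waveform to the same targets
#' is a no-op.
#'
#' @param wf a `waveform`.
#' @param mean_target target cycle-mean pressure, mmHg.
#' @param pulse target pulse amplitude (max - min), mmHg; must be > 0.
#' @param period cardiac cycle duration, s.
#' @return A `waveform` with attribute `period` set.
#' @examples
#' wf <- scale_waveform(aortic_waveform(), 93.33, 40, 0.8)
#' @export
scale_waveform <- function(wf, mean_target, pulse, period) {
  stopifnot(inherits(wf, "waveform"))
  rng <- max(wf$value) - min(wf$value)
  if (rng <= 0) stop("constant waveform: pulse amplitude unachievable")
  if (!is.numeric(pulse) || pulse <= 0) stop("pulse must be positive")
  if (!is.numeric(period) || period <= 0) stop("period must be positive")
  a <- pulse / rng
  b <- mean_target - a * waveform_mean(wf)
  new_waveform(wf$phase, a * wf$value + b, period = period)
}

#' @rdname scale_waveform
#' @param peak target peak pressure, mmHg (the waveform minimum maps to 0).
#' @export
scale_lv_waveform <- function(wf, peak, period) {
  stopifnot(inherits(wf, "waveform"))
  if (!is.numeric(peak) || peak <= 0) stop("peak must be positive")
  v <- wf$value - min(wf$value)
  if (max(v) <= 0) stop("constant waveform: peak unachievable")
  new_waveform(wf$phase, v / max(v) * peak, period = period)
}

# Linear interpolation of a waveform at arbitrary phases (periodic).
waveform_at <- function(wf, phase) {
  phase <- phase %% 1
  stats::approx(wf$phase, wf$value, xout = phase, rule = 2)$y
}

# ---- Windkessel time stepping (reference implementation) --------------------

#' Advance one coronary-bed Windkessel by one time step
#'
#' Reference (R-level) integrator for the two-state outlet model. States
#' are `p1`, the pressure on the arterial compliance `Ca`, and `p2`, the
#' pressure on the myocardial compliance `Cmyo`:
#' \deqn{Ca\,dp1/dt = (p_{out} - p1)/Ra - (p1 - p2)/R_{a,micro}}
#' \deqn{C_{myo}\,d(p2 - P_{LV})/dt = (p1 - p2)/R_{a,micro} - (p2 - p_v)/R_d}
#' The update is a trapezoidal (Crank-Nicolson) step on `(p1, p2)` -- the
#' fluxes are averaged between the step endpoints, with the feeding
#' pressure supplied at both (`p_out_prev` at the start, `p_out` at the
#' end) and the left-ventricular pressure increment applied exactly; the
#' linear 2x2 system is solved in closed form, so the scheme is A-stable
#' and second-order accurate. In the DC limit (constant `p_out`, constant
#' `P_LV`) the steady inflow is `(p_out - p_v) / (Ra + Ra_micro + Rd)`.
#'
#' @param state numeric `c(p1, p2)`, mmHg.
#' @param p_out pressure feeding the bed from the tree outlet at the end
#'   of the step, mmHg.
#' @param p_out_prev feeding pressure at the start of the step (defaults
#'   to `p_out`).
#' @param params one row of [split_windkessel()] output (or any list with
#'   `Ra`, `Ra_micro`, `Rd`, `Ca`, `Cmyo`).
#' @param fluid a [fluid_params()] object (venous pressure).
#' @param dt time step, s (> 0).
#' @param p_lv,p_lv_next left-ventricular pressure at the start and end of
#'   the step, mmHg.
#' @return list with the new `state` and the end-of-step inflow `q_in`
#'   (mL/s).
#' @examples
#' wk <- split_windkessel(30, 0.02)
#' step_windkessel(c(90, 20), p_out = 90, params = wk[1, ], dt = 0.001)
#' @export
step_windkessel <- function(state, p_out, params, fluid = fluid_params(),
                            dt, p_lv = 0, p_lv_next = p_lv,
                            p_out_prev = p_out) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  p1 <- state[1]; p2 <- state[2]
  Ra <- params$Ra; Ram <- params$Ra_micro; Rd <- params$Rd
  Ca <- params$Ca; Cmyo <- params$Cmyo
  p_v <- fluid$venous_pressure
  flux1_old <- (p_out_prev - p1) / Ra - (p1 - p2) / Ram
  flux2_old <- (p1 - p2) / Ram - (p2 - p_v) / Rd
  a11 <- Ca / dt + 0.5 / Ra + 0.5 / Ram
  a12 <- -0.5 / Ram
  a21 <- -0.5 / Ram
  a22 <- Cmyo / dt + 0.5 / Ram + 0.5 / Rd
  b1 <- Ca / dt * p1 + 0.5 * p_out / Ra + 0.5 * flux1_old
  b2 <- Cmyo / dt * p2 + 0.5 * p_v / Rd + 0.5 * flux2_old +
    Cmyo * (p_lv_next - p_lv) / dt
  det <- a11 * a22 - a12 * a21
  p1n <- (b1 * a22 - a12 * b2) / det
  p2n <- (a11 * b2 - a21 * b1) / det
  list(state = c(p1n, p2n), q_in = (p_out - p1n) / Ra)
}
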