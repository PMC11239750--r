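test_that("Windkessel splits follow the bed fractions and conserve totals exactly", {
  wk <- split_windkessel(100, 0.04)
  expect_equal(wk$Ra, 1)
  expect_equal(wk$Ra_micro, 84)
  expect_equal(wk$Rd, 15)
  expect_equal(wk$Ca, 0.001)
  expect_equal(wk$Cmyo, 0.039)
  r <- c(13.7, 91.2, 40.01)
  co <- c(0.011, 0.002, 0.0407)
  wk2 <- split_windkessel(r, co)
  expect_identical(wk2$Ra + wk2$Ra_micro + wk2$Rd, r)   # exact by construction
  expect_identical(wk2$Ca + wk2$Cmyo, co)
  expect_error(split_windkessel(100, 0.04, r_fractions = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(split_windkessel(100, 0.04, c_fractions = c(0.6, 0.3)),
               "summing to 1")
})

test_that("coronary compliance distributes by weight and conserves the total", {
  expect_equal(distribute_compliance(1), 0.045 * 1.7)
  expect_equal(distribute_compliance(c(0.5, 0.5)), rep(0.045 * 1.7 / 2, 2))
  w <- c(0.4, 0.35, 0.15, 0.1)
  expect_lt(abs(sum(distribute_compliance(w)) - 0.045 * 1.7), 1e-12)
})

test_that("waveform scaling hits the mean and pulse targets and is idempotent", {
  wf <- scale_waveform(aortic_waveform(), 93.33, 40, 0.8)
  expect_lt(abs(ffrwire:::waveform_mean(wf) - 93.33), 1e-6)
  expect_lt(abs(diff(range(wf$value)) - 40), 1e-6)
  wf2 <- scale_waveform(wf, 93.33, 40, 0.8)
  expect_equal(wf2$value, wf$value, tolerance = 1e-12)
  expect_error(scale_waveform(aortic_waveform(), 93.33, 0, 0.8), "positive")
  flat <- aortic_waveform(); flat$value[] <- 1
  expect_error(scale_waveform(flat, 90, 40, 0.8), "constant")
})

test_that("LV waveform scales to the systolic peak with a zero floor", {
  lv <- scale_lv_waveform(lv_waveform(), peak = 113.33, period = 0.8)
  expect_equal(max(lv$value), 113.33)
  expect_equal(min(lv$value), 0)
  expect_equal(lv$value[1], lv$value[nrow(lv)])
})

test_that("the bed stepper reaches the series-resistance DC limit", {
  wk <- split_windkessel(30, 0.02)
  fl <- fluid_params()
  st <- c(80, 30)
  for (i in 1:40000) {
    r <- step_windkessel(st, p_out = 90, params = wk[1, ], fluid = fl, dt = 0.001)
    st <- r$state
  }
  expect_equal(r$q_in, (90 - 5) / 30, tolerance = 1e-6)
})

test_that("an LV pressure rise transiently impedes bed inflow", {
  wk <- split_windkessel(30, 0.02)
  fl <- fluid_params()
  st <- c(80, 30)
  for (i in 1:40000) st <- step_windkessel(st, 90, wk[1, ], fl, 0.001)$state
  q0 <- step_windkessel(st, 90, wk[1, ], fl, 0.001)$q_in
  # ramp P_LV up at fixed p_out: systolic impediment lowers q_in
  plv <- 0
  for (i in 1:50) {
    r <- step_windkessel(st, 90, wk[1, ], fl, 0.001,
                         p_lv = plv, p_lv_next = plv + 2)
    st <- r$state; plv <- plv + 2
  }
  expect_lt(r$q_in, q0)
})

test_that("the resistive-divider equilibrium is an exact fixed point", {
  pars <- list(Ra = 0.3, Ra_micro = 25, Rd = 4.5, Ca = 5e-4, Cmyo = 0.019)
  qstar <- (88 - 5) / (0.3 + 25 + 4.5)
  st <- c(88 - 0.3 * qstar, 88 - 0.3 * qstar - 25 * qstar)
  r <- step_windkessel(st, p_out = 88, params = pars, dt = 0.001)
  expect_equal(r$state, st, tolerance = 1e-12)
  expect_equal(r$q_in, qstar, tolerance = 1e-12)
  expect_error(step_windkessel(st, 88, pars, dt = 0), "positive")
})

test_that("the compiled transient kernel matches the R reference stepper", {
  # near-lossless tube: the outlet sees the aortic waveform directly, so an
  # R-level loop over step_windkessel must reproduce the kernel's inflow
  tr <- tube_tree(radius = 5, length = 0.5)
  m <- ffr_model(tr, demo_patient())
  # tol = 0 forces the full 3 cycles; the non-periodicity warning is expected
  sim <- suppressWarnings(simulate(m, max_cycles = 3, tol = 0))
  spc <- attr(sim, "steps_per_cycle")
  wk <- m$windkessel[1, ]
  ph <- (seq_len(spc) %% spc) / spc
  pa <- ffrwire:::waveform_at(m$aortic, ph)
  plv <- ffrwire:::waveform_at(m$lv, ph)
  st <- ffrwire:::steady_core(m)
  state <- c(st$p_out - wk$Ra * st$q_out, st$p_out - wk$Ra * st$q_out -
               wk$Ra_micro * st$q_out)
  q_ref <- numeric(3 * spc)
  p_prev <- st$p_out
  for (k in seq_len(3 * spc)) {
    i <- (k - 1) %% spc + 1
    ip <- (k - 2) %% spc + 1
    r <- step_windkessel(state, p_out = pa[i], params = wk, fluid = m$fluid,
                         dt = attr(sim, "dt"),
                         p_lv = plv[ip], p_lv_next = plv[i],
                         p_out_prev = p_prev)
    state <- r$state
    q_ref[k] <- r$q_in
    p_prev <- pa[i]
  }
  expect_equal(sim$q_in_ml_s, q_ref, tolerance = 1e-5)
})
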