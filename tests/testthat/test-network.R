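test_that("single healthy tube: outlet pressure is MAP minus the Poiseuille drop", {
  tr <- tube_tree(0.15, 2)
  al <- allocate_flow(4.5, 1)
  st <- solve_baseline(tr, 93.33, al)
  expect_equal(st$outlet_pressure, 93.33 - poiseuille_resistance(0.15, 2) * 4.5,
               tolerance = 1e-12)
  expect_equal(st$p_d, st$outlet_pressure)  # measurement at the distal end
})

test_that("symmetric bifurcation with equal flows gives equal outlet pressures", {
  tr <- bif_tree(r1 = 0.119, r2 = 0.119, L1 = 1.2, L2 = 1.2)
  st <- solve_baseline(tr, 90, allocate_flow(4, c(0.5, 0.5)))
  expect_equal(st$outlet_pressure[1], st$outlet_pressure[2], tolerance = 1e-12)
})

test_that("a stenosed solve composes segment-by-segment hand computation", {
  tr <- add_stenosis(bif_tree(L0 = 2), 2, degree = 0.7, stenosis_length = 0.3)
  al <- allocate_flow(4, c(0.6, 0.4))
  st <- solve_baseline(tr, 95, al)
  # independent marching: root, then each daughter
  q_root <- 4; q1 <- 2.4; q2 <- 1.6
  p_mid <- 95 - poiseuille_resistance(0.15, 2) * q_root
  p1 <- p_mid - poiseuille_resistance(0.12, 1 - 0.3) * q1 -
    stenosis_pressure_drop(q1, 0.7, 0.3, 0.12)
  p2 <- p_mid - poiseuille_resistance(0.10, 1) * q2
  expect_equal(st$outlet_pressure, c(p1, p2), tolerance = 1e-12)
  expect_equal(st$p_lesion_prox, p_mid, tolerance = 1e-12)
})

test_that("segment flows conserve mass at every junction", {
  for (s in 1:8) {
    tr <- generate_tree(3, seed = s)
    outs <- tree_outlets(tr)
    d <- 2 * tr$segments$radius_cm[match(outs, tr$segments$id)]
    st <- solve_baseline(tr, 93, allocate_flow(4.5, murray_fractions(d)))
    for (p in setdiff(tr$segments$id, outs)) {
      ch <- tr$segments$id[!is.na(tr$segments$parent) & tr$segments$parent == p]
      qp <- st$segment_flow[match(p, st$segment_id)]
      qc <- sum(st$segment_flow[match(ch, st$segment_id)])
      expect_lt(abs(qp - qc), 1e-9 * qp)
    }
  }
})

test_that("trans-tree pressure drop is positive and vanishes with viscosity", {
  tr <- generate_tree(3, seed = 3)
  outs <- tree_outlets(tr)
  d <- 2 * tr$segments$radius_cm[match(outs, tr$segments$id)]
  al <- allocate_flow(4.5, murray_fractions(d))
  drop_at <- function(mu) {
    st <- solve_baseline(tr, 93, al, fluid_params(viscosity = mu))
    93 - min(st$outlet_pressure)
  }
  expect_gt(drop_at(0.035), 0)
  expect_lt(drop_at(3.5e-6), 1e-3 * drop_at(0.035))
})

test_that("baseline resistance calibration follows the defining ratio", {
  st <- structure(list(outlet_pressure = 85, outlet_flow = 2,
                       fluid = fluid_params()), class = "network_state")
  expect_equal(baseline_outlet_resistances(st), 40)
  st$outlet_flow <- 4
  expect_equal(baseline_outlet_resistances(st), 20)   # doubling q halves R
  st$outlet_pressure <- 5 + 1e-9
  expect_lt(baseline_outlet_resistances(structure(
    list(outlet_pressure = 5 + 1e-6, outlet_flow = 2, fluid = fluid_params()),
    class = "network_state")), 1e-6)
  st$outlet_pressure <- 4
  expect_error(baseline_outlet_resistances(st), "unphysiological")
})

test_that("hyperemic resistances divide by TCRI exactly, once", {
  r <- hyperemic_resistances(c(40, 61.5), tcri = 3)
  expect_identical(r$r_hyp, c(40, 61.5) / 3)
  expect_identical(hyperemic_resistances(40, 1)$r_hyp, 40)
  expect_error(hyperemic_resistances(r), "exactly once")
  expect_error(hyperemic_resistances(40, 0), "positive")
})

test_that("steady loaded solve matches an independent nonlinear root-find", {
  tr <- add_stenosis(bif_tree(L0 = 1.5), 2, 0.6, 0.3)
  cfg <- ffr_config()
  net <- ffrwire:::build_network(tr, fluid_params(), cfg$kt)
  R_load <- c(25, 40); p_in <- 95; p_v <- 5
  ours <- ffrwire:::solve_tree_steady(net, p_in, R_load, p_v)
  # independent formulation: residuals written from scratch, solved by pracma
  resid <- function(q) {
    p_mid <- p_in - poiseuille_resistance(0.15, 1.5) * (q[1] + q[2])
    p1 <- p_mid - poiseuille_resistance(0.12, 0.7) * q[1] -
      stenosis_pressure_drop(q[1], 0.6, 0.3, 0.12)
    p2 <- p_mid - poiseuille_resistance(0.10, 1) * q[2]
    c(p1 - p_v - R_load[1] * q[1], p2 - p_v - R_load[2] * q[2])
  }
  ref <- pracma::fsolve(resid, c(1, 1), tol = 1e-12)$x
  expect_equal(ours$q_out, ref, tolerance = 1e-8)
})
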