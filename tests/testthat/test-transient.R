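test_that("near-lossless tube recovers the DC inflow and the TCRI flow gain", {
  tr <- tube_tree(radius = 5, length = 0.5)   # negligible epicardial resistance
  m <- ffr_model(tr, demo_patient())
  sim <- simulate(m)
  q_mean <- ffrwire:::final_cycle_means(sim)["q_in"]
  R_tot <- sum(with(m$windkessel, Ra + Ra_micro + Rd))
  expect_equal(unname(q_mean), (93.33 - 5) / R_tot, tolerance = 1e-3)
  # hyperemic mean flow over baseline flow recovers TCRI = 3
  expect_equal(unname(q_mean) / m$allocation$q_cor, 3, tolerance = 0.05)
})

test_that("repeated simulations are bit-identical", {
  tr <- add_stenosis(generate_tree(3, seed = 4), 2, 0.6)
  m <- ffr_model(tr, demo_patient())
  s1 <- simulate(m); s2 <- simulate(m)
  expect_identical(s1$p_d_mmHg, s2$p_d_mmHg)
  expect_identical(s1$q_in_ml_s, s2$q_in_ml_s)
  expect_identical(compute_ffr(s1), compute_ffr(s2))
})

test_that("FFR extraction is the ratio of final-cycle pressure means", {
  mk_sim <- function(p_a, p_d) {
    n <- length(p_a)
    structure(data.frame(time_s = seq_len(n) * 1e-3, p_a_mmHg = p_a,
                         p_d_mmHg = p_d, p_lesion_prox_mmHg = p_a,
                         q_in_ml_s = 1),
              steps_per_cycle = n, n_cycles = 1L, converged = TRUE,
              dt = 1e-3, period = n * 1e-3,
              class = c("ffr_sim", "data.frame"))
  }
  expect_equal(compute_ffr(mk_sim(rep(100, 8), rep(100, 8))), 1)
  expect_equal(compute_ffr(mk_sim(rep(100, 8), rep(80, 8))), 0.8)
  pa <- 90 + 10 * sin(seq(0, 2 * pi, length.out = 16))
  pd <- 70 + 5 * cos(seq(0, 2 * pi, length.out = 16))
  expect_equal(compute_ffr(mk_sim(pa, pd)), mean(pd) / mean(pa))
  expect_error(compute_ffr(mk_sim(rep(0, 8), rep(0, 8))), "zero mean")
})

test_that("a lossless tree yields FFR of one; stenoses keep it in (0, 1]", {
  tr <- tube_tree(radius = 5, length = 0.5)
  m <- ffr_model(tr, demo_patient())
  expect_equal(predict(m, "transient"), 1, tolerance = 1e-4)
  base <- generate_tree(3, seed = 4)
  for (d in c(0.3, 0.6, 0.85)) {
    f <- predict(ffr_model(add_stenosis(base, 2, d), demo_patient()))
    expect_gt(f, 0)
    expect_lte(f, 1)
  }
})

test_that("steady and transient FFR agree closely on sample lesions", {
  base <- generate_tree(3, seed = 9)
  for (d in c(0.2, 0.55, 0.8)) {
    m <- ffr_model(add_stenosis(base, 2, d), demo_patient())
    expect_lt(abs(predict(m, "steady") - predict(m, "transient")), 0.02)
  }
})

test_that("including the guidewire always lowers the predicted FFR", {
  base <- generate_tree(3, seed = 10)
  for (d in c(0.1, 0.5, 0.75)) {
    trs <- add_stenosis(base, 2, d)
    f_abs <- predict(ffr_model(trs, demo_patient()))
    f_wire <- predict(ffr_model(insert_guidewire(trs), demo_patient()))
    expect_lt(f_wire, f_abs)
  }
})

test_that("halving the time step leaves FFR essentially unchanged", {
  m <- ffr_model(add_stenosis(generate_tree(3, seed = 12), 2, 0.7),
                 demo_patient())
  f1 <- compute_ffr(simulate(m, dt = 0.001))
  f2 <- compute_ffr(simulate(m, dt = 0.0005))
  expect_lt(abs(f2 - f1), 1e-3)
})

test_that("non-convergence is flagged and warned about, not hidden", {
  m <- ffr_model(add_stenosis(generate_tree(3, seed = 4), 2, 0.6),
                 demo_patient())
  expect_warning(sim <- simulate(m, max_cycles = 1, tol = 1e-12),
                 "periodicity")
  expect_false(attr(sim, "converged"))
  expect_warning(compute_ffr(sim), "converge")
})

test_that("simulations export as tidy CSV", {
  m <- ffr_model(tube_tree(), demo_patient())
  sim <- simulate(m)
  f <- tempfile(fileext = ".csv")
  write_sim(sim, f)
  back <- read.csv(f)
  expect_identical(names(back), names(as.data.frame(sim)))
  expect_equal(nrow(back), nrow(sim))
})
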