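test_that("severity classification uses the six-per-class boundary convention", {
  expect_identical(classify_ffr(0.74), 3L)
  expect_identical(classify_ffr(0.52), 1L)
  expect_identical(classify_ffr(0.72), 3L)
  expect_identical(classify_ffr(1.0), 4L)
  expect_identical(classify_ffr(c(0.38, 0.53, 0.839, 0.84)), c(1L, 2L, 3L, 4L))
  expect_error(classify_ffr(0), "\\(0, 1\\]")
  expect_error(classify_ffr(1.2), "\\(0, 1\\]")
})

test_that("Bland-Altman bias and SD follow the textbook formulas", {
  expect_equal(bland_altman(c(0.8, 0.9), c(0.8, 0.9)),
               list(bias = 0, sd = 0, direction = "invasive_minus_pred"))
  ba <- bland_altman(c(0.7, 0.9), c(0.8, 1.0))
  expect_equal(ba$bias, 0.1)
  expect_equal(ba$sd, 0)
  ba2 <- bland_altman(c(0.7, 0.9), c(0.8, 1.0), direction = "pred_minus_invasive")
  expect_equal(ba2$bias, -0.1)
  for (s in 1:5) {
    v <- with_seed_local(s, list(p = runif(20, 0.4, 1), i = runif(20, 0.4, 1)))
    d <- v$i - v$p
    ba3 <- bland_altman(v$p, v$i)
    expect_equal(ba3$bias, sum(d) / 20)
    expect_equal(ba3$sd, sqrt(sum((d - mean(d))^2) / 19))
  }
  expect_error(bland_altman(1:3 / 4, 1:2 / 4), "equal length")
  expect_error(bland_altman(0.5, 0.5), "two pairs")
})

test_that("diagnostic indices match brute-force 2x2 counting", {
  perfect <- diagnostic_indices(c(0.5, 0.9), c(0.5, 0.9))
  expect_equal(perfect[c("sensitivity", "specificity", "accuracy")],
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  di <- diagnostic_indices(c(0.7, 0.85, 0.6, 0.9), c(0.75, 0.7, 0.6, 0.9))
  expect_equal(di$tp, 2); expect_equal(di$fn, 1)
  expect_equal(di$tn, 1); expect_equal(di$fp, 0)
  expect_equal(di$sensitivity, 2 / 3)
  expect_equal(di$specificity, 1)
  expect_equal(di$accuracy, 3 / 4)
  inverted <- diagnostic_indices(c(0.9, 0.7), c(0.7, 0.9))
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)
  expect_equal(inverted$accuracy, 0)
  # zero-denominator indices are reported missing, not coerced
  allpos <- diagnostic_indices(c(0.5, 0.9), c(0.5, 0.6))
  expect_true(is.na(allpos$specificity))
  # randomized equivalence with explicit counting
  for (s in 1:10) {
    v <- with_seed_local(s, list(p = runif(30, 0.3, 1), i = runif(30, 0.3, 1)))
    di2 <- diagnostic_indices(v$p, v$i)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (k in 1:30) {
      if (v$p[k] <= 0.8 && v$i[k] <= 0.8) tp <- tp + 1
      if (v$p[k] > 0.8 && v$i[k] > 0.8) tn <- tn + 1
      if (v$p[k] <= 0.8 && v$i[k] > 0.8) fp <- fp + 1
      if (v$p[k] > 0.8 && v$i[k] <= 0.8) fn <- fn + 1
    }
    expect_equal(di2$sensitivity, tp / (tp + fn))
    expect_equal(di2$specificity, tn / (tn + fp))
    expect_equal(di2$accuracy, (tp + tn) / 30)
  }
})

test_that("diagnostic indices are invariant to input order", {
  v <- with_seed_local(2, list(p = runif(25, 0.3, 1), i = runif(25, 0.3, 1)))
  perm <- with_seed_local(3, sample(25))
  expect_equal(diagnostic_indices(v$p, v$i),
               diagnostic_indices(v$p[perm], v$i[perm]))
  expect_equal(roc_auc(v$p, v$i), roc_auc(v$p[perm], v$i[perm]))
})

test_that("trapezoidal AUC equals exhaustive pairwise concordance", {
  expect_equal(roc_auc(c(0.5, 0.6, 0.85, 0.9), c(0.7, 0.75, 0.85, 0.95)), 1)
  expect_equal(roc_auc(rep(0.7, 6), c(0.5, 0.6, 0.7, 0.85, 0.9, 0.95)), 0.5)
  toy <- list(p = c(0.55, 0.7, 0.7, 0.82, 0.85, 0.9),
              i = c(0.6, 0.85, 0.7, 0.75, 0.9, 0.95))
  expect_equal(roc_auc(toy$p, toy$i), concordance_auc(toy$p, toy$i))
  for (s in 1:15) {
    n <- with_seed_local(s, sample(4:50, 1))
    v <- with_seed_local(s + 100, list(
      p = round(runif(n, 0.3, 1), 2),   # rounding forces ties
      i = runif(n, 0.3, 1)))
    ok <- any(v$i <= 0.8) && any(v$i > 0.8)
    if (!ok) next
    expect_equal(roc_auc(v$p, v$i), concordance_auc(v$p, v$i))
  }
  expect_error(roc_auc(c(0.5, 0.6), c(0.5, 0.6)), "positive and one negative")
})

test_that("trapezoidal AUC agrees with an established ROC implementation", {
  v <- with_seed_local(8, list(p = round(runif(40, 0.3, 1), 2),
                               i = runif(40, 0.3, 1)))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = v$i <= 0.8, predictor = v$p,
    levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)))
  expect_equal(roc_auc(v$p, v$i), ref)
})

test_that("class aggregates apply the percent-change definitions", {
  row <- data.frame(ffr_id = 1, patient_id = 1, location = "x",
                    flow_method = "murray", ffr_class = 3,
                    ffr_invasive = 0.75, ffr_pred = 0.8, gffr_pred = 0.72,
                    delta_p_abs = 10, delta_p_wire = 14,
                    inflow_abs = 5, inflow_wire = 4.5,
                    error = NA_character_)
  agg <- class_aggregates(row)
  r3 <- agg[agg$ffr_class == 3 & agg$flow_method == "murray", ]
  expect_equal(r3$drop_ffr_pct, 10)
  expect_equal(r3$rise_dp_pct, 40)
  expect_equal(r3$drop_inflow_pct, 10)
  # identical wire and wire-free results aggregate to zero effect
  same <- row
  same$gffr_pred <- same$ffr_pred
  same$delta_p_wire <- same$delta_p_abs
  same$inflow_wire <- same$inflow_abs
  agg0 <- class_aggregates(same)
  expect_equal(agg0$drop_ffr_pct[agg0$ffr_class == 3], 0)
  # duplicating the result set leaves the means unchanged (n doubles)
  cols <- c("drop_ffr_pct", "rise_dp_pct", "drop_inflow_pct")
  expect_equal(class_aggregates(rbind(row, row))[, cols], agg[, cols])
  # empty classes are flagged missing, never zero
  empty <- agg[agg$ffr_class == 1, ]
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$drop_ffr_pct))
})

test_that("study outputs land in tidy CSV files", {
  rows <- data.frame(ffr_id = 1:2, patient_id = 1:2, location = "x",
                     flow_method = "murray", ffr_class = c(2, 4),
                     ffr_invasive = c(0.6, 0.9), ffr_pred = c(0.62, 0.88),
                     gffr_pred = c(0.55, 0.86),
                     delta_p_abs = c(30, 4), delta_p_wire = c(36, 5),
                     inflow_abs = c(10, 12), inflow_wire = c(9.5, 11.8),
                     error = NA_character_)
  d <- file.path(tempdir(), "study_out")
  write_study_outputs(rows, d)
  expect_true(all(file.exists(file.path(
    d, c("lesion_results.csv", "class_aggregates.csv", "diagnostics.csv")))))
  diag <- read.csv(file.path(d, "diagnostics.csv"))
  expect_identical(nrow(diag), 2L)  # wire absent / wire included
})
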