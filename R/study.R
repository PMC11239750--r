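#' Severity class of an FFR value
#'
#' Bins an FFR into the four study severity classes: class 1 (most severe)
#' for values up to 0.52, class 2 for (0.52, 0.72), class 3 for
#' [0.72, 0.84) and class 4 (least severe) for values of 0.84 and above.
#' The boundary convention (lower boundaries closed on classes 1, 3 and 4)
#' is the unique assignment putting exactly six of the 24 packaged
#' invasive measurements in each class.
#'
#' @param value FFR value(s) in (0, 1].
#' @return Integer class(es) 1-4.
#' @examples
#' classify_ffr(c(0.52, 0.72, 0.74, 1.0))
#' @export
classify_ffr <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0) || any(value > 1))
    stop("FFR values must lie in (0, 1]")
  ifelse(value <= 0.52, 1L,
         ifelse(value < 0.72, 2L,
                ifelse(value < 0.84, 3L, 4L)))
}

#' Paired wire-absent / wire-included study
#'
#' Runs the full prediction pipeline for every cohort lesion under each
#' requested flow distribution setup, twice per lesion: once on the bare
#' tree (wire absent) and once with the pressure guidewire inserted along
#' the stenotic branch on the identical tree. Records the predicted FFR,
#' the trans-stenotic cycle-mean pressure drop and the cycle-mean inlet
#' flow for both states. A lesion whose simulation fails is recorded with
#' the failure reason and the study continues.
#'
#' @param cohort an [generate_cohort()] result.
#' @param flow_methods character subset of `c("murray", "length_based")`.
#' @param config an [ffr_config()]; defaults to the cohort's.
#' @return A data.frame of class `wire_study`, one row per lesion and flow
#'   setup, with columns `ffr_id`, `patient_id`, `location`, `flow_method`,
#'   `ffr_class`, `ffr_invasive`, `ffr_pred`, `gffr_pred`, `delta_p_abs`,
#'   `delta_p_wire` (mmHg), `inflow_abs`, `inflow_wire` (mL/s), `error`.
#' @export
paired_wire_study <- function(cohort,
                              flow_methods = c("murray", "length_based"),
                              config = attr(cohort, "config") %||% ffr_config()) {
  stopifnot(inherits(cohort, "ffr_cohort"))
  flow_methods <- match.arg(flow_methods, c("murray", "length_based"),
                            several.ok = TRUE)
  rows <- list()
  for (lesion in cohort) {
    tree_abs <- lesion$tree
    for (fm in flow_methods) {
      row <- data.frame(
        ffr_id = lesion$ffr_id, patient_id = lesion$patient$patient_id,
        location = lesion$location, flow_method = fm,
        ffr_class = lesion$target_class, ffr_invasive = lesion$ffr_invasive,
        ffr_pred = NA_real_, gffr_pred = NA_real_,
        delta_p_abs = NA_real_, delta_p_wire = NA_real_,
        inflow_abs = NA_real_, inflow_wire = NA_real_,
        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        tree_wire <- insert_guidewire(tree_abs, config$wire_diameter_cm,
                                      config$wire_path)
        m_abs <- sim_metrics(simulate(ffr_model(tree_abs, lesion$patient,
                                                fm, config)))
        m_wire <- sim_metrics(simulate(ffr_model(tree_wire, lesion$patient,
                                                 fm, config)))
        list(abs = m_abs, wire = m_wire)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        row$error <- res
      } else {
        row$ffr_pred <- res$abs$ffr
        row$gffr_pred <- res$wire$ffr
        row$delta_p_abs <- res$abs$delta_p
        row$delta_p_wire <- res$wire$delta_p
        row$inflow_abs <- res$abs$inflow
        row$inflow_wire <- res$wire$inflow
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("wire_study", "data.frame"),
            config = config, flow_methods = flow_methods)
}

#' Per-class aggregates of the guidewire effect
#'
#' For each flow setup and severity class: the mean percentage drop in
#' predicted FFR, `100 (FFR_pred - gFFR_pred) / FFR_pred`; the mean
#' percentage rise in trans-stenotic pressure drop,
#' `100 (dP_wire - dP_abs) / dP_abs`; and the mean percentage drop in
#' hyperemic inflow, `100 (q_abs - q_wire) / q_abs`. Lesions are weighted
#' equally; class membership uses the invasive FFR when available and the
#' wire-absent prediction otherwise. Classes with no lesions appear with
#' `n = 0` and missing means (never zero).
#'
#' @param results a `wire_study` data.frame.
#' @return A data.frame with one row per flow setup and class.
#' @export
class_aggregates <- function(results) {
  ok <- !is.na(results$ffr_pred) & !is.na(results$gffr_pred)
  res <- results[ok, , drop = FALSE]
  cls <- ifelse(!is.na(res$ffr_invasive), classify_ffr(res$ffr_invasive),
                classify_ffr(res$ffr_pred))
  out <- list()
  for (fm in unique(results$flow_method)) {
    for (cl in 1:4) {
      sel <- res$flow_method == fm & cls == cl
      n <- sum(sel)
      out[[length(out) + 1L]] <- data.frame(
        flow_method = fm, ffr_class = cl, n = n,
        drop_ffr_pct = if (n) mean(100 * (res$ffr_pred[sel] - res$gffr_pred[sel]) /
                                     res$ffr_pred[sel]) else NA_real_,
        rise_dp_pct = if (n) mean(100 * (res$delta_p_wire[sel] - res$delta_p_abs[sel]) /
                                    res$delta_p_abs[sel]) else NA_real_,
        drop_inflow_pct = if (n) mean(100 * (res$inflow_abs[sel] - res$inflow_wire[sel]) /
                                        res$inflow_abs[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Bland-Altman agreement between predicted and invasive FFR
#'
#' Bias is the mean paired difference and SD its sample standard deviation
#' (n - 1 denominator). The default direction is `invasive - predicted`,
#' so a positive bias means predictions run below the invasive
#' measurements; the direction is configurable and always labelled in the
#' output.
#'
#' @param pred predicted FFR values.
#' @param invasive paired invasive FFR values (same length, n >= 2).
#' @param direction `"invasive_minus_pred"` or `"pred_minus_invasive"`.
#' @return A list with `bias`, `sd` and `direction`.
#' @examples
#' bland_altman(c(0.7, 0.9), c(0.8, 1.0))
#' @export
bland_altman <- function(pred, invasive,
                         direction = c("invasive_minus_pred",
                                       "pred_minus_invasive")) {
  direction <- match.arg(direction)
  if (length(pred) != length(invasive))
    stop("pred and invasive must have equal length")
  if (length(pred) < 2) stop("at least two pairs are required")
  d <- if (direction == "invasive_minus_pred") invasive - pred else pred - invasive
  list(bias = mean(d), sd = stats::sd(d), direction = direction)
}

#' Diagnostic indices of the prediction against invasive FFR
#'
#' A lesion is positive (hemodynamically significant) when its FFR is at
#' or below the cutoff (0.8), for both the prediction and the invasive
#' reference. Sensitivity is TP/(TP+FN), specificity TN/(TN+FP) and
#' accuracy (TP+TN)/n; an index whose denominator is zero is reported as
#' missing, never coerced to 0 or 1.
#'
#' @param pred,invasive paired FFR vectors.
#' @param cutoff positivity cutoff in (0, 1).
#' @return A list with `sensitivity`, `specificity`, `accuracy` and the
#'   2x2 counts `tp`, `tn`, `fp`, `fn`.
#' @examples
#' diagnostic_indices(c(0.7, 0.85, 0.6, 0.9), c(0.75, 0.7, 0.6, 0.9))
#' @export
diagnostic_indices <- function(pred, invasive, cutoff = 0.8) {
  if (length(pred) != length(invasive))
    stop("pred and invasive must have equal length")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  pp <- pred <= cutoff
  ip <- invasive <= cutoff
  tp <- sum(pp & ip); fn <- sum(!pp & ip)
  fp <- sum(pp & !ip); tn <- sum(!pp & !ip)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = if (length(pred) > 0) (tp + tn) / length(pred) else NA_real_,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Area under the ROC curve
#'
#' Ground truth is positivity by invasive FFR at the cutoff; the
#' prediction is used as a continuous score (lower predicted FFR = more
#' diseased). The ROC curve is swept over all distinct predicted values
#' and integrated by the trapezoidal rule, which equals the pairwise
#' concordance probability with ties counted 1/2.
#'
#' @param pred predicted FFR values (continuous score).
#' @param invasive paired invasive FFR values.
#' @param cutoff invasive positivity cutoff.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.5, 0.6, 0.85, 0.9), c(0.7, 0.75, 0.85, 0.95))
#' @export
roc_auc <- function(pred, invasive, cutoff = 0.8) {
  if (length(pred) != length(invasive))
    stop("pred and invasive must have equal length")
  truth <- invasive <= cutoff
  if (!any(truth) || all(truth))
    stop("ROC requires at least one positive and one negative lesion")
  score <- -pred                      # low FFR = high disease score
  th <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(score[truth] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(score[!truth] >= t), numeric(1))
  trapz(fpr, tpr)
}

#' Diagnostic summary of a paired wire study
#'
#' Computes, per flow setup and wire state, the diagnostic indices,
#' Bland-Altman bias and SD, and ROC AUC of the predictions against the
#' invasive measurements.
#'
#' @param results a `wire_study` data.frame with `ffr_invasive` present.
#' @param cutoff FFR positivity cutoff.
#' @return A data.frame, one row per flow setup and wire state.
#' @export
study_diagnostics <- function(results, cutoff = 0.8) {
  ok <- !is.na(results$ffr_pred) & !is.na(results$ffr_invasive)
  res <- results[ok, , drop = FALSE]
  out <- list()
  for (fm in unique(res$flow_method)) {
    sub <- res[res$flow_method == fm, ]
    for (state in c("wire_absent", "wire_included")) {
      pred <- if (state == "wire_absent") sub$ffr_pred else sub$gffr_pred
      di <- diagnostic_indices(pred, sub$ffr_invasive, cutoff)
      ba <- bland_altman(pred, sub$ffr_invasive)
      auc <- tryCatch(roc_auc(pred, sub$ffr_invasive, cutoff),
                      error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        flow_method = fm, model = state, n = nrow(sub),
        sensitivity = di$sensitivity, specificity = di$specificity,
        accuracy = di$accuracy, bias = ba$bias, sd = ba$sd, auc = auc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.wire_study <- function(x, ...) {
  cat(sprintf("Paired guidewire study: %d lesions x %d flow setup(s)\n",
              length(unique(x$ffr_id)), length(unique(x$flow_method))))
  failed <- sum(!is.na(x$error))
  if (failed) cat(sprintf("  %d failed runs\n", failed))
  agg <- class_aggregates(x)
  cat("\nMean guidewire effect by class:\n")
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write tidy study outputs
#'
#' Writes `lesion_results.csv`, `class_aggregates.csv` and
#' `diagnostics.csv` into a directory.
#'
#' @param results a `wire_study`.
#' @param dir output directory.
#' @param cutoff FFR positivity cutoff for the diagnostics table.
#' @return The directory, invisibly.
#' @export
write_study_outputs <- function(results, dir, cutoff = 0.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(results),
                   file.path(dir, "lesion_results.csv"), row.names = FALSE)
  utils::write.csv(class_aggregates(results),
                   file.path(dir, "class_aggregates.csv"), row.names = FALSE)
  utils::write.csv(study_diagnostics(results, cutoff),
                   file.path(dir, "diagnostics.csv"), row.names = FALSE)
  invisible(dir)
}

#' Study plots
#'
#' `plot_ffr_scatter` draws predicted (wire-absent and wire-included)
#' against invasive FFR with the identity line and the 0.8 cutoff;
#' `plot_bland_altman` the paired-difference plot with bias and 1.96 SD
#' limits.
#'
#' @param results a `wire_study`.
#' @param flow_method which flow setup to plot.
#' @param pred,invasive paired FFR vectors.
#' @param cutoff FFR cutoff drawn as dashed lines.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the input.
#' @export
plot_ffr_scatter <- function(results, flow_method = "murray", cutoff = 0.8, ...) {
  sub <- results[results$flow_method == flow_method & !is.na(results$ffr_pred), ]
  graphics::plot(sub$ffr_invasive, sub$ffr_pred, xlim = c(0.3, 1),
                 ylim = c(0.3, 1), pch = 19,
                 xlab = "invasive FFR", ylab = "predicted FFR",
                 main = sprintf("Flow setup: %s", flow_method), ...)
  graphics::points(sub$ffr_invasive, sub$gffr_pred, pch = 1)
  graphics::abline(0, 1, col = "grey50")
  graphics::abline(h = cutoff, v = cutoff, lty = 2, col = "grey50")
  graphics::legend("topleft", legend = c("wire absent", "wire included"),
                   pch = c(19, 1), bty = "n")
  invisible(results)
}

#' @rdname plot_ffr_scatter
#' @export
plot_bland_altman <- function(pred, invasive, ...) {
  ba <- bland_altman(pred, invasive)
  d <- invasive - pred
  m <- (invasive + pred) / 2
  graphics::plot(m, d, pch = 19, xlab = "mean of methods",
                 ylab = "invasive - predicted", ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = ba$bias + c(-1.96, 1.96) * ba$sd, lty = 2)
  invisible(ba)
}
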