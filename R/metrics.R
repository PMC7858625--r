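#' Per-case segmentation metrics
#'
#' Voxel-wise confusion between a predicted and a ground-truth mask on the
#' same grid, converted to volumes in cubic millimetres and to the standard
#' rates: `DSC = 2TP/(2TP+FP+FN)`, `TPR = 100*TP/(TP+FN)`,
#' `FPR = 100*FP/(FP+TN)`, `FNR = 100 - TPR`, `FDR = 100*FP/(TP+FP)`.
#' When both masks are empty, DSC is defined as 1; rates whose denominator
#' is empty are reported as `NA` rather than silently as 0.
#'
#' @param pred A predicted [binary_mask()].
#' @param gt The ground-truth [binary_mask()] on the same grid and spacing.
#' @param case_id Optional identifier stored in the output.
#' @return A one-row tibble with columns `case_id`, `dsc`, `tpr`, `fpr`,
#'   `fnr`, `fdr` (percent), `tp_mm3`, `fp_mm3`, `fn_mm3`, `gt_mm3`,
#'   `pv_mm3`.
#' @export
compute_metrics <- function(pred, gt, case_id = NA_character_) {
  if (!all(dim(pred$voxels) == dim(gt$voxels)) ||
      max(abs(pred$spacing - gt$spacing)) > 1e-9) {
    abort("prediction and ground truth must share grid shape and spacing",
          class = "otoseg_shape_error")
  }
  p <- pred$voxels > 0
  g <- gt$voxels > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  tn <- length(p) - tp - fp - fn
  vv <- voxel_volume(gt)
  dsc <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  tibble(case_id = case_id,
         dsc = dsc,
         tpr = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         fpr = if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_,
         fnr = if (tp + fn > 0) 100 * fn / (tp + fn) else NA_real_,
         fdr = if (tp + fp > 0) 100 * fp / (tp + fp) else NA_real_,
         tp_mm3 = tp * vv, fp_mm3 = fp * vv, fn_mm3 = fn * vv,
         gt_mm3 = (tp + fn) * vv, pv_mm3 = (tp + fp) * vv)
}

#' Metrics from reported volumes
#'
#' Reconstructs the rate metrics from ground-truth, true-positive and
#' (optionally) false-positive volumes, as printed in per-case figure
#' captions: `TPR = 100*TP/GT`, `FNR = 100 - TPR`, and with FP available
#' also `FDR = 100*FP/(TP+FP)` and `DSC = 2TP/(GT + TP + FP)`.
#'
#' @param gt_mm3 Ground-truth volume (mm^3).
#' @param tp_mm3 True-positive volume (mm^3), `0 <= tp <= gt`.
#' @param fp_mm3 Optional false-positive volume (mm^3).
#' @return One-row tibble with `tpr`, `fnr` and, when `fp_mm3` is given,
#'   `fdr`, `dsc`, `pv_mm3`.
#' @examples
#' metrics_from_volumes(465.37, 445.32)  # TPR 95.69, FNR 4.31
#' @export
metrics_from_volumes <- function(gt_mm3, tp_mm3, fp_mm3 = NULL) {
  if (gt_mm3 <= 0) abort("gt_mm3 must be > 0", class = "otoseg_validation_error")
  if (tp_mm3 < 0 || tp_mm3 > gt_mm3) {
    abort("tp_mm3 must satisfy 0 <= tp <= gt", class = "otoseg_validation_error")
  }
  tpr <- 100 * tp_mm3 / gt_mm3
  out <- tibble(gt_mm3 = gt_mm3, tp_mm3 = tp_mm3,
                tpr = tpr, fnr = 100 - tpr)
  if (!is.null(fp_mm3)) {
    if (fp_mm3 < 0) abort("fp_mm3 must be >= 0", class = "otoseg_validation_error")
    out$fp_mm3 <- fp_mm3
    out$pv_mm3 <- tp_mm3 + fp_mm3
    out$fdr <- if (tp_mm3 + fp_mm3 > 0) 100 * fp_mm3 / (tp_mm3 + fp_mm3) else NA_real_
    out$dsc <- 2 * tp_mm3 / (gt_mm3 + tp_mm3 + fp_mm3)
  }
  out
}

#' Cohort summary with t-based 95% confidence intervals
#'
#' Per-case metrics are averaged (not recomputed from pooled volumes) and
#' each mean gets `mean +/- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param cases Tibble of per-case metrics as returned by
#'   [compute_metrics()] (any numeric columns are summarized).
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble with one row per metric: `metric`, `mean`, `ci_lo`,
#'   `ci_hi`, `sd`, `n`.
#' @export
summarize_cohort <- function(cases, conf_level = 0.95) {
  num <- as_tibble(cases[vapply(cases, is.numeric, logical(1))])
  if (nrow(num) < 2L) {
    abort("need at least 2 cases for a confidence interval",
          class = "otoseg_validation_error")
  }
  long <- tidyr::pivot_longer(num, dplyr::everything(),
                              names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop") |>
    dplyr::mutate(
      half = qt(1 - (1 - conf_level) / 2, .data$n - 1) *
        .data$sd / sqrt(.data$n),
      ci_lo = .data$mean - .data$half,
      ci_hi = .data$mean + .data$half) |>
    dplyr::select("metric", "mean", "ci_lo", "ci_hi", "sd", "n")
}

#' Bland-Altman agreement between predicted and ground-truth volumes
#'
#' Per-case percentage difference `100 * (PV - GTV) / mean(PV, GTV)`,
#' summarized by the mean difference and the limits of agreement
#' `mean +/- 1.96 * SD`. With `dsc_cutoff` set, cases with `DSC <= cutoff`
#' are excluded from the summary and listed as outliers.
#'
#' @param cases Tibble with columns `pv_mm3`, `gt_mm3` and (if a cutoff is
#'   used) `dsc`; an optional `case_id` column labels outliers.
#' @param dsc_cutoff Optional DSC threshold; cases at or below it are
#'   excluded.
#' @return Object of class `otoseg_bland_altman`: list with `data` (tibble
#'   with `mean_volume`, `pct_diff`, `outlier`), `mean_diff`, `loa_lower`,
#'   `loa_upper`, `outliers` (tibble of excluded cases), `dsc_cutoff`, `n`.
#' @export
bland_altman <- function(cases, dsc_cutoff = NULL) {
  if (any(cases$pv_mm3 <= 0) || any(cases$gt_mm3 <= 0)) {
    abort("volumes must be strictly positive", class = "otoseg_validation_error")
  }
  df <- dplyr::mutate(
    cases,
    mean_volume = (.data$pv_mm3 + .data$gt_mm3) / 2,
    pct_diff = 100 * (.data$pv_mm3 - .data$gt_mm3) / .data$mean_volume,
    outlier = if (is.null(dsc_cutoff)) FALSE else .data$dsc <= dsc_cutoff)
  kept <- df$pct_diff[!df$outlier]
  m <- mean(kept)
  s <- if (length(kept) > 1) sd(kept) else 0
  structure(list(data = df, mean_diff = m,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 outliers = df[df$outlier, , drop = FALSE],
                 dsc_cutoff = dsc_cutoff, n = sum(!df$outlier)),
            class = "otoseg_bland_altman")
}

#' @export
print.otoseg_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: mean diff %.2f%%, LoA [%.2f%%, %.2f%%]",
    x$n, x$mean_diff, x$loa_lower, x$loa_upper))
  if (!is.null(x$dsc_cutoff)) {
    cat(sprintf(", %d outlier(s) at DSC <= %.2f", nrow(x$outliers),
                x$dsc_cutoff))
  }
  cat("\n")
  invisible(x)
}

#' @rdname bland_altman
#' @param x An `otoseg_bland_altman`.
#' @param ... Unused.
#' @export
tidy.otoseg_bland_altman <- function(x, ...) x$data

#' @rdname bland_altman
#' @export
glance.otoseg_bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, loa_lower = x$loa_lower,
         loa_upper = x$loa_upper, n = x$n, n_outliers = nrow(x$outliers))
}

#' @rdname bland_altman
#' @param object An `otoseg_bland_altman`.
#' @export
autoplot.otoseg_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$mean_volume, .data$pct_diff,
                               colour = .data$outlier)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "mean of predicted and ground-truth volume (mm^3)",
                  y = "percentage difference PV vs GTV (%)") +
    ggplot2::theme_minimal()
}

#' Correlation between ground-truth and true-positive volume
#'
#' Pearson correlation and the least-squares line of the true-positive
#' volume on the ground-truth volume across cases.
#'
#' @param cases Tibble with columns `gt_mm3` and `tp_mm3` (>= 3 rows).
#' @return One-row tibble with `r`, `slope`, `intercept`, `n`.
#' @export
volume_correlation <- function(cases) {
  if (nrow(cases) < 3L) {
    abort("need at least 3 cases", class = "otoseg_validation_error")
  }
  if (sd(cases$gt_mm3) == 0) {
    abort("ground-truth volumes have zero variance; correlation undefined",
          class = "otoseg_validation_error")
  }
  fit <- lm(tp_mm3 ~ gt_mm3, data = cases)
  tibble(r = cor(cases$gt_mm3, cases$tp_mm3),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n = nrow(cases))
}
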