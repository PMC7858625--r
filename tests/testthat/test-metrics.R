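test_that("compute_metrics equals brute-force confusion counting on random masks", {
  set.seed(14)
  sp <- c(0.45, 0.45, 0.45)
  for (i in 1:25) {
    dims <- c(16L, 16L, 16L)
    pr <- random_mask_array(dims, p = runif(1, 0.05, 0.5))
    gt <- random_mask_array(dims, p = runif(1, 0.05, 0.5))
    m <- compute_metrics(binary_mask(pr, sp), binary_mask(gt, sp))
    cf <- brute_force_confusion(pr, gt)
    vv <- prod(sp)
    expect_identical(m$tp_mm3, cf$tp * vv)
    expect_identical(m$fp_mm3, cf$fp * vv)
    expect_identical(m$fn_mm3, cf$fn * vv)
    expect_equal(m$dsc, 2 * cf$tp / (2 * cf$tp + cf$fp + cf$fn))
    expect_equal(m$tpr, 100 * cf$tp / (cf$tp + cf$fn))
    expect_equal(m$fpr, 100 * cf$fp / (cf$fp + cf$tn))
    expect_equal(m$fdr, 100 * cf$fp / (cf$tp + cf$fp))
    # identities: TPR + FNR = 100, volume additivity
    expect_equal(m$tpr + m$fnr, 100, tolerance = 1e-9)
    expect_equal(m$gt_mm3, m$tp_mm3 + m$fn_mm3, tolerance = 1e-9)
    expect_equal(m$pv_mm3, m$tp_mm3 + m$fp_mm3, tolerance = 1e-9)
  }
})

test_that("identity, disjoint and empty-mask conventions", {
  sp <- rep(0.45, 3)
  arr <- array(0, c(10, 10, 10)); arr[2:5, 2:6, 3:7] <- 1
  stopifnot(sum(arr) == 100)
  m <- compute_metrics(binary_mask(arr, sp), binary_mask(arr, sp))
  expect_equal(m$dsc, 1)
  expect_equal(m$tpr, 100)
  expect_equal(m$fdr, 0)
  expect_equal(m$gt_mm3, 100 * 0.45^3)  # 9.1125 mm^3

  dis <- array(0, c(10, 10, 10)); dis[8:9, 8:9, 8:9] <- 1
  d <- compute_metrics(binary_mask(dis, sp), binary_mask(arr, sp))
  expect_equal(d$dsc, 0)
  expect_equal(d$tpr, 0)
  expect_equal(d$fdr, 100)

  empty <- binary_mask(array(0, c(4, 4, 4)), sp)
  e <- compute_metrics(empty, empty)
  expect_equal(e$dsc, 1)
  expect_true(is.na(e$tpr) && is.na(e$fnr) && is.na(e$fdr))

  other <- binary_mask(array(0, c(5, 4, 4)), sp)
  expect_error(compute_metrics(empty, other), class = "otoseg_shape_error")
})

test_that("metrics_from_volumes reproduces per-case rates and validates inputs", {
  # |GT|=100, |TP|=80, |FP|=20 in volume units
  m <- metrics_from_volumes(100, 80, 20)
  expect_equal(m$tpr, 80)
  expect_equal(m$fnr, 20)
  expect_equal(m$fdr, 20)
  expect_equal(m$dsc, 160 / 200)
  expect_error(metrics_from_volumes(100, 120),
               class = "otoseg_validation_error")
  # consistency with compute_metrics on masks built to those volumes
  sp <- c(1, 1, 1)
  gt <- array(0, c(10, 10, 10)); gt[1:100] <- 1
  pr <- array(0, c(10, 10, 10)); pr[21:120] <- 1  # TP 80, FP 20
  cm <- compute_metrics(binary_mask(pr, sp), binary_mask(gt, sp))
  expect_equal(cm$tpr, m$tpr)
  expect_equal(cm$fdr, m$fdr)
  expect_equal(cm$dsc, m$dsc)
})

test_that("cohort summary computes the textbook t-interval per metric", {
  cases <- dplyr::bind_rows(
    metrics_from_volumes(100, 80, 20),
    metrics_from_volumes(100, 90, 10))
  s <- summarize_cohort(cases[, c("tpr", "fnr")])
  tpr_row <- s[s$metric == "tpr", ]
  expect_equal(tpr_row$mean, 85)
  half <- qt(0.975, 1) * sd(c(80, 90)) / sqrt(2)
  expect_equal(tpr_row$ci_lo, 85 - half)
  expect_equal(tpr_row$ci_hi, 85 + half)
  # identical cases give zero-width intervals
  same <- dplyr::bind_rows(metrics_from_volumes(100, 80),
                           metrics_from_volumes(100, 80))
  s2 <- summarize_cohort(same)
  expect_true(all(abs(s2$ci_hi - s2$ci_lo) < 1e-12))
  expect_error(summarize_cohort(cases[1, ]),
               class = "otoseg_validation_error")
})

test_that("Bland-Altman differences, limits of agreement and outlier filter", {
  one <- tibble::tibble(pv_mm3 = 110, gt_mm3 = 100, dsc = 0.9)
  two <- dplyr::bind_rows(one, one)
  ba <- bland_altman(two)
  expect_equal(ba$data$pct_diff[1], 100 * 10 / 105)  # 9.5238%
  expect_equal(ba$mean_diff, 9.523809523809524)

  equal <- tibble::tibble(pv_mm3 = c(100, 200, 300),
                          gt_mm3 = c(100, 200, 300), dsc = rep(0.9, 3))
  be <- bland_altman(equal)
  expect_equal(be$mean_diff, 0)
  expect_equal(c(be$loa_lower, be$loa_upper), c(0, 0))

  five <- tibble::tibble(
    case_id = paste0("c", 1:5),
    pv_mm3 = c(100, 120, 60, 90, 180), gt_mm3 = rep(100, 5),
    dsc = c(0.9, 0.85, 0.7, 0.92, 0.80))
  bo <- bland_altman(five, dsc_cutoff = 0.80)
  expect_setequal(bo$outliers$case_id, c("c3", "c5"))
  expect_equal(bo$n, 3)
  expect_true(bo$loa_lower <= bo$mean_diff && bo$mean_diff <= bo$loa_upper)
  expect_error(bland_altman(tibble::tibble(pv_mm3 = 0, gt_mm3 = 10)),
               class = "otoseg_validation_error")
  g <- glance(bo)
  expect_equal(g$n_outliers, 2)
})

test_that("volume correlation recovers exact linear relations", {
  cases <- tibble::tibble(gt_mm3 = c(300, 400, 500), tp_mm3 = 0.9 * c(300, 400, 500))
  vc <- volume_correlation(cases)
  expect_equal(vc$r, 1)
  expect_equal(vc$slope, 0.9)
  expect_equal(vc$intercept, 0, tolerance = 1e-10)
  # permuting the pairing of a correlated set reduces |r|
  set.seed(2)
  gtv <- runif(20, 300, 500)
  tpv <- 0.92 * gtv + rnorm(20, 0, 5)
  paired <- volume_correlation(tibble::tibble(gt_mm3 = gtv, tp_mm3 = tpv))
  perm <- volume_correlation(tibble::tibble(gt_mm3 = gtv, tp_mm3 = sample(tpv)))
  expect_lt(abs(perm$r), paired$r)
  expect_error(volume_correlation(tibble::tibble(gt_mm3 = c(1, 1, 1),
                                                 tp_mm3 = c(1, 2, 3))),
               class = "otoseg_validation_error")
})
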