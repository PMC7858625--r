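#' Per-participant preference scores
#'
#' In the qualitative comparison, each participant sees every case as a
#' blinded pair (automated vs manual segmentation) and selects the
#' preferred one. The preference score of a participant is the percentage
#' of cases in which the automated segmentation was chosen.
#'
#' @param selections Tibble with columns `participant_id`, `case_id` and
#'   `choice` (each `"automated"` or `"manual"`). The table must be
#'   complete: every participant rates every case, no missing cells.
#' @return Tibble with `participant_id`, `n_cases`, `n_automated`, `score`
#'   (percent in \[0, 100\]).
#' @export
preference_scores <- function(selections) {
  req <- c("participant_id", "case_id", "choice")
  if (!all(req %in% names(selections))) {
    abort(sprintf("selections needs columns %s", paste(req, collapse = ", ")))
  }
  if (any(is.na(selections$choice)) ||
      !all(selections$choice %in% c("automated", "manual"))) {
    abort("every choice must be 'automated' or 'manual' (no missing cells)",
          class = "otoseg_validation_error")
  }
  counts <- dplyr::count(selections, .data$participant_id, .data$case_id)
  if (any(counts$n != 1L)) {
    abort("each participant x case cell must appear exactly once",
          class = "otoseg_validation_error")
  }
  per_case <- dplyr::count(selections, .data$participant_id)
  if (length(unique(per_case$n)) != 1L) {
    abort("incomplete table: participants rated different numbers of cases",
          class = "otoseg_validation_error")
  }
  dplyr::summarise(
    dplyr::group_by(selections, .data$participant_id),
    n_cases = dplyr::n(),
    n_automated = sum(.data$choice == "automated"),
    score = 100 * .data$n_automated / .data$n_cases,
    .groups = "drop")
}

#' One-sided preference test against the 50% null
#'
#' One-sample t-test of the preference scores against `null_value`, upper
#' tail: is the automated segmentation preferred more often than chance?
#' `t = mean(score - null) / (SD / sqrt(n))`, `p` from the t distribution
#' with `n - 1` degrees of freedom.
#'
#' @param scores Numeric vector of preference scores (percent), or the
#'   tibble from [preference_scores()].
#' @param null_value Null preference level, default 50.
#' @return Object of class `otoseg_pref_test` with fields `estimate`
#'   (mean score), `statistic`, `p_value`, `df`, `n`, `null_value`.
#' @export
preference_test <- function(scores, null_value = 50) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) < 2L) {
    abort("need at least 2 scores", class = "otoseg_validation_error")
  }
  if (sd(scores) == 0) {
    abort(paste0(
      "zero variance among scores; the t statistic is undefined",
      if (all(scores > null_value)) " (all scores exceed the null)" else ""),
      class = "otoseg_degenerate_error")
  }
  ht <- t.test(scores, mu = null_value, alternative = "greater")
  structure(list(estimate = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter),
                 n = length(scores), null_value = null_value),
            class = "otoseg_pref_test")
}

#' @export
print.otoseg_pref_test <- function(x, ...) {
  cat(sprintf(
    "<preference test> mean score %.1f%% vs %g%%: t(%d) = %.3f, one-sided p = %.3g\n",
    x$estimate, x$null_value, x$df, x$statistic, x$p_value))
  invisible(x)
}

#' @rdname preference_test
#' @param x An `otoseg_pref_test`.
#' @param ... Unused.
#' @export
tidy.otoseg_pref_test <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic,
         p_value = x$p_value, df = x$df, n = x$n,
         null_value = x$null_value, alternative = "greater")
}

#' Full preference study at a chosen pairing unit
#'
#' Computes scores and runs the one-sided test in one call. The pairing
#' unit is genuinely ambiguous in practice: `"participant"` tests the
#' participant-level scores (n = number of raters); `"rating"` treats every
#' participant x case selection as a 0/100 observation (n = raters x
#' cases). Both are exposed; they answer slightly different questions and
#' can give very different p-values.
#'
#' @param selections As in [preference_scores()].
#' @param unit `"participant"` (default) or `"rating"`.
#' @param null_value Null preference level, default 50.
#' @return An `otoseg_pref_test`.
#' @export
preference_study <- function(selections, unit = c("participant", "rating"),
                             null_value = 50) {
  unit <- match.arg(unit)
  scores <- preference_scores(selections)
  if (unit == "participant") {
    preference_test(scores$score, null_value)
  } else {
    preference_test(100 * (selections$choice == "automated"), null_value)
  }
}
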