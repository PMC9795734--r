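# Laterality statistics: left-right ratios and bias indices, preference
# categories, intraclass-correlation repeatability, Kendall rank
# correlations, fasting deltas, and paired Wilcoxon tests with Holm
# correction.

#' Left-right ratio of a lateralized measure
#'
#' The right-side measure divided by the left+right total, for approach
#' counts (NOA) or adherence durations (DIR). When both sides are zero the
#' ratio is undefined and returned as `NA` (such fish are retained in the
#' records but excluded from histograms and means), never coerced to 0.5.
#'
#' @param left,right non-negative counts or seconds (vectorized).
#' @return `right / (left + right)` in \[0, 1\], or `NA` where both are 0.
#' @export
lr_ratio <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    stop("lr_ratio: left and right must be non-negative")
  }
  tot <- left + right
  ifelse(tot == 0, NA_real_, right / tot)
}

#' Preference category of a left-right ratio
#'
#' Ratios below 0.33 indicate a strong left preference, ratios in the closed
#' interval \[0.33, 0.67\] balanced approaches, and ratios above 0.67 a
#' strong right preference. An undefined (`NA`) ratio maps to `"undefined"`.
#'
#' @param ratio left-right ratio in \[0, 1\] or `NA` (vectorized).
#' @return character: `"left"`, `"balanced"`, `"right"`, or `"undefined"`.
#' @export
classify_preference <- function(ratio) {
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE)) {
    stop("classify_preference: ratio must lie in [0, 1]")
  }
  out <- ifelse(is.na(ratio), "undefined",
                ifelse(ratio < 0.33, "left",
                       ifelse(ratio > 0.67, "right", "balanced")))
  out
}

#' Left-right bias index
#'
#' The larger of the two side measures over their sum:
#' `max(left, right) / (left + right)`, ranging from 0.5 (symmetric) to 1
#' (fully one-sided); equals `max(r, 1 - r)` for the [lr_ratio] `r`.
#' Undefined (`NA`) when both sides are zero.
#'
#' @inheritParams lr_ratio
#' @return bias index in \[0.5, 1\] or `NA`.
#' @export
bias_index <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    stop("bias_index: left and right must be non-negative")
  }
  tot <- left + right
  ifelse(tot == 0, NA_real_, pmax(left, right) / tot)
}

#' Single-rater intraclass correlation repeatability
#'
#' Two-way ANOVA decomposition of a complete subjects-by-repeats matrix into
#' between-subject (MSR), between-repeat (MSC) and residual (MSE) mean
#' squares. Reports the repeatability F statistic `F = MSR / MSE` with
#' `df1 = n - 1`, `df2 = (n - 1)(k - 1)` and its p-value, plus both
#' single-rater ICC variants: consistency,
#' `(MSR - MSE) / (MSR + (k - 1) MSE) = (F - 1) / (F + k - 1)`, and absolute
#' agreement (single random raters),
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`. The reported
#' `kappa` and its interpretation label use the consistency variant, which
#' is the identity linking printed F statistics to printed kappas.
#'
#' @param m numeric matrix, subjects in rows, repeated measurements in
#'   columns; complete (no missing cells), at least 2 x 2.
#' @return list of class `icc_result`: `kappa`, `kappa_consistency`,
#'   `kappa_agreement`, `f`, `df1`, `df2`, `p_value`, `interpretation`,
#'   `n_subjects`, `k_repeats`.
#' @export
icc_repeatability <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("icc_repeatability: missing cells; no imputation is done")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("icc_repeatability: need at least 2 subjects and 2 repeats")
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)            # between subjects
  ssc <- n * sum((col_m - grand)^2)            # between repeats (raters)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  f <- msr / mse
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  kc <- (msr - mse) / (msr + (k - 1) * mse)
  ka <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(kappa = kc, kappa_consistency = kc, kappa_agreement = ka,
                 f = f, df1 = df1, df2 = df2, p_value = p,
                 interpretation = interpret_kappa(kc),
                 n_subjects = n, k_repeats = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC repeatability: kappa = %.3f (%s), F(%d,%d) = %.3f, p = %.4g\n",
              max(0, x$kappa), x$interpretation, x$df1, x$df2, x$f, x$p_value))
  invisible(x)
}

#' Consistency ICC from a repeatability F statistic
#'
#' Inverts the single-rater consistency identity
#' `kappa = (F - 1) / (F + k - 1)` for `k` repeated measurements, clipping
#' below at 0 for reporting (an F below 1 means no detectable between-fish
#' repeatability).
#'
#' @param f repeatability F statistic (positive; vectorized).
#' @param k number of repeated measurements, `k >= 2`.
#' @return kappa in \[0, 1\).
#' @export
icc_from_f <- function(f, k) {
  if (any(f <= 0)) stop("icc_from_f: F must be positive")
  if (k < 2) stop("icc_from_f: k must be at least 2")
  pmax(0, (f - 1) / (f + k - 1))
}

#' Verbal interpretation of a kappa value
#'
#' Bins anchored to the conventional strength-of-agreement labels:
#' below 0.2 none, 0.2-0.4 fair, 0.4-0.6 moderate, 0.6-0.8 substantial,
#' 0.8 and above almost perfect (left-closed bins).
#'
#' @param kappa ICC value, at most 1 (vectorized).
#' @return character label.
#' @export
interpret_kappa <- function(kappa) {
  if (any(kappa > 1, na.rm = TRUE)) stop("interpret_kappa: kappa cannot exceed 1")
  cut_pts <- c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf)
  labels <- c("none", "fair", "moderate", "substantial", "almost perfect")
  as.character(cut(kappa, cut_pts, labels, right = FALSE))
}

#' Kendall rank correlation with tie correction
#'
#' Tie-corrected Kendall tau-b with a two-sided p-value: exact null
#' enumeration for small samples without ties, the tie-corrected normal
#' approximation otherwise (the policy of [stats::cor.test]). A constant
#' vector leaves tau undefined; `NA` is returned with a message.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return list with `tau`, `p_value`, `n`, `method`.
#' @export
kendall_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("kendall_correlation: unequal lengths")
  if (length(x) < 3L) stop("kendall_correlation: need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("kendall_correlation: missing values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    message("kendall_correlation: constant vector, tau undefined")
    return(list(tau = NA_real_, p_value = NA_real_, n = length(x),
                method = "undefined (constant input)"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = ct$method)
}

#' Per-fish change after fasting
#'
#' Matches fish between a before and an after condition and returns per-fish
#' differences (`after - before`) of the supplied measures, ready to join to
#' sensory covariates for correlation analysis.
#'
#' @param before,after data.frames with a `fish_id` column and shared
#'   numeric measure columns (e.g. `noa_total`, `dir_total_s`).
#' @param measures measure columns to difference; default the shared numeric
#'   columns.
#' @return data.frame with `fish_id` and one `delta_<measure>` column per
#'   measure.
#' @export
fasting_delta <- function(before, after, measures = NULL) {
  stopifnot("fish_id" %in% names(before), "fish_id" %in% names(after))
  miss_a <- setdiff(before$fish_id, after$fish_id)
  miss_b <- setdiff(after$fish_id, before$fish_id)
  if (length(miss_a) || length(miss_b)) {
    stop("fasting_delta: unmatched fish ids - missing after: [",
         paste(miss_a, collapse = ", "), "]; missing before: [",
         paste(miss_b, collapse = ", "), "]")
  }
  if (anyDuplicated(before$fish_id) || anyDuplicated(after$fish_id)) {
    stop("fasting_delta: duplicated fish ids within a condition")
  }
  if (is.null(measures)) {
    shared <- intersect(names(before), names(after))
    measures <- shared[shared != "fish_id" &
                         vapply(before[shared], is.numeric, TRUE)]
  }
  after <- after[match(before$fish_id, after$fish_id), , drop = FALSE]
  out <- data.frame(fish_id = before$fish_id)
  for (mcol in measures) {
    out[[paste0("delta_", mcol)]] <- after[[mcol]] - before[[mcol]]
  }
  out
}

#' Paired Wilcoxon signed-rank tests with Holm correction
#'
#' Runs one paired two-sided Wilcoxon signed-rank test per named element of
#' `pairs` and Holm-adjusts the p-values within that family. Tests whose
#' differences are all zero are undefined and reported with `NA` statistics
#' (they still count as members of the family for the adjustment).
#'
#' @param pairs named list; each element a list or data.frame with equal
#'   length numeric `before` and `after`.
#' @return data.frame with one row per test: `test`, `n`, `v_statistic`,
#'   `p_value`, `p_holm`.
#' @export
paired_wilcoxon_holm <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) > 0L)
  if (is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
    stop("paired_wilcoxon_holm: every test in the family must be named")
  }
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    b <- p$before; a <- p$after
    if (length(b) != length(a) || length(b) == 0L) {
      stop("paired_wilcoxon_holm: test '", nm,
           "' needs matched non-empty before/after vectors")
    }
    if (all(a - b == 0)) {
      return(data.frame(test = nm, n = length(b), v_statistic = NA_real_,
                        p_value = NA_real_))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    data.frame(test = nm, n = length(b), v_statistic = unname(wt$statistic),
               p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Build per-fish laterality records
#'
#' Joins behavior summaries to optional sensory covariates and derives the
#' laterality quantities per fish: left-right NOA and DIR ratios, bias
#' indices, and the preference category of the NOA ratio.
#'
#' @param summaries data.frame of per-fish behavior summaries (one row per
#'   fish; columns as from [summarize_behavior] plus `fish_id` and,
#'   optionally, `population` and `condition`).
#' @param sensory optional data.frame keyed by `fish_id` with columns among
#'   `sn_left`, `sn_right`, `ablated_fraction_left`, `ablated_fraction_right`.
#' @return data.frame: one LateralityRecord row per fish with `lr_noa_ratio`,
#'   `lr_dir_ratio`, `bias_index_noa`, `bias_index_dir`, `preference`, and
#'   any joined covariates.
#' @export
laterality_records <- function(summaries, sensory = NULL) {
  stopifnot("fish_id" %in% names(summaries))
  out <- summaries
  out$lr_noa_ratio <- lr_ratio(out$noa_left, out$noa_right)
  out$lr_dir_ratio <- lr_ratio(out$dir_left_s, out$dir_right_s)
  out$bias_index_noa <- bias_index(out$noa_left, out$noa_right)
  out$bias_index_dir <- bias_index(out$dir_left_s, out$dir_right_s)
  out$preference <- classify_preference(out$lr_noa_ratio)
  if (!is.null(sensory)) {
    stopifnot("fish_id" %in% names(sensory))
    if (is.factor(sensory$fish_id)) sensory$fish_id <- as.character(sensory$fish_id)
    if (any(sensory$sn_left < 0, na.rm = TRUE) ||
        any(sensory$sn_right < 0, na.rm = TRUE)) {
      stop("laterality_records: neuromast counts must be non-negative")
    }
    out <- merge(out, sensory, by = "fish_id", all.x = TRUE, sort = FALSE)
  }
  out
}
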