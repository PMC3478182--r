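#' Cooking-water fluoride interval scheme
#'
#' Five categorical intervals of water fluoride concentration (ppm):
#' `<0.20`, `0.20-0.59`, `0.60-0.89`, `0.90-1.59`, `1.60+`, labelled 0-4.
#' Boundaries are lower-inclusive; concentrations are compared after rounding
#' to 2 decimal places, the precision at which the boundaries are defined.
#'
#' @param boundaries Strictly increasing ppm cut points (default
#'   `c(0.20, 0.60, 0.90, 1.60)`).
#' @return A list of class `fq_interval_scheme`.
#' @export
water_interval_scheme <- function(boundaries = c(0.20, 0.60, 0.90, 1.60)) {
  if (length(boundaries) != 4L || any(diff(boundaries) <= 0))
    abort("`boundaries` must be 4 strictly increasing cut points")
  structure(list(boundaries = boundaries,
                 labels = c("<0.20", "0.20-0.59", "0.60-0.89", "0.90-1.59", "1.60+")),
            class = "fq_interval_scheme")
}

#' Assign water-interval labels
#'
#' @param ppm Numeric vector of fluoride concentrations (mg/L, `>= 0`).
#' @param scheme An [water_interval_scheme()].
#' @return Integer vector of interval labels 0-4.
#' @export
assign_interval <- function(ppm, scheme = water_interval_scheme()) {
  if (any(ppm < 0, na.rm = TRUE)) abort("negative fluoride concentration")
  # round to 2 dp on the stored double's true value (0.595 -> 0.59 because
  # its double representation sits just below the midpoint); sprintf avoids
  # the fp drift of round(x * 100) / 100
  r2 <- as.numeric(sprintf("%.2f", ppm))
  findInterval(r2, scheme$boundaries)
}

#' Subject-level scores and metrics
#'
#' The subject-level TF score is the higher of the two maxillary central
#' incisor scores.  Analogously, subject-level metrics are taken from the
#' tooth with the larger `delta_q` (with its companion `area` and `delta_f`
#' from the same tooth), keeping the subject-level comparison coherent.
#'
#' @param records Per-tooth tibble with columns `subject_id`, `tooth`, `tf`,
#'   `method`, `area`, `delta_f`, `delta_q` (plus any carried columns such as
#'   `water_ppm`, `water_interval`).
#' @return Subject-level tibble: one row per subject x method, with
#'   `tf_subject`, the chosen tooth's metrics and `source_tooth`.
#' @export
subject_level <- function(records) {
  need <- c("subject_id", "tooth", "tf", "method", "area", "delta_f", "delta_q")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(sprintf("missing column(s): %s", toString(miss)))
  carry <- intersect(c("water_ppm", "water_interval"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", "method")))) |>
    dplyr::arrange(dplyr::desc(.data$delta_q), .data$tooth, .by_group = TRUE) |>
    dplyr::summarise(
      tf_subject = max(.data$tf),
      area = dplyr::first(.data$area),
      delta_f = dplyr::first(.data$delta_f),
      delta_q = dplyr::first(.data$delta_q),
      source_tooth = dplyr::first(.data$tooth),
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      .groups = "drop")
}

# Spearman's rho with average ranks for ties; p by the t approximation.
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  tibble(rho = rho, p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Rank correlations between metrics and the photographic TF score
#'
#' @param records Subject-level tibble from [subject_level()].
#' @param metrics Metric columns to correlate with `tf_subject`.
#' @return Tibble: `method`, `metric`, `rho`, `p_value`, `n`.
#' @export
spearman_table <- function(records, metrics = c("area", "delta_f", "delta_q")) {
  purrr::map_dfr(split(records, records$method), function(d) {
    purrr::map_dfr(metrics, function(mm) {
      dplyr::bind_cols(tibble(method = d$method[1], metric = mm),
                       spearman_rho(d[[mm]], d$tf_subject))
    })
  })
}

# Two-sided Mann-Whitney U: exact when both groups are small and untied,
# tie-corrected normal approximation (no continuity correction, matching the
# asymptotic p of the usual survey software) otherwise.
mw_u_test <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  tibble(u = unname(wt$statistic), p_value = wt$p.value,
         test = if (exact) "exact" else "normal_approx")
}

#' Pairwise water-interval separation
#'
#' The decision path of the study: a one-way ANOVA across intervals is run
#' with a homogeneity-of-variances check (Levene's test, median-centred);
#' when homogeneity is rejected (p < 0.05) the comparison falls back to the
#' non-parametric Mann-Whitney U test.  All 10 unordered interval pairs are
#' tested two-sided with a simple Bonferroni correction
#' (`p_adj = min(1, 10 p)`).
#'
#' @param records Subject-level tibble (one method) with `water_interval`
#'   and the metric column.
#' @param metric Metric column name (default `"delta_q"`).
#' @return An object of class `fq_separation`: list with `pairs` (tibble of
#'   the 10 comparisons), `levene_p`, `anova_p`, `path`
#'   (`"nonparametric"`/`"anova"`), `metric`, `n_per_interval`.
#' @export
interval_separation <- function(records, metric = "delta_q") {
  if (!metric %in% names(records)) abort(sprintf("no column '%s'", metric))
  if (!"water_interval" %in% names(records)) abort("no column 'water_interval'")
  d <- records[!is.na(records[[metric]]) & !is.na(records$water_interval), ]
  vals <- split(d[[metric]], d$water_interval)
  present <- sort(as.integer(names(vals)))
  counts <- purrr::map_int(vals, length)
  if (length(present) < 2) abort("need at least two non-empty intervals")
  if (any(counts < 2)) abort("need >= 2 subjects in every interval present")

  grp <- factor(d$water_interval)
  # near-zero residual variance on degenerate inputs triggers an unhelpful
  # "essentially perfect fit" warning; the decision path below only consumes
  # the p values
  quiet_perfect_fit <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  lev <- quiet_perfect_fit(car::leveneTest(d[[metric]] ~ grp, center = stats::median))
  levene_p <- lev[["Pr(>F)"]][1]
  an <- quiet_perfect_fit(summary(aov(d[[metric]] ~ grp))[[1]])
  anova_p <- an[["Pr(>F)"]][1]
  path <- if (!is.na(levene_p) && levene_p < 0.05) "nonparametric" else "anova"

  combos <- utils::combn(0:4, 2)
  n_family <- ncol(combos)
  pairs <- purrr::map_dfr(seq_len(n_family), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    xi <- vals[[as.character(i)]]; xj <- vals[[as.character(j)]]
    if (is.null(xi) || is.null(xj)) {
      return(tibble(interval_a = i, interval_b = j, n_a = length(xi),
                    n_b = length(xj), u = NA_real_, p_raw = NA_real_,
                    p_adj = NA_real_, test = "not_computable"))
    }
    res <- mw_u_test(xi, xj)
    tibble(interval_a = i, interval_b = j,
           n_a = length(xi), n_b = length(xj),
           u = res$u, p_raw = res$p_value,
           p_adj = pmin(1, n_family * res$p_value), test = res$test)
  })
  structure(list(pairs = pairs, levene_p = levene_p, anova_p = anova_p,
                 path = path, metric = metric,
                 n_per_interval = counts),
            class = "fq_separation")
}

#' @export
print.fq_separation <- function(x, ...) {
  cat(sprintf("<fq_separation> metric %s, path %s (Levene p = %.3g)\n",
              x$metric, x$path, x$levene_p))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.fq_separation <- function(x, ...) x$pairs

#' @export
glance.fq_separation <- function(x, ...) {
  tibble(metric = x$metric, path = x$path, levene_p = x$levene_p,
         anova_p = x$anova_p,
         n_significant = sum(x$pairs$p_adj < 0.05, na.rm = TRUE))
}

# ICC from the two-way crossed ANOVA decomposition (subjects x captures).
# icc_agreement is the two-way random-effects absolute-agreement
# single-measure form (the headline value); icc_consistency the two-way
# mixed consistency form.
icc_core <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x); k <- 2
  if (n < 5) abort("ICC needs at least 5 complete pairs")
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (sst == 0) {
    # no variance anywhere: between-subject variance is zero, ICC undefined
    return(tibble(icc_agreement = NA_real_, icc_consistency = NA_real_,
                  msr = msr, msc = msc, mse = mse, n = n))
  }
  denom_a <- msr + (k - 1) * mse + k * (msc - mse) / n
  denom_c <- msr + (k - 1) * mse
  tibble(icc_agreement = if (denom_a > 0) (msr - mse) / denom_a else NA_real_,
         icc_consistency = if (denom_c > 0) (msr - mse) / denom_c else NA_real_,
         msr = msr, msc = msc, mse = mse, n = n)
}

#' Repeatability ICC for paired captures
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between the first and repeat capture of each subject
#' (the consistency form is reported alongside).
#'
#' @param records Tibble with one row per subject x method x metric holding
#'   paired values in columns `value_1` (capture 1) and `value_2`
#'   (capture 2), plus grouping columns `method` and `metric`; or a bare
#'   tibble with just `value_1`/`value_2`.
#' @return Tibble with `icc_agreement`, `icc_consistency`, mean squares and
#'   `n` per method x metric.
#' @export
icc_repeatability <- function(records) {
  need <- c("value_1", "value_2")
  if (!all(need %in% names(records)))
    abort("`records` needs paired columns `value_1` and `value_2`")
  grp <- intersect(c("method", "metric"), names(records))
  if (!length(grp)) return(icc_core(records$value_1, records$value_2))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ icc_core(.x$value_1, .x$value_2)) |>
    dplyr::ungroup()
}

#' ROC analysis of a metric against the TF case boundary
#'
#' Cases are subjects with TF score at or above the boundary (the published
#' classifier boundary separates TF <= 2 from TF >= 3).  The curve sweeps
#' every observed metric value as a classification threshold (predict
#' "fluorosis" when the metric is at or above the threshold); AUC is the
#' trapezoidal area, which equals the tie-adjusted Mann-Whitney
#' `U / (n1 n2)`.  The operating point maximizes Youden's J
#' (sensitivity + specificity - 1), ties resolved towards the lower
#' threshold.
#'
#' @param records Subject-level tibble (one method).
#' @param metric Metric column (default `"delta_q"`).
#' @param tf_boundary Minimum TF score counted as a case (default 3).
#' @return An object of class `fq_roc`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `operating_point`,
#'   `n_pos`, `n_neg`, `metric`, `tf_boundary`.
#' @export
roc_analysis <- function(records, metric = "delta_q", tf_boundary = 3L) {
  if (!metric %in% names(records)) abort(sprintf("no column '%s'", metric))
  d <- records[!is.na(records[[metric]]) & !is.na(records$tf_subject), ]
  pos <- d$tf_subject >= tf_boundary
  if (!any(pos) || all(pos))
    abort("ROC needs both classes (TF below and at/above the boundary)")
  v <- d[[metric]]
  thr <- c(sort(unique(v)), Inf)
  sens <- purrr::map_dbl(thr, ~ mean(v[pos] >= .x))
  spec <- purrr::map_dbl(thr, ~ mean(v[!pos] < .x))
  curve <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid over (FPR, TPR), ordered by increasing FPR
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  structure(list(curve = curve, auc = auc,
                 operating_point = list(threshold = thr[best],
                                        sensitivity = sens[best],
                                        specificity = spec[best]),
                 n_pos = sum(pos), n_neg = sum(!pos),
                 metric = metric, tf_boundary = tf_boundary),
            class = "fq_roc")
}

#' @export
print.fq_roc <- function(x, ...) {
  cat(sprintf(
    "<fq_roc> %s, cases TF >= %d (n+ = %d, n- = %d)\n  AUC %.4f; Youden point: threshold %.4g, sens %.1f%%, spec %.1f%%\n",
    x$metric, x$tf_boundary, x$n_pos, x$n_neg, x$auc,
    x$operating_point$threshold, 100 * x$operating_point$sensitivity,
    100 * x$operating_point$specificity))
  invisible(x)
}

#' @export
tidy.fq_roc <- function(x, ...) x$curve

#' @export
glance.fq_roc <- function(x, ...) {
  tibble(auc = x$auc, threshold = x$operating_point$threshold,
         sensitivity = x$operating_point$sensitivity,
         specificity = x$operating_point$specificity,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve plot
#'
#' @param object An `fq_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fq_roc <- function(object, ...) {
  op <- object$operating_point
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - op$specificity, y = op$sensitivity,
                      colour = "red") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC for %s (AUC %.3f)", object$metric,
                                  object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Dose-response report
#'
#' The full statistical read-out over a study population: per-interval
#' descriptive statistics for every metric, the TF distribution (scores of 4
#' or higher grouped as 4+), pairwise interval separation per method,
#' rank correlations against TF, and ROC per method.
#'
#' @param records Per-tooth tibble (see [subject_level()]) with `water_ppm`
#'   or `water_interval`.
#' @param scheme Interval scheme used when `water_interval` is absent.
#' @param roc_metric Metric used for the ROC (default `"delta_q"`).
#' @return An object of class `fq_dose_report`: list with `subjects`,
#'   `descriptives`, `tf_distribution`, `separation` (per method),
#'   `correlations`, `roc` (per method).
#' @export
dose_response_report <- function(records, scheme = water_interval_scheme(),
                                 roc_metric = "delta_q") {
  if (nrow(records) == 0L) abort("empty input")
  if (!"water_interval" %in% names(records)) {
    if (!"water_ppm" %in% names(records))
      abort("need `water_interval` or `water_ppm`")
    records$water_interval <- assign_interval(records$water_ppm, scheme)
  }
  subj <- subject_level(records)
  descr <- subj |>
    tidyr::pivot_longer(c("area", "delta_f", "delta_q"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("method", "metric", "water_interval")))) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), median = median(.data$value),
                     min = min(.data$value), max = max(.data$value),
                     .groups = "drop")
  tf_dist <- subj |>
    dplyr::distinct(.data$subject_id, .data$water_interval, .data$tf_subject) |>
    dplyr::mutate(tf_group = ifelse(.data$tf_subject >= 4, "4+",
                                    as.character(.data$tf_subject))) |>
    dplyr::count(.data$water_interval, .data$tf_group)

  methods <- unique(subj$method)
  single_interval <- length(unique(subj$water_interval)) < 2
  separation <- NULL
  if (single_interval) {
    inform("single water interval: separation analysis skipped")
  } else {
    separation <- purrr::map(rlang::set_names(methods), function(mm) {
      interval_separation(subj[subj$method == mm, ], metric = "delta_q")
    })
  }
  correlations <- spearman_table(subj)
  roc <- purrr::map(rlang::set_names(methods), function(mm) {
    tryCatch(roc_analysis(subj[subj$method == mm, ], metric = roc_metric),
             error = function(e) NULL)
  })
  structure(list(subjects = subj, descriptives = descr,
                 tf_distribution = tf_dist, separation = separation,
                 correlations = correlations, roc = roc),
            class = "fq_dose_report")
}

#' @export
print.fq_dose_report <- function(x, ...) {
  cat(sprintf("<fq_dose_report> %d subjects, methods: %s\n",
              dplyr::n_distinct(x$subjects$subject_id),
              toString(unique(x$subjects$method))))
  print(x$correlations)
  invisible(x)
}

#' Dose-response boxplot
#'
#' `delta_q` by water interval, faceted by method.
#'
#' @param object An `fq_dose_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fq_dose_report <- function(object, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = factor(.data$water_interval), y = .data$delta_q)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "Cooking-water fluoride interval",
                  y = expression(Delta * Q)) +
    ggplot2::theme_minimal()
}
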