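test_that("water intervals partition concentrations with the printed boundaries", {
  expect_equal(assign_interval(c(0, 0.15, 0.20, 0.59, 0.60, 0.89, 0.90, 1.59,
                                 1.60, 2.5)),
               c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4))
  # boundary values compared after rounding to the table's 2 dp precision
  expect_equal(assign_interval(0.595), 1)
  expect_equal(assign_interval(0.596), 2)
  expect_error(assign_interval(-0.1), "negative")
  # every concentration maps to exactly one interval
  set.seed(3)
  ppm <- runif(200, 0, 5)
  iv <- assign_interval(ppm)
  expect_true(all(iv %in% 0:4))
})

test_that("subject level takes the max TF and the higher-dQ tooth's metrics", {
  rec <- tibble::tibble(
    subject_id = c("A", "A", "B", "B"),
    tooth = c("UR1", "UL1", "UR1", "UL1"),
    tf = c(2L, 3L, 0L, 0L),
    method = "hull",
    area = c(0.3, 0.1, 0, 0),
    delta_f = c(0.08, 0.05, 0, 0),
    delta_q = c(0.30, 0.10, 0, 0))
  s <- subject_level(rec)
  expect_equal(s$tf_subject[s$subject_id == "A"], 3L)
  expect_equal(s$tf_subject[s$subject_id == "B"], 0L)
  # all metrics come from the tooth with the larger delta_q
  expect_equal(s$source_tooth[s$subject_id == "A"], "UR1")
  expect_equal(s$area[s$subject_id == "A"], 0.3)
  expect_equal(s$delta_f[s$subject_id == "A"], 0.08)
  expect_error(subject_level(rec[, -3]), "missing column")
})

test_that("Spearman correlations match rank computations and edge cases", {
  s <- tibble::tibble(subject_id = letters[1:6], method = "hull",
                      tf_subject = c(0, 1, 2, 3, 4, 5),
                      area = c(1, 2, 3, 4, 5, 6) / 10,
                      delta_f = c(6, 5, 4, 3, 2, 1) / 10,
                      delta_q = c(0.1, 0.3, 0.2, 0.2, 0.5, 0.6))
  tab <- spearman_table(s)
  expect_equal(tab$rho[tab$metric == "area"], 1)
  expect_equal(tab$rho[tab$metric == "delta_f"], -1)
  # tied fixture agrees with the base implementation's tie handling
  want <- suppressWarnings(cor.test(s$delta_q, s$tf_subject,
                                    method = "spearman"))$estimate
  expect_equal(tab$rho[tab$metric == "delta_q"], unname(want))
  # zero variance reported as undefined
  s0 <- dplyr::mutate(s, delta_q = 0.5)
  expect_true(is.na(spearman_table(s0)$rho[3]))
})

test_that("Mann-Whitney machinery: exact enumeration, ties, Bonferroni", {
  # fully separated 4 vs 4: exact two-sided p = 2 / C(8,4) = 2/70
  res <- fluoroquant:::mw_u_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(res$test, "exact")
  expect_equal(res$u, 0)

  # identical samples: U = n1 n2 / 2, p about 1
  res2 <- fluoroquant:::mw_u_test(rep(c(1, 2, 3), 4), rep(c(1, 2, 3), 4))
  expect_equal(res2$u, 72)
  expect_gt(res2$p_value, 0.9)

  # interval_separation applies the x10 Bonferroni rule and caps at 1
  set.seed(12)
  rec <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:50), method = "hull",
    water_interval = rep(0:4, each = 10),
    tf_subject = 0L,
    delta_q = rnorm(50) + rep(c(0, 0, 0, 0, 3), each = 10),
    area = 0, delta_f = 0)
  sep <- interval_separation(rec, "delta_q")
  expect_equal(nrow(sep$pairs), 10)
  expect_true(all(sep$pairs$p_adj <= 1))
  expect_true(all(sep$pairs$p_adj >= sep$pairs$p_raw))
  expect_equal(sep$pairs$p_adj,
               pmin(1, 10 * sep$pairs$p_raw))
  # the shifted interval separates from every other after correction
  with4 <- sep$pairs$interval_a == 4 | sep$pairs$interval_b == 4
  expect_true(all(sep$pairs$p_adj[with4] < 0.05))
  expect_true(all(sep$pairs$p_adj[!with4] > 0.05))
  # the decision path reports Levene and ANOVA
  expect_true(sep$path %in% c("anova", "nonparametric"))
  expect_true(is.finite(sep$levene_p) && is.finite(sep$anova_p))
  expect_error(interval_separation(rec[rec$water_interval == 0, ], "delta_q"),
               "two non-empty")
})

test_that("ICC: perfect repeats, offset sensitivity, shuffled repeats", {
  set.seed(9)
  base <- rnorm(30, 10, 3)
  # identical repeats with between-subject spread: ICC = 1
  perfect <- tibble::tibble(value_1 = base, value_2 = base)
  expect_equal(icc_repeatability(perfect)$icc_agreement, 1)

  # constant offset lowers absolute agreement below consistency
  off <- tibble::tibble(value_1 = base, value_2 = base + 2)
  r <- icc_repeatability(off)
  expect_lt(r$icc_agreement, r$icc_consistency)
  expect_equal(r$icc_consistency, 1, tolerance = 1e-12)

  # repeats permuted across subjects: no agreement, ICC about 0
  set.seed(10)
  big <- rnorm(200, 10, 3)
  shuf <- tibble::tibble(value_1 = big, value_2 = sample(big))
  expect_lt(abs(icc_repeatability(shuf)$icc_agreement), 0.1)

  # degenerate: all values identical -> undefined
  expect_true(is.na(icc_repeatability(
    tibble::tibble(value_1 = rep(1, 6), value_2 = rep(1, 6)))$icc_agreement))
  expect_error(icc_repeatability(tibble::tibble(value_1 = 1:3, value_2 = 1:3)),
               "5 complete pairs")
})

test_that("ROC: canonical curves, Youden point, AUC equals U/(n1 n2)", {
  # perfectly separating metric
  d <- tibble::tibble(tf_subject = rep(c(0, 5), each = 10),
                      delta_q = c(rnorm(10, 0, 0.01), rnorm(10, 1, 0.01)))
  r <- roc_analysis(d)
  expect_equal(r$auc, 1)
  expect_equal(r$operating_point$sensitivity, 1)
  expect_equal(r$operating_point$specificity, 1)

  # class-independent metric: AUC 1/2 (identical values in both classes)
  d2 <- tibble::tibble(tf_subject = rep(c(0, 5), each = 6),
                       delta_q = rep(c(1, 2, 3), 4))
  expect_equal(roc_analysis(d2)$auc, 0.5)

  # AUC identity with the Mann-Whitney statistic on random fixtures
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    d3 <- tibble::tibble(
      tf_subject = rep(c(5, 0), c(n1, n0)),
      delta_q = round(c(rnorm(n1, 1), rnorm(n0)), sample(0:2, 1)))
    r3 <- roc_analysis(d3)
    u <- suppressWarnings(wilcox.test(d3$delta_q[d3$tf_subject >= 3],
                                      d3$delta_q[d3$tf_subject < 3],
                                      exact = FALSE))$statistic
    expect_equal(r3$auc, unname(u) / (n1 * n0), tolerance = 1e-10)
  }
  expect_error(roc_analysis(tibble::tibble(tf_subject = rep(5, 4),
                                           delta_q = 1:4)), "both classes")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  d <- tibble::tibble(tf_subject = rep(c(0, 4), each = 25),
                      delta_q = c(rnorm(25, 0.3, 0.2), rnorm(25, 0.7, 0.25)))
  r <- roc_analysis(d)
  pr <- pROC::roc(response = d$tf_subject >= 3, predictor = d$delta_q,
                  quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  best <- pROC::coords(pr, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
  expect_equal(r$operating_point$sensitivity, best$sensitivity, tolerance = 1e-10)
  expect_equal(r$operating_point$specificity, best$specificity, tolerance = 1e-10)
})

test_that("dose-response report assembles every table and handles degeneracies", {
  pop <- make_population(population_spec(n_per_interval = 12, seed = 77),
                         render = "metrics")
  rep <- dose_response_report(pop)
  expect_s3_class(rep$descriptives, "tbl_df")
  expect_true(all(c("mean", "sd", "median", "min", "max") %in%
                    names(rep$descriptives)))
  expect_equal(sort(unique(rep$descriptives$water_interval)), 0:4)
  expect_true(all(rep$tf_distribution$tf_group %in% c("0", "1", "2", "3", "4+")))
  expect_s3_class(rep$separation$hull, "fq_separation")
  expect_s3_class(rep$roc$hull, "fq_roc")
  # tidier surfaces
  expect_s3_class(tidy(rep$roc$hull), "tbl_df")
  expect_equal(nrow(glance(rep$roc$hull)), 1)
  expect_s3_class(autoplot(rep$roc$hull), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")

  # single interval: separation skipped with a notice
  single <- pop[pop$water_interval == 2, ]
  expect_message(r1 <- dose_response_report(single), "single water interval")
  expect_null(r1$separation)
  expect_error(dose_response_report(pop[0, ]), "empty")
})
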