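#' Analyze one capture with one or both techniques
#'
#' Validates the masks, locates the gingival point, selects the reference
#' area (blur method) and runs the requested technique(s) on each tooth.
#'
#' @param image An `fq_image`.
#' @param masks The matching `fq_mask_set`.
#' @param method `"hull"`, `"blur"` or `"both"`.
#' @param blur,hull Parameter objects ([blur_params()], [hull_params()]).
#' @param patch_px Reference window side for the blur method.
#' @param max_gap_frac Diastema exclusion threshold (fraction of width).
#' @return Tibble with one row per tooth per method (exclusion rows carry
#'   `NA` metrics and the reason).
#' @export
analyze_image <- function(image, masks, method = c("both", "hull", "blur"),
                          blur = blur_params(), hull = hull_params(),
                          patch_px = 9L, max_gap_frac = 0.05) {
  method <- match.arg(method)
  report <- check_analyzable(masks, max_gap_frac = max_gap_frac,
                             subject_id = image$subject_id)
  if (!report$analyzable) {
    return(tibble(subject_id = image$subject_id,
                  capture_index = image$capture_index,
                  tooth = NA_character_, method = NA_character_,
                  area = NA_real_, delta_f = NA_real_, delta_q = NA_real_,
                  n_lesion_px = NA_integer_, area_unit = NA_character_,
                  excluded = TRUE,
                  exclusion_reason = paste(report$reasons[[1]], collapse = ";")))
  }
  green <- extract_green(image)
  rows <- list()
  reference <- NULL
  if (method %in% c("both", "blur")) {
    gp <- locate_gingival_point(masks)
    reference <- select_reference_area(masks, gp, green, patch_px = patch_px)
  }
  for (tooth in names(masks)) {
    m <- masks[[tooth]]
    if (method %in% c("both", "hull")) {
      res <- analyze_hull_tooth(green, m, hull)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        res$metrics, subject_id = image$subject_id,
        capture_index = image$capture_index, tooth = tooth, .before = 1)
    }
    if (method %in% c("both", "blur")) {
      res <- analyze_blur_tooth(green, m, reference, blur,
                                mm_per_pixel = image$mm_per_pixel)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        res$metrics, subject_id = image$subject_id,
        capture_index = image$capture_index, tooth = tooth, .before = 1)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(excluded = FALSE, exclusion_reason = NA_character_) |>
    dplyr::select(-dplyr::any_of("n_skipped_px"))
}

#' Run configuration
#'
#' A validated bundle of every tunable the pipeline uses; serialized next to
#' the outputs so a run can be reproduced exactly.
#'
#' @param method `"both"`, `"hull"` or `"blur"`.
#' @param blur,hull Parameter objects.
#' @param scheme An [water_interval_scheme()].
#' @param mm_per_pixel Optional physical scale.
#' @param patch_px Reference window side.
#' @param max_gap_frac Diastema threshold as a fraction of image width.
#' @param n_per_interval Subjects per interval for simulation.
#' @param repeat_fraction Share of subjects recaptured.
#' @param seed Master seed.
#' @return A list of class `fq_run_config` with a `hash` field.
#' @export
run_config <- function(method = "both", blur = blur_params(),
                       hull = hull_params(), scheme = water_interval_scheme(),
                       mm_per_pixel = NULL, patch_px = 9L, max_gap_frac = 0.05,
                       n_per_interval = 30L, repeat_fraction = 0.08, seed = 1L) {
  method <- match.arg(method, c("both", "hull", "blur"))
  cfg <- list(method = method, blur = unclass(blur), hull = unclass(hull),
              scheme = unclass(scheme), mm_per_pixel = mm_per_pixel,
              patch_px = as.integer(patch_px), max_gap_frac = max_gap_frac,
              n_per_interval = as.integer(n_per_interval),
              repeat_fraction = repeat_fraction, seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "fq_run_config")
}

write_config <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA, force = TRUE)
}

# CSV with a config-hash comment header; read back with read_metrics_csv().
write_metrics_csv <- function(metrics, path, config) {
  con <- file(path, open = "wb")
  writeLines(sprintf("# fluoroquant_config_hash: %s", config$hash), con)
  readr::write_csv(metrics, con)
  close(con)
  invisible(path)
}

#' Read a metrics CSV written by [run_analyze()]
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_metrics_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Analyze a subject table
#'
#' Reads every capture listed in a subject CSV
#' (`subject_id,water_ppm,tf_ul1,tf_ur1,capture_index,image_path,mask_path`),
#' validates its masks and computes the per-tooth metrics.  Per-subject
#' failures (missing files, unreadable images) are recorded and the run
#' continues; the run fails only when every capture fails.
#'
#' @param subjects Subject tibble or path to the CSV.
#' @param config An [run_config()].
#' @param out_path Optional path for the metrics CSV.
#' @return Tibble of per-tooth metrics joined with the subject columns.
#' @export
run_analyze <- function(subjects, config = run_config(), out_path = NULL) {
  if (is.character(subjects)) {
    base_dir <- dirname(subjects)
    subjects <- readr::read_csv(subjects, show_col_types = FALSE)
    rel <- !grepl("^(/|[A-Za-z]:)", subjects$image_path)
    subjects$image_path[rel] <- file.path(base_dir, subjects$image_path[rel])
    rel <- !grepl("^(/|[A-Za-z]:)", subjects$mask_path)
    subjects$mask_path[rel] <- file.path(base_dir, subjects$mask_path[rel])
  }
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    res <- tryCatch({
      img <- read_image(s$image_path, mm_per_pixel = config$mm_per_pixel,
                        subject_id = s$subject_id,
                        capture_index = s$capture_index)
      msk <- read_mask_set(s$mask_path, img)
      analyze_image(img, msk, method = config$method, blur = blur_params(
                      config$blur$blur_size_px, config$blur$k_sd,
                      config$blur$mask_aware),
                    hull = hull_params(config$hull$threshold_level,
                                       config$hull$opening_radius_px),
                    patch_px = config$patch_px,
                    max_gap_frac = config$max_gap_frac)
    }, error = function(e) {
      warn(sprintf("subject %s capture %s failed: %s",
                   s$subject_id, s$capture_index, conditionMessage(e)))
      tibble(subject_id = s$subject_id, capture_index = s$capture_index,
             tooth = NA_character_, method = NA_character_, area = NA_real_,
             delta_f = NA_real_, delta_q = NA_real_, n_lesion_px = NA_integer_,
             area_unit = NA_character_, excluded = TRUE,
             exclusion_reason = paste0("error: ", conditionMessage(e)))
    })
    rows[[i]] <- dplyr::left_join(
      res, dplyr::select(s, dplyr::any_of(c("subject_id", "capture_index",
                                            "water_ppm", "tf_ul1", "tf_ur1"))),
      by = intersect(c("subject_id", "capture_index"), names(res)))
  }
  metrics <- dplyr::bind_rows(rows)
  if (all(metrics$excluded)) abort("all captures failed analysis")
  if (!is.null(out_path)) write_metrics_csv(metrics, out_path, config)
  metrics
}

# Per-tooth TF attached to the metrics rows (UL1 -> tf_ul1, UR1 -> tf_ur1).
attach_tooth_tf <- function(metrics) {
  dplyr::mutate(metrics, tf = ifelse(.data$tooth == "UL1", .data$tf_ul1,
                                     ifelse(.data$tooth == "UR1", .data$tf_ur1, NA)))
}

#' Compare metrics with the photographic scores
#'
#' Builds the subject-level records from a metrics table (first captures,
#' non-excluded), runs the dose-response report, the repeatability ICC over
#' repeat captures, and writes the report CSVs when `out_dir` is given
#' (`descriptives.csv`, `pairwise_pvalues.csv`, `correlations.csv`,
#' `icc.csv`, `roc_points.csv`, `exclusions.csv`, `report.txt`).
#'
#' @param metrics Metrics tibble from [run_analyze()] (or its CSV path).
#' @param config An [run_config()].
#' @param out_dir Optional output directory.
#' @return List with `report` (an `fq_dose_report`) and `icc` (tibble or
#'   `NULL` when too few repeat pairs exist).
#' @export
run_compare <- function(metrics, config = run_config(), out_dir = NULL) {
  if (is.character(metrics)) metrics <- read_metrics_csv(metrics)
  excl <- metrics |>
    dplyr::filter(.data$excluded) |>
    dplyr::distinct(.data$subject_id, .data$exclusion_reason)
  ok <- metrics |> dplyr::filter(!.data$excluded)
  first <- ok |>
    dplyr::filter(.data$capture_index == 1L) |>
    attach_tooth_tf() |>
    dplyr::mutate(water_interval = assign_interval(
      .data$water_ppm, water_interval_scheme(config$scheme$boundaries)))
  report <- dose_response_report(first)

  icc <- NULL
  reps <- ok |> dplyr::filter(.data$capture_index == 2L)
  if (nrow(reps) > 0) {
    subj1 <- subject_level(attach_tooth_tf(
      ok |> dplyr::filter(.data$capture_index == 1L,
                          .data$subject_id %in% reps$subject_id)))
    subj2 <- subject_level(attach_tooth_tf(
      reps |> dplyr::mutate(capture_index = 1L)))
    paired <- dplyr::inner_join(
      tidyr::pivot_longer(subj1, c("area", "delta_f", "delta_q"),
                          names_to = "metric", values_to = "value_1"),
      tidyr::pivot_longer(subj2, c("area", "delta_f", "delta_q"),
                          names_to = "metric", values_to = "value_2") |>
        dplyr::select("subject_id", "method", "metric", "value_2"),
      by = c("subject_id", "method", "metric"))
    n_pairs <- paired |> dplyr::count(.data$method, .data$metric)
    if (all(n_pairs$n >= 5)) icc <- icc_repeatability(paired)
    else inform("fewer than 5 repeat pairs: ICC skipped")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, out_dir)
    readr::write_csv(report$descriptives, file.path(out_dir, "descriptives.csv"))
    if (!is.null(report$separation)) {
      pair_tbl <- purrr::imap_dfr(report$separation, function(s, mm) {
        dplyr::mutate(tidy(s), method = mm, path = s$path,
                      levene_p = s$levene_p, .before = 1)
      })
      readr::write_csv(pair_tbl, file.path(out_dir, "pairwise_pvalues.csv"))
    }
    readr::write_csv(report$correlations, file.path(out_dir, "correlations.csv"))
    if (!is.null(icc)) readr::write_csv(icc, file.path(out_dir, "icc.csv"))
    roc_tbl <- purrr::imap_dfr(report$roc, function(r, mm) {
      if (is.null(r)) return(tibble())
      dplyr::mutate(tidy(r), method = mm, .before = 1)
    })
    if (ncol(roc_tbl) == 0)
      roc_tbl <- tibble(method = character(), threshold = double(),
                        sensitivity = double(), specificity = double())
    readr::write_csv(roc_tbl, file.path(out_dir, "roc_points.csv"))
    readr::write_csv(excl, file.path(out_dir, "exclusions.csv"))
    writeLines(report_text(report, icc, excl, config),
               file.path(out_dir, "report.txt"))
  }
  list(report = report, icc = icc, exclusions = excl)
}

report_text <- function(report, icc, excl, config) {
  out <- c(sprintf("fluoroquant run (config %s)", config$hash),
           sprintf("subjects analyzed: %d; excluded: %d",
                   dplyr::n_distinct(report$subjects$subject_id), nrow(excl)),
           "", "Spearman correlations vs photographic TF score:")
  ct <- report$correlations
  out <- c(out, sprintf("  %-5s %-8s rho = %6.3f  (p = %.3g, n = %d)",
                        ct$method, ct$metric, ct$rho, ct$p_value, ct$n))
  for (mm in names(report$roc)) {
    r <- report$roc[[mm]]
    if (is.null(r)) next
    op <- r$operating_point
    out <- c(out, "", sprintf(
      "ROC (%s, delta_q, TF >= %d): AUC %.4f; sens %.2f%%, spec %.2f%% at threshold %.4g",
      mm, r$tf_boundary, r$auc, 100 * op$sensitivity, 100 * op$specificity,
      op$threshold))
  }
  if (!is.null(report$separation)) {
    for (mm in names(report$separation)) {
      s <- report$separation[[mm]]
      sig <- sum(s$pairs$p_adj < 0.05, na.rm = TRUE)
      out <- c(out, sprintf(
        "Interval separation (%s, delta_q): %d/10 pairs significant after Bonferroni (path: %s)",
        mm, sig, s$path))
    }
  }
  if (!is.null(icc)) {
    out <- c(out, "", "Repeatability ICC (absolute agreement):")
    out <- c(out, sprintf("  %-5s %-8s ICC = %.3f (n = %d)",
                          icc$method, icc$metric, icc$icc_agreement, icc$n))
  }
  out
}

#' End-to-end run: simulate, analyze, compare
#'
#' Generates a synthetic population, analyzes every capture with both
#' techniques and produces the full statistical report.  A fixed seed
#' reproduces the output directory byte for byte (no timestamps are
#' written).
#'
#' @param config An [run_config()].
#' @param out_dir Output directory; receives `data/` (images, masks,
#'   subjects.csv), `metrics.csv` and `report/`.
#' @return The [run_compare()] result, invisibly.
#' @export
run_end_to_end <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, out_dir)
  pop_spec <- population_spec(
    n_per_interval = config$n_per_interval,
    repeat_fraction = config$repeat_fraction, seed = config$seed,
    phantom = phantom_spec(mm_per_pixel = config$mm_per_pixel,
                           seed = config$seed))
  pop <- make_population(pop_spec, render = "images",
                         out_dir = file.path(out_dir, "data"))
  metrics <- run_analyze(file.path(out_dir, "data", "subjects.csv"), config,
                         out_path = file.path(out_dir, "metrics.csv"))
  metrics <- dplyr::left_join(
    metrics,
    dplyr::distinct(pop$subjects, .data$subject_id, .data$water_interval),
    by = "subject_id")
  invisible(run_compare(metrics, config, out_dir = file.path(out_dir, "report")))
}
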