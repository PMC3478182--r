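#' Specification of a synthetic tooth phantom
#'
#' Phantoms emulate a green-channel-dominant fluorescence capture of the two
#' maxillary central incisors: two rounded (superellipse) incisor outlines
#' over a dark background, a smooth concave sound-enamel brightness surface
#' (dome plus cervico-incisal gradient), and diffuse fluorosis lesions built
#' by thresholding a smooth correlated random field so the lesion can extend
#' across the whole surface, as diffuse hypomineralization does.  Lesioned
#' pixels have their brightness multiplied by `1 - depth`.
#'
#' @param image_size `c(height, width)` in pixels (default `c(120, 160)`).
#' @param diastema_px Horizontal gap between the two incisors (default 2).
#' @param base_brightness Mean sound green level (default 180).
#' @param gradient_amplitude Amplitude of the smooth cervico-incisal
#'   brightness gradient plus dome falloff (default 12 brightness units).
#' @param lesion_area_fraction Target lesioned fraction of each tooth, in
#'   `[0, 1]`; length 1 or 2 (per tooth `UR1`, `UL1`).
#' @param lesion_depth_fraction Target fractional fluorescence loss inside
#'   the lesion, in `[0, 1)`; length 1 or 2.
#' @param lesion_texture_scale Correlation length (pixels) of the diffuse
#'   field (default 7).
#' @param confounders Character subset of
#'   `c("stain_patch", "demarcated_opacity", "missing_tooth")`.
#' @param noise_sd Additive Gaussian noise SD in brightness units (default 2).
#' @param mm_per_pixel Optional physical scale propagated to the image.
#' @param quantize Round the image to 8-bit integers (default `TRUE`).
#'   Continuous intensities (`FALSE`) are useful for validating the
#'   reconstruction algorithms in isolation from quantization noise.
#' @param seed Integer; fixes every random draw.
#' @return A list of class `fq_phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(120L, 160L), diastema_px = 2L,
                         base_brightness = 180, gradient_amplitude = 12,
                         lesion_area_fraction = 0, lesion_depth_fraction = 0,
                         lesion_texture_scale = 7L, confounders = character(),
                         noise_sd = 2, mm_per_pixel = NULL,
                         quantize = TRUE, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 20L))
  lesion_area_fraction <- rep_len(lesion_area_fraction, 2L)
  lesion_depth_fraction <- rep_len(lesion_depth_fraction, 2L)
  if (any(lesion_area_fraction < 0 | lesion_area_fraction > 1))
    abort("`lesion_area_fraction` must lie in [0, 1]")
  if (any(lesion_depth_fraction < 0 | lesion_depth_fraction >= 1))
    abort("`lesion_depth_fraction` must lie in [0, 1)")
  if (length(confounders))
    confounders <- match.arg(confounders,
      c("stain_patch", "demarcated_opacity", "missing_tooth"), several.ok = TRUE)
  structure(list(image_size = as.integer(image_size),
                 diastema_px = as.integer(diastema_px),
                 base_brightness = base_brightness,
                 gradient_amplitude = gradient_amplitude,
                 lesion_area_fraction = lesion_area_fraction,
                 lesion_depth_fraction = lesion_depth_fraction,
                 lesion_texture_scale = as.integer(lesion_texture_scale),
                 confounders = confounders, noise_sd = noise_sd,
                 mm_per_pixel = mm_per_pixel,
                 quantize = isTRUE(quantize), seed = as.integer(seed)),
            class = "fq_phantom_spec")
}

# Smooth correlated field: white noise box-smoothed three times (approximately
# Gaussian) at the requested correlation length, then standardized.
correlated_field <- function(h, w, scale) {
  f <- matrix(rnorm(h * w), h, w)
  s <- max(3L, scale); if (s %% 2L == 0L) s <- s + 1L
  lo <- -((s - 1L) %/% 2L); hi <- s %/% 2L
  ones <- sat(matrix(1, h, w))
  for (k in 1:3) f <- window_sum(sat(f), h, w, lo, hi) / window_sum(ones, h, w, lo, hi)
  (f - mean(f)) / sd(f)
}

superellipse_q <- function(h, w, cx, cy, a, b) {
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(seq_len(h), h, w)
  sqrt(((x - cx) / a)^4 + ((y - cy) / b)^4)
}

#' Generate a synthetic tooth phantom
#'
#' @param spec An [phantom_spec()].
#' @return A list of class `fq_phantom`: `image` (an `fq_image`), `masks`
#'   (an `fq_mask_set`), `truth` (tibble with per-tooth realized
#'   `area_fraction` and `mean_depth`, measured on the generated field, not
#'   the targets), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "fq_phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    tw <- 0.27 * w; th <- 0.55 * h
    cy <- 0.52 * h
    cx_r <- w / 2 - spec$diastema_px / 2 - tw / 2   # UR1 (subject's right = image left)
    cx_l <- w / 2 + spec$diastema_px / 2 + tw / 2
    geom <- list(UR1 = cx_r, UL1 = cx_l)

    g <- matrix(0, h, w)
    masks <- list()
    truth <- list()
    for (i in seq_along(geom)) {
      tooth <- names(geom)[i]
      q <- superellipse_q(h, w, geom[[i]], cy, tw / 2, th / 2)
      m <- q <= 1
      masks[[tooth]] <- m
      # concave sound surface: dome (negated convex squared-L4 radius) plus an
      # affine cervico-incisal gradient (gingival/top brighter)
      yy <- matrix(seq_len(h), h, w)
      dome <- spec$base_brightness - 0.6 * spec$gradient_amplitude * q^2 +
        0.4 * spec$gradient_amplitude * (0.5 - (yy - (cy - th / 2)) / th)
      sound <- dome
      # diffuse lesion: quantile-thresholded correlated field
      af <- spec$lesion_area_fraction[i]
      dp <- spec$lesion_depth_fraction[i]
      lesion <- matrix(FALSE, h, w)
      if (af > 0 && dp > 0) {
        f <- correlated_field(h, w, spec$lesion_texture_scale)
        cut <- quantile(f[m], probs = 1 - af, names = FALSE)
        lesion <- m & f > cut
      }
      val <- ifelse(lesion, sound * (1 - dp), sound)
      g[m] <- val[m]
      n_lesion <- sum(lesion & m)
      truth[[tooth]] <- tibble(
        tooth = tooth,
        area_fraction = n_lesion / sum(m),
        mean_depth = if (n_lesion > 0) dp else 0,
        n_lesion_px = as.integer(n_lesion), n_mask_px = as.integer(sum(m)))
    }
    mask_union <- masks[["UR1"]] | masks[["UL1"]]

    # optional confounders
    if ("stain_patch" %in% spec$confounders) {
      m <- masks[["UR1"]]
      cenx <- cx_r + runif(1, -0.15, 0.15) * tw
      ceny <- cy + runif(1, -0.15, 0.15) * th
      patch <- superellipse_q(h, w, cenx, ceny, 0.14 * tw, 0.14 * th) <= 1 & m
      g[patch] <- g[patch] * 0.5   # stain: markedly deeper fluorescence loss
    }
    if ("demarcated_opacity" %in% spec$confounders) {
      m <- masks[["UL1"]]
      x0 <- round(cx_l - 0.15 * tw); y0 <- round(cy - 0.2 * th)
      rect <- matrix(FALSE, h, w)
      rect[y0:(y0 + round(0.18 * th)), x0:(x0 + round(0.2 * tw))] <- TRUE
      rect <- rect & m
      g[rect] <- g[rect] * 0.7     # sharp-edged loss region
    }
    if (spec$noise_sd > 0) g <- g + rnorm(h * w, sd = spec$noise_sd) * mask_union
    g <- pmin(pmax(g, 0), 255)
    if (spec$quantize) g <- round(g)

    if ("missing_tooth" %in% spec$confounders) {
      masks[["UL1"]] <- NULL
      truth[["UL1"]] <- NULL
    }

    r <- if (spec$quantize) round(0.35 * g) else 0.35 * g
    b <- if (spec$quantize) round(0.22 * g) else 0.22 * g
    px <- array(0, dim = c(h, w, 3))
    px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
    image <- if (spec$quantize) {
      fluorescence_image(px, mm_per_pixel = spec$mm_per_pixel)
    } else {
      # continuous-intensity variant bypasses the 8-bit validator
      structure(list(pixels = px, height = h, width = w,
                     mm_per_pixel = spec$mm_per_pixel,
                     subject_id = NA_character_, capture_index = 1L),
                class = "fq_image")
    }
    structure(list(image = image, masks = mask_set(masks),
                   truth = dplyr::bind_rows(truth), spec = spec),
              class = "fq_phantom")
  })
}

#' Simulate a repeat capture
#'
#' Applies a small integer translation, a global illumination gain and fresh
#' additive noise to an existing capture; masks are re-derived by the same
#' translation.  Emulates the repeat fluorescence images taken to assess
#' repeatability.
#'
#' @param image An `fq_image`.
#' @param masks The matching `fq_mask_set`.
#' @param translation Integer `c(dy, dx)` pixel shift.
#' @param gain Multiplicative illumination factor (default 1).
#' @param noise_sd Additive noise SD (default 2).
#' @param seed Integer seed for the noise.
#' @return List with translated `image` (`capture_index = 2`) and `masks`.
#' @export
make_repeat <- function(image, masks, translation = c(0L, 0L), gain = 1,
                        noise_sd = 2, seed = 1L) {
  stopifnot(inherits(image, "fq_image"), inherits(masks, "fq_mask_set"))
  dy <- as.integer(translation[1]); dx <- as.integer(translation[2])
  h <- image$height; w <- image$width
  shift1 <- function(m, fill = 0) {
    out <- matrix(fill, h, w)
    r_src <- max(1, 1 - dy):min(h, h - dy)
    c_src <- max(1, 1 - dx):min(w, w - dx)
    out[r_src + dy, c_src + dx] <- m[r_src, c_src]
    out
  }
  new_masks <- purrr::map(unclass(masks), function(m) {
    if (sum(shift1(m, FALSE)) != sum(m))
      abort("translation pushes a tooth outside the frame")
    shift1(m, FALSE) > 0
  })
  mask_union <- Reduce(`|`, new_masks)
  with_seed(seed, {
    px <- array(0, dim = c(h, w, 3))
    for (k in 1:3) {
      ch <- shift1(image$pixels[, , k]) * gain
      if (noise_sd > 0) ch <- ch + rnorm(h * w, sd = noise_sd) * mask_union
      px[, , k] <- round(pmin(pmax(ch, 0), 255))
    }
    list(image = fluorescence_image(px, mm_per_pixel = image$mm_per_pixel,
                                    subject_id = image$subject_id,
                                    capture_index = image$capture_index + 1L),
         masks = mask_set(new_masks))
  })
}

#' Severity-to-lesion map
#'
#' Monotone map from a Thylstrup-Fejerskov (TF) score to the generator's
#' `(area_fraction, depth_fraction)` pair.  Anchored at TF 0 (sound), with
#' linear interpolation between anchors and a plateau from TF 5 up; the
#' magnitudes sit inside the observed ranges of the hull metrics in the
#' study population.
#'
#' @param tf Integer vector of TF scores (0-9).
#' @return Tibble with columns `area_fraction`, `depth_fraction`.
#' @export
tf_to_lesion <- function(tf) {
  anchors_tf <- c(0, 1, 3, 5)
  anchors_area <- c(0, 0.10, 0.35, 0.70)
  anchors_depth <- c(0, 0.04, 0.08, 0.15)
  tibble(
    area_fraction = stats::approx(anchors_tf, anchors_area, xout = pmin(tf, 5),
                                  method = "linear", rule = 2)$y,
    depth_fraction = stats::approx(anchors_tf, anchors_depth, xout = pmin(tf, 5),
                                   method = "linear", rule = 2)$y)
}

#' Specification of a synthetic dose-response population
#'
#' Calibrated to the study population: five cooking-water fluoride intervals
#' with approximately equal subject counts, and per-interval TF-score
#' distributions matching the published interval means and SDs
#' (0.70/0.93, 1.01/1.02, 1.28/1.30, 1.65/1.47, 2.30/1.90).  TF per tooth is
#' a discretized truncated normal clipped to 0-7; the two incisors share a
#' latent correlation.
#'
#' @param n_per_interval Subjects per water interval (default 30; `>= 2`).
#' @param interval_tf_means,interval_tf_sds Length-5 TF distribution
#'   parameters per interval.
#' @param tooth_tf_correlation Latent correlation between the two incisors'
#'   TF scores (default 0.8).
#' @param tf_map Function mapping TF to lesion parameters
#'   (default [tf_to_lesion()]); must be monotone non-decreasing.
#' @param repeat_fraction Share of subjects given a second capture
#'   (default 0.08, the study's 44/553).
#' @param seed Integer master seed.
#' @param phantom Template [phantom_spec()] providing image geometry, noise
#'   and brightness settings for rendered subjects.
#' @return A list of class `fq_population_spec`.
#' @export
population_spec <- function(n_per_interval = 30L,
                            interval_tf_means = c(0.70, 1.01, 1.28, 1.65, 2.30),
                            interval_tf_sds = c(0.93, 1.02, 1.30, 1.47, 1.90),
                            tooth_tf_correlation = 0.8,
                            tf_map = tf_to_lesion,
                            repeat_fraction = 0.08,
                            seed = 1L,
                            phantom = phantom_spec()) {
  if (n_per_interval < 2L) abort("`n_per_interval` must be >= 2")
  stopifnot(length(interval_tf_means) == 5L, length(interval_tf_sds) == 5L)
  structure(list(n_per_interval = as.integer(n_per_interval),
                 interval_tf_means = interval_tf_means,
                 interval_tf_sds = interval_tf_sds,
                 tooth_tf_correlation = tooth_tf_correlation,
                 tf_map = tf_map, repeat_fraction = repeat_fraction,
                 seed = as.integer(seed), phantom = phantom),
            class = "fq_population_spec")
}

INTERVAL_PPM_LO <- c(0.01, 0.20, 0.60, 0.90, 1.60)
INTERVAL_PPM_HI <- c(0.19, 0.59, 0.89, 1.59, 2.50)

#' Generate a synthetic dose-response population
#'
#' Draws per-subject cooking-water fluoride (uniform within its interval),
#' per-tooth TF scores from the interval's discretized truncated normal, and
#' lesion parameters through the severity map.
#'
#' With `render = "images"` every capture is rendered as a phantom and
#' (optionally) written to `out_dir` together with its mask PNG and the
#' subject CSV (`subject_id,water_ppm,tf_ul1,tf_ur1,capture_index,image_path,mask_path`).
#' With `render = "metrics"` no images are rendered; instead per-tooth hull
#' metrics are drawn from the generator's measurement model (ground-truth
#' lesion parameters plus the analysis-scale observation noise), which is the
#' statistical surrogate used for large replicate studies of the inference
#' machinery.
#'
#' @param spec An [population_spec()].
#' @param render `"images"` or `"metrics"`.
#' @param out_dir Directory for rendered output (`NULL` keeps phantoms in
#'   memory).
#' @return For `render = "metrics"`: a tibble, one row per subject x tooth,
#'   with water data, TF scores, ground truth and observed hull metrics.
#'   For `render = "images"`: list with `subjects` (tibble; one row per
#'   capture) and `phantoms` (list, when `out_dir` is `NULL`).
#' @export
make_population <- function(spec = population_spec(),
                            render = c("metrics", "images"), out_dir = NULL) {
  stopifnot(inherits(spec, "fq_population_spec"))
  render <- match.arg(render)
  with_seed(spec$seed, {
    n <- spec$n_per_interval
    intervals <- rep(0:4, each = n)
    n_tot <- length(intervals)
    ppm <- runif(n_tot, INTERVAL_PPM_LO[intervals + 1], INTERVAL_PPM_HI[intervals + 1])
    mu <- spec$interval_tf_means[intervals + 1]
    sdv <- spec$interval_tf_sds[intervals + 1]
    z1 <- rnorm(n_tot)
    z2 <- spec$tooth_tf_correlation * z1 +
      sqrt(1 - spec$tooth_tf_correlation^2) * rnorm(n_tot)
    tf_ur1 <- pmin(7L, pmax(0L, as.integer(round(mu + sdv * z1))))
    tf_ul1 <- pmin(7L, pmax(0L, as.integer(round(mu + sdv * z2))))
    subjects <- tibble(
      subject_id = sprintf("S%04d", seq_len(n_tot)),
      water_ppm = ppm, water_interval = intervals,
      tf_ur1 = tf_ur1, tf_ul1 = tf_ul1)

    long <- subjects |>
      tidyr::pivot_longer(c("tf_ur1", "tf_ul1"), names_to = "tooth",
                          names_prefix = "tf_", values_to = "tf") |>
      dplyr::mutate(tooth = toupper(.data$tooth))
    lesion <- spec$tf_map(long$tf)
    long$area_true <- lesion$area_fraction
    long$depth_true <- lesion$depth_fraction

    if (render == "metrics") {
      # measurement model for the hull metrics, calibrated against the image
      # pipeline's measured error on rendered phantoms under the default
      # conditions (noise SD 2, 8-bit, threshold 5, opening radius 1):
      # a severity-dependent bias (noise floor at zero severity from residual
      # supra-threshold loss, mild underestimation at high severity from
      # hull-edge effects) plus additive observation noise
      nl <- nrow(long)
      area_obs <- pmin(1, pmax(0, long$area_true + 0.02 - 0.06 * long$area_true +
                                 rnorm(nl, sd = 0.010)))
      depth_obs <- pmax(0, long$depth_true + 0.032 - 0.27 * long$depth_true +
                          rnorm(nl, sd = 0.003))
      out <- long |>
        dplyr::mutate(method = "hull", area = area_obs, delta_f = depth_obs,
                      delta_q = area_obs * depth_obs, capture_index = 1L)
      return(out)
    }

    n_rep <- ceiling(spec$repeat_fraction * n_tot)
    repeat_ids <- if (n_rep > 0) sample(subjects$subject_id, n_rep) else character()

    if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list(); phantoms <- list()
    for (i in seq_len(n_tot)) {
      sid <- subjects$subject_id[i]
      les <- long[long$subject_id == sid, ]
      les <- les[match(c("UR1", "UL1"), les$tooth), ]
      ph_spec <- spec$phantom
      ph_spec$lesion_area_fraction <- les$area_true
      ph_spec$lesion_depth_fraction <- les$depth_true
      ph_spec$seed <- derive_seed(spec$seed, i)
      ph <- make_phantom(ph_spec)
      ph$image$subject_id <- sid
      captures <- list(list(image = ph$image, masks = ph$masks, capture_index = 1L))
      if (sid %in% repeat_ids) {
        rep_seed <- derive_seed(spec$seed, i + n_tot)
        jitter <- with_seed(rep_seed, list(
          translation = sample(-3:3, 2, replace = TRUE),
          gain = runif(1, 0.97, 1.05)))
        rep_cap <- make_repeat(ph$image, ph$masks,
                               translation = jitter$translation,
                               gain = jitter$gain,
                               noise_sd = spec$phantom$noise_sd,
                               seed = derive_seed(spec$seed, i + 2L * n_tot))
        captures[[2]] <- list(image = rep_cap$image, masks = rep_cap$masks,
                              capture_index = 2L)
      }
      for (cap in captures) {
        img_path <- mask_path <- NA_character_
        if (!is.null(out_dir)) {
          # stored relative to the CSV so a run directory is relocatable
          # (and reruns are byte-identical); run_analyze() resolves them
          img_path <- sprintf("%s_c%d.png", sid, cap$capture_index)
          mask_path <- sprintf("%s_c%d_mask.png", sid, cap$capture_index)
          write_image(cap$image, file.path(out_dir, img_path))
          write_mask_set(cap$masks, file.path(out_dir, mask_path))
        }
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = sid, water_ppm = subjects$water_ppm[i],
          water_interval = subjects$water_interval[i],
          tf_ul1 = subjects$tf_ul1[i], tf_ur1 = subjects$tf_ur1[i],
          capture_index = cap$capture_index,
          image_path = img_path, mask_path = mask_path)
      }
      phantoms[[sid]] <- list(phantom = ph, captures = captures)
    }
    subj_tbl <- dplyr::bind_rows(rows)
    if (!is.null(out_dir)) {
      csv <- subj_tbl |>
        dplyr::select("subject_id", "water_ppm", "tf_ul1", "tf_ur1",
                      "capture_index", "image_path", "mask_path")
      readr::write_csv(csv, file.path(out_dir, "subjects.csv"))
    }
    list(subjects = subj_tbl, truth = long,
         phantoms = if (is.null(out_dir)) phantoms else NULL)
  })
}
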