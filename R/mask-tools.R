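#' Mask analyzability check (exclusion rules)
#'
#' A capture can only be analyzed when both central incisors have masks and
#' the two incisors are not separated by a large diastema.  Subjects failing
#' either rule are excluded from downstream statistics (but retained in output
#' tables with their reason, for auditability).
#'
#' @param masks An [mask_set()].
#' @param max_gap Maximum tolerated horizontal gap (pixels) between the two
#'   masks' bounding boxes.  Defaults to `max_gap_frac` of the image width.
#' @param max_gap_frac Fraction of image width used when `max_gap` is `NULL`.
#' @param subject_id Carried into the report.
#' @return A one-row tibble with columns `subject_id`, `analyzable`,
#'   `reasons` (list column, values among `missing_mask`, `large_diastema`)
#'   and `diastema_gap_px`.
#' @export
check_analyzable <- function(masks, max_gap = NULL, max_gap_frac = 0.05,
                             subject_id = NA_character_) {
  stopifnot(inherits(masks, "fq_mask_set"))
  reasons <- character()
  gap <- NA_real_
  if (length(masks) < 2L) {
    reasons <- c(reasons, "missing_mask")
  } else {
    width <- ncol(masks[[1]])
    if (is.null(max_gap)) max_gap <- max_gap_frac * width
    boxes <- purrr::map(masks, bbox)
    boxes <- boxes[order(purrr::map_dbl(boxes, "xmin"))]
    gap <- max(0, boxes[[2]]$xmin - boxes[[1]]$xmax - 1)
    if (gap > max_gap) reasons <- c(reasons, "large_diastema")
  }
  tibble(subject_id = subject_id,
         analyzable = length(reasons) == 0L,
         reasons = list(reasons),
         diastema_gap_px = gap)
}

bbox <- function(m) {
  rc <- which(m, arr.ind = TRUE)
  list(ymin = min(rc[, 1]), ymax = max(rc[, 1]),
       xmin = min(rc[, 2]), xmax = max(rc[, 2]))
}

mask_centroid <- function(m) {
  rc <- which(m, arr.ind = TRUE)
  c(x = mean(rc[, 2]), y = mean(rc[, 1]))
}

#' Locate the gingival triangulation point
#'
#' The reference-area selection is anchored at a point on the gingival tissue
#' between the two incisors, found by triangulation from the masks under the
#' assumption that gingiva lies above the teeth (image top): the point sits at
#' the horizontal midpoint of the two mask centroids, offset above the higher
#' of the two mask top edges by a fraction of the mean mask height, clamped to
#' the image.
#'
#' @inheritParams check_analyzable
#' @param offset_frac Fraction of the mean mask height by which the point is
#'   raised above the higher top edge (default 0.25).
#' @return Named numeric `c(x, y)` in pixel coordinates (column, row).
#' @export
locate_gingival_point <- function(masks, offset_frac = 0.25) {
  stopifnot(inherits(masks, "fq_mask_set"))
  if (length(masks) < 2L)
    abort("gingival point needs both incisor masks; exclude this subject")
  cents <- purrr::map(masks, mask_centroid)
  boxes <- purrr::map(masks, bbox)
  tops <- purrr::map_dbl(boxes, "ymin")
  heights <- purrr::map_dbl(boxes, ~ .x$ymax - .x$ymin + 1)
  y <- min(tops) - offset_frac * mean(heights)
  c(x = mean(purrr::map_dbl(cents, "x")), y = max(1, y))
}

#' Automatic reference-area selection
#'
#' For each tooth, casts the segment from the gingival point through the tooth
#' centroid into the incisal half of the mask and picks the square window
#' centred on that segment with the brightest median green value (a bright
#' window is sound enamel; lesions are dark, so the objective avoids them).
#' Ties are broken towards the smallest (row, column) centre.  The returned
#' reference area is the union of the per-tooth windows.
#'
#' @inheritParams check_analyzable
#' @param gingival_point From [locate_gingival_point()].
#' @param green An [green_image()].
#' @param patch_px Odd side length of the square window (pixels, `>= 3`;
#'   default 9).
#' @return An object of class `fq_reference`: list with `pixels` (logical
#'   matrix), `centroid`, `source` and the per-tooth window centres.
#' @export
select_reference_area <- function(masks, gingival_point, green, patch_px = 9L) {
  stopifnot(inherits(masks, "fq_mask_set"), inherits(green, "fq_green"))
  patch_px <- as.integer(patch_px)
  if (patch_px < 3L || patch_px %% 2L == 0L)
    abort("`patch_px` must be an odd integer >= 3")
  if (length(masks) < 2L)
    abort("reference selection needs both incisor masks; exclude this subject")
  half <- patch_px %/% 2L
  g <- green$values
  ref <- matrix(FALSE, nrow(g), ncol(g))
  centres <- list()
  for (tooth in names(masks)) {
    m <- masks[[tooth]]
    cen <- mask_centroid(m)
    box <- bbox(m)
    mid_row <- (box$ymin + box$ymax) / 2
    # walk the ray gingival point -> centroid, extended to the mask bottom
    dir <- c(cen["x"] - gingival_point["x"], cen["y"] - gingival_point["y"])
    if (all(abs(dir) < 1e-9)) dir <- c(0, 1)
    dir <- dir / sqrt(sum(dir^2))
    t_max <- sqrt(nrow(g)^2 + ncol(g)^2)
    ts <- seq(0, t_max, by = 0.5)
    px <- unique(round(cbind(gingival_point["x"] + ts * dir[1],
                             gingival_point["y"] + ts * dir[2])))
    keep <- px[, 1] >= 1 & px[, 1] <= ncol(g) & px[, 2] >= 1 & px[, 2] <= nrow(g)
    px <- px[keep, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(px))) {
      cx <- px[i, 1]; cy <- px[i, 2]
      if (cy < mid_row) next                      # incisal half only
      if (cy - half < 1 || cy + half > nrow(g) ||
          cx - half < 1 || cx + half > ncol(g)) next
      win_m <- m[(cy - half):(cy + half), (cx - half):(cx + half)]
      if (!all(win_m)) next                       # window must sit inside the mask
      score <- median(g[(cy - half):(cy + half), (cx - half):(cx + half)])
      if (is.null(best) || score > best$score ||
          (score == best$score && (cy < best$cy || (cy == best$cy && cx < best$cx))))
        best <- list(score = score, cx = cx, cy = cy)
    }
    if (is.null(best))
      abort(sprintf(
        "no %d x %d reference window fits inside the %s mask; try a smaller `patch_px`",
        patch_px, patch_px, tooth))
    ref[(best$cy - half):(best$cy + half), (best$cx - half):(best$cx + half)] <- TRUE
    centres[[tooth]] <- c(x = best$cx, y = best$cy)
  }
  rc <- which(ref, arr.ind = TRUE)
  structure(list(pixels = ref,
                 centroid = c(x = mean(rc[, 2]), y = mean(rc[, 1])),
                 source = "auto_triangulation",
                 window_centres = centres,
                 patch_px = patch_px),
            class = "fq_reference")
}
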