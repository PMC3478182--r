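#' Parameters for the blur (unsharp-mask) technique
#'
#' The technique replaces each pixel by the mean of a surrounding window
#' ("blur effect"), then subtracts, so the blurred image acts as the local
#' sound-enamel estimate.  The optimum published settings are a 30-pixel blur
#' with lesion pixels selected 2 standard deviations beyond the base level.
#'
#' @param blur_size_px Side of the square mean-filter window (default 30).
#'   For even sizes the extra row/column of the window falls right/down.
#' @param k_sd Number of base-level standard deviations a pixel's loss must
#'   exceed to be selected as lesion (default 2).
#' @param mask_aware Exclude out-of-mask pixels from window averages,
#'   renormalizing by the in-mask count (default `TRUE`).  The naive variant
#'   averages the raw window including background.
#' @return A list of class `fq_blur_params`.
#' @export
blur_params <- function(blur_size_px = 30L, k_sd = 2, mask_aware = TRUE) {
  blur_size_px <- as.integer(blur_size_px)
  if (blur_size_px < 1L) abort("`blur_size_px` must be >= 1")
  if (k_sd < 0) abort("`k_sd` must be >= 0")
  structure(list(blur_size_px = blur_size_px, k_sd = k_sd,
                 mask_aware = isTRUE(mask_aware)),
            class = "fq_blur_params")
}

# Summed-area table with a zero top/left guard row/column.
sat <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# Window sums over rows r+lo..r+hi, cols c+lo..c+hi (clamped to the image)
# for every pixel at once, from a summed-area table.
window_sum <- function(S, h, w, lo, hi) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(rep(seq_len(w), each = h), h, w)
  r0 <- pmax(r + lo, 1L); r1 <- pmin(r + hi, h)
  c0 <- pmax(c + lo, 1L); c1 <- pmin(c + hi, w)
  idx <- function(rr, cc) (cc) * (h + 1L) + rr + 1L  # into S (h+1 x w+1), 1-based
  matrix(S[idx(r1, c1)] - S[idx(r0 - 1L, c1)] - S[idx(r1, c0 - 1L)] +
           S[idx(r0 - 1L, c0 - 1L)], h, w)
}

#' Mask-aware mean blur
#'
#' Each in-mask pixel is replaced by the mean of the window around it; with
#' `mask_aware = TRUE` out-of-mask pixels are excluded and the average is
#' renormalized by the in-mask count, so the dark background cannot bleed
#' spurious "loss" into the tooth outline.  Output is zero outside the mask.
#'
#' @param green An [green_image()].
#' @param mask Logical matrix (single tooth mask).
#' @param params An [blur_params()].
#' @return An `fq_green` holding the (real-valued) blurred estimate.
#' @export
mean_blur <- function(green, mask, params = blur_params()) {
  stopifnot(inherits(green, "fq_green"), inherits(params, "fq_blur_params"))
  mask <- mask > 0
  if (!any(mask)) abort("mask is empty")
  g <- green$values
  h <- nrow(g); w <- ncol(g)
  s <- params$blur_size_px
  lo <- -((s - 1L) %/% 2L); hi <- s %/% 2L
  if (params$mask_aware) {
    num <- window_sum(sat(g * mask), h, w, lo, hi)
    den <- window_sum(sat(mask * 1), h, w, lo, hi)
  } else {
    num <- window_sum(sat(g), h, w, lo, hi)
    den <- window_sum(sat(matrix(1, h, w)), h, w, lo, hi)
  }
  if (any(den[mask] == 0))
    abort("blur window contains no countable pixel inside the mask")
  out <- matrix(0, h, w)
  out[mask] <- num[mask] / den[mask]
  green_image(pmin(pmax(out, 0), 255), provenance = green$provenance)
}

#' Unsharp-mask subtraction
#'
#' Subtracting the capture from its blurred copy leaves the areas darker than
#' their local sound estimate, i.e. the candidate fluorosis.  Loss is clamped
#' at zero (pixels brighter than the blur are not negative fluorosis) and is
#' zero outside the mask.
#'
#' @param green Original green channel.
#' @param blurred Result of [mean_blur()].
#' @param mask Logical matrix.
#' @return An unthresholded [loss_map()] tagged `"blur"`.
#' @export
unsharp_difference <- function(green, blurred, mask) {
  stopifnot(inherits(green, "fq_green"), inherits(blurred, "fq_green"))
  if (!identical(dim(green$values), dim(blurred$values)))
    abort("image and blur dimensions differ")
  mask <- mask > 0
  loss <- pmax(blurred$values - green$values, 0)
  loss[!mask] <- 0
  loss_map(loss, threshold_applied = FALSE, method_tag = "blur")
}

#' Lesion pixel selection at k standard deviations from the base level
#'
#' The base level is the mean and SD of the loss map over the automatically
#' selected reference area; lesion pixels are the in-mask pixels whose loss
#' exceeds `mean + k_sd * SD`.  When the reference SD is exactly zero the
#' degenerate rule `loss > mean` applies.
#'
#' @param loss Unthresholded [loss_map()].
#' @param mask Logical matrix.
#' @param reference An `fq_reference` from [select_reference_area()].
#' @param params An [blur_params()].
#' @return Logical lesion mask.
#' @export
select_lesion_pixels <- function(loss, mask, reference, params = blur_params()) {
  stopifnot(inherits(loss, "fq_loss_map"), inherits(reference, "fq_reference"))
  if (loss$threshold_applied) abort("expected an unthresholded loss map")
  mask <- mask > 0
  ref_px <- reference$pixels & mask
  if (!any(reference$pixels)) abort("reference area is empty")
  # reference windows may belong to the other tooth; fall back to the union
  if (!any(ref_px)) ref_px <- reference$pixels
  base <- loss$values[ref_px]
  base_mean <- mean(base)
  base_sd <- if (length(base) > 1) sd(base) else 0
  cut <- if (base_sd == 0) base_mean else base_mean + params$k_sd * base_sd
  mask & loss$values > cut
}

#' Blur-method fluorosis metrics
#'
#' `delta_f` is the mean percentage fluorescence loss of lesion pixels
#' relative to the local sound estimate (the blurred image), `area` the
#' lesion extent (mm^2 when the pixel pitch is known, else a pixel count,
#' flagged by `area_unit`), and `delta_q = delta_f * area` the summary metric.
#'
#' @param green Original green channel (unused beyond validation; kept for a
#'   uniform signature).
#' @param loss Unthresholded [loss_map()] from [unsharp_difference()].
#' @param lesion_mask Logical matrix from [select_lesion_pixels()].
#' @param blurred The [mean_blur()] estimate (denominator of the loss ratio).
#' @param mm_per_pixel Optional physical scale.
#' @return One-row tibble: `method`, `area`, `delta_f`, `delta_q`,
#'   `n_lesion_px`, `area_unit`, `n_skipped_px`.
#' @export
blur_metrics <- function(green, loss, lesion_mask, blurred, mm_per_pixel = NULL) {
  stopifnot(inherits(loss, "fq_loss_map"), inherits(blurred, "fq_green"))
  lesion <- lesion_mask > 0
  usable <- lesion & blurred$values > 0
  n_skipped <- sum(lesion) - sum(usable)
  n <- sum(usable)
  if (n == 0L) {
    df <- 0; area <- 0; dq <- 0
  } else {
    df <- mean(100 * loss$values[usable] / blurred$values[usable])
    area <- if (is.null(mm_per_pixel)) n else n * mm_per_pixel^2
    dq <- df * area
  }
  tibble(method = "blur", area = area, delta_f = df, delta_q = dq,
         n_lesion_px = as.integer(n),
         area_unit = if (is.null(mm_per_pixel)) "px" else "mm2",
         n_skipped_px = as.integer(n_skipped))
}

#' Run the full blur technique on one tooth
#'
#' Chains [mean_blur()], [unsharp_difference()], [select_lesion_pixels()] and
#' [blur_metrics()].
#'
#' @inheritParams mean_blur
#' @param reference An `fq_reference`.
#' @param mm_per_pixel Optional physical scale.
#' @return List with `metrics` (tibble row), `loss`, `blurred`, `lesion_mask`.
#' @export
analyze_blur_tooth <- function(green, mask, reference, params = blur_params(),
                               mm_per_pixel = NULL) {
  blurred <- mean_blur(green, mask, params)
  loss <- unsharp_difference(green, blurred, mask)
  lesion <- select_lesion_pixels(loss, mask, reference, params)
  metrics <- blur_metrics(green, loss, lesion, blurred, mm_per_pixel)
  list(metrics = metrics, loss = loss, blurred = blurred, lesion_mask = lesion)
}
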