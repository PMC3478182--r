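#' Parameters for the convex-hull technique
#'
#' @param threshold_level Background-noise threshold on the loss map, in
#'   brightness units out of 255 (default 5, the setting chosen to include
#'   milder fluorosis); loss strictly below it is set to zero.
#' @param opening_radius_px Radius of the disk structuring element of the
#'   grayscale morphological opening applied before reconstruction
#'   (default 1; 0 disables the opening).
#' @return A list of class `fq_hull_params`.
#' @export
hull_params <- function(threshold_level = 5L, opening_radius_px = 1L) {
  threshold_level <- as.numeric(threshold_level)
  if (threshold_level < 0 || threshold_level > 255)
    abort("`threshold_level` must lie in [0, 255]")
  opening_radius_px <- as.integer(opening_radius_px)
  if (opening_radius_px < 0L) abort("`opening_radius_px` must be >= 0")
  structure(list(threshold_level = threshold_level,
                 opening_radius_px = opening_radius_px),
            class = "fq_hull_params")
}

disk_offsets <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  d[d$dy^2 + d$dx^2 <= r^2, , drop = FALSE]
}

# min/max over the structuring element restricted to the mask: out-of-mask
# neighbours are ignored, which behaves like mask-border replication rather
# than letting the zero background erode the tooth rim.
mask_extremum <- function(values, mask, offsets, op = c("min", "max")) {
  op <- match.arg(op)
  h <- nrow(values); w <- ncol(values)
  vm <- ifelse(mask, values, NA_real_)
  acc <- matrix(NA_real_, h, w)
  for (i in seq_len(nrow(offsets))) {
    dy <- offsets$dy[i]; dx <- offsets$dx[i]
    sh <- matrix(NA_real_, h, w)
    r_src <- max(1, 1 + dy):min(h, h + dy)
    c_src <- max(1, 1 + dx):min(w, w + dx)
    sh[r_src - dy, c_src - dx] <- vm[r_src, c_src]
    acc <- if (op == "min") pmin(acc, sh, na.rm = TRUE)
           else pmax(acc, sh, na.rm = TRUE)
  }
  acc[!mask] <- NA_real_
  acc
}

#' Mask-aware grayscale morphological opening
#'
#' Erosion followed by dilation with a disk structuring element; removes
#' bright specks (noise) at the element's scale before the hull
#' reconstruction.  Restricted to the mask: out-of-mask pixels never enter
#' the min/max.
#'
#' @param green An [green_image()].
#' @param mask Logical matrix.
#' @param params An [hull_params()].
#' @return An `fq_green`, zero outside the mask.
#' @export
open_image <- function(green, mask, params = hull_params()) {
  stopifnot(inherits(green, "fq_green"), inherits(params, "fq_hull_params"))
  mask <- mask > 0
  if (!any(mask)) abort("mask is empty")
  r <- params$opening_radius_px
  g <- green$values
  if (r > 0L) {
    offs <- disk_offsets(r)
    er <- mask_extremum(g, mask, offs, "min")
    op <- mask_extremum(er, mask, offs, "max")
  } else {
    op <- ifelse(mask, g, NA_real_)
  }
  op[!mask] <- 0
  green_image(op, provenance = green$provenance)
}

#' Clean-surface reconstruction by the 3D upper convex hull
#'
#' Converts the in-mask pixels into points `(x, y, brightness)`, computes
#' their three-dimensional convex hull and renders the upper facets (outward
#' normal with a positive brightness component) back to an image by planar
#' interpolation.  The result is the "clean" tooth surface: dark (lesioned)
#' areas are filled by interpolation between the surrounding sound areas, and
#' the surface dominates the input brightness everywhere in-mask.
#'
#' Degenerate clouds are handled exactly: masks whose pixels are collinear in
#' `(x, y)` get the one-dimensional upper concave chain; fully coplanar
#' clouds (e.g. constant or planar-ramp brightness) are returned unchanged.
#' Fewer than 3 in-mask pixels is an error.
#'
#' @param green_opened Output of [open_image()] (or a raw green image).
#' @param mask Logical matrix.
#' @return An object of class `fq_clean`: list with `values` (matrix, zero
#'   outside the mask) and `mask`.
#' @export
upper_hull_surface <- function(green_opened, mask) {
  stopifnot(inherits(green_opened, "fq_green"))
  mask <- mask > 0
  rc <- which(mask, arr.ind = TRUE)
  n <- nrow(rc)
  if (n < 3L) abort("upper hull needs at least 3 in-mask pixels")
  x <- as.double(rc[, 2]); y <- as.double(rc[, 1])
  z <- green_opened$values[mask]

  env <- if (collinear_xy(x, y)) {
    chain_envelope_1d(x, y, z)
  } else if (coplanar_xyz(x, y, z)) {
    z
  } else {
    cpp_upper_envelope(x, y, z, as.integer(x), as.integer(y))
  }
  # hard guarantees: dominate the input, stay within the brightness range;
  # snap values within numeric tolerance of the data back onto it so pixels
  # that lie on the hull carry exactly zero loss
  env <- pmin(pmax(env, z), max(z))
  env[env - z < 1e-6] <- z[env - z < 1e-6]
  out <- matrix(0, nrow(green_opened$values), ncol(green_opened$values))
  out[mask] <- env
  structure(list(values = out, mask = mask), class = "fq_clean")
}

collinear_xy <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  s <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  s[2] <= 1e-9 * max(s[1], 1)
}

coplanar_xyz <- function(x, y, z) {
  m <- cbind(x - mean(x), y - mean(y), z - mean(z))
  s <- svd(m, nu = 0, nv = 0)$d
  s[3] <= 1e-9 * max(s[1], 1)
}

# 1D upper concave majorant for masks whose (x, y) footprint is a line:
# project onto the line, take the 2D upper hull (monotone chain) of
# (t, brightness) and interpolate linearly.
chain_envelope_1d <- function(x, y, z) {
  xc <- x - mean(x); yc <- y - mean(y)
  v <- svd(cbind(xc, yc))$v[, 1]
  t <- xc * v[1] + yc * v[2]
  o <- order(t)
  ts <- t[o]; zs <- z[o]
  hull <- integer()
  for (i in seq_along(ts)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b when it lies on or below segment a -> i
      cr <- (ts[b] - ts[a]) * (zs[i] - zs[a]) - (zs[b] - zs[a]) * (ts[i] - ts[a])
      if (cr >= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  env_sorted <- stats::approx(ts[hull], zs[hull], xout = ts,
                              method = "linear", rule = 2)$y
  env <- numeric(length(t))
  env[o] <- env_sorted
  env
}

#' Loss map and background threshold
#'
#' Raw loss is the clean surface minus the (opened) capture, non-negative by
#' the hull's dominance property.  Pixels with loss strictly below the
#' threshold are set to zero to remove background noise; those at or above it
#' are kept at their raw value.
#'
#' @param clean An `fq_clean` from [upper_hull_surface()].
#' @param green_opened The image the surface was built from.
#' @param mask Logical matrix.
#' @param params An [hull_params()].
#' @return A thresholded [loss_map()] tagged `"hull"`.
#' @export
loss_and_threshold <- function(clean, green_opened, mask, params = hull_params()) {
  stopifnot(inherits(clean, "fq_clean"), inherits(green_opened, "fq_green"))
  if (!identical(dim(clean$values), dim(green_opened$values)))
    abort("surface and image dimensions differ")
  mask <- mask > 0
  loss <- pmax(clean$values - green_opened$values, 0)
  loss[!mask] <- 0
  loss[loss < params$threshold_level] <- 0
  loss_map(loss, threshold_applied = TRUE, method_tag = "hull",
           threshold_level = params$threshold_level)
}

#' Convex-hull fluorosis metrics
#'
#' `area` is the fraction of the tooth surface considered fluorosis,
#' `delta_f` the average fractional fluorescence loss of those areas
#' (relative to the clean surface), and `delta_q` the average fractional loss
#' over the entire tooth surface; by construction
#' `delta_q = area * delta_f`.
#'
#' @param loss Thresholded [loss_map()].
#' @param mask Logical matrix.
#' @param clean The `fq_clean` surface (ratio denominator).
#' @return One-row tibble: `method`, `area`, `delta_f`, `delta_q`,
#'   `n_lesion_px`, `area_unit`, `n_skipped_px`.
#' @export
hull_metrics <- function(loss, mask, clean) {
  stopifnot(inherits(loss, "fq_loss_map"), inherits(clean, "fq_clean"))
  if (!loss$threshold_applied) abort("expected a thresholded loss map")
  mask <- mask > 0
  valid <- mask & clean$values > 0
  n_skipped <- sum(mask) - sum(valid)
  frac <- loss$values[valid] / clean$values[valid]
  lesion <- loss$values[valid] > 0
  n_mask <- sum(valid)
  n_lesion <- sum(lesion)
  if (n_lesion == 0L || n_mask == 0L) {
    area <- 0; df <- 0; dq <- 0
  } else {
    area <- n_lesion / n_mask
    df <- mean(frac[lesion])
    dq <- mean(frac)
  }
  tibble(method = "hull", area = area, delta_f = df, delta_q = dq,
         n_lesion_px = as.integer(n_lesion), area_unit = "fraction",
         n_skipped_px = as.integer(n_skipped))
}

#' Run the full convex-hull technique on one tooth
#'
#' Chains [open_image()], [upper_hull_surface()], [loss_and_threshold()] and
#' [hull_metrics()].
#'
#' @inheritParams open_image
#' @return List with `metrics` (tibble row), `loss`, `clean`, `opened`.
#' @export
analyze_hull_tooth <- function(green, mask, params = hull_params()) {
  opened <- open_image(green, mask, params)
  clean <- upper_hull_surface(opened, mask)
  loss <- loss_and_threshold(clean, opened, mask, params)
  metrics <- hull_metrics(loss, mask, clean)
  list(metrics = metrics, loss = loss, clean = clean, opened = opened)
}
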