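#' Fluorescence image object
#'
#' An 8-bit RGB fluorescence capture of the two maxillary central incisors.
#' Pixels are stored as an integer array `height x width x 3` with channel
#' values in `[0, 255]`.  Under 405-nm illumination through a long-pass filter
#' sound enamel fluoresces predominantly in the green channel, so all analysis
#' downstream operates on the green channel only.
#'
#' @param pixels Integer array `h x w x 3`, values in `[0, 255]`.
#' @param mm_per_pixel Optional physical scale (mm per pixel side, `> 0`).
#'   When absent, blur-method areas are reported in pixels and flagged.
#' @param subject_id Subject identifier.
#' @param capture_index Integer `>= 1`; 1 is the original capture, `>= 2` a
#'   repeat capture taken to assess repeatability.
#' @return An object of class `fq_image`.
#' @export
fluorescence_image <- function(pixels, mm_per_pixel = NULL,
                               subject_id = NA_character_, capture_index = 1L) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    abort("`pixels` must be an h x w x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort("channel values must lie in [0, 255]")
  if (any(pixels != round(pixels)))
    abort("channel values must be integers (8-bit)")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    abort("image must have at least one row and one column")
  if (!is.null(mm_per_pixel)) {
    if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1 || mm_per_pixel <= 0)
      abort("`mm_per_pixel` must be a single positive number")
  }
  structure(
    list(pixels = array(as.integer(round(pixels)), dim = dim(pixels)),
         height = dim(pixels)[1], width = dim(pixels)[2],
         mm_per_pixel = mm_per_pixel,
         subject_id = subject_id,
         capture_index = as.integer(capture_index)),
    class = "fq_image")
}

#' @export
print.fq_image <- function(x, ...) {
  cat(sprintf("<fq_image> %d x %d px, subject %s, capture %d%s\n",
              x$height, x$width, x$subject_id, x$capture_index,
              if (is.null(x$mm_per_pixel)) "" else
                sprintf(", %.4g mm/px", x$mm_per_pixel)))
  invisible(x)
}

#' Single-channel green image
#'
#' @param values Integer (or real, for filtered intermediates) matrix with
#'   values in `[0, 255]`.
#' @param provenance Identifier of the source image.
#' @return An object of class `fq_green`.
#' @export
green_image <- function(values, provenance = NA_character_) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  if (anyNA(values) || min(values) < 0 || max(values) > 255)
    abort("green values must lie in [0, 255]")
  structure(list(values = values, provenance = provenance), class = "fq_green")
}

#' Extract the green channel
#'
#' Only the green channel carries the fluorescence signal of interest; red and
#' blue are discarded before any reconstruction step.
#'
#' @param image An [fluorescence_image()].
#' @return An `fq_green` whose values equal the G channel exactly.
#' @export
extract_green <- function(image) {
  stopifnot(inherits(image, "fq_image"))
  green_image(image$pixels[, , 2], provenance = image$subject_id)
}

#' Loss map
#'
#' Per-pixel fluorescence loss (brightness units on the 0-255 scale) produced
#' by either reconstruction technique.  Zero outside the tooth mask; when
#' thresholded, every retained value is at least the threshold.
#'
#' @param values Non-negative numeric matrix.
#' @param threshold_applied Has the background-noise threshold been applied?
#' @param method_tag `"blur"` or `"hull"`.
#' @param threshold_level Threshold used (recorded when applied).
#' @return An object of class `fq_loss_map`.
#' @export
loss_map <- function(values, threshold_applied, method_tag,
                     threshold_level = NA_real_) {
  if (!is.matrix(values) || anyNA(values) || min(values) < 0)
    abort("loss values must be a non-negative matrix")
  method_tag <- match.arg(method_tag, c("blur", "hull"))
  if (isTRUE(threshold_applied) && !is.na(threshold_level)) {
    nz <- values[values > 0]
    if (length(nz) && min(nz) < threshold_level)
      abort("thresholded loss map contains nonzero values below the threshold")
  }
  structure(list(values = values, threshold_applied = isTRUE(threshold_applied),
                 method_tag = method_tag, threshold_level = threshold_level),
            class = "fq_loss_map")
}

# ---- file I/O --------------------------------------------------------------

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("bmp")) return("bmp")
  abort(sprintf("unsupported image format '%s' for '%s' (PNG or BMP)", ext, path))
}

#' Read a fluorescence image (PNG or BMP)
#'
#' Files must be 8-bit RGB (an alpha channel, if present, is dropped);
#' grayscale, indexed or 16-bit files are rejected rather than rescaled.
#'
#' @param path File path ending in `.png` or `.bmp`.
#' @inheritParams fluorescence_image
#' @return An `fq_image` whose pixels match the file bit-exactly.
#' @export
read_image <- function(path, mm_per_pixel = NULL,
                       subject_id = NA_character_, capture_index = 1L) {
  if (!file.exists(path)) abort(sprintf("image file '%s' does not exist", path))
  fmt <- img_format(path)
  if (fmt == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) != 3L || dim(a)[3] < 3L)
      abort(sprintf("'%s' is not an RGB PNG (8-bit RGB required)", path))
    px <- round(a[, , 1:3] * 255)
  } else {
    px <- read_bmp(path)
  }
  fluorescence_image(px, mm_per_pixel = mm_per_pixel,
                     subject_id = subject_id, capture_index = capture_index)
}

#' Write a fluorescence image (PNG or BMP)
#'
#' @param image An `fq_image`.
#' @param path Destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "fq_image"))
  fmt <- img_format(path)
  if (fmt == "png") {
    png::writePNG(image$pixels / 255, target = path)
  } else {
    write_bmp(image$pixels, path)
  }
  invisible(path)
}

# Minimal 24-bit uncompressed (BI_RGB) BMP codec.  BMP rows are stored
# bottom-up, BGR, padded to 4-byte boundaries.
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    abort(sprintf("'%s' is not a BMP file", path))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.double(raw[i + 0:3]) * c(1, 256, 65536, 16777216))
  off <- u32(11); w <- u32(19); h <- u32(23)
  bpp <- u16(29); comp <- u32(31)
  if (bpp != 24L || comp != 0)
    abort(sprintf("'%s': only 24-bit uncompressed BMP is supported", path))
  stride <- 4 * ceiling(3 * w / 4)
  px <- array(0L, dim = c(h, w, 3))
  for (r in seq_len(h)) {
    # BMP row r (from bottom) -> image row h - r + 1
    base <- off + (r - 1) * stride
    row <- as.integer(raw[(base + 1):(base + 3 * w)])
    m <- matrix(row, nrow = 3) # B, G, R per column
    px[h - r + 1, , 1] <- m[3, ]
    px[h - r + 1, , 2] <- m[2, ]
    px[h - r + 1, , 3] <- m[1, ]
  }
  px
}

write_bmp <- function(pixels, path) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  stride <- 4 * ceiling(3 * w / 4)
  data_size <- stride * h
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
  u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                              x %/% 65536 %% 256, x %/% 16777216 %% 256))
  header <- c(charToRaw("BM"), u32(54 + data_size), u16(0), u16(0), u32(54),
              u32(40), u32(w), u32(h), u16(1), u16(24), u32(0), u32(data_size),
              u32(2835), u32(2835), u32(0), u32(0))
  body <- raw(data_size)
  pad <- stride - 3 * w
  for (r in seq_len(h)) {
    img_row <- h - r + 1
    m <- rbind(pixels[img_row, , 3], pixels[img_row, , 2], pixels[img_row, , 1])
    body[((r - 1) * stride + 1):((r - 1) * stride + 3 * w)] <- as.raw(as.vector(m))
    # padding bytes stay zero
  }
  writeBin(c(header, body), path)
  invisible(path)
}

# ---- tooth masks -----------------------------------------------------------

TOOTH_LABELS <- c(UR1 = 1L, UL1 = 2L)

#' Tooth mask set
#'
#' A named list of per-tooth binary masks (`UR1`, `UL1`) sharing the image's
#' dimensions.  Masks gate every analysis step: no pixel outside a mask is
#' ever analyzed.  Each mask is reduced to its largest 8-connected component
#' on construction.
#'
#' @param masks Named list of logical matrices (names among `UR1`, `UL1`).
#' @param dim Expected dimensions `c(h, w)` (checked when given).
#' @return An object of class `fq_mask_set`; teeth absent from `masks` are
#'   recorded in `attr(, "missing")`.
#' @export
mask_set <- function(masks, dim = NULL) {
  if (!is.list(masks)) abort("`masks` must be a named list of logical matrices")
  bad <- setdiff(names(masks), names(TOOTH_LABELS))
  if (length(bad)) abort(sprintf("unknown tooth label(s): %s", toString(bad)))
  masks <- masks[intersect(names(TOOTH_LABELS), names(masks))]
  masks <- purrr::map(masks, function(m) {
    m <- m > 0
    if (!is.null(dim) && !identical(base::dim(m), as.integer(dim)))
      abort("mask dimensions do not match the image")
    largest_component(m)
  })
  masks <- masks[purrr::map_lgl(masks, any)]
  structure(masks, class = "fq_mask_set",
            missing = setdiff(names(TOOTH_LABELS), names(masks)))
}

#' Read a mask set
#'
#' Masks are stored as one grayscale PNG per capture with raw pixel levels
#' 0 (background), 1 (`UR1`) and 2 (`UL1`).
#'
#' @param path Mask PNG path.
#' @param image The capture the masks belong to (dimension check).
#' @return An `fq_mask_set`; absent labels are flagged in `attr(, "missing")`
#'   and surface as `missing_mask` in [check_analyzable()].
#' @export
read_mask_set <- function(path, image = NULL) {
  if (!file.exists(path)) abort(sprintf("mask file '%s' does not exist", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  lab <- round(a * 255)
  if (!is.null(image) && !identical(dim(lab), c(image$height, image$width)))
    abort(sprintf("mask dimensions %s do not match image %s",
                  paste(dim(lab), collapse = "x"),
                  paste(c(image$height, image$width), collapse = "x")))
  masks <- list()
  for (tooth in names(TOOTH_LABELS))
    if (any(lab == TOOTH_LABELS[[tooth]]))
      masks[[tooth]] <- lab == TOOTH_LABELS[[tooth]]
  mask_set(masks, dim = dim(lab))
}

#' Write a mask set
#'
#' @param masks An `fq_mask_set`.
#' @param path Destination PNG path.
#' @param dim Image dimensions `c(h, w)` used when the set is empty.
#' @return `path`, invisibly.
#' @export
write_mask_set <- function(masks, path, dim = NULL) {
  if (length(masks)) dim <- base::dim(masks[[1]])
  if (is.null(dim)) abort("`dim` required to write an empty mask set")
  lab <- matrix(0L, dim[1], dim[2])
  for (tooth in names(masks)) lab[masks[[tooth]]] <- TOOTH_LABELS[[tooth]]
  png::writePNG(lab / 255, target = path)
  invisible(path)
}

# Largest 8-connected component of a binary matrix (queue-free frontier
# expansion on matrix indices; masks are small so this is plenty fast).
largest_component <- function(m) {
  if (!any(m)) return(m)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(m & lab == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    frontier <- todo[1]
    lab[frontier] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      c <- (frontier - 1L) %/% h + 1L
      nb_r <- rep(r, each = 8L) + rep(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L), length(r))
      nb_c <- rep(c, each = 8L) + rep(c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L), length(r))
      ok <- nb_r >= 1L & nb_r <= h & nb_c >= 1L & nb_c <= w
      nb <- unique((nb_c[ok] - 1L) * h + nb_r[ok])
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
    todo <- which(m & lab == 0L)
  }
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}
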