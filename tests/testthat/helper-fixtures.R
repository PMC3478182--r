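# Small deterministic fixtures shared across test files.

rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# Two side-by-side rectangular "incisors" with a configurable gap, plus a
# uniform green image.
two_rect_teeth <- function(h = 60, w = 80, gap = 2, top = 11, height = 40,
                           tooth_w = 25, brightness = 180) {
  left_c0 <- round(w / 2) - gap %/% 2 - tooth_w
  masks <- mask_set(list(
    UR1 = rect_mask(h, w, top:(top + height - 1), left_c0:(left_c0 + tooth_w - 1)),
    UL1 = rect_mask(h, w, top:(top + height - 1),
                    (left_c0 + tooth_w + gap):(left_c0 + 2 * tooth_w + gap - 1))))
  g <- matrix(0, h, w)
  for (m in masks) g[m] <- brightness
  list(masks = masks, green = green_image(g))
}

# 3 x 3 BMP with G = 128 everywhere, written by an independent image tool
# (PIL); frozen as bytes so the reader is checked against a foreign writer.
pil_bmp_g128 <- function(path) {
  hex <- "424d5a0000000000000036000000280000000300000003000000010018000000000024000000c40e0000c40e00000000000000000000008000008000008000000000008000008000008000000000008000008000008000000000"
  bytes <- as.raw(strtoi(substring(hex, seq(1, nchar(hex) - 1, 2),
                                   seq(2, nchar(hex), 2)), 16L))
  writeBin(bytes, path)
  path
}
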