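#' Label masks and their color-coded file form
#'
#' A label mask is a per-pixel class grid over a scene with three classes:
#' `background`, `wheal`, and `rt` (the 3 x 3 cm reference tag). The on-disk
#' form is a color-coded RGB PNG using the annotation palette: wheal pixels
#' magenta (255, 0, 255), reference-tag pixels black (0, 0, 0), and all
#' remaining pixels red (255, 0, 0).
#'
#' @name label-masks
NULL

MASK_CLASSES <- c("background", "wheal", "rt")

# palette rows indexed by class code + 1 (background = 0, wheal = 1, rt = 2)
MASK_PALETTE <- rbind(
  background = c(255L, 0L, 0L),
  wheal      = c(255L, 0L, 255L),
  rt         = c(0L, 0L, 0L)
)

#' Construct a label mask
#'
#' @param grid integer matrix with values 0 (background), 1 (wheal), 2 (rt).
#' @return a `label_mask`: an integer matrix with class attribute.
#' @export
label_mask <- function(grid) {
  if (!is.matrix(grid)) stop_input("label mask grid must be a matrix")
  g <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  if (anyNA(g) || any(g < 0L | g > 2L)) {
    stop_input("label mask values must be class codes 0, 1 or 2")
  }
  structure(g, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf(
    "<label_mask %d x %d: background=%d wheal=%d rt=%d>\n",
    nrow(x), ncol(x), tab[1], tab[2], tab[3]
  ))
  invisible(x)
}

is_label_mask <- function(x) inherits(x, "label_mask")

#' Encode a label mask as a color-coded RGB image
#'
#' @param mask a [label_mask()].
#' @return integer array `dim c(H, W, 3)` with values in 0..255 following the
#'   annotation palette (wheal magenta, tag black, background red).
#' @export
encode_label_mask <- function(mask) {
  if (!is_label_mask(mask)) mask <- label_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0L, c(h, w, 3L))
  for (ch in 1:3) {
    img[, , ch] <- MASK_PALETTE[as.integer(mask) + 1L, ch]
  }
  img
}

#' Decode a color-coded RGB image into a label mask
#'
#' The palette is strict: every pixel must match one of the three code colors
#' exactly. Values may be given in 0..255 or on the 0..1 PNG scale.
#'
#' @param img numeric/integer array `dim c(H, W, 3)` (a fourth alpha channel,
#'   if present, is ignored).
#' @return a [label_mask()].
#' @export
decode_label_mask <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop_input("expected an H x W x 3 RGB array")
  }
  img <- img[, , 1:3, drop = FALSE]
  if (max(img) <= 1) img <- img * 255
  img <- round(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  # pack RGB into one integer per pixel for exact palette matching
  key <- img[, , 1] * 65536 + img[, , 2] * 256 + img[, , 3]
  pal_key <- MASK_PALETTE[, 1] * 65536 + MASK_PALETTE[, 2] * 256 +
    MASK_PALETTE[, 3]
  code <- match(key, pal_key)
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    r <- (bad - 1L) %% h + 1L
    c <- (bad - 1L) %/% h + 1L
    stop_input(
      "off-palette pixel at (row=%d, col=%d): RGB (%d, %d, %d)",
      r, c, img[r, c, 1], img[r, c, 2], img[r, c, 3]
    )
  }
  label_mask(matrix(code - 1L, h, w))
}

#' Read / write color-coded mask PNG files
#'
#' Masks are stored as lossless RGB PNGs so the palette round-trips
#' bit-exactly.
#'
#' @param mask a [label_mask()].
#' @param path file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png` returns
#'   a [label_mask()].
#' @export
write_mask_png <- function(mask, path) {
  img <- encode_label_mask(mask) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  decode_label_mask(png::readPNG(path))
}

#' Read / write scene PNG files
#'
#' @param image numeric array `dim c(H, W, 3)` with values in `[0, 1]`.
#' @param path file path.
#' @export
write_scene_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_scene_png
#' @export
read_scene_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}
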