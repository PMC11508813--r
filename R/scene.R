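#' Synthetic SPT scene specification
#'
#' Describes a synthetic skin-prick-test photograph: a skin-toned canvas
#' carrying a 3 x 3 cm chroma-key reference tag (RT) and a set of wheal
#' shapes. Capture conditions in the emulated protocol are deliberately
#' unstandardized, so tone, noise and scale are parameters rather than
#' constants.
#'
#' @param canvas_px integer length 2, `(width, height)` in pixels.
#' @param pixels_per_cm rasterization scale. The default 100/3 px/cm renders
#'   the RT at about 100 x 100 px on the standard 640 x 480 canvas.
#' @param rt_side_cm reference tag side length (3 cm in the protocol).
#' @param rt_position_px numeric length 2, `(x, y)` of the tag's top-left
#'   corner in pixels.
#' @param wheal_specs list of [shape_spec()]s (centers in cm).
#' @param skin_tone_rgb base skin color, 0..255.
#' @param noise_sigma Gaussian intensity noise SD on the 0..1 scale.
#' @param seed integer seed; rendering is bit-reproducible given the spec.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(canvas_px = c(640L, 480L),
                       pixels_per_cm = 100 / 3,
                       rt_side_cm = 3,
                       rt_position_px = c(16, 16),
                       wheal_specs = list(),
                       skin_tone_rgb = c(224, 172, 138),
                       noise_sigma = 0.02,
                       seed = 1L) {
  structure(
    list(
      canvas_px = as.integer(canvas_px),
      pixels_per_cm = pixels_per_cm,
      rt_side_cm = rt_side_cm,
      rt_position_px = rt_position_px,
      wheal_specs = wheal_specs,
      skin_tone_rgb = as.numeric(skin_tone_rgb),
      noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

# Reference-tag pixel membership on a (H, W) canvas: pixel centers falling in
# the half-open square [x0, x0 + side) x [y0, y0 + side).
rt_pixel_window <- function(spec) {
  side <- spec$rt_side_cm * spec$pixels_per_cm
  x0 <- spec$rt_position_px[1]
  y0 <- spec$rt_position_px[2]
  cols <- which(seq_len(spec$canvas_px[1]) - 1 >= x0 &
                  seq_len(spec$canvas_px[1]) - 1 < x0 + side)
  rows <- which(seq_len(spec$canvas_px[2]) - 1 >= y0 &
                  seq_len(spec$canvas_px[2]) - 1 < y0 + side)
  list(rows = rows, cols = cols)
}

# Pixel set of one shape on the scene canvas; 1-based (row, col) matrix.
# Errors if the shape's analytic bounding box leaves the canvas.
scene_shape_pixels <- function(spec, shape, label) {
  w <- spec$canvas_px[1]
  h <- spec$canvas_px[2]
  ppcm <- spec$pixels_per_cm
  rmax <- shape_max_radius_cm(shape) * ppcm
  cx <- shape$center_cm[1] * ppcm
  cy <- shape$center_cm[2] * ppcm
  if (cx - rmax < -0.5 || cx + rmax > w - 0.5 ||
      cy - rmax < -0.5 || cy + rmax > h - 0.5) {
    stop_input("shape %s extends outside the canvas", label)
  }
  x0 <- max(0, floor(cx - rmax) - 1)
  x1 <- min(w - 1, ceiling(cx + rmax) + 1)
  y0 <- max(0, floor(cy - rmax) - 1)
  y1 <- min(h - 1, ceiling(cy + rmax) + 1)
  xs <- x0:x1
  ys <- y0:y1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- shape_contains(shape, px, py, ppcm)
  cbind(row = py[inside] + 1L, col = px[inside] + 1L)
}

#' Render a synthetic SPT scene
#'
#' Rasterizes the reference tag and every wheal by the pixel-center rule,
#' producing the RGB photograph emulation and its color-coded label mask.
#' Wheals are filled with a redder tone than the surrounding skin; the tag is
#' rendered chroma green in the scene (its mask class is `rt`, encoded black
#' on file). Gaussian intensity noise is added under the scene seed.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 array, 0..1), `mask` (a
#'   [label_mask()]), and `specs`, the input shape specs each augmented with
#'   its ground-truth `pixels` (1-based `(row, col)` matrix) and
#'   `pixel_count`.
#' @export
render_scene <- function(spec) {
  w <- spec$canvas_px[1]
  h <- spec$canvas_px[2]
  grid <- matrix(0L, h, w)
  rtw <- rt_pixel_window(spec)
  if (length(rtw$rows) == 0 || length(rtw$cols) == 0) {
    stop_input("reference tag falls outside the canvas")
  }
  grid[rtw$rows, rtw$cols] <- 2L
  specs <- spec$wheal_specs
  for (i in seq_along(specs)) {
    px <- scene_shape_pixels(spec, specs[[i]], label = i)
    if (nrow(px) == 0) stop_input("shape %d rasterizes to no pixels", i)
    occ <- grid[px]
    if (any(occ != 0L)) {
      stop_input(
        "shape %d overlaps %s", i,
        if (any(occ == 2L)) "the reference tag" else "another wheal"
      )
    }
    grid[px] <- 1L
    specs[[i]]$pixels <- px
    specs[[i]]$pixel_count <- nrow(px)
  }
  mask <- label_mask(grid)

  img <- with_seed(spec$seed, {
    base <- spec$skin_tone_rgb / 255
    wheal_rgb <- pmin(base * c(1.06, 0.82, 0.82) + c(0.04, 0, 0), 1)
    chroma_rgb <- c(0, 0.85, 0.25)
    im <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(base[ch], h, w)
      plane[grid == 1L] <- wheal_rgb[ch]
      plane[grid == 2L] <- chroma_rgb[ch]
      im[, , ch] <- plane + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    pmin(pmax(im, 0), 1)
  })
  list(image = img, mask = mask, specs = specs)
}

#' Generate the regular / irregular shape study groups
#'
#' Produces labeled image files emulating the shape study: each file is a
#' canvas carrying one 3 x 3 cm reference square plus `shapes_per_file`
#' shapes — circles/ellipses with exact analytic areas for the regular
#' group, connected pseudopods for the irregular group. Placement is by
#' rejection sampling with a guaranteed 3 px clearance so shapes never touch
#' (8-connected components stay distinct).
#'
#' @param group `"regular"` or `"irregular"`.
#' @param n_files number of image files.
#' @param shapes_per_file shapes per file.
#' @param axis_range_cm numeric length 2, uniform sampling interval for both
#'   semi-axes in cm.
#' @param pixels_per_cm rasterization scale.
#' @param seed integer seed.
#' @param canvas_px `(width, height)` of each file.
#' @return list of length `n_files`; each element has `mask` (a
#'   [label_mask()]) and `specs` (shape specs with ground-truth `pixels`,
#'   `pixel_count`, and `analytic_area_cm2` where defined).
#' @export
make_shape_group <- function(group = c("regular", "irregular"),
                             n_files, shapes_per_file,
                             axis_range_cm = c(0.5, 1.5),
                             pixels_per_cm = 100 / 3,
                             seed = 1L,
                             canvas_px = c(640L, 480L)) {
  group <- match.arg(group)
  if (shapes_per_file < 1) stop_input("need shapes_per_file >= 1")
  if (n_files <= 0) return(list())
  if (axis_range_cm[1] <= 0) stop_input("axis_range_cm must be positive")
  with_seed(seed, {
    lapply(seq_len(n_files), function(f) {
      generate_group_file(group, shapes_per_file, axis_range_cm,
                          pixels_per_cm, canvas_px)
    })
  })
}

generate_group_file <- function(group, shapes_per_file, axis_range_cm,
                                pixels_per_cm, canvas_px) {
  w <- canvas_px[1]
  h <- canvas_px[2]
  ppcm <- pixels_per_cm
  rt_xy <- c(12, 12)
  side <- 3 * ppcm
  clearance <- 3
  placed <- list()   # (cx, cy, rmax) in px of accepted shapes
  specs <- list()
  for (i in seq_len(shapes_per_file)) {
    ok <- FALSE
    for (try in 1:500) {
      kind <- if (group == "regular") {
        sample(c("circle", "ellipse"), 1)
      } else {
        "pseudopod"
      }
      sh <- random_shape_spec(kind, axis_range_cm)
      rmax <- shape_max_radius_cm(sh) * ppcm
      if (2 * rmax + 4 > min(w, h)) next
      cx <- runif(1, rmax + 1, w - 2 - rmax)
      cy <- runif(1, rmax + 1, h - 2 - rmax)
      # clearance vs the reference square (point-to-rectangle distance)
      qx <- min(max(cx, rt_xy[1] - clearance), rt_xy[1] + side + clearance)
      qy <- min(max(cy, rt_xy[2] - clearance), rt_xy[2] + side + clearance)
      if (sqrt((cx - qx)^2 + (cy - qy)^2) < rmax + clearance) next
      # clearance vs accepted shapes (circumscribed circles)
      clash <- FALSE
      for (p in placed) {
        if (sqrt((cx - p[1])^2 + (cy - p[2])^2) <
            rmax + p[3] + clearance) {
          clash <- TRUE
          break
        }
      }
      if (clash) next
      sh$center_cm <- c(cx, cy) / ppcm
      placed[[length(placed) + 1L]] <- c(cx, cy, rmax)
      specs[[i]] <- sh
      ok <- TRUE
      break
    }
    if (!ok) {
      stop_input(
        "could not place shape %d of %d after 500 attempts; canvas too full",
        i, shapes_per_file
      )
    }
  }
  sp <- scene_spec(
    canvas_px = canvas_px, pixels_per_cm = ppcm,
    rt_position_px = rt_xy, wheal_specs = specs
  )
  grid <- matrix(0L, h, w)
  rtw <- rt_pixel_window(sp)
  grid[rtw$rows, rtw$cols] <- 2L
  for (i in seq_along(specs)) {
    px <- scene_shape_pixels(sp, specs[[i]], label = i)
    grid[px] <- 1L
    specs[[i]]$pixels <- px
    specs[[i]]$pixel_count <- nrow(px)
  }
  list(mask = label_mask(grid), specs = specs)
}

#' Mirroring augmentation for image / mask pairs
#'
#' Applies the sequential mirroring chain used to quadruple the training
#' set: the original, its horizontal mirror, a further vertical mirror (a
#' 180 degree rotation of the original), and a final horizontal mirror (the
#' vertical mirror of the original). Image and mask are transformed
#' identically.
#'
#' @param image numeric array `c(H, W, 3)` or matrix `c(H, W)`.
#' @param mask a [label_mask()] with the same spatial dimensions.
#' @return list of 4 `list(image, mask)` pairs (original first).
#' @export
augment_mirror <- function(image, mask) {
  dim_img <- dim(image)[1:2]
  if (!all(dim_img == dim(mask))) {
    stop_input(
      "image (%d x %d) and mask (%d x %d) dimensions differ",
      dim_img[1], dim_img[2], nrow(mask), ncol(mask)
    )
  }
  flip <- function(x, rows) {
    if (is.matrix(x)) {
      if (rows) x[nrow(x):1, , drop = FALSE] else x[, ncol(x):1, drop = FALSE]
    } else {
      if (rows) x[dim(x)[1]:1, , , drop = FALSE] else x[, dim(x)[2]:1, , drop = FALSE]
    }
  }
  flip_mask <- function(m, rows) label_mask(flip(unclass(m), rows))
  out <- vector("list", 4L)
  out[[1]] <- list(image = image, mask = mask)
  img_h <- flip(image, rows = FALSE)
  msk_h <- flip_mask(mask, rows = FALSE)
  out[[2]] <- list(image = img_h, mask = msk_h)
  img_hv <- flip(img_h, rows = TRUE)
  msk_hv <- flip_mask(msk_h, rows = TRUE)
  out[[3]] <- list(image = img_hv, mask = msk_hv)
  out[[4]] <- list(image = flip(img_hv, rows = FALSE),
                   mask = flip_mask(msk_hv, rows = FALSE))
  out
}
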