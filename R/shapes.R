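#' Analytic wheal shape specifications
#'
#' A shape spec describes one synthetic wheal in physical (cm) units:
#' a circle, an ellipse, or a pseudopod (a base ellipse perturbed by
#' Gaussian radial lobes, emulating the finger-like protrusions of strong
#' allergic reactions). Circles and ellipses carry their exact analytic area
#' `pi * a * b`; pseudopods have no closed-form area and serve as the
#' irregular-contour test bed.
#'
#' @param kind one of `"circle"`, `"ellipse"`, `"pseudopod"`.
#' @param center_cm numeric length 2, shape center `(x, y)` in cm from the
#'   canvas origin (the center of pixel (0, 0)).
#' @param semi_major_cm,semi_minor_cm semi-axes in cm, `a >= b > 0`.
#' @param rotation_deg rotation of the major axis, degrees counterclockwise
#'   from the +x (column) axis.
#' @param lobes for pseudopods, a data frame with columns `angle_deg`,
#'   `amplitude_cm`, `width_deg` — one Gaussian radial lobe per row.
#' @return a `shape_spec` list.
#' @export
shape_spec <- function(kind = c("circle", "ellipse", "pseudopod"),
                       center_cm, semi_major_cm, semi_minor_cm,
                       rotation_deg = 0, lobes = NULL) {
  kind <- match.arg(kind)
  if (semi_minor_cm <= 0 || semi_major_cm < semi_minor_cm) {
    stop_input("need semi_major_cm >= semi_minor_cm > 0")
  }
  if (kind == "circle" && semi_major_cm != semi_minor_cm) {
    stop_input("a circle needs equal semi-axes")
  }
  if (kind == "pseudopod") {
    if (is.null(lobes) || nrow(lobes) == 0) {
      stop_input("a pseudopod needs at least one lobe")
    }
    if (any(lobes$amplitude_cm <= 0) || any(lobes$width_deg <= 0)) {
      stop_input("lobe amplitudes and widths must be positive")
    }
  } else if (!is.null(lobes) && nrow(lobes) > 0) {
    stop_input("lobes are only valid for pseudopods")
  }
  structure(
    list(
      kind = kind,
      center_cm = as.numeric(center_cm),
      semi_major_cm = semi_major_cm,
      semi_minor_cm = semi_minor_cm,
      rotation_deg = rotation_deg,
      lobes = lobes,
      analytic_area_cm2 = if (kind == "pseudopod") {
        NA_real_
      } else {
        pi * semi_major_cm * semi_minor_cm
      }
    ),
    class = "shape_spec"
  )
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf(
    "<shape_spec %s: a=%.3f b=%.3f cm at (%.2f, %.2f), rot=%.1f deg%s>\n",
    x$kind, x$semi_major_cm, x$semi_minor_cm,
    x$center_cm[1], x$center_cm[2], x$rotation_deg,
    if (is.na(x$analytic_area_cm2)) {
      sprintf(", %d lobes", nrow(x$lobes))
    } else {
      sprintf(", area=%.4f cm2", x$analytic_area_cm2)
    }
  ))
  invisible(x)
}

# Boundary radius (cm) of a shape in polar coordinates about its center;
# theta is absolute (canvas frame), in radians.
shape_radius_cm <- function(spec, theta) {
  th <- theta - spec$rotation_deg * pi / 180
  a <- spec$semi_major_cm
  b <- spec$semi_minor_cm
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  if (spec$kind == "pseudopod") {
    for (i in seq_len(nrow(spec$lobes))) {
      mu <- spec$lobes$angle_deg[i] * pi / 180
      sig <- spec$lobes$width_deg[i] * pi / 180
      r <- r + spec$lobes$amplitude_cm[i] *
        exp(-ang_diff(th, mu)^2 / (2 * sig^2))
    }
  }
  r
}

# Conservative outer radius bound (cm), used for bounding boxes and
# placement checks.
shape_max_radius_cm <- function(spec) {
  r <- spec$semi_major_cm
  if (spec$kind == "pseudopod") r <- r + sum(spec$lobes$amplitude_cm)
  r
}

# Membership test under the pixel-center rasterization rule: a pixel belongs
# to the shape iff its center lies strictly inside the analytic boundary.
# px, py are pixel-center coordinates (0-based column/x and row/y indices).
shape_contains <- function(spec, px, py, pixels_per_cm) {
  dx <- px / pixels_per_cm - spec$center_cm[1]
  dy <- py / pixels_per_cm - spec$center_cm[2]
  if (spec$kind == "pseudopod") {
    rho <- sqrt(dx^2 + dy^2)
    rho < shape_radius_cm(spec, atan2(dy, dx))
  } else {
    phi <- spec$rotation_deg * pi / 180
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    (u / spec$semi_major_cm)^2 + (v / spec$semi_minor_cm)^2 < 1
  }
}

#' Rasterize a shape on its own canvas
#'
#' Applies the pixel-center rule (a pixel is in the shape iff its center lies
#' inside the analytic boundary) on a canvas just covering the shape.
#'
#' @param spec a [shape_spec()]. Its `center_cm` is interpreted relative to
#'   the returned canvas, whose pixel (1, 1) center is the origin.
#' @param pixels_per_cm rasterization scale.
#' @param margin_px extra border pixels around the analytic bounding box.
#' @return list with `mask` (logical matrix, rows = y, cols = x),
#'   `pixel_count`, and `centroid_px` (0-based `(row, col)` of the pixel
#'   centroid).
#' @export
rasterize_shape <- function(spec, pixels_per_cm, margin_px = 2) {
  rmax <- shape_max_radius_cm(spec) * pixels_per_cm
  cx <- spec$center_cm[1] * pixels_per_cm
  cy <- spec$center_cm[2] * pixels_per_cm
  x0 <- floor(cx - rmax) - margin_px
  x1 <- ceiling(cx + rmax) + margin_px
  y0 <- floor(cy - rmax) - margin_px
  y1 <- ceiling(cy + rmax) + margin_px
  xs <- x0:x1
  ys <- y0:y1
  px <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  py <- matrix(rep(ys, times = length(xs)), length(ys), length(xs))
  inside <- matrix(
    shape_contains(spec, as.vector(px), as.vector(py), pixels_per_cm),
    length(ys), length(xs)
  )
  idx <- which(inside, arr.ind = TRUE)
  list(
    mask = inside,
    pixel_count = nrow(idx),
    centroid_px = c(
      mean(idx[, 1] - 1 + y0),
      mean(idx[, 2] - 1 + x0)
    ),
    origin_px = c(y0, x0)
  )
}

# Draw one random shape spec (no placement). Used by the generators.
# axis_range_cm bounds both semi-axes; pseudopod lobes follow the package's
# stated defaults: 3-8 lobes, amplitudes 15-45% of the minor semi-axis,
# angular widths 10-35 degrees.
random_shape_spec <- function(kind, axis_range_cm, center_cm = c(0, 0)) {
  ax <- sort(runif(2, axis_range_cm[1], axis_range_cm[2]), decreasing = TRUE)
  rot <- runif(1, 0, 180)
  if (kind == "circle") {
    shape_spec("circle", center_cm, ax[1], ax[1], rotation_deg = 0)
  } else if (kind == "ellipse") {
    shape_spec("ellipse", center_cm, ax[1], ax[2], rotation_deg = rot)
  } else {
    n_lobes <- sample(3:8, 1)
    lobes <- data.frame(
      angle_deg = runif(n_lobes, 0, 360),
      amplitude_cm = runif(n_lobes, 0.15, 0.45) * ax[2],
      width_deg = runif(n_lobes, 10, 35)
    )
    shape_spec("pseudopod", center_cm, ax[1], ax[2], rotation_deg = rot,
               lobes = lobes)
  }
}
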