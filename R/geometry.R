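#' Wheal pixel clustering
#'
#' Connected-component labeling (8-connectivity) of one mask class.
#' Components smaller than `min_size` are discarded as speckle; survivors
#' are sorted by centroid in row-major order and numbered from 1.
#'
#' @param mask a [label_mask()].
#' @param target_class class to cluster, default `"wheal"`.
#' @param min_size minimum component pixel count (default 10).
#' @return list of `wheal_cluster` objects, each with `id`, `pixels`
#'   (1-based `(row, col)` matrix), `pixel_count`, and `centroid` (`(row,
#'   col)`, 0-based reals).
#' @export
cluster_pixels <- function(mask, target_class = "wheal", min_size = 10) {
  code <- match(target_class, MASK_CLASSES) - 1L
  if (is.na(code)) stop_input("unknown class '%s'", target_class)
  lab <- .label_components(unclass(mask) == code, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  clusters <- lapply(seq_len(n), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    list(
      pixels = px,
      pixel_count = nrow(px),
      centroid = c(mean(px[, 1]) - 1, mean(px[, 2]) - 1)
    )
  })
  clusters <- Filter(function(cl) cl$pixel_count >= min_size, clusters)
  if (length(clusters) == 0L) return(list())
  ord <- order(
    vapply(clusters, function(cl) cl$centroid[1], 0),
    vapply(clusters, function(cl) cl$centroid[2], 0)
  )
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i
    class(clusters[[i]]) <- "wheal_cluster"
  }
  clusters
}

#' @export
print.wheal_cluster <- function(x, ...) {
  cat(sprintf(
    "<wheal_cluster #%d: %d px, centroid (%.1f, %.1f)>\n",
    x$id, x$pixel_count, x$centroid[1], x$centroid[2]
  ))
  invisible(x)
}

#' Pixel-to-area calibration from the reference tag
#'
#' The 3 x 3 cm reference tag photographed in frame provides the scale: the
#' largest 8-connected `rt` component is taken as the tag (smaller
#' components are assumed misclassifications) and every pixel is worth
#' `9 cm^2 / rt_pixel_count`.
#'
#' @param mask a [label_mask()].
#' @param rt_area_cm2 physical tag area, default 9 (3 x 3 cm).
#' @return a `calibration` list: `rt_pixel_count`, `rt_area_cm2`,
#'   `cm2_per_pixel`, `cm_per_pixel`.
#' @export
calibrate <- function(mask, rt_area_cm2 = 9) {
  lab <- .label_components(unclass(mask) == 2L, 8L)
  n <- max(lab)
  if (n == 0L) stop_input("no reference-tag pixels: cannot calibrate")
  counts <- tabulate(lab[lab > 0L], nbins = n)
  calibration(max(counts), rt_area_cm2)
}

#' @rdname calibrate
#' @param rt_pixel_count pixel count of the tag (for building a calibration
#'   directly, e.g. an exact one from a known rasterization scale).
#' @export
calibration <- function(rt_pixel_count, rt_area_cm2 = 9) {
  if (rt_pixel_count <= 0) stop_input("rt_pixel_count must be positive")
  structure(
    list(
      rt_pixel_count = rt_pixel_count,
      rt_area_cm2 = rt_area_cm2,
      cm2_per_pixel = rt_area_cm2 / rt_pixel_count,
      cm_per_pixel = sqrt(rt_area_cm2 / rt_pixel_count)
    ),
    class = "calibration"
  )
}

#' Pixel-proportion wheal area
#'
#' The area estimator at the core of the protocol: a simple proportion
#' between the wheal's pixel count and the reference tag's, which has known
#' area. It is invariant to the wheal's geometric contour.
#'
#' @param cluster a `wheal_cluster` (or anything with `pixel_count`).
#' @param cal a [calibration()].
#' @return area in cm^2.
#' @export
cluster_area_cm2 <- function(cluster, cal) {
  cluster$pixel_count * cal$cm2_per_pixel
}

#' Computational largest and perpendicular diameters
#'
#' Sweeps chords through the cluster's pixel centroid: for each angle, the
#' chord is the distance between the two extreme boundary intersections of
#' the centroid line with the pixel region, extended by 0.5 px at each end
#' (unbiased for center-sampled rasterization). The largest diameter (LD) is
#' the maximal chord (smallest angle wins ties); the perpendicular diameter
#' (PD) is the chord at the LD angle + 90 degrees. If the centroid falls
#' outside the region (strongly non-convex shape) the chord falls back to
#' the total in-region extent along the line and a warning is issued.
#'
#' @param cluster a `wheal_cluster`.
#' @param cal a [calibration()] supplying `cm_per_pixel`.
#' @param angle_step_deg angular resolution of the sweep, default 1 (must be
#'   <= 1).
#' @return list `LD_cm`, `PD_cm`, `LD_angle_deg`, plus the pixel-unit
#'   lengths `LD_px`, `PD_px`.
#' @export
computational_diameters <- function(cluster, cal, angle_step_deg = 1) {
  if (angle_step_deg > 1) stop_input("angle_step_deg must be <= 1")
  if (cluster$pixel_count == 0) stop_input("empty cluster")
  px <- cluster$pixels
  cy <- cluster$centroid[1]
  cx <- cluster$centroid[2]
  # region membership within the cluster's bounding box
  r0 <- min(px[, 1]); r1 <- max(px[, 1])
  c0 <- min(px[, 2]); c1 <- max(px[, 2])
  region <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  region[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
  # local coordinates within the bounding box (0-based)
  cy_loc <- cy - (r0 - 1)
  cx_loc <- cx - (c0 - 1)
  centroid_in <- {
    rr <- round(cy_loc) + 1
    cc <- round(cx_loc) + 1
    rr >= 1 && rr <= nrow(region) && cc >= 1 && cc <= ncol(region) &&
      region[rr, cc]
  }
  if (!centroid_in) {
    warning("cluster centroid lies outside the region; ",
            "chords use total in-region extent", call. = FALSE)
  }
  chord_col <- if (centroid_in) 1L else 2L
  sweep_step <- 0.25
  chord_at <- function(theta) {
    .chord_sweep(region, cy_loc, cx_loc, theta, sweep_step)[, chord_col]
  }
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg) * pi / 180
  chords <- chord_at(angles)
  best <- which.max(chords)   # first maximum: smallest angle wins ties
  ld_px <- chords[best]
  pd_px <- chord_at(angles[best] + pi / 2)
  # the perpendicular chord is evaluated off the sweep grid and can exceed
  # the gridded maximum by a sub-pixel sliver; clamp to keep LD >= PD
  pd_px <- min(pd_px, ld_px)
  list(
    LD_cm = ld_px * cal$cm_per_pixel,
    PD_cm = pd_px * cal$cm_per_pixel,
    LD_angle_deg = angles[best] * 180 / pi,
    LD_px = ld_px,
    PD_px = pd_px
  )
}

#' Diameter-based area approximations MA1 and MA2
#'
#' The standard medical protocol approximates the wheal area from its
#' largest diameter (LD) and the perpendicular diameter (PD): `ma1_area` as
#' a circle with diameter `(LD + PD) / 2`, `ma2_area` as an ellipse with
#' axes LD and PD. By AM-GM, `MA1 >= MA2` with equality iff `LD == PD`.
#'
#' @param LD_cm,PD_cm diameters in cm, `LD_cm >= PD_cm > 0`.
#' @return area in cm^2.
#' @export
ma1_area <- function(LD_cm, PD_cm) {
  check_diameters(LD_cm, PD_cm)
  pi * ((LD_cm + PD_cm) / 2 / 2)^2
}

#' @rdname ma1_area
#' @export
ma2_area <- function(LD_cm, PD_cm) {
  check_diameters(LD_cm, PD_cm)
  pi * (LD_cm / 2) * (PD_cm / 2)
}

check_diameters <- function(LD_cm, PD_cm) {
  if (any(PD_cm <= 0) || any(LD_cm < PD_cm)) {
    stop_input("need LD_cm >= PD_cm > 0")
  }
  invisible(TRUE)
}

#' Measure all wheals in a mask
#'
#' End-to-end geometric measurement: cluster the wheal class, calibrate from
#' the reference tag (unless an explicit calibration is supplied), and
#' compute per wheal the pixel-proportion area, computational LD/PD, and the
#' MA1/MA2 diameter-based approximations.
#'
#' @param mask a [label_mask()].
#' @param cal optional [calibration()]; by default derived from the mask's
#'   `rt` class.
#' @param min_size cluster size filter, see [cluster_pixels()].
#' @param angle_step_deg chord sweep resolution, see
#'   [computational_diameters()].
#' @return data frame with one row per wheal: `id`, `pixel_count`,
#'   `centroid_row`, `centroid_col`, `area_cm2`, `LD_cm`, `PD_cm`,
#'   `MA1_cm2`, `MA2_cm2`.
#' @export
measure_wheals <- function(mask, cal = NULL, min_size = 10,
                           angle_step_deg = 1) {
  if (is.null(cal)) cal <- calibrate(mask)
  clusters <- cluster_pixels(mask, "wheal", min_size = min_size)
  rows <- lapply(clusters, function(cl) {
    d <- computational_diameters(cl, cal, angle_step_deg)
    data.frame(
      id = cl$id,
      pixel_count = cl$pixel_count,
      centroid_row = cl$centroid[1],
      centroid_col = cl$centroid[2],
      area_cm2 = cluster_area_cm2(cl, cal),
      LD_cm = d$LD_cm,
      PD_cm = d$PD_cm,
      MA1_cm2 = ma1_area(d$LD_cm, d$PD_cm),
      MA2_cm2 = ma2_area(d$LD_cm, d$PD_cm)
    )
  })
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(
      id = integer(), pixel_count = integer(), centroid_row = numeric(),
      centroid_col = numeric(), area_cm2 = numeric(), LD_cm = numeric(),
      PD_cm = numeric(), MA1_cm2 = numeric(), MA2_cm2 = numeric()
    )
  }
  attr(out, "calibration") <- cal
  out
}
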