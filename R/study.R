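#' Per-shape area table for a generated shape group
#'
#' Runs the full measurement protocol over a group produced by
#' [make_shape_group()]: calibrates each file from its reference square,
#' clusters the shape pixels, matches clusters to the generator's
#' ground-truth specs by nearest centroid, and tabulates every area method
#' per shape — `Expected` (analytic, `NA` for pseudopods), `AIS` (the
#' pixel-proportion estimate), and `MA1` / `MA2` from the computational
#' LD/PD diameters.
#'
#' @param group list of files from [make_shape_group()].
#' @param angle_step_deg chord sweep resolution for LD/PD.
#' @param min_size cluster size filter.
#' @return data frame with columns `file`, `shape`, `pixel_count`,
#'   `Expected`, `AIS`, `MA1`, `MA2`, `LD_cm`, `PD_cm`.
#' @export
group_area_table <- function(group, angle_step_deg = 1, min_size = 10) {
  rows <- lapply(seq_along(group), function(f) {
    file <- group[[f]]
    cal <- calibrate(file$mask)
    clusters <- cluster_pixels(file$mask, "wheal", min_size = min_size)
    # match generator specs to clusters by nearest pixel centroid
    spec_cent <- t(vapply(file$specs, function(s) {
      px <- s$pixels
      c(mean(px[, 1]) - 1, mean(px[, 2]) - 1)
    }, numeric(2)))
    clus_cent <- t(vapply(clusters, function(cl) cl$centroid, numeric(2)))
    out <- lapply(seq_along(file$specs), function(i) {
      d2 <- (clus_cent[, 1] - spec_cent[i, 1])^2 +
        (clus_cent[, 2] - spec_cent[i, 2])^2
      cl <- clusters[[which.min(d2)]]
      dm <- computational_diameters(cl, cal, angle_step_deg)
      data.frame(
        file = f,
        shape = i,
        pixel_count = cl$pixel_count,
        Expected = file$specs[[i]]$analytic_area_cm2,
        AIS = cluster_area_cm2(cl, cal),
        MA1 = ma1_area(dm$LD_cm, dm$PD_cm),
        MA2 = ma2_area(dm$LD_cm, dm$PD_cm),
        LD_cm = dm$LD_cm,
        PD_cm = dm$PD_cm
      )
    })
    do.call(rbind, out)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Diameter accuracy study on standalone rasterized regular shapes
#'
#' Rasterizes `n` random circles/ellipses at high resolution on per-shape
#' canvases with exact calibration, runs the centroid-chord sweep, and
#' reports the percentage deviation of computational LD and PD from their
#' analytic values (`2a` and `2b`).
#'
#' @param n number of shapes.
#' @param axis_range_cm uniform sampling interval for the semi-axes (cm).
#' @param pixels_per_cm rasterization scale (default 100).
#' @param angle_step_deg chord sweep resolution (default 0.5).
#' @param seed integer seed.
#' @return data frame with one row per shape: `kind`, `a_cm`, `b_cm`,
#'   `rotation_deg`, `LD_cm`, `PD_cm`, `LD_dev_pct`, `PD_dev_pct`.
#' @export
diameter_accuracy_study <- function(n = 150, axis_range_cm = c(1, 2),
                                    pixels_per_cm = 100,
                                    angle_step_deg = 0.5, seed = 1L) {
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kind <- sample(c("circle", "ellipse"), 1)
      random_shape_spec(kind, axis_range_cm)
    })
  })
  cal <- calibration(pixels_per_cm^2 * 9)  # exact scale: 9 cm2 of pixels
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    center <- sp$semi_major_cm + 4 / pixels_per_cm
    sp$center_cm <- c(center, center)
    ras <- rasterize_shape(sp, pixels_per_cm)
    px <- which(ras$mask, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    cl <- structure(
      list(
        id = 1L, pixels = px, pixel_count = nrow(px),
        centroid = c(mean(px[, 1]) - 1, mean(px[, 2]) - 1)
      ),
      class = "wheal_cluster"
    )
    dm <- computational_diameters(cl, cal, angle_step_deg)
    ld_true <- 2 * sp$semi_major_cm
    pd_true <- 2 * sp$semi_minor_cm
    data.frame(
      kind = sp$kind,
      a_cm = sp$semi_major_cm,
      b_cm = sp$semi_minor_cm,
      rotation_deg = sp$rotation_deg,
      LD_cm = dm$LD_cm,
      PD_cm = dm$PD_cm,
      LD_dev_pct = 100 * abs(dm$LD_cm - ld_true) / ld_true,
      PD_dev_pct = 100 * abs(dm$PD_cm - pd_true) / pd_true
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
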