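test_that("cluster_pixels labels, filters and orders components", {
  g <- matrix(0L, 40, 40)
  g[5:14, 5:14] <- 1L      # 100 px
  g[20:29, 15:34] <- 1L    # 200 px
  g[38, 38] <- 1L          # speckle
  cls <- cluster_pixels(label_mask(g), "wheal", min_size = 10)
  expect_length(cls, 2)
  expect_setequal(vapply(cls, function(c) c$pixel_count, 0L), c(100L, 200L))
  expect_equal(vapply(cls, function(c) c$id, 0L), 1:2)
  # row-major centroid ordering
  expect_lt(cls[[1]]$centroid[1], cls[[2]]$centroid[1])
  expect_equal(cls[[1]]$centroid, c(mean(5:14) - 1, mean(5:14) - 1))

  # a single pixel falls below min_size
  g1 <- matrix(0L, 10, 10)
  g1[5, 5] <- 1L
  expect_length(cluster_pixels(label_mask(g1), "wheal", min_size = 10), 0)
})

test_that("cluster_pixels agrees with a flood-fill oracle on random masks", {
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(runif(2500) < 0.35, 50, 50)
    cls <- cluster_pixels(label_mask(matrix(as.integer(m), 50, 50)),
                          "wheal", min_size = 1)
    lab <- oracle_flood_fill(m, 8)
    expect_length(cls, max(lab))
    # identical partitions: each cluster's pixels map to one oracle label
    seen <- integer(0)
    for (cl in cls) {
      labs <- unique(lab[cl$pixels])
      expect_length(labs, 1)
      expect_equal(cl$pixel_count, sum(lab == labs))
      seen <- c(seen, labs)
    }
    expect_setequal(seen, seq_len(max(lab)))
  }
})

test_that("calibration follows the reference-tag pixel count", {
  g <- matrix(0L, 120, 120)
  g[11:110, 11:110] <- 2L  # 10000 px tag
  cal <- calibrate(label_mask(g))
  expect_equal(cal$cm2_per_pixel, 9e-4)
  expect_equal(cal$cm_per_pixel, 0.03)

  # a small spurious rt component (e.g. a misclassified mole) is ignored
  g[1:3, 1:4] <- 2L
  expect_equal(calibrate(label_mask(g))$rt_pixel_count, 10000)

  expect_error(calibrate(label_mask(matrix(0L, 5, 5))), "cannot calibrate")

  # rendered scene at 100/3 px/cm: within 2% of (3/100)^2 cm2/px
  sc <- render_scene(scene_spec(seed = 1))
  expect_lt(abs(calibrate(sc$mask)$cm2_per_pixel - 9e-4) / 9e-4, 0.02)
})

test_that("pixel-proportion area is exact arithmetic and shape-invariant", {
  cal <- calibration(10000)   # 9e-4 cm2 per pixel
  expect_equal(cluster_area_cm2(list(pixel_count = 1000), cal), 0.9)
  # the tag measured against itself returns its own 9 cm2
  g <- matrix(0L, 60, 60)
  g[6:45, 11:50] <- 2L
  mask <- label_mask(g)
  rt_cluster <- cluster_pixels(mask, "rt")[[1]]
  expect_equal(cluster_area_cm2(rt_cluster, calibrate(mask)), 9)
  # equal pixel counts => equal areas regardless of contour
  expect_equal(
    cluster_area_cm2(list(pixel_count = 4321), cal),
    cluster_area_cm2(list(pixel_count = 4321), cal)
  )
  # rasterized 1 cm circle at 50 px/cm with exact calibration: ~pi cm2
  cl <- raster_cluster(shape_spec("circle", c(3, 3), 1, 1), 50)
  expect_lt(abs(cluster_area_cm2(cl, calibration(50^2 * 9)) - pi) / pi, 0.01)
})

test_that("computational diameters recover analytic LD and PD", {
  # circle: LD ~ PD, relative difference < 1%
  cal50 <- calibration(50^2 * 9)
  cl <- raster_cluster(shape_spec("circle", c(3, 3), 1, 1), 50)
  d <- computational_diameters(cl, cal50, 1)
  expect_lt(abs(d$LD_cm - d$PD_cm) / d$LD_cm, 0.01)
  expect_lt(abs(d$LD_cm - 2) / 2, 0.01)

  # axis-aligned ellipse a = 2, b = 1 cm at 100 px/cm: within 0.6%
  cal100 <- calibration(100^2 * 9)
  cl2 <- raster_cluster(shape_spec("ellipse", c(4, 4), 2, 1), 100)
  d2 <- computational_diameters(cl2, cal100, 1)
  expect_lt(abs(d2$LD_cm - 4) / 4, 0.006)
  expect_lt(abs(d2$PD_cm - 2) / 2, 0.006)
  # near-degenerate chords around the major axis: allow a few degrees
  expect_lt(min(d2$LD_angle_deg, 180 - d2$LD_angle_deg), 3)

  # rotated ellipse: LD angle tracks the rotation
  cl3 <- raster_cluster(
    shape_spec("ellipse", c(4, 4), 2, 1, rotation_deg = 40), 100
  )
  d3 <- computational_diameters(cl3, cal100, 1)
  expect_lt(abs(d3$LD_cm - 4) / 4, 0.006)
  expect_lt(abs(d3$LD_angle_deg - 40), 2)

  expect_error(computational_diameters(cl, cal50, 2), "angle_step")
})

test_that("1-degree sweep LD matches the dense 0.1-degree oracle", {
  set.seed(14)
  specs <- list(
    shape_spec("ellipse", c(3, 3), 1.4, 0.7, rotation_deg = 63),
    shape_spec("circle", c(3, 3), 1.1, 1.1),
    whealmeter:::random_shape_spec("pseudopod", c(0.7, 1.1),
                                   center_cm = c(3, 3))
  )
  cal <- calibration(30^2 * 9)
  for (sp in specs) {
    ras <- rasterize_shape(sp, 30)
    cl <- cluster_from_region(ras$mask)
    d <- computational_diameters(cl, cal, 1)
    ld_oracle <- oracle_ld(ras$mask, cl$centroid[1], cl$centroid[2], 0.1)
    expect_lt(abs(d$LD_px - ld_oracle), 1)  # within one pixel-equivalent
  }
})

test_that("MA1 and MA2 implement the circle and ellipse approximations", {
  expect_equal(ma1_area(1, 1), pi / 4)
  expect_equal(ma2_area(1, 1), pi / 4)
  expect_equal(ma1_area(0.5, 0.3), pi * 0.04)
  expect_equal(ma2_area(0.5, 0.3), pi * 0.0375)
  expect_error(ma1_area(0.3, 0.5), "LD_cm >= PD_cm")
  expect_error(ma2_area(1, 0), "LD_cm >= PD_cm")
  # AM-GM: MA1 >= MA2, equality iff LD == PD
  set.seed(4)
  for (i in 1:50) {
    pd <- runif(1, 0.1, 2)
    ld <- pd + rexp(1, 2)
    expect_gt(ma1_area(ld, pd), ma2_area(ld, pd))
  }
  expect_equal(ma1_area(1.3, 1.3), ma2_area(1.3, 1.3))
})

test_that("measure_wheals ties the geometric pipeline together", {
  grp <- make_shape_group("regular", 1, 4, c(0.6, 1.2), 100 / 3, seed = 17)
  tab <- measure_wheals(grp[[1]]$mask)
  expect_equal(nrow(tab), 4)
  cal <- attr(tab, "calibration")
  expect_equal(tab$area_cm2, tab$pixel_count * cal$cm2_per_pixel)
  expect_true(all(tab$LD_cm >= tab$PD_cm))
  expect_true(all(tab$MA1_cm2 >= tab$MA2_cm2))
  # no wheals: empty table, still calibrated
  empty <- measure_wheals(render_scene(scene_spec(seed = 3))$mask)
  expect_equal(nrow(empty), 0)
  expect_s3_class(attr(empty, "calibration"), "calibration")
})
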