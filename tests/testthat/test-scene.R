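test_that("render_scene produces consistent image, mask and ground truth", {
  sp <- scene_spec(
    canvas_px = c(320L, 240L), pixels_per_cm = 50,
    rt_position_px = c(8, 8),
    wheal_specs = list(shape_spec("circle", c(4.5, 3), 1, 1)),
    seed = 5
  )
  out <- render_scene(sp)
  expect_equal(dim(out$image)[1:2], dim(out$mask))
  # rt pixel count ~ (3 cm * 50 px/cm)^2
  expect_equal(sum(out$mask == 2L), 150^2)
  # wheal pixel count within 1% of pi * 50^2
  expect_lt(abs(sum(out$mask == 1L) - pi * 2500) / (pi * 2500), 0.01)
  expect_equal(out$specs[[1]]$pixel_count, sum(out$mask == 1L))

  # empty scene: only background and rt classes
  empty <- render_scene(scene_spec(seed = 2))
  expect_setequal(unique(as.integer(empty$mask)), c(0L, 2L))

  # determinism: identical spec -> bit-identical outputs
  again <- render_scene(sp)
  expect_identical(out$image, again$image)
  expect_identical(unclass(out$mask), unclass(again$mask))
})

test_that("render_scene rejects overlap and out-of-canvas placement", {
  base <- scene_spec(
    canvas_px = c(320L, 240L), pixels_per_cm = 50, rt_position_px = c(8, 8)
  )
  base$wheal_specs <- list(
    shape_spec("circle", c(4.5, 3), 0.8, 0.8),
    shape_spec("circle", c(4.6, 3), 0.8, 0.8)
  )
  expect_error(render_scene(base), "shape 2 overlaps another wheal")
  base$wheal_specs <- list(shape_spec("circle", c(1.5, 1.5), 1, 1))
  expect_error(render_scene(base), "overlaps the reference tag")
  base$wheal_specs <- list(shape_spec("circle", c(0.2, 3), 1, 1))
  expect_error(render_scene(base), "outside the canvas")
})

test_that("make_shape_group produces the requested study structure", {
  grp <- make_shape_group("regular", 3, 10, c(0.5, 1.5), 100 / 3, seed = 9)
  expect_length(grp, 3)
  areas <- unlist(lapply(grp, function(f) {
    vapply(f$specs, function(s) s$analytic_area_cm2, 0)
  }))
  expect_length(areas, 30)
  expect_true(all(areas >= pi * 0.25 & areas <= pi * 2.25))
  # every file carries the 3 x 3 cm reference square
  for (f in grp) {
    expect_equal(sum(f$mask == 2L), 100^2)
  }
  # reproducibility
  grp2 <- make_shape_group("regular", 3, 10, c(0.5, 1.5), 100 / 3, seed = 9)
  expect_identical(unclass(grp[[2]]$mask), unclass(grp2[[2]]$mask))

  irr <- make_shape_group("irregular", 1, 1, c(0.8, 1.2), 40, seed = 3)
  wheal <- unclass(irr[[1]]$mask) == 1L
  expect_equal(max(oracle_flood_fill(wheal, 8)), 1L)
  expect_true(is.na(irr[[1]]$specs[[1]]$analytic_area_cm2))

  expect_length(make_shape_group("regular", 0, 10), 0)
  expect_error(make_shape_group("regular", 1, 0), "shapes_per_file")
})

test_that("augment_mirror implements the mirroring chain", {
  # asymmetric 2 x 2 image: all four outputs distinct, chain is an involution
  img <- array(c(1, 2, 3, 4) / 4, c(2, 2, 3))
  msk <- label_mask(matrix(c(0L, 1L, 2L, 0L), 2, 2))
  out <- augment_mirror(img, msk)
  expect_length(out, 4)
  keys <- vapply(out, function(p) paste(p$image, collapse = ","), "")
  expect_length(unique(keys), 4)
  # the four masks are: original, H, 180-degree rotation, V
  m <- unclass(msk)
  expect_identical(unclass(out[[2]]$mask), m[, 2:1])
  expect_identical(unclass(out[[3]]$mask), m[2:1, 2:1])
  expect_identical(unclass(out[[4]]$mask), m[2:1, ])
  # applying the chain to the last output returns to the original
  again <- augment_mirror(out[[4]]$image, out[[4]]$mask)
  expect_identical(again[[4]]$image, img)
  # class histograms identical across all outputs
  hists <- lapply(out, function(p) tabulate(as.integer(p$mask) + 1L, 3))
  for (h in hists) expect_identical(h, hists[[1]])

  # uniform input: all four outputs identical
  u <- augment_mirror(array(0.5, c(2, 2, 3)),
                      label_mask(matrix(0L, 2, 2)))
  for (p in u) expect_identical(p$image, u[[1]]$image)

  expect_error(
    augment_mirror(array(0, c(2, 3, 3)), label_mask(matrix(0L, 2, 2))),
    "dimensions differ"
  )
})

test_that("label mask color coding round-trips bit-exactly", {
  m <- label_mask(matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 2, 3))
  img <- encode_label_mask(m)
  expect_identical(img[1, 1, ], c(255L, 0L, 0L))      # background red
  expect_identical(img[2, 1, ], c(255L, 0L, 255L))    # wheal magenta
  expect_identical(img[1, 2, ], c(0L, 0L, 0L))        # rt black
  expect_identical(unclass(decode_label_mask(img)), unclass(m))

  # decode -> encode identity on a synthetic palette image
  img2 <- encode_label_mask(label_mask(matrix(c(2L, 0L), 1, 2)))
  expect_identical(encode_label_mask(decode_label_mask(img2)), img2)

  # strict palette: off-by-one color is rejected with coordinates
  bad <- img
  bad[2, 1, 1] <- 254L
  expect_error(decode_label_mask(bad), "row=2, col=1.*254, 0, 255")

  # PNG file round trip
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(unclass(read_mask_png(path)), unclass(m))
})
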