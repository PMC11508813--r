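#' Run configuration for the end-to-end pipeline
#'
#' @param images character vector of scene image paths (PNG).
#' @param out_dir output directory (created if missing).
#' @param model_path optional model checkpoint; when `NULL`, `mask_paths`
#'   must supply an oracle/reference mask per image.
#' @param mask_paths optional color-coded mask PNGs, one per image, used
#'   instead of model inference.
#' @param min_size,angle_step_deg,pad_px geometry parameters (see
#'   [cluster_pixels()], [computational_diameters()],
#'   [cluster_confusion_metrics()]).
#' @param seed integer seed recorded in every report.
#' @param quiet suppress progress messages.
#' @return a `run_config` list.
#' @export
run_config <- function(images, out_dir, model_path = NULL,
                       mask_paths = NULL, min_size = 10,
                       angle_step_deg = 1, pad_px = 5, seed = 1L,
                       quiet = FALSE) {
  if (is.null(model_path) && is.null(mask_paths)) {
    stop_input("need a model checkpoint or oracle mask paths")
  }
  if (!is.null(mask_paths) && length(mask_paths) != length(images)) {
    stop_input("mask_paths must match images one-to-one")
  }
  for (p in c(images, model_path, mask_paths)) {
    if (!file.exists(p)) stop_input("input path does not exist: %s", p)
  }
  structure(
    list(
      images = images, out_dir = out_dir, model_path = model_path,
      mask_paths = mask_paths, min_size = min_size,
      angle_step_deg = angle_step_deg, pad_px = pad_px,
      seed = as.integer(seed), quiet = quiet
    ),
    class = "run_config"
  )
}

# Polynomial rolling hash (mod 2^31 - 1) of the deparsed configuration, as
# 8 hex digits; used to stamp reports with the resolved configuration.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% m
  sprintf("%08x", h)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full SPT reading pipeline
#'
#' For every input image: obtain a label mask (model inference or supplied
#' oracle mask), calibrate from the reference tag, cluster and measure all
#' wheals, and write three artifacts per image into `out_dir`: an annotated
#' overlay PNG (numbered wheal contours plus an upper-left legend of areas
#' in cm^2), a per-wheal CSV, and a JSON run record embedding the resolved
#' configuration and its hash. Images without a detectable reference tag
#' are skipped with a logged calibration error; unreadable files are logged
#' and the run continues.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of run records, one per processed image.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- if (!is.null(config$model_path)) {
    load_model(config$model_path)
  } else {
    NULL
  }
  resolved <- config[c("images", "model_path", "mask_paths", "min_size",
                       "angle_step_deg", "pad_px", "seed")]
  hash <- config_hash(resolved)
  records <- list()
  for (i in seq_along(config$images)) {
    img_path <- config$images[i]
    stem <- sub("\\.[^.]+$", "", basename(img_path))
    res <- tryCatch({
      image <- read_scene_png(img_path)
      mask <- if (is.null(model)) {
        read_mask_png(config$mask_paths[i])
      } else {
        predict_mask(model, image)
      }
      cal <- calibrate(mask)
      meas <- measure_wheals(mask, cal, min_size = config$min_size,
                             angle_step_deg = config$angle_step_deg)
      clusters <- cluster_pixels(mask, "wheal", min_size = config$min_size)
      overlay <- render_overlay(image, clusters, meas)
      write_scene_png(overlay, file.path(config$out_dir,
                                         paste0(stem, "_overlay.png")))
      record <- list(
        image = basename(img_path),
        config = resolved,
        config_hash = hash,
        seed = config$seed,
        calibration = cal[c("rt_pixel_count", "rt_area_cm2",
                            "cm2_per_pixel")],
        wheals = meas
      )
      write_report(record, file.path(config$out_dir, paste0(stem, ".json")))
      utils::write.csv(meas, file.path(config$out_dir, paste0(stem, ".csv")),
                       row.names = FALSE)
      pipeline_log(config$quiet, "[%s] %d wheal(s) measured", stem,
                   nrow(meas))
      record
    }, error = function(e) {
      pipeline_log(config$quiet, "[%s] skipped: %s", stem,
                   conditionMessage(e))
      NULL
    })
    if (!is.null(res)) records[[length(records) + 1L]] <- res
  }
  invisible(records)
}

#' Write / read a machine-readable run record
#'
#' Records round-trip losslessly through JSON: numeric values are
#' serialized at full precision. `read_report` validates the schema and
#' reports the path of the first missing field.
#'
#' @param record a run record (see [run_pipeline()]).
#' @param path JSON file path.
#' @export
write_report <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- list(
    "image" = c("image"),
    "config_hash" = c("config_hash"),
    "calibration.rt_pixel_count" = c("calibration", "rt_pixel_count"),
    "calibration.cm2_per_pixel" = c("calibration", "cm2_per_pixel"),
    "wheals" = c("wheals")
  )
  for (fp in names(required)) {
    if (is.null(rec[[required[[fp]]]])) {
      stop_input("report schema violation: missing field '%s'", fp)
    }
  }
  rec$wheals <- as.data.frame(rec$wheals)
  rec
}

# --- annotated overlay -----------------------------------------------------

# 3x5 bitmap glyphs for the legend (digits, separator characters).
overlay_font <- local({
  g <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"),
    "." = c("000", "000", "000", "000", "010"),
    ":" = c("000", "010", "000", "010", "000"),
    " " = c("000", "000", "000", "000", "000")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]]) == 1L
    }))
  })
})

# Stamp text (digits / '.' / ':') onto an image plane at (row, col), scale
# by integer factor.
draw_text <- function(image, text, row, col, scale = 2,
                      color = c(1, 1, 1)) {
  chars <- strsplit(text, "")[[1]]
  h <- dim(image)[1]; w <- dim(image)[2]
  x <- col
  for (ch in chars) {
    glyph <- overlay_font[[ch]]
    if (is.null(glyph)) glyph <- overlay_font[[" "]]
    for (gr in 1:5) {
      for (gc in 1:3) {
        if (!glyph[gr, gc]) next
        rr <- row + (gr - 1) * scale + seq_len(scale) - 1
        cc <- x + (gc - 1) * scale + seq_len(scale) - 1
        rr <- rr[rr >= 1 & rr <= h]
        cc <- cc[cc >= 1 & cc <= w]
        if (length(rr) && length(cc)) {
          for (k in 1:3) image[rr, cc, k] <- color[k]
        }
      }
    }
    x <- x + 4 * scale
  }
  image
}

#' Render the annotated report overlay
#'
#' Draws each wheal's contour and its cluster number on the scene, plus an
#' upper-left legend listing the measured areas in cm^2 (2 decimals; the
#' machine-readable record keeps full precision). Legend entries correspond
#' one-to-one with the numbered contours: numbering is the row-major
#' centroid order of [cluster_pixels()], stable across runs.
#'
#' @param image H x W x 3 scene array in `[0, 1]`.
#' @param clusters clusters from [cluster_pixels()].
#' @param measurements data frame from [measure_wheals()].
#' @return the annotated image array.
#' @export
render_overlay <- function(image, clusters, measurements) {
  out <- image
  contour_rgb <- c(0, 0.35, 1)
  for (cl in clusters) {
    px <- cl$pixels
    keyset <- (px[, 1] - 1) * 2^26 + px[, 2]
    on_boundary <- !((px[, 1] - 2) * 2^26 + px[, 2]) %in% keyset |
      !((px[, 1]) * 2^26 + px[, 2]) %in% keyset |
      !((px[, 1] - 1) * 2^26 + px[, 2] - 1) %in% keyset |
      !((px[, 1] - 1) * 2^26 + px[, 2] + 1) %in% keyset
    bpx <- px[on_boundary, , drop = FALSE]
    for (k in 1:3) {
      out[cbind(bpx, k)] <- contour_rgb[k]
    }
    out <- draw_text(out, as.character(cl$id),
                     round(cl$centroid[1]) - 4, round(cl$centroid[2]) - 2,
                     scale = 2, color = c(0, 0, 0))
  }
  for (i in seq_len(nrow(measurements))) {
    line <- sprintf("%d: %.2f", measurements$id[i],
                    measurements$area_cm2[i])
    out <- draw_text(out, line, 4 + (i - 1) * 12, 4, scale = 2,
                     color = c(0, 0, 0))
  }
  out
}
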