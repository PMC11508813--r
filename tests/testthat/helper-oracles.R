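# Independent oracles used to cross-check package implementations.
# These deliberately use different algorithms from the package code paths.

# Flood-fill connected-component labeling (BFS over an explicit queue).
oracle_flood_fill <- function(mask, connectivity = 8) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (c0 in seq_len(w)) {
    for (r0 in seq_len(h)) {
      if (!mask[r0, c0] || lab[r0, c0] > 0L) next
      nxt <- nxt + 1L
      queue <- matrix(c(r0, c0), 1, 2)
      lab[r0, c0] <- nxt
      while (nrow(queue) > 0) {
        cur <- queue[1, ]
        queue <- queue[-1, , drop = FALSE]
        for (k in seq_len(nrow(offs))) {
          rr <- cur[1] + offs[k, 1]
          cc <- cur[2] + offs[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue <- rbind(queue, c(rr, cc))
          }
        }
      }
    }
  }
  lab
}

# Chord through a point at one angle, measured by projecting every region
# pixel center and taking the extent of the half-pixel band around the line.
oracle_chord <- function(region, cy, cx, theta) {
  idx <- which(region, arr.ind = TRUE)
  bx <- (idx[, 2] - 1) - cx
  by <- (idx[, 1] - 1) - cy
  t <- bx * cos(theta) + by * sin(theta)
  v <- -bx * sin(theta) + by * cos(theta)
  band <- abs(v) <= 0.5
  if (!any(band)) return(0)
  max(t[band]) - min(t[band]) + 1
}

# Dense-sweep largest chord: brute force over a fine angle grid.
oracle_ld <- function(region, cy, cx, step_deg = 0.1) {
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  max(vapply(angles, function(a) oracle_chord(region, cy, cx, a), 0))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(seq_len(2^n) - 1L, function(bits) {
    signs <- bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, 0)
  p_low <- mean(vs <= v_obs)
  p_high <- mean(vs >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exhaustive one-to-one assignment maximizing total IoU (for <= ~5 clusters).
oracle_best_matching <- function(iou) {
  np <- nrow(iou)
  ne <- ncol(iou)
  best <- list(score = -Inf, pairs = NULL)
  assignments <- function(pred_left, exp_left, pairs, score) {
    if (score > best$score) {
      best$score <<- score
      best$pairs <<- pairs
    }
    if (length(pred_left) == 0 || length(exp_left) == 0) return()
    i <- pred_left[1]
    # leave i unmatched
    assignments(pred_left[-1], exp_left, pairs, score)
    for (j in exp_left) {
      if (iou[i, j] > 0) {
        assignments(pred_left[-1], setdiff(exp_left, j),
                    rbind(pairs, c(i, j)), score + iou[i, j])
      }
    }
  }
  assignments(seq_len(np), seq_len(ne), NULL, 0)
  best
}

# Build a wheal_cluster directly from a logical matrix (1-based pixels).
cluster_from_region <- function(region, id = 1L) {
  px <- which(region, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  structure(
    list(
      id = id, pixels = px, pixel_count = nrow(px),
      centroid = c(mean(px[, 1]) - 1, mean(px[, 2]) - 1)
    ),
    class = "wheal_cluster"
  )
}

# Rasterize a standalone shape and wrap it as a cluster.
raster_cluster <- function(spec, pixels_per_cm) {
  cluster_from_region(rasterize_shape(spec, pixels_per_cm)$mask)
}

# Random blob mask for property tests: a few rectangles on an h x w grid.
random_blob_mask <- function(h = 50, w = 50, n_blobs = 3) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_blobs)) {
    r0 <- sample(h - 8, 1)
    c0 <- sample(w - 8, 1)
    m[r0:(r0 + sample(3:7, 1)), c0:(c0 + sample(3:7, 1))] <- TRUE
  }
  m
}

# Smoke-test scene used by the training acceptance test: a 64 x 64 close-up
# crop at 6 px/cm with the reference tag in the corner and one large
# regular wheal.
smoke_scene <- function(seed) {
  grp <- make_shape_group("regular", 1, 1, axis_range_cm = c(1.9, 2.7),
                          pixels_per_cm = 6, seed = seed,
                          canvas_px = c(64L, 64L))
  sc <- scene_spec(canvas_px = c(64L, 64L), pixels_per_cm = 6,
                   rt_position_px = c(1, 1), wheal_specs = grp[[1]]$specs,
                   noise_sigma = 0.015, seed = seed)
  render_scene(sc)
}
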