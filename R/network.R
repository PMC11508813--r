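#' Fully convolutional segmentation network configuration
#'
#' The segmentation model is a VGG-16-encoder FCN: five convolutional
#' blocks (2, 2, 3, 3, 3 convolutions of 3 x 3, ReLU) each followed by 2 x 2
#' max-pooling; a two-layer convolutional head (7 x 7 then 1 x 1, 4096
#' filters each at full width); a 1 x 1 class-score convolution; then the
#' skip decoder: 2x learnable upsampling summed with a 1 x 1-adjusted pool4
#' score, another 2x upsampling summed with the adjusted pool3 score, and a
#' final 8x upsampling into a per-pixel softmax over the three classes.
#' `width_multiplier` scales every filter count for desk-scale (CPU)
#' training; the full 640 x 480 / 4096-filter configuration is supported but
#' GPU-recommended.
#'
#' @param input_size integer length 2, `(width, height)`; both must be
#'   divisible by 32 (five 2x poolings).
#' @param n_classes number of mask classes (3).
#' @param encoder_widths per-block filter counts (VGG-16 defaults).
#' @param head_width filters in the two head convolutions (default 4096).
#' @param width_multiplier scale factor applied to all widths (> 0).
#' @return a `network_config` list with resolved (scaled) widths.
#' @export
network_config <- function(input_size = c(640L, 480L),
                           n_classes = 3L,
                           encoder_widths = c(64L, 128L, 256L, 512L, 512L),
                           head_width = 4096L,
                           width_multiplier = 1) {
  if (any(input_size %% 32 != 0)) {
    stop_input(
      "input dimensions must be divisible by 32 (five 2x poolings); got %d x %d",
      input_size[1], input_size[2]
    )
  }
  if (width_multiplier <= 0) stop_input("width_multiplier must be > 0")
  structure(
    list(
      input_size = as.integer(input_size),
      n_classes = as.integer(n_classes),
      encoder_widths = pmax(1L, as.integer(round(encoder_widths *
                                                   width_multiplier))),
      head_width = max(1L, as.integer(round(head_width * width_multiplier))),
      width_multiplier = width_multiplier,
      block_convs = c(2L, 2L, 3L, 3L, 3L)
    ),
    class = "network_config"
  )
}

# Parameter shapes for every layer: list of (name, kh, kw, cin, cout, type)
layer_shapes <- function(config) {
  shapes <- list()
  cin <- 3L
  for (b in 1:5) {
    k <- config$encoder_widths[b]
    for (j in seq_len(config$block_convs[b])) {
      shapes[[sprintf("b%dc%d", b, j)]] <-
        list(kh = 3L, kw = 3L, cin = cin, cout = k, type = "conv")
      cin <- k
    }
  }
  nc <- config$n_classes
  hw <- config$head_width
  shapes$head7 <- list(kh = 7L, kw = 7L, cin = cin, cout = hw, type = "conv")
  shapes$head1 <- list(kh = 1L, kw = 1L, cin = hw, cout = hw, type = "conv")
  shapes$score <- list(kh = 1L, kw = 1L, cin = hw, cout = nc, type = "conv")
  shapes$score4 <- list(kh = 1L, kw = 1L, cin = config$encoder_widths[4],
                        cout = nc, type = "conv")
  shapes$score3 <- list(kh = 1L, kw = 1L, cin = config$encoder_widths[3],
                        cout = nc, type = "conv")
  shapes$up1 <- list(kh = 4L, kw = 4L, cin = nc, cout = nc, type = "tconv",
                     stride = 2L, pad = 1L)
  shapes$up2 <- list(kh = 4L, kw = 4L, cin = nc, cout = nc, type = "tconv",
                     stride = 2L, pad = 1L)
  shapes$up8 <- list(kh = 16L, kw = 16L, cin = nc, cout = nc, type = "tconv",
                     stride = 8L, pad = 4L)
  shapes
}

#' Count trainable parameters of a configuration
#'
#' @param config a [network_config()].
#' @return total number of weights and biases.
#' @export
network_param_count <- function(config) {
  sum(vapply(layer_shapes(config), function(s) {
    s$kh * s$kw * s$cin * s$cout + s$cout
  }, 0))
}

# Bilinear interpolation kernel of size k for upsampling factor f.
bilinear_kernel <- function(k, f) {
  ctr <- (2 * f - 1 - f %% 2) / (2 * f)
  v <- 1 - abs((seq_len(k) - 1) / f - ctr)
  outer(v, v)
}

#' Build the segmentation network
#'
#' Initializes all parameters: He-normal encoder/head weights, zero-filled
#' skip score convolutions (so early training follows the skip-free path),
#' and transposed convolutions initialized to bilinear interpolation.
#'
#' @param config a [network_config()].
#' @param seed integer seed for the random initialization.
#' @return an `fcn_model` list with `config`, `params`, and Adam `opt`
#'   state.
#' @export
build_network <- function(config, seed = 1L) {
  shapes <- layer_shapes(config)
  params <- with_seed(seed, {
    out <- list()
    for (nm in names(shapes)) {
      s <- shapes[[nm]]
      if (s$type == "conv") {
        fan_in <- s$kh * s$kw * s$cin
        w <- if (nm %in% c("score3", "score4")) {
          matrix(0, fan_in, s$cout)
        } else {
          matrix(rnorm(fan_in * s$cout, 0, sqrt(2 / fan_in)), fan_in, s$cout)
        }
        out[[paste0(nm, ".w")]] <- w
        out[[paste0(nm, ".b")]] <- numeric(s$cout)
      } else {
        kern <- bilinear_kernel(s$kh, s$stride)
        w <- array(0, c(s$kh, s$kw, s$cin, s$cout))
        for (c in seq_len(min(s$cin, s$cout))) w[, , c, c] <- kern
        out[[paste0(nm, ".w")]] <- w
        out[[paste0(nm, ".b")]] <- numeric(s$cout)
      }
    }
    out
  })
  structure(
    list(config = config, shapes = shapes, params = params, opt = NULL,
         epochs_trained = 0L),
    class = "fcn_model"
  )
}

#' @export
print.fcn_model <- function(x, ...) {
  cat(sprintf(
    "<fcn_model: input %d x %d, widths %s, head %d, %s parameters, %d epochs trained>\n",
    x$config$input_size[1], x$config$input_size[2],
    paste(x$config$encoder_widths, collapse = "/"),
    x$config$head_width,
    format(network_param_count(x$config), big.mark = ","),
    x$epochs_trained
  ))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax3 <- function(x) {
  m <- pmax(x[, , 1], x[, , 2])
  for (k in 3:dim(x)[3]) m <- pmax(m, x[, , k])
  e <- x
  for (k in seq_len(dim(x)[3])) e[, , k] <- exp(x[, , k] - m)
  s <- e[, , 1]
  for (k in 2:dim(x)[3]) s <- s + e[, , k]
  for (k in seq_len(dim(x)[3])) e[, , k] <- e[, , k] / s
  e
}

# Forward pass. x: H x W x 3 array in [0, 1]. Returns the pre-softmax
# scores, class probabilities, and (optionally) the cache for backprop.
fcn_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  cache <- list(x = x)
  a <- x
  pools <- list()
  for (b in 1:5) {
    for (j in seq_len(cfg$block_convs[b])) {
      nm <- sprintf("b%dc%d", b, j)
      cache[[paste0(nm, ".in")]] <- a
      a <- relu(.conv_fwd(a, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                          3L, 3L, 1L))
      cache[[paste0(nm, ".out")]] <- a
    }
    mp <- .maxpool_fwd(a)
    cache[[sprintf("pool%d.idx", b)]] <- mp$idx
    cache[[sprintf("pool%d.dim", b)]] <- dim(a)[1:2]
    a <- mp$y
    pools[[b]] <- a
  }
  cache$head7.in <- a
  h <- relu(.conv_fwd(a, p$head7.w, p$head7.b, 7L, 7L, 3L))
  cache$head7.out <- h
  cache$head1.in <- h
  h <- relu(.conv_fwd(h, p$head1.w, p$head1.b, 1L, 1L, 0L))
  cache$head1.out <- h
  s <- .conv_fwd(h, p$score.w, p$score.b, 1L, 1L, 0L)
  cache$score.in <- h
  u1 <- .tconv_fwd(s, p$up1.w, p$up1.b, 4L, 2L, 1L)
  cache$up1.in <- s
  s4 <- .conv_fwd(pools[[4]], p$score4.w, p$score4.b, 1L, 1L, 0L)
  f4 <- u1 + s4
  u2 <- .tconv_fwd(f4, p$up2.w, p$up2.b, 4L, 2L, 1L)
  cache$up2.in <- f4
  s3 <- .conv_fwd(pools[[3]], p$score3.w, p$score3.b, 1L, 1L, 0L)
  f3 <- u2 + s3
  out <- .tconv_fwd(f3, p$up8.w, p$up8.b, 16L, 8L, 4L)
  cache$up8.in <- f3
  cache$pool3.out <- pools[[3]]
  cache$pool4.out <- pools[[4]]
  list(
    scores = out,
    prob = softmax3(out),
    cache = if (keep_cache) cache else NULL
  )
}

# Backward pass given d(loss)/d(scores); returns gradients named like params.
fcn_backward <- function(model, cache, dscores) {
  p <- model$params
  cfg <- model$config
  g <- list()
  bw <- .tconv_bwd(cache$up8.in, p$up8.w, dscores, 16L, 8L, 4L)
  g$up8.w <- bw$dw; g$up8.b <- bw$db
  df3 <- bw$dx
  # f3 = up2(f4) + score3(pool3)
  cb <- .conv_bwd(cache$pool3.out, p$score3.w, df3, 1L, 1L, 0L)
  g$score3.w <- cb$dW; g$score3.b <- cb$db
  dpool3_skip <- cb$dx
  bw <- .tconv_bwd(cache$up2.in, p$up2.w, df3, 4L, 2L, 1L)
  g$up2.w <- bw$dw; g$up2.b <- bw$db
  df4 <- bw$dx
  cb <- .conv_bwd(cache$pool4.out, p$score4.w, df4, 1L, 1L, 0L)
  g$score4.w <- cb$dW; g$score4.b <- cb$db
  dpool4_skip <- cb$dx
  bw <- .tconv_bwd(cache$up1.in, p$up1.w, df4, 4L, 2L, 1L)
  g$up1.w <- bw$dw; g$up1.b <- bw$db
  ds <- bw$dx
  cb <- .conv_bwd(cache$score.in, p$score.w, ds, 1L, 1L, 0L)
  g$score.w <- cb$dW; g$score.b <- cb$db
  dh <- cb$dx * (cache$head1.out > 0)
  cb <- .conv_bwd(cache$head1.in, p$head1.w, dh, 1L, 1L, 0L)
  g$head1.w <- cb$dW; g$head1.b <- cb$db
  dh <- cb$dx * (cache$head7.out > 0)
  cb <- .conv_bwd(cache$head7.in, p$head7.w, dh, 7L, 7L, 3L)
  g$head7.w <- cb$dW; g$head7.b <- cb$db
  da <- cb$dx   # gradient at pool5 output
  for (b in 5:1) {
    if (b == 4) da <- da + dpool4_skip
    if (b == 3) da <- da + dpool3_skip
    dim_in <- cache[[sprintf("pool%d.dim", b)]]
    da <- .maxpool_bwd(cache[[sprintf("pool%d.idx", b)]], da,
                       dim_in[1], dim_in[2])
    for (j in rev(seq_len(cfg$block_convs[b]))) {
      nm <- sprintf("b%dc%d", b, j)
      da <- da * (cache[[paste0(nm, ".out")]] > 0)
      cb <- .conv_bwd(cache[[paste0(nm, ".in")]], p[[paste0(nm, ".w")]], da,
                      3L, 3L, 1L)
      g[[paste0(nm, ".w")]] <- cb$dW
      g[[paste0(nm, ".b")]] <- cb$db
      da <- cb$dx
    }
  }
  g
}

#' Predict a label mask for an image
#'
#' Runs the forward pass and takes the per-pixel argmax of the class
#' probabilities; exact probability ties resolve toward `background` (the
#' first class). Images whose size differs from the model input are resized
#' bilinearly first, and the predicted mask is resized back with
#' nearest-neighbor interpolation.
#'
#' @param model an `fcn_model`.
#' @param image H x W x 3 array in `[0, 1]`.
#' @return a [label_mask()] with the image's original dimensions.
#' @export
predict_mask <- function(model, image) {
  in_wh <- model$config$input_size
  orig <- dim(image)[1:2]
  if (orig[1] != in_wh[2] || orig[2] != in_wh[1]) {
    image <- resize_image(image, c(in_wh[2], in_wh[1]))
  }
  prob <- fcn_forward(model, image)$prob
  mask <- prob_to_mask(prob)
  if (any(dim(mask) != orig)) mask <- resize_mask_nn(mask, orig)
  mask
}

#' Convert a probability map to a label mask (argmax, ties to background)
#'
#' @param prob H x W x n_classes array of per-pixel class probabilities.
#' @return a [label_mask()].
#' @export
prob_to_mask <- function(prob) {
  h <- dim(prob)[1]; w <- dim(prob)[2]; k <- dim(prob)[3]
  m <- matrix(prob, h * w, k)
  cls <- max.col(m, ties.method = "first") - 1L  # first max: background wins
  label_mask(matrix(as.integer(cls), h, w))
}

# Bilinear image resize to out_hw = c(H, W).
resize_image <- function(image, out_hw) {
  h <- dim(image)[1]; w <- dim(image)[2]
  oh <- out_hw[1]; ow <- out_hw[2]
  ys <- (seq_len(oh) - 0.5) / oh * h - 0.5
  xs <- (seq_len(ow) - 0.5) / ow * w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(oh, ow, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) {
    pl <- image[, , ch]
    a <- pl[cbind(rep(y0 + 1, ow), rep(x0 + 1, each = oh))]
    b <- pl[cbind(rep(y0 + 1, ow), rep(x1 + 1, each = oh))]
    c2 <- pl[cbind(rep(y1 + 1, ow), rep(x0 + 1, each = oh))]
    d <- pl[cbind(rep(y1 + 1, ow), rep(x1 + 1, each = oh))]
    wfx <- rep(fx, each = oh); wfy <- rep(fy, ow)
    out[, , ch] <- matrix(
      (a * (1 - wfx) + b * wfx) * (1 - wfy) +
        (c2 * (1 - wfx) + d * wfx) * wfy,
      oh, ow
    )
  }
  out
}

# Nearest-neighbor mask resize to out_hw = c(H, W).
resize_mask_nn <- function(mask, out_hw) {
  h <- nrow(mask); w <- ncol(mask)
  ys <- pmin(pmax(ceiling((seq_len(out_hw[1]) - 0.5) / out_hw[1] * h), 1), h)
  xs <- pmin(pmax(ceiling((seq_len(out_hw[2]) - 0.5) / out_hw[2] * w), 1), w)
  label_mask(unclass(mask)[ys, xs, drop = FALSE])
}

#' Save / load a model checkpoint
#'
#' @param model an `fcn_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
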