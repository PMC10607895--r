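#' Configuration for the gated CNN classifier
#'
#' The network is a stack of eight "gated" convolution blocks (conv ->
#' batch norm -> sigmoid gate, i.e. the block output is `u * sigmoid(u)` on
#' the normalised convolution output), followed by global average pooling and
#' a softmax classifier. Blocks 1--7 carry the channel schedule
#' (64, 128, 128, 256, 256, 512, 512) with strides (2, 2, 2, 1, 1, 1, 1);
#' block 8 maps to `num_classes` channels at stride 1, so for a 224 input its
#' output grid is 28 x 28 with one channel per class. Pooling that grid gives
#' the logits directly.
#'
#' Four kernel variants exist: `"1"` (all blocks 1x1), `"3"` (all 3x3),
#' `"1+3"` (blocks 1--7 use 1x1, block 8 uses 3x3) and `"3+1"` (blocks 1--7
#' use 3x3, block 8 uses 1x1).
#'
#' @param variant one of `"1"`, `"3"`, `"1+3"`, `"3+1"`.
#' @param num_classes positive integer; channel count of block 8.
#' @param input_size square input side in pixels (default 224).
#' @param width_divisor integer scaling the channel schedule down (e.g. 8
#'   gives the (8, 16, 16, 32, 32, 64, 64) schedule used for desk-scale runs).
#' @return A `gcnn_config` list with fields `variant`, `k`, `j`, `channels`,
#'   `strides`, `num_classes`, `input_size`.
#' @export
gcnn_config <- function(variant = "1", num_classes,
                        input_size = 224L, width_divisor = 1L) {
  kj <- switch(variant,
    "1"   = c(1L, 1L),
    "3"   = c(3L, 3L),
    "1+3" = c(1L, 3L),
    "3+1" = c(3L, 1L),
    stop("invalid variant tag: ", variant,
         " (expected one of \"1\", \"3\", \"1+3\", \"3+1\")"))
  stopifnot(num_classes >= 1L, input_size >= 8L, width_divisor >= 1L)
  channels <- c(64L, 128L, 128L, 256L, 256L, 512L, 512L)
  if (any(channels %% width_divisor != 0L))
    stop("width_divisor must divide the channel schedule")
  structure(list(
    variant = variant, k = kj[1L], j = kj[2L],
    channels = as.integer(channels / width_divisor),
    strides = c(2L, 2L, 2L, 1L, 1L, 1L, 1L),
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size)
  ), class = "gcnn_config")
}

#' Build the single-level gated CNN classifier
#'
#' @param config a [gcnn_config()].
#' @param seed optional integer; when given, weight initialisation uses a
#'   private RNG stream so identical seeds give identical models.
#' @return A `gcnn` model: `config` plus a list of 8 block parameter sets.
#' @export
build_gated_cnn <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gcnn_config"))
  builder <- function() {
    chans <- c(3L, config$channels)
    blocks <- vector("list", 8L)
    for (i in 1:7)
      blocks[[i]] <- new_block(chans[i], chans[i + 1L], config$k,
                               config$strides[i])
    blocks[[8L]] <- new_block(config$channels[7L], config$num_classes,
                              config$j, 1L)
    blocks
  }
  blocks <- if (is.null(seed)) builder() else with_seed(seed, builder())
  structure(list(config = config, blocks = blocks), class = "gcnn")
}

#' Build the multi-level gated CNN classifier
#'
#' Shares blocks 1--7 as a trunk, then stacks four gated blocks bottom-up,
#' one per taxonomy level ordered level 4 -> level 1. The level-`l` block
#' emits `C_l` channels and feeds both its own global-average-pool + softmax
#' classifier and the next (upper) level's block, so upper levels reuse lower-
#' level features.
#'
#' @param config a [gcnn_config()]; its `num_classes` is ignored in favour of
#'   the taxonomy's per-level counts.
#' @param tax an [ingredient_taxonomy()] supplying `C1..C4`.
#' @param seed optional integer for reproducible initialisation.
#' @return A `gcnn_multilevel` model with `blocks` (trunk) and `heads`
#'   (blocks for levels 4, 3, 2, 1 in stack order).
#' @export
build_multilevel_gcnn <- function(config, tax, seed = NULL) {
  stopifnot(inherits(config, "gcnn_config"),
            inherits(tax, "ingredient_taxonomy"))
  builder <- function() {
    chans <- c(3L, config$channels)
    blocks <- vector("list", 7L)
    for (i in 1:7)
      blocks[[i]] <- new_block(chans[i], chans[i + 1L], config$k,
                               config$strides[i])
    cl <- as.integer(tax$counts)                    # C1, C2, C3, C4
    cin <- c(config$channels[7L], cl[4L], cl[3L], cl[2L])
    heads <- lapply(1:4, function(i)
      new_block(cin[i], cl[5L - i], config$j, 1L))  # level 4, 3, 2, 1
    names(heads) <- paste0("level", 4:1)
    list(blocks = blocks, heads = heads)
  }
  parts <- if (is.null(seed)) builder() else with_seed(seed, builder())
  structure(list(config = config, blocks = parts$blocks, heads = parts$heads,
                 class_counts = as.integer(tax$counts)),
            class = "gcnn_multilevel")
}

#' Forward pass of a single gated block
#'
#' Applies one block (convolution, batch normalisation with the block's
#' stored statistics, sigmoid gating) to a feature grid. The output equals
#' `u * sigmoid(u)` elementwise, where `u` is the normalised convolution
#' output; its spatial size follows the block's stride.
#'
#' @param x `H x W x Cin` numeric array.
#' @param params a block parameter set (e.g. `model$blocks[[i]]`).
#' @return `H' x W' x Cout` numeric array.
#' @export
gated_block_forward <- function(x, params) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (dim(x)[3L] != params$Cin)
    stop("channel mismatch: block expects ", params$Cin,
         " input channels, got ", dim(x)[3L])
  X <- images_to_mat(list(x))
  fw <- block_forward(params, X, attr(X, "dims"), training = FALSE)
  mat_to_array(fw$out, fw$dims)
}

# internal full forward; returns logits, per-stage dims, optional caches
gcnn_forward <- function(model, X, dims, training = FALSE, keep = FALSE) {
  caches <- if (keep) vector("list", 8L) else NULL
  for (i in 1:8) {
    fw <- block_forward(model$blocks[[i]], X, dims, training)
    if (training) model$blocks[[i]] <- fw$blk
    if (keep) caches[[i]] <- fw$cache
    X <- fw$out
    dims <- fw$dims
  }
  logits <- gap_forward(X, dims)
  list(logits = logits, feat = X, feat_dims = dims, caches = caches,
       model = model)
}

gcnn_ml_forward <- function(model, X, dims, training = FALSE, keep = FALSE) {
  tcache <- if (keep) vector("list", 7L) else NULL
  for (i in 1:7) {
    fw <- block_forward(model$blocks[[i]], X, dims, training)
    if (training) model$blocks[[i]] <- fw$blk
    if (keep) tcache[[i]] <- fw$cache
    X <- fw$out; dims <- fw$dims
  }
  hcache <- if (keep) vector("list", 4L) else NULL
  logits <- vector("list", 4L)                       # slot l = level l
  feats <- vector("list", 4L)
  for (i in 1:4) {                                   # stack: level 4 -> 1
    fw <- block_forward(model$heads[[i]], X, dims, training)
    if (training) model$heads[[i]] <- fw$blk
    if (keep) hcache[[i]] <- fw$cache
    X <- fw$out; dims <- fw$dims
    lev <- 5L - i
    logits[[lev]] <- gap_forward(X, dims)
    feats[[lev]] <- X
  }
  list(logits = logits, feats = feats, feat_dims = dims,
       tcache = tcache, hcache = hcache, model = model)
}

# bilinear resize of an H x W x C array to th x tw
resize_bilinear <- function(img, th, tw) {
  d <- dim(img)
  if (d[1L] == th && d[2L] == tw) return(img)
  sy <- d[1L] / th; sx <- d[2L] / tw
  yc <- (seq_len(th) - 0.5) * sy + 0.5               # source coords
  xc <- (seq_len(tw) - 0.5) * sx + 0.5
  y0 <- pmin(pmax(floor(yc), 1), d[1L]); y1 <- pmin(y0 + 1, d[1L])
  x0 <- pmin(pmax(floor(xc), 1), d[2L]); x1 <- pmin(x0 + 1, d[2L])
  wy <- pmin(pmax(yc - y0, 0), 1); wx <- pmin(pmax(xc - x0, 0), 1)
  out <- array(0, dim = c(th, tw, d[3L]))
  for (c in seq_len(d[3L])) {
    ch <- img[, , c]
    a <- ch[y0, x0]; bq <- ch[y0, x1]; cq <- ch[y1, x0]; dq <- ch[y1, x1]
    top <- a * (1 - rep(wx, each = th)) + bq * rep(wx, each = th)
    bot <- cq * (1 - rep(wx, each = th)) + dq * rep(wx, each = th)
    out[, , c] <- top * (1 - wy) + bot * wy
  }
  out
}

prep_input <- function(img, input_size) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3L] == 3L)
  img <- pmin(pmax(img, 0), 1)
  resize_bilinear(img, input_size, input_size)
}

#' Predict class probabilities
#'
#' Runs inference (batch-norm statistics frozen) and returns softmax
#' probabilities. For multi-level models a list of four probability matrices
#' (levels 1..4) is returned.
#'
#' @param object a `gcnn` or `gcnn_multilevel` model.
#' @param images one `H x W x 3` array in `[0, 1]` or a list of them; images
#'   are bilinearly resized to the model input size.
#' @param ... unused.
#' @return `N x C` probability matrix (rows sum to 1), or a list of four.
#' @export
predict.gcnn <- function(object, images, ...) {
  if (is.array(images)) images <- list(images)
  images <- lapply(images, prep_input, object$config$input_size)
  X <- images_to_mat(images)
  softmax_rows(gcnn_forward(object, X, attr(X, "dims"))$logits)
}

#' @rdname predict.gcnn
#' @export
predict.gcnn_multilevel <- function(object, images, ...) {
  if (is.array(images)) images <- list(images)
  images <- lapply(images, prep_input, object$config$input_size)
  X <- images_to_mat(images)
  lapply(gcnn_ml_forward(object, X, attr(X, "dims"))$logits, softmax_rows)
}

#' Extract last-stage feature maps for segmentation
#'
#' Returns the output grid of the final gated block (post-gating, pre-
#' pooling): for a single-level model this is block 8 (one channel per class);
#' for a multi-level model, the level-4 head block (C4 channels). These
#' per-pixel class activations are the raw material of both mask-generation
#' methods.
#'
#' The network is fully convolutional, so by default the image is processed
#' at its native resolution (multi-ingredient dish photos are typically much
#' larger than the training crops); set `resize = "input"` to force the
#' classifier's fixed training size instead.
#'
#' @param model a `gcnn` or `gcnn_multilevel` model.
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param resize `"native"` (default) or `"input"`.
#' @return A `feature_maps` object: `H' x W' x C` array with attribute
#'   `source_image_size = c(height, width)` of the original input.
#' @export
forward_feature_maps <- function(model, image,
                                 resize = c("native", "input")) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  resize <- match.arg(resize)
  src <- dim(image)[1:2]
  x <- if (resize == "input") prep_input(image, model$config$input_size)
       else pmin(pmax(image, 0), 1)
  X <- images_to_mat(list(x))
  if (inherits(model, "gcnn_multilevel")) {
    fw <- gcnn_ml_forward(model, X, attr(X, "dims"))
    f <- mat_to_array(fw$feats[[4L]], attr(fw$feats[[4L]], "dims"))
  } else if (inherits(model, "gcnn")) {
    fw <- gcnn_forward(model, X, attr(X, "dims"))
    f <- mat_to_array(fw$feat, fw$feat_dims)
  } else stop("model must be a gcnn or gcnn_multilevel")
  structure(f, source_image_size = src, class = c("feature_maps", "array"))
}

#' Per-stage output shapes of a gated CNN
#'
#' @param model a `gcnn`, `gcnn_multilevel`, or `gcnn_config`.
#' @return data.frame with columns `stage`, `kernel`, `stride`, `out_h`,
#'   `out_w`, `channels`; stage 0 is the input.
#' @export
gcnn_shapes <- function(model) {
  cfg <- if (inherits(model, "gcnn_config")) model else model$config
  ks <- c(rep(cfg$k, 7L), cfg$j)
  st <- c(cfg$strides, 1L)
  ch <- c(cfg$channels,
          if (inherits(model, "gcnn_multilevel")) model$class_counts[4L]
          else cfg$num_classes)
  h <- cfg$input_size
  out <- data.frame(stage = 0L, kernel = NA_integer_, stride = NA_integer_,
                    out_h = h, out_w = h, channels = 3L)
  for (i in 1:8) {
    h <- conv_out_size(h, ks[i], st[i])
    out <- rbind(out, data.frame(stage = i, kernel = ks[i], stride = st[i],
                                 out_h = h, out_w = h, channels = ch[i]))
  }
  out
}

#' Attach a classification head to a third-party backbone feature grid
#'
#' Appends a 1x1 convolution mapping backbone channels to `num_classes`,
#' then global average pooling: the pooled logits are exactly the per-channel
#' spatial means of the resulting grid, so the same segmentation framework
#' applies to any spatial feature extractor.
#'
#' @param feature_grid an example `H x W x C` backbone output (only its
#'   channel count is used), or a single integer channel count.
#' @param num_classes number of output classes.
#' @param seed optional integer for reproducible initialisation.
#' @return A `gcnn_head` with `$forward(grid)` returning
#'   `list(feature_maps, logits)`.
#' @export
build_backbone_head <- function(feature_grid, num_classes, seed = NULL) {
  cin <- if (length(feature_grid) == 1L && is.numeric(feature_grid)) {
    as.integer(feature_grid)
  } else {
    if (!is.array(feature_grid) || length(dim(feature_grid)) != 3L)
      stop("backbone output must be a spatial H x W x C grid")
    dim(feature_grid)[3L]
  }
  blk <- if (is.null(seed)) new_block(cin, num_classes, 1L, 1L)
         else with_seed(seed, new_block(cin, num_classes, 1L, 1L))
  head <- list(block = blk, num_classes = as.integer(num_classes))
  head$forward <- function(grid) {
    if (!is.array(grid) || length(dim(grid)) != 3L)
      stop("backbone output must be a spatial H x W x C grid")
    f <- gated_block_forward(grid, blk)
    X <- images_to_mat(list(f))
    list(feature_maps = structure(
           f, source_image_size = dim(grid)[1:2],
           class = c("feature_maps", "array")),
         logits = drop(gap_forward(X, attr(X, "dims"))))
  }
  structure(head, class = "gcnn_head")
}
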