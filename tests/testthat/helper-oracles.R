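# Independent oracles and fixture builders shared across test files.
# Oracles deliberately use a different computational route than the package
# (index-set arithmetic, scalar loops) so agreement is informative.

# ---- set-counting segmentation metric oracles -------------------------------

.px <- function(m) which(as.vector(m) != 0)

bf_iou <- function(A, B) {
  a <- .px(A); b <- .px(B)
  length(intersect(a, b)) / length(union(a, b))
}

bf_dice <- function(A, B) {
  a <- .px(A); b <- .px(B)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

bf_purity <- function(A, B) {
  a <- .px(A); b <- .px(B)
  length(intersect(a, b)) / length(b)
}

bf_entirety <- function(A, B) {
  a <- .px(A); b <- .px(B)
  length(intersect(a, b)) / length(a)
}

bf_logts <- function(gts, segs) {
  ua <- unique(unlist(lapply(gts, .px)))
  ub <- unique(unlist(lapply(segs, .px)))
  (length(ua) - length(intersect(ua, ub))) / length(ua)
}

bf_image_metrics <- function(gts, segs) {
  I <- length(gts); J <- length(segs)
  list(
    mPurity = mean(vapply(segs, function(B)
      max(vapply(gts, bf_purity, numeric(1), B = B)), numeric(1))),
    mEntirety = mean(vapply(gts, function(A)
      max(vapply(segs, function(B) bf_entirety(A, B), numeric(1))),
      numeric(1))),
    LoGTs = bf_logts(gts, segs),
    mIoU = mean(vapply(gts, function(A)
      max(vapply(segs, function(B) bf_iou(A, B), numeric(1))), numeric(1))),
    mDice = mean(vapply(gts, function(A)
      max(vapply(segs, function(B) bf_dice(A, B), numeric(1))), numeric(1))))
}

random_mask <- function(h = 8, w = 8, p = 0.4) {
  matrix(stats::runif(h * w) < p, h, w)
}

# non-empty random mask
random_mask_ne <- function(h = 8, w = 8, p = 0.4) {
  repeat {
    m <- random_mask(h, w, p)
    if (any(m)) return(m)
  }
}

# ---- gated block scalar oracle ---------------------------------------------

# scalar re-evaluation of a 1x1-kernel gated block (fresh batch-norm stats:
# running mean 0, var 1), looping over every grid cell and channel
bf_gated_block_1x1 <- function(x, W, b, eps = 1e-5) {
  d <- dim(x)
  Cout <- ncol(W)
  out <- array(0, dim = c(d[1], d[2], Cout))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (co in seq_len(Cout)) {
    u <- sum(x[i, j, ] * W[, co]) + b[co]
    u <- u / sqrt(1 + eps)                 # batch norm with mean 0, var 1
    out[i, j, co] <- u * (1 / (1 + exp(-u)))
  }
  out
}

# ---- toy taxonomies ---------------------------------------------------------

chain_taxonomy <- function() {
  load_taxonomy(data.frame(
    level = 1:4, name = c("Crop", "Fruits", "pome", "apple"),
    parent = c("", "Crop", "Fruits", "pome")))
}

random_taxonomy <- function(c1 = 2, c2 = 3, c3 = 5, c4 = 9) {
  ingredient_taxonomy(
    levels = list(paste0("a", 1:c1), paste0("b", 1:c2),
                  paste0("c", 1:c3), paste0("d", 1:c4)),
    parents = list(sample(0:(c1 - 1), c2, replace = TRUE),
                   sample(0:(c2 - 1), c3, replace = TRUE),
                   sample(0:(c3 - 1), c4, replace = TRUE)))
}

# tiny configs used across files
tiny_cfg <- function(n_classes = 2, size = 32)
  gcnn_config("1", n_classes, input_size = size, width_divisor = 8L)
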