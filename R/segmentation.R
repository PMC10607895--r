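#' Parameters for channel-merging mask generation (Method 1)
#'
#' @param score_threshold retain a channel when `sigmoid(mean)` exceeds this
#'   (default 0.5, i.e. positive global mean).
#' @param correlation_threshold merge channels whose Pearson correlation
#'   exceeds this (default 0).
#' @param binarization `"minmax"` (per-map min-max normalisation then 0.5
#'   cut) or `"otsu"`.
#' @return A `method1_params` list.
#' @export
method1_params <- function(score_threshold = 0.5, correlation_threshold = 0,
                           binarization = c("minmax", "otsu")) {
  structure(list(score_threshold = score_threshold,
                 correlation_threshold = correlation_threshold,
                 binarization = match.arg(binarization)),
            class = "method1_params")
}

#' Parameters for pixel-clustering mask generation (Method 2)
#'
#' @param k number of ingredients in the image (assumed known).
#' @param background_present when `TRUE` one extra cluster is fitted
#'   (`k + 1` total) and the cluster best overlapping the blue background
#'   region of the source image is dropped.
#' @param restarts k-means restarts (default 5).
#' @param seed integer seed for the clustering RNG.
#' @return A `method2_params` list.
#' @export
method2_params <- function(k, background_present = FALSE, restarts = 5L,
                           seed = 1L) {
  stopifnot(k >= 1L, restarts >= 1L)
  structure(list(k = as.integer(k), background_present = background_present,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "method2_params")
}

new_mask_set <- function(masks, method, provenance, shape) {
  structure(list(masks = masks, method = method, provenance = provenance,
                 shape = as.integer(shape)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d mask(s), %dx%d, method %s\n",
              length(x$masks), x$shape[1L], x$shape[2L], x$method))
  invisible(x)
}

otsu_threshold <- function(v, nbins = 64L) {
  h <- tabulate(cut(v, breaks = nbins, labels = FALSE), nbins)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mt <- mu[nbins]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  which.max(sb) / nbins
}

binarize_map <- function(m, policy) {
  rng <- range(m)
  if (rng[2L] <= rng[1L]) return(NULL)         # constant map: no mask
  v <- (m - rng[1L]) / (rng[2L] - rng[1L])
  thr <- if (policy == "otsu") otsu_threshold(as.vector(v)) else 0.5
  mask <- v > thr
  if (!any(mask)) return(NULL)
  mask
}

#' Generate masks by filtering, correlating and merging feature channels
#'
#' Method 1: (i) each channel is scored by the sigmoid of its global mean and
#' kept when the score exceeds `score_threshold` (0.5, equivalent to a
#' positive mean); (ii) retained channels are grouped by transitive closure
#' over pairwise Pearson correlations above `correlation_threshold` (0), and
#' each group is merged by pixelwise mean -- positively correlated channels
#' encode redundant activations of the same component; (iii) each merged map
#' is binarised into a mask. Constant (zero-variance) channels correlate with
#' nothing; merged maps that binarise to an empty mask are discarded.
#'
#' @param f a [forward_feature_maps()] result or any `H x W x C` array.
#' @param p a [method1_params()].
#' @return A `mask_set` at feature resolution; may hold zero masks when every
#'   channel is filtered out. `provenance` lists the source channels of each
#'   mask.
#' @export
method1_generate_masks <- function(f, p = method1_params()) {
  stopifnot(is.array(f), length(dim(f)) == 3L)
  d <- dim(f)
  scores <- sigmoid(apply(f, 3L, mean))
  keep <- which(scores > p$score_threshold)
  if (length(keep) == 0L)
    return(new_mask_set(list(), "method1", list(), d[1:2]))
  flat <- matrix(f[, , keep, drop = FALSE], d[1L] * d[2L], length(keep))
  # group retained channels: edge when Pearson r > threshold; zero-variance
  # channels are treated as correlation 0 with everything
  nk <- length(keep)
  sds <- apply(flat, 2L, stats::sd)
  adj <- diag(nk) > 0
  if (nk > 1L) {
    for (i in 1:(nk - 1L)) for (j in (i + 1L):nk) {
      r <- if (sds[i] == 0 || sds[j] == 0) 0
           else stats::cor(flat[, i], flat[, j])
      adj[i, j] <- adj[j, i] <- isTRUE(r > p$correlation_threshold)
    }
  }
  comp <- rep(NA_integer_, nk)                 # connected components (BFS)
  cid <- 0L
  for (s in seq_len(nk)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  masks <- list(); prov <- list()
  for (g in seq_len(cid)) {
    members <- which(comp == g)
    merged <- matrix(rowMeans(flat[, members, drop = FALSE]), d[1L], d[2L])
    mask <- binarize_map(merged, p$binarization)
    if (is.null(mask)) {
      message("method1: merged map of channels [",
              paste(keep[members], collapse = ", "),
              "] binarised to an empty mask; discarded")
      next
    }
    masks[[length(masks) + 1L]] <- mask
    prov[[length(prov) + 1L]] <- keep[members]
  }
  new_mask_set(masks, "method1", prov, d[1:2])
}

#' Generate masks by k-means clustering of pixel feature vectors
#'
#' Method 2: the `H x W x C` feature grid is reshaped to `H*W` vectors of
#' dimension `C` and clustered with k-means (k-means++-free stats::kmeans
#' with multiple restarts) into `k` clusters -- or `k + 1` when a background
#' is present, in which case the cluster overlapping the blue background
#' region of the source image most is dropped. Each remaining cluster's pixel
#' set becomes one mask, so the masks partition the retained pixels.
#'
#' @param f a [forward_feature_maps()] result or `H x W x C` array.
#' @param p a [method2_params()].
#' @param image source RGB image (any resolution); required when
#'   `p$background_present` to locate the blue background.
#' @return A `mask_set` of exactly `k` masks at feature resolution;
#'   `provenance` records each mask's cluster id.
#' @export
method2_generate_masks <- function(f, p, image = NULL) {
  stopifnot(is.array(f), length(dim(f)) == 3L, inherits(p, "method2_params"))
  d <- dim(f)
  n_clusters <- p$k + as.integer(p$background_present)
  if (n_clusters > d[1L] * d[2L])
    stop("more clusters (", n_clusters, ") than pixels (", d[1L] * d[2L], ")")
  vecs <- matrix(f, d[1L] * d[2L], d[3L])
  if (n_clusters > 1L && nrow(unique(vecs)) < n_clusters)
    stop("degenerate feature maps: fewer than ", n_clusters,
         " distinct pixel vectors (all-identical input cannot be split)")
  cl <- with_seed(p$seed,
    stats::kmeans(vecs, centers = n_clusters, nstart = p$restarts,
                  iter.max = 100L))
  assign_mat <- matrix(cl$cluster, d[1L], d[2L])
  ids <- seq_len(n_clusters)
  if (p$background_present) {
    if (is.null(image))
      stop("background_present requires the source image to locate the blue",
           " background")
    bg <- is_blue_background(image)
    # compare at feature resolution: nearest-neighbour downsample of bg mask
    bg_small <- nn_resize_mask(bg, d[1L], d[2L])
    overlap <- vapply(ids, function(i)
      sum(assign_mat == i & bg_small), numeric(1))
    drop_id <- which.max(overlap)
    ids <- setdiff(ids, drop_id)
  }
  masks <- lapply(ids, function(i) assign_mat == i)
  new_mask_set(masks, "method2", as.list(ids), d[1:2])
}

is_blue_background <- function(image, tol = 0.02) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  image[, , 1L] < tol & image[, , 2L] < tol & image[, , 3L] > 1 - tol
}

# nearest-neighbour resize of a logical/numeric matrix (pixel-centre mapping)
nn_resize_mask <- function(m, th, tw) {
  sh <- nrow(m); sw <- ncol(m)
  ri <- pmin(floor((seq_len(th) - 0.5) * sh / th) + 1L, sh)
  ci <- pmin(floor((seq_len(tw) - 0.5) * sw / tw) + 1L, sw)
  m[ri, ci, drop = FALSE]
}

#' Upscale masks to image resolution
#'
#' Nearest-neighbour resizing, which keeps masks strictly binary.
#'
#' @param m a `mask_set`.
#' @param target `c(height, width)` of the image.
#' @return A `mask_set` at the target resolution.
#' @export
upscale_masks <- function(m, target) {
  stopifnot(inherits(m, "mask_set"), length(target) == 2L, all(target >= 1L))
  out <- lapply(m$masks, nn_resize_mask, target[1L], target[2L])
  new_mask_set(out, m$method, m$provenance, target)
}

#' Cut segments out of an image with binary masks
#'
#' Element-wise multiplication of each mask with the image: pixels outside a
#' mask become black, pixels inside keep their source values.
#'
#' @param image `H x W x 3` array.
#' @param m a `mask_set` at the same resolution.
#' @return List of `H x W x 3` segment images.
#' @export
extract_segments <- function(image, m) {
  stopifnot(is.array(image), length(dim(image)) == 3L,
            inherits(m, "mask_set"))
  if (!all(dim(image)[1:2] == m$shape))
    stop("mask shape ", paste(m$shape, collapse = "x"),
         " does not match image ", paste(dim(image)[1:2], collapse = "x"))
  lapply(m$masks, function(mask) {
    seg <- image
    for (c in 1:dim(image)[3L]) seg[, , c] <- image[, , c] * mask
    seg
  })
}

#' Paint background pixels blue
#'
#' Implements the evaluation convention of replacing non-food background with
#' pure blue, RGB (0, 0, 255), a colour rarely seen in ingredients, so the
#' background forms its own well-separated cluster.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param label_map integer matrix of the same height/width; `0` marks
#'   background.
#' @return The image with background pixels set to `(0, 0, 1)`.
#' @export
blue_background_composite <- function(image, label_map) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  if (!all(dim(image)[1:2] == dim(label_map)))
    stop("label map shape does not match image")
  bg <- label_map == 0L
  image[, , 1L][bg] <- 0
  image[, , 2L][bg] <- 0
  image[, , 3L][bg] <- 1
  image
}

#' Segment an image end to end
#'
#' Composes feature-map extraction, mask generation (Method 1 or 2), mask
#' upscaling to image resolution and segment extraction.
#'
#' @param model a trained `gcnn` or `gcnn_multilevel`.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param method `1` (channel merging) or `2` (pixel clustering).
#' @param params a [method1_params()] or [method2_params()] to match.
#' @return `list(masks, segments, feature_maps)` with `masks` a `mask_set`
#'   at image resolution.
#' @export
segment_image <- function(model, image, method = 2L, params = NULL) {
  f <- forward_feature_maps(model, image)
  if (method == 1L) {
    if (is.null(params)) params <- method1_params()
    m <- method1_generate_masks(f, params)
  } else if (method == 2L) {
    if (is.null(params)) stop("method 2 requires method2_params (k is not guessed)")
    m <- method2_generate_masks(f, params, image = image)
  } else stop("method must be 1 or 2")
  m_img <- upscale_masks(m, dim(image)[1:2])
  list(masks = m_img, segments = extract_segments(image, m_img),
       feature_maps = f)
}
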