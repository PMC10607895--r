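# Image, label-map, mask and checkpoint I/O.
#
# Coordinate convention everywhere: row-major, 0-based labels, pixel-centre;
# images are H x W x 3 arrays in [0, 1]. Label maps are 8-bit grayscale PNGs
# whose pixel value is the integer label id (0 = background), which carries
# the same information as an indexed PNG without requiring palette support.

#' Read / write an RGB image
#'
#' @param path PNG file path.
#' @return `read_image`: `H x W x 3` array in `[0, 1]` (alpha dropped,
#'   grayscale expanded).
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a ground-truth label map
#'
#' The PNG must be grayscale with pixel values equal to integer label ids
#' (0 = background). Returns one binary mask per non-zero label present.
#'
#' @param path PNG path, or an integer matrix to convert directly.
#' @return `list(masks, labels, label_map)`; `masks[[i]]` is the logical
#'   mask of `labels[i]`. Zero masks (with a warning) when the map is all
#'   background.
#' @export
read_label_map <- function(path) {
  lm <- if (is.matrix(path)) {
    matrix(as.integer(path), nrow(path), ncol(path))
  } else {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (!all(abs(img[, , 1L] - img[, , 2L]) < 1e-9) ||
          !all(abs(img[, , 1L] - img[, , 3L]) < 1e-9))
        stop("label map must be a grayscale (single-channel) PNG: ", path)
      img <- img[, , 1L]
    }
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  }
  labels <- sort(setdiff(unique(as.vector(lm)), 0L))
  if (length(labels) == 0L)
    warning("label map contains only background: ",
            if (is.character(path)) path else "<matrix>")
  list(masks = lapply(labels, function(l) lm == l),
       labels = labels, label_map = lm)
}

#' @rdname read_label_map
#' @param label_map integer matrix with values in 0..255.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(all(label_map >= 0L), all(label_map <= 255L))
  png::writePNG(matrix(label_map / 255, nrow(label_map), ncol(label_map)),
                path)
  invisible(path)
}

#' Write a mask set as PNGs with a JSON sidecar
#'
#' Each mask becomes an 8-bit PNG (0/255) named `mask_XXX.png`; the sidecar
#' `masks.json` records the method, shape and per-mask provenance so a run
#' is reconstructible from its output directory.
#'
#' @param m a `mask_set`.
#' @param dir output directory (created if needed).
#' @param extra named list merged into the sidecar (e.g. seeds, params).
#' @return Invisibly, the sidecar path.
#' @export
write_masks <- function(m, dir, extra = list()) {
  stopifnot(inherits(m, "mask_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(m$masks))
  for (i in seq_along(m$masks)) {
    files[i] <- file.path(dir, sprintf("mask_%03d.png", i))
    png::writePNG(m$masks[[i]] * 1, files[i])
  }
  side <- c(list(method = m$method, shape = m$shape,
                 n_masks = length(m$masks),
                 provenance = m$provenance, files = basename(files)),
            extra)
  sp <- file.path(dir, "masks.json")
  jsonlite::write_json(side, sp, auto_unbox = TRUE, pretty = TRUE)
  invisible(sp)
}

#' Read a mask set written by [write_masks()]
#'
#' @param dir directory holding `masks.json` and the mask PNGs.
#' @return A `mask_set`.
#' @export
read_masks <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "masks.json"),
                              simplifyVector = TRUE)
  masks <- lapply(side$files, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img > 0.5
  })
  new_mask_set(masks, side$method, as.list(side$provenance), side$shape)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: the configuration travels with the
#' weights, so a loaded model is immediately usable.
#'
#' @param model a `gcnn` or `gcnn_multilevel`.
#' @param path file path (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("gcnn", "gcnn_multilevel")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("gcnn", "gcnn_multilevel")))
    stop("not a model checkpoint: ", path)
  model
}
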