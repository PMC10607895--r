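#' Segmentation-for-recognition metrics
#'
#' Five pixel-set metrics score class-agnostic segments `B_j` against
#' ground-truth ingredient regions `A_i`:
#' \itemize{
#'   \item IoU `= |A \& B| / |A | B|`
#'   \item Dice `= 2 |A \& B| / (|A| + |B|)`
#'   \item purity `= |A \& B| / |B|` -- how much of a segment is ingredient
#'   \item entirety `= |A \& B| / |A|` -- how much of an ingredient the
#'     segment recovers
#'   \item LoGTs `= (|U A| - |U A \& U B|) / |U A|` -- ground-truth
#'     foreground lost by all segments together
#' }
#' All masks must be logical (or 0/1) matrices of one shape.
#'
#' @param A,B binary masks.
#' @return Scalar in `[0, 1]`.
#' @name seg_metrics
NULL

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  stopifnot(all(m %in% c(0, 1)))
  m > 0
}

check_pair <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  list(A = as_mask(A), B = as_mask(B))
}

#' @rdname seg_metrics
#' @export
iou <- function(A, B) {
  p <- check_pair(A, B)
  u <- sum(p$A | p$B)
  if (u == 0L) stop("IoU undefined: both masks empty")
  sum(p$A & p$B) / u
}

#' @rdname seg_metrics
#' @export
dice <- function(A, B) {
  p <- check_pair(A, B)
  s <- sum(p$A) + sum(p$B)
  if (s == 0L) stop("Dice undefined: both masks empty")
  2 * sum(p$A & p$B) / s
}

#' @rdname seg_metrics
#' @export
purity <- function(A, B) {
  p <- check_pair(A, B)
  if (sum(p$B) == 0L) stop("purity undefined: empty segment mask")
  sum(p$A & p$B) / sum(p$B)
}

#' @rdname seg_metrics
#' @export
entirety <- function(A, B) {
  p <- check_pair(A, B)
  if (sum(p$A) == 0L) stop("entirety undefined: empty ground-truth mask")
  sum(p$A & p$B) / sum(p$A)
}

#' Loss of ground truths
#'
#' Fraction of the union of ground-truth regions left uncovered by the union
#' of all segments; 0 when the segments jointly cover every ground-truth
#' pixel, 1 when no segment touches the foreground.
#'
#' @param gts list of ground-truth binary masks `A_1..A_I`.
#' @param segments list of predicted binary masks `B_1..B_J` (may be empty).
#' @return Scalar in `[0, 1]`.
#' @export
logts <- function(gts, segments) {
  stopifnot(length(gts) >= 1L)
  uA <- Reduce(`|`, lapply(gts, as_mask))
  nA <- sum(uA)
  if (nA == 0L) stop("LoGTs undefined: empty ground-truth union")
  if (length(segments) == 0L) return(1)
  uB <- Reduce(`|`, lapply(segments, as_mask))
  (nA - sum(uA & uB)) / nA
}

#' Per-image segmentation metrics
#'
#' Aggregates the pairwise metrics over one image: each segment contributes
#' its best purity over ground truths (mean = `mPurity`); each ground truth
#' contributes its best entirety, IoU and Dice over segments (means =
#' `mEntirety`, `mIoU`, `mDice`); `LoGTs` is computed on the unions. With no
#' segments, `mPurity` is `NA` (flagged), `mEntirety`/`mIoU`/`mDice` are 0
#' and `LoGTs` is 1. Empty segment masks are dropped with a message.
#'
#' @param gts list of `I >= 1` ground-truth binary masks.
#' @param segments list of predicted binary masks, e.g. `mask_set$masks`.
#' @return data.frame row: `mPurity`, `mEntirety`, `LoGTs`, `mIoU`, `mDice`,
#'   `I`, `J`.
#' @export
image_metrics <- function(gts, segments) {
  if (inherits(segments, "mask_set")) segments <- segments$masks
  stopifnot(length(gts) >= 1L)
  gts <- lapply(gts, as_mask)
  segments <- lapply(segments, as_mask)
  empty <- vapply(segments, function(b) sum(b) == 0L, logical(1))
  if (any(empty)) {
    message("image_metrics: dropping ", sum(empty), " empty segment(s)")
    segments <- segments[!empty]
  }
  I <- length(gts); J <- length(segments)
  if (J == 0L)
    return(data.frame(mPurity = NA_real_, mEntirety = 0, LoGTs = 1,
                      mIoU = 0, mDice = 0, I = I, J = 0L))
  pur <- matrix(0, I, J); ent <- pur; io <- pur; di <- pur
  for (i in seq_len(I)) for (j in seq_len(J)) {
    inter <- sum(gts[[i]] & segments[[j]])
    nA <- sum(gts[[i]]); nB <- sum(segments[[j]])
    pur[i, j] <- inter / nB
    ent[i, j] <- inter / nA
    io[i, j] <- inter / (nA + nB - inter)
    di[i, j] <- 2 * inter / (nA + nB)
  }
  data.frame(
    mPurity = mean(apply(pur, 2L, max)),
    mEntirety = mean(apply(ent, 1L, max)),
    LoGTs = logts(gts, segments),
    mIoU = mean(apply(io, 1L, max)),
    mDice = mean(apply(di, 1L, max)),
    I = I, J = J)
}

#' Dataset-level metric summary
#'
#' Unweighted means of the per-image values over all images; `NA` per-image
#' values (no-segment images) are excluded from the `mPurity` mean and
#' counted in `n_flagged`.
#'
#' @param records data.frame of [image_metrics()] rows.
#' @return A `metrics_report`: list with `per_image` and `dataset` (named
#'   means `mPurity`, `mEntirety`, `mLoGTs`, `mIoU`, `mDice`).
#' @export
dataset_metrics <- function(records) {
  stopifnot(nrow(records) >= 1L)
  ds <- c(mPurity = mean(records$mPurity, na.rm = TRUE),
          mEntirety = mean(records$mEntirety),
          mLoGTs = mean(records$LoGTs),
          mIoU = mean(records$mIoU),
          mDice = mean(records$mDice))
  structure(list(per_image = records, dataset = ds,
                 n_flagged = sum(is.na(records$mPurity))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", nrow(x$per_image), "image(s)\n")
  print(round(x$dataset, 4))
  if (x$n_flagged > 0L)
    cat(x$n_flagged, "image(s) had no segments (mPurity flagged NA)\n")
  invisible(x)
}
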