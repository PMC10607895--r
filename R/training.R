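#' Per-level loss weights for multi-level training
#'
#' The four cross-entropy terms are weighted in descending order from the
#' leaf level (level 4) to the top level: the default is
#' `lambda4 = 1.0, lambda3 = 0.5, lambda2 = 0.3, lambda1 = 0.1`, which
#' emphasises the fine-grained task while still propagating signal from the
#' coarser levels.
#'
#' @param lambda1,lambda2,lambda3,lambda4 non-negative weights.
#' @param check enforce the descending-weight invariant (`lambda4 >=
#'   lambda3 >= lambda2 >= lambda1`, `lambda4 > 0`). Disable only for
#'   diagnostic runs that deliberately isolate one level.
#' @return Named numeric vector `c(lambda1, ..., lambda4)` of class
#'   `level_weights`.
#' @export
level_weights <- function(lambda1 = 0.1, lambda2 = 0.3,
                          lambda3 = 0.5, lambda4 = 1.0, check = TRUE) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2,
         lambda3 = lambda3, lambda4 = lambda4)
  if (any(w < 0)) stop("level weights must be non-negative")
  if (check) {
    if (w[4L] <= 0) stop("lambda4 must be positive")
    if (is.unsorted(w))
      stop("level weights must be descending from level 4 to 1")
  }
  structure(w, class = "level_weights")
}

#' Training configuration
#'
#' Defaults follow the reference recipe: 30 epochs (single-level; use 50 for
#' multi-level), mini-batches of 32, initial learning rate 3e-2 on a piecewise
#' schedule that multiplies the rate by 0.2 every `lr_drop_period` epochs, and
#' an Adam optimiser with squared-gradient decay factor 0.9.
#'
#' @param epochs,batch_size,initial_lr,lr_drop_factor,lr_drop_period,seed
#'   scalar hyperparameters.
#' @param sq_grad_decay Adam second-moment decay (beta2).
#' @param grad_decay Adam first-moment decay (beta1); unstated in the
#'   reference recipe, kept at the conventional 0.9.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, initial_lr = 3e-2,
                         lr_drop_factor = 0.2, lr_drop_period = 10L,
                         sq_grad_decay = 0.9, grad_decay = 0.9, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, initial_lr > 0,
            lr_drop_factor > 0, lr_drop_factor < 1, lr_drop_period >= 1L,
            sq_grad_decay > 0, sq_grad_decay < 1,
            grad_decay >= 0, grad_decay < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period),
                 sq_grad_decay = sq_grad_decay, grad_decay = grad_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Weighted multi-level cross-entropy loss
#'
#' Computes `sum_i lambda_i * CE(softmax(z_i), y_i)` over the four taxonomy
#' levels, where `z_i` are pooled score vectors and `y_i` the per-level
#' ground-truth ids. With a batch, each level's CE is the batch mean.
#'
#' @param zs list of 4 score vectors (length `C_i`) or `N x C_i` matrices,
#'   ordered level 1..4.
#' @param labels a [lift_label()] result, an integer vector `c(y1..y4)`
#'   (0-based), or an `N x 4` matrix of such rows.
#' @param w a [level_weights()].
#' @return Non-negative scalar loss.
#' @export
multilevel_loss <- function(zs, labels, w = level_weights()) {
  stopifnot(length(zs) == 4L)
  if (!is.matrix(labels)) labels <- matrix(as.integer(labels), nrow = 1L)
  total <- 0
  for (l in 1:4) {
    z <- zs[[l]]
    if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
    y <- labels[, l]
    if (nrow(z) != length(y))
      stop("level ", l, ": ", nrow(z), " score rows vs ", length(y), " labels")
    if (any(y < 0L | y >= ncol(z)))
      stop("level ", l, ": label out of range [0, ", ncol(z) - 1L, "]")
    total <- total + w[l] * softmax_ce(z, y)$loss
  }
  unname(total)
}

# learning rate for a given epoch under the piecewise schedule
lr_at_epoch <- function(cfg, epoch) {
  cfg$initial_lr * cfg$lr_drop_factor^((epoch - 1L) %/% cfg$lr_drop_period)
}

.block_params <- function(blk) blk[c("W", "b", "gamma", "beta")]

.update_block <- function(blk, grads, state, lr, t, b1, b2) {
  up <- adam_step(.block_params(blk), grads, state, lr, t, b1, b2)
  blk[c("W", "b", "gamma", "beta")] <- up$params
  list(blk = blk, state = up$state)
}

.check_finite <- function(loss, epoch, batch, lr) {
  if (!is.finite(loss))
    stop(sprintf(
      "non-finite loss (%s) at epoch %d, batch %d (lr = %g); %s",
      format(loss), epoch, batch, lr,
      "consider lowering initial_lr or checking the input range"))
}

#' Train a single-level model on leaf labels
#'
#' Optimises the level-4 (leaf) cross-entropy with Adam under the piecewise
#' learning-rate schedule of the supplied [train_config()]. All randomness
#' (initial shuffling included) runs in a private stream seeded from
#' `cfg$seed`, so identical calls give identical results.
#'
#' @param model a `gcnn` built by [build_gated_cnn()].
#' @param images list of `H x W x 3` arrays in `[0, 1]`.
#' @param labels 0-based integer leaf class ids, one per image.
#' @param cfg a [train_config()].
#' @return `list(model, history)`; `history` is a data.frame with columns
#'   `epoch`, `loss` (mean batch loss) and `lr`.
#' @export
train_slm <- function(model, images, labels, cfg = train_config()) {
  stopifnot(inherits(model, "gcnn"))
  n <- length(images)
  if (n == 0L) stop("empty training set")
  labels <- as.integer(labels)
  if (length(labels) != n) stop("one label per image required")
  if (any(labels < 0L | labels >= model$config$num_classes))
    stop("labels must be 0-based ids below num_classes")
  with_seed(cfg$seed, {
    imgs <- lapply(images, prep_input, model$config$input_size)
    states <- lapply(model$blocks, function(b) adam_init(.block_params(b)))
    hist <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
    t <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample.int(n)
      losses <- c()
      starts <- seq(1L, n, by = cfg$batch_size)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        X <- images_to_mat(imgs[idx])
        fw <- gcnn_forward(model, X, attr(X, "dims"),
                           training = TRUE, keep = TRUE)
        model <- fw$model
        sc <- softmax_ce(fw$logits, labels[idx])
        .check_finite(sc$loss, epoch, bi, lr)
        losses <- c(losses, sc$loss)
        d <- gap_backward(sc$dlogits, fw$feat_dims)
        t <- t + 1L
        for (i in 8:1) {
          bb <- block_backward(model$blocks[[i]], fw$caches[[i]], d)
          d <- bb$dX
          up <- .update_block(model$blocks[[i]], bb$grads, states[[i]],
                              lr, t, cfg$grad_decay, cfg$sq_grad_decay)
          model$blocks[[i]] <- up$blk
          states[[i]] <- up$state
        }
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                     lr = lr))
    }
    list(model = model, history = hist)
  })
}

#' Train a multi-level model on hierarchical labels
#'
#' Optimises the weighted sum of the four per-level cross-entropies (see
#' [multilevel_loss()]) over the shared trunk and the bottom-up head stack.
#'
#' @param model a `gcnn_multilevel` from [build_multilevel_gcnn()].
#' @param images list of `H x W x 3` arrays in `[0, 1]`.
#' @param labels `N x 4` integer matrix of 0-based ids (columns = levels
#'   1..4), or a list of [lift_label()] results.
#' @param cfg a [train_config()] (reference recipe: 50 epochs).
#' @param w a [level_weights()].
#' @return `list(model, history)`; `history` has `epoch`, `loss` (weighted),
#'   `loss_l1`..`loss_l4` (unweighted per-level means) and `lr`.
#' @export
train_mlm <- function(model, images, labels, cfg = train_config(epochs = 50L),
                      w = level_weights()) {
  stopifnot(inherits(model, "gcnn_multilevel"))
  n <- length(images)
  if (n == 0L) stop("empty training set")
  if (is.list(labels)) labels <- do.call(rbind, lapply(labels, as.integer))
  labels <- matrix(as.integer(labels), ncol = 4L)
  if (nrow(labels) != n) stop("one hierarchical label per image required")
  for (l in 1:4)
    if (any(labels[, l] < 0L | labels[, l] >= model$class_counts[l]))
      stop("level ", l, " labels out of range")
  with_seed(cfg$seed, {
    imgs <- lapply(images, prep_input, model$config$input_size)
    tstates <- lapply(model$blocks, function(b) adam_init(.block_params(b)))
    hstates <- lapply(model$heads, function(b) adam_init(.block_params(b)))
    hist <- NULL
    t <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample.int(n)
      losses <- matrix(0, 0L, 5L)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        X <- images_to_mat(imgs[idx])
        fw <- gcnn_ml_forward(model, X, attr(X, "dims"),
                              training = TRUE, keep = TRUE)
        model <- fw$model
        sc <- lapply(1:4, function(l)
          softmax_ce(fw$logits[[l]], labels[idx, l]))
        lvl <- vapply(sc, `[[`, numeric(1), "loss")
        total <- sum(w * lvl)
        .check_finite(total, epoch, bi, lr)
        losses <- rbind(losses, c(total, lvl))
        t <- t + 1L
        # heads in reverse stack order: level 1 (top, index 4) first
        d <- NULL
        for (i in 4:1) {
          lev <- 5L - i
          dims_i <- fw$hcache[[i]]$cv$dims_out
          dOut <- gap_backward(w[lev] * sc[[lev]]$dlogits, dims_i)
          if (!is.null(d)) dOut <- dOut + d
          bb <- block_backward(model$heads[[i]], fw$hcache[[i]], dOut)
          d <- bb$dX
          up <- .update_block(model$heads[[i]], bb$grads, hstates[[i]],
                              lr, t, cfg$grad_decay, cfg$sq_grad_decay)
          model$heads[[i]] <- up$blk
          hstates[[i]] <- up$state
        }
        for (i in 7:1) {
          bb <- block_backward(model$blocks[[i]], fw$tcache[[i]], d)
          d <- bb$dX
          up <- .update_block(model$blocks[[i]], bb$grads, tstates[[i]],
                              lr, t, cfg$grad_decay, cfg$sq_grad_decay)
          model$blocks[[i]] <- up$blk
          tstates[[i]] <- up$state
        }
      }
      m <- colMeans(losses)
      hist <- rbind(hist, data.frame(
        epoch = epoch, loss = m[1L], loss_l1 = m[2L], loss_l2 = m[3L],
        loss_l3 = m[4L], loss_l4 = m[5L], lr = lr))
    }
    list(model = model, history = hist)
  })
}

#' Classification report from predictions
#'
#' @param truth,pred vectors of class ids (any common coding).
#' @return A `classification_report`: `accuracy`, macro `precision`,
#'   `recall`, `f1` (unweighted means over classes present in `truth`;
#'   a class never predicted contributes precision 0), plus a `per_class`
#'   data.frame.
#' @export
classification_report <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0L)
  classes <- sort(unique(truth))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cl, n = tp + fn, precision = p, recall = r, f1 = f)
  }))
  structure(list(
    accuracy = mean(pred == truth),
    precision = mean(per$precision), recall = mean(per$recall),
    f1 = mean(per$f1), per_class = per
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes)\n",
    x$accuracy, x$precision, x$recall, x$f1, nrow(x$per_class)))
  invisible(x)
}

#' Evaluate a trained classifier on a test set
#'
#' Runs inference and scores leaf-level (or any level's) predictions with
#' accuracy and macro precision/recall/F1.
#'
#' @param model a trained `gcnn` or `gcnn_multilevel`.
#' @param images list of test images.
#' @param labels 0-based true ids at `level`.
#' @param level taxonomy level to score for multi-level models (default 4).
#' @return A [classification_report()].
#' @export
evaluate_classification <- function(model, images, labels, level = 4L) {
  if (length(images) == 0L) stop("empty test set")
  probs <- predict(model, images)
  if (is.list(probs)) probs <- probs[[level]]
  pred <- max.col(probs, ties.method = "first") - 1L
  classification_report(as.integer(labels), pred)
}

#' Seed-stable train/test split
#'
#' Randomly assigns `floor(train_frac * n)` items (per class when
#' stratified) to the training set and the remainder to the test set.
#'
#' @param labels class ids (used only when `stratify = TRUE`).
#' @param train_frac fraction for training (default 0.8).
#' @param seed integer seed; identical seeds give identical membership.
#' @param stratify split within each class (default) or globally.
#' @return Logical vector: `TRUE` = training member.
#' @export
train_test_split <- function(labels, train_frac = 0.8, seed = 1L,
                             stratify = TRUE) {
  n <- length(labels)
  stopifnot(n > 0L, train_frac > 0, train_frac < 1)
  with_seed(seed, {
    is_train <- logical(n)
    if (stratify) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < 2L)
          stop("class ", cl, " has fewer than 2 items; cannot stratify")
        is_train[sample(idx, floor(train_frac * length(idx)))] <- TRUE
      }
    } else {
      is_train[sample.int(n, floor(train_frac * n))] <- TRUE
    }
    is_train
  })
}
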