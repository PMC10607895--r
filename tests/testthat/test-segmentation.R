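fmap <- function(..., h = 2, w = 2) {
  chans <- list(...)
  array(unlist(chans), dim = c(h, w, length(chans)))
}

test_that("method 1 filters channels by sigmoid of the global mean", {
  # constant-zero channel scores sigmoid(0) = 0.5, not > 0.5: dropped;
  # a channel with mean 1 scores ~0.731: retained
  f <- fmap(c(0, 0, 0, 0), c(2, 0, 2, 0))
  m <- method1_generate_masks(f)
  expect_length(m$masks, 1)
  expect_equal(m$provenance[[1]], 2L)
  # all channels filtered out -> empty mask set, not an error
  none <- method1_generate_masks(fmap(c(-1, -1, -1, -1)))
  expect_length(none$masks, 0)
  # filter decision is equivalent to mean > 0 on random maps
  set.seed(8)
  for (case in 1:20) {
    ch <- matrix(rnorm(16, sd = 2), 4, 4)
    got <- method1_generate_masks(array(ch, c(4, 4, 1)))
    expect_equal(length(got$masks) == 1L, mean(ch) > 0)
  }
})

test_that("method 1 merges positively correlated channels transitively", {
  # B = 2A (r = 1): merged into a single mask
  A <- c(3, 1, 2, 4)
  two <- method1_generate_masks(fmap(A, 2 * A))
  expect_length(two$masks, 1)
  expect_equal(two$provenance[[1]], c(1L, 2L))
  # orthogonal patterns (shifted +1.5 to pass the filter): r = 0, not merged
  p1 <- 1.5 + c(1, -1, 1, -1)
  p2 <- 1.5 + c(1, 1, -1, -1)
  expect_equal(cor(p1, p2), 0)
  sep <- method1_generate_masks(fmap(p1, p2))
  expect_length(sep$masks, 2)
  # transitive chain: r(c1,c2) > 0, r(c2,c3) > 0 can bridge c1 and c3
  c1 <- c(4, 1, 1, 1); c2 <- c(4, 1, 4, 1); c3 <- c(1, 1, 4, 1)
  chain <- method1_generate_masks(fmap(c1, c2, c3))
  expect_length(chain$masks, 1)
  expect_equal(chain$provenance[[1]], 1:3)
  # a constant channel correlates with nothing, forms its own group, and its
  # merged map (zero range) binarises to nothing: discarded with a log line
  expect_message(const <- method1_generate_masks(fmap(A, rep(5, 4))),
                 "empty mask")
  expect_length(const$masks, 1)
  expect_equal(const$provenance[[1]], 1L)
})

test_that("method 1 masks are binary and invariant to channel permutation", {
  set.seed(15)
  f <- array(rnorm(8 * 8 * 6, mean = 0.2), dim = c(8, 8, 6))
  m <- method1_generate_masks(f)
  for (mask in m$masks) {
    expect_type(mask, "logical")
    expect_true(any(mask))
  }
  canon <- function(ms) {
    keys <- sort(vapply(ms$masks, function(x) paste(which(x), collapse = ","),
                        character(1)))
    keys
  }
  for (rep in 1:5) {
    perm <- sample(6)
    mp <- method1_generate_masks(f[, , perm])
    expect_equal(canon(mp), canon(m))
  }
})

test_that("method 2 recovers planted clusters exactly", {
  # K = 1, no background: the single mask covers everything
  f1 <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  m1 <- method2_generate_masks(f1, method2_params(1))
  expect_length(m1$masks, 1)
  expect_true(all(m1$masks[[1]]))

  # left half u, right half v: K = 2 recovers the halves up to order
  u <- c(5, 0, 0); v <- c(0, 5, 0)
  f2 <- array(0, dim = c(6, 8, 3))
  for (c in 1:3) {
    f2[, 1:4, c] <- u[c]
    f2[, 5:8, c] <- v[c]
  }
  m2 <- method2_generate_masks(f2, method2_params(2, seed = 4))
  left <- matrix(FALSE, 6, 8); left[, 1:4] <- TRUE
  got <- lapply(m2$masks, which)
  expect_setequal(
    vapply(got, paste, "", collapse = ","),
    c(paste(which(left), collapse = ","),
      paste(which(!left), collapse = ",")))

  # masks partition the grid for any K
  set.seed(5)
  f3 <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
  m3 <- method2_generate_masks(f3, method2_params(3, seed = 2))
  expect_length(m3$masks, 3)
  expect_true(all(Reduce(`+`, lapply(m3$masks, `+`, 0)) == 1))

  # degenerate input is refused with a named reason
  flat <- array(1, dim = c(4, 4, 2))
  expect_error(method2_generate_masks(flat, method2_params(2)), "degenerate")
  expect_error(method2_generate_masks(f3, method2_params(100)),
               "more clusters")
})

test_that("method 2 drops the background cluster under the blue convention", {
  # image: top third blue background, bottom two planted regions
  img <- array(0, dim = c(9, 9, 3))
  img[1:3, , 3] <- 1                               # pure blue rows
  img[4:6, , 1] <- 1                               # red region
  img[7:9, , 2] <- 1                               # green region
  f <- array(0, dim = c(9, 9, 3))
  f[1:3, , 1] <- 4                                 # distinct embeddings
  f[4:6, , 2] <- 4
  f[7:9, , 3] <- 4
  m <- method2_generate_masks(f, method2_params(2, background_present = TRUE,
                                                seed = 1), image = img)
  expect_length(m$masks, 2)                        # 3 fitted, 1 dropped
  rows_covered <- sort(unique(unlist(lapply(m$masks, function(x)
    which(apply(x, 1, any))))))
  expect_equal(rows_covered, 4:9)                  # background rows gone
  expect_error(
    method2_generate_masks(f, method2_params(2, background_present = TRUE)),
    "requires the source image")
})

test_that("mask upscaling is nearest-neighbour and binarity-preserving", {
  m <- structure(
    list(masks = list(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)),
         method = "method1", provenance = list(1L), shape = c(2L, 2L)),
    class = "mask_set")
  up <- upscale_masks(m, c(4, 4))
  # 2x2 -> 4x4 is exact 2x2 block expansion
  expect_equal(up$masks[[1]], kronecker(m$masks[[1]], matrix(TRUE, 2, 2),
                                        FUN = `&`))
  ones <- structure(list(masks = list(matrix(TRUE, 3, 3)), method = "m",
                         provenance = list(1L), shape = c(3L, 3L)),
                    class = "mask_set")
  expect_true(all(upscale_masks(ones, c(7, 5))$masks[[1]]))
  # foreground fraction is preserved up to boundary quantisation
  set.seed(3)
  for (case in 1:20) {
    mk <- random_mask_ne(6, 6, 0.5)
    ms <- structure(list(masks = list(mk), method = "m",
                         provenance = list(1L), shape = c(6L, 6L)),
                    class = "mask_set")
    big <- upscale_masks(ms, c(24, 24))$masks[[1]]
    expect_equal(mean(big), mean(mk), tolerance = 1 / 6)
    expect_type(big, "logical")
  }
})

test_that("segment extraction and blue compositing act pixelwise", {
  set.seed(10)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  mask <- random_mask_ne(8, 8)
  ms <- structure(list(masks = list(matrix(TRUE, 8, 8), mask),
                       method = "m", provenance = list(1L, 2L),
                       shape = c(8L, 8L)), class = "mask_set")
  segs <- extract_segments(img, ms)
  expect_equal(segs[[1]], img)                     # all-ones mask: identity
  for (c in 1:3) {
    expect_true(all(segs[[2]][, , c][!mask] == 0))
    expect_equal(segs[[2]][, , c][mask], img[, , c][mask])
  }
  zero <- structure(list(masks = list(matrix(FALSE, 8, 8)), method = "m",
                         provenance = list(1L), shape = c(8L, 8L)),
                    class = "mask_set")
  expect_true(all(extract_segments(img, zero)[[1]] == 0))
  expect_error(extract_segments(img[1:4, , , drop = FALSE], ms),
               "does not match")

  lm <- matrix(0L, 8, 8); lm[3:6, 3:6] <- 1L
  blue <- blue_background_composite(img, lm)
  bg <- lm == 0
  expect_true(all(blue[, , 1][bg] == 0) && all(blue[, , 3][bg] == 1))
  expect_equal(blue[, , 2][!bg], img[, , 2][!bg])
  expect_equal(blue_background_composite(img, matrix(1L, 8, 8)), img)
  all_bg <- blue_background_composite(img, matrix(0L, 8, 8))
  expect_true(all(all_bg[, , 3] == 1) && all(all_bg[, , 1:2] == 0))
})

test_that("segment_image composes the pipeline deterministically", {
  specs <- default_class_specs(2)
  ds <- generate_dataset(specs, images_per_variant = 5, size = 32, seed = 7)
  fit <- train_slm(build_gated_cnn(tiny_cfg(2, 32), seed = 3),
                   ds$images, ds$labels, train_config(epochs = 30, seed = 3))
  sc <- compose_multi_ingredient_scene(scene_spec(2, 64, seed = 12), specs)
  out <- segment_image(fit$model, sc$image, 2,
                       method2_params(2, background_present = TRUE, seed = 2))
  expect_length(out$masks$masks, 2)
  expect_equal(out$masks$shape, c(64L, 64L))
  out2 <- segment_image(fit$model, sc$image, 2,
                        method2_params(2, background_present = TRUE, seed = 2))
  expect_identical(out$masks$masks, out2$masks$masks)
  expect_error(segment_image(fit$model, sc$image, 2), "method2_params")
  m1 <- segment_image(fit$model, sc$image, 1)
  expect_s3_class(m1$masks, "mask_set")
})
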