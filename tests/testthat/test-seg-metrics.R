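block_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

test_that("pairwise metrics reproduce worked pixel-counting examples", {
  A <- block_mask(4, 4, 1:2, 1:2)            # 2x2 block at the origin
  B <- block_mask(4, 4, 1:2, 2:3)            # same block shifted right by 1
  expect_equal(iou(A, A), 1)
  expect_equal(iou(A, B), 1 / 3)             # 2 shared / 6 union
  expect_equal(dice(A, B), 0.5)              # 2*2 / (4+4)
  expect_equal(purity(A, B), 0.5)
  expect_equal(entirety(A, B), 0.5)
  disjoint <- block_mask(4, 4, 3:4, 3:4)
  expect_equal(iou(A, disjoint), 0)
  expect_error(iou(A * 0, A * 0), "both masks empty")
  expect_error(purity(A, A * 0), "empty segment")
  expect_error(entirety(A * 0, B), "empty ground-truth")
})

test_that("LoGTs counts uncovered ground-truth foreground", {
  A1 <- block_mask(5, 5, 1:2, 1:3)           # 6 px
  A2 <- block_mask(5, 5, 4:5, 4:5)           # 4 px, union 10
  segs_exact <- list(A1, A2)
  expect_equal(logts(list(A1, A2), segs_exact), 0)
  expect_equal(logts(list(A1, A2), list()), 1)
  B <- block_mask(5, 5, 1:2, 1:3)            # covers 6 of the 10
  expect_equal(logts(list(A1, A2), list(B)), 0.4)
  # covering superset of the union zeroes the loss despite fragmentation
  expect_equal(logts(list(A1, A2), list(block_mask(5, 5, 1:5, 1:5))), 0)
  expect_error(logts(list(A1 * 0 > 0), list(B)), "empty ground-truth union")
})

test_that("per-image aggregation follows the max-matching rules", {
  A <- block_mask(6, 6, 1:3, 1:3)
  r <- image_metrics(list(A), list(A))
  expect_equal(unlist(r[1, 1:5]),
               c(mPurity = 1, mEntirety = 1, LoGTs = 0, mIoU = 1, mDice = 1))

  # two disjoint GTs, one segment equal to the first
  A2 <- block_mask(6, 6, 5:6, 5:6)
  r2 <- image_metrics(list(A, A2), list(A))
  expect_equal(r2$mEntirety, 0.5)            # (1 + 0) / 2
  expect_equal(r2$LoGTs, sum(A2) / (sum(A) + sum(A2)))
  expect_equal(r2$mIoU, 0.5)

  # no segments: flagged purity, zero coverage
  r0 <- image_metrics(list(A), list())
  expect_true(is.na(r0$mPurity))
  expect_equal(r0$mEntirety, 0)
  expect_equal(r0$LoGTs, 1)

  # segment order is irrelevant
  set.seed(42)
  gts <- list(random_mask_ne(), random_mask_ne())
  segs <- list(random_mask_ne(), random_mask_ne(), random_mask_ne())
  expect_equal(image_metrics(gts, segs)[1, 1:5],
               image_metrics(gts, rev(segs))[1, 1:5])
})

test_that("metrics agree exactly with the set-counting oracle on random instances", {
  set.seed(2024)
  for (case in 1:200) {
    I <- sample(1:3, 1); J <- sample(1:3, 1)
    gts <- replicate(I, random_mask_ne(), simplify = FALSE)
    segs <- replicate(J, random_mask_ne(), simplify = FALSE)
    got <- image_metrics(gts, segs)
    want <- bf_image_metrics(gts, segs)
    expect_identical(got$mPurity, want$mPurity)
    expect_identical(got$mEntirety, want$mEntirety)
    expect_identical(got$LoGTs, want$LoGTs)
    expect_identical(got$mIoU, want$mIoU)
    expect_identical(got$mDice, want$mDice)
  }
})

test_that("metric identities and invariances hold on random masks", {
  set.seed(77)
  for (case in 1:50) {
    A <- random_mask_ne(); B <- random_mask_ne()
    i <- iou(A, B)
    expect_equal(dice(A, B), 2 * i / (1 + i), tolerance = 1e-12)
    expect_gte(dice(A, B), i)
    expect_equal(purity(A, B) * sum(B), entirety(A, B) * sum(A))
    # simultaneous pixel permutation leaves every metric unchanged
    perm <- sample(64)
    Ap <- matrix(as.vector(A)[perm], 8, 8)
    Bp <- matrix(as.vector(B)[perm], 8, 8)
    expect_equal(iou(Ap, Bp), i)
    expect_equal(purity(Ap, Bp), purity(A, B))
    # monotonicity: adding true pixels to B never decreases entirety;
    # removing false pixels never decreases purity
    B_plus <- B | A
    expect_gte(entirety(A, B_plus), entirety(A, B))
    B_clean <- B & A
    if (any(B_clean))
      expect_gte(purity(A, B_clean), purity(A, B))
  }
})

test_that("dataset aggregation is the unweighted mean over images", {
  r1 <- image_metrics(list(block_mask(4, 4, 1:2, 1:2)),
                      list(block_mask(4, 4, 1:2, 1:2)))
  r2 <- image_metrics(list(block_mask(4, 4, 1:2, 1:2)),
                      list(block_mask(4, 4, 1:3, 1:2)))
  rep1 <- dataset_metrics(rbind(r1, r1))
  expect_equal(unname(rep1$dataset["mIoU"]), r1$mIoU)
  rep <- dataset_metrics(rbind(r1, r2))
  expect_equal(unname(rep$dataset["mIoU"]), mean(c(r1$mIoU, r2$mIoU)))
  # LoGTs 0 and 0.4 average to 0.2
  expect_equal(mean(c(0, 0.4)), 0.2)
  ra <- image_metrics(list(block_mask(5, 5, 1:2, 1:3),
                           block_mask(5, 5, 4:5, 4:5)),
                      list(block_mask(5, 5, 1:2, 1:3)))
  repb <- dataset_metrics(rbind(r1, ra))
  expect_equal(unname(repb$dataset["mLoGTs"]), mean(c(0, 0.4)))
})
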