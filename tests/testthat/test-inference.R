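# Tiled inference and voxel-wise evaluation.

test_that("confusion counts match their definitions and the naive oracle", {
  d <- c(6, 5, 4)
  truth <- array(0L, d); truth[2:4, 2:4, 2:3] <- 1L
  # prediction identical -> no errors anywhere
  for (cl in 1:3) {
    cc <- confusion_counts(truth, truth, cl)
    expect_equal(cc$FP, 0); expect_equal(cc$FN, 0)
  }
  # all-background prediction vs 18 VB voxels
  pred0 <- array(0L, d)
  cc <- confusion_counts(pred0, truth, 1)
  expect_equal(cc, list(TP = 0L, FP = 0L, FN = sum(truth == 1L)))
  # 9 overlapping + 1 missed + 1 spurious
  truth2 <- array(0L, c(4, 5, 1)); truth2[cbind(
    c(1, 1, 1, 1, 2, 2, 2, 2, 2, 1), c(1, 2, 3, 4, 1, 2, 3, 4, 5, 5), 1)] <- 1L
  pred2 <- array(0L, c(4, 5, 1)); pred2[cbind(
    c(1, 1, 1, 1, 2, 2, 2, 2, 2, 3), c(1, 2, 3, 4, 1, 2, 3, 4, 5, 1), 1)] <- 1L
  cc2 <- confusion_counts(pred2, truth2, 1)
  expect_equal(cc2, list(TP = 9L, FP = 1L, FN = 1L))
  m <- precision_recall_dice(cc2)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$dice, 0.9)
  # random volumes against the brute-force per-voxel oracle
  set.seed(7)
  for (rep in 1:3) {
    dd <- c(sample(3:12, 1), sample(3:12, 1), sample(2:6, 1))
    p <- array(sample(0:3, prod(dd), TRUE), dd)
    t <- array(sample(0:3, prod(dd), TRUE), dd)
    for (cl in 1:3) {
      fast <- confusion_counts(p, t, cl)
      slow <- confusion_oracle(p, t, cl)
      expect_identical(lapply(fast, as.integer), slow)
    }
  }
  expect_error(confusion_counts(array(0L, c(2, 2, 2)),
                                array(0L, c(3, 2, 2)), 1), "grids differ")
})

test_that("metric identities and degenerate conventions hold", {
  # dice = 2PR/(P+R) whenever defined
  set.seed(3)
  for (i in 1:50) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               FN = sample(0:50, 1))
    m <- precision_recall_dice(cc)
    if (m$present && m$precision + m$recall > 0) {
      expect_equal(m$dice,
                   2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
  }
  # class absent from both -> all metrics 1, excluded from averages
  m0 <- precision_recall_dice(list(TP = 0, FP = 0, FN = 0))
  expect_equal(unlist(m0[1, 1:3]), c(precision = 1, recall = 1, dice = 1))
  expect_false(m0$present)
  # absent in truth but predicted -> precision 0
  mfp <- precision_recall_dice(list(TP = 0, FP = 5, FN = 0))
  expect_equal(mfp$precision, 0)
  # swapping prediction and truth swaps precision and recall, fixes dice
  p <- array(sample(0:1, 60, TRUE), c(5, 4, 3))
  t <- array(sample(0:1, 60, TRUE), c(5, 4, 3))
  m1 <- precision_recall_dice(confusion_counts(p, t, 1))
  m2 <- precision_recall_dice(confusion_counts(t, p, 1))
  expect_equal(m1$precision, m2$recall)
  expect_equal(m1$recall, m2$precision)
  expect_equal(m1$dice, m2$dice)
})

test_that("a tile-sized volume equals direct forward + argmax", {
  net <- tiny_network()
  vol <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  seg <- segment_volume(net, vol, tile = c(16, 16, 4), qc = FALSE)
  probs <- forward(net, spinemorph::normalize_intensities(vol))
  direct <- array(max.col(matrix(probs, ncol = 4), ties.method = "first") - 1L,
                  dim(vol))
  expect_identical(seg$data, direct)
})

test_that("tiled inference covers volumes larger than one tile", {
  net <- tiny_network()
  vol <- array(rnorm(24 * 20 * 6), c(24, 20, 6))
  seg <- segment_volume(net, vol, tile = c(16, 16, 4), overlap = 0.5,
                        qc = FALSE)
  expect_identical(dim(seg$data), dim(vol))
  expect_true(all(seg$data %in% 0:3))
  # deterministic
  seg2 <- segment_volume(net, vol, tile = c(16, 16, 4), overlap = 0.5,
                         qc = FALSE)
  expect_identical(seg$data, seg2$data)
})

test_that("QC-rejected volumes are refused with the reasons", {
  net <- tiny_network()
  arr <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  aff <- diag(c(0.9, 0.9, 3, 1)); aff[1, 3] <- 1
  bad <- image_volume(arr, c(0.9, 0.9, 3), affine = aff)
  expect_error(segment_volume(net, bad, tile = c(16, 16, 4)),
               "non_orthogonal_axes")
})

test_that("test-set evaluation averages correctly", {
  net <- tiny_network()
  set.seed(8)
  vols <- lapply(1:2, function(i) array(rnorm(16 * 16 * 4), c(16, 16, 4)))
  truths <- lapply(vols, function(v)
    array(sample(0:3, length(v), TRUE), dim(v)))
  ev1 <- evaluate_test_set(net, vols[1], truths[1], tile = c(16, 16, 4),
                           qc = FALSE)
  # single subject: macro mean equals that subject's metrics
  expect_equal(ev1$macro$dice,
               ev1$per_subject$dice[match(c("VB", "VD", "SC"),
                                          ev1$per_subject$class)])
  # permuting subject order leaves the macro means unchanged
  ev12 <- evaluate_test_set(net, vols, truths, tile = c(16, 16, 4),
                            qc = FALSE)
  ev21 <- evaluate_test_set(net, rev(vols), rev(truths),
                            tile = c(16, 16, 4), qc = FALSE)
  expect_equal(ev12$macro$precision, ev21$macro$precision)
  expect_equal(ev12$macro$dice, ev21$macro$dice)
  expect_equal(ev12$pooled, ev21$pooled)
  expect_error(evaluate_test_set(net, list(), list()), "empty")
})

test_that("perfect predictions evaluate to all ones", {
  ph <- generate_phantom(tiny_spec(grid = c(64, 64, 12), n_vb = 2))
  for (cl in 1:3) {
    m <- precision_recall_dice(confusion_counts(ph$labels$data,
                                                ph$labels$data, cl))
    expect_equal(unlist(m[1, 1:3]), c(precision = 1, recall = 1, dice = 1))
  }
})
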