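# Whole-volume segmentation by tiled inference and voxel-wise evaluation
# (precision, recall, Dice) against reference segmentations.

#' Segment a whole volume by tiled inference
#'
#' Applies the network over a grid of tiles, averages the class
#' probabilities of overlapping tiles and takes the per-voxel argmax.
#' Tiles overlap by `overlap` in-plane (the slice axis is tiled without
#' overlap).  Volumes smaller than a tile are padded by edge replication
#' and cropped back afterwards.
#'
#' @param network a `spine_unet`
#' @param volume a [image_volume()] or 3D numeric array
#' @param tile tile extents (in-plane, in-plane, slices); in-plane
#'   extents must be multiples of `2^(depth-1)`
#' @param overlap in-plane tile overlap fraction in `[0, 1)`
#' @param qc apply [qc_check()] first and refuse rejected volumes
#' @return a [label_volume()] on the input grid
#' @export
segment_volume <- function(network, volume, tile = c(96, 96, 8),
                           overlap = 0.5, qc = TRUE) {
  stopifnot(inherits(network, "spine_unet"), overlap >= 0, overlap < 1)
  spacing <- c(1, 1, 1)
  affine <- NULL
  if (inherits(volume, "spine_volume")) {
    if (qc) {
      rep <- qc_check(volume)
      if (!rep$accepted) {
        stop("volume rejected by quality control: ",
             paste(rep$reasons, collapse = ", "))
      }
    }
    spacing <- volume$spacing
    affine <- volume$affine
    volume <- volume$data
  }
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  tile <- as.integer(tile)
  check_patch_dims(network$spec, tile)

  d0 <- dim(volume)
  vol <- pad_edge(normalize_intensities(volume), tile)
  d <- dim(vol)
  ns <- network$spec

  starts <- function(n, t, stride) {
    s <- unique(c(seq(1L, n - t + 1L, by = stride), n - t + 1L))
    as.integer(s)
  }
  sx <- starts(d[1], tile[1], max(1L, as.integer(round(tile[1] * (1 - overlap)))))
  sy <- starts(d[2], tile[2], max(1L, as.integer(round(tile[2] * (1 - overlap)))))
  sz <- starts(d[3], tile[3], tile[3])

  psum <- array(0, c(d, ns$n_classes))
  cnt <- array(0, d)
  for (ox in sx) for (oy in sy) for (oz in sz) {
    ix <- ox:(ox + tile[1] - 1L)
    iy <- oy:(oy + tile[2] - 1L)
    iz <- oz:(oz + tile[3] - 1L)
    probs <- cpp_unet_forward(unname(network$weights), ns$features,
                              ns$enc_residual_blocks, ns$dec_residual_blocks,
                              ns$n_classes,
                              as.numeric(vol[ix, iy, iz]), tile, TRUE)
    psum[ix, iy, iz, ] <- psum[ix, iy, iz, ] +
      array(probs, c(tile, ns$n_classes))
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  pm <- matrix(psum, ncol = ns$n_classes)
  pred <- array(max.col(pm, ties.method = "first") - 1L, d)

  # crop padding back to the input grid (pad_edge centres the original)
  off <- floor((d - d0) / 2)
  pred <- pred[off[1] + seq_len(d0[1]), off[2] + seq_len(d0[2]),
               off[3] + seq_len(d0[3]), drop = FALSE]
  label_volume(pred, spacing, affine)
}

#' Voxel-wise confusion counts for one class
#'
#' @param prediction,truth [label_volume()]s or integer arrays on the
#'   same grid
#' @param class class code (1 = VB, 2 = VD, 3 = SC)
#' @return list with `TP`, `FP`, `FN` voxel counts
#' @export
confusion_counts <- function(prediction, truth, class) {
  p <- if (inherits(prediction, "spine_labels")) prediction$data else prediction
  t <- if (inherits(truth, "spine_labels")) truth$data else truth
  if (!all(dim(p) == dim(t))) stop("prediction and truth grids differ")
  list(TP = sum(p == class & t == class),
       FP = sum(p == class & t != class),
       FN = sum(p != class & t == class))
}

#' Precision, recall and Dice from confusion counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' dice = 2TP/(2TP+FP+FN).  When a class is absent from both prediction
#' and truth (TP = FP = FN = 0) all three metrics are defined as 1 and
#' the row is marked `present = FALSE` so it can be excluded from
#' averages.
#'
#' @param counts result of [confusion_counts()]
#' @return one-row data.frame with `precision`, `recall`, `dice`,
#'   `present`
#' @export
precision_recall_dice <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP + FN == 0) {
    return(data.frame(precision = 1, recall = 1, dice = 1, present = FALSE))
  }
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  dice <- 2 * TP / (2 * TP + FP + FN)
  data.frame(precision = precision, recall = recall, dice = dice,
             present = TRUE)
}

#' Evaluate a network on a test set
#'
#' Computes per-subject voxel-wise metrics for the three foreground
#' classes, their macro-average over subjects, and metrics from pooled
#' confusion counts.
#'
#' @param network a `spine_unet`
#' @param volumes list of test volumes (arrays or `spine_volume`s)
#' @param truths list of matching reference label volumes
#' @param ids subject identifiers
#' @param csv optional path for the per-subject metrics CSV
#' @param ... passed to [segment_volume()]
#' @return list with `per_subject`, `macro` and `pooled` data.frames
#' @export
evaluate_test_set <- function(network, volumes, truths, ids = NULL,
                              csv = NULL, ...) {
  if (length(volumes) == 0) stop("empty test set")
  stopifnot(length(volumes) == length(truths))
  if (is.null(ids)) ids <- sprintf("subj_%04d", seq_along(volumes))
  classes <- c(VB = CLASS_VB, VD = CLASS_VD, SC = CLASS_SC)

  rows <- list()
  pooled <- lapply(classes, function(cl) list(TP = 0, FP = 0, FN = 0))
  for (i in seq_along(volumes)) {
    pred <- segment_volume(network, volumes[[i]], ...)
    truth <- truths[[i]]
    for (cn in names(classes)) {
      cc <- confusion_counts(pred, truth, classes[[cn]])
      m <- precision_recall_dice(cc)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject_id = ids[i], class = cn), m)
      pooled[[cn]]$TP <- pooled[[cn]]$TP + cc$TP
      pooled[[cn]]$FP <- pooled[[cn]]$FP + cc$FP
      pooled[[cn]]$FN <- pooled[[cn]]$FN + cc$FN
    }
  }
  per_subject <- do.call(rbind, rows)

  macro <- do.call(rbind, lapply(names(classes), function(cn) {
    sub <- per_subject[per_subject$class == cn & per_subject$present, ]
    data.frame(class = cn, n_subjects = nrow(sub),
               precision = mean(sub$precision), recall = mean(sub$recall),
               dice = mean(sub$dice))
  }))
  pooled_df <- do.call(rbind, lapply(names(classes), function(cn) {
    cbind(data.frame(class = cn),
          precision_recall_dice(pooled[[cn]])[, 1:3])
  }))
  if (!is.null(csv)) utils::write.csv(per_subject, csv, row.names = FALSE)
  list(per_subject = per_subject, macro = macro, pooled = pooled_df)
}
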