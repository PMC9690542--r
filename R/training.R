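# Patch sampling, sagittal-plane augmentation, focal cross-entropy loss
# and the training loop.
#
# The network is trained as a voxel classifier on sub-volumes sampled
# uniformly from the training images.  All geometric augmentation acts in
# the sagittal (in-plane) axes only, applied identically to image (linear
# interpolation) and labels (nearest neighbour); photometric augmentation
# (contrast, blur) touches the image only.

#' Augmentation parameters
#'
#' All ranges must contain the identity (scale 1, rotation 0, contrast 1,
#' blur 0) so that augmentation never forces a transform.
#'
#' @param scale multiplicative in-plane scale range
#' @param rotation maximum in-plane rotation (degrees, symmetric)
#' @param flip_axes in-plane axes eligible for flipping: subset of
#'   `c("x", "y")`
#' @param flip_prob probability of flipping each eligible axis
#' @param contrast multiplicative intensity range
#' @param blur in-plane Gaussian blur sigma range (voxels); lower bound 0
#' @return an object of class `augmentation_params`
#' @export
augmentation_params <- function(scale = c(0.9, 1.1), rotation = 10,
                                flip_axes = "x", flip_prob = 0.5,
                                contrast = c(0.8, 1.25), blur = c(0, 1)) {
  if (scale[1] > 1 || scale[2] < 1) {
    stop("configuration error: scale range must contain 1")
  }
  if (rotation < 0) stop("configuration error: rotation range must contain 0")
  if (contrast[1] > 1 || contrast[2] < 1) {
    stop("configuration error: contrast range must contain 1")
  }
  if (blur[1] > 0) stop("configuration error: blur range must contain 0")
  stopifnot(all(flip_axes %in% c("x", "y")), flip_prob >= 0, flip_prob <= 1)
  structure(list(scale = scale, rotation = rotation, flip_axes = flip_axes,
                 flip_prob = flip_prob, contrast = contrast, blur = blur),
            class = "augmentation_params")
}

#' Identity augmentation (no-op)
#' @return `augmentation_params` that always reproduce the input
#' @export
no_augmentation <- function() {
  augmentation_params(scale = c(1, 1), rotation = 0, flip_axes = "x",
                      flip_prob = 0, contrast = c(1, 1), blur = c(0, 0))
}

#' Training hyper-parameters
#'
#' Defaults reproduce the reference schedule: 400x400x16 patches, 1024
#' samples per epoch for 400 epochs, ADAM with a decaying learning rate,
#' and cross-entropy with focal weighting (gamma = 1).
#'
#' @param patch_size patch extents (in-plane, in-plane, slices)
#' @param samples_per_epoch patches sampled per epoch
#' @param epochs number of epochs
#' @param lr_init,lr_final initial and final learning rate of the
#'   exponential decay schedule
#' @param lr_hold fraction of the epochs over which the rate is held at
#'   `lr_init` before the exponential decay begins (0 = decay from the
#'   start, the reference behaviour)
#' @param gamma focal-loss exponent (>= 0; 0 = plain cross-entropy)
#' @param augmentation an [augmentation_params()]
#' @param focus_sampling restrict patch offsets to those intersecting
#'   the foreground bounding box (see [sample_patch()]); uniform over
#'   the whole volume when `FALSE`
#' @param split dataset split sizes (train, validation, test); recorded
#'   for provenance, the loop itself takes explicit train/val sets
#' @param val_patches_per_epoch fixed validation patches evaluated after
#'   every epoch
#' @param seed integer seed controlling sampling, augmentation and the
#'   validation draw
#' @return an object of class `train_spec`
#' @export
train_spec <- function(patch_size = c(400, 400, 16),
                       samples_per_epoch = 1024, epochs = 400,
                       lr_init = 1e-3, lr_final = 1e-5, lr_hold = 0,
                       gamma = 1.0,
                       augmentation = augmentation_params(),
                       focus_sampling = TRUE,
                       split = c(train = 250, validation = 50, test = 30),
                       val_patches_per_epoch = 16, seed = 1L) {
  stopifnot(length(patch_size) == 3, all(patch_size >= 1),
            samples_per_epoch >= 1, epochs >= 1, gamma >= 0,
            lr_init > 0, lr_final > 0, lr_final <= lr_init,
            lr_hold >= 0, lr_hold < 1,
            inherits(augmentation, "augmentation_params"))
  structure(list(patch_size = as.integer(patch_size),
                 samples_per_epoch = as.integer(samples_per_epoch),
                 epochs = as.integer(epochs),
                 lr_init = lr_init, lr_final = lr_final, lr_hold = lr_hold,
                 gamma = gamma,
                 augmentation = augmentation,
                 focus_sampling = isTRUE(focus_sampling), split = split,
                 val_patches_per_epoch = as.integer(val_patches_per_epoch),
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Learning-rate schedule
#'
#' Exponential decay from `lr_init` to `lr_final` over the scheduled
#' epochs, optionally after an initial hold phase (`lr_hold` fraction of
#' the epochs at `lr_init`); non-increasing and positive throughout.
#'
#' @param epoch 0-based epoch index
#' @param spec a [train_spec()]
#' @return learning rate
#' @export
lr_schedule <- function(epoch, spec) {
  stopifnot(all(epoch >= 0))
  hold <- floor((spec$lr_hold %||% 0) * spec$epochs)
  span <- spec$epochs - 1 - hold
  if (span <= 0) return(rep(spec$lr_init, length(epoch)))
  e <- pmax(epoch - hold, 0)
  spec$lr_init * (spec$lr_final / spec$lr_init)^(e / span)
}

# Edge-replicate an array up to target dims (centred original content).
pad_edge <- function(arr, target) {
  d <- dim(arr)
  target <- pmax(d, target)
  if (all(d == target)) return(arr)
  idx <- lapply(1:3, function(a) {
    extra <- target[a] - d[a]
    lo <- floor(extra / 2)
    pmin(pmax(seq_len(target[a]) - lo, 1), d[a])
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Sample a training patch
#'
#' Cuts paired image/label patches at a uniformly drawn offset.  Volumes
#' thinner than the patch along the slice axis are first padded by edge
#' replication; volumes smaller than the patch in-plane are an error.
#' Uses the current R random-number stream.
#'
#' With `focus` (a 2 x 3 matrix of 1-based index bounds, typically the
#' bounding box of the foreground), the offset is drawn uniformly among
#' the offsets whose patch intersects that box.  This emulates the
#' patch-to-anatomy coverage of the source acquisition, where the patch
#' spans nearly the full image so every sample contains the spine; it
#' performs no per-class balancing within the admissible offsets.
#'
#' @param image 3D numeric array
#' @param labels 3D integer array of the same shape
#' @param patch_size patch extents
#' @param focus optional 2 x 3 index-bound matrix restricting offsets to
#'   patches that intersect it; `NULL` = uniform over the whole volume
#' @return list with `image`, `labels` (patch arrays) and `offset`
#'   (1-based corner index)
#' @export
sample_patch <- function(image, labels, patch_size, focus = NULL) {
  stopifnot(all(dim(image) == dim(labels)))
  patch_size <- as.integer(patch_size)
  if (any(dim(image)[1:2] < patch_size[1:2])) {
    stop("volume (", paste(dim(image), collapse = " x "),
         ") is smaller than the patch in-plane")
  }
  pad3 <- c(dim(image)[1:2], patch_size[3])
  image <- pad_edge(image, pad3)
  labels <- pad_edge(labels, pad3)
  d <- dim(image)
  off <- vapply(1:3, function(a) {
    lo <- 1L
    hi <- d[a] - patch_size[a] + 1L
    if (!is.null(focus)) {
      lo <- max(lo, as.integer(focus[1, a]) - patch_size[a] + 1L)
      hi <- min(hi, as.integer(focus[2, a]))
      if (hi < lo) { lo <- 1L; hi <- d[a] - patch_size[a] + 1L }
    }
    lo + sample.int(hi - lo + 1L, 1) - 1L
  }, integer(1))
  ix <- lapply(1:3, function(a) off[a]:(off[a] + patch_size[a] - 1L))
  list(image = image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       offset = off)
}

# 2 x 3 bounding box of foreground voxels (1-based), or NULL when empty.
foreground_bbox <- function(labels) {
  w <- which(labels > 0L)
  if (!length(w)) return(NULL)
  d <- dim(labels)
  i <- (w - 1) %% d[1] + 1
  j <- ((w - 1) %/% d[1]) %% d[2] + 1
  k <- (w - 1) %/% (d[1] * d[2]) + 1
  rbind(c(min(i), min(j), min(k)), c(max(i), max(j), max(k)))
}

#' Augment a paired patch
#'
#' Draws one transform from `params` using the current R random-number
#' stream and applies it: geometric action (scale, rotation, flips) is
#' identical for image and labels and confined to the in-plane axes;
#' contrast and blur touch the image only.  Label values stay in
#' 0..3 (nearest-neighbour resampling).
#'
#' @param image,labels paired 3D patch arrays
#' @param params an [augmentation_params()]
#' @return list with transformed `image` and `labels`
#' @export
augment_patch <- function(image, labels, params) {
  stopifnot(inherits(params, "augmentation_params"),
            all(dim(image) == dim(labels)))
  d <- dim(image)
  s <- stats::runif(1, params$scale[1], params$scale[2])
  th <- stats::runif(1, -params$rotation, params$rotation) * pi / 180
  fx <- "x" %in% params$flip_axes && stats::runif(1) < params$flip_prob
  fy <- "y" %in% params$flip_axes && stats::runif(1) < params$flip_prob
  cval <- stats::runif(1, params$contrast[1], params$contrast[2])
  bsig <- stats::runif(1, params$blur[1], params$blur[2])

  geometric <- s != 1 || th != 0 || fx || fy
  if (geometric) {
    # inverse map: source = A %*% (dest - centre) + centre
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)  # R(-th)
    Fm <- diag(c(if (fx) -1 else 1, if (fy) -1 else 1))
    A <- Fm %*% R / s
    sh <- c(0, 0)
    image <- array(cpp_resample_inplane(as.numeric(image), d, A, sh, FALSE), d)
    lab <- array(cpp_resample_inplane(as.numeric(labels), d, A, sh, TRUE), d)
    labels <- array(as.integer(round(lab)), d)
  }
  if (cval != 1) image <- image * cval
  if (bsig > 1e-8) {
    image <- array(cpp_blur_inplane(as.numeric(image), d, bsig), d)
  }
  list(image = image, labels = labels)
}

#' Focal cross-entropy loss
#'
#' `mean over voxels of (1 - p_true)^gamma * (-log p_true)`; `gamma = 0`
#' reduces exactly to cross-entropy.  Probabilities are floored at 1e-12
#' inside the logarithm, so the loss is always finite.
#'
#' @param probabilities 4D array (nx, ny, nz, C) of per-voxel class
#'   probabilities (each voxel sums to 1), or an (N x C) matrix
#' @param labels integer array/vector of true classes (0-based codes)
#' @param gamma focal exponent (>= 0)
#' @return scalar loss (>= 0)
#' @export
focal_cross_entropy <- function(probabilities, labels, gamma = 1.0) {
  stopifnot(gamma >= 0)
  if (is.array(probabilities) && length(dim(probabilities)) == 4) {
    C <- dim(probabilities)[4]
    probabilities <- matrix(probabilities, ncol = C)
  }
  lab <- as.integer(labels)
  stopifnot(length(lab) == nrow(probabilities),
            all(lab >= 0), all(lab < ncol(probabilities)))
  p <- probabilities[cbind(seq_along(lab), lab + 1L)]
  p <- pmax(p, 1e-12)
  mean((1 - p)^gamma * (-log(p)))
}

# Per-class Dice of an argmax prediction against labels (codes 1..3).
patch_dice <- function(pred, truth, classes = 1:3) {
  vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    den <- 2 * tp + sum(pred == cl & truth != cl) + sum(pred != cl & truth == cl)
    if (den == 0) NA_real_ else 2 * tp / den
  }, numeric(1))
}

#' Train the network
#'
#' Runs the ADAM-optimised patch training loop.  Per-epoch training loss,
#' validation loss and per-class validation Dice (on a fixed set of
#' validation patches) are recorded; the returned network carries the
#' weights with the best mean validation Dice.  Given the same seed and a
#' single-threaded BLAS the run is reproducible.
#'
#' @param network a [build_network()] result
#' @param train,validation lists of datasets, each element a list with 3D
#'   arrays `image` and `labels` (or the result of [generate_phantom()])
#' @param spec a [train_spec()]
#' @param verbose print per-epoch progress
#' @return list with `network` (best validation weights), `final_network`
#'   (last epoch), and `history` (data.frame: epoch, lr, train_loss,
#'   val_loss, val_dice_vb, val_dice_vd, val_dice_sc)
#' @export
train_network <- function(network, train, validation, spec,
                          verbose = FALSE) {
  stopifnot(inherits(network, "spine_unet"), inherits(spec, "train_spec"))
  if (length(train) == 0) stop("empty training split")
  if (length(validation) == 0) stop("empty validation split")
  train <- lapply(train, as_training_pair)
  validation <- lapply(validation, as_training_pair)
  check_patch_dims(network$spec, spec$patch_size)

  ns <- network$spec
  wts <- network$weights
  adam_m <- lapply(wts, function(w) w * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tstep <- 0

  set.seed(spec$seed)
  # fixed validation patches, drawn once; re-draw (up to a cap) until the
  # patch contains some foreground so that validation Dice is informative
  focus_of <- function(vol) if (spec$focus_sampling) vol$bbox else NULL
  val_set <- lapply(seq_len(spec$val_patches_per_epoch), function(i) {
    for (try in 1:20) {
      vol <- validation[[sample.int(length(validation), 1)]]
      pt <- sample_patch(vol$image, vol$labels, spec$patch_size,
                         focus = focus_of(vol))
      if (mean(pt$labels > 0) > 0.005) break
    }
    pt
  })

  history <- vector("list", spec$epochs)
  best <- list(dice = -Inf, loss = Inf, weights = wts, by_dice = FALSE)

  for (epoch in seq_len(spec$epochs) - 1L) {
    lr <- lr_schedule(epoch, spec)
    losses <- numeric(spec$samples_per_epoch)
    for (s in seq_len(spec$samples_per_epoch)) {
      vol <- train[[sample.int(length(train), 1)]]
      pt <- sample_patch(vol$image, vol$labels, spec$patch_size,
                         focus = focus_of(vol))
      pt <- augment_patch(pt$image, pt$labels, spec$augmentation)
      res <- cpp_unet_loss_grad(unname(wts), ns$features,
                                ns$enc_residual_blocks,
                                ns$dec_residual_blocks, ns$n_classes,
                                as.numeric(pt$image), spec$patch_size,
                                as.integer(pt$labels), spec$gamma)
      losses[s] <- res$loss
      g <- res$grads
      tstep <- tstep + 1
      c1 <- 1 / (1 - b1^tstep)
      c2 <- 1 / (1 - b2^tstep)
      for (i in seq_along(wts)) {
        adam_m[[i]] <- b1 * adam_m[[i]] + (1 - b1) * g[[i]]
        adam_v[[i]] <- b2 * adam_v[[i]] + (1 - b2) * g[[i]]^2
        wts[[i]] <- wts[[i]] -
          lr * (adam_m[[i]] * c1) / (sqrt(adam_v[[i]] * c2) + eps)
      }
    }
    # validation on the fixed patch set
    vloss <- numeric(length(val_set))
    vdice <- matrix(NA_real_, length(val_set), 3)
    for (i in seq_along(val_set)) {
      vp <- val_set[[i]]
      probs <- cpp_unet_forward(unname(wts), ns$features,
                                ns$enc_residual_blocks,
                                ns$dec_residual_blocks, ns$n_classes,
                                as.numeric(vp$image), spec$patch_size, TRUE)
      vloss[i] <- focal_cross_entropy(probs, vp$labels, spec$gamma)
      pred <- max.col(probs, ties.method = "first") - 1L
      vdice[i, ] <- patch_dice(pred, as.integer(vp$labels))
    }
    dice_cls <- colMeans(vdice, na.rm = TRUE)
    mean_dice <- mean(dice_cls, na.rm = TRUE)
    if (is.finite(mean_dice)) {
      if (!best$by_dice || mean_dice > best$dice) {
        best <- list(dice = mean_dice, loss = mean(vloss), weights = wts,
                     by_dice = TRUE)
      }
    } else if (!best$by_dice && mean(vloss) < best$loss) {
      # no foreground in any validation patch: fall back to validation loss
      best <- list(dice = -Inf, loss = mean(vloss), weights = wts,
                   by_dice = FALSE)
    }
    history[[epoch + 1]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_loss = mean(vloss), val_dice_vb = dice_cls[1],
      val_dice_vd = dice_cls[2], val_dice_sc = dice_cls[3])
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  train %.4f  val %.4f  dice %.3f/%.3f/%.3f",
        epoch, lr, mean(losses), mean(vloss), dice_cls[1], dice_cls[2],
        dice_cls[3]))
    }
  }
  hist_df <- do.call(rbind, history)
  net_best <- structure(list(spec = ns, weights = best$weights),
                        class = "spine_unet")
  net_final <- structure(list(spec = ns, weights = wts), class = "spine_unet")
  list(network = net_best, final_network = net_final, history = hist_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept generate_phantom() results, spine_volume/spine_labels pairs or
# plain arrays; images are z-scored per volume.
as_training_pair <- function(x) {
  img <- x$image
  lab <- x$labels
  if (inherits(img, "spine_volume")) img <- img$data
  if (inherits(lab, "spine_labels")) lab <- lab$data
  stopifnot(is.array(img), is.array(lab))
  list(image = normalize_intensities(img), labels = lab,
       bbox = foreground_bbox(lab))
}

#' Z-score intensity normalisation
#'
#' Volumes are normalised to zero mean and unit standard deviation
#' before entering the network, both during training and at inference;
#' the network therefore never sees raw scanner units.
#'
#' @param x numeric array
#' @return normalised array
#' @export
normalize_intensities <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}
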