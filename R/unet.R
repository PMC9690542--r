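# Depth-IV residual 3D U-Net with anisotropy-aware kernels.
#
# The acquisition this network targets has ~0.9 mm in-plane spacing and
# 3.0 mm slices, so convolutions at depth I use (3,3,3) kernels while all
# deeper stages convolve only in the sagittal plane with (1,3,3) kernels,
# and down/up-sampling acts on the two in-plane axes only.  No batch
# normalisation, no dropout.  Weight matrices are stored in the
# (K x Cout) layout consumed directly by the C++ GEMM engine, where
# K = Cin * prod(kernel).

#' Specify the segmentation network
#'
#' @param depth number of resolution levels (>= 2; default 4)
#' @param features feature maps per depth, strictly increasing
#' @param enc_residual_blocks residual blocks per encoder stage
#' @param dec_residual_blocks residual blocks per decoder stage
#' @param n_classes output channels; 4 = background + VB + VD + SC.
#'   Background is channel 1 and is excluded from reported metrics.
#' @param in_channels input channels (1 for T2 intensity)
#' @return an object of class `unet_spec`
#' @export
network_spec <- function(depth = 4, features = c(32, 64, 128, 256),
                         enc_residual_blocks = 2, dec_residual_blocks = 1,
                         n_classes = 4, in_channels = 1) {
  if (depth < 2) stop("configuration error in field 'depth': must be >= 2")
  if (length(features) != depth) {
    stop("configuration error in field 'features': need one count per depth")
  }
  if (any(diff(features) <= 0)) {
    stop("configuration error in field 'features': ",
         "must be strictly increasing with depth")
  }
  stopifnot(enc_residual_blocks >= 1, dec_residual_blocks >= 1,
            n_classes >= 2, in_channels >= 1)
  structure(list(depth = as.integer(depth),
                 features = as.integer(features),
                 enc_residual_blocks = as.integer(enc_residual_blocks),
                 dec_residual_blocks = as.integer(dec_residual_blocks),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "unet_spec")
}

kernel_at_depth <- function(d) if (d == 1) c(3L, 3L, 3L) else c(1L, 3L, 3L)

# Canonical weight order; must match the C++ traversal exactly.
weight_layout <- function(spec) {
  out <- list()
  D <- spec$depth
  f <- spec$features
  add <- function(name, cin, cout, kernel) {
    out[[length(out) + 1]] <<- list(name = name, cin = cin, cout = cout,
                                    kernel = kernel)
  }
  for (d in seq_len(D)) {
    k <- kernel_at_depth(d)
    cin <- if (d == 1) spec$in_channels else f[d - 1]
    add(sprintf("enc%d_lift", d), cin, f[d], k)
    for (b in seq_len(spec$enc_residual_blocks)) {
      add(sprintf("enc%d_block%d_conv1", d, b), f[d], f[d], k)
      add(sprintf("enc%d_block%d_conv2", d, b), f[d], f[d], k)
    }
  }
  for (d in rev(seq_len(D - 1))) {
    k <- kernel_at_depth(d)
    add(sprintf("dec%d_lift", d), f[d] + f[d + 1], f[d], k)
    for (b in seq_len(spec$dec_residual_blocks)) {
      add(sprintf("dec%d_block%d_conv1", d, b), f[d], f[d], k)
      add(sprintf("dec%d_block%d_conv2", d, b), f[d], f[d], k)
    }
  }
  add("final", f[1], spec$n_classes, c(1L, 1L, 1L))
  out
}

#' Build a network with freshly initialised weights
#'
#' Convolution weights use He initialisation (sd = sqrt(2 / fan-in)),
#' biases start at zero.  The second convolution of every residual block
#' is down-scaled at initialisation (factor 0.25) so the identity paths
#' dominate and activation variance stays bounded through the residual
#' stack, and the classification head starts small (factor 0.1) so the
#' initial probabilities are near-uniform rather than saturated — both
#' standard measures that keep the early optimisation out of softmax
#' saturation.
#'
#' @param spec a [network_spec()]
#' @param seed integer seed for the weight initialisation
#' @return an object of class `spine_unet`
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  layout <- weight_layout(spec)
  weights <- with_seed(as.integer(seed), {
    w <- list()
    for (ly in layout) {
      K <- ly$cin * prod(ly$kernel)
      scale <- if (grepl("_conv2$", ly$name)) 0.25
               else if (ly$name == "final") 0.1
               else 1
      w[[paste0(ly$name, "_W")]] <-
        matrix(stats::rnorm(K * ly$cout, 0, scale * sqrt(2 / K)), K, ly$cout)
      w[[paste0(ly$name, "_b")]] <- numeric(ly$cout)
    }
    w
  })
  structure(list(spec = spec, weights = weights), class = "spine_unet")
}

#' Number of trainable parameters
#' @param network a `spine_unet`
#' @return integer parameter count
#' @export
n_parameters <- function(network) {
  sum(vapply(network$weights, length, numeric(1)))
}

#' @export
print.spine_unet <- function(x, ...) {
  s <- x$spec
  cat("<spine_unet> depth ", s$depth, ", features ",
      paste(s$features, collapse = "/"), ", ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

check_patch_dims <- function(spec, dims) {
  m <- 2^(spec$depth - 1)
  if (dims[1] %% m != 0 || dims[2] %% m != 0) {
    stop("in-plane patch dimensions (", dims[1], " x ", dims[2],
         ") must be multiples of ", m,
         " (the total in-plane down-sampling factor)")
  }
}

#' Forward pass: per-voxel class probabilities
#'
#' @param network a `spine_unet`
#' @param patch 3D numeric array (in-plane, in-plane, slices); the two
#'   in-plane dimensions must be multiples of `2^(depth-1)`
#' @return 4D array (dim(patch), n_classes) of probabilities; every
#'   voxel's channel vector sums to 1
#' @export
forward <- function(network, patch) {
  stopifnot(inherits(network, "spine_unet"), is.array(patch),
            length(dim(patch)) == 3)
  dims <- dim(patch)
  check_patch_dims(network$spec, dims)
  probs <- cpp_unet_forward(unname(network$weights), network$spec$features,
                            network$spec$enc_residual_blocks,
                            network$spec$dec_residual_blocks,
                            network$spec$n_classes,
                            as.numeric(patch), as.integer(dims), TRUE)
  array(probs, c(dims, network$spec$n_classes))
}

#' Residual block
#'
#' `out = x + F(x)` where `F` is two convolutions, each followed by a
#' rectified-linear activation.  Input and output feature counts must be
#' equal.
#'
#' @param x 4D array (nx, ny, nz, C)
#' @param W1,b1,W2,b2 convolution weights, `(C*prod(kernel)) x C`
#'   matrices and length-C biases
#' @param kernel kernel extents (slice, in-plane, in-plane)
#' @return array of the same shape as `x`
#' @export
residual_block <- function(x, W1, b1, W2, b2, kernel = c(3, 3, 3)) {
  stopifnot(is.array(x), length(dim(x)) == 4)
  C <- dim(x)[4]
  if (ncol(W1) != C || ncol(W2) != C) {
    stop("residual block requires equal input and output feature counts")
  }
  dims <- dim(x)[1:3]
  xm <- matrix(x, ncol = C)
  t1 <- pmax(cpp_conv3d(xm, as.integer(dims), W1, b1, as.integer(kernel)), 0)
  t2 <- pmax(cpp_conv3d(t1, as.integer(dims), W2, b2, as.integer(kernel)), 0)
  array(xm + t2, dim(x))
}

#' Reference forward pass composed from layer primitives
#'
#' A slow, transparent re-composition of the network from the exported
#' layer primitives, used to cross-check the fused C++ forward pass.
#'
#' @inheritParams forward
#' @return 4D probability array as in [forward()]
#' @export
forward_reference <- function(network, patch) {
  spec <- network$spec
  w <- network$weights
  dims <- dim(patch)
  check_patch_dims(spec, dims)
  D <- spec$depth
  f <- spec$features
  dmat <- function(d) as.integer(c(dims[1] / 2^(d - 1), dims[2] / 2^(d - 1),
                                   dims[3]))
  conv_relu <- function(x, nm, d) {
    k <- kernel_at_depth(d)
    pmax(cpp_conv3d(x, dmat(d), w[[paste0(nm, "_W")]], w[[paste0(nm, "_b")]],
                    k), 0)
  }
  block <- function(x, nm, d) {
    t1 <- conv_relu(x, paste0(nm, "_conv1"), d)
    t2 <- conv_relu(t1, paste0(nm, "_conv2"), d)
    x + t2
  }
  enc <- vector("list", D)
  cur <- matrix(as.numeric(patch), ncol = 1)
  for (d in seq_len(D)) {
    if (d > 1) cur <- cpp_maxpool_inplane(cur, dmat(d - 1))
    cur <- conv_relu(cur, sprintf("enc%d_lift", d), d)
    for (b in seq_len(spec$enc_residual_blocks)) {
      cur <- block(cur, sprintf("enc%d_block%d", d, b), d)
    }
    enc[[d]] <- cur
  }
  dec <- enc[[D]]
  for (d in rev(seq_len(D - 1))) {
    up <- cpp_upsample_inplane(dec, dmat(d + 1))
    cur <- cbind(enc[[d]], up)
    cur <- conv_relu(cur, sprintf("dec%d_lift", d), d)
    for (b in seq_len(spec$dec_residual_blocks)) {
      cur <- block(cur, sprintf("dec%d_block%d", d, b), d)
    }
    dec <- cur
  }
  logits <- sweep(dec %*% w$final_W, 2, w$final_b, "+")
  e <- exp(logits - apply(logits, 1, max))
  array(e / rowSums(e), c(dims, spec$n_classes))
}

#' Save / load a network checkpoint
#'
#' One checkpoint file holds the weights together with the network
#' specification embedded as JSON metadata.
#'
#' @param network a `spine_unet`
#' @param path checkpoint path (`.rds`)
#' @return `path` invisibly; `load_network()` returns the `spine_unet`
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "spine_unet"))
  obj <- list(spec_json = jsonlite::toJSON(unclass(network$spec),
                                           auto_unbox = TRUE),
              weights = network$weights)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  sp <- jsonlite::fromJSON(obj$spec_json)
  spec <- network_spec(depth = sp$depth, features = sp$features,
                       enc_residual_blocks = sp$enc_residual_blocks,
                       dec_residual_blocks = sp$dec_residual_blocks,
                       n_classes = sp$n_classes, in_channels = sp$in_channels)
  structure(list(spec = spec, weights = obj$weights), class = "spine_unet")
}
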