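# Patch sampling, augmentation, focal loss, schedule and the training
# loop.

test_that("focal cross-entropy matches its closed forms", {
  # perfect prediction -> zero loss
  p <- matrix(0, 10, 4); p[cbind(1:10, c(1:4, 1:4, 1:2))] <- 1
  lab <- c(0:3, 0:3, 0:1)
  expect_equal(focal_cross_entropy(p, lab, gamma = 1), 0)
  # uniform 4-class probabilities at gamma = 1: 0.75 * ln 4 per voxel
  u <- matrix(0.25, 64, 4)
  expect_equal(focal_cross_entropy(u, sample(0:3, 64, TRUE), gamma = 1),
               0.75 * log(4), tolerance = 1e-12)
  # gamma = 0 reduces exactly to cross-entropy
  set.seed(1)
  z <- matrix(rexp(40), 10, 4); z <- z / rowSums(z)
  lab <- sample(0:3, 10, TRUE)
  ce <- mean(-log(z[cbind(1:10, lab + 1)]))
  expect_equal(focal_cross_entropy(z, lab, gamma = 0), ce, tolerance = 1e-15)
  # never infinite, even with a zero probability at the true class
  z0 <- matrix(c(0, 1, 0, 0), 1, 4)
  expect_true(is.finite(focal_cross_entropy(z0, 0L, gamma = 1)))
})

test_that("focal loss is non-increasing in gamma for imperfect predictions", {
  set.seed(2)
  z <- matrix(rexp(400), 100, 4); z <- z / rowSums(z)
  lab <- sample(0:3, 100, TRUE)
  gammas <- c(0, 0.5, 1, 2, 5)
  losses <- vapply(gammas, function(g) focal_cross_entropy(z, lab, g),
                   numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("the C++ training loss agrees with the R focal loss", {
  net <- tiny_network()
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  lab <- array(sample(0:3, 16 * 16 * 4, TRUE), c(16, 16, 4))
  ns <- net$spec
  for (g in c(0, 1)) {
    res <- spinemorph:::cpp_unet_loss_grad(
      unname(net$weights), ns$features, 2L, 1L, 4L, as.numeric(x), dim(x),
      as.integer(lab), g)
    expect_equal(res$loss, focal_cross_entropy(forward(net, x), lab, g),
                 tolerance = 1e-5)
  }
})

test_that("learning-rate schedule is positive, non-increasing, exponential", {
  sp <- train_spec(epochs = 400, lr_init = 1e-3, lr_final = 1e-5)
  rates <- lr_schedule(0:399, sp)
  expect_equal(rates[1], 1e-3)
  expect_equal(rates[400], 1e-5, tolerance = 1e-12)
  expect_true(all(diff(rates) < 0))
  f <- (1e-5 / 1e-3)^(1 / 399)
  expect_equal(rates, 1e-3 * f^(0:399), tolerance = 1e-12)
  # hold phase: flat at lr_init, then non-increasing decay to lr_final
  sph <- train_spec(epochs = 10, lr_init = 3e-3, lr_final = 1e-4,
                    lr_hold = 0.4)
  rh <- lr_schedule(0:9, sph)
  expect_true(all(rh[1:4] == 3e-3))
  expect_true(all(diff(rh) <= 0))
  expect_equal(rh[10], 1e-4, tolerance = 1e-12)
})

test_that("training defaults mirror the reference schedule", {
  sp <- train_spec()
  expect_equal(sp$patch_size, c(400L, 400L, 16L))
  expect_equal(sp$samples_per_epoch, 1024L)
  expect_equal(sp$epochs, 400L)
  expect_equal(sp$gamma, 1.0)
  expect_equal(unname(sp$split), c(250, 50, 30))
})

test_that("patch sampling covers the contract", {
  img <- array(rnorm(20 * 24 * 8), c(20, 24, 8))
  lab <- array(sample(0:3, 20 * 24 * 8, TRUE), c(20, 24, 8))
  # volume exactly patch-sized: only one patch possible
  set.seed(1)
  pt <- sample_patch(img, lab, c(20, 24, 8))
  expect_identical(pt$image, img)
  expect_identical(pt$labels, lab)
  # same seed, same offsets
  set.seed(42); a <- sample_patch(img, lab, c(8, 8, 4))
  set.seed(42); b <- sample_patch(img, lab, c(8, 8, 4))
  expect_identical(a, b)
  # thin volumes are padded along the slice axis by edge replication
  thin <- sample_patch(img[, , 1:2, drop = FALSE],
                       lab[, , 1:2, drop = FALSE], c(8, 8, 4))
  expect_equal(dim(thin$image), c(8, 8, 4))
  # in-plane undersized volumes are an error
  expect_error(sample_patch(img[1:4, , ], lab[1:4, , ], c(8, 8, 4)),
               "smaller than the patch in-plane")
})

test_that("augmentation ranges must contain the identity", {
  expect_error(augmentation_params(scale = c(1.05, 1.2)), "contain 1")
  expect_error(augmentation_params(contrast = c(1.1, 1.2)), "contain 1")
  expect_error(augmentation_params(blur = c(0.5, 1)), "contain 0")
  expect_error(augmentation_params(rotation = -3), "contain 0")
})

test_that("identity augmentation reproduces the input exactly", {
  img <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  lab <- array(sample(0:3, 16 * 16 * 4, TRUE), c(16, 16, 4))
  out <- augment_patch(img, lab, no_augmentation())
  expect_identical(out$image, img)
  expect_identical(out$labels, lab)
})

test_that("flips are involutions and labels stay categorical", {
  img <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  lab <- array(sample(0:3, 16 * 16 * 4, TRUE), c(16, 16, 4))
  flip_once <- function(im, lb) {
    A <- diag(c(-1, 1))
    d <- dim(im)
    list(image = array(spinemorph:::cpp_resample_inplane(
           as.numeric(im), d, A, c(0, 0), FALSE), d),
         labels = array(as.integer(spinemorph:::cpp_resample_inplane(
           as.numeric(lb), d, A, c(0, 0), TRUE)), d))
  }
  once <- flip_once(img, lab)
  expect_false(identical(once$image, img))
  twice <- flip_once(once$image, once$labels)
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_identical(twice$labels, lab)
  # a random augmentation keeps labels in 0..3
  set.seed(3)
  out <- augment_patch(img, lab, augmentation_params())
  expect_true(all(out$labels %in% 0:3))
  expect_equal(dim(out$image), dim(img))
})

test_that("a 90-degree rotation moves a label centroid as geometry says", {
  d <- c(21, 21, 2)
  lab <- array(0L, d)
  lab[15:17, 4:6, ] <- 1L  # off-centre blob
  ctr <- (d[1:2] - 1) / 2  # 0-based rotation centre
  # inverse map for a forward rotation by +90 degrees
  th <- pi / 2
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- array(as.integer(spinemorph:::cpp_resample_inplane(
    as.numeric(lab), d, A, c(0, 0), TRUE)), d)
  cent <- function(a) {
    w <- which(a[, , 1] == 1L, arr.ind = TRUE) - 1
    colMeans(w)
  }
  c0 <- cent(lab) - ctr
  c1 <- cent(rot) - ctr
  phi <- -th  # the inverse map A = R(th) rotates content by -th
  expected <- c(cos(phi) * c0[1] - sin(phi) * c0[2],
                sin(phi) * c0[1] + cos(phi) * c0[2])
  expect_lt(max(abs(c1 - expected)), 1)
})

test_that("augmentation cannot create or destroy classes wholesale", {
  ph <- generate_phantom(tiny_spec(grid = c(64, 64, 12), n_vb = 2))
  set.seed(5)
  pt <- sample_patch(ph$image$data, ph$labels$data, c(48, 48, 8))
  before <- tabulate(pt$labels + 1L, 4)
  out <- augment_patch(pt$image, pt$labels, augmentation_params())
  after <- tabulate(out$labels + 1L, 4)
  present_before <- before > 50
  expect_true(all(after[present_before] > 0))
})

test_that("training reduces the loss and is seed-reproducible", {
  set.seed(10)
  phantoms <- lapply(1:4, function(i)
    generate_phantom(do.call(phantom_spec, tiny_phantom_args(
      n_vertebral_bodies = 2, grid_shape = c(64, 64, 16), seed = i))))
  net <- tiny_network(depth = 2, features = c(4, 8), seed = 1)
  tsp <- train_spec(patch_size = c(32, 32, 8), samples_per_epoch = 10,
                    epochs = 3, lr_init = 1e-3, lr_final = 5e-4,
                    val_patches_per_epoch = 2, seed = 4)
  fit1 <- train_network(net, phantoms[1:3], phantoms[4], tsp)
  expect_lt(fit1$history$train_loss[3], fit1$history$train_loss[1])
  expect_equal(nrow(fit1$history), 3)
  fit2 <- train_network(net, phantoms[1:3], phantoms[4], tsp)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$network$weights, fit2$network$weights)
  expect_error(train_network(net, list(), phantoms[4], tsp), "empty")
})
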