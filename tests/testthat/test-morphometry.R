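# Morphometry engine: instances, volumetry, plane fitting, hull area.

test_that("convex hull area matches simple shapes and the O(n^3) oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull_area(sq), 1.0)
  col <- cbind(1:5, 2 * (1:5))
  expect_equal(convex_hull_area(col), 0.0)
  expect_equal(convex_hull_area(rbind(c(1, 2))), 0.0)
  expect_error(convex_hull_area(matrix(0, 0, 2)), "empty")
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:100, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    expect_equal(convex_hull_area(pts), hull_area_oracle(pts),
                 tolerance = 1e-9)
  }
})

test_that("disc volume is voxel count times voxel dimension", {
  expect_equal(disc_volume(100, c(0.9, 0.9, 3.0)), 243.0)
  expect_equal(disc_volume(1, c(1, 1, 1)), 1.0)
  expect_equal(disc_volume(list(voxels = 1:7), c(2, 1, 0.5)), 7.0)
  expect_error(disc_volume(0, c(1, 1, 1)), "empty")
})

test_that("PCA plane fitting recovers flat and rotated configurations", {
  set.seed(21)
  flat <- cbind(runif(60, -10, 10), runif(60, -6, 6), 5)
  pl <- fit_disc_plane(flat)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$centroid[3], 5)
  expect_equal(crossprod(cbind(pl$basis, pl$normal)), diag(3),
               tolerance = 1e-9, ignore_attr = TRUE)
  # rotate by a known rotation; the normal must follow
  th <- 0.43
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  pl2 <- fit_disc_plane(flat %*% t(R))
  target <- as.numeric(R %*% c(0, 0, 1))
  err <- min(sqrt(sum((pl2$normal - target)^2)),
             sqrt(sum((pl2$normal + target)^2)))
  expect_lt(err, 1e-6)
  # degenerate inputs
  expect_error(fit_disc_plane(flat[1:2, ]), class = "degenerate_disc")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_disc_plane(line), class = "degenerate_disc")
  # normal sign convention: toward superior (+y)
  tilted <- cbind(runif(50, -10, 10), 0.2 * runif(50, -1, 1),
                  runif(50, -8, 8))
  expect_gt(fit_disc_plane(tilted)$normal[2], 0)
})

test_that("instances are found, named cranio-caudally and flagged", {
  ph <- generate_phantom(tiny_spec(n_vb = 3), image = FALSE)
  li <- label_instances(ph$labels, expected_vb = 3)
  expect_length(li$flags, 0)
  vb <- Filter(function(i) i$structure == "VB", li$instances)
  vd <- Filter(function(i) i$structure == "VD", li$instances)
  sc <- Filter(function(i) i$structure == "SC", li$instances)
  expect_length(vb, 3); expect_length(vd, 4); expect_length(sc, 1)
  # names run cranial (superior, larger y) to caudal
  ys <- vapply(vb, function(i) i$centroid[2], numeric(1))
  expect_true(all(diff(ys) < 0))
  expect_equal(vapply(vb, `[[`, "", "segment"), c("VB01", "VB02", "VB03"))

  # merged vertebrae: bridge two VBs -> count mismatch flag
  lab2 <- ph$labels$data
  yr <- round(vapply(vb[1:2], function(i) i$centroid[2] / 0.9, numeric(1)))
  xr <- round(vb[[1]]$centroid[1] / 0.9)
  zr <- round(vb[[1]]$centroid[3] / 3) + 1
  lab2[xr + (0:1), (yr[2]:yr[1]) + 1, zr] <- 1L
  li2 <- suppressWarnings(
    label_instances(label_volume(lab2, ph$labels$spacing), expected_vb = 3))
  expect_true(any(grepl("VB_count_2_expected_3", li2$flags)))

  # empty class -> flag
  lab3 <- ph$labels$data
  lab3[lab3 == 2L] <- 0L
  li3 <- label_instances(label_volume(lab3, ph$labels$spacing),
                         expected_vb = 3)
  expect_true("no_VD_components" %in% li3$flags)
})

test_that("the full 23-vertebra spine is named anatomically", {
  ph <- generate_phantom(phantom_spec(seed = 6), image = FALSE)
  li <- label_instances(ph$labels)
  expect_length(li$flags, 0)
  vb <- Filter(function(i) i$structure == "VB", li$instances)
  vd <- Filter(function(i) i$structure == "VD", li$instances)
  expect_equal(vapply(vb, `[[`, "", "segment")[c(1, 6, 7, 19, 23)],
               c("C2", "C7", "T1", "L1", "L5"))
  expect_equal(vapply(vd, `[[`, "", "segment")[c(1, 24)],
               c("C1/C2", "L5/S1"))
})

test_that("measured morphometry matches the analytic phantom truth", {
  sp <- tiny_spec(n_vb = 3, seed = 8)
  ph <- generate_phantom(sp, image = FALSE)
  rec <- measure_subject(ph$labels, expected_vb = 3)
  expect_length(attr(rec, "flags"), 0)
  vd <- rec[rec$metric == "disc_volume", ]
  expect_equal(nrow(vd), 4)
  expect_true(all(abs(vd$value - ph$truth$disc_volume_mm3) /
                    ph$truth$disc_volume_mm3 < 0.05))
  sc <- rec[rec$metric == "canal_area", ]
  expect_equal(nrow(sc), 4)
  expect_true(all(abs(sc$value - ph$truth$canal_area_mm2) /
                    ph$truth$canal_area_mm2 < 0.10))
})

test_that("canal slab misses and degenerate discs become flags, not aborts", {
  ph <- generate_phantom(tiny_spec(n_vb = 3), image = FALSE)
  # plane far outside the canal -> empty slab
  pl <- structure(list(centroid = c(0, 1e5, 0),
                       basis = cbind(c(1, 0, 0), c(0, 0, 1)),
                       normal = c(0, 1, 0)), class = "disc_plane")
  res <- canal_area_at_disc(ph$labels, pl)
  expect_equal(res$area, 0)
  expect_equal(res$flag, "empty_slab")
  # a subject with one disc removed still yields a record
  lab <- ph$labels$data
  li <- label_instances(ph$labels, expected_vb = 3)
  vd1 <- Filter(function(i) i$structure == "VD", li$instances)[[1]]
  lab[vd1$voxels] <- 0L
  rec <- suppressWarnings(
    measure_subject(label_volume(lab, ph$labels$spacing), expected_vb = 3))
  expect_equal(sum(rec$metric == "disc_volume"), 3)
  expect_true(length(attr(rec, "flags")) > 0)
})

test_that("the subject 3D-model summary serialises instances to JSON", {
  ph <- generate_phantom(tiny_spec(n_vb = 3), image = FALSE)
  mod <- subject_model(ph$labels, expected_vb = 3, subject_id = "s1")
  expect_equal(mod$subject_id, "s1")
  expect_length(mod$instances, 3 + 4 + 1)
  discs <- Filter(function(i) i$structure == "VD", mod$instances)
  expect_true(all(vapply(discs, function(i)
    is.numeric(i$disc_volume) && i$disc_volume > 0, logical(1))))
  expect_true(all(vapply(discs, function(i)
    is.numeric(i$canal_area) && i$canal_area > 0, logical(1))))
  js <- jsonlite::toJSON(mod, auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})

test_that("morphometry is invariant under rigid motions of the volume", {
  sp <- tiny_spec(n_vb = 2, grid = c(64, 96, 16), seed = 12)
  ph <- generate_phantom(sp, image = FALSE)
  rec <- measure_subject(ph$labels, expected_vb = 2)
  # translation: shift the world origin via the affine
  aff <- ph$labels$affine
  aff[1:3, 4] <- c(17.3, -4.2, 8)
  rec_t <- measure_subject(label_volume(ph$labels$data, ph$labels$spacing,
                                        affine = aff), expected_vb = 2)
  expect_equal(rec_t$value, rec$value, tolerance = 1e-9)
  # axis-aligned 90-degree rotation: swap x and z axes losslessly
  rot <- aperm(ph$labels$data, c(3, 2, 1))
  rec_r <- measure_subject(label_volume(rot, rev(ph$labels$spacing)),
                           expected_vb = 2)
  expect_equal(rec_r$value[rec_r$metric == "disc_volume"],
               rec$value[rec$metric == "disc_volume"], tolerance = 1e-9)
  expect_equal(rec_r$value[rec_r$metric == "canal_area"],
               rec$value[rec$metric == "canal_area"], tolerance = 1e-9)
})
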