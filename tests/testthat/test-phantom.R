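# Spine phantom generator: geometry, determinism, analytic oracle.

test_that("phantom builds the expected structure counts and label values", {
  ph <- generate_phantom(tiny_spec(n_vb = 3), image = FALSE)
  lab <- ph$labels
  expect_s3_class(lab, "spine_labels")
  expect_true(all(lab$data %in% 0:3))
  d <- dim(lab$data)
  vb <- cpp_components <- spinemorph:::cpp_label_components(
    as.integer(lab$data), d, 1L, 26L)
  expect_equal(attr(vb, "n_components"), 3)
  vd <- spinemorph:::cpp_label_components(as.integer(lab$data), d, 2L, 26L)
  expect_equal(attr(vd, "n_components"), 4)  # always one disc more than VBs
  sc <- spinemorph:::cpp_label_components(as.integer(lab$data), d, 3L, 26L)
  expect_equal(attr(sc, "n_components"), 1)  # one continuous canal
})

test_that("noise sigma 0 gives exactly the class-mean intensities", {
  sp <- tiny_spec(noise_sigma = 0)
  ph <- generate_phantom(sp)
  means <- sp$intensity_means
  expect_identical(unname(ph$image$data[1, 1, 1]), means[1])
  expect_true(all(ph$image$data == means[ph$labels$data + 1L]))
  # nearest-class-mean classification reproduces the label map exactly
  recovered <- array(match(ph$image$data, means) - 1L, dim(ph$image$data))
  expect_equal(recovered, unname(ph$labels$data))
})

test_that("identical specs give bit-identical phantoms", {
  a <- generate_phantom(tiny_spec(seed = 9))
  b <- generate_phantom(tiny_spec(seed = 9))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
})

test_that("analytic morphometry matches the closed forms", {
  sp <- phantom_spec(n_vertebral_bodies = 2, vd_semiaxes = c(15, 4, 10),
                     vb_semiaxes = c(16, 8, 11), grid_shape = c(128, 128, 24),
                     age = 45, seed = 1)  # age 45: no disc-thickness scaling
  tr <- analytic_morphometry(sp)
  expect_equal(tr$disc_volume_mm3, rep(4 / 3 * pi * 600, 3), tolerance = 1e-12)
  # elliptical canal: pi * a * b
  expect_equal(tr$canal_area_mm2[1],
               pi * sp$canal_semi[1] * sp$canal_semi[2], tolerance = 1e-12)
  sp2 <- phantom_spec(n_vertebral_bodies = 2, canal_semiaxes = c(5, 6),
                      canal_shape = "rect", grid_shape = c(128, 128, 24),
                      seed = 1)
  expect_equal(analytic_morphometry(sp2)$canal_area_mm2[1], 120)
  sp3 <- phantom_spec(n_vertebral_bodies = 2, canal_semiaxes = c(8, 6),
                      grid_shape = c(128, 128, 24), seed = 1)
  expect_equal(analytic_morphometry(sp3)$canal_area_mm2[1], pi * 48,
               tolerance = 1e-12)
})

test_that("voxel-counted disc volume is within 5% and improves on refinement", {
  errs <- sapply(c(1, 2), function(f) {
    sp <- phantom_spec(n_vertebral_bodies = 3,
                       spacing = c(0.9, 0.9, 3.0) / f, seed = 4)
    ph <- generate_phantom(sp, image = FALSE)
    counts <- table(factor(ph$labels$data, levels = 0:3))
    # total disc voxel volume vs total analytic disc volume
    v <- counts[["2"]] * prod(sp$spacing)
    abs(v - sum(ph$truth$disc_volume_mm3)) / sum(ph$truth$disc_volume_mm3)
  })
  expect_lt(errs[1], 0.05)
  expect_lt(errs[2], errs[1])
})

test_that("structures that cannot fit the grid raise a named error", {
  expect_error(
    generate_phantom(phantom_spec(n_vertebral_bodies = 2,
                                  vb_semiaxes = c(100, 6, 8),
                                  grid_shape = c(64, 96, 24))),
    "exceeds the grid")
  expect_error(phantom_spec(n_vertebral_bodies = 23,
                            grid_shape = c(192, 192, 48)),
               "exceeds the grid")
})

test_that("cohorts are stratified over the 30 cells and reproducible", {
  specs <- generate_cohort(30, seed = 3, n_vertebral_bodies = 2)
  cov <- attr(specs, "covariates")
  cells <- assign_cohort(cov$age, cov$sex, cov$height_cm)
  tab <- table(interaction(cells$age_bin, cells$sex, cells$height_bin))
  expect_equal(length(specs), 30)
  expect_true(all(tab[tab > 0] == 1))
  expect_equal(sum(tab > 0), 30)

  specs330 <- generate_cohort(330, seed = 3, n_vertebral_bodies = 2)
  cov330 <- attr(specs330, "covariates")
  cells330 <- assign_cohort(cov330$age, cov330$sex, cov330$height_cm)
  t330 <- table(interaction(cells330$age_bin, cells330$sex,
                            cells330$height_bin))
  expect_true(all(t330[t330 > 0] == 11))

  again <- attr(generate_cohort(30, seed = 3, n_vertebral_bodies = 2),
                "covariates")
  expect_identical(cov, again)
  expect_error(generate_cohort(0), "at least 1")
})

test_that("covariates steer structure sizes the documented way", {
  tall <- phantom_spec(n_vertebral_bodies = 2, height_cm = 190, seed = 1)
  short <- phantom_spec(n_vertebral_bodies = 2, height_cm = 155, seed = 1)
  expect_true(all(tall$vb_semi > short$vb_semi))
  old <- phantom_spec(n_vertebral_bodies = 2, age = 70, seed = 1)
  young <- phantom_spec(n_vertebral_bodies = 2, age = 25, seed = 1)
  expect_true(all(old$vd_semi[, 2] < young$vd_semi[, 2]))
  # canal cross-section is intentionally not covariate-scaled
  expect_identical(tall$canal_semi, short$canal_semi)
})

test_that("cohort writing produces paired NIfTI volumes and tables", {
  dir <- withr::local_tempdir()
  specs <- do.call(generate_cohort, tiny_phantom_args(
    n = 2, seed = 5, n_vertebral_bodies = 2, grid_shape = c(64, 96, 16)))
  write_cohort(specs, dir)
  expect_true(file.exists(file.path(dir, "subj_0001_t2.nii.gz")))
  expect_true(file.exists(file.path(dir, "subj_0001_seg.nii.gz")))
  cov <- read.csv(file.path(dir, "covariates.csv"))
  expect_equal(nrow(cov), 2)
  truth <- read.csv(file.path(dir, "morphometry_truth.csv"))
  expect_true(all(c("disc_volume", "canal_area", "vb_volume") %in%
                    truth$metric))
  lab <- read_volume(file.path(dir, "subj_0001_seg.nii.gz"), labels = TRUE)
  expect_identical(lab$data,
                   generate_phantom(specs[[1]])$labels$data)
})
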