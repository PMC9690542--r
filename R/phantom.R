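# Parametric spine phantom with analytically known morphometry.
#
# The phantom emulates the geometry of a composed sagittal T2-weighted
# whole-spine acquisition: ~0.9 mm in-plane spacing, 3.0 mm slices, a
# column of vertebral bodies (ellipsoids) alternating with intervertebral
# discs (flat ellipsoids) along the superior-inferior axis, and a
# continuous spinal canal (elliptical tube) running posterior to them.
# A sagittal sinusoidal curvature bends the column in the
# anterior-posterior direction.  Because every structure is an analytic
# primitive, per-disc volumes and canal cross-section areas are known in
# closed form and serve as ground truth for the morphometry engine.
#
# Axis convention: x = anterior-posterior (in-plane), y =
# superior-inferior (in-plane, the spine axis), z = left-right (slice
# axis).  Discs are thin along y, so their smallest extent is sampled at
# the fine in-plane spacing, as in the real acquisition.

#' Specify a synthetic spine phantom
#'
#' Builds the complete parametric description of one phantom, including
#' per-structure effective sizes after the covariate model and
#' per-subject size jitter have been applied.  All downstream outputs
#' (label map, image, analytic morphometry) are deterministic functions
#' of this specification.
#'
#' The covariate model (used to give normative tables a recoverable
#' signal; magnitudes are configuration, not biology): vertebral-body
#' and disc sizes scale linearly with height (factor `height_cm / 170`),
#' male subjects are 4 percent larger, and disc thickness decreases by
#' `age_slope` (fraction per year) away from age 45.  The canal
#' cross-section is held fixed across subjects: canal dimensions
#' correlate only weakly with body size, and a fixed cross-section keeps
#' the analytic area oracle sharp.
#'
#' @param n_vertebral_bodies number of vertebral bodies (23 = C2..L5);
#'   the phantom always carries one disc more than vertebral bodies
#'   (C1/2 through L5/S1)
#' @param vb_semiaxes base VB ellipsoid semi-axes (mm) along (x, y, z);
#'   the defaults approximate a lumbar vertebral body (30 x 22 x 32 mm).
#'   All vertebrae share one size: cranio-caudal tapering of the real
#'   spine is not modelled.
#' @param vd_semiaxes base disc ellipsoid semi-axes (mm) along (x, y, z);
#'   defaults give a ~10 mm thick lumbar-like disc
#' @param canal_semiaxes canal tube cross-section semi-axes (mm) along
#'   (x, z)
#' @param canal_shape `"ellipse"` or `"rect"` cross-section
#' @param canal_gap clearance (mm) between the VB surface and the canal
#' @param disc_gap clearance (mm) between VB and disc surfaces along y
#' @param curvature_amplitude sagittal sinusoid amplitude (mm)
#' @param curvature_wavelength sagittal sinusoid wavelength (mm);
#'   `NULL` = one period over the spine length
#' @param intensity_means class intensity means (background, VB, VD, SC)
#'   in arbitrary units
#' @param noise_sigma additive Gaussian intensity noise (arbitrary units)
#' @param smooth_sigma in-plane Gaussian smoothing of the noise-free
#'   class-mean image (voxels), for partial-volume realism; 0 = off
#' @param spacing voxel spacing (mm) along (x, y, z)
#' @param grid_shape voxel counts (nx, ny, nz); `NULL` auto-fits the grid
#'   to the spine with a small margin
#' @param age,sex,height_cm subject covariates (years, `"F"`/`"M"`, cm)
#' @param size_jitter lognormal sd of the per-subject global size factor
#' @param disc_jitter lognormal sd of additional per-disc thickness
#'   variation
#' @param age_slope fractional disc-thickness change per year of age
#' @param seed integer seed; identical specs give bit-identical phantoms
#' @return an object of class `spine_phantom_spec`
#' @export
phantom_spec <- function(n_vertebral_bodies = 23,
                         vb_semiaxes = c(15, 11, 16),
                         vd_semiaxes = c(15, 5, 16),
                         canal_semiaxes = c(8.1, 15.2),
                         canal_shape = c("ellipse", "rect"),
                         canal_gap = 2,
                         disc_gap = 1.8,
                         curvature_amplitude = 6,
                         curvature_wavelength = NULL,
                         intensity_means = c(30, 100, 170, 240),
                         noise_sigma = 15,
                         smooth_sigma = 0,
                         spacing = c(0.9, 0.9, 3.0),
                         grid_shape = NULL,
                         age = 50, sex = "F", height_cm = 170,
                         size_jitter = 0, disc_jitter = 0,
                         age_slope = 0.004,
                         seed = 1L) {
  canal_shape <- match.arg(canal_shape)
  stopifnot(n_vertebral_bodies >= 1,
            length(vb_semiaxes) == 3, all(vb_semiaxes > 0),
            length(vd_semiaxes) == 3, all(vd_semiaxes > 0),
            length(canal_semiaxes) == 2, all(canal_semiaxes > 0),
            disc_gap > 0, canal_gap > 0,
            length(spacing) == 3, all(spacing > 0),
            length(intensity_means) == 4, noise_sigma >= 0,
            sex %in% c("F", "M"), age > 0, height_cm > 0)

  n_vb <- as.integer(n_vertebral_bodies)
  n_vd <- n_vb + 1L

  # covariate model
  hf <- height_cm / 170
  sf <- if (sex == "M") 1.04 else 1.0
  af <- max(0.5, 1 - age_slope * (age - 45))

  # jitter draws are winsorised at +/- 2 sd so that extreme draws cannot
  # push a phantom outside a fixed grid
  with_seed(as.integer(seed), {
    subj_factor <- exp(clamp(stats::rnorm(1, 0, size_jitter),
                             -2 * size_jitter, 2 * size_jitter))
    disc_factors <- exp(clamp(stats::rnorm(n_vd, 0, disc_jitter),
                              -2 * disc_jitter, 2 * disc_jitter))
  })

  g <- hf * sf * subj_factor
  vb_semi <- matrix(rep(vb_semiaxes * g, each = n_vb), nrow = n_vb)
  vd_semi <- matrix(rep(vd_semiaxes * g, each = n_vd), nrow = n_vd)
  vd_semi[, 2] <- vd_semi[, 2] * af * disc_factors
  # the canal cross-section is held fixed across subjects: spinal canal
  # dimensions correlate only weakly with body size, and a fixed
  # cross-section keeps the analytic area oracle sharp
  canal_semi <- canal_semiaxes

  # y layout from the top (superior): disc 1 (C1/2), VB 1 (C2), disc 2, ...
  y_margin <- 4
  centers_y <- numeric(n_vb + n_vd)  # interleaved: d1, v1, d2, v2, ..., d_{n+1}
  pos <- 0
  k <- 1
  for (i in seq_len(n_vb)) {
    if (i == 1) pos <- -vd_semi[1, 2]  # top disc centre below y_top
    centers_y[k] <- pos  # disc i
    pos <- pos - (vd_semi[i, 2] + disc_gap + vb_semi[i, 2])
    centers_y[k + 1] <- pos  # VB i
    pos <- pos - (vb_semi[i, 2] + disc_gap + vd_semi[i + 1, 2])
    k <- k + 2
  }
  centers_y[k] <- pos  # last disc
  spine_len <- -(pos - vd_semi[n_vd, 2]) + 2 * y_margin

  if (is.null(curvature_wavelength)) curvature_wavelength <- spine_len

  spec <- structure(list(
    n_vb = n_vb, n_vd = n_vd,
    vb_semi = vb_semi, vd_semi = vd_semi,
    canal_semi = canal_semi, canal_shape = canal_shape,
    canal_gap = canal_gap, disc_gap = disc_gap,
    curvature_amplitude = curvature_amplitude,
    curvature_wavelength = curvature_wavelength,
    intensity_means = as.numeric(intensity_means),
    noise_sigma = noise_sigma, smooth_sigma = smooth_sigma,
    spacing = as.numeric(spacing),
    grid_shape = grid_shape,
    age = age, sex = sex, height_cm = height_cm,
    seed = as.integer(seed),
    rel_centers_y = centers_y,  # relative to y_top, negative downwards
    spine_len = spine_len, y_margin = y_margin),
    class = "spine_phantom_spec")

  spec$grid_shape <- phantom_grid(spec)
  phantom_layout(spec)  # validates that everything fits
  spec
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

phantom_grid <- function(spec) {
  if (!is.null(spec$grid_shape)) return(as.integer(spec$grid_shape))
  sp <- spec$spacing
  A <- spec$curvature_amplitude
  span_left <- max(spec$vb_semi[, 1]) + A
  span_right <- canal_offset_x(spec) + spec$canal_semi[1] + A
  nx <- ceiling((span_left + span_right + 8) / sp[1])
  ny <- ceiling(spec$spine_len / sp[2])
  nz <- ceiling((2 * max(max(spec$vb_semi[, 3]), spec$canal_semi[2]) + 12) /
                  sp[3])
  as.integer(c(nx, ny, nz))
}

canal_offset_x <- function(spec) {
  max(spec$vb_semi[, 1]) + spec$canal_gap + spec$canal_semi[1]
}

# Absolute world-mm centres of all structures on the grid.
phantom_layout <- function(spec) {
  gs <- spec$grid_shape
  sp <- spec$spacing
  ext <- (gs - 1) * sp  # world extent of voxel centres
  A <- spec$curvature_amplitude
  span_left <- max(spec$vb_semi[, 1]) + A
  span_right <- canal_offset_x(spec) + spec$canal_semi[1] + A
  xc <- (ext[1] - (span_left + span_right)) / 2 + span_left
  if (xc - span_left < -1e-9 || xc + span_right > ext[1] + 1e-9) {
    stop("spine (x extent ", round(span_left + span_right, 1),
         " mm) exceeds the grid (", round(ext[1], 1), " mm): ",
         "widen grid_shape[1]")
  }
  y_top <- ext[2] - (ext[2] - (spec$spine_len - 2 * spec$y_margin)) / 2
  if (spec$spine_len - 2 * spec$y_margin > ext[2] + 1e-9) {
    stop("spine (y extent ", round(spec$spine_len, 1),
         " mm) exceeds the grid (", round(ext[2], 1), " mm): ",
         "widen grid_shape[2] or reduce n_vertebral_bodies")
  }
  # snap the common z centre to a voxel centre: the structure midplane then
  # coincides with a slice, which conditions voxel-based measurements well
  zc <- round(ext[3] / 2 / sp[3]) * sp[3]
  if (max(max(spec$vb_semi[, 3]), spec$canal_semi[2]) * 2 > ext[3] + 1e-9) {
    stop("structures exceed the grid along z: widen grid_shape[3]")
  }
  y_abs <- y_top + spec$rel_centers_y
  is_disc <- rep(c(TRUE, FALSE), length.out = 2 * spec$n_vb + 1)
  curve_x <- function(y) {
    xc + A * sin(2 * pi * (y_top - y) / spec$curvature_wavelength)
  }
  list(xc = xc, zc = zc, y_top = y_top, curve_x = curve_x,
       disc_y = y_abs[is_disc], vb_y = y_abs[!is_disc],
       canal_x = function(y) curve_x(y) + canal_offset_x(spec))
}

#' Closed-form morphometry of a phantom
#'
#' Computes the analytic ground truth implied by a phantom specification:
#' ellipsoid volumes 4/3*pi*a*b*c for discs and vertebral bodies, and the
#' canal tube cross-section area (pi*a*b for the elliptical tube,
#' width x height for the rectangular option) at every disc level.
#'
#' @param spec a [phantom_spec()]
#' @return a list with `disc_names`, `vb_names`, `disc_volume_mm3`,
#'   `vb_volume_mm3`, `canal_area_mm2` (one entry per disc level)
#' @export
analytic_morphometry <- function(spec) {
  stopifnot(inherits(spec, "spine_phantom_spec"))
  disc_vol <- 4 / 3 * pi * apply(spec$vd_semi, 1, prod)
  vb_vol <- 4 / 3 * pi * apply(spec$vb_semi, 1, prod)
  area <- if (spec$canal_shape == "ellipse") {
    pi * spec$canal_semi[1] * spec$canal_semi[2]
  } else {
    4 * spec$canal_semi[1] * spec$canal_semi[2]
  }
  list(disc_names = disc_names(spec$n_vb),
       vb_names = vb_names(spec$n_vb),
       disc_volume_mm3 = unname(disc_vol),
       vb_volume_mm3 = unname(vb_vol),
       canal_area_mm2 = rep(area, spec$n_vd))
}

#' Anatomical names for vertebral bodies and discs
#'
#' For the full 23-body spine (C2..L5) the standard anatomical names are
#' used; other counts get positional names.
#'
#' @param n_vb number of vertebral bodies
#' @return character vector of names, cranial to caudal
#' @export
vb_names <- function(n_vb) {
  if (n_vb == 23) {
    c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5))
  } else {
    sprintf("VB%02d", seq_len(n_vb))
  }
}

#' @rdname vb_names
#' @export
disc_names <- function(n_vb) {
  if (n_vb == 23) {
    vb <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5), "S1")
    paste0(vb[-length(vb)], "/", vb[-1])
  } else {
    sprintf("D%02d", seq_len(n_vb + 1))
  }
}

#' Generate a phantom volume, label map and ground truth
#'
#' Renders the phantom onto its voxel grid.  The label map assigns
#' 1 = VB, 2 = VD, 3 = SC (0 background) by testing voxel centres against
#' the analytic primitives; the image is the class-mean intensity plus
#' optional in-plane smoothing and Gaussian noise.  Identical specs give
#' bit-identical outputs.
#'
#' @param spec a [phantom_spec()]
#' @param image logical; render the intensity volume (set `FALSE` when
#'   only labels and ground truth are needed, e.g. for morphometry
#'   studies)
#' @return list with elements `image` ([image_volume()] or `NULL`),
#'   `labels` ([label_volume()]) and `truth` ([analytic_morphometry()])
#' @export
generate_phantom <- function(spec, image = TRUE) {
  stopifnot(inherits(spec, "spine_phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$spacing
  lay <- phantom_layout(spec)
  lab <- array(0L, dim = gs)

  xs <- (seq_len(gs[1]) - 1) * sp[1]
  ys <- (seq_len(gs[2]) - 1) * sp[2]
  zs <- (seq_len(gs[3]) - 1) * sp[3]

  fill_ellipsoid <- function(lab, center, semi, value, what) {
    lo <- center - semi
    hi <- center + semi
    if (any(lo < -sp / 2) || any(hi > (gs - 0.5) * sp)) {
      stop(what, " exceeds the grid")
    }
    ix <- which(xs >= lo[1] & xs <= hi[1])
    iy <- which(ys >= lo[2] & ys <= hi[2])
    iz <- which(zs >= lo[3] & zs <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) return(lab)
    dx2 <- ((xs[ix] - center[1]) / semi[1])^2
    dy2 <- ((ys[iy] - center[2]) / semi[2])^2
    dz2 <- ((zs[iz] - center[3]) / semi[3])^2
    m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    sub <- lab[ix, iy, iz, drop = FALSE]
    sub[m] <- value
    lab[ix, iy, iz] <- sub
    lab
  }

  for (i in seq_len(spec$n_vb)) {
    yc <- lay$vb_y[i]
    lab <- fill_ellipsoid(lab, c(lay$curve_x(yc), yc, lay$zc),
                          spec$vb_semi[i, ], CLASS_VB,
                          paste("vertebral body", i))
  }
  for (i in seq_len(spec$n_vd)) {
    yc <- lay$disc_y[i]
    lab <- fill_ellipsoid(lab, c(lay$curve_x(yc), yc, lay$zc),
                          spec$vd_semi[i, ], CLASS_VD,
                          paste("disc", i))
  }

  # canal tube: constant (x, z) cross-section extruded along y with the
  # same sagittal drift as the column, so a y = const cut has the exact
  # analytic area
  y_hi <- lay$disc_y[1] + spec$vd_semi[1, 2] + 2
  y_lo <- lay$disc_y[spec$n_vd] - spec$vd_semi[spec$n_vd, 2] - 2
  iy_canal <- which(ys >= max(y_lo, 0) & ys <= min(y_hi, max(ys)))
  rx <- spec$canal_semi[1]
  rz <- spec$canal_semi[2]
  iz_all <- seq_len(gs[3])
  for (iy in iy_canal) {
    cx <- lay$canal_x(ys[iy])
    if (cx + rx > max(xs) || cx - rx < 0) stop("spinal canal exceeds the grid")
    ix <- which(xs >= cx - rx & xs <= cx + rx)
    inside <- if (spec$canal_shape == "ellipse") {
      outer(((xs[ix] - cx) / rx)^2, ((zs - lay$zc) / rz)^2, "+") <= 1
    } else {
      outer(abs(xs[ix] - cx) <= rx, abs(zs - lay$zc) <= rz, "&")
    }
    sub <- lab[ix, iy, iz_all, drop = FALSE]
    if (any(sub[inside] != 0L)) {
      stop("spinal canal overlaps another structure; increase canal_gap")
    }
    sub[inside] <- CLASS_SC
    lab[ix, iy, ] <- sub
  }

  labels <- label_volume(lab, sp)
  img <- NULL
  if (image) {
    mean_img <- array(spec$intensity_means[lab + 1L], dim = gs)
    if (spec$smooth_sigma > 0) {
      mean_img <- array(cpp_blur_inplane(as.numeric(mean_img), gs,
                                         spec$smooth_sigma), dim = gs)
    }
    noise <- with_seed(spec$seed + 500000L,
                       stats::rnorm(length(mean_img), 0, spec$noise_sigma))
    img <- image_volume(mean_img + array(noise, dim = gs), sp)
  }
  list(image = img, labels = labels, truth = analytic_morphometry(spec))
}

#' Generate a stratified phantom cohort
#'
#' Draws `n` phantom specifications whose covariates cover the 30 cohort
#' cells (5 age bins x 2 sexes x 3 height bins) as uniformly as possible:
#' subjects are assigned to cells in round-robin order, so `n = 30` puts
#' exactly one subject in every cell and `n = 330` puts 11.  Covariates
#' are drawn uniformly within each cell; structure sizes then follow the
#' covariate model of [phantom_spec()], giving the normative module a
#' recoverable planted signal.
#'
#' @param n number of subjects (>= 1)
#' @param seed integer seed; the covariate list is reproducible
#' @param size_jitter,disc_jitter per-subject / per-disc size variation
#'   (lognormal sd) passed to [phantom_spec()]
#' @param ... further arguments passed to [phantom_spec()] (e.g.
#'   `n_vertebral_bodies`, `grid_shape`, `noise_sigma`)
#' @return list of `spine_phantom_spec`, with a `covariates` attribute
#'   (data.frame `subject_id`, `age`, `sex`, `height_cm`)
#' @export
generate_cohort <- function(n, seed = 1L, size_jitter = 0.05,
                            disc_jitter = 0.03, ...) {
  if (n < 1) stop("cohort size must be at least 1")
  cells <- expand.grid(age_bin = seq_len(5), sex = c("F", "M"),
                       height_bin = seq_len(3), stringsAsFactors = FALSE)
  age_lo <- c(20, 30.5, 40.5, 50.5, 60.5)
  age_hi <- c(30.5, 40.5, 50.5, 60.5, 72)
  h_lo <- c(150, 165, 175)
  h_hi <- c(165, 175, 195)

  cov <- with_seed(as.integer(seed), {
    idx <- ((seq_len(n) - 1) %% nrow(cells)) + 1
    ab <- cells$age_bin[idx]
    hb <- cells$height_bin[idx]
    # clamp rounded draws back into their half-open bin: age bins are
    # [lo, hi), height bins (lo, hi]
    age <- pmin(round(stats::runif(n, age_lo[ab], age_hi[ab]), 1),
                age_hi[ab] - 0.1)
    height <- pmax(round(stats::runif(n, h_lo[hb], h_hi[hb]), 1),
                   h_lo[hb] + 0.1)
    data.frame(
      subject_id = sprintf("subj_%04d", seq_len(n)),
      age = age,
      sex = cells$sex[idx],
      height_cm = height,
      seed = sample.int(.Machine$integer.max - 1L, n),
      stringsAsFactors = FALSE)
  })

  specs <- lapply(seq_len(n), function(i) {
    phantom_spec(age = cov$age[i], sex = cov$sex[i],
                 height_cm = cov$height_cm[i], seed = cov$seed[i],
                 size_jitter = size_jitter, disc_jitter = disc_jitter, ...)
  })
  names(specs) <- cov$subject_id
  attr(specs, "covariates") <- cov[, c("subject_id", "age", "sex",
                                       "height_cm")]
  specs
}

#' Write a phantom cohort to disk
#'
#' Writes paired NIfTI volumes (`<id>_t2.nii.gz`, `<id>_seg.nii.gz`), a
#' covariate table `covariates.csv` and the analytic ground-truth
#' morphometry `morphometry_truth.csv`.
#'
#' @param specs result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @param image write intensity volumes as well as label maps
#' @return `dir`, invisibly
#' @export
write_cohort <- function(specs, dir, image = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- attr(specs, "covariates")
  truth <- list()
  for (id in names(specs)) {
    ph <- generate_phantom(specs[[id]], image = image)
    if (image) write_volume(ph$image, file.path(dir, paste0(id, "_t2.nii.gz")))
    write_volume(ph$labels, file.path(dir, paste0(id, "_seg.nii.gz")))
    tr <- ph$truth
    truth[[id]] <- rbind(
      data.frame(subject_id = id, structure = "VD", segment = tr$disc_names,
                 metric = "disc_volume", value = tr$disc_volume_mm3,
                 units = "mm3"),
      data.frame(subject_id = id, structure = "SC", segment = tr$disc_names,
                 metric = "canal_area", value = tr$canal_area_mm2,
                 units = "mm2"),
      data.frame(subject_id = id, structure = "VB", segment = tr$vb_names,
                 metric = "vb_volume", value = tr$vb_volume_mm3,
                 units = "mm3"))
  }
  utils::write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth),
                   file.path(dir, "morphometry_truth.csv"), row.names = FALSE)
  invisible(dir)
}
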