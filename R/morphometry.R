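# Morphometry engine: instance labelling of spine structures, disc
# volumetry, PCA disc-plane fitting and convex-hull paraxial canal area.
#
# All world-coordinate computation is done at voxel centres in RAS+ mm
# via the volume affine.  Components use 26-connectivity by default:
# with anisotropic voxels (3 mm slices) 6-connectivity can fragment thin
# discs that touch only diagonally across slices.

#' Label anatomical instances in a segmentation
#'
#' Finds connected components per foreground class and names them
#' positionally from cranial (superior) to caudal: vertebral bodies C2
#' downwards, discs C1/2 downwards.  When the component count differs
#' from the expected count the record is flagged and naming falls back
#' to positional labels; a fragmented spinal canal is flagged as well.
#'
#' @param labels a [label_volume()]
#' @param expected_vb expected number of vertebral bodies (default 23,
#'   C2..L5; expected discs = `expected_vb + 1`)
#' @param connectivity 6 or 26 (default)
#' @return list with `instances` (list of per-instance lists: `structure`,
#'   `segment`, `voxels` (linear indices), `centroid` world mm) and
#'   `flags` (character vector)
#' @export
label_instances <- function(labels, expected_vb = 23, connectivity = 26) {
  stopifnot(inherits(labels, "spine_labels"))
  d <- dim(labels$data)
  flags <- character(0)
  instances <- list()

  comp_list <- function(cls) {
    comp <- cpp_label_components(as.integer(labels$data), as.integer(d),
                                 as.integer(cls), as.integer(connectivity))
    k <- attr(comp, "n_components")
    if (k == 0) return(list())
    lapply(seq_len(k), function(i) which(comp == i))
  }
  centroid_world <- function(vox) {
    idx0 <- cbind((vox - 1) %% d[1],
                  ((vox - 1) %/% d[1]) %% d[2],
                  (vox - 1) %/% (d[1] * d[2]))
    colMeans(voxel_to_world(idx0, labels$affine))
  }

  for (cls in c(CLASS_VB, CLASS_VD)) {
    comps <- comp_list(cls)
    sname <- class_name(cls)
    expected <- if (cls == CLASS_VB) expected_vb else expected_vb + 1
    if (length(comps) == 0) {
      flags <- c(flags, paste0("no_", sname, "_components"))
      next
    }
    if (length(comps) != expected) {
      flags <- c(flags, sprintf("%s_count_%d_expected_%d", sname,
                                length(comps), expected))
      warning(sname, ": found ", length(comps), " components, expected ",
              expected, "; naming positionally", call. = FALSE)
    }
    cents <- lapply(comps, centroid_world)
    ord <- order(vapply(cents, `[`, numeric(1), 2), decreasing = TRUE)
    nm <- if (length(comps) == expected) {
      if (cls == CLASS_VB) vb_names(expected_vb) else disc_names(expected_vb)
    } else {
      sprintf("%s%02d", sname, seq_along(comps))  # positional fallback
    }
    for (j in seq_along(ord)) {
      i <- ord[j]
      instances[[length(instances) + 1]] <- list(
        structure = sname, segment = nm[j], voxels = comps[[i]],
        centroid = cents[[i]])
    }
  }

  sc <- comp_list(CLASS_SC)
  if (length(sc) == 0) {
    flags <- c(flags, "no_SC_components")
  } else {
    if (length(sc) > 1) {
      flags <- c(flags, sprintf("SC_fragmented_%d", length(sc)))
      warning("spinal canal fragmented into ", length(sc), " components",
              call. = FALSE)
    }
    # keep the largest component as the canal
    main <- which.max(lengths(sc))
    instances[[length(instances) + 1]] <- list(
      structure = "SC", segment = "SC", voxels = sc[[main]],
      centroid = centroid_world(sc[[main]]))
  }
  list(instances = instances, flags = flags)
}

#' Disc (or any instance) volume from voxel count
#'
#' volume = number of voxels x voxel dimension (product of spacings).
#'
#' @param instance an instance from [label_instances()], or a voxel count
#' @param spacing voxel spacing (mm)
#' @return volume in mm^3
#' @export
disc_volume <- function(instance, spacing) {
  n <- if (is.list(instance)) length(instance$voxels) else instance
  if (n == 0) stop("empty voxel set")
  n * prod(spacing)
}

#' Fit a disc plane by principal component analysis
#'
#' The plane through the disc centroid spanned by the two
#' largest-variance principal axes of the voxel world coordinates; the
#' third eigenvector is the plane normal, oriented toward superior
#' (+y in RAS+).
#'
#' @param coords n x 3 matrix of world coordinates (mm)
#' @return a `disc_plane`: list with `centroid`, `basis` (3 x 2), and
#'   `normal` (unit length)
#' @export
fit_disc_plane <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) {
    stop(degenerate_disc_error("fewer than 3 points"))
  }
  ctr <- colMeans(coords)
  cv <- stats::cov(coords)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-9 * max(eg$values[1], 1e-30)) {
    stop(degenerate_disc_error("points are collinear (rank < 2)"))
  }
  basis <- eg$vectors[, 1:2, drop = FALSE]
  normal <- eg$vectors[, 3]
  if (normal[2] < 0) normal <- -normal
  structure(list(centroid = ctr, basis = basis, normal = normal),
            class = "disc_plane")
}

degenerate_disc_error <- function(msg) {
  structure(class = c("degenerate_disc", "error", "condition"),
            list(message = paste0("degenerate disc: ", msg), call = NULL))
}

#' Paraxial spinal canal area at a disc plane
#'
#' Extracts the spinal-canal voxels whose world coordinates lie within
#' `half_thickness` of the disc plane, projects them onto the plane
#' basis and returns the area of the minimal convex hull around the
#' projected 2D point set.
#'
#' @param labels a [label_volume()]
#' @param plane a [fit_disc_plane()] result
#' @param half_thickness slab half-thickness in mm (default 1.5 = half
#'   the 3.0 mm slice thickness)
#' @param sc_coords optional pre-computed n x 3 world coordinates of all
#'   canal voxels (avoids re-extraction per disc level)
#' @param search_offsets offsets (mm) along the plane normal; the
#'   returned area is the minimum over the parallel planes at these
#'   offsets.  The default `0` measures in the single PCA plane.
#' @return list with `area` (mm^2) and `flag` (`NA`, `"empty_slab"` or
#'   `"degenerate_projection"`)
#' @export
canal_area_at_disc <- function(labels, plane, half_thickness = 1.5,
                               sc_coords = NULL, search_offsets = 0) {
  stopifnot(inherits(plane, "disc_plane"), half_thickness > 0,
            length(search_offsets) >= 1)
  if (is.null(sc_coords)) {
    sc_coords <- instance_world_coords(labels, CLASS_SC)
  }
  if (nrow(sc_coords) == 0) {
    return(list(area = 0, flag = "empty_slab"))
  }
  rel <- sweep(sc_coords, 2, plane$centroid)
  dist <- as.numeric(rel %*% plane$normal)
  one_plane <- function(off) {
    sel <- abs(dist - off) <= half_thickness
    if (!any(sel)) {
      return(list(area = 0, flag = "empty_slab"))
    }
    pts2d <- rel[sel, , drop = FALSE] %*% plane$basis
    area <- convex_hull_area(pts2d)
    list(area = area,
         flag = if (area == 0) "degenerate_projection" else NA_character_)
  }
  results <- lapply(search_offsets, one_plane)
  areas <- vapply(results, `[[`, numeric(1), "area")
  if (all(areas == 0)) return(results[[1]])
  # minimum over the planes that actually intersect the canal
  results[[which(areas == min(areas[areas > 0]))[1]]]
}

# World coordinates of all voxels of one class.
instance_world_coords <- function(labels, cls) {
  d <- dim(labels$data)
  vox <- which(labels$data == cls)
  idx0 <- cbind((vox - 1) %% d[1],
                ((vox - 1) %/% d[1]) %% d[2],
                (vox - 1) %/% (d[1] * d[2]))
  voxel_to_world(idx0, labels$affine)
}

#' Area of the minimal convex hull of a 2D point set
#'
#' Shoelace area over the convex hull vertices; single, double and
#' collinear point sets have area 0.
#'
#' @param points n x 2 matrix
#' @return area (same squared units as the input)
#' @export
convex_hull_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  if (nrow(points) < 3) return(0)
  h <- grDevices::chull(points[, 1], points[, 2])
  if (length(h) < 3) return(0)
  x <- points[h, 1]; y <- points[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Per-subject 3D model summary
#'
#' A serialisable summary of the labelled anatomy: one entry per
#' instance with its anatomical name, voxel count, centroid (world mm)
#' and measurements (disc volume / canal area where applicable).  Write
#' it with `jsonlite::write_json(model, path, auto_unbox = TRUE)`.
#'
#' @inheritParams measure_subject
#' @return a list with elements `subject_id`, `flags` and `instances`
#' @export
subject_model <- function(labels, expected_vb = 23, half_thickness = 1.5,
                          subject_id = "subject") {
  inst <- withCallingHandlers(
    label_instances(labels, expected_vb = expected_vb),
    warning = function(w) invokeRestart("muffleWarning"))
  rec <- measure_subject(labels, expected_vb = expected_vb,
                         half_thickness = half_thickness,
                         subject_id = subject_id)
  instances <- lapply(inst$instances, function(it) {
    out <- list(structure = it$structure, segment = it$segment,
                n_voxels = length(it$voxels),
                centroid_mm = round(unname(it$centroid), 3))
    sub <- rec[rec$segment == it$segment &
                 (rec$structure == it$structure |
                    (it$structure == "VD" & rec$structure == "SC")), ]
    for (i in seq_len(nrow(sub))) {
      out[[sub$metric[i]]] <- sub$value[i]
    }
    out
  })
  list(subject_id = subject_id, flags = as.list(inst$flags),
       instances = instances)
}

#' Measure one subject
#'
#' Extracts the full morphometry record from a label volume: one volume
#' per named disc and one paraxial canal area per disc level.  Instance
#' errors become flags; the subject is never aborted.
#'
#' @param labels a [label_volume()]
#' @param expected_vb expected vertebral body count (see
#'   [label_instances()])
#' @param half_thickness canal slab half-thickness (mm)
#' @param subject_id identifier recorded in the output
#' @return data.frame with columns `subject_id`, `structure`, `segment`,
#'   `metric`, `value`, `units`, `flags`; subject-level flags in
#'   attribute `"flags"`
#' @export
measure_subject <- function(labels, expected_vb = 23, half_thickness = 1.5,
                            subject_id = "subject") {
  inst <- withCallingHandlers(
    label_instances(labels, expected_vb = expected_vb),
    warning = function(w) invokeRestart("muffleWarning"))
  spacing <- labels$spacing
  sc_coords <- instance_world_coords(labels, CLASS_SC)
  rows <- list()

  d <- dim(labels$data)
  for (it in inst$instances) {
    if (it$structure == "VB") {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, structure = "VB", segment = it$segment,
        metric = "vb_volume", value = disc_volume(it, spacing),
        units = "mm3", flags = "")
    } else if (it$structure == "VD") {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, structure = "VD", segment = it$segment,
        metric = "disc_volume", value = disc_volume(it, spacing),
        units = "mm3", flags = "")
      # canal area at this disc level
      idx0 <- cbind((it$voxels - 1) %% d[1],
                    ((it$voxels - 1) %/% d[1]) %% d[2],
                    (it$voxels - 1) %/% (d[1] * d[2]))
      coords <- voxel_to_world(idx0, labels$affine)
      res <- tryCatch({
        plane <- fit_disc_plane(coords)
        canal_area_at_disc(labels, plane, half_thickness,
                           sc_coords = sc_coords)
      }, degenerate_disc = function(e) list(area = 0,
                                            flag = "degenerate_disc"))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, structure = "SC", segment = it$segment,
        metric = "canal_area", value = res$area, units = "mm2",
        flags = if (is.na(res$flag)) "" else res$flag)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "flags") <- inst$flags
  out
}
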