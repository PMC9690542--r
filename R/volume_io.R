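# Volume containers, NIfTI-1 input/output and dataset quality control.
#
# Conventions: voxel indices are 0-based in world-coordinate computations;
# the affine maps homogeneous 0-based voxel indices to RAS+ world
# coordinates in mm; voxel centres sit at integer indices.  Axes x and y
# are the in-plane (sagittal) axes at ~0.9 mm, z is the slice axis at
# ~3.0 mm.

#' Create an image volume
#'
#' A light container for a 3D scalar intensity grid together with its
#' voxel spacing (mm) and voxel-to-world affine.
#'
#' @param data 3D numeric array of intensities (all finite)
#' @param spacing numeric length-3 voxel spacing in mm, strictly positive
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, RAS+ mm);
#'   defaults to `diag(c(spacing, 1))`
#' @param slice_positions optional numeric vector of slice positions (mm)
#'   along the slice normal, one per slice; used by [qc_check()] to detect
#'   missing slices when the acquisition geometry is known independently
#'   of the NIfTI header.  `NULL` means positions follow the affine.
#' @return an object of class `spine_volume`
#' @export
image_volume <- function(data, spacing, affine = NULL,
                         slice_positions = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) {
    stop("image intensities must all be finite")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be three strictly positive values (mm)")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("affine must be invertible")
  }
  if (!is.null(slice_positions)) {
    stopifnot(length(slice_positions) == dim(data)[3])
  }
  structure(list(data = data, spacing = spacing, affine = affine,
                 slice_positions = slice_positions),
            class = "spine_volume")
}

#' Create a label volume
#'
#' Integer grid on the same lattice as its paired image; 0 = background,
#' 1 = vertebral body (VB), 2 = intervertebral disc (VD), 3 = spinal
#' canal (SC).
#'
#' @inheritParams image_volume
#' @param data 3D integer array with values in 0..3
#' @return an object of class `spine_labels`
#' @export
label_volume <- function(data, spacing, affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  if (!all(data %in% 0:3)) {
    stop("label values must lie in {0, 1, 2, 3}")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("voxel spacing must be three strictly positive values (mm)")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = spacing, affine = as.matrix(affine)),
            class = "spine_labels")
}

#' @export
print.spine_volume <- function(x, ...) {
  cat("<spine_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.spine_labels <- function(x, ...) {
  counts <- tabulate(x$data + 1L, nbins = 4)
  cat("<spine_labels> ", paste(dim(x$data), collapse = " x "),
      " voxels; VB/VD/SC voxels: ", paste(counts[2:4], collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Reads an image (or label map) from a `.nii`/`.nii.gz` file, taking the
#' spacing and voxel-to-world affine from the header.  A sidecar file
#' `<stem>_slices.txt` (one slice position in mm per line), when present,
#' supplies acquisition slice positions for quality control.
#'
#' @param path file path
#' @param labels logical; read as a label volume
#' @return a [image_volume()] or [label_volume()]
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) {
    stop(unreadable_error(path, "file does not exist"))
  }
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
                    stop(unreadable_error(path, conditionMessage(e)))
                  })
  arr <- as.array(img)
  if (length(dim(arr)) != 3) {
    stop(unreadable_error(path, "not a 3D volume"))
  }
  arr <- array(as.vector(arr), dim = dim(arr))  # drop NIfTI header attrs
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0)) {
    stop("non-positive voxel spacing in NIfTI header of ", path)
  }
  aff <- unclass(RNifti::xform(img))
  sidecar <- slice_sidecar_path(path)
  slices <- if (file.exists(sidecar)) scan(sidecar, quiet = TRUE) else NULL
  if (labels) {
    lv <- label_volume(arr, pd, aff)
    lv
  } else {
    image_volume(arr, pd, aff, slice_positions = slices)
  }
}

unreadable_error <- function(path, msg) {
  structure(class = c("spinemorph_unreadable", "error", "condition"),
            list(message = paste0("unreadable volume '", path, "': ", msg),
                 call = NULL, path = path))
}

slice_sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, "_slices.txt")
}

#' Write a volume to NIfTI-1
#'
#' Images are stored as 32-bit float, label maps as unsigned 8-bit.
#'
#' @param vol a `spine_volume` or `spine_labels`
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  is_labels <- inherits(vol, "spine_labels")
  stopifnot(is_labels || inherits(vol, "spine_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  # sform only: the qform quaternion cannot represent sheared axes exactly
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (is_labels) "uint8" else "float")
  if (!is.null(vol$slice_positions)) {
    writeLines(format(vol$slice_positions, digits = 12),
               slice_sidecar_path(path))
  }
  invisible(path)
}

#' Quality-control check for a volume
#'
#' Applies the dataset rejection rules used before large-scale analysis:
#' a volume is rejected when its axes are not mutually orthogonal
#' (`non_orthogonal_axes`) or when the inter-slice distances are not
#' uniform, indicating missing slices (`missing_slices`).  Unreadable
#' files are reported by [qc_check_file()] with reason `unreadable`.
#'
#' @param vol a `spine_volume`
#' @param cos_tol maximum |cosine| allowed between distinct direction
#'   columns of the affine (default 1e-3)
#' @param slice_tol maximum relative deviation of any inter-slice gap from
#'   the nominal spacing (default 0.01, i.e. 1 percent)
#' @return a `qc_report`: list with elements `accepted` (logical) and
#'   `reasons` (character vector, empty iff accepted)
#' @export
qc_check <- function(vol, cos_tol = 1e-3, slice_tol = 0.01) {
  stopifnot(inherits(vol, "spine_volume"))
  reasons <- character(0)
  dirs <- vol$affine[1:3, 1:3]
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  cosines <- abs(crossprod(dirs))
  diag(cosines) <- 0
  if (max(cosines) > cos_tol) {
    reasons <- c(reasons, "non_orthogonal_axes")
  }
  pos <- vol$slice_positions
  if (is.null(pos)) {
    # affine implies uniform slice positions; derive them for completeness
    nz <- dim(vol$data)[3]
    pos <- (seq_len(nz) - 1) * sqrt(sum(vol$affine[1:3, 3]^2))
  }
  if (length(pos) >= 2) {
    gaps <- diff(sort(pos))
    nominal <- stats::median(gaps)
    if (any(abs(gaps - nominal) > slice_tol * nominal)) {
      reasons <- c(reasons, "missing_slices")
    }
  }
  structure(list(accepted = length(reasons) == 0, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  if (x$accepted) cat("QC: accepted\n")
  else cat("QC: rejected (", paste(x$reasons, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Quality-control check for a file on disk
#'
#' @param path NIfTI file path
#' @inheritParams qc_check
#' @return a `qc_report`; unreadable files yield reason `unreadable`
#' @export
qc_check_file <- function(path, cos_tol = 1e-3, slice_tol = 0.01) {
  vol <- tryCatch(read_volume(path), error = function(e) e)
  if (inherits(vol, "condition")) {
    return(structure(list(accepted = FALSE, reasons = "unreadable"),
                     class = "qc_report"))
  }
  qc_check(vol, cos_tol = cos_tol, slice_tol = slice_tol)
}

#' Batch quality control
#'
#' @param paths character vector of NIfTI paths
#' @param ids subject identifiers (defaults to file stems)
#' @param csv optional path to write the report as CSV
#' @inheritParams qc_check
#' @return data.frame with columns `subject_id`, `accepted`, `reasons`
#' @export
qc_batch <- function(paths, ids = NULL, csv = NULL,
                     cos_tol = 1e-3, slice_tol = 0.01) {
  if (is.null(ids)) ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  reports <- lapply(paths, qc_check_file, cos_tol = cos_tol,
                    slice_tol = slice_tol)
  out <- data.frame(
    subject_id = ids,
    accepted = vapply(reports, function(r) r$accepted, logical(1)),
    reasons = vapply(reports, function(r) paste(r$reasons, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

# World coordinates (mm) of voxels given 0-based index matrix (n x 3)
voxel_to_world <- function(idx, affine) {
  idx <- cbind(idx, 1)
  t(affine %*% t(idx))[, 1:3, drop = FALSE]
}
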