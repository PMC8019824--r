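#' Binary voxel volume
#'
#' A `binary_volume` is a 3D boolean lattice with millimetre voxel spacing.
#' Black (`TRUE`) voxels carry the object — a fiber-bundle mask or a
#' skeleton; everything outside the array bounds is implicitly white.
#' Voxel indices are 0-based throughout the package and the world
#' coordinate of a voxel is its centre, `index * spacing_mm`.
#'
#' @param occupancy logical 3D array (or coercible numeric array of 0/1).
#' @param spacing_mm numeric length-3 positive voxel spacing in mm.
#' @return An object of class `binary_volume` with elements `occupancy`
#'   (logical array), `shape` and `spacing_mm`.
#' @export
binary_volume <- function(occupancy, spacing_mm = c(1, 1, 1)) {
  if (length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3D array")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be positive")
  occ <- array(as.logical(occupancy), dim = dim(occupancy))
  if (anyNA(occ)) stop("occupancy contains NA")
  structure(
    list(occupancy = occ, shape = dim(occ), spacing_mm = spacing_mm),
    class = "binary_volume"
  )
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf(
    "<binary_volume %s, spacing %s mm, %d black voxels>\n",
    paste(x$shape, collapse = "x"),
    paste(signif(x$spacing_mm, 4), collapse = "x"),
    sum(x$occupancy)
  ))
  invisible(x)
}

n_black <- function(vol) sum(vol$occupancy)

#' Black voxel indices of a volume
#'
#' @param vol a [binary_volume()].
#' @return integer matrix with one 0-based `(i, j, k)` row per black voxel.
#' @export
black_points <- function(vol) {
  which(vol$occupancy, arr.ind = TRUE) - 1L
}

#' World coordinates of voxel indices
#'
#' @param vol a [binary_volume()] (or anything with a `spacing_mm` field).
#' @param idx integer matrix of 0-based voxel index triples.
#' @return numeric matrix of voxel-centre positions in mm.
#' @export
voxel_centers <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx, 2, vol$spacing_mm, `*`)
}

#' Intersect subject bundle masks
#'
#' Computes the multi-subject overlap bundle: a voxel is black in the
#' result if and only if it is black in every subject's mask. All masks
#' must share the same grid.
#'
#' @param masks list of [binary_volume()] objects on one grid.
#' @return A [binary_volume()] of the voxelwise intersection.
#' @export
intersect_subject_masks <- function(masks) {
  if (length(masks) == 0L) stop("no subjects")
  ref <- masks[[1L]]
  acc <- ref$occupancy
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!identical(m$shape, ref$shape))
      stop(sprintf("mask %d has shape %s, expected %s", i,
                   paste(m$shape, collapse = "x"),
                   paste(ref$shape, collapse = "x")))
    if (max(abs(m$spacing_mm - ref$spacing_mm)) > 1e-9)
      stop(sprintf("mask %d has mismatching spacing", i))
    if (i > 1L) acc <- acc & m$occupancy
  }
  binary_volume(acc, ref$spacing_mm)
}

#' Lattice adjacency sets
#'
#' Returns the `j`-adjacent neighbours of a lattice point on the infinite
#' lattice: the 6 face neighbours, the 18 face+edge neighbours, or the full
#' 26-neighbourhood. The caller clips to volume bounds where needed.
#'
#' @param p integer length-3 voxel index (0-based).
#' @param j adjacency order, one of 6, 18 or 26.
#' @return integer matrix of neighbour index triples, one per row.
#' @export
adjacency <- function(p, j = 26) {
  if (!j %in% c(6L, 18L, 26L)) stop("j must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(off))
  keep <- switch(as.character(j),
    "6"  = l1 == 1,
    "18" = l1 >= 1 & l1 <= 2,
    "26" = l1 >= 1
  )
  out <- sweep(off[keep, , drop = FALSE], 2, as.integer(p), `+`)
  dimnames(out) <- NULL
  out
}

#' Simple-point test
#'
#' A black point is *simple* when deleting it preserves local topology:
#' the black points of its 26-neighbourhood form exactly one 26-connected
#' component, and the white points of its 18-neighbourhood form exactly one
#' 6-connected component that is 6-adjacent to the point.
#'
#' @param vol a [binary_volume()].
#' @param p 0-based voxel index triple; must be black.
#' @return logical.
#' @export
is_simple_point <- function(vol, p) {
  p <- as.integer(p)
  if (any(p < 0L) || any(p >= vol$shape))
    stop("point outside volume bounds")
  if (!vol$occupancy[p[1] + 1L, p[2] + 1L, p[3] + 1L])
    stop("point is white")
  cpp_is_simple(as.logical(vol$occupancy), as.integer(vol$shape),
                p[1], p[2], p[3])
}

#' Curve thinning to a one-voxel-wide skeleton
#'
#' Six-subiteration sequential directional thinning with curve-endpoint
#' preservation. The fixed subiteration order is U, D, N, S, E, W
#' (+z, -z, +y, -y, +x, -x): in each subiteration, black points whose
#' neighbour in that direction is white, that are simple points and that
#' are not curve endpoints (a black point with exactly one black
#' 26-neighbour) are deleted sequentially. The six subiterations are
#' repeated until a full cycle deletes nothing. Deleting only simple
#' points guarantees that the number of 26-connected components never
#' changes.
#'
#' @param vol a [binary_volume()] with at least one black point.
#' @return The skeleton as a [binary_volume()].
#' @export
curve_thin <- function(vol) {
  if (n_black(vol) == 0L) stop("empty volume")
  out <- cpp_curve_thin(as.logical(vol$occupancy), as.integer(vol$shape))
  binary_volume(array(out, dim = vol$shape), vol$spacing_mm)
}

#' Label connected components
#'
#' @param vol a [binary_volume()].
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = white).
#' @export
label_components <- function(vol, connectivity = 26) {
  if (!connectivity %in% c(6L, 18L, 26L)) stop("invalid connectivity")
  lab <- cpp_label_components(as.logical(vol$occupancy),
                              as.integer(vol$shape), as.integer(connectivity))
  array(lab, dim = vol$shape)
}

#' @rdname label_components
#' @export
n_components <- function(vol, connectivity = 26) {
  max(label_components(vol, connectivity), 0L)
}

#' Keep the largest 26-connected component
#'
#' Used after mask intersection to drop stray outlier fragments before
#' skeletonization. Ties are broken by the smallest component label, which
#' is itself deterministic (first voxel in column-major order).
#'
#' @param vol a [binary_volume()].
#' @return A [binary_volume()] retaining only the largest component.
#' @export
largest_component <- function(vol) {
  lab <- label_components(vol, 26)
  if (max(lab) == 0L) return(vol)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  binary_volume(lab == keep, vol$spacing_mm)
}

# 26-neighbour counts for every black voxel (0 elsewhere)
neighbor_counts <- function(vol) {
  array(cpp_neighbor_counts(as.logical(vol$occupancy),
                            as.integer(vol$shape)),
        dim = vol$shape)
}

#' Read and write binary masks as NIfTI-1
#'
#' Masks are stored as uint8 0/1 volumes; the voxel spacing is carried in
#' the NIfTI pixdim field.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [binary_volume()].
#' @return `read_mask_nifti` returns a [binary_volume()];
#'   `write_mask_nifti` returns `path` invisibly.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  binary_volume(array(as.logical(img != 0), dim = dim(img)),
                RNifti::pixdim(img)[1:3])
}

#' @rdname read_mask_nifti
#' @export
write_mask_nifti <- function(vol, path) {
  arr <- array(as.integer(vol$occupancy), dim = vol$shape)
  img <- RNifti::asNifti(
    arr,
    reference = list(pixdim = c(-1, vol$spacing_mm, 1, 1, 1, 1)),
    datatype = "uint8"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write integer label volumes as NIfTI-1
#'
#' @param path file path.
#' @param labels integer 3D array of region labels (0 = background).
#' @param spacing_mm voxel spacing.
#' @return `read_labels_nifti` returns a list with `labels` and
#'   `spacing_mm`; `write_labels_nifti` returns `path` invisibly.
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(labels = array(as.integer(img), dim = dim(img)),
       spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname read_labels_nifti
#' @export
write_labels_nifti <- function(labels, spacing_mm, path) {
  img <- RNifti::asNifti(
    array(as.integer(labels), dim = dim(labels)),
    reference = list(pixdim = c(-1, rep_len(spacing_mm, 3), 1, 1, 1, 1)),
    datatype = "int16"
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}
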