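#' Specify a synthetic fiber bundle
#'
#' A tube of given radius around a parametric centerline (straight
#' segment, circular arc, or helix), voxelised on an isotropic grid. The
#' default spacing of 2.2 mm matches a typical clinical DTI acquisition.
#' The grid is sized automatically so the tube keeps at least a
#' two-voxel margin to every face.
#'
#' @param kind `"straight"`, `"arc"` or `"helix"`.
#' @param length_mm centerline arc length (mm).
#' @param radius_mm tube radius (mm).
#' @param spacing_mm isotropic voxel spacing (mm, default 2.2).
#' @param arc_radius_mm circle radius for `kind = "arc"`.
#' @param helix_radius_mm,helix_pitch_mm helix geometry for
#'   `kind = "helix"`.
#' @return A `bundle_spec` with the centerline function, grid shape and
#'   spacing.
#' @export
bundle_spec <- function(kind = c("straight", "arc", "helix"),
                        length_mm = 40, radius_mm = 5, spacing_mm = 2.2,
                        arc_radius_mm = length_mm, helix_radius_mm = 8,
                        helix_pitch_mm = 30) {
  kind <- match.arg(kind)
  curve <- switch(kind,
    straight = function(t) {
      cbind(t * length_mm, 0 * t, 0 * t)
    },
    arc = function(t) {
      phi <- t * length_mm / arc_radius_mm
      cbind(arc_radius_mm * sin(phi), arc_radius_mm * (1 - cos(phi)), 0 * t)
    },
    helix = {
      circ <- sqrt((2 * pi * helix_radius_mm)^2 + helix_pitch_mm^2)
      function(t) {
        phi <- 2 * pi * t * length_mm / circ
        cbind(helix_radius_mm * cos(phi), helix_radius_mm * sin(phi),
              helix_pitch_mm * phi / (2 * pi))
      }
    })
  tg <- seq(0, 1, length.out = 257L)
  pts <- curve(tg)
  margin <- radius_mm + 2 * spacing_mm
  lo <- apply(pts, 2, min) - margin
  # align the grid so the centerline start sits at a 0.35-voxel offset
  # from the nearest voxel centers; this keeps the partial-volume
  # rasterization of the tube close to volume-unbiased (a grid running
  # exactly through or exactly between voxel centers maximises the
  # discretization bias of the circular cross-section)
  frac <- ((pts[1, ] - lo) / spacing_mm) %% 1
  lo <- lo + (frac - 0.35) * spacing_mm
  hi <- apply(pts, 2, max) + margin
  shape <- as.integer(ceiling((hi - lo) / spacing_mm)) + 1L
  offset <- lo
  structure(list(kind = kind, length_mm = length_mm, radius_mm = radius_mm,
                 spacing_mm = rep_len(spacing_mm, 3), curve = curve,
                 offset = offset, shape = shape),
            class = "bundle_spec")
}

# centerline samples in grid world coordinates, with tangents and arc length
centerline_samples <- function(spec, n = 257L) {
  tg <- seq(0, 1, length.out = n)
  pts <- sweep(spec$curve(tg), 2, spec$offset, `-`)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  tan <- rbind(pts[2, ] - pts[1, ], pts[-1, ] - pts[-n, ])
  tan <- tan / sqrt(rowSums(tan^2))
  list(points = pts, tangents = tan, s = s)
}

# minimum distance from each row of `ctr` to the sampled centerline
dist_to_centerline <- function(ctr, cl_points) {
  dmin <- rep(Inf, nrow(ctr))
  for (r in seq_len(nrow(cl_points))) {
    d2 <- (ctr[, 1] - cl_points[r, 1])^2 + (ctr[, 2] - cl_points[r, 2])^2 +
      (ctr[, 3] - cl_points[r, 3])^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Voxelise a bundle specification into a binary mask
#'
#' Partial-volume rasterization: a voxel is black when at least half of
#' its volume (estimated on a 5x5x5 subgrid) lies within the tube
#' radius of the centerline; voxels whose centre is more than half a
#' voxel diagonal away from the boundary are decided directly from the
#' centre distance. Optional per-subject boundary jitter perturbs
#' boundary sites (mask voxels with a white 6-neighbour may be eroded,
#' white voxels 6-adjacent to the mask may be dilated) with total
#' probability `jitter_prob` per site, split evenly between the two
#' operations — this emulates inter-subject bundle variation.
#'
#' @param spec a [bundle_spec()].
#' @param jitter_prob boundary perturbation probability (0 disables).
#' @param seed integer seed for the jitter.
#' @return A [binary_volume()].
#' @export
make_bundle_mask <- function(spec, jitter_prob = 0, seed = NULL) {
  cl <- centerline_samples(spec)
  if (any(cl$points < spec$radius_mm) ||
      any(sweep(cl$points, 2, (spec$shape - 1) * spec$spacing_mm) >
            -spec$radius_mm))
    stop("tube exits the grid")
  cl_pts <- centerline_samples(spec, n = 129L)$points
  grid <- as.matrix(expand.grid(i = 0:(spec$shape[1] - 1),
                                j = 0:(spec$shape[2] - 1),
                                k = 0:(spec$shape[3] - 1)))
  ctr <- sweep(grid, 2, spec$spacing_mm, `*`)
  dmin <- dist_to_centerline(ctr, cl_pts)
  half_diag <- sqrt(3) / 2 * max(spec$spacing_mm)
  inside <- dmin <= spec$radius_mm - half_diag
  shell <- which(!inside & dmin <= spec$radius_mm + half_diag)
  if (length(shell)) {
    nsub <- 4L
    off1 <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
    sub <- as.matrix(expand.grid(dx = off1 * spec$spacing_mm[1],
                                 dy = off1 * spec$spacing_mm[2],
                                 dz = off1 * spec$spacing_mm[3]))
    pts <- ctr[rep(shell, each = nrow(sub)), , drop = FALSE] +
      sub[rep(seq_len(nrow(sub)), length(shell)), , drop = FALSE]
    hit <- dist_to_centerline(pts, cl_pts) <= spec$radius_mm
    frac <- colMeans(matrix(hit, nrow = nrow(sub)))
    inside[shell[frac >= 0.5]] <- TRUE
  }
  occ <- array(inside, dim = spec$shape)
  vol <- binary_volume(occ, spec$spacing_mm)
  if (jitter_prob > 0) vol <- jitter_boundary(vol, jitter_prob, seed)
  vol
}

# flip boundary voxels with the given probability (erode black boundary,
# dilate white voxels 6-adjacent to black)
jitter_boundary <- function(vol, prob, seed = NULL) {
  occ <- vol$occupancy
  sh <- vol$shape
  shift <- function(a, d, axis) {
    out <- array(FALSE, dim = dim(a))
    idx <- lapply(dim(a), seq_len)
    src <- idx
    src[[axis]] <- idx[[axis]] - d
    keep <- src[[axis]] >= 1 & src[[axis]] <= dim(a)[axis]
    dst <- idx
    dst[[axis]] <- idx[[axis]][keep]
    src[[axis]] <- src[[axis]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  has_white_nb <- array(FALSE, dim = sh)
  has_black_nb <- array(FALSE, dim = sh)
  for (axis in 1:3) for (d in c(-1L, 1L)) {
    nb <- shift(occ, d, axis)
    edge <- shift(array(TRUE, dim = sh), d, axis)
    has_white_nb <- has_white_nb | (!nb & edge) | !edge
    has_black_nb <- has_black_nb | nb
  }
  erode_cand <- occ & has_white_nb
  dilate_cand <- (!occ) & has_black_nb
  # each candidate site is perturbed with total probability `prob`,
  # split evenly between erosion and dilation
  with_seed(seed, {
    u <- array(runif(length(occ)), dim = sh)
    occ[erode_cand & u < prob / 2] <- FALSE
    occ[dilate_cand & u < prob / 2] <- TRUE
  })
  binary_volume(occ, vol$spacing_mm)
}

#' Simulate a per-voxel PDD field over a bundle mask
#'
#' At each black voxel an axis is drawn from a Bingham distribution whose
#' mean axis is the local centerline tangent (nearest centerline point)
#' and whose concentrations are given in the `(0, k2, k3)` gauge. An
#' optional group-difference effect rotates the local mean axis by a
#' fixed angle about the first centerline normal for voxels whose
#' nearest-centerline arc length falls inside the effect window.
#'
#' @param mask a [binary_volume()] bundle mask.
#' @param spec the [bundle_spec()] the mask was built from.
#' @param kappas Bingham concentrations `c(0, k2, k3)`, `0 >= k2 >= k3`.
#' @param seed integer seed.
#' @param effect optional [group_effect()] applied to this subject.
#' @return A `pdd_field`: list with `axis` (n_black x 3 unit rows,
#'   aligned with `black_points(mask)` order), `valid` (logical array)
#'   and `spacing_mm`.
#' @export
make_pdd_field <- function(mask, spec, kappas = c(0, -5, -40), seed = NULL,
                           effect = NULL) {
  if (kappas[1] != 0 || kappas[2] < kappas[3] || kappas[2] > 0)
    stop("kappas must satisfy 0 = k1 >= k2 >= k3")
  pts <- black_points(mask)
  ctr <- voxel_centers(mask, pts)
  cl <- centerline_samples(spec)
  nearest <- integer(nrow(ctr))
  d2min <- rep(Inf, nrow(ctr))
  for (r in seq_len(nrow(cl$points))) {
    d2 <- (ctr[, 1] - cl$points[r, 1])^2 + (ctr[, 2] - cl$points[r, 2])^2 +
      (ctr[, 3] - cl$points[r, 3])^2
    upd <- d2 < d2min
    nearest[upd] <- r
    d2min[upd] <- d2[upd]
  }
  axes <- with_seed(seed, {
    y <- sample_bingham_canonical(nrow(pts), kappas)
    out <- matrix(NA_real_, nrow(pts), 3)
    for (r in seq_len(nrow(pts))) {
      tangent <- cl$tangents[nearest[r], ]
      if (!is.null(effect)) {
        s_here <- cl$s[nearest[r]]
        if (s_here >= effect$slice_range[1] && s_here <= effect$slice_range[2]) {
          B <- orthonormal_complement(tangent)
          tangent <- as.numeric(
            rotation_about(B[, 1], effect$rotation_deg * pi / 180) %*% tangent)
        }
      }
      U <- cbind(tangent, orthonormal_complement(tangent))
      out[r, ] <- U %*% y[r, ]
    }
    out
  })
  structure(list(axis = canonical_signs(axes), voxels = pts,
                 valid = mask$occupancy, spacing_mm = mask$spacing_mm),
            class = "pdd_field")
}

# axes of a pdd_field at the given 0-based voxel rows (matrix); NA rows
# for voxels without a valid axis
pdd_axes_at <- function(field, vox) {
  if (nrow(vox) == 0L)
    return(matrix(numeric(0), 0, 3))
  key <- paste(field$voxels[, 1], field$voxels[, 2], field$voxels[, 3])
  hit <- match(paste(vox[, 1], vox[, 2], vox[, 3]), key)
  field$axis[hit[!is.na(hit)], , drop = FALSE]
}

#' Group-difference effect for synthetic cohorts
#'
#' Describes a rigid rotation of the local mean PDD axis applied to one
#' group over a window of centerline arc length — the synthetic analogue
#' of a mean-direction difference between patient and control groups.
#'
#' @param rotation_deg rotation angle (degrees, >= 0).
#' @param slice_range length-2 arc-length window (mm) over which the
#'   rotation applies.
#' @param applies_to group label receiving the effect (default "B").
#' @return A `group_effect` list.
#' @export
group_effect <- function(rotation_deg, slice_range, applies_to = "B") {
  if (rotation_deg < 0) stop("rotation_deg must be >= 0")
  slice_range <- as.numeric(slice_range)
  if (length(slice_range) != 2L || slice_range[1] > slice_range[2])
    stop("slice_range must be an increasing length-2 window")
  structure(list(rotation_deg = rotation_deg, slice_range = slice_range,
                 applies_to = applies_to),
            class = "group_effect")
}

#' Simulate a two-group cohort with known ground truth
#'
#' Generates per-subject jittered bundle masks and Bingham-dispersed PDD
#' fields on a common grid, places two terminal region-of-interest label
#' blobs at the tube ends, and (optionally) applies a [group_effect()]
#' to one group. The returned ground truth records which 2-mm profile
#' slices overlap the effect window, for scoring detection experiments.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param spec a [bundle_spec()].
#' @param kappas Bingham concentrations of the PDD dispersion.
#' @param effect a [group_effect()] or `NULL`.
#' @param seed integer seed; the whole cohort is a pure function of
#'   `(spec, kappas, effect, seed)`.
#' @param jitter_prob per-subject boundary jitter probability.
#' @param slice_spacing_mm slice spacing used to express the truth in
#'   slice indices (default 2).
#' @return A `cohort` (see [cohort_spec()]) with an extra `truth` field:
#'   list with `effect`, `affected_s_mm` and `affected_slices`
#'   (0-based slice indices at `slice_spacing_mm`).
#' @export
make_cohort <- function(n_per_group = 8, spec = bundle_spec(),
                        kappas = c(0, -5, -40), effect = NULL, seed = 1,
                        jitter_prob = 0.1, slice_spacing_mm = 2) {
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  groups <- rep(c("A", "B"), each = n_per_group)
  ids <- sprintf("s%02d", seq_along(groups))
  masks <- vector("list", length(ids))
  fields <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub_seed <- if (is.null(seed)) NULL else (seed * 1000L + i) %% .Machine$integer.max
    masks[[i]] <- make_bundle_mask(spec, jitter_prob = jitter_prob,
                                   seed = sub_seed)
    eff_i <- if (!is.null(effect) && groups[i] == effect$applies_to) effect
             else NULL
    fields[[i]] <- make_pdd_field(masks[[i]], spec, kappas,
                                  seed = if (is.null(sub_seed)) NULL
                                         else sub_seed + 500000L,
                                  effect = eff_i)
  }
  labels <- roi_end_labels(spec)
  truth <- list(
    effect = if (is.null(effect)) NULL else unclass(effect),
    affected_s_mm = if (is.null(effect)) numeric(0) else effect$slice_range,
    affected_slices = if (is.null(effect)) integer(0) else {
      smax <- spec$length_mm
      idx <- 0:floor(smax / slice_spacing_mm)
      idx[idx * slice_spacing_mm >= effect$slice_range[1] &
            idx * slice_spacing_mm <= effect$slice_range[2]]
    }
  )
  cohort_spec(subject_id = ids, group = groups,
              bundle_masks = list("1-2" = masks), pdd_fields = fields,
              roi_labels = labels, spacing_mm = spec$spacing_mm,
              truth = truth)
}

# two spherical ROI blobs (labels 1 and 2) at the centerline ends
roi_end_labels <- function(spec, blob_radius_mm = NULL) {
  if (is.null(blob_radius_mm)) blob_radius_mm <- spec$radius_mm
  cl <- centerline_samples(spec)
  ends <- rbind(cl$points[1, ], cl$points[nrow(cl$points), ])
  lab <- array(0L, dim = spec$shape)
  grid <- as.matrix(expand.grid(i = 0:(spec$shape[1] - 1),
                                j = 0:(spec$shape[2] - 1),
                                k = 0:(spec$shape[3] - 1)))
  ctr <- sweep(grid, 2, spec$spacing_mm, `*`)
  for (e in 1:2) {
    d2 <- rowSums(sweep(ctr, 2, ends[e, ], `-`)^2)
    lab[grid[d2 <= blob_radius_mm^2, , drop = FALSE] + 1L] <- e
  }
  lab
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject mask and PDD NIfTI volumes, the ROI label volume, a
#' cohort manifest CSV (`subject_id, group, mask_path, pdd_path`) and the
#' ground-truth record as JSON.
#'
#' @param cohort a cohort from [make_cohort()].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- cohort$bundle_masks[[1]]
  rows <- lapply(seq_along(cohort$subject_id), function(i) {
    mp <- file.path(dir, sprintf("%s_mask.nii.gz", cohort$subject_id[i]))
    pp <- file.path(dir, sprintf("%s_pdd.nii.gz", cohort$subject_id[i]))
    write_mask_nifti(masks[[i]], mp)
    write_pdd_nifti(cohort$pdd_fields[[i]], pp)
    data.frame(subject_id = cohort$subject_id[i], group = cohort$group[i],
               mask_path = mp, pdd_path = pp)
  })
  write_labels_nifti(cohort$roi_labels, cohort$spacing_mm,
                     file.path(dir, "roi_labels.nii.gz"))
  manifest <- file.path(dir, "cohort.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  if (!is.null(cohort$truth))
    writeLines(jsonlite::toJSON(cohort$truth, digits = NA, auto_unbox = TRUE,
                                null = "null"),
               file.path(dir, "truth.json"))
  invisible(manifest)
}

# PDD fields are stored as 4D float NIfTI (x, y, z, 3); invalid voxels 0
write_pdd_nifti <- function(field, path) {
  sh <- dim(field$valid)
  arr <- array(0, dim = c(sh, 3L))
  for (c_ in 1:3)
    arr[cbind(field$voxels + 1L, c_)] <- field$axis[, c_]
  img <- RNifti::asNifti(
    arr, reference = list(pixdim = c(-1, field$spacing_mm, 1, 1, 1, 1)),
    datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_cohort
#' @param path a PDD NIfTI path written by the cohort writer.
#' @export
read_pdd_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  nrm2 <- sqrt(arr[, , , 1]^2 + arr[, , , 2]^2 + arr[, , , 3]^2)
  valid <- nrm2 > 0.5
  vox <- which(valid, arr.ind = TRUE) - 1L
  axis <- cbind(arr[, , , 1][valid], arr[, , , 2][valid], arr[, , , 3][valid])
  structure(list(axis = canonical_signs(axis / sqrt(rowSums(axis^2))),
                 voxels = vox, valid = valid,
                 spacing_mm = RNifti::pixdim(img)[1:3]),
            class = "pdd_field")
}
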