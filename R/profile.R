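#' Cohort specification
#'
#' Bundles together everything a group comparison needs: per-subject
#' bundle masks for each region pair, per-subject PDD fields, group
#' labels, and the ROI label volume. All volumes must share one grid.
#'
#' @param subject_id character vector of subject identifiers.
#' @param group group label per subject (two levels, e.g. "A"/"B").
#' @param bundle_masks named list keyed `"i-j"` by region pair; each
#'   element is a list of per-subject [binary_volume()] masks in subject
#'   order.
#' @param pdd_fields list of per-subject `pdd_field` objects.
#' @param roi_labels integer 3D array of region labels.
#' @param spacing_mm voxel spacing shared by all volumes.
#' @param truth optional ground-truth record (synthetic cohorts).
#' @return A `cohort` object.
#' @export
cohort_spec <- function(subject_id, group, bundle_masks, pdd_fields,
                        roi_labels, spacing_mm, truth = NULL) {
  group <- as.character(group)
  if (length(unique(group)) != 2L)
    stop("need exactly two groups")
  if (min(table(group)) < 2L)
    stop("need at least 2 subjects per group")
  structure(list(subject_id = subject_id, group = group,
                 bundle_masks = bundle_masks, pdd_fields = pdd_fields,
                 roi_labels = roi_labels,
                 spacing_mm = rep_len(spacing_mm, 3), truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects (%s), %d bundle pair(s)>\n",
              length(x$subject_id),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                    collapse = ", "),
              length(x$bundle_masks)))
  invisible(x)
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns `subject_id, group, mask_path, pdd_path`;
#' volumes are NIfTI files as written by [write_cohort()].
#'
#' @param manifest_path manifest CSV path.
#' @param roi_path ROI label NIfTI path.
#' @param pair key under which the masks are stored (default "1-2").
#' @return A `cohort`.
#' @export
read_cohort <- function(manifest_path, roi_path, pair = "1-2") {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  masks <- lapply(man$mask_path, read_mask_nifti)
  fields <- lapply(man$pdd_path, read_pdd_nifti)
  roi <- read_labels_nifti(roi_path)
  bl <- list(masks)
  names(bl) <- pair
  cohort_spec(man$subject_id, man$group, bl, fields, roi$labels,
              roi$spacing_mm)
}

pair_key <- function(roi_pair) {
  p <- sort(as.integer(roi_pair))
  paste0(p[1], "-", p[2])
}

empty_profile <- function(roi_pair, reason) {
  structure(list(roi_pair = roi_pair, slices = list(), length_mm = 0,
                 curve = NULL, reason = reason),
            class = "tract_profile")
}

#' Build a tract profile for a region pair
#'
#' Runs the along-tract pipeline: intersect all subjects' bundle masks
#' (both groups), keep the largest 26-connected component, thin it to a
#' medial curve, order and smooth it with a least-squares B-spline,
#' place cross-sectional slabs at regular arc-length intervals, and pool
#' each group's PDD axes over the slab voxels where the individual
#' subject's own mask is black and its PDD valid. Slices where either
#' group pools fewer than `min_axes` axes are marked untestable.
#'
#' @param cohort a `cohort`.
#' @param roi_pair length-2 integer region pair (key into the cohort's
#'   bundle list).
#' @param spacing_mm slice spacing along the medial line (default 2 mm).
#' @param min_axes minimum per-group axes for a testable slice
#'   (default 10).
#' @param n_ctrl,degree B-spline fitting controls (defaults as in
#'   [fit_bspline()]).
#' @return A `tract_profile`: `roi_pair`, `length_mm`, `curve`, and a
#'   list `slices`, each slice holding `index`, `s_mm`, `frame`,
#'   `voxels`, `samples` (named list of per-group [axial_sample()]s) and
#'   `testable`.
#' @export
build_profile <- function(cohort, roi_pair = c(1, 2), spacing_mm = 2,
                          min_axes = 10, n_ctrl = NULL, degree = 3L) {
  key <- pair_key(roi_pair)
  masks <- cohort$bundle_masks[[key]]
  if (is.null(masks) || all(vapply(masks, n_black, 0L) == 0L))
    return(empty_profile(roi_pair, "no bundle for this pair"))
  overlap <- intersect_subject_masks(masks)
  if (n_black(overlap) == 0L)
    return(empty_profile(roi_pair, "empty overlap after intersection"))
  overlap <- largest_component(overlap)
  skel <- curve_thin(overlap)
  poly <- tryCatch(order_skeleton(skel),
                   error = function(e) skeleton_to_polyline(skel))
  if (nrow(poly) < degree + 2L)
    return(empty_profile(roi_pair, "medial line too short"))
  if (is.null(n_ctrl)) n_ctrl <- max(4L, round(nrow(poly) / 4))
  n_ctrl <- min(n_ctrl, nrow(poly))
  curve <- fit_bspline(poly, n_ctrl = n_ctrl, degree = degree)
  frames <- suppressWarnings(sample_slices(curve, spacing_mm))
  groups <- unique(cohort$group)
  slices <- vector("list", nrow(frames))
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    vox <- cut_cross_section(overlap, fr)
    samples <- list()
    for (g in groups) {
      axes <- matrix(numeric(0), 0, 3)
      for (sidx in which(cohort$group == g)) {
        m <- masks[[sidx]]
        if (nrow(vox) == 0L) next
        inmask <- m$occupancy[vox + 1L]
        v <- vox[inmask, , drop = FALSE]
        if (nrow(v) > 0L)
          axes <- rbind(axes, pdd_axes_at(cohort$pdd_fields[[sidx]], v))
      }
      samples[[g]] <- if (nrow(axes) > 0L) axial_sample(axes) else axes
    }
    testable <- nrow(vox) > 0L &&
      all(vapply(samples, nrow, 0L) >= min_axes)
    slices[[i]] <- list(index = i - 1L, s_mm = fr$s_mm, frame = fr,
                        voxels = vox, samples = samples,
                        testable = testable)
  }
  structure(list(roi_pair = roi_pair, slices = slices,
                 length_mm = max(frames$s_mm), curve = curve,
                 reason = NULL),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat(sprintf("<tract_profile %s: %d slices over %.1f mm%s>\n",
              pair_key(x$roi_pair), length(x$slices), x$length_mm,
              if (!is.null(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Per-slice two-group directional test
#'
#' For every testable slice, fits a Bingham model to each group's pooled
#' axes, builds the confidence ellipse at the given error rate, and
#' applies the separated-cones criterion ([groups_differ()]). Slices
#' whose fit or ellipse is degenerate are marked untestable.
#'
#' @param profile a `tract_profile`.
#' @param alpha per-slice error rate (default 0.005).
#' @return character vector, one of `"significant"`, `"not"`,
#'   `"untestable"` per slice.
#' @export
test_profile <- function(profile, alpha = 0.005) {
  vapply(profile$slices, function(sl) {
    if (!isTRUE(sl$testable)) return("untestable")
    res <- tryCatch({
      cis <- lapply(sl$samples, function(sm)
        confidence_ellipse(bingham_mle(sm), alpha = alpha))
      if (groups_differ(cis[[1]], cis[[2]])) "significant" else "not"
    }, error = function(e) "untestable", warning = function(w) "untestable")
    res
  }, character(1))
}

#' Count significant slice clusters
#'
#' The profile-level group-difference weight: the number of maximal runs
#' of consecutive `"significant"` slices of length at least `n_min`.
#' Untestable slices break contiguity.
#'
#' @param flags character vector from [test_profile()].
#' @param n_min minimum run length (default 4).
#' @return integer cluster count.
#' @export
count_clusters <- function(flags, n_min = 4L) {
  if (length(flags) == 0L) return(0L)
  r <- rle(flags == "significant")
  sum(r$values & r$lengths >= n_min)
}

#' Region-pair difference matrix
#'
#' Builds, for every region pair with a bundle in the cohort, the tract
#' profile, tests it slice-by-slice, and records the cluster count as
#' the pair's weight. Pairs with no overlap (or failed profiles) get
#' weight 0. The matrix is symmetric with a zero diagonal.
#'
#' @param cohort a `cohort`.
#' @param alpha per-slice error rate (default 0.005).
#' @param n_min minimum cluster length (default 4).
#' @param spacing_mm slice spacing (default 2 mm).
#' @param min_axes per-group minimum axes per testable slice.
#' @return A `difference_matrix`: list with `labels`, `weights`
#'   (symmetric integer matrix) and `lengths_mm` (per-pair tract length,
#'   same shape).
#' @export
difference_matrix <- function(cohort, alpha = 0.005, n_min = 4L,
                              spacing_mm = 2, min_axes = 10) {
  labels <- sort(unique(cohort$roi_labels[cohort$roi_labels > 0L]))
  L <- length(labels)
  W <- matrix(0L, L, L, dimnames = list(labels, labels))
  Len <- matrix(0, L, L, dimnames = list(labels, labels))
  for (key in names(cohort$bundle_masks)) {
    pr <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    i <- match(pr[1], labels); j <- match(pr[2], labels)
    if (is.na(i) || is.na(j)) next
    w <- 0L; len <- 0
    tryCatch({
      prof <- build_profile(cohort, pr, spacing_mm = spacing_mm,
                            min_axes = min_axes)
      len <- prof$length_mm
      w <- count_clusters(test_profile(prof, alpha = alpha), n_min = n_min)
    }, error = function(e)
      message(sprintf("pair %s failed: %s", key, conditionMessage(e))))
    W[i, j] <- W[j, i] <- w
    Len[i, j] <- Len[j, i] <- len
  }
  structure(list(labels = labels, weights = W, lengths_mm = Len),
            class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, ...) {
  cat(sprintf("<difference_matrix over %d regions, total weight %d>\n",
              length(x$labels), sum(x$weights) / 2))
  print(x$weights)
  invisible(x)
}

#' Write a difference matrix as CSV and edge list
#'
#' @param m a `difference_matrix`.
#' @param matrix_path CSV path for the square weight matrix.
#' @param edges_path optional CSV path for the
#'   `(label_i, label_j, weight, length_mm)` edge list.
#' @return `matrix_path`, invisibly.
#' @export
write_difference_matrix <- function(m, matrix_path, edges_path = NULL) {
  write.csv(m$weights, matrix_path, row.names = TRUE)
  if (!is.null(edges_path)) {
    idx <- which(upper.tri(m$weights), arr.ind = TRUE)
    write.csv(data.frame(label_i = m$labels[idx[, 1]],
                         label_j = m$labels[idx[, 2]],
                         weight = m$weights[idx],
                         length_mm = m$lengths_mm[idx]),
              edges_path, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Length-effect regression of cluster counts on tract lengths
#'
#' Standardises both variables to z-scores and fits an ordinary
#' least-squares line of the cluster-count z on the tract-length z —
#' asking whether longer tracts accumulate more significant clusters.
#'
#' @param m a `difference_matrix`, or a numeric vector of cluster counts.
#' @param lengths_mm per-pair tract lengths (taken from the matrix when
#'   `m` is a `difference_matrix`).
#' @return list with `slope`, `p_value` (two-sided) and `adj_r2`.
#' @export
length_cluster_regression <- function(m, lengths_mm = NULL) {
  if (inherits(m, "difference_matrix")) {
    idx <- which(upper.tri(m$weights), arr.ind = TRUE)
    w <- m$weights[idx]
    len <- m$lengths_mm[idx]
  } else {
    w <- as.numeric(m)
    len <- as.numeric(lengths_mm)
  }
  keep <- len > 0
  w <- w[keep]; len <- len[keep]
  if (length(w) < 3L) stop("need at least 3 pairs with nonzero length")
  if (sd(w) == 0 || sd(len) == 0)
    stop("zero variance in cluster counts or lengths")
  zy <- (w - mean(w)) / sd(w)
  zx <- (len - mean(len)) / sd(len)
  fit <- lm(zy ~ zx)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       p_value = sm$coefficients[2, 4],
       adj_r2 = sm$adj.r.squared)
}

#' Region-level model fits under three aggregation modes
#'
#' Pools PDD axes over a labelled region under one of three aggregation
#' modes — every region voxel (voxel-based analysis), the curve-thinned
#' skeleton of the region (skeleton-based), or the union of profile
#' slice slabs along the region's medial line (profile-based) — then
#' fits Watson and Bingham models and scores each with the azimuthal
#' chi-square structure test against a uniform reference (700 synthetic
#' axes, 50 bins). A model is a candidate when its structure test is
#' significant at `select_alpha` (`"no fit"` otherwise); between
#' candidates the selection falls to the model with the larger
#' calibration p-value under the model-reference reading of
#' [goodness_of_fit()], which penalises a rotationally symmetric Watson
#' fit on elliptically dispersed axes.
#'
#' @param cohort a `cohort`.
#' @param region integer region label (in `roi_labels`) or a
#'   [binary_volume()] region mask.
#' @param mode `"voxels"`, `"skeleton"` or `"profile"`.
#' @param seed seed for the synthetic reference axes.
#' @param n_synth,n_bins chi-square protocol controls.
#' @param select_alpha selection threshold (default 0.05).
#' @param min_axes minimum pooled axes to attempt a fit (default 50).
#' @return list with `mode`, `n_axes`, `p_watson`, `p_bingham`,
#'   `selected` and the fitted models.
#' @export
aggregate_mode_fit <- function(cohort, region,
                               mode = c("voxels", "skeleton", "profile"),
                               seed = NULL, n_synth = 700L, n_bins = 50L,
                               select_alpha = 0.05, min_axes = 50L) {
  mode <- match.arg(mode)
  mask <- if (inherits(region, "binary_volume")) region
          else binary_volume(cohort$roi_labels == as.integer(region),
                             cohort$spacing_mm)
  if (n_black(mask) == 0L)
    return(list(mode = mode, n_axes = 0L, p_watson = NA_real_,
                p_bingham = NA_real_, selected = "no fit",
                reason = "empty region"))
  vox <- switch(mode,
    voxels = black_points(mask),
    skeleton = black_points(curve_thin(largest_component(mask))),
    profile = {
      skel <- curve_thin(largest_component(mask))
      poly <- tryCatch(order_skeleton(skel),
                       error = function(e) skeleton_to_polyline(skel))
      curve <- fit_bspline(poly, n_ctrl = min(max(4L, round(nrow(poly) / 4)),
                                              nrow(poly)))
      frames <- suppressWarnings(sample_slices(curve, 2))
      vx <- do.call(rbind, lapply(seq_len(nrow(frames)), function(i)
        cut_cross_section(mask, frames[i, ])))
      unique(vx)
    })
  axes <- do.call(rbind, lapply(cohort$pdd_fields, pdd_axes_at, vox = vox))
  if (is.null(axes) || nrow(axes) < min_axes)
    return(list(mode = mode, n_axes = if (is.null(axes)) 0L else nrow(axes),
                p_watson = NA_real_, p_bingham = NA_real_,
                selected = "no fit", reason = "too few axes"))
  s <- axial_sample(axes)
  wfit <- watson_mle(s)
  bfit <- bingham_mle(s)
  gof_p <- function(fit, ref) suppressWarnings(
    goodness_of_fit(s, fit, n_bins = n_bins, n_synth = n_synth,
                    seed = seed, reference = ref)$p_value)
  pw <- gof_p(wfit, "uniform")
  pb <- gof_p(bfit, "uniform")
  cand <- c(Watson = pw < select_alpha, Bingham = pb < select_alpha)
  selected <- if (!any(cand)) "no fit"
  else if (all(cand)) {
    calib <- c(Watson = gof_p(wfit, "model"), Bingham = gof_p(bfit, "model"))
    names(which.max(calib))
  } else names(which(cand))
  list(mode = mode, n_axes = nrow(s), p_watson = pw, p_bingham = pb,
       selected = selected, watson = wfit, bingham = bfit)
}
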