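# Reproducibility/accuracy metrics between two segmentations.

#' Dice similarity coefficient between two contours
#'
#' Region overlap `2 |M1 n M2| / (|M1| + |M2|)` where `M1`, `M2` are the
#' regions enclosed by the two boundaries. Areas are evaluated by
#' rasterization on a shared fine pixel grid.
#'
#' @param c1,c2 contours of the same boundary kind.
#' @param grid_spacing rasterization pixel size in mm (default 0.05).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(c1, c2, grid_spacing = 0.05) {
  stopifnot(inherits(c1, "carotid_contour"), inherits(c2, "carotid_contour"))
  if (c1$kind != c2$kind) stop("contours must share the same boundary kind")
  if (abs(polygon_area(c1$points)) < 1e-9 ||
      abs(polygon_area(c2$points)) < 1e-9)
    stop("degenerate contour")
  b1 <- contour_bbox(c1$points); b2 <- contour_bbox(c2$points)
  # disjoint bounding boxes: no overlap
  if (b1[["xmax"]] < b2[["xmin"]] || b2[["xmax"]] < b1[["xmin"]] ||
      b1[["ymax"]] < b2[["ymin"]] || b2[["ymax"]] < b1[["ymin"]])
    return(0)
  bb <- joint_bounds(c1$points, c2$points, pad = 2 * grid_spacing)
  g <- grid_axes(bb, grid_spacing)
  m1 <- cpp_pip_mask(c1$points, g$x, g$y)
  m2 <- cpp_pip_mask(c2$points, g$x, g$y)
  s1 <- sum(m1); s2 <- sum(m2)
  if (s1 + s2 == 0) return(0)
  2 * sum(m1 & m2) / (s1 + s2)
}

#' Hausdorff distance between two contours
#'
#' Symmetric worst-case boundary distance
#' `max(h(M1, M2), h(M2, M1))` with `h(A, B)` the maximum over points of A of
#' the minimum Euclidean distance to the boundary of B. Both contours are
#' densely resampled along their arc length before evaluation.
#'
#' @param c1,c2 contours.
#' @param resample_step arc-length resampling step in mm (default 0.05).
#' @return Hausdorff distance in mm.
#' @export
hausdorff <- function(c1, c2, resample_step = 0.05) {
  stopifnot(inherits(c1, "carotid_contour"), inherits(c2, "carotid_contour"))
  if (abs(polygon_area(c1$points)) < 1e-9 ||
      abs(polygon_area(c2$points)) < 1e-9)
    stop("degenerate contour")
  p1 <- resample_ring(c1$points, step = resample_step)
  p2 <- resample_ring(c2$points, step = resample_step)
  h12 <- max(cpp_dist_to_poly(p1, c2$points))
  h21 <- max(cpp_dist_to_poly(p2, c1$points))
  max(h12, h21)
}

#' Longitudinal distance between the bifurcations of two stacks
#'
#' @param stack1,stack2 [contour_stack()] objects of the same volume.
#' @return `|bifurcation_z1 - bifurcation_z2|` in mm.
#' @export
bifurcation_distance <- function(stack1, stack2) {
  abs(stack1$bifurcation_z - stack2$bifurcation_z)
}

#' Slice-by-slice comparison of two contour stacks
#'
#' Both stacks are resliced by shape-based interpolation onto a common axial
#' grid with step `step` (absolute multiples of `step`, so the grid is shared
#' even when the stacks are anchored at different bifurcations) over the
#' intersection of their z-ranges; Dice and Hausdorff distance are then
#' computed per common slice and boundary kind.
#'
#' @param s1,s2 [contour_stack()] objects with overlapping z-ranges.
#' @param step common grid step in mm; defaults to 0.35 (the longitudinal
#'   voxel size Vz).
#' @param grid_spacing rasterization/SDF pixel size in mm.
#' @return data frame with columns `z`, `vessel`, `kind`, `dsc`, `hd`, `bf`
#'   (`bf` marks the CCA slice most proximal to the bifurcation of `s1`).
#' @export
compare_stacks <- function(s1, s2, step = 0.35, grid_spacing = 0.05) {
  z1 <- stack_z(s1); z2 <- stack_z(s2)
  lo <- max(min(z1), min(z2)); hi <- min(max(z1), max(z2))
  if (lo > hi) stop("stacks have no overlapping z-range")
  r1 <- reslice_any(s1, step, anchor = 0, grid_spacing = grid_spacing)
  r2 <- reslice_any(s2, step, anchor = 0, grid_spacing = grid_spacing)
  za <- stack_z(r1); zb <- stack_z(r2)
  common <- za[vapply(za, function(z) any(abs(zb - z) < 1e-6), TRUE)]
  common <- common[common >= lo - 1e-9 & common <= hi + 1e-9]
  if (length(common) == 0L) stop("stacks have no common slices")
  cca_z <- common[common <= s1$bifurcation_z + 1e-9]
  bf_z <- if (length(cca_z)) max(cca_z) else NA_real_
  rows <- list()
  for (z in common) {
    a <- r1$slices[[which(abs(za - z) < 1e-6)[1L]]]
    b <- r2$slices[[which(abs(zb - z) < 1e-6)[1L]]]
    for (kind in c("mab", "lib")) {
      if (is.null(a[[kind]]) || is.null(b[[kind]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        z = z, vessel = slice_vessel(z, s1$bifurcation_z),
        kind = toupper(kind),
        dsc = dice(a[[kind]], b[[kind]], grid_spacing = grid_spacing),
        hd = hausdorff(a[[kind]], b[[kind]]),
        bf = !is.na(bf_z) && abs(z - bf_z) < 1e-9)
    }
  }
  do.call(rbind, rows)
}

#' Stratified summary of a slice-wise comparison
#'
#' Aggregates per-slice Dice/Hausdorff values into the strata
#' CCA, ICA, BF (the single CCA slice most proximal to the bifurcation,
#' one per volume), CCA without BF, and Overall, for each boundary kind.
#'
#' @param comparison data frame from [compare_stacks()] (several volumes may
#'   be pooled by row-binding; the `bf` flag must mark one slice per volume).
#' @return data frame with `stratum`, `kind`, `n`, and mean/sd of DSC and HD.
#' @export
stratify_comparison <- function(comparison) {
  strata <- list(
    CCA = comparison$vessel == "CCA",
    ICA = comparison$vessel == "ICA",
    BF = comparison$bf,
    `CCA w/o BF` = comparison$vessel == "CCA" & !comparison$bf,
    Overall = rep(TRUE, nrow(comparison)))
  rows <- list()
  for (sn in names(strata)) {
    for (kind in c("MAB", "LIB")) {
      sel <- strata[[sn]] & comparison$kind == kind
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = sn, kind = kind, n = n,
        dsc_mean = if (n) mean(comparison$dsc[sel]) else NA_real_,
        dsc_sd = if (n > 1L) sd(comparison$dsc[sel]) else NA_real_,
        hd_mean = if (n) mean(comparison$hd[sel]) else NA_real_,
        hd_sd = if (n > 1L) sd(comparison$hd[sel]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Stratified evaluation of an automatic against a manual segmentation
#'
#' Runs [compare_stacks()] and aggregates with [stratify_comparison()].
#'
#' @param auto,manual [contour_stack()] objects (algorithm and manual).
#' @param ... passed to [compare_stacks()].
#' @return stratified summary data frame.
#' @export
stratified_eval <- function(auto, manual, ...) {
  stratify_comparison(compare_stacks(auto, manual, ...))
}
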