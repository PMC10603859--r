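# VWV and point-wise VWT quantification from MAB/LIB contour stacks.

# reslice one boundary kind of one branch onto a fine z grid and return
# (z, polygon area) pairs for longitudinal integration
branch_areas <- function(slices, step, grid_spacing) {
  z <- vapply(slices, function(s) s$z, 1)
  if (length(z) < 2L) stop("a branch needs at least 2 slices for integration")
  targets <- seq(min(z), max(z), by = step)
  if (abs(targets[length(targets)] - max(z)) > 1e-9)
    targets <- c(targets, max(z))
  areas <- numeric(length(targets))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(targets)) {
    zt <- targets[i]
    hit <- which(abs(z - zt) < 1e-9)
    if (length(hit)) {
      areas[i] <- polygon_area(slices[[hit[1L]]]$cont$points)
      next
    }
    j <- findInterval(zt, z)
    t <- (zt - z[j]) / (z[j + 1L] - z[j])
    key <- as.character(j)
    ent <- if (exists(key, envir = cache)) get(key, envir = cache) else {
      pa <- slices[[j]]$cont$points; pb <- slices[[j + 1L]]$cont$points
      bb <- joint_bounds(pa, pb, pad = 1)
      g <- grid_axes(bb, grid_spacing)
      e <- list(g = g, s1 = cpp_sdf_grid(pa, g$x, g$y),
                s2 = cpp_sdf_grid(pb, g$x, g$y))
      assign(key, e, envir = cache)
      e
    }
    p <- level_set_polygon((1 - t) * ent$s1 + t * ent$s2, ent$g$x, ent$g$y,
                           warn_multi = FALSE)
    if (is.null(p)) {
      warning(sprintf("no zero level set at z = %.3f; position skipped", zt))
      areas[i] <- NA_real_
      next
    }
    areas[i] <- abs(polygon_area(p))
  }
  ok <- is.finite(areas)
  if (sum(ok) < 2L) stop("too few valid cross-sections for integration")
  list(z = targets[ok], area = areas[ok])
}

#' Volume enclosed by one boundary surface of a stack
#'
#' The stack is resliced to a fine longitudinal step by shape-based
#' interpolation and the cross-sectional polygon areas are integrated along
#' z with the trapezoid rule. The CCA and ICA branches are integrated
#' separately over their own extents and summed.
#'
#' @param stack a [contour_stack()] with at least 2 slices of the requested
#'   boundary.
#' @param kind `"MAB"` or `"LIB"`.
#' @param step integration reslice step in mm (default 0.1).
#' @param grid_spacing SDF grid spacing for the interpolation.
#' @param branch `"both"` (default), `"CCA"` or `"ICA"`.
#' @return enclosed volume in mm^3.
#' @export
vessel_volume <- function(stack, kind = c("MAB", "LIB"), step = 0.1,
                          grid_spacing = 0.05, branch = c("both", "CCA", "ICA")) {
  kind <- match.arg(kind)
  branch <- match.arg(branch)
  field <- tolower(kind)
  z <- stack_z(stack)
  keep <- !vapply(stack$slices, function(s) is.null(s[[field]]), TRUE)
  slices <- lapply(stack$slices[keep], function(s)
    list(z = s$z, cont = s[[field]]))
  z <- z[keep]
  if (length(z) < 2L) stop("need at least 2 slices of the requested boundary")
  total <- 0
  for (br in c("CCA", "ICA")) {
    if (branch != "both" && br != branch) next
    sel <- slice_vessel(z, stack$bifurcation_z) == br
    if (sum(sel) < 2L) {
      if (branch == br) stop(sprintf("branch %s has fewer than 2 slices", br))
      next
    }
    ba <- branch_areas(slices[sel], step, grid_spacing)
    if (max(ba$z) - min(ba$z) < 1e-9) stop("zero-length branch extent")
    total <- total + sum(diff(ba$z) *
                           (head(ba$area, -1) + tail(ba$area, -1)) / 2)
  }
  total
}

#' Vessel wall volume (VWV) of a contour stack
#'
#' The volume enclosed by the MAB surface minus the volume enclosed by the
#' LIB surface.
#'
#' @inheritParams vessel_volume
#' @return VWV in mm^3 (strictly positive for valid stacks).
#' @export
vwv <- function(stack, step = 0.1, grid_spacing = 0.05,
                branch = c("both", "CCA", "ICA")) {
  branch <- match.arg(branch)
  vessel_volume(stack, "MAB", step, grid_spacing, branch) -
    vessel_volume(stack, "LIB", step, grid_spacing, branch)
}

#' Symmetric point correspondence between MAB and LIB contours
#'
#' Both contours are resampled to `n_points` by normalized arc length,
#' starting at the intersection with the ray from the MAB centroid along +x.
#' The LIB parameterization is then cyclically shifted to minimize the total
#' pair distance (order-preserving alignment). The distance between a pair is
#' the point-wise vessel-wall-plus-plaque thickness (VWT).
#'
#' @param mab,lib MAB and LIB contours on one slice, LIB inside MAB.
#' @param n_points number of correspondence pairs (>= 16).
#' @return data frame with `theta` (normalized circumferential coordinate
#'   from the MAB parameterization), MAB and LIB point coordinates, and the
#'   pair distance `vwt` in mm.
#' @export
correspond <- function(mab, lib, n_points = 100) {
  stopifnot(inherits(mab, "carotid_contour"), inherits(lib, "carotid_contour"))
  if (n_points < 16) stop("n_points must be at least 16")
  if (!all(cpp_points_in_poly(lib$points, mab$points)))
    stop("LIB contour is not inside the MAB contour")
  ctr <- polygon_centroid(mab$points)
  pm <- resample_ring(mab$points, n = n_points, center = ctr)
  pl <- resample_ring(lib$points, n = n_points, center = ctr)
  # order-preserving cyclic alignment of the LIB parameterization
  best_s <- 0L; best_d <- Inf
  for (s in 0:(n_points - 1L)) {
    idx <- ((seq_len(n_points) - 1L + s) %% n_points) + 1L
    d <- sum(sqrt(rowSums((pm - pl[idx, , drop = FALSE])^2)))
    if (d < best_d) { best_d <- d; best_s <- s }
  }
  idx <- ((seq_len(n_points) - 1L + best_s) %% n_points) + 1L
  pl <- pl[idx, , drop = FALSE]
  data.frame(theta = (seq_len(n_points) - 1L) / n_points,
             mab_x = pm[, 1L], mab_y = pm[, 2L],
             lib_x = pl[, 1L], lib_y = pl[, 2L],
             vwt = sqrt(rowSums((pm - pl)^2)))
}

#' Flattened 2D L-shaped vessel-wall thickness map
#'
#' The stack is resliced to `row_step`; on each slice the point-wise VWT is
#' computed by [correspond()] and laid out on a 2D grid: rows run from the
#' proximal CCA to the bifurcation and then along the ICA; columns are the
#' normalized circumferential arc length. CCA rows span all `n_cols`
#' columns; ICA rows occupy the first columns scaled by the ICA/CCA mean
#' MAB-perimeter ratio, the remaining cells being missing — giving the
#' L-shaped carotid atlas layout.
#'
#' @param stack a [contour_stack()] with MAB and LIB on its slices.
#' @param n_cols number of circumferential columns (default 100).
#' @param row_step longitudinal row spacing in mm (default 1).
#' @param grid_spacing SDF grid spacing for the reslicing.
#' @return an object of class `vwt_map`: list with `grid` (rows x `n_cols`
#'   matrix of thickness in mm, `NA` for missing cells), `z` (row positions),
#'   `vessel` (per-row branch), `bifurcation_z`.
#' @export
vwt_map <- function(stack, n_cols = 100, row_step = 1, grid_spacing = 0.05) {
  ok <- vapply(stack$slices, function(s)
    !is.null(s$mab) && !is.null(s$lib), TRUE)
  if (!any(ok)) stop("no slices with both MAB and LIB")
  st <- contour_stack(stack$slices[ok], stack$bifurcation_z, stack$isd,
                      check = FALSE)
  rs <- reslice_any(st, row_step, grid_spacing = grid_spacing)
  z <- stack_z(rs)
  ves <- slice_vessel(z, rs$bifurcation_z)
  perim <- vapply(rs$slices, function(s)
    if (is.null(s$mab)) NA_real_ else polygon_perimeter(s$mab$points), 1)
  n_ica_cols <- if (any(ves == "ICA")) {
    ratio <- mean(perim[ves == "ICA"], na.rm = TRUE) /
      mean(perim[ves == "CCA"], na.rm = TRUE)
    max(16L, min(n_cols, round(n_cols * ratio)))
  } else 0L
  grid <- matrix(NA_real_, nrow = length(z), ncol = n_cols)
  for (i in seq_along(z)) {
    s <- rs$slices[[i]]
    if (is.null(s$mab) || is.null(s$lib)) next
    nc <- if (ves[i] == "CCA") n_cols else n_ica_cols
    cp <- tryCatch(correspond(s$mab, s$lib, n_points = nc),
                   error = function(e) NULL)
    if (!is.null(cp)) grid[i, seq_len(nc)] <- cp$vwt
  }
  structure(list(grid = grid, z = z, vessel = ves,
                 bifurcation_z = rs$bifurcation_z, row_step = row_step),
            class = "vwt_map")
}

#' @export
print.vwt_map <- function(x, ...) {
  cat(sprintf(paste0("<vwt_map> %d rows (%d CCA / %d ICA) x %d columns, ",
                     "mean VWT %.3f mm, max %.3f mm\n"),
              nrow(x$grid), sum(x$vessel == "CCA"), sum(x$vessel == "ICA"),
              ncol(x$grid), map_summary(x), max(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' Mean thickness of a VWT map
#'
#' Mean over non-missing cells; the map-level VWT summary used when
#' comparing algorithm and manual maps.
#'
#' @param map a [vwt_map()].
#' @return mean thickness in mm.
#' @export
map_summary <- function(map) {
  v <- map$grid[is.finite(map$grid)]
  if (length(v) == 0L) stop("empty VWT map")
  mean(v)
}

#' Cell-wise values of two VWT maps on their common grid
#'
#' Pairs cells by identical (row, column) indexing over the jointly
#' non-missing region of the two maps (rows are matched from the
#' bifurcation outward so maps with different row counts align at the
#' anatomy's anchor).
#'
#' @param m1,m2 [vwt_map()] objects of the same artery.
#' @return data frame with columns `v1` and `v2` of paired cell values (mm).
#' @export
map_pairs <- function(m1, m2) {
  align <- function(m) {
    list(cca = which(m$vessel == "CCA"), ica = which(m$vessel == "ICA"))
  }
  a1 <- align(m1); a2 <- align(m2)
  pairs <- list()
  # CCA rows aligned at the bifurcation (last CCA row), ICA at the first
  ncca <- min(length(a1$cca), length(a2$cca))
  if (ncca > 0L) {
    r1 <- tail(a1$cca, ncca); r2 <- tail(a2$cca, ncca)
    pairs[[1L]] <- cbind(as.vector(m1$grid[r1, , drop = FALSE]),
                         as.vector(m2$grid[r2, , drop = FALSE]))
  }
  nica <- min(length(a1$ica), length(a2$ica))
  if (nica > 0L) {
    r1 <- head(a1$ica, nica); r2 <- head(a2$ica, nica)
    k <- min(ncol(m1$grid), ncol(m2$grid))
    pairs[[length(pairs) + 1L]] <-
      cbind(as.vector(m1$grid[r1, seq_len(k), drop = FALSE]),
            as.vector(m2$grid[r2, seq_len(k), drop = FALSE]))
  }
  m <- do.call(rbind, pairs)
  keep <- is.finite(m[, 1L]) & is.finite(m[, 2L])
  data.frame(v1 = m[keep, 1L], v2 = m[keep, 2L])
}

#' Plot a VWT map
#'
#' Renders the L-shaped thickness map as an image with the bifurcation row
#' marked.
#'
#' @param x a [vwt_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot.vwt_map <- function(x, ...) {
  graphics::image(x = seq_len(nrow(x$grid)), y = seq_len(ncol(x$grid)),
                  z = x$grid, xlab = "longitudinal row", ylab = "arc column",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  bf <- max(which(x$vessel == "CCA"))
  graphics::abline(v = bf + 0.5, lty = 2)
  invisible(x)
}
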