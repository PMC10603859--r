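#' @useDynLib caroseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma rlnorm approx sd shapiro.test t.test
#'   wilcox.test cor.test pf qf aggregate complete.cases quantile
#' @importFrom grDevices contourLines gray
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Contour: a closed, simple, counter-clockwise polygon on one axial slice,
# in physical mm. MAB = media-adventitia boundary (outer wall), LIB =
# lumen-intima boundary (inner). Stored as an open ring (no repeated vertex).
# ---------------------------------------------------------------------------

#' Create an axial vessel-boundary contour
#'
#' A contour is a closed simple polygon in physical millimetres on one axial
#' slice of a 3D carotid ultrasound volume. Vertices are stored
#' counter-clockwise as an open ring (the closing edge is implicit).
#'
#' @param points numeric n x 2 matrix of (x, y) vertices in mm, n >= 8.
#'   Clockwise input is reversed to counter-clockwise.
#' @param z axial slice position in mm.
#' @param kind boundary kind, `"MAB"` or `"LIB"`.
#' @param vessel branch label, `"CCA"` or `"ICA"`.
#' @param validate check polygon simplicity (O(n^2); disable in hot loops).
#' @return an object of class `carotid_contour`.
#' @export
contour <- function(points, z = 0, kind = c("MAB", "LIB"),
                    vessel = c("CCA", "ICA"), validate = TRUE) {
  kind <- match.arg(kind)
  vessel <- match.arg(vessel)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour points must be an n x 2 matrix")
  if (!all(is.finite(points))) stop("contour points must be finite")
  # drop an explicit closing vertex
  n <- nrow(points)
  if (n > 1L && all(abs(points[1L, ] - points[n, ]) < 1e-12))
    points <- points[-n, , drop = FALSE]
  if (nrow(points) < 8L) stop("a contour needs at least 8 distinct points")
  a <- polygon_area(points)
  if (abs(a) < 1e-9) stop("degenerate contour: polygon area is zero")
  if (a < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (validate && !is_simple_polygon(points))
    stop("contour polygon is self-intersecting")
  structure(list(points = points, z = as.numeric(z), kind = kind,
                 vessel = vessel),
            class = "carotid_contour")
}

#' @export
print.carotid_contour <- function(x, ...) {
  cat(sprintf("<%s %s contour> %d vertices, z = %.3f mm, area = %.3f mm^2\n",
              x$vessel, x$kind, nrow(x$points), x$z, polygon_area(x$points)))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param p n x 2 vertex matrix (open ring).
#' @return signed area in mm^2.
#' @export
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

polygon_perimeter <- function(p) {
  d <- p - p[c(2:nrow(p), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Simplicity: no two non-adjacent edges intersect. Vectorized O(n^2).
is_simple_polygon <- function(p) {
  n <- nrow(p)
  a1 <- p; a2 <- p[c(2:n, 1L), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j > i + 1L & !(i == 1L & j == n)),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d1 <- a2[i, , drop = FALSE] - a1[i, , drop = FALSE]
  d2 <- a2[j, , drop = FALSE] - a1[j, , drop = FALSE]
  r <- a1[j, , drop = FALSE] - a1[i, , drop = FALSE]
  den <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  t1 <- (r[, 1L] * d2[, 2L] - r[, 2L] * d2[, 1L]) / den
  t2 <- (r[, 1L] * d1[, 2L] - r[, 2L] * d1[, 1L]) / den
  hit <- is.finite(t1) & is.finite(t2) &
    t1 > 1e-12 & t1 < 1 - 1e-12 & t2 > 1e-12 & t2 < 1 - 1e-12
  !any(hit)
}

contour_bbox <- function(cont, pad = 0) {
  p <- if (inherits(cont, "carotid_contour")) cont$points else cont
  c(xmin = min(p[, 1L]) - pad, xmax = max(p[, 1L]) + pad,
    ymin = min(p[, 2L]) - pad, ymax = max(p[, 2L]) + pad)
}

grid_axes <- function(bounds, spacing) {
  list(x = seq(bounds[["xmin"]] + spacing / 2, bounds[["xmax"]], by = spacing),
       y = seq(bounds[["ymin"]] + spacing / 2, bounds[["ymax"]], by = spacing),
       spacing = spacing)
}

#' Rasterize a contour to a binary pixel mask
#'
#' A pixel is 1 exactly when its centre lies inside the polygon, so the mask
#' area converges to the polygon area as the spacing shrinks.
#'
#' @param cont a [contour()].
#' @param grid_spacing pixel size in mm.
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` containing the contour;
#'   defaults to the bounding box padded by one pixel.
#' @return list with `mask` (0/1 integer matrix indexed `[x, y]`), grid centre
#'   coordinates `x`, `y`, and `spacing`.
#' @export
rasterize <- function(cont, grid_spacing = 0.05, bounds = NULL) {
  p <- if (inherits(cont, "carotid_contour")) cont$points else cont
  if (abs(polygon_area(p)) < 1e-9) stop("degenerate contour: area is zero")
  if (is.null(bounds)) bounds <- contour_bbox(p, pad = 2 * grid_spacing)
  bb <- contour_bbox(p)
  if (bb[["xmin"]] < bounds[["xmin"]] || bb[["xmax"]] > bounds[["xmax"]] ||
      bb[["ymin"]] < bounds[["ymin"]] || bb[["ymax"]] > bounds[["ymax"]])
    stop("bounds do not contain the contour")
  g <- grid_axes(bounds, grid_spacing)
  list(mask = cpp_pip_mask(p, g$x, g$y), x = g$x, y = g$y,
       spacing = grid_spacing)
}

#' Signed distance field of a contour on a pixel grid
#'
#' Negative inside the polygon, positive outside, zero on the boundary;
#' the magnitude is the exact Euclidean distance to the polygon.
#'
#' @inheritParams rasterize
#' @param pad padding (mm) added around the contour bounding box when
#'   `bounds` is not given.
#' @return list with `values` (matrix indexed `[x, y]`), `x`, `y`, `spacing`.
#' @export
signed_distance_field <- function(cont, grid_spacing = 0.05, bounds = NULL,
                                  pad = 2) {
  p <- if (inherits(cont, "carotid_contour")) cont$points else cont
  if (abs(polygon_area(p)) < 1e-9) stop("degenerate contour: area is zero")
  if (is.null(bounds)) bounds <- contour_bbox(p, pad = pad)
  g <- grid_axes(bounds, grid_spacing)
  list(values = cpp_sdf_grid(p, g$x, g$y), x = g$x, y = g$y,
       spacing = grid_spacing)
}

# Extract the zero level set of a scalar field (marching squares with linear
# sub-cell interpolation via contourLines). Returns the largest closed loop.
level_set_polygon <- function(values, x, y, level = 0, warn_multi = TRUE) {
  cl <- contourLines(x = x, y = y, z = values, levels = level)
  if (length(cl) == 0L) return(NULL)
  polys <- lapply(cl, function(l) {
    p <- cbind(l$x, l$y)
    n <- nrow(p)
    if (n > 1L && all(abs(p[1L, ] - p[n, ]) < 1e-12)) p <- p[-n, , drop = FALSE]
    p
  })
  polys <- polys[vapply(polys, nrow, 1L) >= 3L]
  if (length(polys) == 0L) return(NULL)
  areas <- vapply(polys, function(p) abs(polygon_area(p)), 1)
  if (length(polys) > 1L && warn_multi)
    warning("level set has multiple closed components; keeping the largest")
  p <- polys[[which.max(areas)]]
  if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

#' Shape-based interpolation between two contours
#'
#' The interpolated contour is the zero level set of the linear blend
#' `(1 - t) * SDF(proximal) + t * SDF(distal)` of the two signed distance
#' fields, extracted by marching squares with linear sub-cell interpolation.
#' If the blend has several closed components the largest is kept with a
#' warning. `t = 0` / `t = 1` reproduce the inputs within one grid step.
#'
#' @param c_prox,c_dist contours of the same boundary kind.
#' @param t interpolation fraction in \[0, 1\] (0 = proximal).
#' @param grid_spacing SDF grid spacing in mm (default 0.05).
#' @param pad padding around the joint bounding box in mm.
#' @return interpolated [contour()].
#' @export
interpolate_contour <- function(c_prox, c_dist, t, grid_spacing = 0.05,
                                pad = 2) {
  stopifnot(inherits(c_prox, "carotid_contour"),
            inherits(c_dist, "carotid_contour"))
  if (c_prox$kind != c_dist$kind)
    stop("contours must share the same boundary kind")
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  bb <- joint_bounds(c_prox$points, c_dist$points, pad)
  g <- grid_axes(bb, grid_spacing)
  s1 <- cpp_sdf_grid(c_prox$points, g$x, g$y)
  s2 <- cpp_sdf_grid(c_dist$points, g$x, g$y)
  p <- level_set_polygon((1 - t) * s1 + t * s2, g$x, g$y)
  if (is.null(p))
    stop("blended signed distance field has no zero level set")
  src <- if (t <= 0.5) c_prox else c_dist
  contour(p, z = (1 - t) * c_prox$z + t * c_dist$z, kind = src$kind,
          vessel = src$vessel, validate = FALSE)
}

joint_bounds <- function(p1, p2, pad = 2) {
  c(xmin = min(p1[, 1L], p2[, 1L]) - pad, xmax = max(p1[, 1L], p2[, 1L]) + pad,
    ymin = min(p1[, 2L], p2[, 2L]) - pad, ymax = max(p1[, 2L], p2[, 2L]) + pad)
}

# ---------------------------------------------------------------------------
# ContourStack: ordered per-slice (MAB, LIB) pairs anchored at a bifurcation.
# ---------------------------------------------------------------------------

#' Create a contour stack
#'
#' A contour stack holds the per-slice MAB and LIB contours of one carotid
#' volume. Slice positions form an arithmetic sequence with step `isd`
#' anchored at the bifurcation; slices with `z <= bifurcation_z` belong to
#' the common carotid artery (CCA), more distal slices to the internal
#' carotid artery (ICA).
#'
#' @param slices list of `list(z =, mab =, lib =)` entries (contours may be
#'   `NULL` when a slice is missing one boundary).
#' @param bifurcation_z bifurcation position in mm.
#' @param isd inter-slice distance in mm.
#' @param check verify the arithmetic slice grid and LIB-inside-MAB.
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(slices, bifurcation_z, isd, check = TRUE) {
  z <- vapply(slices, function(s) s$z, 1)
  o <- order(z)
  slices <- slices[o]; z <- z[o]
  if (check && length(z) > 1L) {
    k <- (z - bifurcation_z) / isd
    if (any(abs(k - round(k)) > 1e-6))
      stop("slice positions must lie on the ISD grid anchored at the bifurcation")
  }
  if (check) {
    for (s in slices) {
      if (!is.null(s$mab) && !is.null(s$lib) &&
          !all(cpp_points_in_poly(s$lib$points, s$mab$points)))
        stop(sprintf("LIB not inside MAB on slice z = %.3f", s$z))
    }
  }
  structure(list(slices = slices, bifurcation_z = bifurcation_z,
                 isd = isd,
                 extents = c(proximal = bifurcation_z - min(z),
                             distal = max(z) - bifurcation_z)),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  z <- stack_z(x)
  cat(sprintf(paste0("<contour_stack> %d slices, ISD %.3g mm, bifurcation at ",
                     "%.2f mm, z in [%.2f, %.2f] mm (%d CCA / %d ICA)\n"),
              length(z), x$isd, x$bifurcation_z, min(z), max(z),
              sum(z <= x$bifurcation_z + 1e-9),
              sum(z > x$bifurcation_z + 1e-9)))
  invisible(x)
}

#' Slice positions of a contour stack
#' @param stack a [contour_stack()].
#' @return numeric vector of z positions in mm.
#' @export
stack_z <- function(stack) vapply(stack$slices, function(s) s$z, 1)

slice_vessel <- function(z, bifurcation_z) {
  ifelse(z <= bifurcation_z + 1e-9, "CCA", "ICA")
}

#' Reslice a contour stack by shape-based interpolation
#'
#' Produces contours at every multiple of `target_step` (anchored at
#' `anchor`) inside the stack's z-range. Positions coinciding with original
#' slices keep the original contours; intermediate positions are obtained by
#' [interpolate_contour()] with `t` equal to the fractional position between
#' the bracketing slices.
#'
#' @param stack a [contour_stack()].
#' @param target_step new inter-slice distance in mm (must not exceed the
#'   stack's ISD).
#' @param anchor grid anchor in mm; defaults to the stack's bifurcation.
#' @param grid_spacing SDF grid spacing for the interpolation.
#' @return a [contour_stack()] with `isd = target_step`.
#' @export
reslice_stack <- function(stack, target_step, anchor = stack$bifurcation_z,
                          grid_spacing = 0.05) {
  if (target_step > stack$isd + 1e-9)
    stop("target_step must not exceed the stack ISD")
  reslice_any(stack, target_step, anchor, grid_spacing)
}

# reslicing onto an arbitrary grid (also coarser than the stack ISD, as
# needed when two stacks of different ISDs are brought onto a common grid)
reslice_any <- function(stack, target_step, anchor = stack$bifurcation_z,
                        grid_spacing = 0.05) {
  if (length(stack$slices) == 0L) stop("cannot reslice an empty stack")
  if (target_step <= 0) stop("target_step must be positive")
  z <- stack_z(stack)
  zmin <- min(z); zmax <- max(z)
  k <- seq(ceiling((zmin - anchor) / target_step - 1e-9),
           floor((zmax - anchor) / target_step + 1e-9))
  targets <- anchor + k * target_step
  out <- vector("list", length(targets))
  sdf_cache <- new.env(parent = emptyenv())
  for (i in seq_along(targets)) {
    zt <- targets[i]
    hit <- which(abs(z - zt) < 1e-6)
    if (length(hit)) { out[[i]] <- stack$slices[[hit[1L]]]; next }
    j <- findInterval(zt, z)
    t <- (zt - z[j]) / (z[j + 1L] - z[j])
    out[[i]] <- list(
      z = zt,
      mab = interp_cached(stack, j, "mab", t, zt, grid_spacing, sdf_cache),
      lib = interp_cached(stack, j, "lib", t, zt, grid_spacing, sdf_cache))
  }
  keep <- vapply(out, function(s) !is.null(s$mab) || !is.null(s$lib), TRUE)
  contour_stack(out[keep], stack$bifurcation_z, target_step, check = FALSE)
}

# interpolation with per-(pair, kind) SDF caching so a fine reslice reuses
# the two bracketing SDFs for all intermediate positions
interp_cached <- function(stack, j, kind, t, zt, grid_spacing, cache) {
  ca <- stack$slices[[j]][[kind]]
  cb <- stack$slices[[j + 1L]][[kind]]
  if (is.null(ca) || is.null(cb)) return(NULL)
  key <- sprintf("%d_%s", j, kind)
  ent <- if (exists(key, envir = cache)) get(key, envir = cache) else {
    bb <- joint_bounds(ca$points, cb$points, pad = 2)
    g <- grid_axes(bb, grid_spacing)
    e <- list(g = g, s1 = cpp_sdf_grid(ca$points, g$x, g$y),
              s2 = cpp_sdf_grid(cb$points, g$x, g$y))
    assign(key, e, envir = cache)
    e
  }
  p <- level_set_polygon((1 - t) * ent$s1 + t * ent$s2, ent$g$x, ent$g$y)
  if (is.null(p) || nrow(p) < 8L) {
    warning(sprintf(
      "interpolation failed between z = %.3f and %.3f (%s); slice skipped",
      ca$z, cb$z, kind))
    return(NULL)
  }
  src <- if (t <= 0.5) ca else cb
  tryCatch(
    contour(p, z = zt, kind = src$kind,
            vessel = slice_vessel(zt, stack$bifurcation_z), validate = FALSE),
    error = function(e) NULL)
}

# uniform arc-length resampling of a closed ring; optionally anchored at the
# intersection of the +x ray from `center` with the polygon
resample_ring <- function(p, n = NULL, step = NULL, center = NULL) {
  m <- nrow(p)
  pc <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums((pc[-1L, , drop = FALSE] - pc[-(m + 1L), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[m + 1L]
  s0 <- 0
  if (!is.null(center)) {
    s0 <- ray_arc_position(pc, cum, center)
  }
  if (is.null(n)) n <- max(8L, ceiling(L / step))
  s <- (s0 + (seq_len(n) - 1L) / n * L) %% L
  xi <- approx(cum, pc[, 1L], xout = s, rule = 2)$y
  yi <- approx(cum, pc[, 2L], xout = s, rule = 2)$y
  cbind(xi, yi, deparse.level = 0)
}

# arc-length position where the +x ray from `center` crosses the ring
ray_arc_position <- function(pc, cum, center) {
  m <- nrow(pc) - 1L
  best_t <- Inf; best_s <- 0
  for (i in seq_len(m)) {
    a <- pc[i, ]; b <- pc[i + 1L, ]
    dy <- b[2L] - a[2L]
    if (abs(dy) < 1e-15) next
    u <- (center[2L] - a[2L]) / dy
    if (u < 0 || u > 1) next
    x <- a[1L] + u * (b[1L] - a[1L])
    t <- x - center[1L]
    if (t > 0 && t < best_t) {
      best_t <- t
      best_s <- cum[i] + u * (cum[i + 1L] - cum[i])
    }
  }
  best_s
}
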