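# Slice preprocessing, training-set construction/augmentation, flip-ensemble
# inference, ICA region-of-interest propagation, and volume segmentation.

#' Preprocess an axial slice for the network
#'
#' Bilinear resampling to the fixed network input size followed by min-max
#' normalization to \[0, 1\].
#'
#' @param image numeric matrix (any size).
#' @param size target `c(rows, cols)`; default 192 x 256.
#' @return normalized matrix of dimension `size`.
#' @export
preprocess <- function(image, size = c(192L, 256L)) {
  rng <- range(image)
  if (rng[2L] - rng[1L] < 1e-12) stop("constant image cannot be normalized")
  out <- resize_bilinear(image, size[1L], size[2L])
  (out - min(out)) / (max(out) - min(out))
}

resize_bilinear <- function(image, nr, nc) {
  # clamp to the source extent so border pixels replicate instead of
  # falling into the out-of-range fill
  ri <- pmin(pmax((seq_len(nr) - 0.5) * nrow(image) / nr + 0.5, 1),
             nrow(image))
  ci <- pmin(pmax((seq_len(nc) - 0.5) * ncol(image) / nc + 0.5, 1),
             ncol(image))
  g <- expand.grid(r = ri, c = ci)
  matrix(cpp_bilinear_sample(image, g$r, g$c, 0), nr, nc)
}

resize_nearest <- function(image, nr, nc) {
  ri <- pmin(pmax((seq_len(nr) - 0.5) * nrow(image) / nr + 0.5, 1),
             nrow(image))
  ci <- pmin(pmax((seq_len(nc) - 0.5) * ncol(image) / nc + 0.5, 1),
             ncol(image))
  g <- expand.grid(r = ri, c = ci)
  matrix(cpp_nearest_sample(image, g$r, g$c, 0), nr, nc)
}

# affine warp about the image centre; bilinear for images, nearest for labels
warp_affine <- function(image, angle = 0, shift = c(0, 0), nearest = FALSE) {
  nr <- nrow(image); nc <- ncol(image)
  cr <- (nr + 1) / 2; ccol <- (nc + 1) / 2
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  # inverse mapping: rotate target coords back, then un-shift
  th <- -angle * pi / 180
  rr <- g$r - cr - shift[1L]; cc <- g$c - ccol - shift[2L]
  rs <- cr + cos(th) * rr - sin(th) * cc
  cs <- ccol + sin(th) * rr + cos(th) * cc
  v <- if (nearest) cpp_nearest_sample(image, rs, cs, 0)
  else cpp_bilinear_sample(image, rs, cs, 0)
  matrix(v, nr, nc)
}

flip_h <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
flip_v <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

apply_to_labels <- function(labels, f) {
  out <- labels
  for (k in seq_len(dim(labels)[3L])) out[, , k] <- f(labels[, , k])
  out
}

# random flip/translate/rotate applied identically to image and labels
augment_sample <- function(sample, switches = list(flip = TRUE,
                                                   translate = TRUE,
                                                   rotate = TRUE)) {
  img <- sample$image; lab <- sample$labels
  if (isTRUE(switches$flip)) {
    if (runif(1) < 0.5) { img <- flip_h(img); lab <- apply_to_labels(lab, flip_h) }
    if (runif(1) < 0.5) { img <- flip_v(img); lab <- apply_to_labels(lab, flip_v) }
  }
  angle <- if (isTRUE(switches$rotate)) runif(1, -15, 15) else 0
  shift <- if (isTRUE(switches$translate))
    c(runif(1, -0.1, 0.1) * nrow(img), runif(1, -0.1, 0.1) * ncol(img))
  else c(0, 0)
  if (angle != 0 || any(shift != 0)) {
    img <- warp_affine(img, angle, shift)
    lab <- apply_to_labels(lab, function(m)
      warp_affine(m, angle, shift, nearest = TRUE))
  }
  list(image = img, labels = lab)
}

#' Build network training samples from one phantom case
#'
#' Reslices the given contour stack (typically the manual/ground-truth
#' segmentation at the working ISD) to `reslice_step` by shape-based
#' interpolation, rasterizes the MAB/LIB labels on the volume pixel grid of
#' each slice, and preprocesses image and labels to the network input size.
#'
#' @param case a `phantom_case` with a rendered volume.
#' @param stack contour stack supervising the training; defaults to the
#'   case's ground truth.
#' @param reslice_step longitudinal reslicing step in mm (default 0.5).
#' @param size network input size `c(rows, cols)`.
#' @param slice_stride keep every `slice_stride`-th resliced position
#'   (for scaled-down training runs).
#' @return list of `list(image, labels, z)` samples.
#' @export
make_slide_samples <- function(case, stack = case$truth, reslice_step = 0.5,
                               size = c(192L, 256L), slice_stride = 1L) {
  if (is.null(case$volume)) stop("case has no rendered volume")
  rs <- if (abs(reslice_step - stack$isd) < 1e-9) stack
  else reslice_stack(stack, reslice_step)
  vol <- case$volume
  zs <- stack_z(rs)
  keep <- seq(1L, length(zs), by = slice_stride)
  out <- list()
  for (i in keep) {
    s <- rs$slices[[i]]
    if (is.null(s$mab) || is.null(s$lib)) next
    sl <- volume_slice(vol, s$z)
    xs <- sl$x0 + (seq_len(nrow(sl$image)) - 1L) * sl$dx
    ys <- sl$y0 + (seq_len(ncol(sl$image)) - 1L) * sl$dy
    mab <- cpp_pip_mask(s$mab$points, xs, ys)
    lib <- cpp_pip_mask(s$lib$points, xs, ys)
    img <- preprocess(sl$image, size)
    lab <- array(0, dim = c(size[1L], size[2L], 2L))
    lab[, , 1L] <- resize_nearest(mab + 0, size[1L], size[2L])
    lab[, , 2L] <- resize_nearest(lib + 0, size[1L], size[2L])
    out[[length(out) + 1L]] <- list(image = img, labels = lab, z = s$z)
  }
  out
}

#' Assemble (and statically augment) a training set from several cases
#'
#' @param cases list of `phantom_case` objects.
#' @param hflip,vflip append horizontally / vertically flipped copies
#'   (doubling / quadrupling the sample count).
#' @param ... passed to [make_slide_samples()].
#' @return list of training samples for [unet_fit()].
#' @export
augment_training_set <- function(cases, hflip = FALSE, vflip = FALSE, ...) {
  samples <- do.call(c, lapply(cases, make_slide_samples, ...))
  if (hflip)
    samples <- c(samples, lapply(samples, function(s)
      list(image = flip_h(s$image),
           labels = apply_to_labels(s$labels, flip_h), z = s$z)))
  if (vflip)
    samples <- c(samples, lapply(samples, function(s)
      list(image = flip_v(s$image),
           labels = apply_to_labels(s$labels, flip_v), z = s$z)))
  samples
}

# per-pixel majority vote of three thresholded probability maps
vote_majority <- function(p1, p2, p3, threshold = 0.5) {
  (((p1 > threshold) + (p2 > threshold) + (p3 > threshold)) >= 2) + 0
}

# run the model on a list of images; `model` may be a fitted carotid_unet or
# a function(image, z) returning an H x W x 2 probability array (used e.g.
# for oracle substitution in harness tests)
model_predict <- function(model, images, z = NULL) {
  if (is.function(model)) lapply(images, model, z = z)
  else predict(model, images)
}

#' Flip-ensemble (test-time augmentation) prediction
#'
#' Predicts on the original, horizontally flipped and vertically flipped
#' image, un-flips the latter two, thresholds each at 0.5, and takes a
#' per-pixel, per-channel majority vote.
#'
#' @param model a fitted `carotid_unet`, or a function `(image, z)`
#'   returning an H x W x 2 probability array.
#' @param image preprocessed input matrix.
#' @param threshold probability threshold (default 0.5).
#' @param z slice position, forwarded to function models.
#' @return list with binary matrices `mab` and `lib`.
#' @export
predict_with_flip_ensemble <- function(model, image, threshold = 0.5,
                                       z = NULL) {
  preds <- model_predict(model, list(image, flip_h(image), flip_v(image)), z)
  vote <- function(ch) {
    vote_majority(preds[[1L]][, , ch], flip_h(preds[[2L]][, , ch]),
                  flip_v(preds[[3L]][, , ch]), threshold)
  }
  list(mab = vote(1L), lib = vote(2L))
}

#' Linearly interpolated ICA region-of-interest boxes
#'
#' Given the manually identified boxes on the ICA slices closest to and
#' furthest from the bifurcation, each box corner is linearly interpolated
#' in z for the remaining ICA slices.
#'
#' @param first_box,last_box boxes `c(xmin, xmax, ymin, ymax)` in mm at
#'   `z_range[1]` and `z_range[2]`.
#' @param z ICA slice positions (>= 2 slices).
#' @param z_range z of the two given boxes; defaults to `range(z)`.
#' @return matrix with one row per slice: `z, xmin, xmax, ymin, ymax`.
#' @export
ica_roi_boxes <- function(first_box, last_box, z, z_range = range(z)) {
  if (length(z) < 2L) stop("need at least 2 ICA slices")
  if (diff(z_range) <= 0) stop("z_range must be increasing")
  t <- (z - z_range[1L]) / (z_range[2L] - z_range[1L])
  out <- cbind(z = z,
               xmin = first_box[["xmin"]] + t * (last_box[["xmin"]] - first_box[["xmin"]]),
               xmax = first_box[["xmax"]] + t * (last_box[["xmax"]] - first_box[["xmax"]]),
               ymin = first_box[["ymin"]] + t * (last_box[["ymin"]] - first_box[["ymin"]]),
               ymax = first_box[["ymax"]] + t * (last_box[["ymax"]] - first_box[["ymax"]]))
  out
}

# extract the largest-component 0.5 level set of a binary mask defined on
# physical coordinates xs x ys; returns an n x 2 polygon or NULL
mask_to_polygon <- function(mask, xs, ys, smooth_px = 1) {
  if (sum(mask) < 8) return(NULL)
  mm <- cpp_largest_component(matrix(as.integer(mask > 0), nrow(mask)))
  sm <- cpp_gauss_blur(mm + 0, smooth_px)
  p <- tryCatch(level_set_polygon(sm, xs, ys, level = 0.5,
                                  warn_multi = FALSE),
                error = function(e) NULL)
  if (!is.null(p) && nrow(p) < 8L) p <- NULL
  p
}

# radial profile of a star-shaped polygon about `center`
radial_profile <- function(p, center, thetas) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
  ax <- a[, 1L] - center[1L]; ay <- a[, 2L] - center[2L]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  r <- numeric(length(thetas))
  for (i in seq_along(thetas)) {
    dx <- cos(thetas[i]); dy <- sin(thetas[i])
    den <- ex * dy - ey * dx
    u <- (ay * dx - ax * dy) / den
    tt <- (ax + u * ex) * dx + (ay + u * ey) * dy
    ok <- is.finite(u) & abs(den) > 1e-15 & u >= 0 & u <= 1 & tt > 0
    r[i] <- if (any(ok)) max(tt[ok]) else NA_real_
  }
  r
}

# clip a LIB polygon radially inside a MAB polygon (margin in mm)
clip_inside <- function(lib_p, mab_p, margin = 0.05, n_theta = 96) {
  ctr <- polygon_centroid(mab_p)
  thetas <- (seq_len(n_theta) - 1L) / n_theta * 2 * pi
  rm <- radial_profile(mab_p, ctr, thetas)
  rl <- radial_profile(lib_p, ctr, thetas)
  if (anyNA(rm) || anyNA(rl)) return(lib_p)
  r <- pmax(pmin(rl, rm - margin), 0.05)
  cbind(ctr[1L] + r * cos(thetas), ctr[2L] + r * sin(thetas))
}

#' Segment a 3DUS volume into a contour stack
#'
#' For each axial slice at the working ISD around the given bifurcation:
#' preprocess, flip-ensemble predict, apply the (interpolated) ICA
#' region-of-interest box on ICA slices, keep the largest connected
#' component per channel, extract the boundary contour, and clip the LIB
#' inside the MAB. The bifurcation position and the two ICA boxes are user
#' inputs, mirroring the manual interactions of the workflow.
#'
#' @param model a fitted `carotid_unet`, or a function `(image, z)`
#'   returning an H x W x 2 probability array.
#' @param volume a `volume3d`.
#' @param bifurcation_z bifurcation position in mm.
#' @param ica_boxes list with `first`, `last` boxes and `z = c(z_first,
#'   z_last)` as from [truth_ica_boxes()], or `NULL` to skip ROI masking.
#' @param isd working inter-slice distance in mm.
#' @param coverage `c(proximal, distal)` coverage in mm.
#' @param size network input size.
#' @param tta use the flip-ensemble majority vote (`FALSE` gives a single
#'   thresholded forward pass).
#' @return a [contour_stack()]; slices with an empty or degenerate
#'   prediction are omitted and listed in `attr(, "missing_z")`.
#' @export
segment_volume <- function(model, volume, bifurcation_z, ica_boxes = NULL,
                           isd = 1, coverage = c(15, 10),
                           size = c(192L, 256L), tta = TRUE) {
  zv <- volume$origin[3L] + (seq_len(dim(volume$voxels)[3L]) - 1L) *
    volume$spacing[3L]
  zlo <- max(bifurcation_z - coverage[1L], min(zv))
  zhi <- min(bifurcation_z + coverage[2L], max(zv))
  z <- c(rev(seq(bifurcation_z, zlo + 1e-9, by = -isd)),
         seq(bifurcation_z + isd, zhi + 1e-9, by = isd))
  ica_z <- z[z > bifurcation_z + 1e-9]
  boxes <- NULL
  if (!is.null(ica_boxes) && length(ica_z) >= 2L)
    boxes <- ica_roi_boxes(ica_boxes$first, ica_boxes$last, ica_z,
                           z_range = ica_boxes$z)
  slices <- list()
  missing_z <- numeric()
  for (zz in z) {
    sl <- volume_slice(volume, zz)
    xs_vox <- sl$x0 + (seq_len(nrow(sl$image)) - 1L) * sl$dx
    ys_vox <- sl$y0 + (seq_len(ncol(sl$image)) - 1L) * sl$dy
    img <- preprocess(sl$image, size)
    pred <- if (tta) predict_with_flip_ensemble(model, img, z = zz)
    else {
      pr <- model_predict(model, list(img), z = zz)[[1L]]
      list(mab = (pr[, , 1L] > 0.5) + 0, lib = (pr[, , 2L] > 0.5) + 0)
    }
    # network-frame pixel centres in mm
    xs <- sl$x0 + ((seq_len(size[1L]) - 0.5) * nrow(sl$image) / size[1L] -
                     0.5) * sl$dx
    ys <- sl$y0 + ((seq_len(size[2L]) - 0.5) * ncol(sl$image) / size[2L] -
                     0.5) * sl$dy
    if (!is.null(boxes) && zz > bifurcation_z + 1e-9) {
      b <- boxes[which.min(abs(boxes[, "z"] - zz)), ]
      if (b[["xmin"]] < min(xs_vox) - 5 || b[["xmax"]] > max(xs_vox) + 5 ||
          b[["ymin"]] < min(ys_vox) - 5 || b[["ymax"]] > max(ys_vox) + 5)
        stop("ICA box lies outside the image")
      inx <- xs >= b[["xmin"]] & xs <= b[["xmax"]]
      iny <- ys >= b[["ymin"]] & ys <= b[["ymax"]]
      roi <- outer(inx, iny)
      pred$mab <- pred$mab * roi
      pred$lib <- pred$lib * roi
    }
    pm <- mask_to_polygon(pred$mab, xs, ys)
    pl <- mask_to_polygon(pred$lib, xs, ys)
    if (is.null(pm) || is.null(pl)) {
      missing_z <- c(missing_z, zz)
      next
    }
    pl <- clip_inside(pl, pm)
    vessel <- slice_vessel(zz, bifurcation_z)
    cm <- tryCatch(contour(pm, z = zz, kind = "MAB", vessel = vessel,
                           validate = FALSE), error = function(e) NULL)
    cl <- tryCatch(contour(pl, z = zz, kind = "LIB", vessel = vessel,
                           validate = FALSE), error = function(e) NULL)
    if (is.null(cm) || is.null(cl)) {
      missing_z <- c(missing_z, zz)
      next
    }
    slices[[length(slices) + 1L]] <- list(z = zz, mab = cm, lib = cl)
  }
  if (length(slices) == 0L) stop("no slice produced a valid segmentation")
  st <- contour_stack(slices, bifurcation_z, isd, check = FALSE)
  attr(st, "missing_z") <- missing_z
  st
}
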