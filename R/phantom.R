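# Synthetic carotid phantom: bifurcating geometry, speckle-textured 3DUS-like
# volumes, exact ground-truth contour stacks, baseline/follow-up cohorts and a
# virtual observer emulating repeated manual segmentation.

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom generator parameters
#'
#' Defaults emulate the study anatomy: a common carotid artery (CCA) covered
#' 15 mm proximal to the bifurcation and an internal carotid artery (ICA)
#' 10 mm distal, with an external carotid (ECA) rendered as a distractor;
#' MAB radii lognormal around 3.5 mm, wall thickness around 1 mm (putting
#' the LIB near 2.5 mm), 0-3 plaques per artery as smooth inward wall
#' thickening, and voxels of 0.21 x 0.21 x 0.35 mm.
#'
#' @param spacing voxel spacing (Vx, Vy, Vz) in mm.
#' @param coverage c(proximal CCA, distal ICA) coverage in mm.
#' @param mab_meanlog,mab_sdlog lognormal parameters of the CCA MAB radius.
#' @param wall_meanlog,wall_sdlog lognormal parameters of wall thickness (mm).
#' @param max_plaques maximum number of baseline plaques per artery.
#' @param plaque_thickness range (mm) of maximum plaque thickness.
#' @param plaque_zext,plaque_text ranges of plaque longitudinal half-extent
#'   (mm) and angular half-extent (rad).
#' @param p_calcified probability a plaque is calcified (casts a shadow).
#' @param progression_scale scales follow-up progression; 0 gives a
#'   follow-up geometry identical to baseline.
#' @param p_new_plaque probability of one new small plaque at follow-up.
#' @param intensities named tissue-class means (arbitrary units in \[0, 1\]).
#' @param speckle_shape gamma shape of the multiplicative speckle (mean 1).
#' @param blur_sigma in-plane Gaussian blur in mm.
#' @param shadow_factor intensity multiplier inside calcification shadows.
#' @return list of parameters for [sample_cohort()] and [render_volume()].
#' @export
phantom_params <- function(spacing = c(0.21, 0.21, 0.35),
                           coverage = c(15, 10),
                           mab_meanlog = log(3.5), mab_sdlog = 0.10,
                           wall_meanlog = log(1.0), wall_sdlog = 0.15,
                           max_plaques = 3,
                           plaque_thickness = c(0.5, 2.0),
                           plaque_zext = c(1.5, 4.0),
                           plaque_text = c(0.5, 1.1),
                           p_calcified = 0.25,
                           progression_scale = 1,
                           p_new_plaque = 0.3,
                           intensities = c(lumen = 0.10, wall = 0.65,
                                           background = 0.35,
                                           calcification = 0.95),
                           speckle_shape = 4,
                           blur_sigma = 0.25,
                           shadow_factor = 0.35) {
  as.list(environment())
}

# smooth C1 bump: cos^2 window on |u| <= 1
bump1 <- function(u) ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)

ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Draw one synthetic carotid geometry
#'
#' @param params from [phantom_params()].
#' @param bifurcation_z bifurcation position in mm (default drawn near 15.5).
#' @return object of class `carotid_geometry` with smooth centerlines,
#'   per-branch MAB radius and wall-thickness functions, and a plaque list.
#' @export
sample_geometry <- function(params = phantom_params(), bifurcation_z = NULL) {
  if (is.null(bifurcation_z)) bifurcation_z <- 15.2 + runif(1, 0, 0.6)
  r_cca <- rlnorm(1, params$mab_meanlog, params$mab_sdlog)
  wall <- rlnorm(1, params$wall_meanlog, params$wall_sdlog)
  wall <- max(wall, 0.5)
  mk_branch <- function(r0, r_slope, wall, dir) {
    list(c0 = c(0, 0), dir = dir,
         wob_amp = runif(1, 0, 0.25), wob_phase = runif(1, 0, 2 * pi),
         r0 = r0, r_slope = r_slope, wall = wall,
         amp2 = rnorm(1, 0, 0.025), ph2 = runif(1, 0, 2 * pi),
         amp3 = rnorm(1, 0, 0.02), ph3 = runif(1, 0, 2 * pi))
  }
  cca <- mk_branch(r_cca, runif(1, -0.01, 0.02), wall,
                   dir = c(runif(1, -0.05, 0.05), runif(1, -0.05, 0.05)))
  ica <- mk_branch(r_cca * runif(1, 0.78, 0.9), -runif(1, 0.01, 0.03),
                   wall * runif(1, 0.9, 1.05),
                   dir = c(runif(1, 0.25, 0.45), runif(1, -0.1, 0.1)))
  eca <- mk_branch(r_cca * runif(1, 0.5, 0.6), -runif(1, 0.01, 0.02),
                   wall * 0.8,
                   dir = c(-runif(1, 0.25, 0.4), runif(1, -0.1, 0.1)))
  n_pl <- sample(0:params$max_plaques, 1)
  plaques <- list()
  for (i in seq_len(n_pl)) {
    branch <- sample(c("CCA", "ICA"), 1, prob = c(0.6, 0.4))
    zc <- if (branch == "CCA")
      bifurcation_z - runif(1, 0, params$coverage[1L])
    else bifurcation_z + runif(1, 0.5, params$coverage[2L])
    plaques[[i]] <- list(
      branch = branch, z_center = zc,
      theta_center = runif(1, 0, 2 * pi),
      z_extent = runif(1, params$plaque_zext[1L], params$plaque_zext[2L]),
      theta_extent = runif(1, params$plaque_text[1L], params$plaque_text[2L]),
      max_thickness = runif(1, params$plaque_thickness[1L],
                            params$plaque_thickness[2L]),
      calcified = runif(1) < params$p_calcified)
  }
  structure(list(bifurcation_z = bifurcation_z, coverage = params$coverage,
                 branches = list(CCA = cca, ICA = ica, ECA = eca),
                 plaques = plaques),
            class = "carotid_geometry")
}

# follow-up = baseline + plaque growth (+ possibly one new small plaque)
progress_geometry <- function(geom, params) {
  s <- params$progression_scale
  g <- geom
  g$plaques <- lapply(geom$plaques, function(p) {
    p$max_thickness <- p$max_thickness * (1 + s * runif(1, 0.05, 0.35))
    p$z_extent <- p$z_extent * (1 + s * runif(1, 0, 0.15))
    p
  })
  if (s > 0 && runif(1) < params$p_new_plaque) {
    branch <- sample(c("CCA", "ICA"), 1)
    zc <- if (branch == "CCA")
      geom$bifurcation_z - runif(1, 0, params$coverage[1L])
    else geom$bifurcation_z + runif(1, 0.5, params$coverage[2L])
    g$plaques[[length(g$plaques) + 1L]] <- list(
      branch = branch, z_center = zc,
      theta_center = runif(1, 0, 2 * pi),
      z_extent = runif(1, 1.0, 2.0),
      theta_extent = runif(1, 0.4, 0.8),
      max_thickness = s * runif(1, 0.3, 0.8),
      calcified = FALSE)
  }
  g
}

branch_center <- function(br, z, dz) {
  # dz: signed distance from the bifurcation along z
  c(br$c0[1L] + br$dir[1L] * dz + br$wob_amp * sin(dz / 6 + br$wob_phase),
    br$c0[2L] + br$dir[2L] * dz + br$wob_amp * cos(dz / 7 + br$wob_phase))
}

branch_mab_radius <- function(br, dz, theta) {
  pmax(0.8, br$r0 * (1 + br$r_slope * dz) *
         (1 + br$amp2 * cos(2 * (theta - br$ph2)) +
            br$amp3 * cos(3 * (theta - br$ph3))))
}

branch_wall <- function(geom, branch_name, br, z, theta) {
  w <- rep(br$wall, length(theta))
  for (p in geom$plaques) {
    if (p$branch != branch_name) next
    w <- w + p$max_thickness * bump1((z - p$z_center) / p$z_extent) *
      bump1(ang_diff(theta, p$theta_center) / p$theta_extent)
  }
  w
}

geom_branch_at <- function(geom, z) {
  if (z <= geom$bifurcation_z + 1e-9) "CCA" else "ICA"
}

#' Ground-truth contour of a phantom geometry at one slice
#'
#' Evaluates the geometry's radius functions exactly; the branch is the CCA
#' at and proximal to the bifurcation and the ICA distal to it.
#'
#' @param geom a [sample_geometry()] object.
#' @param z slice position in mm.
#' @param kind `"MAB"` or `"LIB"`.
#' @param n_theta number of boundary points.
#' @param vessel branch label to evaluate; defaults by `z`.
#' @return a [contour()].
#' @export
truth_contour <- function(geom, z, kind = c("MAB", "LIB"), n_theta = 96,
                          vessel = NULL) {
  kind <- match.arg(kind)
  if (is.null(vessel)) vessel <- geom_branch_at(geom, z)
  br <- geom$branches[[vessel]]
  dz <- z - geom$bifurcation_z
  theta <- (seq_len(n_theta) - 1L) / n_theta * 2 * pi
  rm <- branch_mab_radius(br, dz, theta)
  r <- if (kind == "MAB") rm else
    pmax(rm - branch_wall(geom, vessel, br, z, theta), 0.25)
  ctr <- branch_center(br, z, dz)
  contour(cbind(ctr[1L] + r * cos(theta), ctr[2L] + r * sin(theta)),
          z = z, kind = kind, vessel = vessel, validate = FALSE)
}

#' Ground-truth contour stack of a phantom geometry
#'
#' Slices at multiples of `isd` anchored at the bifurcation, covering the
#' configured proximal CCA and distal ICA extents.
#'
#' @param geom a [sample_geometry()] object.
#' @param isd inter-slice distance in mm.
#' @param n_theta boundary points per contour.
#' @return a [contour_stack()].
#' @export
truth_stack <- function(geom, isd, n_theta = 96) {
  bz <- geom$bifurcation_z
  z <- c(rev(seq(bz, bz - geom$coverage[1L] + 1e-9, by = -isd)),
         seq(bz + isd, bz + geom$coverage[2L] + 1e-9, by = isd))
  slices <- lapply(z, function(zz) list(
    z = zz,
    mab = truth_contour(geom, zz, "MAB", n_theta),
    lib = truth_contour(geom, zz, "LIB", n_theta)))
  contour_stack(slices, bz, isd, check = FALSE)
}

#' Render a 3DUS-like volume from a phantom geometry
#'
#' Tissue-class means (dark lumen, bright wall, mid background) modulated by
#' multiplicative gamma speckle and an in-plane Gaussian blur. Calcified
#' plaques render as a bright arc with an intensity-dropout shadow cast
#' along the beam (+y) direction.
#'
#' @param geom a [sample_geometry()] object.
#' @param params from [phantom_params()].
#' @param speckle,blur,shadows feature switches.
#' @return object of class `volume3d`: `voxels` array indexed `[x, y, z]`,
#'   `spacing`, `origin` (mm of the centre of voxel \[1, 1, 1\]).
#' @export
render_volume <- function(geom, params = phantom_params(), speckle = TRUE,
                          blur = TRUE, shadows = TRUE) {
  sp <- params$spacing
  if (any(sp <= 0)) stop("voxel spacing must be positive")
  bz <- geom$bifurcation_z
  z0 <- bz - geom$coverage[1L] - 2 * sp[3L]
  z1 <- bz + geom$coverage[2L] + 2 * sp[3L]
  # lateral field of view from the centerline excursions plus margin
  zs <- seq(z0, z1, length.out = 24)
  ctrs <- do.call(rbind, lapply(zs, function(z) {
    nm <- if (z <= bz) "CCA" else c("ICA", "ECA")
    do.call(rbind, lapply(nm, function(b)
      branch_center(geom$branches[[b]], z, z - bz)))
  }))
  rmax <- max(vapply(geom$branches, function(b) b$r0, 1)) + 2.5
  xr <- range(ctrs[, 1L]) + c(-rmax - 2, rmax + 2)
  yr <- range(ctrs[, 2L]) + c(-rmax - 2, rmax + 2)
  nx <- ceiling(diff(xr) / sp[1L]); ny <- ceiling(diff(yr) / sp[2L])
  nz <- floor((z1 - z0) / sp[3L]) + 1L
  origin <- c(xr[1L], yr[1L], z0)
  xs <- origin[1L] + (seq_len(nx) - 1L) * sp[1L]
  ys <- origin[2L] + (seq_len(ny) - 1L) * sp[2L]
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  ints <- params$intensities
  vox <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    z <- z0 + (k - 1L) * sp[3L]
    nm <- if (z <= bz) "CCA" else c("ICA", "ECA")
    img <- matrix(ints[["background"]], nx, ny)
    wall_any <- lumen_any <- matrix(FALSE, nx, ny)
    calc_any <- shadow_any <- matrix(FALSE, nx, ny)
    for (b in nm) {
      br <- geom$branches[[b]]
      dz <- z - bz
      ctr <- branch_center(br, z, dz)
      dx <- X - ctr[1L]; dy <- Y - ctr[2L]
      r <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      rm <- branch_mab_radius(br, dz, th)
      rl <- pmax(rm - branch_wall(geom, b, br, z, th), 0.25)
      wall_any <- wall_any | (r <= rm & r > rl)
      lumen_any <- lumen_any | (r <= rl)
      for (p in geom$plaques) {
        if (p$branch != b || !p$calcified) next
        bz_w <- bump1((z - p$z_center) / p$z_extent)
        if (bz_w < 0.3) next
        in_arc <- abs(ang_diff(th, p$theta_center)) < p$theta_extent * 0.6
        calc_any <- calc_any | (in_arc & r > rl & r <= rl + 0.5)
        shadow_any <- shadow_any |
          (in_arc & dy > 0 & r > rl + 0.5)
      }
    }
    img[wall_any] <- ints[["wall"]]
    img[lumen_any] <- ints[["lumen"]]
    if (shadows) {
      img[calc_any] <- ints[["calcification"]]
      img[shadow_any & !calc_any] <- img[shadow_any & !calc_any] *
        params$shadow_factor
    }
    if (speckle)
      img <- img * matrix(rgamma(nx * ny, shape = params$speckle_shape,
                                 rate = params$speckle_shape), nx, ny)
    if (blur) img <- cpp_gauss_blur(img, params$blur_sigma / sp[1L])
    vox[, , k] <- img
  }
  vox <- pmin(pmax(vox, 0), 2)
  structure(list(voxels = vox, spacing = sp, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  invisible(x)
}

# axial slice at arbitrary z by linear interpolation between stored slices
volume_slice <- function(vol, z) {
  nz <- dim(vol$voxels)[3L]
  k <- (z - vol$origin[3L]) / vol$spacing[3L] + 1
  k0 <- max(1L, min(nz, floor(k)))
  k1 <- min(nz, k0 + 1L)
  f <- min(max(k - k0, 0), 1)
  img <- (1 - f) * vol$voxels[, , k0] + f * vol$voxels[, , k1]
  list(image = img,
       x0 = vol$origin[1L], y0 = vol$origin[2L],
       dx = vol$spacing[1L], dy = vol$spacing[2L])
}

#' Generate a synthetic baseline/follow-up cohort
#'
#' Each synthetic patient gets a baseline geometry drawn from the parameter
#' distributions in [phantom_params()] and a follow-up geometry equal to
#' baseline plus plaque progression (growth and possibly one new plaque).
#' Both are rendered (optionally) and paired with exact ground-truth contour
#' stacks at the longitudinal voxel size Vz.
#'
#' @param n_patients number of patients (>= 1).
#' @param params from [phantom_params()].
#' @param seed RNG seed; the cohort is fully reproducible from it.
#' @param render render image volumes (set `FALSE` for contour-only studies).
#' @return list (one element per patient) of
#'   `list(baseline = , followup = )` `phantom_case` objects with fields
#'   `patient_id`, `timepoint`, `geometry`, `volume`, `truth`,
#'   `bifurcation_z`.
#' @export
sample_cohort <- function(n_patients, params = phantom_params(), seed = 1,
                          render = TRUE) {
  if (n_patients < 1) stop("n_patients must be at least 1")
  with_seed(seed, {
    lapply(seq_len(n_patients), function(pid) {
      g0 <- sample_geometry(params)
      g1 <- progress_geometry(g0, params)
      mk <- function(g, tp) {
        structure(list(patient_id = pid, timepoint = tp, geometry = g,
                       volume = if (render) render_volume(g, params) else NULL,
                       truth = truth_stack(g, params$spacing[3L]),
                       bifurcation_z = g$bifurcation_z),
                  class = "phantom_case")
      }
      list(baseline = mk(g0, "baseline"), followup = mk(g1, "followup"))
    })
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> patient %d, %s: bifurcation %.2f mm, %d plaques%s\n",
              x$patient_id, x$timepoint, x$bifurcation_z,
              length(x$geometry$plaques),
              if (is.null(x$volume)) " (not rendered)" else ""))
  invisible(x)
}

#' Virtual observer model
#'
#' Emulates repeated manual segmentation: the bifurcation is localized with
#' an ISD-dependent jitter (larger inter-slice distances make the topology
#' change harder to pin down) and contours are perturbed by smooth radial
#' noise built from low-order Fourier harmonics. The parameters are stand-in
#' choices, not estimates of any particular human observer.
#'
#' @param radial_noise_sd SD of the radial boundary perturbation in mm.
#' @param harmonics highest angular harmonic of the perturbation.
#' @param bifurcation_sd_per_isd named vector mapping ISD (mm, as names) to
#'   the SD (mm) of the bifurcation localization jitter.
#' @return list of class `observer_model`.
#' @export
observer_model <- function(radial_noise_sd = 0.15, harmonics = 6,
                           bifurcation_sd_per_isd = c("1" = 0.2, "2" = 0.3,
                                                      "3" = 0.6)) {
  structure(list(radial_noise_sd = radial_noise_sd, harmonics = harmonics,
                 bifurcation_sd_per_isd = bifurcation_sd_per_isd),
            class = "observer_model")
}

# smooth angular noise: truncated Fourier series with Gaussian coefficients,
# scaled so the pointwise SD equals `sd`
fourier_noise <- function(theta, sd, harmonics) {
  if (sd <= 0) return(rep(0, length(theta)))
  tau <- sd / sqrt(harmonics + 1)
  f <- rnorm(1, 0, tau)
  for (h in seq_len(harmonics))
    f <- f + rnorm(1, 0, tau) * cos(h * theta) +
      rnorm(1, 0, tau) * sin(h * theta)
  f
}

#' Simulate one manual segmentation trial
#'
#' Draws a jittered bifurcation position (rounded to the axial voxel grid),
#' samples the ground-truth geometry at slice positions spaced `isd` from
#' the jittered bifurcation (15 mm proximal, 10 mm distal, truncated to the
#' phantom's coverage with a warning), and perturbs each contour with smooth
#' radial noise, clipping the LIB inside the MAB.
#'
#' @param case a `phantom_case`.
#' @param isd inter-slice distance in mm (the study used 1, 2 and 3).
#' @param model an [observer_model()].
#' @param trial_seed RNG seed of this trial.
#' @param n_theta boundary points per contour.
#' @return a [contour_stack()].
#' @export
virtual_observer <- function(case, isd, model = observer_model(),
                             trial_seed = 1, n_theta = 96) {
  geom <- case$geometry
  vz <- 0.35
  if (!is.null(case$volume)) vz <- case$volume$spacing[3L]
  bsd <- model$bifurcation_sd_per_isd[[as.character(isd)]]
  if (is.null(bsd) || is.na(bsd)) bsd <- 0.2 * isd
  with_seed(trial_seed, {
    jb <- geom$bifurcation_z + round(rnorm(1, 0, bsd) / vz) * vz
    zlo <- jb - geom$coverage[1L]; zhi <- jb + geom$coverage[2L]
    glo <- geom$bifurcation_z - geom$coverage[1L]
    ghi <- geom$bifurcation_z + geom$coverage[2L]
    if (zlo < glo - 1e-9 || zhi > ghi + 1e-9) {
      warning("jittered coverage truncated to the phantom extent")
      zlo <- max(zlo, glo); zhi <- min(zhi, ghi)
    }
    z <- c(rev(seq(jb, zlo + 1e-9, by = -isd)),
           seq(jb + isd, zhi + 1e-9, by = isd))
    theta <- (seq_len(n_theta) - 1L) / n_theta * 2 * pi
    slices <- lapply(z, function(zz) {
      vessel_geom <- geom_branch_at(geom, zz)
      br <- geom$branches[[vessel_geom]]
      dz <- zz - geom$bifurcation_z
      ctr <- branch_center(br, zz, dz)
      rm <- branch_mab_radius(br, dz, theta) +
        fourier_noise(theta, model$radial_noise_sd, model$harmonics)
      rl <- pmax(branch_mab_radius(br, dz, theta) -
                   branch_wall(geom, vessel_geom, br, zz, theta), 0.25) +
        fourier_noise(theta, model$radial_noise_sd, model$harmonics)
      rm <- pmax(rm, 0.4)
      rl <- pmax(pmin(rl, rm - 0.05), 0.2)
      vessel <- slice_vessel(zz, jb)
      list(z = zz,
           mab = contour(cbind(ctr[1L] + rm * cos(theta),
                               ctr[2L] + rm * sin(theta)),
                         z = zz, kind = "MAB", vessel = vessel,
                         validate = FALSE),
           lib = contour(cbind(ctr[1L] + rl * cos(theta),
                               ctr[2L] + rl * sin(theta)),
                         z = zz, kind = "LIB", vessel = vessel,
                         validate = FALSE))
    })
    contour_stack(slices, jb, isd, check = FALSE)
  })
}

#' Ground-truth ICA bounding boxes of a phantom case
#'
#' Axis-aligned boxes (mm) around the MAB on the ICA slices closest to and
#' furthest from the bifurcation, padded; these stand in for the manual ICA
#' region-of-interest interaction of the segmentation workflow.
#'
#' @param case a `phantom_case`.
#' @param isd working inter-slice distance in mm.
#' @param pad padding in mm.
#' @return list with `first`, `last` boxes `c(xmin, xmax, ymin, ymax)` and
#'   their `z` positions.
#' @export
truth_ica_boxes <- function(case, isd = 1, pad = 1.5) {
  geom <- case$geometry
  bz <- geom$bifurcation_z
  z_first <- bz + isd
  z_last <- bz + floor(geom$coverage[2L] / isd) * isd
  bb <- function(z) contour_bbox(truth_contour(geom, z, "MAB")$points,
                                 pad = pad)
  list(first = bb(z_first), last = bb(z_last), z = c(z_first, z_last))
}
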