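test_that("cohort sampling is reproducible and validates its inputs", {
  c1 <- sample_cohort(2, seed = 7, render = FALSE)
  c2 <- sample_cohort(2, seed = 7, render = FALSE)
  expect_identical(c1, c2)
  expect_error(sample_cohort(0), "at least 1")
  expect_length(c1, 2)
  expect_equal(c1[[2]]$followup$timepoint, "followup")
})

test_that("progression-only follow-up never shrinks the vessel wall volume", {
  coh <- sample_cohort(3, seed = 5, render = FALSE)
  for (p in coh) {
    v0 <- vwv(p$baseline$truth, step = 0.35, grid_spacing = 0.1)
    v1 <- vwv(p$followup$truth, step = 0.35, grid_spacing = 0.1)
    expect_gte(v1, v0 - 1e-6)
  }
})

test_that("ground-truth VWV matches the analytic volume integral", {
  geom <- caroseg:::with_seed(9, sample_geometry())
  # analytic: V = int_z (1/2) int_theta r(z, theta)^2 dtheta dz per branch
  analytic <- function(kind) {
    total <- 0
    for (br in c("CCA", "ICA")) {
      zr <- if (br == "CCA")
        c(geom$bifurcation_z - geom$coverage[1], geom$bifurcation_z)
      else c(geom$bifurcation_z + 0.35,
             geom$bifurcation_z + floor(geom$coverage[2] / 0.35) * 0.35)
      zs <- seq(zr[1], zr[2], length.out = 400)
      th <- 2 * pi * (0:719) / 720
      area <- vapply(zs, function(z) {
        b <- geom$branches[[br]]
        rm <- caroseg:::branch_mab_radius(b, z - geom$bifurcation_z, th)
        r <- if (kind == "MAB") rm else
          pmax(rm - caroseg:::branch_wall(geom, br, b, z, th), 0.25)
        sum(r^2) / 2 * (2 * pi / 720)
      }, 1)
      total <- total + sum(diff(zs) * (head(area, -1) + tail(area, -1)) / 2)
    }
    total
  }
  st <- truth_stack(geom, 0.35)
  v_num <- vessel_volume(st, "MAB", step = 0.1, grid_spacing = 0.1)
  expect_equal(v_num, analytic("MAB"), tolerance = 0.01)
})

test_that("rendered volumes have the documented intensity structure", {
  geom <- caroseg:::with_seed(3, sample_geometry())
  geom$plaques <- list()
  vol <- caroseg:::with_seed(4, render_volume(geom, speckle = FALSE,
                                              blur = FALSE, shadows = FALSE))
  # noise off: piecewise-constant classes, lumen darker than wall
  expect_lte(length(unique(round(as.vector(vol$voxels), 6))), 4)
  sl <- caroseg:::volume_slice(vol, geom$bifurcation_z - 5)
  xs <- sl$x0 + (seq_len(nrow(sl$image)) - 1) * sl$dx
  ys <- sl$y0 + (seq_len(ncol(sl$image)) - 1) * sl$dy
  lib <- truth_contour(geom, geom$bifurcation_z - 5, "LIB")
  mab <- truth_contour(geom, geom$bifurcation_z - 5, "MAB")
  inside_lib <- caroseg:::cpp_pip_mask(lib$points, xs, ys) == 1
  inside_mab <- caroseg:::cpp_pip_mask(mab$points, xs, ys) == 1
  wall <- inside_mab & !inside_lib
  expect_lt(mean(sl$image[inside_lib]), mean(sl$image[wall]))
  # determinism
  v1 <- caroseg:::with_seed(4, render_volume(geom))
  v2 <- caroseg:::with_seed(4, render_volume(geom))
  expect_identical(v1, v2)
})

test_that("calcification shadows reduce intensity behind the plaque", {
  geom <- caroseg:::with_seed(6, sample_geometry())
  geom$plaques <- list(list(branch = "CCA",
                            z_center = geom$bifurcation_z - 7,
                            theta_center = pi / 2, z_extent = 3,
                            theta_extent = 0.9, max_thickness = 1.5,
                            calcified = TRUE))
  v_on <- caroseg:::with_seed(8, render_volume(geom, speckle = FALSE,
                                               blur = FALSE, shadows = TRUE))
  v_off <- caroseg:::with_seed(8, render_volume(geom, speckle = FALSE,
                                                blur = FALSE,
                                                shadows = FALSE))
  diffvox <- v_on$voxels - v_off$voxels
  expect_lt(min(diffvox), 0)          # shadow dropout present
  expect_gt(max(diffvox), 0)          # bright calcification arc present
})

test_that("a noise-free virtual observer reproduces the ground truth", {
  coh <- sample_cohort(1, seed = 11, render = FALSE)
  case <- coh[[1]]$baseline
  obs0 <- observer_model(radial_noise_sd = 0,
                         bifurcation_sd_per_isd = c("1" = 0, "2" = 0,
                                                    "3" = 0))
  t1 <- virtual_observer(case, 2, obs0, trial_seed = 1)
  t2 <- virtual_observer(case, 2, obs0, trial_seed = 99)
  expect_equal(bifurcation_distance(t1, t2), 0)
  cmp <- compare_stacks(t1, t2, step = 1, grid_spacing = 0.1)
  expect_true(all(cmp$dsc == 1))
  # the noise-free contours equal the ground-truth geometry at every one of
  # the observer's own slice positions
  for (s in t1$slices) {
    expect_equal(dice(s$mab, truth_contour(case$geometry, s$z, "MAB"),
                      grid_spacing = 0.1), 1, tolerance = 1e-9)
    expect_equal(dice(s$lib, truth_contour(case$geometry, s$z, "LIB"),
                      grid_spacing = 0.1), 1, tolerance = 1e-9)
  }
})

test_that("observer noise lowers Dice and preserves contour invariants", {
  coh <- sample_cohort(1, seed = 12, render = FALSE)
  case <- coh[[1]]$baseline
  obs <- observer_model(radial_noise_sd = 0.15)
  t1 <- quiet(virtual_observer(case, 2, obs, trial_seed = 21))
  t2 <- quiet(virtual_observer(case, 2, obs, trial_seed = 22))
  cmp <- compare_stacks(t1, t2, step = 2, grid_spacing = 0.1)
  expect_lt(mean(cmp$dsc), 1)
  for (s in t1$slices) {
    expect_gt(polygon_area(s$mab$points), 0)
    expect_true(caroseg:::is_simple_polygon(s$mab$points))
    expect_true(all(caroseg:::cpp_points_in_poly(s$lib$points,
                                                 s$mab$points)))
  }
})

test_that("stronger radial noise lowers the mean inter-trial Dice", {
  coh <- sample_cohort(1, seed = 13, render = FALSE)
  case <- coh[[1]]$baseline
  mean_dsc <- function(sd) {
    obs <- observer_model(radial_noise_sd = sd,
                          bifurcation_sd_per_isd = c("2" = 0))
    vals <- vapply(1:10, function(tr) {
      a <- quiet(virtual_observer(case, 2, obs, trial_seed = 100 + tr))
      b <- quiet(virtual_observer(case, 2, obs, trial_seed = 200 + tr))
      cmp <- quiet(compare_stacks(a, b, step = 2, grid_spacing = 0.1))
      mean(cmp$dsc)
    }, 1)
    mean(vals)
  }
  expect_gt(mean_dsc(0.05), mean_dsc(0.30))
})
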