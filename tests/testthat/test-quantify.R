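test_that("vessel volumes match analytic cylinders, cones and annuli", {
  st <- cylinder_stack(0:10, R = 4, r = 2)
  expect_equal(vessel_volume(st, "LIB"), 40 * pi, tolerance = 0.01)
  expect_equal(vwv(st), 120 * pi, tolerance = 0.01)
  # linear cone r: 2 -> 4 over 9 mm
  zs <- seq(0, 9, by = 1)
  cone <- contour_stack(lapply(zs, function(z) list(
    z = z, mab = circle_contour(2 + 2 * z / 9, z = z),
    lib = circle_contour(1, z = z, kind = "LIB"))),
    bifurcation_z = 9, isd = 1)
  expect_equal(vessel_volume(cone, "MAB"), pi * 9 / 3 * (4 + 8 + 16),
               tolerance = 0.01)
  expect_error(vessel_volume(cylinder_stack(0), "MAB"), "2 slices")
})

test_that("VWV scales quadratically with radius and is branch-additive", {
  st1 <- cylinder_stack(0:6, R = 3, r = 1.5)
  st2 <- cylinder_stack(0:6, R = 6, r = 3)
  expect_equal(vwv(st2) / vwv(st1), 4, tolerance = 0.01)
  # stack straddling the bifurcation: CCA + ICA volumes sum to the total
  st <- cylinder_stack(0:8, bifurcation_z = 4)
  expect_equal(vwv(st, branch = "CCA") + vwv(st, branch = "ICA"),
               vwv(st), tolerance = 1e-9)
})

test_that("VWV is stable when the integration step is halved", {
  st <- cylinder_stack(seq(0, 8, by = 2), R = 3.5, r = 2.2)
  v1 <- vwv(st, step = 0.2)
  v2 <- vwv(st, step = 0.1)
  expect_lt(abs(v1 - v2) / v2, 0.002)
})

test_that("symmetric correspondence matches analytic configurations", {
  mab <- circle_contour(4)
  lib <- circle_contour(2, kind = "LIB")
  cp <- correspond(mab, lib, 100)
  expect_equal(mean(cp$vwt), 2, tolerance = 0.01)
  expect_lt(diff(range(cp$vwt)), 0.02)
  expect_true(all(diff(cp$theta) > 0))
  # eccentric: wall thins to ~1 mm and thickens to ~3 mm
  ecc <- correspond(mab, circle_contour(2, center = c(1, 0), kind = "LIB"),
                    100)
  expect_equal(min(ecc$vwt), 1, tolerance = 0.05)
  expect_equal(max(ecc$vwt), 3, tolerance = 0.05)
  # resolution convergence
  c16 <- correspond(mab, lib, 16)
  c256 <- correspond(mab, lib, 256)
  expect_equal(mean(c16$vwt), mean(c256$vwt), tolerance = 0.01)
  expect_error(correspond(mab, lib, 8), "16")
  expect_error(correspond(circle_contour(2), circle_contour(4, kind = "LIB")),
               "inside")
})

test_that("correspondence distances are invariant under joint rigid motion", {
  mab <- circle_contour(4, center = c(0.3, 0))
  lib <- circle_contour(2, center = c(0.8, 0.2), kind = "LIB")
  mv <- function(ct, a, d) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    contour(sweep(ct$points %*% R, 2, d, "+"), kind = ct$kind,
            validate = FALSE)
  }
  d0 <- sort(correspond(mab, lib, 64)$vwt)
  d1 <- sort(correspond(mv(mab, 1.1, c(5, -3)), mv(lib, 1.1, c(5, -3)),
                        64)$vwt)
  expect_equal(d0, d1, tolerance = 0.02)
})

test_that("VWT maps have the L-shaped layout and analytic values", {
  # CCA of radius 4/2, narrower ICA of radius 3/1 beyond the bifurcation
  slices <- lapply(0:10, function(z) {
    R <- if (z <= 6) 4 else 3
    r <- if (z <= 6) 2 else 1
    list(z = z, mab = circle_contour(R, z = z),
         lib = circle_contour(r, z = z, kind = "LIB"))
  })
  st <- contour_stack(slices, bifurcation_z = 6, isd = 1, check = FALSE)
  m <- vwt_map(st)
  expect_s3_class(m, "vwt_map")
  expect_equal(ncol(m$grid), 100)
  expect_equal(map_summary(m), 2, tolerance = 0.01)
  # ICA rows occupy a column sub-range, remaining cells missing
  ica_rows <- which(m$vessel == "ICA")
  expect_true(length(ica_rows) > 0)
  expect_true(anyNA(m$grid[ica_rows, ]))
  expect_false(anyNA(m$grid[m$vessel == "CCA", ]))
})

test_that("a focal plaque appears at its (z, theta) footprint in the map", {
  params <- phantom_params()
  geom <- caroseg:::with_seed(21, sample_geometry(params))
  geom$plaques <- list(list(branch = "CCA",
                            z_center = geom$bifurcation_z - 7,
                            theta_center = pi / 2, z_extent = 3,
                            theta_extent = 0.9, max_thickness = 2,
                            calcified = FALSE))
  m <- vwt_map(truth_stack(geom, 1))
  peak <- which(m$grid == max(m$grid, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(abs(m$z[peak[1, 1]] - (geom$bifurcation_z - 7)), 1.5)
  theta_peak <- (peak[1, 2] - 1) / 100 * 2 * pi
  expect_lt(abs(Arg(exp(1i * (theta_peak - pi / 2)))), 0.5)
})

test_that("map summaries and pairings behave on constant and shifted maps", {
  st <- cylinder_stack(0:6, R = 4, r = 2)
  m1 <- vwt_map(st)
  m2 <- m1
  m2$grid <- m2$grid + 0.3
  pr <- map_pairs(m1, m2)
  ds <- delta_summary(pr$v2, pr$v1)
  expect_equal(ds$mean_delta, 0.3, tolerance = 1e-9)
  expect_equal(ds$mean_abs_delta, 0.3, tolerance = 1e-9)
  same <- delta_summary(pr$v1, pr$v1)
  expect_equal(same$mean_delta, 0)
  expect_equal(same$mean_abs_delta, 0)
  empty <- m1; empty$grid[] <- NA_real_
  expect_error(map_summary(empty), "empty")
})
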