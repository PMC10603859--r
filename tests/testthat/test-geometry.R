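test_that("contour construction enforces the polygon invariants", {
  th <- 2 * pi * (0:11) / 12
  p <- cbind(cos(th), sin(th))
  expect_s3_class(contour(p, kind = "MAB"), "carotid_contour")
  # clockwise input is reoriented counter-clockwise
  cw <- contour(p[rev(seq_len(nrow(p))), ], kind = "MAB")
  expect_gt(polygon_area(cw$points), 0)
  expect_error(contour(p[1:5, ], kind = "MAB"), "8")
  # self-intersecting bowtie
  bow <- rbind(c(0, 0), c(0.5, 0.1), c(1, 0), c(0.1, 1.05), c(0.5, 0.9),
               c(0.9, 1.02), c(0.3, 0.05), c(0, 1))
  expect_error(contour(bow, kind = "MAB"), "intersect")
  # degenerate (collinear) polygon
  line <- cbind(seq(0, 1, length.out = 9), seq(0, 1, length.out = 9))
  expect_error(contour(line, kind = "MAB"), "degenerate|intersect")
})

test_that("rasterization recovers analytic areas", {
  sq <- square_contour(1)
  r <- rasterize(sq, 0.01)
  expect_lt(abs(sum(r$mask) * 0.01^2 - 1), 0.01)
  ci <- circle_contour(2, n = 256)
  r2 <- rasterize(ci, 0.02)
  expect_lt(abs(sum(r2$mask) * 0.02^2 - 4 * pi) / (4 * pi), 0.005)
  expect_error(rasterize(sq, 0.05, bounds = c(xmin = 0.2, xmax = 2,
                                              ymin = 0, ymax = 2)),
               "bounds")
})

test_that("rasterized area is monotone under polygon containment", {
  inner <- circle_contour(1.5)
  outer <- circle_contour(2.5)
  bb <- c(xmin = -3, xmax = 3, ymin = -3, ymax = 3)
  a_in <- sum(rasterize(inner, 0.05, bb)$mask)
  a_out <- sum(rasterize(outer, 0.05, bb)$mask)
  expect_lt(a_in, a_out)
  expect_true(all(rasterize(inner, 0.05, bb)$mask <=
                    rasterize(outer, 0.05, bb)$mask))
})

test_that("signed distance field matches analytic distances", {
  # bounds chosen so grid centres hit integer coordinates exactly
  ci <- circle_contour(3, n = 512)
  s <- signed_distance_field(ci, grid_spacing = 0.05,
                             bounds = c(xmin = -6.025, xmax = 6.025,
                                        ymin = -6.025, ymax = 6.025))
  at <- function(x, y) s$values[which.min(abs(s$x - x)),
                                which.min(abs(s$y - y))]
  expect_lt(abs(at(0, 0) - (-3)), 0.05)   # centre of the circle
  expect_lt(abs(at(5, 0) - 2), 0.05)      # outside along +x
  sq <- contour(rbind(c(-1, -1), c(0, -1), c(1, -1), c(1, 0), c(1, 1),
                      c(0, 1), c(-1, 1), c(-1, 0)), kind = "MAB")
  s2 <- signed_distance_field(sq, grid_spacing = 0.05,
                              bounds = c(xmin = -2.025, xmax = 2.025,
                                         ymin = -2.025, ymax = 2.025))
  at2 <- function(x, y) s2$values[which.min(abs(s2$x - x)),
                                  which.min(abs(s2$y - y))]
  expect_lt(abs(at2(1, 1)), 0.05)         # corner lies on the boundary
})

test_that("shape-based interpolation of concentric circles is radially linear", {
  c2 <- circle_contour(2); c4 <- circle_contour(4)
  for (t in c(0.25, 0.5, 0.75)) {
    ct <- interpolate_contour(c2, c4, t)
    rad <- sqrt(rowSums(ct$points^2))
    expect_lt(max(abs(rad - (2 + 2 * t))), 0.05)
  }
  expect_lt(hausdorff(interpolate_contour(c2, c4, 0), c2), 0.05)
  expect_lt(hausdorff(interpolate_contour(c2, c4, 1), c4), 0.05)
  same <- interpolate_contour(c2, c2, 0.37)
  expect_lt(hausdorff(same, c2), 0.05)
  expect_error(interpolate_contour(c2, circle_contour(2, kind = "LIB"), 0.5),
               "kind")
})

test_that("interpolation commutes with reflection", {
  set.seed(11)
  th <- 2 * pi * (0:63) / 64
  mk <- function(r, bump) contour(
    cbind((r + bump * cos(3 * th)) * cos(th),
          (r + bump * sin(2 * th)) * sin(th)), kind = "MAB",
    validate = FALSE)
  c1 <- mk(2, 0.3); c2 <- mk(3.2, 0.2)
  flip <- function(ct) contour(cbind(-ct$points[, 1], ct$points[, 2]),
                               z = ct$z, kind = ct$kind, validate = FALSE)
  a <- interpolate_contour(flip(c1), flip(c2), 0.4)
  b <- flip(interpolate_contour(c1, c2, 0.4))
  expect_lt(hausdorff(a, b), 0.1)
})

test_that("reslicing produces the documented slice grids", {
  # linearly varying radius: every interpolated radius is linear in z
  zs <- seq(0, 8, by = 2)
  slices <- lapply(zs, function(z) list(
    z = z, mab = circle_contour(2 + 0.25 * z, z = z),
    lib = circle_contour(1 + 0.1 * z, z = z, kind = "LIB")))
  st <- contour_stack(slices, bifurcation_z = 8, isd = 2)
  rs <- reslice_stack(st, 0.5)
  expect_equal(stack_z(rs), seq(0, 8, by = 0.5))
  for (s in rs$slices) {
    rad <- sqrt(rowSums(sweep(s$mab$points, 2, c(0, 0))^2))
    expect_lt(max(abs(rad - (2 + 0.25 * s$z))), 0.06)
  }
  # target_step = isd reproduces the stack
  id <- reslice_stack(st, 2)
  expect_equal(stack_z(id), zs)
  expect_equal(id$slices[[2]]$mab$points, st$slices[[2]]$mab$points)
  # interior-inclusive count on a 2-slice stack at the axial voxel size
  st2 <- contour_stack(list(
    list(z = 0, mab = circle_contour(2, z = 0),
         lib = circle_contour(1, z = 0, kind = "LIB")),
    list(z = 1, mab = circle_contour(2, z = 1),
         lib = circle_contour(1, z = 1, kind = "LIB"))),
    bifurcation_z = 0, isd = 1)
  rs2 <- reslice_stack(st2, 0.35, anchor = 0)
  expect_equal(length(rs2$slices), 1 + floor(1 / 0.35))
  expect_error(reslice_stack(st, 3), "ISD")
})
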