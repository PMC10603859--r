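test_that("Dice matches analytic and brute-force overlaps", {
  c1 <- circle_contour(2)
  expect_equal(dice(c1, circle_contour(2)), 1, tolerance = 1e-6)
  expect_equal(dice(c1, circle_contour(1, center = c(10, 0))), 0)
  s1 <- square_contour(1)
  s2 <- square_contour(1, origin = c(0.5, 0))
  expect_equal(dice(s1, s2), 0.5, tolerance = 0.005)
  expect_equal(dice(s1, s2), brute_force_dice(s1, s2), tolerance = 0.005)
  expect_error(dice(c1, circle_contour(2, kind = "LIB")), "kind")
})

test_that("Dice is symmetric and rigid-motion invariant", {
  set.seed(4)
  th <- 2 * pi * (0:47) / 48
  c1 <- contour(cbind((2 + 0.2 * cos(2 * th)) * cos(th),
                      (2 + 0.2 * cos(2 * th)) * sin(th)), kind = "MAB")
  c2 <- circle_contour(2, center = c(0.7, 0.3))
  expect_equal(dice(c1, c2), dice(c2, c1), tolerance = 1e-6)
  rot <- function(ct, a, d) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    contour(sweep(ct$points %*% R, 2, d, "+"), kind = ct$kind,
            validate = FALSE)
  }
  expect_equal(dice(rot(c1, 0.6, c(3, -2)), rot(c2, 0.6, c(3, -2))),
               dice(c1, c2), tolerance = 0.01)
})

test_that("Hausdorff distance matches analytic values and brute force", {
  c3 <- circle_contour(3, n = 256)
  expect_lt(hausdorff(c3, circle_contour(3, n = 256)), 1e-9)
  hd <- hausdorff(c3, circle_contour(3, n = 256, center = c(1, 0)))
  expect_equal(hd, 1, tolerance = 0.02)
  expect_equal(hausdorff(circle_contour(2, n = 256), c3), 1,
               tolerance = 0.02)
  # brute-force oracle on an irregular pair
  set.seed(7)
  th <- 2 * pi * (0:63) / 64
  p1 <- cbind((2 + 0.3 * cos(3 * th)) * cos(th),
              (2 + 0.3 * cos(3 * th)) * sin(th))
  p2 <- cbind(0.4 + 2.2 * cos(th), -0.2 + 2.2 * sin(th))
  a <- contour(p1, kind = "MAB", validate = FALSE)
  b <- contour(p2, kind = "MAB", validate = FALSE)
  expect_equal(hausdorff(a, b), brute_force_hausdorff(p1, p2),
               tolerance = 0.02)
  expect_equal(hausdorff(a, b), hausdorff(b, a), tolerance = 1e-9)
  # linear scaling
  sc <- function(ct, s) contour(ct$points * s, kind = ct$kind,
                                validate = FALSE)
  expect_equal(hausdorff(sc(a, 2), sc(b, 2)), 2 * hausdorff(a, b),
               tolerance = 0.02)
})

test_that("bifurcation distance is an absolute difference", {
  s1 <- cylinder_stack(0:5, bifurcation_z = 10.0)
  s2 <- cylinder_stack(0:5, bifurcation_z = 11.19)
  expect_equal(bifurcation_distance(s1, s2), 1.19)
  expect_equal(bifurcation_distance(s2, s1), 1.19)
  expect_equal(bifurcation_distance(s1, s1), 0)
})

test_that("comparing a stack with itself is perfect on every common slice", {
  st <- cylinder_stack(seq(0, 6, by = 2))
  cmp <- compare_stacks(st, st, step = 0.5)
  expect_true(all(cmp$dsc == 1))
  expect_true(all(cmp$hd < 1e-9))
  expect_setequal(unique(cmp$kind), c("MAB", "LIB"))
})

test_that("stacks with offset coverage compare on the shrunken common grid", {
  s1 <- cylinder_stack(seq(0, 6, by = 2), bifurcation_z = 6)
  s2 <- cylinder_stack(seq(2, 8, by = 2), bifurcation_z = 8)
  cmp <- compare_stacks(s1, s2, step = 1)
  expect_true(all(cmp$z >= 2 - 1e-9 & cmp$z <= 6 + 1e-9))
  expect_error(compare_stacks(s1, cylinder_stack(seq(20, 26, by = 2))),
               "overlap")
})

test_that("stratified evaluation has the documented strata and BF slice", {
  geom <- caroseg:::with_seed(5, sample_geometry())
  st <- truth_stack(geom, 2)
  ev <- stratified_eval(st, st, step = 1)
  expect_setequal(unique(ev$stratum),
                  c("CCA", "ICA", "BF", "CCA w/o BF", "Overall"))
  expect_true(all(ev$dsc_mean == 1))
  expect_true(all(ev$hd_mean < 1e-9))
  # exactly one BF slice per volume, and Overall pools CCA + ICA slices
  cmp <- compare_stacks(st, st, step = 1)
  expect_equal(sum(cmp$bf & cmp$kind == "MAB"), 1)
  sm <- stratify_comparison(cmp)
  n_overall <- sm$n[sm$stratum == "Overall" & sm$kind == "MAB"]
  expect_equal(n_overall, sm$n[sm$stratum == "CCA" & sm$kind == "MAB"] +
                 sm$n[sm$stratum == "ICA" & sm$kind == "MAB"])
  # Overall mean is the slice-weighted mean of the CCA and ICA strata
  w_mean <- with(sm[sm$kind == "MAB" & sm$stratum %in% c("CCA", "ICA"), ],
                 sum(dsc_mean * n) / sum(n))
  expect_equal(sm$dsc_mean[sm$stratum == "Overall" & sm$kind == "MAB"],
               w_mean, tolerance = 1e-12)
})
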