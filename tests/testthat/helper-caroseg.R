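# Shared fixtures: analytic contours and stacks built in code.

circle_contour <- function(r, n = 96, center = c(0, 0), z = 0,
                           kind = "MAB", vessel = "CCA") {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  contour(cbind(center[1L] + r * cos(th), center[2L] + r * sin(th)),
          z = z, kind = kind, vessel = vessel, validate = FALSE)
}

square_contour <- function(side = 1, origin = c(0, 0), z = 0, kind = "MAB") {
  s <- side
  p <- rbind(c(0, 0), c(s / 2, 0), c(s, 0), c(s, s / 2), c(s, s),
             c(s / 2, s), c(0, s), c(0, s / 2))
  contour(sweep(p, 2, origin, "+"), z = z, kind = kind)
}

# coaxial circular cylinders: MAB radius R, LIB radius r, slices at `zs`
cylinder_stack <- function(zs, R = 4, r = 2, center = c(0, 0),
                           bifurcation_z = max(zs)) {
  isd <- if (length(zs) > 1L) zs[2L] - zs[1L] else 1
  slices <- lapply(zs, function(z) list(
    z = z,
    mab = circle_contour(R, center = center, z = z),
    lib = circle_contour(r, center = center, z = z, kind = "LIB")))
  contour_stack(slices, bifurcation_z, isd, check = FALSE)
}

# brute-force area-overlap Dice via independent point-in-polygon (pracma);
# the sample grid is offset by an irrational-ish fraction of the spacing so
# no sample point falls exactly on a polygon edge
brute_force_dice <- function(c1, c2, spacing = 0.01) {
  skip_if_not_installed("pracma")
  bb <- rbind(c1$points, c2$points)
  off <- spacing * 0.37
  xs <- seq(min(bb[, 1]) - spacing + off, max(bb[, 1]) + spacing,
            by = spacing)
  ys <- seq(min(bb[, 2]) - spacing + off, max(bb[, 2]) + spacing,
            by = spacing)
  g <- expand.grid(x = xs, y = ys)
  in1 <- pracma::inpolygon(g$x, g$y, c1$points[, 1], c1$points[, 2])
  in2 <- pracma::inpolygon(g$x, g$y, c2$points[, 1], c2$points[, 2])
  2 * sum(in1 & in2) / (sum(in1) + sum(in2))
}

# brute-force symmetric Hausdorff distance over dense boundary samplings
brute_force_hausdorff <- function(p1, p2, n = 1500) {
  densify <- function(p, n) {
    pc <- rbind(p, p[1, ])
    seg <- sqrt(rowSums(diff(pc)^2))
    cum <- c(0, cumsum(seg))
    s <- seq(0, cum[length(cum)], length.out = n + 1L)[-1L]
    cbind(approx(cum, pc[, 1], xout = s)$y, approx(cum, pc[, 2], xout = s)$y)
  }
  a <- densify(p1, n); b <- densify(p2, n)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  h12 <- sqrt(max(apply(d2, 1, min)))
  h21 <- sqrt(max(apply(d2, 2, min)))
  max(h12, h21)
}

quiet <- function(expr) suppressWarnings(expr)
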