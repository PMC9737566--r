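test_that("contour construction enforces the invariants", {
  expect_error(contour(c(0, 1), c(0, 0)), "at least 3")
  expect_error(contour(c(0, 1, 2), c(0, 0, 0)), "degenerate")
  # bowtie self-intersects
  expect_error(contour(c(0, 3, 0, 1), c(0, 1, 1, 0)), "self-intersecting")
  # clockwise input is reversed to counterclockwise
  cw <- contour(c(0, 0, 1, 1), c(0, 1, 1, 0))
  expect_gt(polygon_area(cw), 0)
  # explicit closing vertex and consecutive duplicates are dropped
  cc <- contour(c(0, 1, 1, 1, 0, 0), c(0, 0, 0, 1, 1, 0))
  expect_length(cc$x, 4)
})

test_that("area and perimeter match closed forms", {
  sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1.0)
  expect_equal(polygon_perimeter(sq), 4.0)
  tri <- contour(c(0, 1, 0), c(0, 0, 1))
  expect_equal(polygon_area(tri), 0.5)
  tri345 <- contour(c(0, 3, 0), c(0, 0, 4))
  expect_equal(polygon_perimeter(tri345), 12.0)
  # inscribed 256-gon: A = (n/2) sin(2*pi/n), P = 2 n sin(pi/n)
  n <- 256
  cc <- poly_circle(n)
  expect_equal(polygon_area(cc), n / 2 * sin(2 * pi / n), tolerance = 1e-12)
  expect_equal(polygon_area(cc), pi, tolerance = 1e-3)
  expect_equal(polygon_perimeter(cc), 2 * n * sin(pi / n), tolerance = 1e-12)
  expect_equal(polygon_perimeter(cc), 2 * pi, tolerance = 1e-3)
})

test_that("fitted ellipse axes recover true ellipse axes and agree with a
          pixel-moment oracle on the square", {
  el <- poly_ellipse(512, a = 2, b = 1)
  ax <- fitted_ellipse_axes(el)
  expect_equal(unname(ax["L"]), 4, tolerance = 0.01)
  expect_equal(unname(ax["W"]), 2, tolerance = 0.01)
  ci <- poly_circle(512)
  ax <- fitted_ellipse_axes(ci)
  expect_equal(unname(ax["L"]), 2, tolerance = 0.01)
  expect_equal(unname(ax["W"]), 2, tolerance = 0.01)
  sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  ax <- fitted_ellipse_axes(sq)
  expect_equal(unname(ax["L"]), unname(ax["W"]))
  orc <- pixel_oracle(sq, npx = 1000)
  expect_equal(unname(ax["L"]), orc$L, tolerance = 0.005)
})

test_that("convex hull covers the input and handles concave shapes", {
  hull <- convex_hull(poly_circle(64))
  expect_equal(polygon_area(hull), polygon_area(poly_circle(64)),
               tolerance = 1e-9)
  # 4-spike star on the unit circle: hull is the spike-tip quadrilateral
  star <- contour(c(1, 0.1, 0, -0.1, -1, -0.1, 0, 0.1),
                  c(0, 0.1, 1, 0.1, 0, -0.1, -1, -0.1))
  h <- convex_hull(star)
  expect_length(h$x, 4)
  expect_equal(polygon_area(h), 2)  # square with diagonals 2
  # L-shaped hexagon: hull closes the notch
  ell <- contour(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  expect_equal(polygon_area(ell), 3)
  expect_equal(polygon_area(convex_hull(ell)), 3.5)
})

test_that("descriptor formulas give their closed-form values", {
  ci <- poly_circle(1024)
  d <- compute_descriptors(ci)
  expect_equal(d$C, 1, tolerance = 0.01)
  expect_equal(d$R, 1, tolerance = 0.01)
  expect_equal(d$AR, 1, tolerance = 0.01)
  expect_equal(d$S, 1, tolerance = 0.01)
  sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  d <- compute_descriptors(sq)
  expect_equal(d$C, pi / 4, tolerance = 1e-9)
  expect_equal(d$S, 1, tolerance = 1e-9)
  el <- poly_ellipse(1024, a = 2, b = 1)
  d <- compute_descriptors(el)
  expect_equal(d$AR, 2, tolerance = 0.01)
  expect_equal(d$R, 0.5, tolerance = 0.005)
})

test_that("descriptors are invariant under rigid motion and behave
          correctly under uniform scaling", {
  set.seed(41)
  base <- spiky_ellipse(0.05, 9)
  d0 <- unlist(compute_descriptors(base))
  for (k in 1:5) {
    moved <- transform_contour(base, angle = runif(1, 0, 2 * pi),
                               dx = runif(1, -10, 10), dy = runif(1, -10, 10))
    d1 <- unlist(compute_descriptors(moved))
    expect_lt(max(abs(d1 - d0) / abs(d0)), 1e-6)
  }
  s <- 3.7
  ds <- unlist(compute_descriptors(transform_contour(base, scale = s)))
  expect_equal(ds[["A"]], d0[["A"]] * s^2, tolerance = 1e-9)
  expect_equal(ds[["P"]], d0[["P"]] * s, tolerance = 1e-9)
  expect_equal(ds[["L"]], d0[["L"]] * s, tolerance = 1e-9)
  expect_equal(ds[["W"]], d0[["W"]] * s, tolerance = 1e-9)
  for (v in c("AR", "C", "R", "S")) {
    expect_lt(abs(ds[[v]] - d0[[v]]) / d0[[v]], 1e-6)
  }
})

test_that("surface roughness raises P and lowers C and S but leaves R
          almost unchanged", {
  amps <- seq(0.01, 0.10, length.out = 10)
  d <- lapply(amps, function(a) compute_descriptors(spiky_ellipse(a, 12)))
  P <- vapply(d, `[[`, numeric(1), "P")
  C <- vapply(d, `[[`, numeric(1), "C")
  S <- vapply(d, `[[`, numeric(1), "S")
  R <- vapply(d, `[[`, numeric(1), "R")
  base <- compute_descriptors(spiky_ellipse(0, 12))
  expect_true(all(diff(P) > 0))
  expect_true(all(diff(C) < 0))
  expect_true(all(diff(S) < 0))
  expect_lt(max(abs(R - base$R)), 0.02)
})

test_that("isoperimetric bound holds on random shapes", {
  set.seed(7)
  for (k in 1:20) {
    cc <- spiky_ellipse(runif(1, 0, 0.2), sample(3:20, 1),
                        a = runif(1, 1, 3), phase = runif(1, 0, 2 * pi))
    expect_lte(compute_descriptors(cc)$C, 1)
  }
})

test_that("polygon descriptors agree with brute-force pixel counting", {
  el <- poly_ellipse(720, a = 1.8, b = 1)
  d <- compute_descriptors(el)
  # closed-form side
  expect_equal(d$P, ellipse_perimeter(1.8, 1), tolerance = 0.001)
  orc <- pixel_oracle(el, npx = 2000)
  for (v in c("A", "L", "W", "AR", "R", "S")) {
    expect_equal(d[[v]], orc[[v]], tolerance = 0.01)
  }
  # a non-convex wavy shape against the pixel oracle
  wv <- spiky_ellipse(0.08, 10)
  d <- compute_descriptors(wv)
  orc <- pixel_oracle(wv, npx = 2000)
  for (v in c("A", "L", "W", "AR", "R", "S")) {
    expect_equal(d[[v]], orc[[v]], tolerance = 0.01)
  }
})

test_that("contour CSV round-trips", {
  cc <- poly_ellipse(64, a = 1.4, b = 0.9, angle = 0.3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_contour(cc, f)
  back <- read_contour(f)
  expect_equal(back$x, cc$x, tolerance = 1e-12)
  expect_equal(back$y, cc$y, tolerance = 1e-12)
  expect_error(suppressWarnings(
    read_contour(withr::local_tempfile(fileext = ".csv"))))
})
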