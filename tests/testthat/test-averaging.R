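# a reasonably asymmetric test silhouette: egg-like oval
egg_mask <- function(px = 0.02, angle = 0, stretch = 1) {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  r <- 1 + 0.25 * cos(th) + 0.08 * cos(2 * th)
  cc <- contour(r * cos(th) * stretch, r * sin(th) / stretch,
                check_simple = FALSE)
  if (angle != 0) cc <- transform_contour(cc, angle = angle)
  rasterize_contour(cc, px, pad = 4)
}

test_that("aligning an already-canonical ellipse is a near fixed point", {
  m <- egg_mask(stretch = 1.2)
  al <- align_mask(m, canvas = c(256, 256), normalize_scale = FALSE)
  d0 <- unlist(compute_descriptors(mask_to_contour(m)))
  d1 <- unlist(compute_descriptors(mask_to_contour(al)))
  expect_lt(max(abs(d1 - d0) / abs(d0)), 0.01)
})

test_that("alignment undoes rotation and resolves the 180-degree flip", {
  a0 <- align_mask(egg_mask(), canvas = c(256, 256))
  a37 <- align_mask(egg_mask(angle = 37 * pi / 180), canvas = c(256, 256))
  a180 <- align_mask(egg_mask(angle = pi), canvas = c(256, 256))
  d0 <- compute_descriptors(mask_to_contour(a0))
  d37 <- compute_descriptors(mask_to_contour(a37))
  expect_equal(d37$AR, d0$AR, tolerance = 0.01)
  expect_gt(mask_iou(a0, a37), 0.98)
  expect_gt(mask_iou(a0, a180), 0.99)
})

test_that("alignment refuses a canvas that cannot hold the shape", {
  expect_error(align_mask(egg_mask(), canvas = c(40, 40),
                          normalize_scale = FALSE), "canvas too small")
})

test_that("average of identical masks is that mask (after alignment)", {
  m <- egg_mask()
  avg <- average_silhouette(rep(list(m), 20), canvas = c(256, 256))
  al <- align_mask(m, canvas = c(256, 256))
  expect_equal(mask_iou(avg$mask, al), 1.0)
  expect_equal(avg$n_inputs, 20)
})

test_that("averaging is permutation invariant, bit-exactly", {
  set.seed(3)
  masks <- lapply(1:6, function(i) {
    rasterize_contour(spiky_ellipse(0.05, 8, phase = runif(1, 0, 2 * pi)),
                      0.02, pad = 4)
  })
  a1 <- average_silhouette(masks, canvas = c(256, 256))
  a2 <- average_silhouette(rev(masks), canvas = c(256, 256))
  expect_identical(a1$stack, a2$stack)
  expect_identical(a1$mask$grid, a2$mask$grid)
})

test_that("threshold semantics on two concentric disks", {
  px <- 0.02
  canvas <- c(256, 256)
  d1 <- rasterize_contour(poly_circle(256, r = 1), px, pad = 4)
  d2 <- rasterize_contour(poly_circle(256, r = 2), px, pad = 4)
  # normalize_scale off: per-pixel fractions are 1 inside r=1, 0.5 in the
  # annulus; >= 0.5 keeps the large disk, > 0.5 (threshold 0.6) the small
  a_lo <- average_silhouette(list(d1, d2), threshold = 0.5,
                             normalize_scale = FALSE, canvas = canvas)
  a_hi <- average_silhouette(list(d1, d2), threshold = 0.6,
                             normalize_scale = FALSE, canvas = canvas)
  expect_equal(polygon_area(a_lo$contour), 4 * pi, tolerance = 0.02)
  expect_equal(polygon_area(a_hi$contour), pi, tolerance = 0.02)
})

test_that("averaging requires >= 2 masks and consistent pixel sizes", {
  m <- egg_mask()
  expect_error(average_silhouette(list(m)), "at least 2")
  m2 <- binary_mask(m$grid, pixel_size = m$pixel_size * 2)
  expect_error(average_silhouette(list(m, m2), normalize_scale = FALSE),
               "pixel sizes")
})

test_that("averaging softens ornamented outlines (higher circularity)", {
  set.seed(9)
  masks <- lapply(1:20, function(i) {
    rasterize_contour(spiky_ellipse(0.08, 11, phase = runif(1, 0, 2 * pi)),
                      0.02, pad = 4)
  })
  ind_C <- vapply(masks, function(m) {
    compute_descriptors(mask_to_contour(m))$C
  }, numeric(1))
  avg <- average_silhouette(masks, canvas = c(256, 256))
  avg_d <- compute_descriptors(avg$contour)
  expect_gt(avg_d$C, mean(ind_C))
  # perimeter of the consensus is below the mean individual perimeter
  # (after scale normalization both are comparable through C)
  expect_gt(avg_d$S, mean(vapply(masks, function(m) {
    compute_descriptors(mask_to_contour(m))$S
  }, numeric(1))))
})

test_that("average silhouettes write a complete artifact set", {
  m <- egg_mask()
  avg <- average_silhouette(list(m, m), canvas = c(256, 256))
  stem <- file.path(withr::local_tempdir(), "sp1_lateral")
  write_average_silhouette(avg, stem)
  expect_true(file.exists(paste0(stem, "_mask.png")))
  expect_true(file.exists(paste0(stem, "_contour.csv")))
  sidecar <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(sidecar$n_inputs, 2)
  expect_equal(sidecar$threshold, 0.5)
  expect_true(sidecar$normalize_scale)
})
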