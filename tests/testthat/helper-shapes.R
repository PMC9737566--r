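# shape builders shared across the suite (all analytic, no fixtures on disk)

poly_circle <- function(n = 256, r = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cx + r * cos(th), cy + r * sin(th), check_simple = FALSE)
}

poly_ellipse <- function(n = 256, a = 2, b = 1, angle = 0, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  if (angle != 0) {
    xr <- cos(angle) * x - sin(angle) * y
    y <- sin(angle) * x + cos(angle) * y
    x <- xr
  }
  contour(cx + x, cy + y, check_simple = FALSE)
}

# convex polygon with `k` vertices on an ellipse (vertices of a shape
# inscribed in a convex curve are always in convex position); angles are
# jittered equal spacing, so the polygon is never a degenerate sliver
random_convex_contour <- function(k, axis_ratio = 1) {
  th <- 2 * pi * (seq_len(k) + runif(k, -0.3, 0.3)) / k
  contour(cos(th) * axis_ratio, sin(th), check_simple = FALSE)
}

# ellipse with a multiplicative radial spike perturbation
spiky_ellipse <- function(amp, n_spikes = 12, n = 720, a = 2, b = 1,
                          phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r0 <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  g <- ornament_profile(th, "echinate", n_spikes, phase)
  r <- r0 * (1 + amp * g)
  contour(r * cos(th), r * sin(th), check_simple = FALSE)
}

# Ramanujan's second approximation to the ellipse perimeter (independent
# closed form used as a perimeter oracle)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# brute-force pixel oracle: area, moment axes and hull solidity computed
# by pixel counting on an npx^2 rasterization (independent of the polygon
# formulas under test)
pixel_oracle <- function(cc, npx = 2000) {
  xr <- range(cc$x); yr <- range(cc$y)
  px <- max(diff(xr), diff(yr)) / npx
  xs <- seq(xr[1] - px, xr[2] + px, by = px)
  ys <- seq(yr[1] - px, yr[2] + px, by = px)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- sp::point.in.polygon(gx, gy, cc$x, cc$y) > 0
  n <- sum(inside)
  A <- n * px^2
  mx <- mean(gx[inside]); my <- mean(gy[inside])
  mxx <- mean((gx[inside] - mx)^2); myy <- mean((gy[inside] - my)^2)
  mxy <- mean((gx[inside] - mx) * (gy[inside] - my))
  tr <- mxx + myy; disc <- sqrt(tr^2 / 4 - (mxx * myy - mxy^2))
  L <- 4 * sqrt(tr / 2 + disc); W <- 4 * sqrt(tr / 2 - disc)
  hx <- gx[inside]; hy <- gy[inside]
  h <- grDevices::chull(hx, hy)
  hull_area <- abs(sum(hx[h] * hy[c(h[-1], h[1])] -
                       hx[c(h[-1], h[1])] * hy[h])) / 2
  list(A = A, L = L, W = W, AR = L / W, R = 4 * A / (pi * L^2),
       S = A / hull_area)
}
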