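#' Parametric cardioid-derived seed-shape model
#'
#' Lateral seed views are cardioid-related: the base curve is the polar
#' figure r(theta) = 1 - e*cos(theta) (hilum side at theta = 0), with an
#' optional concave notch of depth `h` and angular width `w_h` carved at
#' the hilum.  Dorsal views are modelled as an ellipse of the given axis
#' ratio with optional symmetric concavities of depth `d` at the top and
#' bottom (theta = +/- pi/2) -- the "channeled back" of dorso-canaliculata
#' seeds.  With h = 0 (and e <= 0.5) or d = 0 the figures are convex.
#'
#' @param family `"lateral"` or `"dorsal"`.
#' @param e Cardioid eccentricity in \[0, 1\] (lateral).
#' @param h Hilum-notch depth in \[0, 1\] (lateral).
#' @param w_h Notch angular width in radians (lateral).
#' @param axis_ratio Major/minor axis ratio >= 1 (dorsal).
#' @param d Dorsal concavity depth in \[0, 1\].
#' @param w_d Dorsal concavity angular width in radians.
#' @param resolution Number of contour vertices (>= 32).
#' @return Object of class `seed_model`.
#' @export
seed_model <- function(family = c("lateral", "dorsal"),
                       e = 0.3, h = 0, w_h = 1.0,
                       axis_ratio = 1.8, d = 0, w_d = 1.2,
                       resolution = 256L) {
  family <- match.arg(family)
  if (resolution < 32) stop("resolution must be >= 32")
  if (e < 0 || e > 1) stop("e must lie in [0, 1]")
  if (h < 0 || h > 1) stop("h must lie in [0, 1]")
  if (d < 0 || d > 1) stop("d must lie in [0, 1]")
  if (w_h <= 0 || w_d <= 0) stop("notch widths must be positive")
  if (axis_ratio < 1) stop("axis_ratio must be >= 1")
  structure(list(family = family, e = e, h = h, w_h = w_h,
                 axis_ratio = axis_ratio, d = d, w_d = w_d,
                 resolution = as.integer(resolution)),
            class = "seed_model")
}

#' @export
print.seed_model <- function(x, ...) {
  if (x$family == "lateral") {
    cat(sprintf("<seed_model lateral: e=%.2f h=%.2f w_h=%.2f, %d vertices>\n",
                x$e, x$h, x$w_h, x$resolution))
  } else {
    cat(sprintf("<seed_model dorsal: axis_ratio=%.2f d=%.2f w_d=%.2f, %d vertices>\n",
                x$axis_ratio, x$d, x$w_d, x$resolution))
  }
  invisible(x)
}

# raised-cosine bump centered at `center`, unit height, half-width w/2
cos_bump <- function(theta, center, w) {
  dt <- atan2(sin(theta - center), cos(theta - center))  # wrapped difference
  ifelse(abs(dt) < w / 2, 0.5 * (1 + cos(2 * pi * dt / w)), 0)
}

#' Polar radius of a seed model
#'
#' @param m A [seed_model].
#' @param theta Angles in radians.
#' @return Radii (dimensionless model units).
#' @export
model_radius <- function(m, theta) {
  if (m$family == "lateral") {
    r <- 1 - m$e * cos(theta)
    r * (1 - m$h * cos_bump(theta, 0, m$w_h))
  } else {
    b <- 1 / m$axis_ratio
    r <- b / sqrt(sin(theta)^2 + (b * cos(theta))^2)  # ellipse a=1, b=1/AR
    r * (1 - m$d * (cos_bump(theta, pi / 2, m$w_d) +
                    cos_bump(theta, -pi / 2, m$w_d)))
  }
}

#' Render a seed model as a contour
#'
#' @param m A [seed_model].
#' @param scale Linear scale factor (mm per model unit).
#' @return A [contour].
#' @examples
#' render_model(seed_model("lateral", e = 0))  # circle
#' @export
render_model <- function(m, scale = 1) {
  stopifnot(inherits(m, "seed_model"))
  theta <- seq(0, 2 * pi, length.out = m$resolution + 1L)[-(m$resolution + 1L)]
  r <- model_radius(m, theta) * scale
  contour(r * cos(theta), r * sin(theta), check_simple = FALSE)
}

#' J index: percentage similarity of two outlines
#'
#' The J index quantifies how closely a seed silhouette matches a geometric
#' model figure.  Both shapes are (optionally) normalized -- centroid at
#' the origin, principal axis horizontal, unit area -- and J is defined as
#' 100 x area(intersection) / area(union), evaluated on a common fine
#' raster.  It is symmetric, bounded in \[0, 100\], and with alignment on
#' it is invariant to rigid motion and uniform scaling of either input.
#' The residual 180-degree ambiguity of the principal axis is resolved by
#' taking the orientation of the second shape that maximizes the overlap.
#'
#' Note the definition is intersection-over-union; J values are not
#' comparable in absolute terms with similarity indices defined as shared
#' area over total area.
#'
#' @param s,m [contour] objects (silhouette and model, interchangeable).
#' @param align Normalize pose and scale before comparing (default TRUE).
#' @param resolution Grid size (pixels across the union bounding box).
#' @return J in \[0, 100\].
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' j_index(sq, sq)  # 100
#' @export
j_index <- function(s, m, align = TRUE, resolution = 512L) {
  stopifnot(inherits(s, "contour"), inherits(m, "contour"))
  if (align) {
    s <- normalize_contour(s)
    m0 <- normalize_contour(m)
    j1 <- raster_iou(s, m0, resolution)
    j2 <- raster_iou(s, transform_contour(m0, angle = pi), resolution)
    return(100 * max(j1, j2))
  }
  100 * raster_iou(s, m, resolution)
}

# IoU of two polygons by even-odd rasterization on a shared grid
raster_iou <- function(a, b, resolution) {
  xr <- range(a$x, b$x); yr <- range(a$y, b$y)
  px <- max(diff(xr), diff(yr)) / resolution
  origin <- c(xr[1] - 2 * px, yr[1] - 2 * px)
  canvas <- c(ceiling(diff(yr) / px) + 4L, ceiling(diff(xr) / px) + 4L)
  ga <- rasterize_contour(a, px, canvas = canvas, origin = origin)$grid
  gb <- rasterize_contour(b, px, canvas = canvas, origin = origin)$grid
  u <- sum(ga | gb)
  if (u == 0) return(0)
  sum(ga & gb) / u
}

#' Fit a seed model to a silhouette
#'
#' Searches the continuous model family for the parameter set maximizing
#' the J index against the silhouette (equivalently minimizing 100 - J),
#' by cyclic coordinate search with shrinking step and 3 restarts.
#'
#' @param s A [contour].
#' @param family `"lateral"` or `"dorsal"`.
#' @param resolution Raster resolution for J evaluations (lower than the
#'   [j_index] default: fitting needs many evaluations).
#' @param n_restarts Random restarts (first start is the family default).
#' @param seed RNG seed for the restarts.
#' @return List with `model` (the fitted [seed_model]), `J`, and `params`.
#' @export
fit_seed_model <- function(s, family = c("lateral", "dorsal"),
                           resolution = 192L, n_restarts = 3L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(s, "contour"))
  sn <- normalize_contour(s)
  if (family == "lateral") {
    lower <- c(e = 0,   h = 0,   w_h = 0.3)
    upper <- c(e = 0.9, h = 0.8, w_h = 2.5)
    start <- c(e = 0.3, h = 0.2, w_h = 1.0)
  } else {
    lower <- c(axis_ratio = 1,   d = 0,   w_d = 0.5)
    upper <- c(axis_ratio = 3.5, d = 0.8, w_d = 2.0)
    start <- c(axis_ratio = 1.8, d = 0.1, w_d = 1.2)
  }
  build <- function(p) {
    if (family == "lateral") {
      seed_model("lateral", e = p[["e"]], h = p[["h"]], w_h = p[["w_h"]],
                 resolution = 128L)
    } else {
      seed_model("dorsal", axis_ratio = p[["axis_ratio"]], d = p[["d"]],
                 w_d = p[["w_d"]], resolution = 128L)
    }
  }
  objective <- function(p) {
    mc <- normalize_contour(render_model(build(p)))
    j1 <- raster_iou(sn, mc, resolution)
    j2 <- raster_iou(sn, transform_contour(mc, angle = pi), resolution)
    100 * max(j1, j2)
  }
  set.seed(seed)
  starts <- list(start)
  for (k in seq_len(n_restarts - 1L)) {
    starts[[k + 1L]] <- lower + stats::runif(length(lower)) * (upper - lower)
    names(starts[[k + 1L]]) <- names(lower)
  }
  best <- NULL
  for (p0 in starts) {
    p <- p0
    jbest <- objective(p)
    step <- (upper - lower) / 4
    for (round in 1:4) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (i in seq_along(p)) {
          for (dir in c(-1, 1)) {
            q <- p
            q[i] <- min(max(q[i] + dir * step[i], lower[i]), upper[i])
            if (q[i] == p[i]) next
            jq <- objective(q)
            if (jq > jbest + 1e-6) {
              p <- q; jbest <- jq; improved <- TRUE
            }
          }
        }
      }
      step <- step / 2
    }
    if (is.null(best) || jbest > best$J) best <- list(params = p, J = jbest)
  }
  list(model = build(best$params), J = best$J, params = best$params)
}
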