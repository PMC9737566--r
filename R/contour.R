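#' Closed planar contour of a seed silhouette
#'
#' A `contour` is a simple (non-self-intersecting) closed polygon stored as
#' an ordered set of vertices in millimetres, counterclockwise, with the
#' closing segment implicit.  It is the basic representation of a seed
#' outline in one view (lateral or dorsal).
#'
#' Construction enforces the class invariants:
#' * at least 3 vertices, no consecutive duplicates, no repeated last point;
#' * strictly positive area (degenerate/collinear rings are an error);
#' * simplicity -- any self-intersection is an error, never repaired;
#' * counterclockwise orientation (clockwise input is reversed silently).
#'
#' @param x,y Numeric vectors of vertex coordinates in mm, or `x` a
#'   two-column matrix/data.frame.
#' @param check_simple Verify that no two non-adjacent edges intersect.
#'   On by default; can be disabled for contours that are simple by
#'   construction (e.g. radial star-shaped outlines).
#' @return An object of class `contour`: a list with numeric vectors
#'   `x` and `y`.
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(sq)
#' @export
contour <- function(x, y = NULL, check_simple = TRUE) {
  if (is.null(y)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2)
    y <- x[, 2]
    x <- x[, 1]
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("contour coordinates must be finite")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3) stop("a contour needs at least 3 distinct vertices")
  dup <- c(diff(x) == 0 & diff(y) == 0, FALSE)
  if (any(dup)) {
    x <- x[!dup]; y <- y[!dup]; n <- length(x)
    if (n < 3) stop("a contour needs at least 3 distinct vertices")
  }
  a <- signed_area(x, y)
  if (abs(a) < 1e-9) stop("degenerate contour: |area| < 1e-9 mm^2")
  if (a < 0) {  # enforce counterclockwise
    x <- rev(x); y <- rev(y)
  }
  if (check_simple && !is_simple_ring(x, y)) {
    stop("contour is self-intersecting")
  }
  structure(list(x = x, y = y), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d vertices, area %.4f mm^2, perimeter %.4f mm>\n",
              length(x$x), polygon_area(x), polygon_perimeter(x)))
  invisible(x)
}

#' @export
as.data.frame.contour <- function(x, ...) {
  data.frame(x_mm = x$x, y_mm = x$y)
}

signed_area <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Simplicity test: checks every pair of non-adjacent edges for proper or
# improper crossing.  Chunked so memory stays O(n) per iteration.
is_simple_ring <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]  # edge n is adjacent to edge 1
    if (!length(j)) next
    # bounding-box prefilter
    keep <- pmin(x[j], x2[j]) <= max(x[i], x2[i]) &
            pmax(x[j], x2[j]) >= min(x[i], x2[i]) &
            pmin(y[j], y2[j]) <= max(y[i], y2[i]) &
            pmax(y[j], y2[j]) >= min(y[i], y2[i])
    j <- j[keep]
    if (!length(j)) next
    d1 <- cross2(x2[i] - x[i], y2[i] - y[i], x[j] - x[i], y[j] - y[i])
    d2 <- cross2(x2[i] - x[i], y2[i] - y[i], x2[j] - x[i], y2[j] - y[i])
    d3 <- cross2(x2[j] - x[j], y2[j] - y[j], x[i] - x[j], y[i] - y[j])
    d4 <- cross2(x2[j] - x[j], y2[j] - y[j], x2[i] - x[j], y2[i] - y[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

#' Polygon area by the shoelace formula
#'
#' @param c A [contour].
#' @return Area in mm^2 (positive; contours are counterclockwise).
#' @export
polygon_area <- function(c) {
  stopifnot(inherits(c, "contour"))
  signed_area(c$x, c$y)
}

#' Polygon perimeter
#'
#' Sum of all segment lengths including the implicit closing segment.
#'
#' @param c A [contour].
#' @return Perimeter in mm.
#' @export
polygon_perimeter <- function(c) {
  stopifnot(inherits(c, "contour"))
  x2 <- c(c$x[-1], c$x[1]); y2 <- c(c$y[-1], c$y[1])
  sum(sqrt((x2 - c$x)^2 + (y2 - c$y)^2))
}

#' Polygon centroid and second central moments
#'
#' Exact area moments of the polygon interior (Green's theorem), used for
#' the moment-equivalent ellipse and for principal-axis alignment.
#'
#' @param c A [contour].
#' @return List with `area`, `cx`, `cy`, and the normalized second central
#'   moments `mxx`, `myy`, `mxy` (units mm^2).
#' @export
polygon_moments <- function(c) {
  stopifnot(inherits(c, "contour"))
  x <- c$x; y <- c$y
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  # raw moments about origin
  ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  list(area = a, cx = cx, cy = cy,
       mxx = ixx / a - cx^2,
       myy = iyy / a - cy^2,
       mxy = ixy / a - cx * cy)
}

#' Major and minor axes of the moment-equivalent ellipse
#'
#' Axes of the ellipse with the same area and the same normalized second
#' central moments as the polygon interior -- the convention of common
#' image-measurement software, and the one that makes roundness equal b/a
#' exactly for ellipses.  Not Feret diameters.
#'
#' @param c A [contour].
#' @return Named numeric vector `c(L = , W = )` with `L >= W > 0`, in mm.
#' @export
fitted_ellipse_axes <- function(c) {
  m <- polygon_moments(c)
  tr <- m$mxx + m$myy
  det <- m$mxx * m$myy - m$mxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  if (l2 <= 0) stop("degenerate contour: zero minor axis")
  # for a solid ellipse with semi-axes a >= b: mxx' = a^2/4 along the axis
  c(L = 4 * sqrt(l1), W = 4 * sqrt(l2))
}

#' Orientation of the principal axis
#'
#' Angle (radians, in (-pi/2, pi/2]) of the major axis of the
#' moment-equivalent ellipse relative to the x axis.
#'
#' @param c A [contour].
#' @return Angle in radians.
#' @export
principal_axis_angle <- function(c) {
  m <- polygon_moments(c)
  0.5 * atan2(2 * m$mxy, m$mxx - m$myy)
}

#' Convex hull of a contour
#'
#' @param c A [contour].
#' @return A [contour] tracing the convex hull, counterclockwise.
#' @export
convex_hull <- function(c) {
  stopifnot(inherits(c, "contour"))
  h <- grDevices::chull(c$x, c$y)   # clockwise indices
  contour(c$x[h], c$y[h], check_simple = FALSE)
}

#' Shape descriptors of a silhouette
#'
#' Computes the eight-descriptor measurement tuple used throughout seed
#' outline morphometrics:
#' \describe{
#'   \item{A}{area, mm^2}
#'   \item{P}{perimeter, mm}
#'   \item{L, W}{major and minor axes of the moment-equivalent ellipse, mm}
#'   \item{AR}{aspect ratio L/W (>= 1)}
#'   \item{C}{circularity 4*pi*A/P^2, 1 for a circle, decreased by
#'     outline roughness}
#'   \item{R}{roundness 4*A/(pi*L^2), penalizes elongation, insensitive
#'     to roughness}
#'   \item{S}{solidity A / area(convex hull), 1 iff convex}
#' }
#'
#' @param c A [contour].
#' @return Named list of class `shape_descriptors` with elements
#'   `A, P, L, W, AR, C, R, S`.
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' compute_descriptors(sq)$C   # pi/4 for a square
#' @export
compute_descriptors <- function(c) {
  a <- polygon_area(c)
  p <- polygon_perimeter(c)
  ax <- fitted_ellipse_axes(c)
  hull_a <- polygon_area(convex_hull(c))
  d <- list(A = a, P = p, L = unname(ax["L"]), W = unname(ax["W"]),
            AR = unname(ax["L"] / ax["W"]),
            C = 4 * pi * a / p^2,
            R = 4 * a / (pi * ax["L"]^2),
            S = a / hull_a)
  d$R <- unname(d$R)
  structure(d, class = "shape_descriptors")
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf(
    "A=%.4f mm^2  P=%.4f mm  L=%.4f  W=%.4f  AR=%.3f  C=%.3f  R=%.3f  S=%.4f\n",
    x$A, x$P, x$L, x$W, x$AR, x$C, x$R, x$S))
  invisible(x)
}

#' Rigid/similarity transform of a contour
#'
#' Applies, in order: translation of the centroid to the origin is NOT
#' implied -- the transform is `scale`, then rotation by `angle` about the
#' origin, then translation by `(dx, dy)`.
#'
#' @param c A [contour].
#' @param angle Rotation angle in radians (counterclockwise).
#' @param scale Uniform scale factor (> 0).
#' @param dx,dy Translation in mm.
#' @return The transformed [contour].
#' @export
transform_contour <- function(c, angle = 0, scale = 1, dx = 0, dy = 0) {
  stopifnot(inherits(c, "contour"), scale > 0)
  x <- c$x * scale; y <- c$y * scale
  if (angle != 0) {
    ca <- cos(angle); sa <- sin(angle)
    xr <- ca * x - sa * y
    y <- sa * x + ca * y
    x <- xr
  }
  contour(x + dx, y + dy, check_simple = FALSE)
}

#' Normalize a contour to a canonical pose
#'
#' Centers the centroid at the origin, rotates the principal axis onto the
#' x axis, resolves the residual 180-degree ambiguity so the heavier half
#' (larger third moment along the axis) points towards +x, and optionally
#' rescales to unit area.  Used by silhouette averaging and the J index.
#'
#' @param c A [contour].
#' @param unit_area Rescale so the area equals `target_area`.
#' @param target_area Area after rescaling, mm^2.
#' @return The normalized [contour].
#' @export
normalize_contour <- function(c, unit_area = TRUE, target_area = 1) {
  m <- polygon_moments(c)
  cc <- contour(c$x - m$cx, c$y - m$cy, check_simple = FALSE)
  th <- principal_axis_angle(cc)
  cc <- transform_contour(cc, angle = -th)
  # third moment along the axis decides which way is +x
  if (third_moment_x(cc) < 0) cc <- transform_contour(cc, angle = pi)
  if (unit_area) {
    s <- sqrt(target_area / polygon_area(cc))
    cc <- transform_contour(cc, scale = s)
  }
  cc
}

# exact polygon integral of x^3 dA about the centroid (skewness along x)
third_moment_x <- function(c) {
  m <- polygon_moments(c)
  x <- c$x - m$cx; y <- c$y - m$cy
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  sum((x^3 + x^2 * x2 + x * x2^2 + x2^3) * cr) / 20
}

#' Read and write contour CSV files
#'
#' The on-disk format is a two-column CSV `x_mm, y_mm`, one row per vertex,
#' header required.
#'
#' @param path File path.
#' @param c A [contour] (for writing).
#' @return `read_contour()` returns a [contour]; `write_contour()` returns
#'   `path` invisibly.
#' @export
read_contour <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(df))) {
    stop("contour CSV must have columns x_mm, y_mm")
  }
  contour(df$x_mm, df$y_mm)
}

#' @rdname read_contour
#' @export
write_contour <- function(c, path) {
  stopifnot(inherits(c, "contour"))
  utils::write.csv(as.data.frame(c), path, row.names = FALSE)
  invisible(path)
}
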