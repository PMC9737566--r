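#' Align a silhouette mask into a canonical pose
#'
#' Extracts the sub-pixel contour, centers its centroid, rotates the
#' principal axis horizontal, resolves the 180-degree ambiguity so the
#' heavier half (larger third moment along the axis) points towards +x,
#' optionally rescales to a reference area, and re-rasterizes onto a fixed
#' canvas centered at the canvas midpoint.  Rotation is applied to the
#' contour, not the raster, so no grey interpolation artifacts arise.
#'
#' @param m A [binary_mask] with a single foreground component.
#' @param canvas `c(nrow, ncol)` canvas size in px.
#' @param normalize_scale Rescale the silhouette area to `reference_area`.
#' @param reference_area Target area in mm^2 when `normalize_scale` is on.
#' @param orient_hilum For lateral views: additionally flip so the deepest
#'   radial concavity (the hilum notch) faces -x.
#' @return A [binary_mask] on the requested canvas, same `pixel_size`.
#' @export
align_mask <- function(m, canvas = c(384L, 384L), normalize_scale = TRUE,
                       reference_area = NULL, orient_hilum = FALSE) {
  stopifnot(inherits(m, "binary_mask"))
  cc <- normalize_contour(mask_to_contour(m), unit_area = FALSE)
  if (normalize_scale) {
    if (is.null(reference_area)) {
      # half the canvas linear size squared, in mm^2: fills the canvas well
      reference_area <- (min(canvas) * m$pixel_size / 2)^2
    }
    s <- sqrt(reference_area / polygon_area(cc))
    cc <- transform_contour(cc, scale = s)
  }
  if (orient_hilum) {
    # flip so the deepest concavity sits on the -x side
    if (cos(hilum_angle(cc)) > 0) cc <- transform_contour(cc, angle = pi)
  }
  half <- c(canvas[2], canvas[1]) / 2 * m$pixel_size  # (x, y) of center
  ext <- c(max(abs(cc$x)), max(abs(cc$y)))
  if (any(ext >= half - m$pixel_size)) {
    stop("canvas too small to contain the aligned silhouette")
  }
  cc <- transform_contour(cc, dx = half[1], dy = half[2])
  rasterize_contour(cc, m$pixel_size, canvas = canvas, origin = c(0, 0))
}

# angular position (radians) of the minimum of the low-pass radial profile
# about the centroid; used to orient the hilum notch.  Only the first three
# harmonics are kept so surface ornament (high angular frequency) cannot
# masquerade as the notch.
hilum_angle <- function(cc) {
  m <- polygon_moments(cc)
  x <- cc$x - m$cx; y <- cc$y - m$cy
  th <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  X <- cbind(1, cos(th), sin(th), cos(2 * th), sin(2 * th),
             cos(3 * th), sin(3 * th))
  beta <- stats::lm.fit(X, r)$coefficients
  grid <- seq(-pi, pi, length.out = 721)[-721]
  Xg <- cbind(1, cos(grid), sin(grid), cos(2 * grid), sin(2 * grid),
              cos(3 * grid), sin(3 * grid))
  grid[which.min(Xg %*% beta)]
}

#' Average silhouette of a set of masks
#'
#' Aligns every mask ([align_mask]), stacks them, and takes the per-pixel
#' inclusion fraction; the average mask is `stack >= threshold` (pixels
#' exactly at the threshold are foreground).  The consensus contour is the
#' boundary of the largest component of that mask.  Averaging perturbed
#' variants of a common base shape yields a softened outline: the consensus
#' loses the high-frequency surface ornamentation of the individuals.
#'
#' @param masks List of [binary_mask] objects (>= 2) with equal
#'   `pixel_size`.
#' @param threshold Inclusion fraction cut in (0, 1\]; default 0.5.
#' @param normalize_scale Rescale each seed to a common area first
#'   (default TRUE).  With it off, masks of different physical scale vote
#'   at their true size.
#' @param canvas Canvas size in px passed to [align_mask].
#' @param orient_hilum Passed to [align_mask].
#' @return Object of class `average_silhouette`: list with `mask`
#'   ([binary_mask]), `contour` ([contour]), `stack` (numeric matrix in
#'   \[0, 1\]), `n_inputs`, and `params`.
#' @export
average_silhouette <- function(masks, threshold = 0.5,
                               normalize_scale = TRUE,
                               canvas = c(384L, 384L),
                               orient_hilum = FALSE) {
  if (!is.list(masks) || length(masks) < 2) {
    stop("need at least 2 masks to average")
  }
  ps <- vapply(masks, function(m) m$pixel_size, numeric(1))
  if (!normalize_scale && diff(range(ps)) > 1e-12) {
    stop("mismatched pixel sizes; enable normalize_scale or resample first")
  }
  aligned <- lapply(masks, align_mask, canvas = canvas,
                    normalize_scale = normalize_scale,
                    orient_hilum = orient_hilum)
  # integer accumulation: bit-exact under permutation of the inputs
  acc <- Reduce(`+`, lapply(aligned, function(m) m$grid * 1L))
  stack <- acc / length(masks)
  grid <- clean_mask_grid(stack >= threshold)
  mask <- binary_mask(grid, pixel_size = masks[[1]]$pixel_size)
  structure(list(mask = mask,
                 contour = mask_to_contour(mask),
                 stack = stack,
                 n_inputs = length(masks),
                 params = list(threshold = threshold,
                               normalize_scale = normalize_scale,
                               canvas = as.integer(canvas),
                               orient_hilum = orient_hilum)),
            class = "average_silhouette")
}

#' @export
print.average_silhouette <- function(x, ...) {
  cat(sprintf("<average_silhouette of %d masks, threshold %.2f>\n",
              x$n_inputs, x$params$threshold))
  print(x$mask)
  invisible(x)
}

#' Write an average silhouette to disk
#'
#' Writes the consensus mask as PNG, the contour as CSV, and a JSON sidecar
#' recording `n_inputs` and all alignment parameters.
#'
#' @param avg An [average_silhouette].
#' @param stem Path stem; files `<stem>_mask.png`, `<stem>_contour.csv`,
#'   `<stem>.json` are produced.
#' @return `stem`, invisibly.
#' @export
write_average_silhouette <- function(avg, stem) {
  stopifnot(inherits(avg, "average_silhouette"))
  write_mask(avg$mask, paste0(stem, "_mask.png"))
  write_contour(avg$contour, paste0(stem, "_contour.csv"))
  jsonlite::write_json(c(list(n_inputs = avg$n_inputs), avg$params),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Pixel intersection-over-union of two masks
#'
#' @param a,b [binary_mask] objects on equal-sized grids.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"),
            all(dim(a$grid) == dim(b$grid)))
  u <- sum(a$grid | b$grid)
  if (u == 0) return(1)
  sum(a$grid & b$grid) / u
}
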