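#' Specification of a synthetic seed species
#'
#' Describes one species of the synthetic seed world: its ornamentation
#' group, the base lateral and dorsal model parameters, the ornament
#' (amplitude, count, tip shape follows the group), the size distribution,
#' and the RNG seed from which every stochastic draw for this species
#' flows.
#'
#' Group semantics follow the outline vocabulary of seed morphometrics:
#' * `smooth` -- no superficial projections (`amplitude` forced to 0);
#' * `rugose` -- rounded tubercles: wide raised-cosine bumps;
#' * `echinate` -- acute spines: narrow triangular spikes;
#' * `papillose` -- long, broad, flat-tipped papillae: smoothed trapezoids.
#'
#' @param species Species label.
#' @param group One of `"smooth"`, `"rugose"`, `"echinate"`, `"papillose"`.
#' @param n_seeds Seeds per species (default 20, the usual sample size for
#'   a species in outline studies).
#' @param lateral,dorsal [seed_model] objects giving the base (clean)
#'   outline per view; defaults depend on the group.
#' @param amplitude Ornament relative amplitude `a`; the outline is
#'   `r(theta) * (1 + a * g(theta))` with `g` in \[0, 1\].  Defaults:
#'   smooth 0, rugose 0.04, echinate 0.08, papillose 0.22.
#' @param n_ornaments Number of ornament repetitions around the outline.
#' @param size_mean_mm2 Mean silhouette area of the lateral view, mm^2.
#' @param size_cv Within-species coefficient of variation of area (%/100),
#'   default 0.10.
#' @param lateral_stretch Mean elongation of the lateral view along the
#'   hilum axis (area-preserving stretch applied to the base model);
#'   default 1.17, which brings the lateral aspect ratio near the 1.25
#'   typical of these seeds.
#' @param stretch_cv Per-seed CV of the elongation jitter (both views),
#'   default 0.07: real seeds vary visibly in elongation, and this is what
#'   gives aspect ratio and roundness their natural dispersion.
#' @param wobble Amplitude of the per-seed low-frequency shape
#'   irregularity (radial harmonics 2-4, relative to the radius), default
#'   0.015.  No two real seeds are the same model figure; this is the
#'   individual variation that silhouette averaging is meant to remove.
#' @param seed Integer RNG seed.
#' @return Object of class `species_spec`.
#' @export
species_spec <- function(species, group, n_seeds = 20L,
                         lateral = NULL, dorsal = NULL,
                         amplitude = NULL, n_ornaments = NULL,
                         size_mean_mm2 = 1.1, size_cv = 0.10,
                         lateral_stretch = 1.17, stretch_cv = 0.07,
                         wobble = 0.015, seed = 1L) {
  group <- match.arg(group, c("smooth", "rugose", "echinate", "papillose"))
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  defaults <- group_defaults(group)
  if (is.null(lateral)) lateral <- defaults$lateral
  if (is.null(dorsal)) dorsal <- defaults$dorsal
  if (is.null(amplitude)) amplitude <- defaults$amplitude
  if (is.null(n_ornaments)) n_ornaments <- defaults$n_ornaments
  if (group == "smooth" && amplitude != 0) {
    stop("smooth seeds have no projections: amplitude must be 0")
  }
  structure(list(species = species, group = group,
                 n_seeds = as.integer(n_seeds),
                 lateral = lateral, dorsal = dorsal,
                 amplitude = amplitude, n_ornaments = as.integer(n_ornaments),
                 size_mean_mm2 = size_mean_mm2, size_cv = size_cv,
                 lateral_stretch = lateral_stretch, stretch_cv = stretch_cv,
                 wobble = wobble, seed = as.integer(seed)),
            class = "species_spec")
}

# Base model and ornament defaults per ornamentation group.  Lateral bases
# differ in hilum-notch depth (echinate/papillose seeds are flatter around
# the hilum); dorsal bases in axis ratio and upper/lower concavity depth
# (rugose backs are channeled, echinate backs mostly convex).
group_defaults <- function(group) {
  switch(group,
    smooth = list(
      lateral = seed_model("lateral", e = 0.35, h = 0.25, w_h = 1.1),
      dorsal = seed_model("dorsal", axis_ratio = 1.85, d = 0.15),
      amplitude = 0, n_ornaments = 0L),
    rugose = list(
      lateral = seed_model("lateral", e = 0.35, h = 0.30, w_h = 1.1),
      dorsal = seed_model("dorsal", axis_ratio = 1.85, d = 0.18),
      amplitude = 0.04, n_ornaments = 9L),
    echinate = list(
      lateral = seed_model("lateral", e = 0.25, h = 0.12, w_h = 0.9),
      dorsal = seed_model("dorsal", axis_ratio = 1.70, d = 0.05),
      amplitude = 0.06, n_ornaments = 14L),
    papillose = list(
      lateral = seed_model("lateral", e = 0.30, h = 0.15, w_h = 0.9),
      dorsal = seed_model("dorsal", axis_ratio = 1.80, d = 0.08),
      amplitude = 0.22, n_ornaments = 8L))
}

#' Ornament profile g(theta) for a group
#'
#' Periodic, in \[0, 1\]: raised-cosine bumps (rugose), narrow triangular
#' spikes (echinate), broad flat-topped trapezoids (papillose); identically
#' 0 for smooth seeds.
#'
#' @param theta Angles in radians.
#' @param group Ornamentation group.
#' @param k Number of repetitions around the outline.
#' @param phase Phase offset in radians.
#' @return Numeric vector in \[0, 1\].
#' @export
ornament_profile <- function(theta, group, k, phase = 0) {
  if (group == "smooth" || k == 0) return(rep(0, length(theta)))
  u <- ((k * theta + phase) / (2 * pi)) %% 1      # position within period
  d <- pmin(u, 1 - u)                              # distance to nearest peak
  switch(group,
    rugose = (0.5 * (1 + cos(2 * pi * u)))^2,      # rounded tubercles
    echinate = pmax(0, 1 - d / 0.10),              # acute narrow spikes
    # broad flat-topped papillae separated by narrow slots
    papillose = pmin(1, pmax(0, (0.41 - d) / 0.08)))
}

#' Generate the seeds of one synthetic species
#'
#' Each seed's outline is the species' base model with a per-seed random
#' ornament phase, ornament count jittered by +/- 1, ornament amplitude
#' jittered by +/- 30%, hilum-notch depth (+/- 20%) and width (+/- 15%)
#' jitter, a low-frequency per-seed shape wobble, and a log-normal area
#' scaling at the stated within-species CV.  Both views are produced per
#' seed.  Deterministic given `spec$seed`.
#'
#' @param spec A [species_spec].
#' @param resolution Vertices per contour.
#' @return A [tibble][tibble::tibble] with one row per seed x view:
#'   columns `seed_id, species, group, view, contour` (list-column of
#'   [contour]).
#' @export
generate_species <- function(spec, resolution = 512L) {
  stopifnot(inherits(spec, "species_spec"))
  set.seed(spec$seed)
  n <- spec$n_seeds
  # log-normal area scaling with mean size_mean_mm2 and CV size_cv
  sdl <- sqrt(log(1 + spec$size_cv^2))
  areas <- stats::rlnorm(n, log(spec$size_mean_mm2) - sdl^2 / 2, sdl)
  phases <- stats::runif(n, 0, 2 * pi)
  amp <- spec$amplitude * stats::runif(n, 0.7, 1.3)
  notch_jit <- stats::runif(n, 0.8, 1.2)
  notch_w_jit <- stats::runif(n, 0.85, 1.15)
  k_jit <- if (spec$n_ornaments > 0) {
    spec$n_ornaments + sample(-1:1, n, replace = TRUE)
  } else integer(n)
  sdj <- sqrt(log(1 + spec$stretch_cv^2))
  stretch <- matrix(stats::rlnorm(2L * n, -sdj^2 / 2, sdj), n, 2L)
  stretch[, 1L] <- stretch[, 1L] * spec$lateral_stretch
  # low-frequency individual shape irregularity, per seed and view
  wob_amp <- array(stats::runif(n * 2L * 3L, 0, spec$wobble), c(n, 2L, 3L))
  wob_ph <- array(stats::runif(n * 2L * 3L, 0, 2 * pi), c(n, 2L, 3L))
  theta <- seq(0, 2 * pi, length.out = resolution + 1L)[-(resolution + 1L)]
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    for (view in c("lateral", "dorsal")) {
      vi <- match(view, c("lateral", "dorsal"))
      base <- spec[[view]]
      m <- base
      if (view == "lateral") {
        m$h <- min(base$h * notch_jit[i], 1)
        m$w_h <- base$w_h * notch_w_jit[i]
      }
      r <- model_radius(m, theta)
      g <- ornament_profile(theta, spec$group, k_jit[i], phases[i])
      r <- r * (1 + amp[i] * g)
      for (harm in 1:3) {
        r <- r * (1 + wob_amp[i, vi, harm] *
                    cos((harm + 1) * theta + wob_ph[i, vi, harm]))
      }
      # area-preserving elongation along the major (x) axis
      sx <- sqrt(stretch[i, vi])
      cc <- contour(r * cos(theta) * sx, r * sin(theta) / sx,
                    check_simple = FALSE)
      # scale so the lateral area hits the drawn size; dorsal views share
      # the seed's linear scale (dorsal area ~ 0.75x lateral, as in seeds)
      target <- if (view == "lateral") areas[i] else 0.75 * areas[i]
      s <- sqrt(target / polygon_area(cc))
      cc <- transform_contour(cc, scale = s)
      rows[[2L * (i - 1L) + match(view, c("lateral", "dorsal"))]] <-
        tibble::tibble(seed_id = sprintf("%s_%02d", spec$species, i),
                       species = spec$species, group = spec$group,
                       view = view, contour = list(cc))
    }
  }
  dplyr::bind_rows(rows)
}

#' Default species specifications for a synthetic study
#'
#' Builds `species_per_group` species for each requested group.  Species
#' mean areas are drawn log-normally around the group mean area with an
#' across-species CV of 45%, which reproduces the empirical pattern that
#' area and perimeter vary far more across species than the dimensionless
#' descriptors.  Group mean lateral areas default to values typical of
#' small-seeded Caryophyllaceae (0.9--1.3 mm^2).  Dorsal axis ratios vary
#' across species (CV 8%) on top of the per-seed elongation jitter.
#'
#' @param groups Character vector of groups to include.
#' @param species_per_group Species per group.
#' @param n_seeds Seeds per species.
#' @param seed Master RNG seed; per-species seeds are derived from it.
#' @return List of [species_spec].
#' @export
default_study_specs <- function(groups = c("smooth", "rugose", "echinate",
                                           "papillose"),
                                species_per_group = 4L, n_seeds = 20L,
                                seed = 1L) {
  if (species_per_group < 1) stop("species_per_group must be >= 1")
  group_area <- c(smooth = 1.31, rugose = 1.19, echinate = 0.89,
                  papillose = 1.22)
  set.seed(seed)
  specs <- list()
  sdl <- sqrt(log(1 + 0.45^2))  # across-species area CV 45%
  sdr <- sqrt(log(1 + 0.08^2))  # across-species dorsal axis-ratio CV 8%
  for (g in groups) {
    for (j in seq_len(species_per_group)) {
      area <- stats::rlnorm(1, log(group_area[[g]]) - sdl^2 / 2, sdl)
      dorsal <- group_defaults(g)$dorsal
      dorsal$axis_ratio <- max(1, dorsal$axis_ratio *
                                    stats::rlnorm(1, -sdr^2 / 2, sdr))
      specs[[length(specs) + 1L]] <- species_spec(
        species = sprintf("%s_%02d", g, j), group = g, n_seeds = n_seeds,
        size_mean_mm2 = area, dorsal = dorsal,
        seed = (seed * 131L + length(specs) * 7919L) %% 2147483647L)
    }
  }
  specs
}

#' Generate a full synthetic study on disk
#'
#' Renders every seed of every species as a mask PNG (default 512 px
#' across the major axis), writes a dataset manifest CSV in the
#' silhouette-reading dialect (`path, seed_id, species, view, group,
#' pixels_per_mm`), and a JSON file with the specs for exact regeneration.
#' Ground-truth group labels are recorded in the manifest.
#'
#' @param specs List of [species_spec] (e.g. from [default_study_specs]).
#' @param dir Output directory (created if needed).
#' @param raster_px Pixels across the major axis of each seed.
#' @return The manifest as a tibble, invisibly; files under `dir`.
#' @export
generate_study <- function(specs, dir, raster_px = 512L) {
  if (!length(specs)) stop("no species specs given")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (spec in specs) {
    recs <- generate_species(spec)
    for (i in seq_len(nrow(recs))) {
      cc <- recs$contour[[i]]
      ext <- max(diff(range(cc$x)), diff(range(cc$y)))
      px <- ext / raster_px
      mask <- rasterize_contour(cc, px, pad = 4L)
      fn <- file.path(dir, paste0(recs$seed_id[i], "_", recs$view[i], ".png"))
      write_mask(mask, fn)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = fn, seed_id = recs$seed_id[i], species = recs$species[i],
        view = recs$view[i], group = recs$group[i], pixels_per_mm = 1 / px)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  spec_json <- lapply(specs, function(s) {
    list(species = s$species, group = s$group, n_seeds = s$n_seeds,
         amplitude = s$amplitude, n_ornaments = s$n_ornaments,
         size_mean_mm2 = s$size_mean_mm2, size_cv = s$size_cv,
         lateral_stretch = s$lateral_stretch, stretch_cv = s$stretch_cv,
         wobble = s$wobble, seed = s$seed,
         lateral = unclass(s$lateral), dorsal = unclass(s$dorsal))
  })
  jsonlite::write_json(spec_json, file.path(dir, "specs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
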