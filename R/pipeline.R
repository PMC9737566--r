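#' Compute shape descriptors for a table of seed records
#'
#' @param records Tibble with a `contour` list-column (as produced by
#'   [generate_species] or [run_study]'s extraction stage).
#' @return The input with the descriptor columns
#'   `A, P, L, W, AR, C, R, S` appended.
#' @export
measure_records <- function(records) {
  stopifnot("contour" %in% names(records))
  d <- lapply(records$contour, compute_descriptors)
  vals <- do.call(rbind, lapply(d, function(x) unlist(x)))
  dplyr::bind_cols(records, tibble::as_tibble(vals))
}

#' Read a dataset manifest
#'
#' Manifest CSV columns: `path, seed_id, species, view, group,
#' pixels_per_mm`.  Paths are resolved relative to the manifest location.
#'
#' @param path Manifest CSV path.
#' @return Tibble.
#' @export
read_manifest <- function(path) {
  mf <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("path", "seed_id", "species", "view", "group", "pixels_per_mm")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(mf)) stop("empty manifest")
  rel <- !file.exists(mf$path)
  mf$path[rel] <- file.path(dirname(path), mf$path[rel])
  mf
}

#' Per-species average silhouettes from seed records
#'
#' Rasterizes each record's contour, aligns and stacks them per species,
#' and measures the consensus.  Lateral views are hilum-oriented before
#' stacking.  A single-seed species yields its aligned individual as the
#' "average".
#'
#' @param records Record tibble with `contour` list-column (one view).
#' @param raster_px Pixels across the major axis of each seed.
#' @param threshold,normalize_scale Passed to [average_silhouette].
#' @return Tibble with one row per species: `species, group, view,
#'   n_inputs, average` (list-column of [average_silhouette]) and the
#'   descriptor columns of the consensus contour.
#' @export
species_averages <- function(records, raster_px = 192L, threshold = 0.5,
                             normalize_scale = TRUE) {
  stopifnot(length(unique(records$view)) == 1)
  view <- records$view[1]
  canvas <- c(2L * raster_px, 2L * raster_px)
  out <- list()
  for (sp in unique(records$species)) {
    rec <- records[records$species == sp, ]
    masks <- lapply(rec$contour, function(cc) {
      ext <- max(diff(range(cc$x)), diff(range(cc$y)))
      rasterize_contour(cc, ext / raster_px, pad = 4L)
    })
    # equalize pixel size: alignment rescales areas anyway when
    # normalize_scale is on; make pixel sizes formally equal
    ps <- stats::median(vapply(masks, function(m) m$pixel_size, numeric(1)))
    masks <- lapply(masks, function(m) binary_mask(m$grid, ps))
    if (length(masks) == 1L) {
      al <- align_mask(masks[[1]], canvas = canvas,
                       normalize_scale = normalize_scale,
                       orient_hilum = view == "lateral")
      avg <- structure(list(mask = al, contour = mask_to_contour(al),
                            stack = al$grid * 1, n_inputs = 1L,
                            params = list(threshold = threshold,
                                          normalize_scale = normalize_scale,
                                          canvas = canvas,
                                          orient_hilum = view == "lateral")),
                       class = "average_silhouette")
    } else {
      avg <- average_silhouette(masks, threshold = threshold,
                                normalize_scale = normalize_scale,
                                canvas = canvas,
                                orient_hilum = view == "lateral")
    }
    desc <- compute_descriptors(avg$contour)
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(species = sp, group = rec$group[1], view = view,
                     n_inputs = avg$n_inputs, average = list(avg)),
      tibble::as_tibble(t(unlist(desc))))
  }
  dplyr::bind_rows(out)
}

#' Run a full silhouette study from a manifest of mask images
#'
#' End-to-end orchestration: read every mask, trace its sub-pixel contour,
#' measure descriptors, build per-species average silhouettes, and produce
#' the standard report tables -- an overall descriptor summary per view, a
#' per-group comparison of individual silhouettes per view
#' (Kruskal-Wallis + Campbell-Skillings letters), and a comparison of the
#' average silhouettes in which area and perimeter are excluded (averaging
#' randomizes absolute size, so only the dimensionless descriptors are
#' compared).  Every parameter used is echoed into the report for
#' provenance.  Per-seed failures are collected, not fatal; partial
#' results are still written.
#'
#' @param manifest Manifest CSV path or a manifest tibble ([read_manifest]
#'   dialect).
#' @param out_dir Output directory for the report CSV/JSON files, or
#'   `NULL` to skip writing.
#' @param config Named list overriding defaults: `alpha` (0.05),
#'   `avg_threshold` (0.5), `normalize_scale` (TRUE), `raster_px` (192),
#'   `descriptors`.
#' @return Report list with elements `desc`, `averages`, `avg_desc`,
#'   `summary`, `group_comparison`, `avg_comparison`, `errors`, `config`.
#' @export
run_study <- function(manifest, out_dir = NULL, config = list()) {
  cfg <- utils::modifyList(list(alpha = 0.05, avg_threshold = 0.5,
                                normalize_scale = TRUE, raster_px = 192L,
                                descriptors = c("A", "P", "AR", "C", "R",
                                                "S")),
                           config)
  mf <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (!nrow(mf)) stop("empty manifest")
  rows <- list(); errors <- list()
  for (i in seq_len(nrow(mf))) {
    res <- tryCatch({
      m <- read_mask(mf$path[i], pixel_size = 1 / mf$pixels_per_mm[i])
      cc <- mask_to_contour(m)
      tibble::tibble(seed_id = mf$seed_id[i], species = mf$species[i],
                     view = mf$view[i], group = mf$group[i],
                     contour = list(cc))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        seed_id = mf$seed_id[i], path = mf$path[i],
        message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no seed could be processed")
  records <- dplyr::bind_rows(rows)
  desc <- measure_records(records)
  views <- intersect(c("lateral", "dorsal"), unique(desc$view))
  summary <- lapply(stats::setNames(views, views), function(v)
    summarize_descriptors(desc, by = "overall", view = v,
                          descriptors = cfg$descriptors))
  n_groups <- length(setdiff(unique(desc$group), "unknown"))
  group_comparison <- if (n_groups >= 2) {
    lapply(stats::setNames(views, views), function(v)
      summarize_descriptors(desc, by = "group", view = v,
                            descriptors = cfg$descriptors,
                            alpha = cfg$alpha))
  } else NULL
  averages <- dplyr::bind_rows(lapply(views, function(v)
    species_averages(desc[desc$view == v, ],
                     raster_px = cfg$raster_px,
                     threshold = cfg$avg_threshold,
                     normalize_scale = cfg$normalize_scale)))
  avg_desc <- dplyr::select(averages, -"average")
  avg_desc$seed_id <- avg_desc$species
  # averages randomize size: A and P are excluded from their comparison
  avg_descriptors <- setdiff(cfg$descriptors, c("A", "P"))
  avg_comparison <- if (n_groups >= 2 &&
                        all(table(avg_desc$group[avg_desc$view == views[1]]) >= 2)) {
    lapply(stats::setNames(views, views), function(v)
      summarize_descriptors(avg_desc, by = "group", view = v,
                            descriptors = avg_descriptors,
                            alpha = cfg$alpha))
  } else NULL
  report <- list(desc = desc, averages = averages, avg_desc = avg_desc,
                 summary = summary, group_comparison = group_comparison,
                 avg_comparison = avg_comparison,
                 errors = if (length(errors)) dplyr::bind_rows(errors) else NULL,
                 config = cfg)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dplyr::select(report$desc, -"contour"),
                   file.path(out_dir, "descriptors.csv"), row.names = FALSE)
  utils::write.csv(report$avg_desc,
                   file.path(out_dir, "average_descriptors.csv"),
                   row.names = FALSE)
  for (v in names(report$summary)) {
    utils::write.csv(report$summary[[v]],
                     file.path(out_dir, paste0("summary_", v, ".csv")),
                     row.names = FALSE)
  }
  for (tab in c("group_comparison", "avg_comparison")) {
    if (is.null(report[[tab]])) next
    for (v in names(report[[tab]])) {
      utils::write.csv(report[[tab]][[v]],
                       file.path(out_dir, paste0(tab, "_", v, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$errors)) {
    utils::write.csv(report$errors, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare descriptor dispersion: individual vs average silhouettes
#'
#' Quantifies how much of the within-group variation is removed by the
#' averaging step: for each group and dimensionless descriptor it reports
#' the CV across individual seeds, the CV across the per-species average
#' silhouettes, and their ratio, together with the compact letter assigned
#' to the group in each analysis (when both comparisons exist).
#'
#' @param report A [run_study] report (needs `desc` and `avg_desc`).
#' @param view View to compare.
#' @param descriptors Descriptors to compare (defaults to the
#'   dimensionless ones).
#' @return Tibble with columns `group, descriptor, cv_individual,
#'   cv_average, reduction` (cv_individual / cv_average) and, when
#'   available, `letters_individual, letters_average`.
#' @export
compare_individual_vs_average <- function(report,
                                          view = "lateral",
                                          descriptors = c("C", "R", "S")) {
  if (is.null(report$desc) || is.null(report$avg_desc)) {
    stop("report lacks individual or average descriptor tables")
  }
  ind <- report$desc[report$desc$view == view, ]
  avg <- report$avg_desc[report$avg_desc$view == view, ]
  if (!setequal(unique(ind$species), unique(avg$species))) {
    stop("species sets differ between individual and average tables")
  }
  out <- list()
  for (g in unique(ind$group)) {
    for (v in descriptors) {
      xi <- ind[[v]][ind$group == g]
      xa <- avg[[v]][avg$group == g]
      cvi <- coefficient_of_variation(xi)
      cva <- if (length(xa) >= 2) coefficient_of_variation(xa) else {
        if (length(xi) == length(xa)) 0 else NA_real_
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, descriptor = v, cv_individual = cvi, cv_average = cva,
        reduction = cvi / ifelse(cva == 0, NA_real_, cva))
    }
  }
  res <- dplyr::bind_rows(out)
  gc_i <- report$group_comparison[[view]]
  gc_a <- report$avg_comparison[[view]]
  if (!is.null(gc_i) && !is.null(gc_a)) {
    for (nm in c("letters_individual", "letters_average")) res[[nm]] <- NA_character_
    for (r in seq_len(nrow(res))) {
      col <- paste0(res$descriptor[r], "_letters")
      if (col %in% names(gc_i)) {
        res$letters_individual[r] <-
          gc_i[[col]][match(res$group[r], gc_i$group)]
      }
      if (col %in% names(gc_a)) {
        res$letters_average[r] <-
          gc_a[[col]][match(res$group[r], gc_a$group)]
      }
    }
  }
  res
}
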