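#' Coefficient of variation
#'
#' `CV = sd/mean * 100`, with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector with at least 2 values and non-zero mean.
#' @return CV as a percentage.
#' @examples
#' coefficient_of_variation(c(2, 4, 4, 4, 5, 5, 7, 9))  # 42.76
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p-value from the chi-square
#' approximation with k-1 degrees of freedom, or from complete enumeration
#' of the group assignments (`p_method = "exact"`, total n <= 12).
#' When every observation is tied across all groups, H = 0 and p = 1.
#'
#' @param groups List of numeric vectors, one per group (k >= 2).
#' @param p_method `"chisq"` (default) or `"exact"`.
#' @return List with `H`, `p`, `df`, and `mean_ranks`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6))$H  # 3.857
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "exact")) {
  p_method <- match.arg(p_method)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1)) stop("every group needs at least 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), ns)
  H <- kw_statistic(x, g, k)
  mr <- tapply(rank(x), g, mean)
  df <- k - 1
  if (p_method == "chisq") {
    p <- if (is.na(H)) 1 else stats::pchisq(H, df, lower.tail = FALSE)
    if (is.na(H)) H <- 0
  } else {
    N <- length(x)
    if (N > 12) stop("exact p-value limited to total n <= 12")
    if (is.na(H)) {
      H <- 0; p <- 1
    } else {
      perms <- group_assignments(N, ns)
      Hs <- apply(perms, 2, function(gg) kw_statistic(x, gg, k))
      Hs[is.na(Hs)] <- 0
      p <- mean(Hs >= H - 1e-12)
    }
  }
  list(H = unname(H), p = unname(p), df = df,
       mean_ranks = as.numeric(mr))
}

# tie-corrected H; NA when all observations are tied
kw_statistic <- function(x, g, k) {
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g, k)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  t <- table(x)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr <= 0) return(NA_real_)
  H / corr
}

# all assignments of N items to groups of sizes ns: one column per
# assignment, entries are group indices (used by the exact p-value)
group_assignments <- function(N, ns) {
  build <- function(avail, sizes, gidx, acc) {
    if (!length(sizes)) return(list(acc))
    out <- list()
    ch <- utils::combn(avail, sizes[1])
    for (ci in seq_len(ncol(ch))) {
      sel <- ch[, ci]
      acc2 <- acc
      acc2[sel] <- gidx
      out <- c(out, build(setdiff(avail, sel), sizes[-1], gidx + 1L, acc2))
    }
    out
  }
  res <- build(seq_len(N), ns, 1L, integer(N))
  do.call(cbind, res)
}

#' Campbell-Skillings step-down multiple comparison
#'
#' Closed step-down testing over groups ordered by mean rank.  The full
#' set of k groups is tested by Kruskal-Wallis at level alpha; on
#' rejection, the two maximal contiguous subsets of size k-1 are examined,
#' and so on.  Each subset is re-ranked internally before its test (true
#' step-down re-ranking).  A subset of size p < k is tested at the adjusted
#' level `alpha_p = 1 - (1 - alpha)^((p-1)/(k-1))`; subsets contained in an
#' already-accepted subset are not tested.  Accepted subsets are the
#' homogeneous subsets; compact letters are assigned left-to-right over
#' mean-rank order, so two groups share a letter iff they co-occur in a
#' homogeneous subset.
#'
#' @param groups Named list of numeric vectors (k >= 2).
#' @param alpha Familywise significance level (default 0.05).
#' @param adjust `"stepdown"` for the adjusted per-size levels (default) or
#'   `"none"` to test every subset at plain alpha.
#' @return Object of class `group_comparison`: list with `omnibus` (full
#'   Kruskal-Wallis result), `subsets` (character vectors of group names),
#'   `letters` (named character map), `alpha`, `order` (group names by
#'   increasing mean rank), per-group `n`, `mean`, `cv`, and `tests`
#'   (tibble of every subset test performed).
#' @export
campbell_skillings <- function(groups, alpha = 0.05,
                               adjust = c("stepdown", "none")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 1)) stop("empty group")
  if (is.null(names(groups)) || anyNA(names(groups)) ||
      any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_len(k))
  }
  omnibus <- kruskal_wallis(groups)
  ord <- order(omnibus$mean_ranks)
  gs <- groups[ord]
  level_alpha <- function(p_len) {
    if (p_len == k || adjust == "none") alpha
    else 1 - (1 - alpha)^((p_len - 1) / (k - 1))
  }
  accepted <- list()           # integer ranges in rank order
  tests <- list()
  cand <- list(c(1L, k))
  for (len in k:1) {
    this <- unique(Filter(function(ij) ij[2] - ij[1] + 1L == len, cand))
    cand <- Filter(function(ij) ij[2] - ij[1] + 1L < len, cand)
    for (ij in this) {
      contained <- any(vapply(accepted,
                              function(a) ij[1] >= a[1] && ij[2] <= a[2],
                              logical(1)))
      if (contained) next
      if (len == 1L) { accepted[[length(accepted) + 1L]] <- ij; next }
      res <- kruskal_wallis(gs[ij[1]:ij[2]])
      a_p <- level_alpha(len)
      tests[[length(tests) + 1L]] <- tibble::tibble(
        subset = paste(names(gs)[ij[1]:ij[2]], collapse = ","),
        size = len, H = res$H, p = res$p, alpha_level = a_p,
        rejected = res$p < a_p)
      if (res$p >= a_p) {
        accepted[[length(accepted) + 1L]] <- ij
      } else {
        cand <- c(cand, list(c(ij[1], ij[2] - 1L), c(ij[1] + 1L, ij[2])))
      }
    }
  }
  accepted <- accepted[order(vapply(accepted, `[`, integer(1), 1L))]
  letters_map <- stats::setNames(rep("", k), names(gs))
  subsets <- list()
  for (s in seq_along(accepted)) {
    rng <- accepted[[s]][1]:accepted[[s]][2]
    subsets[[s]] <- names(gs)[rng]
    letters_map[rng] <- paste0(letters_map[rng], letters[s])
  }
  structure(list(
    omnibus = omnibus,
    subsets = subsets,
    letters = letters_map[names(groups)],
    alpha = alpha,
    adjust = adjust,
    order = names(gs),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    cv = vapply(groups, function(v) if (length(v) > 1) {
      coefficient_of_variation(v)
    } else NA_real_, numeric(1)),
    tests = dplyr::bind_rows(tests)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.4g (alpha = %g)\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p, x$alpha))
  for (g in x$order) {
    cat(sprintf("  %-12s n=%3d  mean=%8.4f  CV=%5.1f  %s\n",
                g, x$n[[g]], x$mean[[g]],
                if (is.na(x$cv[[g]])) NA else x$cv[[g]], x$letters[[g]]))
  }
  invisible(x)
}

#' Descriptor summaries in the style of a morphometric results table
#'
#' With `by = "overall"`, returns one row per descriptor and view with the
#' mean, SD, CV, and the min/max values with the species attaining them.
#' With `by = "group"`, returns per-group means and CVs per descriptor
#' together with the Campbell-Skillings compact letters; descriptors whose
#' omnibus Kruskal-Wallis test accepts at `alpha` are flagged `excluded`
#' (no letters are reported for them, mirroring the practice of dropping
#' descriptors that show no group differences).  With `by = "species"`,
#' per-species means.
#'
#' @param desc Descriptor table (e.g. from [measure_records]): columns
#'   `seed_id, species, view, group` and the descriptor columns.
#' @param by `"overall"`, `"group"`, or `"species"`.
#' @param view `"lateral"` or `"dorsal"`.
#' @param descriptors Which descriptor columns to summarize.
#' @param alpha Significance level for the group comparison.
#' @return A tibble; for `by = "group"` the attribute `comparisons` holds
#'   the full [campbell_skillings] object per descriptor.
#' @export
summarize_descriptors <- function(desc,
                                  by = c("overall", "group", "species"),
                                  view = c("lateral", "dorsal"),
                                  descriptors = c("A", "P", "AR", "C",
                                                  "R", "S"),
                                  alpha = 0.05) {
  by <- match.arg(by)
  view <- match.arg(view)
  if (!nrow(desc)) stop("empty descriptor table")
  need <- c("seed_id", "species", "view", "group", descriptors)
  miss <- setdiff(need, names(desc))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad_view <- setdiff(unique(desc$view), c("lateral", "dorsal"))
  if (length(bad_view)) stop("unknown view labels: ",
                             paste(bad_view, collapse = ", "))
  bad_grp <- setdiff(unique(desc$group),
                     c("smooth", "rugose", "echinate", "papillose",
                       "unknown"))
  if (length(bad_grp)) stop("unknown group labels: ",
                            paste(bad_grp, collapse = ", "))
  d <- desc[desc$view == view, , drop = FALSE]
  if (!nrow(d)) stop("no rows for view ", view)
  if (by == "overall") {
    rows <- lapply(descriptors, function(v) {
      x <- d[[v]]
      tibble::tibble(
        view = view, descriptor = v, n = length(x),
        mean = mean(x), sd = stats::sd(x),
        cv = coefficient_of_variation(x),
        min = min(x), min_species = d$species[which.min(x)],
        max = max(x), max_species = d$species[which.max(x)])
    })
    return(dplyr::bind_rows(rows))
  }
  if (by == "species") {
    return(dplyr::summarise(
      dplyr::group_by(d, .data$species, .data$group),
      dplyr::across(dplyr::all_of(descriptors), mean), .groups = "drop"))
  }
  # by group: means, CVs, letters per descriptor
  comparisons <- list()
  out <- tibble::tibble(group = sort(unique(d$group)))
  for (v in descriptors) {
    gl <- split(d[[v]], d$group)
    cmp <- campbell_skillings(gl, alpha = alpha)
    comparisons[[v]] <- cmp
    excluded <- cmp$omnibus$p >= alpha
    out[[paste0(v, "_mean")]] <- as.numeric(cmp$mean[out$group])
    out[[paste0(v, "_cv")]] <- as.numeric(cmp$cv[out$group])
    out[[paste0(v, "_letters")]] <-
      if (excluded) NA_character_ else as.character(cmp$letters[out$group])
  }
  attr(out, "comparisons") <- comparisons
  out
}
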