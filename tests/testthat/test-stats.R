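test_that("coefficient of variation follows the sample-SD formula", {
  x <- c(45, 50, 55)
  expect_equal(coefficient_of_variation(x), 100 * 5 / 50)
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 4, 4, 5, 5, 7, 9)),
               42.7618, tolerance = 1e-4)
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("Kruskal-Wallis H matches the hand-ranked value and stats::kruskal.test", {
  res <- kruskal_wallis(list(1:3, 4:6))
  # R1 = 6, R2 = 15: H = (12/42)(12 + 75) - 21 = 27/7
  expect_equal(res$H, 27 / 7, tolerance = 1e-9)
  expect_equal(res$df, 1)
  # oracle: stats::kruskal.test on random instances with ties, n <= 8
  set.seed(5)
  for (k in 1:20) {
    g <- lapply(sample(2:4, sample(2:3, 1), replace = TRUE),
                function(n) sample(1:5, n, replace = TRUE))
    ours <- kruskal_wallis(g)
    x <- unlist(g); f <- factor(rep(seq_along(g), lengths(g)))
    if (length(unique(x)) == 1) {
      expect_equal(ours$H, 0)
      expect_equal(ours$p, 1)
    } else {
      orc <- stats::kruskal.test(x, f)
      expect_equal(ours$H, unname(orc$statistic), tolerance = 1e-9)
      expect_equal(ours$p, unname(orc$p.value), tolerance = 1e-9)
    }
  }
})

test_that("tie-heavy input keeps H finite and all-tied input gives p = 1", {
  res <- kruskal_wallis(list(c(1, 1, 1), c(1, 1, 2)))
  expect_true(is.finite(res$H))
  orc <- stats::kruskal.test(c(1, 1, 1, 1, 1, 2), factor(rep(1:2, each = 3)))
  expect_equal(res$H, unname(orc$statistic), tolerance = 1e-9)
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("exact permutation p agrees with explicit enumeration", {
  # oracle written independently: enumerate all choose(6,3) splits
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0)
  obs <- kruskal_wallis(list(x[1:3], x[4:6]), p_method = "exact")
  hs <- apply(utils::combn(6, 3), 2, function(idx) {
    unname(stats::kruskal.test(x, factor(seq_len(6) %in% idx))$statistic)
  })
  h_obs <- unname(stats::kruskal.test(x, factor(rep(1:2, each = 3)))$statistic)
  expect_equal(obs$p, mean(hs >= h_obs - 1e-12), tolerance = 1e-12)
  # three groups with ties
  y <- c(1, 2, 2, 4, 5, 5, 7, 8, 9)
  g <- list(y[1:3], y[4:6], y[7:9])
  obs3 <- kruskal_wallis(g, p_method = "exact")
  idx1 <- utils::combn(9, 3)
  ps <- c()
  for (a in seq_len(ncol(idx1))) {
    rest <- setdiff(1:9, idx1[, a])
    idx2 <- utils::combn(rest, 3)
    for (b in seq_len(ncol(idx2))) {
      f <- integer(9); f[idx1[, a]] <- 1L; f[idx2[, b]] <- 2L
      f[f == 0] <- 3L
      ps <- c(ps, unname(stats::kruskal.test(y, factor(f))$statistic))
    }
  }
  h3 <- unname(stats::kruskal.test(y, factor(rep(1:3, each = 3)))$statistic)
  expect_equal(obs3$p, mean(ps >= h3 - 1e-12), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:7, 8:14), p_method = "exact"),
               "n <= 12")
})

test_that("step-down comparison separates distant groups and merges nulls", {
  res <- campbell_skillings(list(a = 1:10, b = 101:110, c = 201:210))
  expect_equal(unname(res$letters[c("a", "b", "c")]), c("a", "b", "c"))
  expect_length(res$subsets, 3)
  # identical distributions on a fixed seed where the omnibus accepts
  set.seed(4)
  g <- split(rnorm(60), rep(1:3, each = 20))
  names(g) <- c("x", "y", "z")
  res0 <- campbell_skillings(g)
  expect_gte(res0$omnibus$p, 0.05)
  expect_true(all(res0$letters == "a"))
  expect_length(res0$subsets, 1)
})

test_that("k = 2 reduces to a single Kruskal-Wallis test at level alpha", {
  g <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 20))
  res <- campbell_skillings(g, alpha = 0.05)
  expect_equal(nrow(res$tests), 1)
  expect_equal(res$tests$alpha_level, 0.05)
  expect_equal(res$tests$H, kruskal_wallis(g)$H)
})

test_that("letters reconstruct the homogeneous subsets exactly", {
  set.seed(12)
  for (rep in 1:15) {
    k <- sample(3:5, 1)
    shift <- cumsum(c(0, runif(k - 1, 0, 3)))
    g <- lapply(seq_len(k), function(i) rnorm(12) + shift[i])
    names(g) <- paste0("g", seq_len(k))
    res <- campbell_skillings(g)
    # shared letter iff co-occurrence in some homogeneous subset
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        share <- length(intersect(strsplit(res$letters[[i]], "")[[1]],
                                  strsplit(res$letters[[j]], "")[[1]])) > 0
        cooc <- any(vapply(res$subsets, function(s) {
          all(c(names(g)[i], names(g)[j]) %in% s)
        }, logical(1)))
        expect_equal(share, cooc)
      }
    }
    # every group has at least one letter; subsets contiguous in rank order
    expect_true(all(nchar(res$letters) >= 1))
    for (s in res$subsets) {
      pos <- match(s, res$order)
      expect_equal(sort(pos), seq(min(pos), max(pos)))
    }
    # monotone coherence: any split implies omnibus rejection
    if (length(res$subsets) > 1 ||
        length(res$subsets[[1]]) < k) {
      expect_lt(res$omnibus$p, 0.05)
    }
  }
})

test_that("descriptor summaries have the published table structure", {
  specs <- list(species_spec("r1", "rugose", n_seeds = 8, seed = 1,
                             size_mean_mm2 = 1.4),
                species_spec("e1", "echinate", n_seeds = 8, seed = 2,
                             size_mean_mm2 = 0.9))
  desc <- measure_records(dplyr::bind_rows(lapply(specs, generate_species)))
  ov <- summarize_descriptors(desc, "overall", "lateral")
  expect_setequal(ov$descriptor, c("A", "P", "AR", "C", "R", "S"))
  expect_true(all(c("min_species", "max_species", "cv") %in% names(ov)))
  arow <- ov[ov$descriptor == "A", ]
  expect_equal(arow$max_species, "r1")  # larger species attains the max
  bygrp <- summarize_descriptors(desc, "group", "lateral")
  expect_setequal(bygrp$group, c("rugose", "echinate"))
  expect_true(all(c("C_mean", "C_cv", "C_letters") %in% names(bygrp)))
  cmp <- attr(bygrp, "comparisons")
  expect_s3_class(cmp$C, "group_comparison")
  bysp <- summarize_descriptors(desc, "species", "lateral")
  expect_equal(nrow(bysp), 2)
  # single species: min = max = mean
  one <- summarize_descriptors(desc[desc$species == "r1", ], "overall",
                               "lateral")
  expect_equal(one[one$descriptor == "A", ]$min_species, "r1")
  expect_error(summarize_descriptors(desc[0, ], "overall", "lateral"),
               "empty")
  bad <- desc; bad$view[1] <- "oblique"
  expect_error(summarize_descriptors(bad, "overall", "lateral"), "oblique")
})

test_that("descriptors with an accepting omnibus test are flagged excluded", {
  set.seed(31)
  # same distribution for a fabricated descriptor in both groups
  desc <- tibble::tibble(
    seed_id = sprintf("s%02d", 1:40), species = rep(c("u", "v"), each = 20),
    view = "lateral", group = rep(c("rugose", "echinate"), each = 20),
    A = c(rnorm(20, 1), rnorm(20, 4)), P = c(rnorm(20, 4), rnorm(20, 8)),
    AR = rnorm(40, 1.2, 0.05), C = c(rnorm(20, 0.9, 0.02), rnorm(20, 0.6, 0.02)),
    R = rnorm(40, 0.9, 0.02), S = c(rnorm(20, 0.98, 0.005), rnorm(20, 0.93, 0.005)))
  bygrp <- summarize_descriptors(desc, "group", "lateral")
  expect_true(all(is.na(bygrp$AR_letters)))
  expect_true(all(is.na(bygrp$R_letters)))
  expect_false(any(is.na(bygrp$C_letters)))
})
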