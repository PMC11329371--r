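planted_points <- function(n_per, centers, sdv = c(0.01, 0.01, 0.02),
                           seed = 1) {
  withr::with_seed(seed, purrr::imap_dfr(centers, function(mu, lab)
    tibble::tibble(label = lab,
      green_b = rnorm(n_per, mu[1], sdv[1]),
      red_b = rnorm(n_per, mu[2], sdv[2]),
      tau_ns = rnorm(n_per, mu[3], sdv[3]))))
}

test_that("K-means recovers a planted two-cluster partition", {
  pts <- planted_points(30, list(a = c(0.05, 0.25, 0.3),
    b = c(0.2, 0.1, 1.0)))
  cl <- cluster_levels(pts, K = 2, seed = 4)
  expect_equal(length(unique(cl$cluster[cl$label == "a"])), 1)
  expect_equal(length(unique(cl$cluster[cl$label == "b"])), 1)
  expect_false(cl$cluster[cl$label == "a"][1] ==
    cl$cluster[cl$label == "b"][1])
  # K = 1 puts everything together; duplicates do not crash
  expect_equal(unique(cluster_levels(pts, K = 1, seed = 4)$cluster), 1L)
  dup <- dplyr::bind_rows(pts, pts[1, ])
  expect_s3_class(cluster_levels(dup, K = 2, seed = 4), "tbl_df")
  expect_error(cluster_levels(pts[1:3, ], K = 5), "exceeds")
  # auto-K lands on the planted count
  expect_equal(attr(cluster_levels(pts, K = "auto", K_range = 2:6,
    seed = 4), "K"), 2)
})

test_that("Gaussian cluster fits reject outliers and guard degeneracy", {
  pts <- planted_points(200, list(a = c(0.1, 0.2, 0.8)), seed = 2)
  pts$cluster <- 1L
  m <- fit_cluster_gaussian(pts)
  # sampling oracle: mean within 3 standard errors of truth
  expect_lt(abs(m$mu_green - 0.1), 3 * 0.01 / sqrt(200))
  expect_lt(abs(m$mu_tau - 0.8), 3 * 0.02 / sqrt(200))
  # a 10-sigma interloper is rejected and barely moves the mean
  spiked <- dplyr::bind_rows(pts, tibble::tibble(label = "a",
    green_b = 0.1 + 10 * 0.01, red_b = 0.2, tau_ns = 0.8, cluster = 1L))
  m2 <- fit_cluster_gaussian(spiked)
  expect_gte(m2$n_rejected, 1)
  expect_equal(m2$mu_green, m$mu_green, tolerance = 1e-3)
  flat <- tibble::tibble(green_b = rep(1, 10), red_b = 1, tau_ns = 1,
    cluster = 1L)
  expect_error(fit_cluster_gaussian(flat), "zero variance")
  expect_error(fit_cluster_gaussian(pts[1:3, ], min_size = 5), "fewer than")
})

test_that("pairwise overlap matches the 1D Gaussian closed form", {
  a <- model_row("a", c(0, 0, 1), c(1, 0.2, 0.1))
  b <- model_row("b", c(2, 0, 1), c(1, 0.2, 0.1))
  p <- pairwise_misclassification(a, b, n_mc = 2e5, seed = 6)
  # means differ by 2 on one axis with common sigma 1: Phi(-1)
  expect_lt(abs(as.numeric(p) - pnorm(-1)), 3 * attr(p, "se"))
  # identical models: degenerate convention
  expect_equal(as.numeric(pairwise_misclassification(a, a)), 0.5)
  # 10-sigma separation: vanishing overlap
  far <- model_row("f", c(10, 0, 1), c(1, 0.2, 0.1))
  expect_lt(as.numeric(pairwise_misclassification(a, far, n_mc = 1e5,
    seed = 7)), 1e-4)
  # monotone decay with separation at fixed sigma
  ps <- purrr::map_dbl(c(0.5, 1, 2, 4), function(d)
    as.numeric(pairwise_misclassification(a,
      model_row("b", c(d, 0, 1), c(1, 0.2, 0.1)), n_mc = 5e4, seed = 8)))
  expect_true(all(diff(ps) < 0))
})

test_that("confusion matrix enumerates ordered pairs and is near-symmetric", {
  mods <- dplyr::bind_rows(
    model_row("a", c(0, 0, 1), c(1, 1, 1)),
    model_row("b", c(1.5, 0, 1), c(1, 1, 1)),
    model_row("c", c(0, 3, 1), c(1, 1, 1)))
  cm <- confusion_matrix(mods, n_mc = 5e4, seed = 3)
  off <- cm$p[row(cm$p) != col(cm$p)]
  expect_equal(length(off), 6)
  expect_true(all(diag(cm$p) <= 1 & diag(cm$p) >= 0))
  # symmetric geometry (equal sigmas) gives a near-symmetric matrix
  expect_equal(cm$p["a", "b"], cm$p["b", "a"],
    tolerance = 6 / sqrt(5e4) / max(cm$p["a", "b"], 1e-6))
  td <- tidy(cm)
  expect_equal(nrow(td), 9)
  expect_equal(glance(cm)$n_pairs, 6)
  expect_error(confusion_matrix(mods[1, ]), "at least 2")
})

test_that("subset selection is exact against brute-force enumeration", {
  # all compatible: full set comes back
  mods <- purrr::map(1:5, function(i)
    model_row(letters[i], c(i * 3, 0, 1), c(0.1, 0.1, 0.1)))
  cm <- confusion_matrix(dplyr::bind_rows(mods), n_mc = 2e4, seed = 5)
  sel <- select_compatible_subset(cm, 0.025)
  expect_equal(sel$labels, letters[1:5])
  expect_lte(sel$certificate, 0.025)

  # random matrices: maximum clique equals exhaustive search, n <= 12
  withr::with_seed(33, {
    for (n in c(8, 12)) {
      p <- matrix(runif(n * n, 0, 0.06), n)
      diag(p) <- 0
      labs <- sprintf("L%02d", seq_len(n))
      fake <- list(p = `dimnames<-`(p, list(labs, labs)), labels = labs)
      class(fake) <- "fret_confusion"
      sel <- select_compatible_subset(fake, 0.025)
      oracle <- brute_force_subset(p, 0.025)
      expect_equal(sel$n_selected, length(oracle))
    }
  })

  # one planted incompatible pair among 10: drop exactly one of the two
  p10 <- matrix(0, 10, 10)
  p10[1, 2] <- p10[2, 1] <- 0.2
  labs <- sprintf("L%02d", 1:10)
  fake <- structure(list(p = `dimnames<-`(p10, list(labs, labs)),
    labels = labs), class = "fret_confusion")
  sel10 <- select_compatible_subset(fake, 0.025)
  expect_equal(sel10$n_selected, 9)
  expect_equal(sum(c("L01", "L02") %in% sel10$labels), 1)
  expect_error(select_compatible_subset(fake, 0.9), "threshold")
})

test_that("level classification assigns by density with documented ties", {
  mods <- dplyr::bind_rows(
    model_row("a", c(0, 0, 1), c(1, 1, 1)),
    model_row("b", c(2, 0, 1), c(1, 1, 1)))
  at_mean <- tibble::tibble(green_b = 0, red_b = 0, tau_ns = 1)
  cls <- classify_levels(at_mean, mods)
  expect_equal(cls$assigned, "a")
  expect_gt(cls$posterior, 0.5)
  # equidistant point: deterministic lexicographic tie-break, flagged
  mid <- tibble::tibble(green_b = 1, red_b = 0, tau_ns = 1)
  cls2 <- classify_levels(mid, mods)
  expect_equal(cls2$assigned, "a")
  expect_true(cls2$tie)
  # posteriors normalize
  pts <- planted_points(20, list(x = c(0.5, 0.5, 1)), seed = 9)
  cls3 <- classify_levels(pts, mods)
  expect_true(all(cls3$posterior >= 0.5 & cls3$posterior <= 1))
  # density floor leaves far points unassigned
  cls4 <- classify_levels(tibble::tibble(green_b = 50, red_b = 50,
    tau_ns = 50), mods, floor_logdens = -100)
  expect_true(is.na(cls4$assigned))
})

test_that("identification accuracy grows with the photon budget", {
  reg <- load_registry()
  acc <- accuracy_vs_photons(reg, "AB11", c("AB16", "AB10", "AB12"),
    M_grid = c(100, 1000, 4000), n_reps = 60, seed = 14)
  two <- acc[acc$side == "two-sided", ]
  expect_equal(nrow(two), 3)
  # non-decreasing within Monte-Carlo error
  expect_true(all(diff(two$accuracy) > -0.05))
  # distant competitor is easier than the nearest neighbour at small M
  small <- acc[acc$M == 100, ]
  expect_gte(small$accuracy[small$competitor_set == "AB16"],
    small$accuracy[small$competitor_set == "AB12"])
  # lifetime axis unavailable at 100 photons, used at 1000+
  expect_false(any(acc$lifetime_axis[acc$M == 100]))
  expect_true(all(acc$lifetime_axis[acc$M >= 1000]))
  expect_error(accuracy_vs_photons(reg, "AB11", "AB12",
    M_grid = c(200, 100)), "ascending")
})
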