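.signature_axes <- c("green_b", "red_b", "tau_ns")
.axis_mu <- c(green_b = "mu_green", red_b = "mu_red", tau_ns = "mu_tau")
.axis_sd <- c(green_b = "sd_green", red_b = "sd_red", tau_ns = "sd_tau")

# drop rows with missing coordinates on the requested axes
.complete_points <- function(points, axes = .signature_axes) {
  keep <- stats::complete.cases(points[, axes, drop = FALSE])
  points[keep, , drop = FALSE]
}

#' Initial K-means clustering of level signatures
#'
#' K-means in the three-dimensional signature space (green brightness, red
#' brightness, donor lifetime). Axes are standardized to z-scores before
#' distance computation because their units are incommensurate. `K = "auto"`
#' selects the cluster count by minimum AIC over `K_range`.
#'
#' @param points A `level_signatures` table (rows with missing axes are
#'   dropped).
#' @param K Number of clusters, or `"auto"`.
#' @param K_range Candidate range for `"auto"`.
#' @param nstart Random restarts (best of, default 20).
#' @param seed Seed for centroid initialization.
#' @return The input rows (complete cases) with an integer `cluster` column;
#'   attribute `kmeans` holds the fitted object, `K` the chosen count.
#' @export
cluster_levels <- function(points, K = "auto", K_range = 2:12, nstart = 20,
                           seed = 1) {
  pts <- .complete_points(points)
  X <- scale(as.matrix(pts[, .signature_axes]))
  X[is.nan(X)] <- 0      # zero-variance axis: all points equal on it
  fit_k <- function(k) {
    if (k > nrow(X)) rlang::abort("K exceeds the number of points")
    withr::with_seed(seed, {
      fits <- lapply(seq_len(nstart), function(r) suppressWarnings(
        kmeans(X, centers = .kmeanspp_init(X, k), iter.max = 100)))
      fits[[which.min(vapply(fits, function(f) f$tot.withinss,
        numeric(1)))]]
    })
  }
  if (identical(K, "auto")) {
    # pick K by AIC of a diagonal Gaussian mixture: a hard-assignment
    # K-means likelihood keeps rewarding splits of genuine clusters, while
    # the mixture log-likelihood plateaus at the true K
    ks <- K_range[K_range < nrow(X)]
    aic <- purrr::map_dbl(ks, function(k) {
      f <- tryCatch(withr::with_seed(seed, suppressWarnings(
        mclust::Mclust(X, G = k, modelNames = "VVI", verbose = FALSE))),
        error = function(e) NULL)
      if (is.null(f)) return(Inf)
      ll <- stats::logLik(f)
      2 * attr(ll, "df") - 2 * as.numeric(ll)
    })
    if (all(!is.finite(aic)))
      rlang::abort("cluster count selection failed for every candidate K")
    K <- ks[which.min(aic)]
    km <- fit_k(K)
  } else {
    km <- fit_k(K)
  }
  pts$cluster <- km$cluster
  structure(pts, kmeans = km, K = K,
    class = unique(c("clustered_levels", class(tibble::as_tibble(pts)))))
}

# k-means++ seeding: each successive centre is drawn with probability
# proportional to its squared distance from the nearest chosen centre.
# Plain random-point initialization rarely covers K tight, well-separated
# clusters in one draw (coverage probability ~ K!/K^K), and Lloyd iterations
# cannot split a merged pair afterwards.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1) else
        idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  # jitter exact duplicates so stats::kmeans accepts the centre matrix
  dup <- duplicated(centers)
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] +
    stats::rnorm(sum(dup) * ncol(X), 0, 1e-8)
  centers
}

#' Fit axis-aligned 3D Gaussian cluster models with outlier rejection
#'
#' For each cluster, iterates: compute per-axis mean and standard deviation,
#' reject points farther than `z_max` standard deviations from the mean on
#' any axis, recompute — until stable (at most `max_iter` passes). No
#' covariance is fitted: each cluster model is an axis-aligned Gaussian.
#'
#' @param points A clustered table (from [cluster_levels()] or with a
#'   `cluster` column; a character `label` grouping column may be used via
#'   `by`).
#' @param by Column naming the cluster membership (default `"cluster"`).
#' @param z_max Outlier rejection threshold in cluster standard deviations
#'   (default 3).
#' @param min_size Minimum members per cluster (default 5).
#' @param max_iter Maximum rejection passes (default 10).
#' @param axes Signature axes to fit (default all three); e.g. drop
#'   `"tau_ns"` when lifetimes are unavailable at small photon budgets.
#' @param drop_small If TRUE, clusters that are too small or degenerate are
#'   dropped with a warning instead of raising an error (used by the
#'   pipeline, where a stray micro-cluster should not abort a run).
#' @return A `cluster_models` tibble: `label`, per-axis means `mu_green`,
#'   `mu_red`, `mu_tau`, per-axis standard deviations `sd_green`, `sd_red`,
#'   `sd_tau` (NA on unfitted axes), `n_members`, `n_rejected`.
#' @export
fit_cluster_gaussian <- function(points, by = "cluster", z_max = 3,
                                 min_size = 5, max_iter = 10,
                                 axes = .signature_axes,
                                 drop_small = FALSE) {
  pts <- .complete_points(points, axes)
  groups <- split(seq_len(nrow(pts)), pts[[by]])
  fail <- function(msg, lab) {
    if (drop_small) {
      rlang::warn(paste0(msg, "; cluster ", lab, " dropped"))
      NULL
    } else rlang::abort(paste0(msg, " (cluster ", lab, ")"))
  }
  res <- purrr::imap_dfr(groups, function(idx, lab) {
    X <- as.matrix(pts[idx, axes])
    if (nrow(X) < min_size)
      return(fail(paste0("fewer than ", min_size, " members"), lab))
    keep <- rep(TRUE, nrow(X))
    for (it in seq_len(max_iter)) {
      mu <- colMeans(X[keep, , drop = FALSE])
      sdv <- apply(X[keep, , drop = FALSE], 2, sd)
      if (any(sdv <= 0) || any(!is.finite(sdv)))
        return(fail("zero variance on an axis; Gaussian model undefined",
          lab))
      z <- abs(sweep(sweep(X, 2, mu), 2, sdv, "/"))
      new_keep <- apply(z <= z_max, 1, all)
      if (sum(new_keep) == 0)
        return(fail("outlier rejection emptied the cluster", lab))
      if (identical(new_keep, keep)) break
      keep <- new_keep
    }
    mu <- colMeans(X[keep, , drop = FALSE])
    sdv <- apply(X[keep, , drop = FALSE], 2, sd)
    row <- tibble::tibble(label = as.character(lab),
      mu_green = NA_real_, mu_red = NA_real_, mu_tau = NA_real_,
      sd_green = NA_real_, sd_red = NA_real_, sd_tau = NA_real_,
      n_members = sum(keep), n_rejected = sum(!keep))
    row[, .axis_mu[axes]] <- as.list(mu)
    row[, .axis_sd[axes]] <- as.list(sdv)
    row
  })
  structure(res, axes = axes,
    class = c("cluster_models", class(tibble::tibble())))
}

.model_mu <- function(m, axes = .signature_axes)
  as.numeric(m[1, .axis_mu[axes]])
.model_sd <- function(m, axes = .signature_axes)
  as.numeric(m[1, .axis_sd[axes]])

# log density of axis-aligned Gaussian at rows of X (n x 3)
.gauss_logdens <- function(X, mu, sdv) {
  rowSums(dnorm(sweep(X, 2, mu), 0, rep(sdv, each = nrow(X)), log = TRUE))
}

#' Pairwise misclassification probability of two cluster models
#'
#' Probability that a point drawn from model `a`'s axis-aligned Gaussian
#' falls on model `b`'s side of the equal-density (equal-prior likelihood
#' ratio) decision boundary — the tail mass of `a` lost to `b`. Estimated by
#' Monte Carlo with a fixed seed; for two models differing on exactly one
#' axis with equal standard deviations this equals the classical
#' \eqn{\Phi(-d/2\sigma)} tail overlap. Identical models return 0.5 by
#' convention (the degenerate equal-density case).
#'
#' @param a,b Single-row cluster models (rows of a [fit_cluster_gaussian()]
#'   table).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Seed for the draws.
#' @return Scalar probability; attributes `se` (Monte-Carlo standard error).
#' @export
pairwise_misclassification <- function(a, b, n_mc = 1e5, seed = 1) {
  mu_a <- .model_mu(a); sd_a <- .model_sd(a)
  mu_b <- .model_mu(b); sd_b <- .model_sd(b)
  if (all(mu_a == mu_b) && all(sd_a == sd_b))
    return(structure(0.5, se = 0))
  p <- withr::with_seed(seed, {
    X <- matrix(rnorm(n_mc * 3), ncol = 3)
    X <- sweep(sweep(X, 2, sd_a, "*"), 2, mu_a, "+")
    mean(.gauss_logdens(X, mu_b, sd_b) > .gauss_logdens(X, mu_a, sd_a))
  })
  structure(p, se = sqrt(p * (1 - p) / n_mc))
}

#' Pairwise misclassification confusion matrix
#'
#' Evaluates [pairwise_misclassification()] for every ordered pair of
#' cluster models (n models give n(n-1) off-diagonal entries). The diagonal
#' is the self-identification mass 1 minus the row's summed off-diagonal
#' mass — a pairwise approximation, consistent with treating confusability
#' pair by pair rather than as a joint integral over all clusters.
#'
#' @param models A [fit_cluster_gaussian()] table (>= 2 rows).
#' @param n_mc Monte-Carlo draws per pair.
#' @param seed Base seed; each pair gets a distinct derived seed.
#' @return A `fret_confusion` object: matrix `p` (rows = true label,
#'   columns = assigned), with the model table attached. [tidy()] gives the
#'   long form.
#' @export
confusion_matrix <- function(models, n_mc = 2e4, seed = 1) {
  n <- nrow(models)
  if (n < 2) rlang::abort("need at least 2 cluster models")
  labs <- models$label
  p <- matrix(0, n, n, dimnames = list(true = labs, assigned = labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p[i, j] <- as.numeric(pairwise_misclassification(models[i, ],
      models[j, ], n_mc, seed + i * 1009L + j))
  }
  diag(p) <- pmax(0, 1 - rowSums(p))
  structure(list(p = p, labels = labs, models = models, n_mc = n_mc),
    class = "fret_confusion")
}

#' @export
print.fret_confusion <- function(x, ...) {
  cat("<fret_confusion>", length(x$labels), "labels,",
    length(x$labels) * (length(x$labels) - 1), "ordered pairs; max",
    sprintf("off-diagonal %.4f\n", max(x$p[row(x$p) != col(x$p)])))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x A `fret_confusion`.
#' @param ... Unused.
#' @method tidy fret_confusion
#' @export
tidy.fret_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$p, responseName = "p_mis",
    stringsAsFactors = FALSE)) |>
    dplyr::rename(true = "true", assigned = "assigned")
}

#' @rdname confusion_matrix
#' @method glance fret_confusion
#' @export
glance.fret_confusion <- function(x, ...) {
  off <- x$p[row(x$p) != col(x$p)]
  tibble::tibble(n_labels = length(x$labels), n_pairs = length(off),
    max_p_mis = max(off), n_above_2.5pct = sum(off > 0.025))
}

#' Select a maximal subset of mutually distinguishable labels
#'
#' Builds the compatibility graph whose edges connect label pairs with both
#' directed misclassification probabilities at or below `threshold`, and
#' returns a maximum clique (exact search; feasible for registries of tens
#' of labels). Ties are broken toward the lexicographically smallest label
#' set.
#'
#' @param confusion A [confusion_matrix()] result.
#' @param threshold Pairwise misclassification threshold (default 0.025,
#'   i.e. 2.5%).
#' @return A `subset_selection` list: `labels` (selected), `threshold`,
#'   `certificate` (max pairwise misclassification within the subset),
#'   `n_selected`.
#' @export
select_compatible_subset <- function(confusion, threshold = 0.025) {
  if (threshold <= 0 || threshold >= 0.5)
    rlang::abort("`threshold` must be in (0, 0.5)")
  p <- confusion$p
  labs <- confusion$labels
  n <- length(labs)
  ok <- (p <= threshold) & (t(p) <= threshold)
  diag(ok) <- FALSE
  dimnames(ok) <- NULL     # asymmetric dimname labels confuse isSymmetric
  g <- igraph::graph_from_adjacency_matrix(ok, mode = "undirected")
  cliques <- igraph::largest_cliques(g)
  if (!length(cliques)) {
    sel <- labs[1]
  } else {
    cand <- purrr::map(cliques, ~ sort(labs[as.integer(.x)]))
    sel <- cand[[order(purrr::map_chr(cand, paste, collapse = "|"))[1]]]
  }
  idx <- match(sel, labs)
  cert <- if (length(idx) > 1) max(p[idx, idx][row(p[idx, idx]) !=
    col(p[idx, idx])]) else 0
  structure(list(labels = sel, threshold = threshold, certificate = cert,
    n_selected = length(sel)), class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat("<subset_selection>", x$n_selected, "labels, threshold", x$threshold,
    sprintf("(certificate %.4f)\n", x$certificate))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Classify level signatures against cluster models
#'
#' Assigns each point to the model with the highest Gaussian density (equal
#' priors); posteriors are the normalized densities. Points whose best
#' log-density falls below `floor_logdens` are left unassigned. Equal-density
#' ties break deterministically to the lexicographically first label and are
#' flagged.
#'
#' @param points A `level_signatures` table (complete cases used).
#' @param models A [fit_cluster_gaussian()] table.
#' @param floor_logdens Minimum best log-density for assignment (default
#'   `-Inf`: always assign).
#' @param axes Signature axes used (defaults to the axes the models were
#'   fitted on).
#' @return The points with columns `assigned`, `posterior` (winning mass),
#'   `tie` (logical).
#' @export
classify_levels <- function(points, models, floor_logdens = -Inf,
                            axes = NULL) {
  axes <- axes %||% attr(models, "axes") %||% .signature_axes
  pts <- .complete_points(points, axes)
  if (nrow(models) < 1) rlang::abort("need at least one model")
  X <- as.matrix(pts[, axes])
  ld <- vapply(seq_len(nrow(models)), function(j)
    .gauss_logdens(X, .model_mu(models[j, ], axes),
      .model_sd(models[j, ], axes)),
    numeric(nrow(pts)))
  ld <- matrix(ld, nrow = nrow(pts))
  ord <- order(models$label)
  ld <- ld[, ord, drop = FALSE]
  labs <- models$label[ord]
  best <- apply(ld, 1, which.max)      # first max = lexicographic tie-break
  post <- exp(ld - apply(ld, 1, max))
  post <- post / rowSums(post)
  pts$assigned <- labs[best]
  pts$posterior <- post[cbind(seq_len(nrow(pts)), best)]
  pts$tie <- apply(ld, 1, function(r) sum(r == max(r)) > 1)
  unas <- apply(ld, 1, max) < floor_logdens
  pts$assigned[unas] <- NA_character_
  pts
}

#' Identification accuracy as a function of photon budget
#'
#' Simulates levels of a target construct truncated to M photons, recomputes
#' their spectroscopic signatures, and classifies them against competitor
#' cluster models built from matched simulations — tracing how the
#' correct-identification rate grows with the photon budget. "One-sided"
#' rates pit the target against a single competitor; "two-sided" against
#' both flanking competitors.
#'
#' @param registry A registry containing target and competitors.
#' @param target Label of the construct being identified.
#' @param competitors Character vector of competitor labels.
#' @param M_grid Ascending photon budgets.
#' @param n_reps Simulated levels per budget per construct.
#' @param meta An [acquisition_meta()].
#' @param seed Seed.
#' @return Tibble: `M`, `competitor_set`, `accuracy`, `n_reps`.
#' @export
accuracy_vs_photons <- function(registry, target, competitors,
                                M_grid = c(100, 300, 1000, 3000, 6000),
                                n_reps = 200, meta = acquisition_meta(),
                                seed = 1) {
  if (is.unsorted(M_grid)) rlang::abort("`M_grid` must be ascending")
  labs <- c(target, competitors)
  sets <- c(as.list(competitors), if (length(competitors) > 1)
    list(competitors))
  withr::with_seed(seed, {
    purrr::map_dfr(M_grid, function(M) {
      sigs <- purrr::map(labs, function(lab)
        simulate_level_signatures(registry, lab, M, n_reps, meta))
      names(sigs) <- labs
      # lifetime axis is dropped when too few photons reach the fitter
      have_tau <- mean(!is.na(sigs[[target]]$tau_ns)) > 0.9
      axes <- if (have_tau) .signature_axes else c("green_b", "red_b")
      models <- purrr::imap_dfr(sigs, function(s, lab) {
        s$cluster <- lab
        fit_cluster_gaussian(s, z_max = Inf, min_size = 2, axes = axes)
      })
      purrr::map_dfr(sets, function(cs) {
        mods <- models[models$label %in% c(target, cs), ]
        cls <- classify_levels(sigs[[target]], mods, axes = axes)
        tibble::tibble(M = M,
          competitor_set = paste(cs, collapse = "+"),
          side = if (length(cs) == 1) "one-sided" else "two-sided",
          accuracy = mean(cls$assigned == target),
          n_reps = nrow(cls),
          lifetime_axis = have_tau)
      })
    })
  })
}

#' Directly simulate level signatures of one construct
#'
#' Generates `n_reps` independent levels of exactly `M` detected photons for
#' a construct (no background, no bleaching): colour split is binomial with
#' the construct's FRET branching ratio, level duration is the Gamma-
#' distributed waiting time for M photons at the construct's total rate, and
#' donor lifetimes are fitted to the simulated green parallel nanotimes.
#' This is the fast path for photon-budget studies; the full
#' [simulate_stream()] pipeline exercises the same model with background and
#' segmentation in the loop.
#'
#' @param registry,label Construct to simulate.
#' @param M Photons per level.
#' @param n_reps Number of levels.
#' @param meta An [acquisition_meta()].
#' @param min_fit_photons Minimum green parallel photons for a lifetime fit.
#' @return A `level_signatures`-shaped tibble.
#' @export
simulate_level_signatures <- function(registry, label, M, n_reps,
                                      meta = acquisition_meta(),
                                      min_fit_photons = 30) {
  cs <- registry[registry$label == label, ]
  if (nrow(cs) != 1) rlang::abort(paste0("unknown label ", label))
  E <- cs$fret_E
  p_red <- E * cs$acceptor_brightness_scale /
    ((1 - E) + E * cs$acceptor_brightness_scale)
  total_rate <- cs$donor_brightness_0 * ((1 - E) +
    E * cs$acceptor_brightness_scale) * meta$excitation_power   # counts/ms
  tau_eff <- cs$donor_lifetime_0 * (1 - E)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    n_red <- rbinom(1, M, p_red)
    n_green <- M - n_red
    dur <- rgamma(1, shape = M, rate = total_rate)            # ms
    n_gpar <- rbinom(1, n_green, 0.5)
    mt <- sample_nanotime(n_gpar, tau_eff, meta$irf, meta$pulse_period,
      meta$microtime_bin)
    fit <- fit_lifetime_mle(mt, meta$irf, meta$pulse_period,
      meta$microtime_bin, min_fit_photons = min_fit_photons)
    tibble::tibble(label = label, rep = r, n_photons = M,
      duration_ms = dur,
      green_b = n_green / dur / meta$excitation_power,
      red_b = n_red / dur / meta$excitation_power,
      fret_E = fret_efficiency(n_green, n_red),
      tau_ns = fit$tau, tau_se = fit$se, n_fit_photons = fit$n)
  })
}
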