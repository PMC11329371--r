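#' Estimate the diffusion coefficient from a trap trajectory
#'
#' Uses the feedback-corrected increment variance: subtracting the applied
#' feedback kick from each position increment leaves the pure Brownian step,
#' whose variance is \eqn{2 D \Delta t} per axis. The estimate averages both
#' axes; the confidence interval comes from a blocked bootstrap over
#' contiguous trajectory blocks (localization noise inflates the increments
#' and hence biases \eqn{\hat D} upward; with noise-free estimates the
#' estimator is unbiased).
#'
#' @param trajectory A [simulate_trap_trajectory()] result (>= 100 samples).
#' @param n_boot Bootstrap replicates.
#' @param block_len Bootstrap block length in samples.
#' @param seed Seed for the bootstrap.
#' @return A `diffusion_estimate` tibble: `D_hat` (um^2/s), `ci_lo`,
#'   `ci_hi`, `n_samples`.
#' @export
estimate_diffusion <- function(trajectory, n_boot = 200, block_len = 100,
                               seed = 1) {
  n <- nrow(trajectory)
  if (n < 100) rlang::abort("trajectory has fewer than 100 samples")
  dt <- attr(trajectory, "dt_ms")
  g <- attr(trajectory, "feedback_gain")
  inc_x <- diff(trajectory$x) + g * trajectory$x_hat[-n]
  inc_y <- diff(trajectory$y) + g * trajectory$y_hat[-n]
  to_D <- function(ix, iy) {
    v <- (sum(ix^2) + sum(iy^2)) / (length(ix) + length(iy))
    v / (2 * dt) * 1e-3               # nm^2/ms -> um^2/s
  }
  D_hat <- to_D(inc_x, inc_y)
  nb <- max(1L, floor(length(inc_x) / block_len))
  boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    starts <- sample.int(length(inc_x) - block_len + 1L, nb, replace = TRUE)
    idx <- as.vector(outer(seq_len(block_len) - 1L, starts, "+"))
    to_D(inc_x[idx], inc_y[idx])
  }, numeric(1)))
  tibble::tibble(D_hat = D_hat,
    ci_lo = as.numeric(quantile(boots, 0.025)),
    ci_hi = as.numeric(quantile(boots, 0.975)),
    n_samples = n)
}

#' Split confinement points into bound and unbound populations
#'
#' Fits one- and two-component Gaussian mixtures (diagonal covariance) to
#' the (sigma_x, sigma_y) confinement points and keeps the two-component
#' model only when AIC prefers it. The component with the smaller mean
#' radius is labelled `bound` (a larger complex diffuses more slowly and is
#' confined more tightly); points with posterior below `ambiguity` are
#' flagged `ambiguous`. If the one-component model wins, every point is
#' `unbound` and `binding_detected` is FALSE.
#'
#' @param points A [confinement_points()] table (>= 10 rows).
#' @param ambiguity Posterior threshold below which calls are ambiguous
#'   (default 0.9).
#' @return A `binding_split` object: `calls` (the points plus `state` and
#'   `posterior`), `binding_detected`, component summary `components`.
#'   [tidy()] returns the calls, [glance()] the model summary.
#' @export
split_bound_unbound <- function(points, ambiguity = 0.9) {
  if (nrow(points) < 10) rlang::abort("need at least 10 confinement points")
  X <- as.matrix(points[, c("sigma_x", "sigma_y")])
  f1 <- mclust::Mclust(X, G = 1, modelNames = "VVI", verbose = FALSE)
  f2 <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  aic <- function(f) 2 * attr(stats::logLik(f), "df") -
    2 * as.numeric(stats::logLik(f))
  two <- !is.null(f2) && aic(f2) < aic(f1)
  calls <- tibble::as_tibble(points)
  if (!two) {
    calls$state <- "unbound"
    calls$posterior <- 1
    comp <- tibble::tibble(component = "unbound",
      mean_sigma_x = mean(points$sigma_x),
      mean_sigma_y = mean(points$sigma_y), n = nrow(points))
    return(structure(list(calls = calls, binding_detected = FALSE,
      components = comp), class = "binding_split"))
  }
  mu <- f2$parameters$mean                     # 2 x G
  radius <- sqrt(colSums(mu^2))
  bound_comp <- which.min(radius)
  post <- f2$z
  state <- ifelse(apply(post, 1, which.max) == bound_comp, "bound",
    "unbound")
  pmax_post <- apply(post, 1, max)
  state[pmax_post < ambiguity] <- "ambiguous"
  calls$state <- state
  calls$posterior <- pmax_post
  comp <- tibble::tibble(
    component = ifelse(seq_len(2) == bound_comp, "bound", "unbound"),
    mean_sigma_x = mu[1, ], mean_sigma_y = mu[2, ],
    n = as.integer(table(factor(apply(post, 1, which.max), levels = 1:2))))
  structure(list(calls = calls, binding_detected = TRUE,
    components = comp), class = "binding_split")
}

#' @export
print.binding_split <- function(x, ...) {
  cat("<binding_split>", if (x$binding_detected) "two components" else
    "single component (no binding detected)", "\n")
  print(x$components)
  invisible(x)
}

#' @rdname split_bound_unbound
#' @param x A `binding_split`.
#' @param ... Unused.
#' @method tidy binding_split
#' @export
tidy.binding_split <- function(x, ...) x$calls

#' @rdname split_bound_unbound
#' @method glance binding_split
#' @export
glance.binding_split <- function(x, ...) {
  tibble::tibble(binding_detected = x$binding_detected,
    n_bound = sum(x$calls$state == "bound"),
    n_unbound = sum(x$calls$state == "unbound"),
    n_ambiguous = sum(x$calls$state == "ambiguous"))
}

#' Per-label binding efficiency
#'
#' Fraction of unambiguous calls in the bound state, per construct label,
#' with Clopper-Pearson binomial confidence intervals. Ambiguous calls are
#' excluded from the fraction and reported alongside.
#'
#' @param split A [split_bound_unbound()] result, or any tibble with
#'   `label` and `state` columns.
#' @param conf_level Confidence level (default 0.95).
#' @param unit `"point"` counts every confinement point; `"event"` first
#'   collapses calls to one majority call per trapping event (requires an
#'   `event_id` column), the right unit when binding is a per-molecule
#'   property and long dwells would otherwise be over-weighted.
#' @return Tibble: `label`, `n_bound`, `n_unbound`, `n_ambiguous`,
#'   `fraction_bound`, `ci_lo`, `ci_hi` (NA where no usable calls).
#' @export
binding_efficiency <- function(split, conf_level = 0.95,
                               unit = c("point", "event")) {
  unit <- match.arg(unit)
  calls <- if (inherits(split, "binding_split")) split$calls else split
  if (is.null(calls$label)) rlang::abort("calls carry no construct labels")
  if (unit == "event") {
    if (is.null(calls$event_id))
      rlang::abort("event-level efficiency requires an `event_id` column")
    calls <- calls |>
      dplyr::filter(.data$state != "ambiguous") |>
      dplyr::group_by(.data$label, .data$event_id) |>
      dplyr::summarise(state = ifelse(mean(.data$state == "bound") >= 0.5,
        "bound", "unbound"), .groups = "drop")
  }
  out <- calls |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_bound = sum(.data$state == "bound"),
      n_unbound = sum(.data$state == "unbound"),
      n_ambiguous = sum(.data$state == "ambiguous"),
      .groups = "drop")
  rows <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
    nb <- out$n_bound[i]; nu <- out$n_unbound[i]
    if (nb + nu == 0) {
      rlang::warn(paste0("label ", out$label[i],
        ": all calls ambiguous; no binding fraction"))
      return(tibble::tibble(fraction_bound = NA_real_, ci_lo = NA_real_,
        ci_hi = NA_real_))
    }
    bt <- binom.test(nb, nb + nu, conf.level = conf_level)
    tibble::tibble(fraction_bound = nb / (nb + nu),
      ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2])
  })
  dplyr::bind_cols(out, rows)
}
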