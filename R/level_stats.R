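#' FRET correction parameters
#'
#' Spectral crosstalk, direct acceptor excitation and detection-efficiency
#' corrections applied when converting red/green brightness to a FRET value.
#' The neutral defaults (0, 0, 1) reduce the FRET value to the uncorrected
#' proximity ratio red/(red+green), which is sufficient when FRET is used
#' only to separate spectroscopic signatures rather than to measure
#' distances.
#'
#' @param crosstalk_alpha Fraction of donor photons detected in the red
#'   channels.
#' @param direct_excitation_delta Direct acceptor excitation fraction.
#' @param gamma Red/green detection-efficiency ratio.
#' @return A `fret_corrections` list.
#' @export
fret_corrections <- function(crosstalk_alpha = 0,
                             direct_excitation_delta = 0, gamma = 1) {
  stopifnot(crosstalk_alpha >= 0, crosstalk_alpha < 1,
    direct_excitation_delta >= 0, direct_excitation_delta < 1, gamma > 0)
  structure(list(crosstalk_alpha = crosstalk_alpha,
    direct_excitation_delta = direct_excitation_delta, gamma = gamma),
    class = "fret_corrections")
}

#' Background-subtracted, power-normalized level brightness
#'
#' For each level, subtracts the expected background counts from each
#' channel, sums the parallel and perpendicular detectors per colour, and
#' normalizes by duration and excitation power to counts ms^-1 uW^-1.
#' Negative background-subtracted counts are clamped to zero and flagged.
#'
#' @param levels A [build_levels()] table.
#' @param background An [estimate_background()] result.
#' @param power Excitation power in uW.
#' @return The level table with added columns `green_b`, `red_b` (counts
#'   ms^-1 uW^-1) and logical `clamped`.
#' @export
level_brightness <- function(levels, background, power) {
  if (power <= 0) rlang::abort("`power` must be > 0")
  if (any(levels$duration_ms <= 0)) rlang::abort("levels must have duration > 0")
  bg <- setNames(background$rate_hz, background$channel)
  net <- function(ch) levels[[ch]] - bg[[ch]] * levels$duration_ms / 1000
  g <- net("Gpar") + net("Gperp")
  r <- net("Rpar") + net("Rperp")
  levels$clamped <- g < 0 | r < 0
  levels$green_b <- pmax(g, 0) / levels$duration_ms / power
  levels$red_b <- pmax(r, 0) / levels$duration_ms / power
  levels
}

#' FRET value from red and green brightness
#'
#' Computes the corrected acceptor signal
#' \eqn{A' = red - \alpha\,green - \delta\,(green + red)} and the FRET value
#' \eqn{E = A' / (A' + \gamma\,green)}, clamped to `[0, 1]`. With neutral
#' corrections this is the proximity ratio red/(red+green). Undefined (NA)
#' when both inputs are zero.
#'
#' @param green_b,red_b Brightness values (any common unit); vectorized.
#' @param corr A [fret_corrections()].
#' @return FRET values in `[0, 1]`, NA where undefined.
#' @export
fret_efficiency <- function(green_b, red_b, corr = fret_corrections()) {
  if (any(green_b < 0 | red_b < 0)) rlang::abort("brightness must be >= 0")
  a <- red_b - corr$crosstalk_alpha * green_b -
    corr$direct_excitation_delta * (green_b + red_b)
  e <- a / (a + corr$gamma * green_b)
  e[green_b == 0 & red_b == 0] <- NA_real_
  pmin(pmax(e, 0), 1)
}

# discrete model density over the microtime grid: single-exponential decay
# wrapped on [0, period), circularly convolved with the IRF, plus a uniform
# background fraction
.lifetime_model_density <- function(tau, irf_density, n_bins, bin_width,
                                    bkg_fraction = 0) {
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  decay <- exp(-centers / tau)
  decay <- decay / sum(decay)
  p <- Re(fft(fft(irf_density) * fft(decay), inverse = TRUE)) / n_bins
  p <- pmax(p, 0)
  p <- p / sum(p)
  (1 - bkg_fraction) * p + bkg_fraction / n_bins
}

# IRF discretized to the microtime grid, wrapped on one period. The IRF is
# evaluated at bin starts, not centres: photon microtimes are floor-quantized
# while the discrete convolution places mass at summed bin centres, and the
# half-bin offset here cancels the resulting half-bin shift (which would
# otherwise bias tau by ~bin_width/2).
.irf_density_grid <- function(irf, n_bins, bin_width) {
  period <- n_bins * bin_width
  centers <- (seq_len(n_bins) - 1) * bin_width
  if (irf$kind == "gaussian") {
    if (irf$sigma == 0) {
      d <- numeric(n_bins)
      d[floor((irf$center %% period) / bin_width) + 1] <- 1
    } else {
      # wrap the Gaussian over adjacent periods (sigma << period in practice)
      d <- dnorm(centers, irf$center, irf$sigma) +
        dnorm(centers + period, irf$center, irf$sigma) +
        dnorm(centers - period, irf$center, irf$sigma)
    }
  } else {
    src <- irf$density
    src_centers <- (seq_along(src) - 0.5) * irf$pulse_period / length(src)
    d <- stats::approx(src_centers, src, xout = centers %% period,
      rule = 2)$y
  }
  d / sum(d)
}

#' Maximum-likelihood single-exponential lifetime with IRF reconvolution
#'
#' Fits a single-exponential decay to TCSPC microtimes by maximising the
#' per-photon log-likelihood under the model density: exponential decay
#' wrapped on the excitation period (incomplete decay), circularly convolved
#' with the IRF on the microtime grid, plus an optional uniform background
#' fraction. The one-dimensional likelihood is maximised by bracketed search
#' (tolerance 1e-3 ns); the confidence interval comes from the observed
#' information at the maximum. Single-exponential fits are used even where a
#' multi-exponential model would fit better: with the modest photon counts
#' of trap levels they classify labels more robustly.
#'
#' @param microtimes Microtimes in ns (green parallel channel by
#'   convention).
#' @param irf IRF model ([irf_gaussian()] / [irf_histogram()]).
#' @param pulse_period Excitation period in ns.
#' @param microtime_bin Grid resolution in ns.
#' @param bkg_fraction Uniform background fraction in the decay model
#'   (default 0).
#' @param min_fit_photons Below this count the fit is refused (default 100;
#'   the observed-information CI is unreliable for fewer photons).
#' @param tau_range Search bracket in ns.
#' @return A `lifetime_fit` object: elements `tau`, `se`, `ci` (95%),
#'   `loglik`, `n`, `converged`, `refused`. Use [tidy()] / [glance()] for
#'   tibble views.
#' @export
fit_lifetime_mle <- function(microtimes, irf = irf_gaussian(),
                             pulse_period = 1000 / 60,
                             microtime_bin = 0.016,
                             bkg_fraction = 0,
                             min_fit_photons = 100,
                             tau_range = c(0.05, 10)) {
  n <- length(microtimes)
  ans <- structure(list(tau = NA_real_, se = NA_real_,
    ci = c(NA_real_, NA_real_), loglik = NA_real_, n = n,
    converged = FALSE, refused = TRUE), class = "lifetime_fit")
  if (n < min_fit_photons) return(ans)
  n_bins <- round(pulse_period / microtime_bin)
  counts <- tabulate(pmin(floor(microtimes / microtime_bin) + 1L, n_bins),
    nbins = n_bins)
  irf_d <- .irf_density_grid(irf, n_bins, microtime_bin)
  nll <- function(tau) {
    p <- .lifetime_model_density(tau, irf_d, n_bins, microtime_bin,
      bkg_fraction)
    -sum(counts * log(pmax(p, 1e-300)))
  }
  opt <- optimize(nll, tau_range, tol = 1e-3)
  tau <- opt$minimum
  ans$refused <- FALSE
  ans$tau <- tau
  ans$loglik <- -opt$objective
  ans$converged <- tau > tau_range[1] + 5e-3 && tau < tau_range[2] - 5e-3
  h <- max(1e-3, tau * 1e-2)
  d2 <- (nll(tau + h) - 2 * nll(tau) + nll(tau - h)) / h^2
  if (is.finite(d2) && d2 > 0) {
    ans$se <- 1 / sqrt(d2)
    ans$ci <- tau + c(-1, 1) * qnorm(0.975) * ans$se
  }
  ans
}

#' @export
print.lifetime_fit <- function(x, ...) {
  if (x$refused) {
    cat("<lifetime_fit> refused (", x$n, "photons )\n")
  } else {
    cat(sprintf("<lifetime_fit> tau = %.3f ns (se %.3f, n = %d)\n",
      x$tau, x$se, x$n))
  }
  invisible(x)
}

#' @rdname fit_lifetime_mle
#' @param x A `lifetime_fit`.
#' @param ... Unused.
#' @method tidy lifetime_fit
#' @export
tidy.lifetime_fit <- function(x, ...) {
  tibble::tibble(term = "tau_ns", estimate = x$tau, std.error = x$se,
    conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @rdname fit_lifetime_mle
#' @method glance lifetime_fit
#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, converged = x$converged,
    refused = x$refused)
}

#' Group consecutive photons into fixed-size blocks
#'
#' Divides `n` ordered photons into floor(n/M) consecutive groups of exactly
#' M photons; trailing photons beyond the last full group are unused.
#'
#' @param n Number of photons in the level.
#' @param M Group size (>= 1).
#' @return Tibble `group_index`, `idx_start`, `idx_end` (1-based photon
#'   indices within the level).
#' @export
group_photons <- function(n, M) {
  if (M < 1) rlang::abort("`M` must be >= 1")
  k <- floor(n / M)
  if (k == 0) return(tibble::tibble(group_index = integer(),
    idx_start = integer(), idx_end = integer()))
  tibble::tibble(group_index = seq_len(k),
    idx_start = (seq_len(k) - 1L) * M + 1L,
    idx_end = seq_len(k) * M)
}

#' Positional confinement over a time window of a trap trajectory
#'
#' Standard deviation of the estimated (localization-noise-carrying) x and y
#' positions over a window, as an instrument would record it.
#'
#' @param trajectory A [simulate_trap_trajectory()] result.
#' @param t_start_ms,t_stop_ms Window in trajectory time.
#' @return Tibble `sigma_x`, `sigma_y` (nm), `n_samples`.
#' @export
position_sigma <- function(trajectory, t_start_ms = -Inf, t_stop_ms = Inf) {
  sel <- trajectory$time_ms >= t_start_ms & trajectory$time_ms <= t_stop_ms
  if (sum(sel) < 2) rlang::abort("window spans fewer than 2 trajectory samples")
  tibble::tibble(sigma_x = sd(trajectory$x_hat[sel]),
    sigma_y = sd(trajectory$y_hat[sel]), n_samples = sum(sel))
}

#' Per-group confinement points for a simulated stream
#'
#' For each trapping event with an attached trajectory, event photons are
#' divided into consecutive groups of `M` photons ([group_photons()]) and
#' the positional standard deviations over each group's time span are
#' computed ([position_sigma()]). One row per group; groups spanning fewer
#' than 2 trajectory samples are dropped.
#'
#' @param stream A stream processed by [attach_trajectories()].
#' @param M Photons per group (default 1000, the grouping used for
#'   diffusion-based analyses).
#' @return A `confinement_points` tibble: `event_id`, `label`, `bound`,
#'   `group_index`, `sigma_x`, `sigma_y`, `n_samples`.
#' @export
confinement_points <- function(stream, M = 1000) {
  ev <- stream_events(stream)
  if (is.null(ev) || !"trajectory" %in% names(ev))
    rlang::abort("stream has no attached trajectories; see attach_trajectories()")
  purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    tms <- stream$macrotime_ms[!is.na(stream$event_id) &
      stream$event_id == ev$event_id[i]]
    tms <- sort(tms)
    grp <- group_photons(length(tms), M)
    if (nrow(grp) == 0) return(NULL)
    traj <- ev$trajectory[[i]]
    purrr::map_dfr(seq_len(nrow(grp)), function(g) {
      w0 <- tms[grp$idx_start[g]] - ev$start_ms[i]
      w1 <- tms[grp$idx_end[g]] - ev$start_ms[i]
      sel <- traj$time_ms >= w0 & traj$time_ms <= w1
      if (sum(sel) < 2) return(NULL)
      tibble::tibble(event_id = ev$event_id[i], label = ev$label[i],
        bound = ev$bound[i], group_index = grp$group_index[g],
        sigma_x = sd(traj$x_hat[sel]), sigma_y = sd(traj$y_hat[sel]),
        n_samples = sum(sel))
    })
  })
}

#' Per-level spectroscopic signatures
#'
#' Composes the per-level estimators into one signature table: background-
#' subtracted red/green brightness, FRET value, and the MLE donor lifetime
#' fitted to the level's green parallel microtimes. Per-level fit failures
#' are flagged, not fatal.
#'
#' @param levels A [build_levels()] table.
#' @param stream The `photon_stream` the levels came from.
#' @param background An [estimate_background()] result.
#' @param corrections A [fret_corrections()].
#' @param power Excitation power in uW; defaults to the stream metadata.
#' @param bkg_fraction Uniform background fraction passed to
#'   [fit_lifetime_mle()]. The default `NULL` derives it per level from the
#'   measured background rate (expected background photons / observed
#'   photons in the fitting channel); pass a number to fix it.
#' @param min_fit_photons Minimum green parallel photons for a lifetime fit.
#' @param fit_lifetime Set FALSE to skip lifetime fitting.
#' @return A `level_signatures` tibble: level identity and duration columns
#'   plus `green_b`, `red_b`, `fret_E`, `tau_ns`, `tau_se`, `tau_lo`,
#'   `tau_hi`, `n_fit_photons`, `clamped`.
#' @export
summarize_levels <- function(levels, stream, background,
                             corrections = fret_corrections(),
                             power = NULL, bkg_fraction = NULL,
                             min_fit_photons = 100, fit_lifetime = TRUE) {
  if (nrow(levels) == 0) {
    rlang::warn("no retained levels")
    return(structure(tibble::tibble(), class = c("level_signatures",
      class(tibble::tibble()))))
  }
  meta <- stream_meta(stream)
  power <- power %||% meta$excitation_power
  out <- level_brightness(levels, background, power)
  out$fret_E <- fret_efficiency(out$green_b, out$red_b, corrections)
  gp <- stream$channel == "Gpar"
  gp_t <- stream$macrotime_ms[gp]
  gp_mt <- stream$microtime_ns[gp]
  bg_gpar <- background$rate_hz[background$channel == "Gpar"]
  fits <- purrr::map(seq_len(nrow(out)), function(i) {
    if (!fit_lifetime) return(NULL)
    mt <- gp_mt[gp_t >= out$start_ms[i] & gp_t < out$stop_ms[i]]
    bf <- bkg_fraction %||%
      min(0.95, bg_gpar * out$duration_ms[i] / 1000 / max(length(mt), 1))
    fit_lifetime_mle(mt, meta$irf, meta$pulse_period, meta$microtime_bin,
      bf, min_fit_photons)
  })
  if (fit_lifetime) {
    out$tau_ns <- purrr::map_dbl(fits, "tau")
    out$tau_se <- purrr::map_dbl(fits, "se")
    out$tau_lo <- purrr::map_dbl(fits, ~ .x$ci[1])
    out$tau_hi <- purrr::map_dbl(fits, ~ .x$ci[2])
    out$n_fit_photons <- purrr::map_int(fits, ~ as.integer(.x$n))
  } else {
    out$tau_ns <- NA_real_
    out$tau_se <- NA_real_
    out$tau_lo <- NA_real_
    out$tau_hi <- NA_real_
    out$n_fit_photons <- NA_integer_
  }
  structure(tibble::as_tibble(out), class = c("level_signatures",
    class(tibble::tibble())))
}
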