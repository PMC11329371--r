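#' Detection channel identifiers
#'
#' Four detectors: green/red colour split, each split into parallel and
#' perpendicular polarization. Polarization channels are simulated and summed
#' downstream; no anisotropy analysis is performed.
#' @export
fret_channels <- function() c("Gpar", "Gperp", "Rpar", "Rperp")

#' Instrument response function models
#'
#' `irf_gaussian()` describes the detection timing spread as a Gaussian of
#' given centre and width; `irf_histogram()` takes a tabulated density over
#' one excitation period (equal-width bins starting at 0), as obtained from a
#' measured short-lifetime dye.
#'
#' @param center_ns,sigma_ns Gaussian centre and standard deviation in ns.
#' @param density Nonnegative vector of bin densities (normalized internally).
#' @param pulse_period Excitation period the histogram spans, ns.
#' @return An `irf_model` list.
#' @export
irf_gaussian <- function(center_ns = 2, sigma_ns = 0.25) {
  if (sigma_ns < 0) rlang::abort("`sigma_ns` must be >= 0")
  structure(list(kind = "gaussian", center = center_ns, sigma = sigma_ns),
    class = "irf_model")
}

#' @rdname irf_gaussian
#' @export
irf_histogram <- function(density, pulse_period) {
  if (any(density < 0)) rlang::abort("IRF density must be nonnegative")
  if (sum(density) <= 0) rlang::abort("IRF density must have positive mass")
  structure(list(kind = "histogram", density = density / sum(density),
    pulse_period = pulse_period), class = "irf_model")
}

# draw n delays from the IRF (ns, unwrapped)
sample_irf <- function(irf, n) {
  if (irf$kind == "gaussian") {
    if (irf$sigma == 0) rep(irf$center, n) else rnorm(n, irf$center, irf$sigma)
  } else {
    nb <- length(irf$density)
    w <- irf$pulse_period / nb
    idx <- sample.int(nb, n, replace = TRUE, prob = irf$density)
    (idx - 1) * w + runif(n, 0, w)
  }
}

.wrap_quantize <- function(t_ns, pulse_period, microtime_bin) {
  t_ns <- t_ns %% pulse_period
  t_ns <- floor(t_ns / microtime_bin) * microtime_bin
  # guard against rounding exactly onto the period edge
  pmin(t_ns, pulse_period - microtime_bin)
}

#' Sample TCSPC nanotimes for an exponential emitter
#'
#' Draws photon microtimes as (exponential decay + IRF delay), wrapped modulo
#' the excitation period (incomplete-decay conditions at high repetition
#' rate) and quantized to the TCSPC resolution. With `lifetime_tau = 0` the
#' output distribution is the IRF itself.
#'
#' @param n Number of draws.
#' @param lifetime_tau Fluorescence lifetime in ns (>= 0).
#' @param irf An [irf_gaussian()] / [irf_histogram()] model.
#' @param pulse_period Excitation period in ns (default 1/60 MHz).
#' @param microtime_bin TCSPC bin width in ns.
#' @param extra_delay_ns Optional additional per-photon delay (e.g. a FRET
#'   transfer delay preceding acceptor emission); scalar or length-n.
#' @return Numeric vector of microtimes in `[0, pulse_period)`.
#' @export
sample_nanotime <- function(n, lifetime_tau, irf,
                            pulse_period = 1000 / 60,
                            microtime_bin = 0.016,
                            extra_delay_ns = 0) {
  if (lifetime_tau < 0) rlang::abort("`lifetime_tau` must be >= 0")
  decay <- if (lifetime_tau > 0) rexp(n, rate = 1 / lifetime_tau) else
    numeric(n)
  .wrap_quantize(decay + sample_irf(irf, n) + extra_delay_ns,
    pulse_period, microtime_bin)
}

#' Acquisition metadata
#'
#' @param pulse_period_ns Excitation period in ns (default 1/60 MHz pulsed
#'   excitation, ~16.67 ns).
#' @param excitation_power_uW Excitation power in uW. The default of 80 uW
#'   puts a mid-brightness construct at a total arrival rate of ~25 kHz,
#'   the regime the analysis defaults are tuned for.
#' @param microtime_bin_ns TCSPC resolution in ns.
#' @param irf IRF model used both to simulate and to fit nanotimes.
#' @return An `acquisition_meta` list.
#' @export
acquisition_meta <- function(pulse_period_ns = 1000 / 60,
                             excitation_power_uW = 80,
                             microtime_bin_ns = 0.016,
                             irf = irf_gaussian()) {
  stopifnot(pulse_period_ns > 0, microtime_bin_ns > 0,
    microtime_bin_ns < pulse_period_ns, excitation_power_uW > 0)
  structure(list(pulse_period = pulse_period_ns,
    excitation_power = excitation_power_uW,
    microtime_bin = microtime_bin_ns, irf = irf,
    channels = fret_channels()), class = "acquisition_meta")
}

#' Simulation configuration for synthetic trapping experiments
#'
#' Describes a dilute mixture of constructs fed through a single-molecule
#' feedback trap: trapping events arrive one at a time as a Poisson process,
#' reside for an exponential dwell, and emit donor-excitation photons whose
#' colour branching follows the construct's FRET efficiency. The acceptor can
#' photobleach (after which the construct reverts to donor-only emission) and
#' optionally blink via a two-state telegraph.
#'
#' @param mixture Named numeric vector of molar fractions by construct label
#'   (normalized internally).
#' @param event_rate Trapping events per second.
#' @param dwell_mean Mean trap residence in seconds.
#' @param background_rates Named per-channel background rates, counts/s.
#' @param bleach_rate Acceptor photobleach rate, 1/s (0 = never).
#' @param blink_on_rate,blink_off_rate Telegraph rates, 1/s: `blink_off_rate`
#'   is the rate of leaving the emitting state; both default 0 (no blinking).
#' @param bound_fraction Named per-label probability that an event is a
#'   target-bound complex (affects diffusion only); labels absent default 0.
#' @param acceptor_lifetime Acceptor fluorescence lifetime, ns.
#' @param total_duration Acquisition length in seconds.
#' @param meta An [acquisition_meta()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(mixture,
                       event_rate = 0.25,
                       dwell_mean = 1.0,
                       background_rates = c(Gpar = 500, Gperp = 500,
                         Rpar = 250, Rperp = 250),
                       bleach_rate = 0,
                       blink_on_rate = 0, blink_off_rate = 0,
                       bound_fraction = NULL,
                       acceptor_lifetime = 1.0,
                       total_duration = 60,
                       meta = acquisition_meta()) {
  stopifnot(dwell_mean > 0, event_rate >= 0, bleach_rate >= 0,
    total_duration >= 0, all(background_rates >= 0))
  if (length(mixture) && is.null(names(mixture)))
    rlang::abort("`mixture` must be a named vector of fractions")
  if (length(mixture)) mixture <- mixture / sum(mixture)
  bg <- setNames(rep(0, 4), fret_channels())
  bg[names(background_rates)] <- background_rates
  structure(list(mixture = mixture, event_rate = event_rate,
    dwell_mean = dwell_mean, background_rates = bg,
    bleach_rate = bleach_rate, blink_on_rate = blink_on_rate,
    blink_off_rate = blink_off_rate,
    bound_fraction = bound_fraction %||% numeric(),
    acceptor_lifetime = acceptor_lifetime,
    total_duration = total_duration, meta = meta), class = "sim_config")
}

# alternating on/off telegraph segments over [start, end), starting "on"
.telegraph_segments <- function(start, end, off_rate, on_rate) {
  if (off_rate <= 0 || end <= start)
    return(tibble::tibble(seg_start = start, seg_end = end, on = TRUE))
  t <- start; on <- TRUE
  ss <- se <- numeric(0); st <- logical(0)
  while (t < end) {
    len <- rexp(1, rate = if (on) off_rate else on_rate)
    s_end <- min(t + len, end)
    ss <- c(ss, t); se <- c(se, s_end); st <- c(st, on)
    t <- s_end; on <- !on
  }
  tibble::tibble(seg_start = ss, seg_end = se, on = st)
}

#' Simulate a photon stream from a construct mixture
#'
#' The generator realises the statistical model the analysis assumes: Poisson
#' photon arrivals at per-channel rates set by donor brightness, FRET
#' branching and excitation power; single-exponential donor nanotimes with
#' effective lifetime \eqn{\tau_{D0}(1-E)} convolved with the IRF; acceptor
#' nanotimes with a transfer delay; uniform Poisson background per channel;
#' optional acceptor photobleaching and blinking, after/during which the
#' construct emits as donor-only. Events are queued so at most one molecule
#' is trapped at a time. Ground-truth event identities are attached for
#' testing.
#'
#' @param registry A [load_registry()] registry containing every mixture
#'   label.
#' @param config A [sim_config()].
#' @param seed Optional integer seed for exact reproducibility.
#' @return A `photon_stream`: tibble with columns `macrotime_ms`,
#'   `microtime_ns`, `channel`, and truth columns `event_id`, `label`,
#'   `bound` (NA for background photons), sorted by macrotime. Attributes:
#'   `meta` (the [acquisition_meta()]) and `events` (per-event truth table
#'   with start/end/bleach times).
#' @export
simulate_stream <- function(registry, config, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed,
    simulate_stream(registry, config)))
  labs <- names(config$mixture)
  missing <- setdiff(labs, registry$label)
  if (length(missing))
    rlang::abort(paste0("mixture labels not in registry: ",
      paste(missing, collapse = ", ")))
  meta <- config$meta
  total <- config$total_duration

  # --- trapping events: Poisson arrivals, queued one-at-a-time -------------
  ev_start <- ev_end <- numeric(0); ev_lab <- character(0)
  if (length(labs) && config$event_rate > 0 && total > 0) {
    t <- 0
    repeat {
      t_arr <- t + rexp(1, config$event_rate)
      if (t_arr >= total) break
      dwell <- rexp(1, 1 / config$dwell_mean)
      ev_start <- c(ev_start, t_arr)
      ev_end <- c(ev_end, min(t_arr + dwell, total))
      ev_lab <- c(ev_lab, sample(labs, 1, prob = config$mixture))
      t <- t_arr + dwell
    }
  }
  n_ev <- length(ev_start)
  ev_bound <- if (n_ev) {
    pb <- config$bound_fraction[ev_lab]
    pb[is.na(pb)] <- 0
    runif(n_ev) < pb
  } else logical(0)
  ev_bleach <- if (n_ev && config$bleach_rate > 0)
    ev_start + rexp(n_ev, config$bleach_rate) else rep(Inf, n_ev)

  parts <- vector("list", n_ev + 1L)
  for (i in seq_len(n_ev)) {
    cs <- registry[registry$label == ev_lab[i], ]
    # acceptor-active segments: telegraph blinking truncated at bleach
    segs <- .telegraph_segments(ev_start[i], ev_end[i],
      config$blink_off_rate, config$blink_on_rate)
    segs$on <- segs$on & segs$seg_start < ev_bleach[i]
    segs$seg_end2 <- pmin(segs$seg_end, ifelse(segs$on, ev_bleach[i],
      segs$seg_end))
    # re-split the segment containing the bleach time
    extra <- segs[segs$on & segs$seg_end > ev_bleach[i], ]
    if (nrow(extra)) {
      extra$seg_start <- ev_bleach[i]; extra$on <- FALSE
      extra$seg_end2 <- extra$seg_end
    }
    segs$seg_end <- segs$seg_end2
    segs <- rbind(segs[segs$seg_end > segs$seg_start,
      c("seg_start", "seg_end", "on")],
      extra[extra$seg_end > extra$seg_start,
        c("seg_start", "seg_end", "on")])
    seg_parts <- lapply(seq_len(nrow(segs)), function(s) {
      E <- if (segs$on[s]) cs$fret_E else 0
      .simulate_emission(cs, E, segs$seg_start[s], segs$seg_end[s],
        config, meta)
    })
    ph <- dplyr::bind_rows(seg_parts)
    if (nrow(ph)) {
      ph$event_id <- i; ph$label <- ev_lab[i]; ph$bound <- ev_bound[i]
    }
    parts[[i]] <- ph
  }

  # --- background ----------------------------------------------------------
  bgp <- lapply(fret_channels(), function(ch) {
    n <- rpois(1, config$background_rates[[ch]] * total)
    tibble::tibble(
      t_s = runif(n, 0, total),
      microtime_ns = .wrap_quantize(runif(n, 0, meta$pulse_period),
        meta$pulse_period, meta$microtime_bin),
      channel = rep(ch, n))
  })
  bg <- dplyr::bind_rows(bgp)
  if (nrow(bg)) {
    bg$event_id <- NA_integer_; bg$label <- NA_character_; bg$bound <- NA
  }
  parts[[n_ev + 1L]] <- bg

  ph <- dplyr::bind_rows(parts)
  if (!nrow(ph))
    ph <- tibble::tibble(t_s = numeric(), microtime_ns = numeric(),
      channel = character(), event_id = integer(), label = character(),
      bound = logical())
  ph <- ph[order(ph$t_s), ]
  out <- tibble::tibble(
    macrotime_ms = ph$t_s * 1000,
    microtime_ns = ph$microtime_ns,
    channel = ph$channel,
    event_id = as.integer(ph$event_id),
    label = ph$label,
    bound = ph$bound)
  events <- tibble::tibble(event_id = seq_len(n_ev), label = ev_lab,
    bound = ev_bound, start_ms = ev_start * 1000, end_ms = ev_end * 1000,
    bleach_ms = ev_bleach * 1000)
  new_photon_stream(out, meta, events)
}

# photons from one constant-E emission segment of one event
.simulate_emission <- function(cs, E, seg_start, seg_end, config, meta) {
  dur <- seg_end - seg_start
  P <- meta$excitation_power
  tau_eff <- cs$donor_lifetime_0 * (1 - E)
  g_rate <- cs$donor_brightness_0 * (1 - E) * P * 1000          # counts/s
  r_rate <- cs$donor_brightness_0 * E * cs$acceptor_brightness_scale *
    P * 1000
  ng <- rpois(1, g_rate * dur)
  nr <- rpois(1, r_rate * dur)
  g_mt <- sample_nanotime(ng, tau_eff, meta$irf, meta$pulse_period,
    meta$microtime_bin)
  transfer <- if (tau_eff > 0) rexp(nr, 1 / tau_eff) else numeric(nr)
  r_mt <- sample_nanotime(nr, config$acceptor_lifetime, meta$irf,
    meta$pulse_period, meta$microtime_bin, extra_delay_ns = transfer)
  tibble::tibble(
    t_s = runif(ng + nr, seg_start, seg_end),
    microtime_ns = c(g_mt, r_mt),
    channel = c(sample(c("Gpar", "Gperp"), ng, replace = TRUE),
      sample(c("Rpar", "Rperp"), nr, replace = TRUE)))
}

new_photon_stream <- function(tbl, meta, events = NULL) {
  structure(tbl, meta = meta, events = events,
    class = c("photon_stream", class(tibble::tibble())))
}

#' @export
`[.photon_stream` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- new_photon_stream(tibble::as_tibble(out), attr(x, "meta"),
      attr(x, "events"))
  out
}

#' Stream metadata and ground-truth event accessors
#' @param stream A `photon_stream`.
#' @return `stream_meta()`: the [acquisition_meta()]; `stream_events()`: the
#'   truth event table, or NULL for streams without ground truth.
#' @export
stream_meta <- function(stream) attr(stream, "meta")

#' @rdname stream_meta
#' @export
stream_events <- function(stream) attr(stream, "events")

#' Simulate a feedback-trap localization trajectory
#'
#' Discrete-time model of a trapped Brownian particle under proportional
#' feedback: per axis,
#' \eqn{x_{t+1} = x_t - g\,\hat{x}_t + \sqrt{2 D \Delta t}\,\xi_t}
#' with \eqn{\hat{x}_t = x_t + \epsilon_t} the noisy position estimate the
#' controller acts on. With zero localization noise the true position is an
#' AR(1) process with stationary variance \eqn{2 D \Delta t / (1-(1-g)^2)}.
#'
#' @param diffusion_D Diffusion coefficient in um^2/s.
#' @param feedback_gain Proportional gain per step, in (0, 1].
#' @param dt_ms Feedback period in ms.
#' @param n_steps Number of steps.
#' @param localization_noise Localization error sd in nm.
#' @param seed Optional seed.
#' @return A `trap_trajectory` tibble: `time_ms`, true positions `x`, `y`
#'   (nm), estimates `x_hat`, `y_hat`, applied feedback `fx`, `fy`.
#'   Attributes record the generating parameters.
#' @export
simulate_trap_trajectory <- function(diffusion_D, feedback_gain = 0.5,
                                     dt_ms = 0.1, n_steps = 1000,
                                     localization_noise = 0, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed,
    simulate_trap_trajectory(diffusion_D, feedback_gain, dt_ms, n_steps,
      localization_noise)))
  if (dt_ms <= 0) rlang::abort("`dt_ms` must be > 0")
  if (feedback_gain <= 0 || feedback_gain > 1)
    rlang::abort("`feedback_gain` must be in (0, 1]")
  if (diffusion_D < 0) rlang::abort("`diffusion_D` must be >= 0")
  # step displacement sd in nm: D[um^2/s] = 1e6 nm^2/s, dt in s = dt_ms*1e-3
  step_sd <- sqrt(2 * diffusion_D * dt_ms * 1e3)
  one_axis <- function() {
    xi <- rnorm(n_steps, 0, step_sd)
    eps <- if (localization_noise > 0)
      rnorm(n_steps, 0, localization_noise) else numeric(n_steps)
    innov <- -feedback_gain * eps + xi
    x <- as.numeric(stats::filter(innov, 1 - feedback_gain,
      method = "recursive"))
    # x[t] is the position after step t; the estimate used at step t was of
    # the position before the kick. Shift so columns align per sample.
    x_pre <- c(0, x[-n_steps])
    list(x = x_pre, x_hat = x_pre + eps)
  }
  ax <- one_axis(); ay <- one_axis()
  tbl <- tibble::tibble(
    time_ms = (seq_len(n_steps) - 1) * dt_ms,
    x = ax$x, y = ay$x, x_hat = ax$x_hat, y_hat = ay$x_hat,
    fx = -feedback_gain * ax$x_hat, fy = -feedback_gain * ay$x_hat)
  structure(tbl, diffusion_D = diffusion_D, feedback_gain = feedback_gain,
    dt_ms = dt_ms, localization_noise = localization_noise,
    class = c("trap_trajectory", class(tibble::tibble())))
}

#' Default trap-simulation parameters
#'
#' @param D_ref_um2_s Diffusion coefficient of the reference free label
#'   (Stokes-Einstein for a ~2 nm particle in water at room temperature).
#' @param radius_ref_nm Hydrodynamic radius of that reference, nm.
#' @param bound_radius_multiplier Radius multiplier for target-bound
#'   complexes.
#' @param feedback_gain,dt_ms,localization_noise_nm Feedback-loop
#'   parameters, see [simulate_trap_trajectory()].
#' @return A `trap_params` list.
#' @export
trap_params <- function(D_ref_um2_s = 107, radius_ref_nm = 2,
                        bound_radius_multiplier = 3,
                        feedback_gain = 0.5, dt_ms = 0.1,
                        localization_noise_nm = 30) {
  structure(list(D_ref = D_ref_um2_s, radius_ref = radius_ref_nm,
    bound_multiplier = bound_radius_multiplier,
    feedback_gain = feedback_gain, dt_ms = dt_ms,
    localization_noise = localization_noise_nm), class = "trap_params")
}

#' Attach per-event trap trajectories to a simulated stream
#'
#' Each ground-truth trapping event gains a localization trajectory whose
#' diffusion coefficient follows Stokes-Einstein scaling from the event's
#' construct radius, \eqn{D \propto 1/r}, with the radius multiplied by
#' `bound_radius_multiplier` for bound events (slower diffusion, tighter
#' confinement). Photons map to trajectory samples by macrotime.
#'
#' @param stream A simulated `photon_stream` carrying truth events.
#' @param registry The registry used to simulate it.
#' @param trap A [trap_params()].
#' @param seed Optional seed.
#' @return The stream with a `trajectory` list-column added to its events
#'   attribute (see [stream_events()]).
#' @export
attach_trajectories <- function(stream, registry, trap = trap_params(),
                                seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed,
    attach_trajectories(stream, registry, trap)))
  ev <- stream_events(stream)
  if (is.null(ev))
    rlang::abort("stream has no ground-truth events; trajectories require truth")
  radius <- registry$hydrodynamic_radius[match(ev$label, registry$label)]
  radius <- radius * ifelse(ev$bound, trap$bound_multiplier, 1)
  ev$diffusion_D <- trap$D_ref * trap$radius_ref / radius
  ev$trajectory <- lapply(seq_len(nrow(ev)), function(i) {
    n_steps <- max(2L, ceiling((ev$end_ms[i] - ev$start_ms[i]) / trap$dt_ms))
    simulate_trap_trajectory(ev$diffusion_D[i], trap$feedback_gain,
      trap$dt_ms, n_steps, trap$localization_noise)
  })
  new_photon_stream(tibble::as_tibble(stream), stream_meta(stream), ev)
}
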