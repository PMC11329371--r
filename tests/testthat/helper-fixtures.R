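# Shared fixtures, built in code. Heavier simulated objects are memoised per
# test session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a fast acquisition: low background, short dwell, modest power
quick_sim <- function(labels, fractions = NULL, duration = 30,
                      event_rate = 0.4, dwell_mean = 0.6, ...) {
  fr <- fractions %||% rep(1 / length(labels), length(labels))
  sim_config(mixture = setNames(fr, labels), total_duration = duration,
    event_rate = event_rate, dwell_mean = dwell_mean, ...)
}

# two-construct stream reused across segmentation / level tests
two_construct_stream <- function() {
  fixture("two_construct_stream", function() {
    reg <- load_registry()
    st <- simulate_stream(reg, quick_sim(c("AB12", "AB16"), duration = 30),
      seed = 42)
    cps <- merge_change_points(purrr::map(
      setNames(fret_channels(), fret_channels()),
      function(ch) detect_change_points(
        st$macrotime_ms[st$channel == ch], seed = 7)))
    lv <- build_levels(st, cps, 150)
    bg <- estimate_background(bin_stream(st))
    sig <- suppressWarnings(summarize_levels(lv, st, bg))
    list(registry = reg, stream = st, cps = cps, levels = lv,
      background = bg, signatures = sig)
  })
}

# synthetic cluster model row
model_row <- function(label, mu, sdv, n = 100) {
  tibble::tibble(label = label, mu_green = mu[1], mu_red = mu[2],
    mu_tau = mu[3], sd_green = sdv[1], sd_red = sdv[2], sd_tau = sdv[3],
    n_members = n, n_rejected = 0L)
}

# brute-force maximum compatible subset by subset enumeration (oracle)
brute_force_subset <- function(p, threshold) {
  n <- nrow(p)
  ok <- (p <= threshold) & (t(p) <= threshold)
  diag(ok) <- TRUE
  best <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= length(best)) next
    if (all(ok[idx, idx])) best <- idx
  }
  best
}

# per-group confinement points from independent trajectory windows
sigma_points <- function(n, D, label = "AB6", bound = FALSE, seed = 1,
                         event_offset = 0L) {
  # per-group confinement points from independent trajectory windows
  withr::with_seed(seed, purrr::map_dfr(seq_len(n), function(i) {
    tr <- simulate_trap_trajectory(D, 0.5, 0.1, 400, localization_noise = 0)
    ps <- position_sigma(tr)
    tibble::tibble(event_id = event_offset + i, label = label,
      bound = bound, group_index = 1L, sigma_x = ps$sigma_x,
      sigma_y = ps$sigma_y, n_samples = ps$n_samples)
  }))
}

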