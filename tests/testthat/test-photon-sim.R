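test_that("nanotime sampling collapses to the IRF at tau = 0", {
  mt <- sample_nanotime(100, 0, irf_gaussian(3, 0), microtime_bin = 0.016)
  expect_true(all(mt == floor(3 / 0.016) * 0.016))
  # and every draw lies within one excitation period
  mt2 <- sample_nanotime(5000, 2.5, irf_gaussian(), microtime_bin = 0.016)
  expect_true(all(mt2 >= 0 & mt2 < 1000 / 60))
  expect_error(sample_nanotime(10, -1, irf_gaussian()), "lifetime_tau")
})

test_that("nanotime sample mean recovers the lifetime (Monte-Carlo oracle)", {
  withr::with_seed(11, {
    mt <- sample_nanotime(1e6, 1.60, irf_gaussian(0, 0),
      microtime_bin = 0.001)
  })
  # fine quantization: bias ~ bin/2 = 5e-4 ns, well inside the MC band
  expect_equal(mean(mt), 1.60, tolerance = 3 * 1.60 / sqrt(1e6) / 1.60)
})

test_that("histogram IRFs are normalized and sampled within the period", {
  h <- irf_histogram(c(0, 5, 3, 0), pulse_period = 8)
  expect_equal(sum(h$density), 1)
  mt <- withr::with_seed(2, sample_nanotime(2000, 0, h, pulse_period = 8,
    microtime_bin = 0.01))
  expect_true(all(mt >= 2 & mt < 6))   # only bins 2 and 3 have mass
  expect_error(irf_histogram(c(-1, 1), 8), "nonnegative")
})

test_that("stream simulation respects FRET branching and background rates", {
  reg <- load_registry()
  # E = 0 construct: explicit-E config entry, zero background -> all green
  cfg0 <- registry_config(reg)
  cfg0$constructs[[1]]$E <- 0
  reg0 <- load_registry(cfg0)
  st <- simulate_stream(reg0, quick_sim(cfg0$constructs[[1]]$label,
    duration = 10, background_rates = c(Gpar = 0)), seed = 1)
  expect_true(all(st$channel %in% c("Gpar", "Gperp")))

  # background-only: Poisson count oracle at 2000 counts/s x 10 s
  st_bg <- simulate_stream(reg, sim_config(mixture = setNames(1, "AB12"),
    event_rate = 0, total_duration = 10,
    background_rates = c(Gpar = 500, Gperp = 500, Rpar = 500, Rperp = 500)),
    seed = 3)
  expect_lt(abs(nrow(st_bg) - 20000), 3 * sqrt(20000))
  expect_true(all(is.na(st_bg$event_id)))

  # half-transfer construct: red fraction ~ 0.5
  cfg5 <- registry_config(reg)
  cfg5$constructs[[1]]$E <- 0.5
  reg5 <- load_registry(cfg5)
  st5 <- simulate_stream(reg5, quick_sim(cfg5$constructs[[1]]$label,
    duration = 20, background_rates = c(Gpar = 0)), seed = 4)
  red <- mean(st5$channel %in% c("Rpar", "Rperp"))
  expect_equal(red, 0.5, tolerance = 3 / sqrt(nrow(st5)) / 0.5)
})

test_that("streams are ordered, truth-covered, and seed-reproducible", {
  reg <- load_registry()
  cfg <- quick_sim(c("AB10", "AB14"), duration = 10)
  s1 <- simulate_stream(reg, cfg, seed = 99)
  s2 <- simulate_stream(reg, cfg, seed = 99)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_false(is.unsorted(s1$macrotime_ms))
  ev <- stream_events(s1)
  expect_true(all(stats::na.omit(s1$event_id) %in% ev$event_id))
  # zero-length acquisition degenerates to an empty stream with metadata
  s0 <- simulate_stream(reg, quick_sim("AB10", duration = 0), seed = 1)
  expect_equal(nrow(s0), 0)
  expect_s3_class(stream_meta(s0), "acquisition_meta")
  expect_error(simulate_stream(reg, quick_sim("NOPE")), "not in registry")
})

test_that("acceptor photobleaching reverts emission to donor-only", {
  reg <- load_registry()
  st <- simulate_stream(reg, quick_sim("AB14", duration = 40,
    event_rate = 0.5, dwell_mean = 1.5, bleach_rate = 1.5,
    background_rates = c(Gpar = 0)), seed = 21)
  ev <- stream_events(st)
  ev <- ev[ev$bleach_ms < ev$end_ms - 100, ]     # events that bleached
  expect_gt(nrow(ev), 0)
  post <- purrr::map_dfr(seq_len(nrow(ev)), function(i)
    st[!is.na(st$event_id) & st$event_id == ev$event_id[i] &
      st$macrotime_ms > ev$bleach_ms[i], ])
  # post-bleach photons are all green, and their lifetime is donor-only
  expect_true(all(post$channel %in% c("Gpar", "Gperp")))
  mt <- post$microtime_ns[post$channel == "Gpar"]
  fit <- fit_lifetime_mle(mt)
  expect_equal(fit$tau, 1.60, tolerance = 0.05 / 1.60)
})

test_that("trap trajectory matches the discrete OU closed form", {
  tr0 <- simulate_trap_trajectory(0, 0.5, 1, 100, 0, seed = 1)
  expect_true(all(tr0$x == 0) && all(tr0$y == 0))
  tr <- simulate_trap_trajectory(1, 0.5, 1, 1e5, 0, seed = 3)
  v_exp <- 2 * 1 * 1e3 * 1 / (1 - 0.25)
  expect_equal(var(tr$x), v_exp, tolerance = 0.05)
  expect_equal(var(tr$y), v_exp, tolerance = 0.05)
  # linear scaling in D, paired seeds
  tr2 <- simulate_trap_trajectory(2, 0.5, 1, 1e5, 0, seed = 3)
  expect_equal(var(tr2$x) / var(tr$x), 2, tolerance = 0.05)
  expect_error(simulate_trap_trajectory(1, 0.5, 0, 10), "dt")
  expect_error(simulate_trap_trajectory(1, 1.5, 1, 10), "feedback_gain")
})

test_that("trajectories attach with Stokes-Einstein scaled diffusion", {
  reg <- load_registry()
  cfgl <- registry_config(reg)
  cfgl$constructs[[1]]$hydrodynamic_radius_nm <- 6   # 3x the default 2 nm
  regl <- load_registry(cfgl)
  big <- cfgl$constructs[[1]]$label
  small <- cfgl$constructs[[2]]$label
  st <- simulate_stream(regl, quick_sim(c(big, small), duration = 40,
    event_rate = 0.5), seed = 8)
  st <- attach_trajectories(st, regl, seed = 9)
  ev <- stream_events(st)
  expect_equal(unique(ev$diffusion_D[ev$label == small]) /
    unique(ev$diffusion_D[ev$label == big]), 3.0)
  expect_equal(nrow(ev$trajectory[[1]]),
    max(2, ceiling((ev$end_ms[1] - ev$start_ms[1]) / 0.1)))
  # streams without truth cannot get trajectories
  bare <- structure(tibble::as_tibble(st), meta = stream_meta(st),
    class = class(st))
  attr(bare, "events") <- NULL
  expect_error(attach_trajectories(bare, regl), "truth")
})

test_that("bound events are more tightly confined than free ones", {
  reg <- load_registry()
  st <- simulate_stream(reg, quick_sim("AB6", duration = 60,
    event_rate = 0.5, dwell_mean = 1, bound_fraction = c(AB6 = 0.5)),
    seed = 13)
  st <- attach_trajectories(st, reg, seed = 14)
  ev <- stream_events(st)
  sig <- purrr::map_dbl(ev$trajectory, ~ sd(.x$x_hat))
  expect_gt(nrow(ev[ev$bound, ]), 0)
  expect_gt(nrow(ev[!ev$bound, ]), 0)
  expect_lt(mean(sig[ev$bound]), mean(sig[!ev$bound]))
})
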