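mk_level <- function(Gpar = 0, Gperp = 0, Rpar = 0, Rperp = 0,
                     duration = 100) {
  tibble::tibble(level_id = 1L, start_ms = 0, stop_ms = duration,
    duration_ms = duration, Gpar = Gpar, Gperp = Gperp, Rpar = Rpar,
    Rperp = Rperp, n_photons = Gpar + Gperp + Rpar + Rperp)
}

mk_bg <- function(g = 0, r = 0) {
  tibble::tibble(channel = fret_channels(), rate_hz = c(g, g, r, r),
    K = 1L)
}

test_that("level brightness is background-subtracted and power-normalized", {
  # 500 green counts over 100 ms at 10 uW, no background
  b <- level_brightness(mk_level(Gpar = 250, Gperp = 250), mk_bg(), 10)
  expect_equal(b$green_b, 0.5)
  expect_equal(b$red_b, 0)
  # 600 counts with 1000 counts/s background over 100 ms: (600-100)/100/10
  b2 <- level_brightness(mk_level(Gpar = 300, Gperp = 300), mk_bg(g = 500),
    10)
  expect_equal(b2$green_b, 0.5)
  expect_false(b2$clamped)
  # counts below expected background clamp to 0 with a flag
  b3 <- level_brightness(mk_level(Gpar = 10, Gperp = 10), mk_bg(g = 500), 10)
  expect_equal(b3$green_b, 0)
  expect_true(b3$clamped)
  # units contract: doubling power halves brightness
  expect_equal(level_brightness(mk_level(Gpar = 250, Gperp = 250),
    mk_bg(), 20)$green_b, 0.25)
  expect_error(level_brightness(mk_level(), mk_bg(), 0), "power")
})

test_that("FRET value reduces to the proximity ratio and applies corrections", {
  expect_equal(fret_efficiency(0.3, 0.3), 0.5)
  expect_equal(fret_efficiency(0.2, 0), 0)
  expect_equal(fret_efficiency(0.1, 0.3), 0.75)
  expect_true(is.na(fret_efficiency(0, 0)))
  # gamma rebalances the donor term
  expect_equal(fret_efficiency(0.3, 0.3,
    fret_corrections(gamma = 2)), 0.3 / (0.3 + 0.6))
  # crosstalk removes a green leak from the red signal
  expect_equal(fret_efficiency(0.4, 0.24,
    fret_corrections(crosstalk_alpha = 0.1)),
    (0.24 - 0.04) / ((0.24 - 0.04) + 0.4))
  expect_error(fret_efficiency(-1, 0), ">= 0")
})

test_that("lifetime MLE recovers the family lifetimes at 1e4 photons", {
  devs <- withr::with_seed(8, purrr::map_dbl(c(1.07, 1.25, 1.51, 1.60),
    function(tau) {
      fit <- fit_lifetime_mle(sample_nanotime(1e4, tau, irf_gaussian()))
      expect_true(fit$converged)
      expect_lt(abs(fit$ci[2] - fit$ci[1]), 0.2)
      fit$tau - tau
    }))
  expect_true(all(abs(devs) <= 0.03))
})

test_that("lifetime fitting refuses starved input and models background", {
  f <- fit_lifetime_mle(numeric(0))
  expect_true(f$refused)
  expect_true(is.na(f$tau))
  f2 <- fit_lifetime_mle(runif(50, 0, 16))
  expect_true(f2$refused)
  # 20% uniform contamination, declared to the model
  mt <- withr::with_seed(9, c(sample_nanotime(8000, 0.8, irf_gaussian()),
    runif(2000, 0, 1000 / 60)))
  f3 <- fit_lifetime_mle(mt, bkg_fraction = 0.2)
  expect_equal(f3$tau, 0.8, tolerance = 0.04)
  td <- tidy(f3)
  expect_equal(td$estimate, f3$tau)
  expect_true(td$conf.low < f3$tau && td$conf.high > f3$tau)
  expect_false(glance(f3)$refused)
})

test_that("lifetime estimator tightens as 1/sqrt(n)", {
  sds <- withr::with_seed(10, purrr::map_dbl(c(100, 1000, 10000),
    function(n) {
      est <- purrr::map_dbl(1:12, function(r)
        fit_lifetime_mle(sample_nanotime(n, 1.25, irf_gaussian()),
          min_fit_photons = 50)$tau)
      sd(est)
    }))
  expect_true(all(diff(sds) < 0))
  # scatter shrinks roughly threefold per decade
  expect_equal(sds[1] / sds[3], 10, tolerance = 0.6)
})

test_that("photon grouping uses floor division with unused remainder", {
  g <- group_photons(3500, 1000)
  expect_equal(nrow(g), 3)
  expect_equal(g$idx_end[3], 3000)
  expect_equal(nrow(group_photons(999, 1000)), 0)
  expect_error(group_photons(10, 0), "M")
})

test_that("position sigma matches the OU stationary spread", {
  tr <- simulate_trap_trajectory(1, 0.5, 1, 2e4, 0, seed = 12)
  ps <- position_sigma(tr)
  v_exp <- 2 * 1e3 / (1 - 0.25)
  expect_equal(ps$sigma_x, sqrt(v_exp), tolerance = 0.05)
  expect_error(position_sigma(tr, 0, 0.5), "fewer than 2")
  # larger D gives a larger sigma, paired seeds
  tr_big <- simulate_trap_trajectory(4, 0.5, 1, 2e4, 0, seed = 12)
  expect_gt(position_sigma(tr_big)$sigma_x, ps$sigma_x)
})

test_that("level signatures recover simulator ground truth end to end", {
  fx <- two_construct_stream()
  sig <- fx$signatures
  reg <- fx$registry
  for (lab in c("AB12", "AB16")) {
    rows <- sig[!is.na(sig$label) & sig$label == lab &
      sig$n_photons > 3000, ]
    expect_gt(nrow(rows), 0)
    truth <- reg[reg$label == lab, ]
    expect_equal(mean(rows$fret_E), truth$fret_E, tolerance = 0.02)
    expect_equal(mean(rows$tau_ns),
      truth$donor_lifetime_0 * (1 - truth$fret_E), tolerance = 0.06)
    expect_equal(mean(rows$green_b),
      truth$donor_brightness_0 * (1 - truth$fret_E), tolerance = 0.08)
  }
  # realistic trapping levels carry thousands of photons
  expect_gt(median(sig$n_photons[!is.na(sig$label)]), 5000)
  expect_warning(summarize_levels(fx$levels[0, ], fx$stream,
    fx$background), "no retained levels")
})
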