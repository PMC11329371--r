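test_that("binning conserves photons and places them by floor division", {
  reg <- load_registry()
  meta <- acquisition_meta()
  one <- structure(tibble::tibble(macrotime_ms = 25, microtime_ns = 1,
    channel = "Gpar"), meta = meta,
    class = c("photon_stream", class(tibble::tibble())))
  tr <- bin_stream(one, 10)
  expect_equal(tr$Gpar[tr$bin_index == 2], 1)
  expect_equal(sum(tr$Gpar), 1)
  st <- two_construct_stream()$stream
  tr2 <- bin_stream(st)
  expect_equal(attr(tr2, "bin_width"), 10)
  expect_equal(sum(tr2$Gpar, tr2$Gperp, tr2$Rpar, tr2$Rperp), nrow(st))
  empty <- st[0, ]
  expect_warning(tre <- bin_stream(empty), "empty")
  expect_equal(nrow(tre), 0)
})

test_that("background is recovered from a trace with trapping segments", {
  # constant-rate channel: K = 1, background ~ rate
  withr::with_seed(5, {
    counts <- rpois(600, 20)   # 20 per 10 ms bin = 2 kHz
    tr <- structure(tibble::tibble(bin_index = seq_along(counts) - 1,
      start_ms = (seq_along(counts) - 1) * 10, Gpar = counts,
      Gperp = 0L, Rpar = 0L, Rperp = 0L), bin_width = 10,
      class = c("binned_trace", class(tibble::tibble())))
    bg <- estimate_background(tr)
  })
  expect_equal(bg$K[bg$channel == "Gpar"], 1)
  expect_equal(bg$rate_hz[bg$channel == "Gpar"], 2000, tolerance = 0.05)
  expect_equal(bg$rate_hz[bg$channel == "Gperp"], 0)

  # 2 kHz background + 30 kHz occupied segments: K = 2, bg within 10%
  withr::with_seed(6, {
    occupied <- rep(c(FALSE, TRUE), times = c(400, 200))
    counts <- rpois(600, ifelse(occupied, 300, 20))
    tr2 <- structure(tibble::tibble(bin_index = seq_along(counts) - 1,
      start_ms = (seq_along(counts) - 1) * 10, Gpar = counts,
      Gperp = 0L, Rpar = 0L, Rperp = 0L), bin_width = 10,
      class = c("binned_trace", class(tibble::tibble())))
    bg2 <- estimate_background(tr2)
  })
  expect_equal(bg2$K[bg2$channel == "Gpar"], 2)
  expect_equal(bg2$rate_hz[bg2$channel == "Gpar"], 2000, tolerance = 0.10)
})

test_that("change-point detection finds and localizes a rate step", {
  # 5 kHz -> 50 kHz step at t = 100 ms, >= 500 photons per side
  # (uniform order statistics conditional on the per-side counts)
  locs <- withr::with_seed(31, purrr::map_dbl(1:10, function(r) {
    t_left <- sort(runif(500, 0, 100))
    t_right <- sort(runif(1000, 100, 120))
    cps <- detect_change_points(c(t_left, t_right), alpha = 0.05)
    expect_gte(nrow(cps), 1)
    cps$time_ms[which.max(cps$stat)]
  }))
  expect_true(all(abs(locs - 100) <= 2))
  expect_error(detect_change_points(c(3, 1, 2)), "sorted")
  expect_equal(nrow(detect_change_points(c(1))), 0)
  expect_equal(nrow(detect_change_points(numeric(0))), 0)
})

test_that("homogeneous streams rarely trigger a change point", {
  # type-I calibration: detection fraction over homogeneous Poisson streams
  n_streams <- 300
  hits <- withr::with_seed(17, purrr::map_lgl(seq_len(n_streams), function(r)
    nrow(detect_change_points(sort(runif(200, 0, 1000)), alpha = 0.05)) > 0))
  rate <- mean(hits)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_streams))
})

test_that("per-channel change points merge by photon-weighted window", {
  cp <- function(t, n) structure(tibble::tibble(time_ms = t,
    stat = 50, n_segment = n),
    class = c("change_points", class(tibble::tibble())))
  m <- merge_change_points(list(cp(100, 100), cp(100, 300)), 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$time_ms, 100)
  m2 <- merge_change_points(list(cp(100.0, 100), cp(100.4, 300)), 1)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$time_ms, (100 * 100 + 100.4 * 300) / 400)
  m3 <- merge_change_points(list(cp(100, 100), cp(200, 100)), 1)
  expect_equal(nrow(m3), 2)
})

test_that("levels tile the acquisition and respect the duration filter", {
  fx <- two_construct_stream()
  st <- fx$stream
  cp3 <- structure(tibble::tibble(
    time_ms = c(5000, 12000, 20000), stat = 100, n_segment = 1000),
    class = c("change_points", class(tibble::tibble())))
  lv_all <- build_levels(st, cp3, min_duration = 0)
  expect_equal(attr(lv_all, "n_candidate"), 4)
  # partition property: every photon in exactly one candidate level
  expect_equal(sum(lv_all$n_photons), nrow(st))
  expect_true(all(lv_all$start_ms[-1] == lv_all$stop_ms[-nrow(lv_all)]))
  # duration filter boundary: a 149 ms level is excluded at the default
  cp_near <- structure(tibble::tibble(
    time_ms = c(10000, 10149), stat = 100, n_segment = 1000),
    class = c("change_points", class(tibble::tibble())))
  lv_f <- build_levels(st, cp_near, min_duration = 150)
  expect_false(any(abs(lv_f$duration_ms - 149) < 1e-9))
  lv_100 <- build_levels(st, cp_near, min_duration = 100)
  expect_true(any(abs(lv_100$duration_ms - 149) < 1e-9))
  # truth labelling is attached with high purity for trapping levels
  lab <- fx$levels[!is.na(fx$levels$label), ]
  expect_gt(nrow(lab), 0)
  expect_true(all(lab$purity > 0.8))
})
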