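#' Bin a photon stream into a per-channel time trace
#'
#' @param stream A `photon_stream`.
#' @param bin_width Bin width in ms (default 10, the display/background
#'   binning).
#' @return A `binned_trace` tibble: `bin_index`, `start_ms`, and one count
#'   column per detection channel. Attribute `bin_width` records the width.
#' @export
bin_stream <- function(stream, bin_width = 10) {
  if (bin_width <= 0) rlang::abort("`bin_width` must be > 0")
  if (nrow(stream) == 0) {
    rlang::warn("empty stream: returning an empty trace")
    out <- tibble::tibble(bin_index = integer(), start_ms = double())
    for (ch in fret_channels()) out[[ch]] <- integer()
    return(structure(out, bin_width = bin_width,
      class = c("binned_trace", class(tibble::tibble()))))
  }
  idx <- floor(stream$macrotime_ms / bin_width)
  bins <- seq(0L, max(idx))
  out <- tibble::tibble(bin_index = bins, start_ms = bins * bin_width)
  for (ch in fret_channels()) {
    sel <- idx[stream$channel == ch]
    out[[ch]] <- tabulate(sel + 1L, nbins = length(bins))
  }
  structure(out, bin_width = bin_width,
    class = c("binned_trace", class(tibble::tibble())))
}

#' Estimate per-channel background rates by AIC-optimised K-means
#'
#' Clusters the binned counts of each channel for K = 1..`max_K`, scores each
#' model by AIC with a Poisson likelihood (each cluster one rate parameter),
#' and reports the mean rate of the lowest-mean cluster of the AIC-optimal K
#' as the channel background. With trapping events present the counts are
#' bimodal and K = 2 separates background bins from occupied bins.
#'
#' @param trace A [bin_stream()] trace.
#' @param max_K Largest candidate cluster count (default 3).
#' @return Tibble with one row per channel: `channel`, `rate_hz`
#'   (counts/s), `K`. Attribute `aic` holds the per-channel AIC table.
#' @export
estimate_background <- function(trace, max_K = 3) {
  if (max_K < 1) rlang::abort("`max_K` must be >= 1")
  if (nrow(trace) == 0) rlang::abort("`trace` is empty")
  bw <- attr(trace, "bin_width")
  chans <- intersect(fret_channels(), names(trace))
  aic_rows <- list()
  res <- purrr::map_dfr(chans, function(ch) {
    counts <- trace[[ch]]
    if (all(counts == 0)) {
      aic_rows[[ch]] <<- tibble::tibble(channel = ch, K = 1L, aic = NA_real_)
      return(tibble::tibble(channel = ch, rate_hz = 0, K = 1L))
    }
    fits <- purrr::map(seq_len(max_K), function(K) {
      if (length(unique(counts)) < K) return(NULL)
      km <- suppressWarnings(kmeans(counts, centers = K, nstart = 5,
        iter.max = 50))
      lam <- pmax(as.numeric(km$centers), 1e-9)
      prop <- tabulate(km$cluster, K) / length(counts)
      # Poisson mixture likelihood of the K rates found by K-means: a
      # hard-assignment likelihood would keep rewarding splits of a single
      # homogeneous rate, the mixture plateaus at the true cluster count
      dens <- vapply(seq_len(K), function(k)
        prop[k] * stats::dpois(counts, lam[k]), numeric(length(counts)))
      ll <- sum(log(pmax(rowSums(matrix(dens, ncol = K)), 1e-300)))
      list(K = K, aic = 2 * (2 * K - 1) - 2 * ll, centers = lam)
    })
    fits <- purrr::compact(fits)
    aics <- purrr::map_dbl(fits, "aic")
    best <- fits[[which.min(aics)]]
    aic_rows[[ch]] <<- tibble::tibble(channel = ch,
      K = purrr::map_int(fits, ~ as.integer(.x$K)), aic = aics)
    tibble::tibble(channel = ch,
      rate_hz = min(best$centers) / bw * 1000,
      K = as.integer(best$K))
  })
  structure(res, aic = dplyr::bind_rows(aic_rows),
    class = c("background_estimate", class(tibble::tibble())))
}

# ---- change-point detection ------------------------------------------------

# cache of Monte-Carlo critical values, keyed by alpha and photon-count decade
.cp_crit_cache <- new.env(parent = emptyenv())

# max 2*LLR over candidate splits of one homogeneous segment of n photons
.cp_stat <- function(times) {
  n <- length(times)
  t1 <- times[1]; tn <- times[n]
  T <- tn - t1
  if (T <= 0 || n < 3) return(list(stat = -Inf, k = NA_integer_))
  k <- seq_len(n - 1L)
  T1 <- times[k] - t1
  T2 <- tn - times[k]
  ok <- T1 > 0 & T2 > 0
  llr <- rep(-Inf, n - 1L)
  kk <- k[ok]
  llr[ok] <- kk * log(kk / T1[ok]) + (n - kk) * log((n - kk) / T2[ok]) -
    n * log(n / T)
  j <- which.max(llr)
  list(stat = 2 * llr[j], k = j)
}

# alpha-critical value for a segment of n photons, calibrated by simulation
# of homogeneous Poisson segments, cached per photon-count decade
.cp_critical <- function(n, alpha, n_reps = 1000) {
  decade <- max(2L, ceiling(log10(n)))
  n_rep_cal <- min(10^decade, 10^4)   # representative n: decade upper bound
  key <- sprintf("a%.6f_d%d_r%d", alpha, decade, n_reps)
  if (!is.null(.cp_crit_cache[[key]])) return(.cp_crit_cache[[key]])
  stats <- vapply(seq_len(n_reps), function(i)
    .cp_stat(sort(runif(n_rep_cal)))$stat, numeric(1))
  crit <- as.numeric(quantile(stats, 1 - alpha, type = 8))
  .cp_crit_cache[[key]] <- crit
  crit
}

#' Detect brightness change points in a photon arrival sequence
#'
#' Photon-by-photon maximum-likelihood change-point detection by recursive
#' bisection: for a segment of n photons spanning T, the split at photon k
#' maximising the Poisson log-likelihood ratio
#' \eqn{LLR(k) = k \ln(k/T_1) + (n-k)\ln((n-k)/T_2) - n\ln(n/T)}
#' is accepted when \eqn{2\,LLR} exceeds the alpha-critical value, then both
#' sides are searched recursively. Critical values are calibrated by Monte
#' Carlo on homogeneous Poisson segments (cached per photon-count decade), so
#' the per-segment false-positive rate is `alpha` by construction.
#'
#' @param photon_times Sorted photon macrotimes in ms (one channel).
#' @param alpha Per-test false-positive rate (default 0.05).
#' @param min_photons Segments with fewer photons are never split
#'   (default 30; guards the likelihood-ratio asymptotics).
#' @param n_reps Monte-Carlo replicates for critical-value calibration.
#' @param seed Optional seed for the calibration simulation.
#' @return A `change_points` tibble: `time_ms`, `stat` (the 2 LLR value),
#'   `n_segment` (photons in the segment that produced the split).
#' @export
detect_change_points <- function(photon_times, alpha = 0.05,
                                 min_photons = 30, n_reps = 1000,
                                 seed = NULL) {
  if (is.unsorted(photon_times)) rlang::abort("`photon_times` must be sorted")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must be in (0, 1)")
  empty <- tibble::tibble(time_ms = double(), stat = double(),
    n_segment = integer())
  if (length(photon_times) < 2)
    return(structure(empty, class = c("change_points",
      class(tibble::tibble()))))
  crit_fun <- function(n) {
    if (!is.null(seed)) withr::with_seed(seed + n %% 97,
      .cp_critical(n, alpha, n_reps)) else .cp_critical(n, alpha, n_reps)
  }
  out <- list()
  recurse <- function(times) {
    n <- length(times)
    if (n < min_photons) return(invisible(NULL))
    s <- .cp_stat(times)
    if (!is.finite(s$stat) || s$stat <= crit_fun(n)) return(invisible(NULL))
    out[[length(out) + 1L]] <<- tibble::tibble(time_ms = times[s$k],
      stat = s$stat, n_segment = n)
    recurse(times[seq_len(s$k)])
    recurse(times[(s$k + 1L):n])
    invisible(NULL)
  }
  recurse(photon_times)
  res <- if (length(out)) dplyr::arrange(dplyr::bind_rows(out),
    .data$time_ms) else empty
  structure(res, class = c("change_points", class(tibble::tibble())))
}

#' Merge per-channel change points into a single list
#'
#' Points from all channels are pooled and points closer than `merge_window`
#' are collapsed to their photon-weighted mean time (weights = photons in the
#' detecting segment).
#'
#' @param per_channel List of [detect_change_points()] results (optionally
#'   named by channel).
#' @param merge_window Collapse window in ms (default 10, one display bin).
#' @return A `change_points` tibble: `time_ms`, `stat` (max over merged),
#'   `n_segment` (sum), `n_merged`.
#' @export
merge_change_points <- function(per_channel, merge_window = 10) {
  if (merge_window < 0) rlang::abort("`merge_window` must be >= 0")
  all_cp <- dplyr::bind_rows(per_channel)
  if (nrow(all_cp) == 0)
    return(structure(tibble::tibble(time_ms = double(), stat = double(),
      n_segment = integer(), n_merged = integer()),
      class = c("change_points", class(tibble::tibble()))))
  all_cp <- dplyr::arrange(all_cp, .data$time_ms)
  grp <- cumsum(c(1, diff(all_cp$time_ms) > merge_window))
  res <- all_cp |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      time_ms = sum(.data$time_ms * .data$n_segment) / sum(.data$n_segment),
      stat = max(.data$stat),
      n_segment = sum(.data$n_segment),
      n_merged = dplyr::n(), .groups = "drop") |>
    dplyr::select(-".grp")
  structure(res, class = c("change_points", class(tibble::tibble())))
}

#' Assemble duration-filtered levels from merged change points
#'
#' k change points partition the acquisition into k+1 candidate levels; each
#' photon belongs to exactly one candidate level. Levels not exceeding
#' `min_duration` are dropped (150 ms default; a 100 ms profile is used for
#' simple mixtures), since short levels degrade classification accuracy.
#'
#' @param stream A `photon_stream`.
#' @param cps A merged [merge_change_points()] set (or any `change_points`).
#' @param min_duration Minimum retained level duration in ms.
#' @return A `level_table` tibble: `level_id`, `start_ms`, `stop_ms`,
#'   `duration_ms`, per-channel counts, `n_photons`, and, when the stream
#'   carries ground truth, the majority `event_id`, `label` and truth
#'   `purity` of each level. Attribute `n_candidate` counts pre-filter
#'   levels; `boundaries` stores the partition edges.
#' @export
build_levels <- function(stream, cps, min_duration = 150) {
  chans <- fret_channels()
  if (nrow(stream) == 0)
    return(structure(tibble::tibble(), n_candidate = 0L,
      class = c("level_table", class(tibble::tibble()))))
  t0 <- min(stream$macrotime_ms); t1 <- max(stream$macrotime_ms)
  bounds <- c(t0, cps$time_ms[cps$time_ms > t0 & cps$time_ms < t1], t1)
  lev_idx <- pmin(findInterval(stream$macrotime_ms, bounds,
    rightmost.closed = TRUE), length(bounds) - 1L)
  n_lev <- length(bounds) - 1L
  out <- tibble::tibble(
    level_id = seq_len(n_lev),
    start_ms = bounds[-length(bounds)],
    stop_ms = bounds[-1])
  out$duration_ms <- out$stop_ms - out$start_ms
  for (ch in chans)
    out[[ch]] <- tabulate(lev_idx[stream$channel == ch], nbins = n_lev)
  out$n_photons <- tabulate(lev_idx, nbins = n_lev)
  if (!is.null(stream$event_id)) {
    ev_by_level <- split(stream$event_id,
      factor(lev_idx, levels = seq_len(n_lev)))
    maj <- purrr::map_dfr(ev_by_level, function(ev) {
      if (!length(ev)) return(tibble::tibble(event_id = NA_integer_,
        purity = NA_real_))
      tb <- table(ev, useNA = "ifany")
      top <- names(tb)[which.max(tb)]
      tibble::tibble(
        event_id = if (is.na(top) || top == "") NA_integer_ else
          as.integer(top),
        purity = max(tb) / length(ev))
    })
    out$event_id <- maj$event_id
    out$purity <- maj$purity
    ev <- stream_events(stream)
    out$label <- if (!is.null(ev))
      ev$label[match(out$event_id, ev$event_id)] else NA_character_
  }
  retained <- out[out$duration_ms > min_duration, ]
  retained$level_id <- seq_len(nrow(retained))
  structure(retained, n_candidate = n_lev, boundaries = bounds,
    min_duration = min_duration,
    class = c("level_table", class(tibble::tibble())))
}
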