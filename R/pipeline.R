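#' Write / read a photon stream as a portable CSV container
#'
#' The container is a plain CSV with columns `macrotime_ms`, `microtime_ns`,
#' `channel` (plus truth columns for simulated streams), preceded by
#' comment lines carrying the acquisition metadata and, when present, the
#' ground-truth event table as JSON. Doubles are written in shortest
#' round-trippable form, so a write/read round trip reproduces the records
#' exactly.
#'
#' @param stream A `photon_stream`.
#' @param path Output path (`.csv`).
#' @return `write_stream()`: the path, invisibly. `read_stream()`: a
#'   `photon_stream`.
#' @export
write_stream <- function(stream, path) {
  meta <- stream_meta(stream)
  meta_json <- jsonlite::toJSON(list(
    pulse_period = meta$pulse_period,
    excitation_power = meta$excitation_power,
    microtime_bin = meta$microtime_bin,
    irf = meta$irf[setdiff(names(meta$irf), "class")],
    channels = meta$channels), auto_unbox = TRUE, digits = I(17))
  lines <- paste0("#meta ", meta_json)
  ev <- stream_events(stream)
  if (!is.null(ev)) {
    ev_plain <- ev[, setdiff(names(ev), "trajectory")]
    # JSON has no Inf: encode never-bleached events as null, restored on read
    if (!is.null(ev_plain$bleach_ms))
      ev_plain$bleach_ms[!is.finite(ev_plain$bleach_ms)] <- NA_real_
    lines <- c(lines, paste0("#events ",
      jsonlite::toJSON(ev_plain, digits = I(17), na = "null")))
  }
  writeLines(lines, path)
  readr::write_csv(tibble::as_tibble(stream), path, append = TRUE,
    col_names = TRUE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  hdr <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  meta_ln <- hdr[startsWith(hdr, "#meta ")]
  if (!length(meta_ln)) rlang::abort("malformed stream file: no #meta header")
  m <- jsonlite::fromJSON(sub("^#meta ", "", meta_ln[1]))
  irf <- if (m$irf$kind == "gaussian")
    irf_gaussian(as.numeric(m$irf$center), as.numeric(m$irf$sigma)) else
    irf_histogram(as.numeric(m$irf$density), as.numeric(m$irf$pulse_period))
  meta <- acquisition_meta(as.numeric(m$pulse_period),
    as.numeric(m$excitation_power), as.numeric(m$microtime_bin), irf)
  ev_ln <- hdr[startsWith(hdr, "#events ")]
  events <- if (length(ev_ln)) {
    e <- tibble::as_tibble(jsonlite::fromJSON(sub("^#events ", "",
      ev_ln[1])))
    if (!is.null(e$bleach_ms)) e$bleach_ms[is.na(e$bleach_ms)] <- Inf
    e
  } else NULL
  # data.table::fread: correctly-rounded double parsing, so the write/read
  # round trip is bit-exact
  tbl <- tibble::as_tibble(data.table::fread(path, skip = length(hdr),
    na.strings = "NA", showProgress = FALSE))
  req <- c("macrotime_ms", "microtime_ns", "channel")
  miss <- setdiff(req, names(tbl))
  if (length(miss))
    rlang::abort(paste0("malformed stream file: missing column(s) ",
      paste(miss, collapse = ", ")))
  if (nrow(tbl)) {
    if (any(tbl$macrotime_ms < 0))
      rlang::abort("validation error: negative macrotime")
    if (any(tbl$microtime_ns < 0 | tbl$microtime_ns >= meta$pulse_period))
      rlang::abort("validation error: microtime outside [0, pulse_period)")
    bad <- setdiff(unique(tbl$channel), fret_channels())
    if (length(bad))
      rlang::abort(paste0("validation error: unknown channel(s) ",
        paste(bad, collapse = ", ")))
    if (is.unsorted(tbl$macrotime_ms))
      rlang::abort("validation error: records not ordered by macrotime")
  }
  if ("event_id" %in% names(tbl)) tbl$event_id <- as.integer(tbl$event_id)
  if ("label" %in% names(tbl)) tbl$label <- as.character(tbl$label)
  if ("bound" %in% names(tbl)) tbl$bound <- as.logical(tbl$bound)
  new_photon_stream(tbl, meta, events)
}

#' Pipeline run configuration
#'
#' Exactly one of `input` (a stream file) or `simulation` (a registry +
#' [sim_config()] pair) must be supplied.
#'
#' @param input Path to a stream container.
#' @param simulation List with elements `registry` (a `fret_registry`) and
#'   `config` (a [sim_config()]); optional `trap` (a [trap_params()]) to
#'   attach trajectories.
#' @param min_level_ms Level duration filter in ms (150 default; 100 for
#'   simple mixtures).
#' @param corrections A [fret_corrections()].
#' @param K Cluster count or `"auto"`.
#' @param min_brightness Total (green + red) brightness floor in counts
#'   ms^-1 uW^-1 for a level to enter the clustering stage; excludes
#'   empty-trap levels between events, which carry only background.
#' @param nstart K-means restarts for the clustering stage (the pipeline
#'   default is higher than [cluster_levels()]'s own: full runs usually
#'   carry more clusters, where restarts buy global-optimum reliability).
#' @param threshold Misclassification threshold for subset selection.
#' @param confinement_M Photons per confinement group (binding stage).
#' @param n_mc Monte-Carlo draws per confusion-matrix pair.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for TSV/YAML exports.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, simulation = NULL, min_level_ms = 150,
                       corrections = fret_corrections(), K = "auto",
                       min_brightness = 0.02, threshold = 0.025,
                       confinement_M = 1000, n_mc = 2e4, nstart = 50,
                       seed = 1, out_dir = NULL) {
  if (is.null(input) == is.null(simulation))
    rlang::abort("exactly one of `input` or `simulation` must be given")
  structure(list(input = input, simulation = simulation,
    min_level_ms = min_level_ms, corrections = corrections, K = K,
    min_brightness = min_brightness, threshold = threshold,
    confinement_M = confinement_M, n_mc = n_mc, nstart = nstart,
    seed = seed, out_dir = out_dir), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: background estimation -> per-channel change points -> merge
#' -> level assembly -> per-level signatures -> K-means clustering ->
#' Gaussian cluster models -> confusion matrix and compatible-subset
#' selection -> level classification -> (when trajectories are available)
#' confinement-based binding analysis. Deterministic given the config and
#' its seed. Optional stages degrade gracefully with warnings.
#'
#' @param config A [run_config()].
#' @return A `fret_run` list: `stream` summary, `background`, `change_points`,
#'   `levels`, `signatures`, `clustered`, `models`, `confusion`, `subset`,
#'   `classified`, `binding`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) rlang::abort("need a run_config()")
  if (!is.null(config$input) && !file.exists(config$input))
    rlang::abort(paste0("input not found: ", config$input))
  stream <- if (!is.null(config$input)) read_stream(config$input) else {
    s <- simulate_stream(config$simulation$registry,
      config$simulation$config, seed = config$seed)
    if (!is.null(config$simulation$trap))
      s <- attach_trajectories(s, config$simulation$registry,
        config$simulation$trap, seed = config$seed + 1L)
    s
  }
  trace <- bin_stream(stream)
  background <- estimate_background(trace)
  cps_by_ch <- purrr::map(setNames(fret_channels(), fret_channels()),
    function(ch) detect_change_points(
      stream$macrotime_ms[stream$channel == ch], seed = config$seed + 2L))
  cps <- merge_change_points(cps_by_ch)
  levels <- build_levels(stream, cps, config$min_level_ms)
  signatures <- summarize_levels(levels, stream, background,
    config$corrections)
  bright <- if (nrow(signatures))
    signatures[signatures$green_b + signatures$red_b >=
      config$min_brightness, ] else signatures
  n_complete <- if (nrow(bright))
    sum(stats::complete.cases(bright[, .signature_axes])) else 0L
  clustered <- models <- confusion <- subset_sel <- classified <- NULL
  if (n_complete >= 10) {
    clustered <- cluster_levels(bright, config$K, nstart = config$nstart,
      seed = config$seed + 3L)
    models <- fit_cluster_gaussian(clustered, drop_small = TRUE)
    if (nrow(models) >= 2) {
      confusion <- confusion_matrix(models, n_mc = config$n_mc,
        seed = config$seed + 4L)
      subset_sel <- select_compatible_subset(confusion, config$threshold)
    }
    if (nrow(models))
      classified <- classify_levels(bright, models)
    else models <- NULL
  } else {
    rlang::warn("too few complete signatures for clustering; stage skipped")
  }
  binding <- NULL
  ev <- stream_events(stream)
  if (!is.null(ev) && "trajectory" %in% names(ev)) {
    cp_pts <- confinement_points(stream, config$confinement_M)
    if (nrow(cp_pts) >= 10) {
      bs <- split_bound_unbound(cp_pts)
      binding <- list(points = cp_pts, split = bs,
        efficiency = tryCatch(binding_efficiency(bs),
          error = function(e) NULL))
    } else {
      rlang::warn("fewer than 10 confinement points; binding stage skipped")
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fretfluor")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    counts = list(
      n_photons = nrow(stream),
      n_change_points = nrow(cps),
      n_candidate_levels = attr(levels, "n_candidate"),
      n_retained_levels = nrow(levels),
      n_clusters = if (!is.null(models)) nrow(models) else 0L))
  run <- structure(list(stream = stream, background = background,
    change_points = cps, levels = levels, signatures = signatures,
    clustered = clustered, models = models, confusion = confusion,
    subset = subset_sel, classified = classified, binding = binding,
    manifest = manifest, config = config), class = "fret_run")
  if (!is.null(config$out_dir)) export_run(run, config$out_dir)
  run
}

#' @export
print.fret_run <- function(x, ...) {
  cn <- x$manifest$counts
  cat("<fret_run>\n")
  cat("  photons:         ", cn$n_photons, "\n")
  cat("  change points:   ", cn$n_change_points, "\n")
  cat("  levels:          ", cn$n_retained_levels, "retained of",
    cn$n_candidate_levels, "candidates\n")
  cat("  clusters:        ", cn$n_clusters, "\n")
  if (!is.null(x$subset))
    cat("  compatible set:  ", x$subset$n_selected, "labels\n")
  if (!is.null(x$binding))
    cat("  binding points:  ", nrow(x$binding$points), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `fret_run`.
#' @param ... Unused.
#' @method glance fret_run
#' @export
glance.fret_run <- function(x, ...) {
  cn <- x$manifest$counts
  tibble::tibble(n_photons = cn$n_photons,
    n_change_points = cn$n_change_points,
    n_candidate_levels = cn$n_candidate_levels,
    n_retained_levels = cn$n_retained_levels,
    n_clusters = cn$n_clusters,
    n_compatible = if (!is.null(x$subset)) x$subset$n_selected else
      NA_integer_)
}

#' Export a pipeline run as TSV tables plus a YAML manifest
#'
#' @param run A `fret_run`.
#' @param out_dir Directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(tibble::as_tibble(x),
    file.path(out_dir, f))
  lv <- run$levels
  if (!is.null(lv) && nrow(lv)) {
    out <- tibble::tibble(level_id = lv$level_id, start_ms = lv$start_ms,
      stop_ms = lv$stop_ms, duration_ms = lv$duration_ms,
      counts_Gpar = lv$Gpar, counts_Gperp = lv$Gperp,
      counts_Rpar = lv$Rpar, counts_Rperp = lv$Rperp)
    w(out, "levels.tsv")
  }
  if (!is.null(run$signatures) && nrow(run$signatures))
    w(run$signatures, "signatures.tsv")
  if (!is.null(run$confusion))
    w(tidy(run$confusion), "confusion.tsv")
  if (!is.null(run$subset))
    yaml::write_yaml(list(labels = run$subset$labels,
      threshold = run$subset$threshold,
      certificate = run$subset$certificate),
      file.path(out_dir, "subset.yaml"))
  if (!is.null(run$classified))
    w(run$classified, "classified.tsv")
  if (!is.null(run$binding)) {
    w(run$binding$split$calls, "binding_calls.tsv")
    if (!is.null(run$binding$efficiency))
      w(run$binding$efficiency, "binding_report.tsv")
  }
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
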