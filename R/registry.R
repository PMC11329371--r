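#' Predict FRET efficiency from donor-acceptor spacing
#'
#' Maps the base-pair separation between donor and acceptor dyes on a DNA
#' duplex to a FRET efficiency through the standard sixth-power distance law
#' \eqn{E = 1 / (1 + (r/R_0)^6)} with \eqn{r = N \cdot rise}. The linear-rise
#' distance model deliberately ignores helical geometry; it is monotone
#' decreasing in `spacing_N`, which is all the downstream label design needs.
#'
#' @param spacing_N Integer vector, base pairs between donor and acceptor
#'   (\eqn{\ge 0}).
#' @param forster_radius Förster radius \eqn{R_0} in nm (default 5.4, a
#'   literature-scale Cy3/Cy5 value).
#' @param rise_per_bp Helical rise per base pair in nm (default 0.34).
#' @return Numeric vector of efficiencies in `[0, 1]`.
#' @examples
#' predict_fret_efficiency(0)            # 1: zero separation
#' predict_fret_efficiency(9)            # ~0.97 at the defaults
#' @export
predict_fret_efficiency <- function(spacing_N, forster_radius = 5.4,
                                    rise_per_bp = 0.34) {
  if (forster_radius <= 0) rlang::abort("`forster_radius` must be > 0")
  if (rise_per_bp <= 0) rlang::abort("`rise_per_bp` must be > 0")
  if (any(spacing_N < 0)) rlang::abort("`spacing_N` must be >= 0")
  1 / (1 + (spacing_N * rise_per_bp / forster_radius)^6)
}

#' Load a FRETfluor construct registry
#'
#' Reads a YAML registry configuration describing label families (donor-only
#' lifetime and brightness) and individual constructs (label, family,
#' donor-acceptor spacing, optional explicit FRET efficiency), and returns a
#' validated registry tibble. Constructs without an explicit `E` get a
#' model-derived value from [predict_fret_efficiency()] using the config's
#' `fret_model` block.
#'
#' @param config Path to a YAML file, or an already-parsed list with elements
#'   `families`, `constructs`, and optionally `fret_model` and `defaults`.
#'   Defaults to the packaged 41-construct registry (15 ABN, 8 AB_skN,
#'   9 A_cBN, 9 AB_inN).
#' @return A tibble of class `fret_registry` with one row per construct:
#'   `label`, `family`, `spacing_N`, `fret_E`, `donor_lifetime_0` (ns),
#'   `donor_brightness_0` (counts ms^-1 uW^-1), `acceptor_brightness_scale`,
#'   `hydrodynamic_radius` (nm). Family parameters and the FRET distance
#'   model are attached as attributes `families`, `fret_model`, `defaults`.
#' @examples
#' reg <- load_registry()
#' dplyr::count(reg, family)
#' @export
load_registry <- function(config = default_registry_path()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  fams <- dplyr::bind_rows(lapply(cfg$families, function(f) {
    tibble::tibble(
      family = f$name,
      donor_lifetime_0 = as.numeric(f$donor_lifetime_0_ns),
      donor_brightness_0 = as.numeric(f$donor_brightness_0)
    )
  }))
  if (any(fams$donor_lifetime_0 <= 0) || any(fams$donor_brightness_0 <= 0))
    rlang::abort("family donor lifetime and brightness must be > 0")
  fm <- cfg$fret_model %||% list(R0_nm = 5.4, rise_nm = 0.34)
  defs <- cfg$defaults %||% list()
  radius_default <- defs$hydrodynamic_radius_nm %||% 2.0
  abs_default <- defs$acceptor_brightness_scale %||% 1.0

  if (length(cfg$constructs) == 0) {
    rlang::warn("registry config lists zero constructs")
    reg <- tibble::tibble(
      label = character(), family = character(), spacing_N = integer(),
      fret_E = double(), donor_lifetime_0 = double(),
      donor_brightness_0 = double(), acceptor_brightness_scale = double(),
      hydrodynamic_radius = double()
    )
    return(new_fret_registry(reg, fams, fm, defs))
  }

  cons <- dplyr::bind_rows(lapply(cfg$constructs, function(x) {
    tibble::tibble(
      label = as.character(x$label),
      family = as.character(x$family),
      spacing_N = as.integer(x$N),
      fret_E = as.numeric(x$E %||% NA_real_),
      hydrodynamic_radius = as.numeric(x$hydrodynamic_radius_nm %||%
        radius_default),
      acceptor_brightness_scale = as.numeric(x$acceptor_brightness_scale %||%
        abs_default)
    )
  }))
  if (anyDuplicated(cons$label))
    rlang::abort(paste0("duplicate construct labels: ",
      paste(unique(cons$label[duplicated(cons$label)]), collapse = ", ")))
  unknown <- setdiff(cons$family, fams$family)
  if (length(unknown))
    rlang::abort(paste0("unknown families: ", paste(unknown, collapse = ", ")))
  if (any(cons$spacing_N < 0, na.rm = TRUE))
    rlang::abort("spacing_N must be >= 0")

  reg <- cons |>
    dplyr::left_join(fams, by = "family") |>
    dplyr::mutate(fret_E = ifelse(is.na(.data$fret_E),
      predict_fret_efficiency(.data$spacing_N, fm$R0_nm, fm$rise_nm),
      .data$fret_E)) |>
    dplyr::select("label", "family", "spacing_N", "fret_E",
      "donor_lifetime_0", "donor_brightness_0",
      "acceptor_brightness_scale", "hydrodynamic_radius")
  if (any(reg$fret_E < 0 | reg$fret_E > 1))
    rlang::abort("fret_E must lie in [0, 1]")
  if (any(reg$hydrodynamic_radius <= 0))
    rlang::abort("hydrodynamic_radius must be > 0")
  new_fret_registry(reg, fams, fm, defs)
}

new_fret_registry <- function(reg, fams, fret_model, defaults) {
  structure(reg, families = fams, fret_model = fret_model,
    defaults = defaults, class = c("fret_registry", class(tibble::tibble())))
}

#' @export
`[.fret_registry` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- new_fret_registry(tibble::as_tibble(out), attr(x, "families"),
      attr(x, "fret_model"), attr(x, "defaults"))
  out
}

#' Path to the packaged default registry configuration
#' @return Path to the YAML file shipped with the package.
#' @export
default_registry_path <- function() {
  system.file("extdata", "registry.yaml", package = "fretfluor",
    mustWork = TRUE)
}

#' Donor-only reference constructs per family
#'
#' The four acceptor-free reference constructs (AB0, AB_sk0, A_cB0, AB_in0)
#' that define each family's donor lifetime and green brightness. These are
#' the spectroscopic anchors of the registry; they are not part of the
#' 41-construct barcode set itself.
#'
#' @param registry A `fret_registry`.
#' @return Tibble with `label`, `family`, `donor_lifetime_0`,
#'   `donor_brightness_0`.
#' @export
donor_references <- function(registry) {
  fams <- attr(registry, "families")
  prefix <- c(ABN = "AB0", AB_skN = "AB_sk0", A_cBN = "A_cB0",
    AB_inN = "AB_in0")
  fams |>
    dplyr::mutate(label = unname(prefix[.data$family])) |>
    dplyr::select("label", "family", "donor_lifetime_0", "donor_brightness_0")
}

#' Serialize a registry back to a configuration list
#'
#' Inverse of [load_registry()]: the returned list (written via
#' [save_registry()]) reloads to an identical registry.
#'
#' @param registry A `fret_registry`.
#' @return A list with `families`, `constructs`, `fret_model`, `defaults`.
#' @export
registry_config <- function(registry) {
  fams <- attr(registry, "families")
  list(
    families = lapply(seq_len(nrow(fams)), function(i) list(
      name = fams$family[i],
      donor_lifetime_0_ns = fams$donor_lifetime_0[i],
      donor_brightness_0 = fams$donor_brightness_0[i]
    )),
    constructs = lapply(seq_len(nrow(registry)), function(i) list(
      label = registry$label[i],
      family = registry$family[i],
      N = registry$spacing_N[i],
      E = registry$fret_E[i],
      hydrodynamic_radius_nm = registry$hydrodynamic_radius[i],
      acceptor_brightness_scale = registry$acceptor_brightness_scale[i]
    )),
    fret_model = attr(registry, "fret_model"),
    defaults = attr(registry, "defaults")
  )
}

#' Write a registry configuration to YAML
#'
#' Serializes at full double precision so that load -> save -> load is
#' idempotent.
#'
#' @param registry A `fret_registry`.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
save_registry <- function(registry, path) {
  yaml::write_yaml(registry_config(registry), path, precision = 15)
  invisible(path)
}

#' Predicted cluster models for every registry construct
#'
#' Design-stage signature predictions: each construct's expected cluster
#' centre in (green brightness, red brightness, donor lifetime) space
#' follows from its family photophysics and FRET efficiency —
#' green \eqn{= B_0 (1-E)}, red \eqn{= B_0 E s}, lifetime
#' \eqn{= \tau_0 (1-E)} — with nominal per-axis widths (a relative
#' coefficient of variation with absolute floors). Useful for evaluating a
#' palette's pairwise confusability before any data are measured; cluster
#' widths from real measurements should replace the nominal ones when
#' available.
#'
#' @param registry A `fret_registry`.
#' @param cv Relative cluster width per axis (default 0.05).
#' @param sd_floor_b,sd_floor_tau Absolute width floors for the brightness
#'   axes (counts ms^-1 uW^-1) and the lifetime axis (ns).
#' @return A `cluster_models` tibble, one row per construct.
#' @export
registry_cluster_models <- function(registry, cv = 0.05,
                                    sd_floor_b = 0.002,
                                    sd_floor_tau = 0.02) {
  mu_g <- registry$donor_brightness_0 * (1 - registry$fret_E)
  mu_r <- registry$donor_brightness_0 * registry$fret_E *
    registry$acceptor_brightness_scale
  mu_t <- registry$donor_lifetime_0 * (1 - registry$fret_E)
  res <- tibble::tibble(label = registry$label,
    mu_green = mu_g, mu_red = mu_r, mu_tau = mu_t,
    sd_green = pmax(cv * mu_g, sd_floor_b),
    sd_red = pmax(cv * mu_r, sd_floor_b),
    sd_tau = pmax(cv * mu_t, sd_floor_tau),
    n_members = NA_integer_, n_rejected = NA_integer_)
  structure(res, axes = c("green_b", "red_b", "tau_ns"),
    class = c("cluster_models", class(tibble::tibble())))
}

#' Photon-budget acquisition time
#'
#' Wall-clock time needed to accumulate a photon budget at a given total
#' arrival rate; used for throughput estimates of trap-and-identify
#' experiments (e.g. 10^4 photons at 25 kHz take 400 ms).
#'
#' @param n_photons Photons required per identification.
#' @param rate_hz Total photon arrival rate in counts per second.
#' @return Time in milliseconds.
#' @export
photon_budget_ms <- function(n_photons, rate_hz) {
  if (any(rate_hz <= 0)) rlang::abort("`rate_hz` must be > 0")
  1000 * n_photons / rate_hz
}

#' Total concentration of an equimolar label mixture
#'
#' @param n_labels Number of labels mixed.
#' @param each_fM Concentration of each label in femtomolar.
#' @return Total concentration in picomolar.
#' @export
mixture_total_pM <- function(n_labels, each_fM) {
  n_labels * each_fM / 1000
}
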