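#' Pipeline configuration
#'
#' Every tunable parameter of the pipeline lives in one nested list with
#' documented defaults; unknown keys are rejected so typos fail loudly
#' rather than silently falling back to defaults. Values can be overridden
#' programmatically (`default_config(permeability = list(guard_px = 3))`)
#' or from a YAML file ([load_config()]).
#'
#' Parameter blocks (units in brackets):
#' \describe{
#'   \item{physical}{`mu_pa_s` dynamic viscosity of the perfusate
#'     (Pa s, default 7e-4, aqueous buffer at 37 C); `gap_L_um` channel-to-
#'     channel gel gap for Darcy conversion (um; no default — must be set,
#'     see [darcy_permeability()]); `dextran_D_um2_s` free diffusivity of
#'     70-kDa dextran in collagen used by the phantom generator (um^2/s,
#'     default 25).}
#'   \item{geometry}{`threshold_method` ("otsu"/"fixed"), `fixed_threshold`,
#'     `speckle_px` minimum object area kept (px, default 10),
#'     `connectivity` (8 or 4), `min_columns` for diameter profiles.}
#'   \item{permeability}{`guard_px` wall guard band (px, default 2),
#'     `background` ("first-frame-exterior"/"fixed"), `fixed_background`,
#'     `window` ("auto" or c(a, b) frame indices), `i0` ("window-mean" or
#'     "per-frame").}
#'   \item{frap}{`search_radius_px` (default 20), `fail_limit` consecutive
#'     detection failures ending a track (default 3), `min_frames` (5).}
#'   \item{alignment}{`patch_px` (default 64), `low_freq_cycles` exclusion
#'     radius (cycles/patch, default 2), `high_freq_frac` of Nyquist kept
#'     (default 0.7; the near-Nyquist band is aliasing-dominated), `n_bins` orientation bins (default 180).}
#'   \item{extravasation}{`mono_max_diam_um` (default 9), `min_sphericity`
#'     (default 0.8), `wall_tol_um` (default 5), `detect_sigma_lo_um` /
#'     `detect_sigma_hi_um` band-pass scales bracketing nuclear diameters
#'     5-15 um (defaults 2 and 6), `peak_snr` threshold in noise SDs
#'     (default 6), `match_radius_um` truth-matching radius (5).}
#'   \item{stats}{`fence_mult` Tukey fence multiplier (1.5), `bonferroni`
#'     (FALSE).}
#'   \item{seed}{global run seed (integer, default 1), expanded per stage
#'     via [stage_seed()].}
#' }
#'
#' @param ... named blocks of overrides, e.g.
#'   `alignment = list(patch_px = 32)`.
#' @return a named nested list of class `PipelineConfig`.
#' @export
default_config <- function(...) {
  cfg <- list(
    physical = list(mu_pa_s = 7e-4, gap_L_um = NULL, dextran_D_um2_s = 25),
    geometry = list(threshold_method = "otsu", fixed_threshold = NULL,
                    speckle_px = 10, connectivity = 8, min_columns = 10),
    permeability = list(guard_px = 2, background = "first-frame-exterior",
                        fixed_background = 0, window = "auto",
                        i0 = "window-mean"),
    frap = list(search_radius_px = 20, fail_limit = 3, min_frames = 5),
    alignment = list(patch_px = 64, low_freq_cycles = 2,
                     high_freq_frac = 0.7, n_bins = 180),
    extravasation = list(mono_max_diam_um = 9, min_sphericity = 0.8,
                         wall_tol_um = 5, detect_sigma_lo_um = 2,
                         detect_sigma_hi_um = 6, peak_snr = 6,
                         match_radius_um = 5),
    stats = list(fence_mult = 1.5, bonferroni = FALSE),
    seed = 1L)
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "PipelineConfig"
  cfg
}

# Recursive override with unknown-key rejection
merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, k, "."))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Keys must match [default_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("<PipelineConfig>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Pressure unit conversion: mmH2O to Pa
#' @param mmH2O pressure in millimetres of water column.
#' @return pressure in pascal (1 mmH2O = 9.80665 Pa).
#' @export
mmh2o_to_pa <- function(mmH2O) mmH2O * 9.80665
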