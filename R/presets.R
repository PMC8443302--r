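# Named phantom presets encoding the study's reported condition means, so
# acceptance tests and demos can ask for "the static condition" by name.

preset_table <- function() list(
  # diffusive permeability condition means (um/s)
  "static-2.5mg" = list(
    kind = "dextran",
    spec = vessel_phantom_spec(pd_true = 1.45, radius_um = 100),
    truth = list(pd_um_s = 1.45)),
  "flow-2.5mg" = list(
    kind = "dextran",
    spec = vessel_phantom_spec(pd_true = 0.10, radius_um = 100),
    truth = list(pd_um_s = 0.10)),
  "flow-6mg" = list(
    kind = "dextran",
    spec = vessel_phantom_spec(pd_true = 0.60, radius_um = 100),
    truth = list(pd_um_s = 0.60)),
  # monocyte migration distance (um)
  "migration-20um" = list(
    kind = "cells",
    spec = cell_phantom_spec(n_extravasated = 30, n_adhered = 5,
                             migration_mean_um = 20, migration_sd_um = 5),
    truth = list(migration_mean_um = 20, migration_sd_um = 5)),
  # adhered-count ranges per condition (counts drawn per seed)
  "counts-static" = list(
    kind = "cells",
    spec = cell_phantom_spec(adhered_range = c(3, 10),
                             extravasated_range = c(5, 20),
                             n_extravasated = 0, n_adhered = 0),
    truth = list(adhered_range = c(3, 10), extravasated_range = c(5, 20))),
  "counts-flow" = list(
    kind = "cells",
    spec = cell_phantom_spec(adhered_range = c(5, 20),
                             extravasated_range = c(1, 10),
                             n_extravasated = 0, n_adhered = 0),
    truth = list(adhered_range = c(5, 20), extravasated_range = c(1, 10))),
  # vessel diameter range endpoints (um)
  "diam-hi" = list(
    kind = "projection",
    spec = list(diameter_um = 250, wall_um = 6, axis_angle_deg = 0,
                field_px = c(192, 256), pixel_size_um = 2, noise_sd = 0),
    truth = list(diameter_um = 250)),
  "diam-lo" = list(
    kind = "projection",
    spec = list(diameter_um = 125, wall_um = 6, axis_angle_deg = 0,
                field_px = c(192, 256), pixel_size_um = 2, noise_sd = 0),
    truth = list(diameter_um = 125)),
  # fiber-texture extremes
  "aligned" = list(
    kind = "fiber",
    spec = fiber_phantom_spec(kappa = Inf, axis_angle_deg = 0, noise_sd = 0),
    truth = list(alpha = 1)),
  "random" = list(
    kind = "fiber",
    spec = fiber_phantom_spec(kappa = 0, axis_angle_deg = 0, noise_sd = 0),
    truth = list(alpha = 0)))

#' Retrieve a named phantom preset
#'
#' Presets fix generator parameters at the study's reported condition
#' means: `"static-2.5mg"` (P_d 1.45 um/s), `"flow-2.5mg"` (0.10 um/s),
#' `"flow-6mg"` (0.60 um/s), `"migration-20um"` (mean 20 um, sd 5 um),
#' `"counts-static"` (adhered drawn from 3..10), `"counts-flow"` (5..20),
#' `"diam-hi"`/`"diam-lo"` (250/125 um), `"aligned"`/`"random"` (parallel /
#' isotropic fibers).
#'
#' @param name preset name.
#' @return `list(name, kind, spec, truth)`; `kind` selects the simulator
#'   ([simulate_dextran_timelapse()], [simulate_cell_stack()],
#'   [simulate_vessel_projection()], [simulate_fiber_field()]).
#' @export
get_preset <- function(name) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(tab), collapse = ", "))
  c(list(name = name), tab[[name]])
}

#' Simulate a preset by name
#'
#' @param name preset name (see [get_preset()]).
#' @param seed integer seed.
#' @return the simulator's `list(stack-or-image, truth)` with the preset
#'   name attached.
#' @export
simulate_preset <- function(name, seed = 1L) {
  p <- get_preset(name)
  out <- switch(p$kind,
    dextran = simulate_dextran_timelapse(p$spec, seed = seed),
    cells = simulate_cell_stack(p$spec, seed = seed),
    fiber = simulate_fiber_field(p$spec, seed = seed),
    projection = do.call(simulate_vessel_projection, c(p$spec, seed = seed)))
  out$preset <- p$name
  out
}
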