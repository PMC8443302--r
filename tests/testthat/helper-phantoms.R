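# Shared small fixtures, built in code at test time.

# compact dextran phantom for fast unit tests (not the acceptance geometry)
small_dextran <- function(pd = 0.5, noise_sd = 0, seed = 1, frames = 20,
                          r_um = 40, field = c(160, 160)) {
  simulate_dextran_timelapse(
    vessel_phantom_spec(pd_true = pd, radius_um = r_um, frames = frames,
                        pixel_size_um = 1, field_px = field,
                        noise_sd = noise_sd),
    seed = seed)
}

# compact cell phantom: small vessel, few nuclei
small_cells <- function(n_endo = 12, n_adh = 3, n_ext = 4, noise_sd = 0,
                        seed = 1, ...) {
  simulate_cell_stack(
    cell_phantom_spec(radius_um = 30, n_endothelial = n_endo,
                      n_adhered = n_adh, n_extravasated = n_ext,
                      n_x = 48, n_y = 84, noise_sd = noise_sd, ...),
    seed = seed)
}

vessel_of <- function(truth) {
  v <- attr(truth, "vessel")
  list(radius_um = v$radius_um, axis_y_um = v$axis_y_um,
       axis_z_um = v$axis_z_um)
}
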