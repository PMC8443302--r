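# FRAP phantom: a uniform fluorescent background with a radially symmetric
# photobleached dip that is advected by interstitial flow and refills by
# diffusion, emulating spot tracking for hydraulic-permeability assays.

#' Specification of a FRAP bleach-spot phantom
#'
#' Defaults mirror the stated acquisition: a 50-pixel-diameter bleach spot
#' imaged every second for 30 s ("50 pixel circle" is read as a diameter;
#' configurable).
#'
#' @param spot_radius_px bleach-spot radius (px; default 25, i.e. 50 px
#'   diameter). The rendered dip is Gaussian with sigma = radius / 2.
#' @param spot_depth fractional bleach depth in `[0, 1]` (0 allowed and
#'   produces a flat stack on which detection must fail loudly).
#' @param velocity_um_s true advection speed (um/s, >= 0).
#' @param direction_deg flow direction (degrees; 0 = +col, 90 = +row).
#' @param diffusion_recovery_um2_s recovery diffusivity (um^2/s); widens the
#'   dip as `sigma^2(t) = sigma0^2 + 2 D t` and shrinks its amplitude by
#'   `sigma0^2 / sigma^2(t)` (2D mass-conserving Gaussian relaxation).
#' @param frames number of frames (>= 5).
#' @param dt frame interval (s).
#' @param pixel_size_um pixel size (um).
#' @param field_px image size `c(rows, cols)`.
#' @param start_px starting dip centre `c(row, col)`; default places the
#'   trajectory symmetrically about the field centre.
#' @param background background intensity (a.u.).
#' @param noise_sd additive Gaussian noise SD as a fraction of background.
#' @return a validated `FrapPhantomSpec` list.
#' @export
frap_phantom_spec <- function(spot_radius_px = 25, spot_depth = 0.8,
                              velocity_um_s = 0.5, direction_deg = 0,
                              diffusion_recovery_um2_s = 0.5,
                              frames = 30, dt = 1, pixel_size_um = 1,
                              field_px = c(128, 128), start_px = NULL,
                              background = 1000, noise_sd = 0.02) {
  stopifnot(spot_radius_px > 0, spot_depth >= 0, spot_depth <= 1,
            velocity_um_s >= 0, diffusion_recovery_um2_s >= 0,
            frames >= 5, dt > 0, pixel_size_um > 0, background > 0,
            noise_sd >= 0, length(field_px) == 2L)
  field_px <- as.integer(field_px)
  total_px <- velocity_um_s * (frames - 1) * dt / pixel_size_um
  dirv <- c(sin(direction_deg * pi / 180), cos(direction_deg * pi / 180))
  if (is.null(start_px))
    start_px <- (field_px + 1) / 2 - dirv * total_px / 2
  end_px <- start_px + dirv * total_px
  margin <- spot_radius_px / 2           # one dip sigma inside the field
  for (p in list(start_px, end_px))
    if (p[1L] < 1 + margin || p[1L] > field_px[1L] - margin ||
        p[2L] < 1 + margin || p[2L] > field_px[2L] - margin)
      stop("bleach spot leaves the field of view before the final frame")
  structure(list(spot_radius_px = spot_radius_px, spot_depth = spot_depth,
                 velocity_um_s = velocity_um_s, direction_deg = direction_deg,
                 diffusion_recovery_um2_s = diffusion_recovery_um2_s,
                 frames = as.integer(frames), dt = dt,
                 pixel_size_um = pixel_size_um, field_px = field_px,
                 start_px = start_px, background = background,
                 noise_sd = noise_sd),
            class = "FrapPhantomSpec")
}

#' Simulate a FRAP spot-advection time-lapse
#'
#' @param spec a [frap_phantom_spec()].
#' @param seed integer seed for the noise stream.
#' @return `list(stack = ImageStack, truth = list(...))`; truth records the
#'   velocity, direction, and per-frame true centres (row, col, px).
#' @export
simulate_frap_timelapse <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "FrapPhantomSpec"))
  set.seed(stage_seed(seed, 21L))
  nr <- spec$field_px[1L]; nc <- spec$field_px[2L]
  t_s <- (seq_len(spec$frames) - 1L) * spec$dt
  dirv <- c(sin(spec$direction_deg * pi / 180),
            cos(spec$direction_deg * pi / 180))
  centers <- cbind(spec$start_px[1L] + dirv[1L] * spec$velocity_um_s * t_s /
                     spec$pixel_size_um,
                   spec$start_px[2L] + dirv[2L] * spec$velocity_um_s * t_s /
                     spec$pixel_size_um)
  sigma0 <- spec$spot_radius_px / 2
  data <- array(0, c(spec$frames, nr, nc))
  for (f in seq_len(spec$frames)) {
    s2 <- sigma0^2 + 2 * spec$diffusion_recovery_um2_s * t_s[f] /
      spec$pixel_size_um^2
    amp <- spec$spot_depth * sigma0^2 / s2
    rho2 <- radial_map(nr, nc, centers[f, 1L], centers[f, 2L])^2
    img <- spec$background * (1 - amp * exp(-rho2 / (2 * s2)))
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0,
                                spec$noise_sd * spec$background)
    data[f, , ] <- pmax(img, 0)
  }
  stack <- image_stack(data, "time", pixel_size_um = spec$pixel_size_um,
                       step = spec$dt)
  truth <- list(velocity_um_s = spec$velocity_um_s,
                direction_deg = spec$direction_deg,
                centers_px = centers, sigma0_px = sigma0, seed = seed)
  list(stack = stack, truth = truth)
}
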