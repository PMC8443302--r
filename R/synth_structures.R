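# Structural phantoms: 2D cylinder-wall projections for diameter
# measurement and junction lattices for monolayer-continuity checks.

#' Simulate a phalloidin-like projection of a cylindrical vessel
#'
#' Renders the two wall bands of a horizontal (or tilted) cylinder as seen
#' in a maximum-intensity projection. `diameter_um` is the OUTER wall
#' envelope: walls are bands of thickness `wall_um` whose outer edges sit at
#' perpendicular distance `diameter_um / 2` from the axis, which matches the
#' outermost-half-maximum convention used by [estimate_axis_and_diameter()]
#' (phalloidin stains the cell body, so the outer envelope is the natural
#' vessel diameter).
#'
#' @param diameter_um outer vessel diameter (um).
#' @param wall_um wall-band thickness (um, default 6).
#' @param axis_angle_deg axis tilt (degrees; 0 = horizontal).
#' @param field_px image size `c(rows, cols)`.
#' @param pixel_size_um pixel size (um).
#' @param interior_frac interior (luminal projection) intensity relative to
#'   the wall bands; kept below 0.5 so the half-maximum edge criterion sees
#'   the walls only.
#' @param noise_sd additive Gaussian noise SD (fraction of wall intensity).
#' @param seed integer seed (noise only).
#' @return `list(image = matrix, truth = list(diameter_um, axis_angle_deg))`.
#' @export
simulate_vessel_projection <- function(diameter_um, wall_um = 6,
                                       axis_angle_deg = 0,
                                       field_px = c(192, 256),
                                       pixel_size_um = 2,
                                       interior_frac = 0.15,
                                       noise_sd = 0, seed = 1L) {
  stopifnot(diameter_um > 0, wall_um > 0, interior_frac >= 0,
            interior_frac < 0.5, pixel_size_um > 0)
  set.seed(stage_seed(seed, 51L))
  nr <- field_px[1L]; nc <- field_px[2L]
  if (diameter_um / pixel_size_um > nr - 10)
    stop("vessel walls do not fit inside the field of view")
  g <- pixel_grid(nr, nc)
  th <- axis_angle_deg * pi / 180
  # signed perpendicular distance (um) of each pixel from the axis line
  # through the field centre
  d_um <- (cos(th) * (g$row - (nr + 1) / 2) -
           sin(th) * (g$col - (nc + 1) / 2)) * pixel_size_um
  R_out <- diameter_um / 2
  R_in <- R_out - wall_um
  # edge ramps centred on the boundaries (pixel-coverage convention), so
  # the half-intensity point of each band edge sits exactly at R_in/R_out
  edge <- pixel_size_um
  band <- clamp01((R_out - abs(d_um)) / edge + 0.5) *
          clamp01((abs(d_um) - R_in) / edge + 0.5)
  interior <- interior_frac * clamp01((R_in - abs(d_um)) / edge + 0.5)
  img <- band + interior
  if (noise_sd > 0)
    img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
  list(image = img,
       truth = list(diameter_um = diameter_um,
                    axis_angle_deg = axis_angle_deg, wall_um = wall_um))
}

#' Simulate a junction lattice (intact or with cuts)
#'
#' A grid of bright horizontal and vertical strands on a dark background,
#' emulating a thresholded adherens-junction network. With no cuts the
#' rendered foreground is 8-connected (a single object); each cut erases
#' one horizontal strand segment between two vertical strands, which can
#' split the lattice.
#'
#' @param n_rows,n_cols number of lattice cells.
#' @param cell_px lattice cell size (px).
#' @param line_px strand thickness (px).
#' @param cut_columns integer vector of column-cell indices; for each, the
#'   horizontal strands spanning that cell column are erased on every row
#'   line, splitting the lattice into independent left/right objects.
#' @param intensity foreground intensity (a.u.).
#' @return `list(image = matrix, mask = logical matrix)` (the rendered
#'   ground-truth foreground).
#' @export
simulate_junction_lattice <- function(n_rows = 5, n_cols = 7, cell_px = 24,
                                      line_px = 2, cut_columns = integer(),
                                      intensity = 100) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_px > 2 * line_px)
  nr <- n_rows * cell_px + line_px
  nc <- n_cols * cell_px + line_px
  mask <- matrix(FALSE, nr, nc)
  row_lines <- (0:n_rows) * cell_px + 1L
  col_lines <- (0:n_cols) * cell_px + 1L
  for (r0 in row_lines) mask[r0:(r0 + line_px - 1L), ] <- TRUE
  for (c0 in col_lines) mask[, c0:(c0 + line_px - 1L)] <- TRUE
  for (cc in cut_columns) {
    stopifnot(cc >= 1, cc <= n_cols)
    c_from <- col_lines[cc] + line_px
    c_to <- col_lines[cc + 1L] - 1L
    for (r0 in row_lines)
      mask[r0:(r0 + line_px - 1L), c_from:c_to] <- FALSE
  }
  list(image = mask * intensity, mask = mask)
}
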