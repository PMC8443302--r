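# 3D nuclear-stack phantom: endothelial nuclei on a cylindrical vessel
# surface plus monocyte nuclei either adhered at the wall or extravasated
# into the surrounding gel at known radial migration distances.

#' Specification of a two-population nuclear z-stack phantom
#'
#' The vessel axis runs along image columns (x) through the centre of the
#' (y, z) cross-section. Endothelial nuclei are ellipsoids flattened
#' radially (monolayer cells hug the wall); monocyte nuclei are spheres
#' ("small size, rounded shape"), so the two classes separate on both
#' equivalent diameter and sphericity.
#'
#' @param radius_um vessel radius (um).
#' @param n_endothelial,n_adhered,n_extravasated nucleus counts (>= 0).
#'   `n_adhered`/`n_extravasated` may instead be drawn per-simulation by
#'   giving `adhered_range`/`extravasated_range`.
#' @param adhered_range,extravasated_range optional integer `c(lo, hi)`;
#'   when supplied the corresponding count is drawn uniformly from
#'   `lo:hi` at simulation time (seeded).
#' @param migration_mean_um,migration_sd_um truncated-normal parameters of
#'   extravasated radial excess (um; truncated below at `wall_tol_um`).
#' @param wall_tol_um wall tolerance separating adhered from extravasated
#'   (um, default 5, about one endothelial cell thickness).
#' @param endo_nucleus_diam_um,mono_nucleus_diam_um class diameters (um;
#'   monocyte must be the smaller).
#' @param pixel_size_um,z_step_um lateral pixel size and z spacing (um).
#' @param n_x,n_y number of columns/rows; z-extent is chosen to cover the
#'   cylinder plus the migration range.
#' @param noise_sd additive Gaussian noise SD (fraction of nucleus peak).
#' @return a validated `CellPhantomSpec` list.
#' @export
cell_phantom_spec <- function(radius_um = 50, n_endothelial = 40,
                              n_adhered = 5, n_extravasated = 5,
                              adhered_range = NULL, extravasated_range = NULL,
                              migration_mean_um = 20, migration_sd_um = 5,
                              wall_tol_um = 5,
                              endo_nucleus_diam_um = 12,
                              mono_nucleus_diam_um = 7,
                              pixel_size_um = 2, z_step_um = 2,
                              n_x = 96, n_y = 108, noise_sd = 0.02) {
  stopifnot(radius_um > 0, n_endothelial >= 0, n_adhered >= 0,
            n_extravasated >= 0, migration_mean_um >= 0,
            migration_sd_um >= 0, wall_tol_um > 0,
            mono_nucleus_diam_um < endo_nucleus_diam_um,
            pixel_size_um > 0, z_step_um > 0, noise_sd >= 0)
  for (rg in list(adhered_range, extravasated_range))
    if (!is.null(rg)) stopifnot(length(rg) == 2L, rg[1L] <= rg[2L], rg[1L] >= 0)
  # z-extent: cylinder + migration tail + one nucleus + margin
  reach_um <- radius_um + migration_mean_um + 4 * migration_sd_um +
    endo_nucleus_diam_um
  n_z <- ceiling(2 * reach_um / z_step_um) + 4L
  need_y <- 2 * reach_um / pixel_size_um
  if (n_y < need_y)
    stop("n_y too small for the cylinder plus migration range (need >= ",
         ceiling(need_y), ")")
  structure(list(radius_um = radius_um, n_endothelial = as.integer(n_endothelial),
                 n_adhered = as.integer(n_adhered),
                 n_extravasated = as.integer(n_extravasated),
                 adhered_range = adhered_range,
                 extravasated_range = extravasated_range,
                 migration_mean_um = migration_mean_um,
                 migration_sd_um = migration_sd_um, wall_tol_um = wall_tol_um,
                 endo_nucleus_diam_um = endo_nucleus_diam_um,
                 mono_nucleus_diam_um = mono_nucleus_diam_um,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 n_x = as.integer(n_x), n_y = as.integer(n_y),
                 n_z = as.integer(n_z), noise_sd = noise_sd),
            class = "CellPhantomSpec")
}

# normal truncated below at `lower`, by rejection
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Simulate a 3D nuclear stack with known adhered/extravasated truth
#'
#' @param spec a [cell_phantom_spec()].
#' @param seed integer seed.
#' @param max_retries placement retries per nucleus before giving up.
#' @return `list(stack = ImageStack (z), truth = data.frame)`; the truth
#'   table lists one row per nucleus: class, position class, centroid (um,
#'   in x/y/z stack coordinates), radial excess (um) and rendered diameter.
#' @export
simulate_cell_stack <- function(spec, seed = 1L, max_retries = 200L) {
  stopifnot(inherits(spec, "CellPhantomSpec"))
  set.seed(stage_seed(seed, 41L))
  n_adh <- if (!is.null(spec$adhered_range))
    sample(spec$adhered_range[1L]:spec$adhered_range[2L], 1L) else spec$n_adhered
  n_ext <- if (!is.null(spec$extravasated_range))
    sample(spec$extravasated_range[1L]:spec$extravasated_range[2L], 1L)
  else spec$n_extravasated
  r <- spec$radius_um
  x_len <- spec$n_x * spec$pixel_size_um
  y_c <- (spec$n_y + 1) / 2 * spec$pixel_size_um
  z_c <- (spec$n_z + 1) / 2 * spec$z_step_um
  margin <- spec$endo_nucleus_diam_um
  place <- list()   # each: x, y, z (um), class, pos, excess, diam, min_gap
  draw_one <- function(class, pos, excess, diam) {
    phi <- stats::runif(1, 0, 2 * pi)
    x <- stats::runif(1, margin, x_len - margin)
    rho <- r + excess
    c(x = x, y = y_c + rho * cos(phi), z = z_c + rho * sin(phi))
  }
  add_class <- function(n, class, pos, excess_fun, diam) {
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        excess <- excess_fun()
        p <- draw_one(class, pos, excess, diam)
        crowded <- FALSE
        for (q in place) {
          min_gap <- 0.45 * (diam + q["diam"])
          if (sum((p - q[c("x", "y", "z")])^2) < min_gap^2) {
            crowded <- TRUE; break
          }
        }
        if (!crowded) {
          place[[length(place) + 1L]] <<- c(p, diam = diam, excess = excess,
                                            class_i = match(class, c("endothelial", "monocyte")),
                                            pos_i = match(pos, c("wall", "luminal_adherent", "extravasated")))
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place a ", class, " nucleus (", pos,
                    ") without overlap after ", max_retries, " retries")
    }
  }
  add_class(spec$n_endothelial, "endothelial", "wall",
            function() 0, spec$endo_nucleus_diam_um)
  add_class(n_adh, "monocyte", "luminal_adherent",
            function() stats::runif(1, -2, 2), spec$mono_nucleus_diam_um)
  add_class(n_ext, "monocyte", "extravasated",
            function() rtruncnorm_lower(1L, spec$migration_mean_um,
                                        spec$migration_sd_um,
                                        spec$wall_tol_um),
            spec$mono_nucleus_diam_um)

  # render: ellipsoid blobs in physical (um) coordinates
  arr <- array(0, c(spec$n_z, spec$n_y, spec$n_x))
  zs <- seq_len(spec$n_z) * spec$z_step_um
  ys <- seq_len(spec$n_y) * spec$pixel_size_um
  xs <- seq_len(spec$n_x) * spec$pixel_size_um
  edge_um <- 1.5
  for (p in place) {
    diam <- p[["diam"]]
    if (p[["class_i"]] == 1L) {
      # endothelial: elongated along the vessel axis, flattened radially
      ax <- c(x = 1.3, y = 1.0, z = 0.55) * diam / 2
      # flatten along the local radial direction (y/z swap by angle)
      ang <- atan2(p[["z"]] - z_c, p[["y"]] - y_c)
    } else {
      ax <- c(x = 1, y = 1, z = 1) * diam / 2
      ang <- 0
    }
    reach <- max(ax) + edge_um
    zi <- which(abs(zs - p[["z"]]) <= reach)
    yi <- which(abs(ys - p[["y"]]) <= reach)
    xi <- which(abs(xs - p[["x"]]) <= reach)
    if (!length(zi) || !length(yi) || !length(xi)) next
    dz <- zs[zi] - p[["z"]]; dy <- ys[yi] - p[["y"]]; dx <- xs[xi] - p[["x"]]
    g <- expand.grid(dz = dz, dy = dy, dx = dx)
    if (p[["class_i"]] == 1L) {
      # rotate (dy, dz) so the ellipsoid short axis points radially
      u <- g$dy * cos(ang) + g$dz * sin(ang)     # radial
      v <- -g$dy * sin(ang) + g$dz * cos(ang)    # tangential
      m2 <- (g$dx / ax[["x"]])^2 + (v / ax[["y"]])^2 + (u / ax[["z"]])^2
    } else {
      m2 <- (g$dx / ax[["x"]])^2 + (g$dy / ax[["y"]])^2 + (g$dz / ax[["z"]])^2
    }
    val <- clamp01((1 - sqrt(m2)) * mean(ax) / edge_um + 0.5)
    arr[zi, yi, xi] <- pmax(array(arr[zi, yi, xi],
                                  c(length(zi), length(yi), length(xi))),
                            array(val, c(length(zi), length(yi), length(xi))))
  }
  if (spec$noise_sd > 0)
    arr <- pmax(arr + stats::rnorm(length(arr), 0, spec$noise_sd), 0)
  stack <- image_stack(arr, "z", pixel_size_um = spec$pixel_size_um,
                       step = spec$z_step_um)
  truth <- do.call(rbind, lapply(seq_along(place), function(i) {
    p <- place[[i]]
    data.frame(id = i,
               class = c("endothelial", "monocyte")[p[["class_i"]]],
               position_class = c("wall", "luminal_adherent",
                                  "extravasated")[p[["pos_i"]]],
               x_um = p[["x"]], y_um = p[["y"]], z_um = p[["z"]],
               radial_excess_um = p[["excess"]],
               diameter_um = p[["diam"]])
  }))
  if (is.null(truth))
    truth <- data.frame(id = integer(), class = character(),
                        position_class = character(), x_um = numeric(),
                        y_um = numeric(), z_um = numeric(),
                        radial_excess_um = numeric(), diameter_um = numeric())
  attr(truth, "vessel") <- list(radius_um = r, axis_y_um = y_c,
                                axis_z_um = z_c,
                                n_adhered = n_adh, n_extravasated = n_ext)
  list(stack = stack, truth = truth)
}
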