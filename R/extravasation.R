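# 3D nucleus detection and transendothelial-migration scoring: find nuclei
# in a z-stack, split monocytes from endothelial cells by size and
# roundness, and classify each monocyte as luminal-adherent or extravasated
# by its radial distance from the vessel axis.

# keep only voxels (linear indices into an array of dim d) lying in a
# 26-connected component that contains at least one seed voxel
connected_to_seeds <- function(reg, seeds, d) {
  inreg <- logical(prod(d))
  inreg[reg] <- TRUE
  pos <- arrayInd(reg, d)
  id <- integer(prod(d))
  id[reg] <- seq_along(reg)
  shifts <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0 &
                     (shifts[, 1] > 0 | (shifts[, 1] == 0 & shifts[, 2] > 0) |
                        (shifts[, 1] == 0 & shifts[, 2] == 0 &
                           shifts[, 3] > 0)), , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(shifts))) {
    p2 <- pos + matrix(shifts[i, ], nrow(pos), 3L, byrow = TRUE)
    ok <- p2[, 1] >= 1 & p2[, 1] <= d[1L] & p2[, 2] >= 1 & p2[, 2] <= d[2L] &
      p2[, 3] >= 1 & p2[, 3] <= d[3L]
    lin <- (p2[ok, 3] - 1L) * d[1L] * d[2L] + (p2[ok, 2] - 1L) * d[1L] +
      p2[ok, 1]
    hit <- inreg[lin]
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(id[reg[ok]][hit], id[lin[hit]])
  }
  g <- igraph::make_empty_graph(n = length(reg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  seed_in <- seeds[inreg[seeds]]
  keep_comp <- unique(memb[id[seed_in]])
  reg[memb %in% keep_comp]
}

# separable 3x3x3 running-max filter
maxfilter3 <- function(arr) {
  d <- dim(arr)
  shift_max <- function(a, ax) {
    perm <- c(ax, setdiff(1:3, ax))
    b <- aperm(a, perm)
    dp <- dim(b)
    m <- matrix(b, dp[1L])
    up <- rbind(m[-1L, , drop = FALSE], m[dp[1L], , drop = FALSE])
    dn <- rbind(m[1L, , drop = FALSE], m[-dp[1L], , drop = FALSE])
    out <- pmax(m, up, dn)
    dim(out) <- dp
    aperm(out, order(perm))
  }
  for (ax in 1:3) arr <- shift_max(arr, ax)
  arr
}

#' Detect nuclei in a 3D z-stack
#'
#' Difference-of-Gaussians band-pass bracketing nuclear sizes (5-15 um),
#' 3D local maxima above a noise-scaled threshold as seeds, then
#' nearest-seed region growing over above-half-peak voxels to split
#' touching nuclei. All distances honour the stack's pixel size and
#' z-step, so detections are reported in physical micrometres.
#'
#' @param stack a z-axis [image_stack()].
#' @param sigma_lo_um,sigma_hi_um band-pass smoothing scales (um).
#' @param peak_snr seed threshold in units of the band-pass image's robust
#'   noise SD (MAD).
#' @param region_frac voxels above this fraction of the median seed
#'   intensity are assigned to regions (default 0.5, the half-maximum
#'   surface of a rendered nucleus).
#' @param min_voxels discard regions smaller than this (default 5).
#' @return a data.frame of detections: `x_um`, `y_um`, `z_um` (centroid),
#'   `diameter_um` (equivalent-sphere), `sphericity` (minor/major axis SD
#'   ratio, in `[0, 1]`), `peak`, `n_voxels`. Zero rows if nothing found.
#' @export
detect_nuclei <- function(stack, sigma_lo_um = 2, sigma_hi_um = 6,
                          peak_snr = 6, region_frac = 0.5, min_voxels = 5) {
  stopifnot(inherits(stack, "ImageStack"), stack$axis_kind == "z")
  arr <- stack$data
  d <- dim(arr)
  if (any(d < 3L)) stop("stack too small for 3D detection")
  px <- stack$pixel_size_um; zs <- stack$step
  vox <- c(zs, px, px)                       # um per voxel along (z, y, x)
  dog <- blur3d(arr, sigma_lo_um / vox) - blur3d(arr, sigma_hi_um / vox)
  noise <- max(stats::mad(dog), 1e-12)
  thr <- peak_snr * noise
  peaks <- dog >= maxfilter3(dog) & dog > thr
  seeds <- which(peaks)
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      diameter_um = numeric(), sphericity = numeric(),
                      peak = numeric(), n_voxels = integer())
  if (!length(seeds)) return(empty)
  # seed coordinates in um
  sz <- ((seeds - 1L) %% d[1L]) + 1L
  sy <- (((seeds - 1L) %/% d[1L]) %% d[2L]) + 1L
  sx <- ((seeds - 1L) %/% (d[1L] * d[2L])) + 1L
  seed_um <- cbind(z = sz * zs, y = sy * px, x = sx * px)
  # collapse plateau/adjacent seeds closer than half the band-pass midpoint
  merge_r <- sigma_hi_um / 2
  ord <- order(-dog[seeds])
  kept <- integer()
  for (i in ord) {
    if (!length(kept) ||
        min(colSums((t(seed_um[kept, , drop = FALSE]) - seed_um[i, ])^2)) >
          merge_r^2)
      kept <- c(kept, i)
  }
  seed_um <- seed_um[kept, , drop = FALSE]
  seeds <- seeds[kept]
  # region voxels: above half the typical nucleus amplitude (scale-free),
  # and 26-connected to a seed — scattered supra-threshold noise voxels
  # must not be swept into a nucleus
  level <- region_frac * stats::median(arr[seeds])
  reg <- which(arr > level)
  if (!length(reg)) return(empty)
  reg <- connected_to_seeds(reg, seeds, d)
  if (!length(reg)) return(empty)
  rz <- (((reg - 1L) %% d[1L]) + 1L) * zs
  ry <- ((((reg - 1L) %/% d[1L]) %% d[2L]) + 1L) * px
  rx <- (((reg - 1L) %/% (d[1L] * d[2L])) + 1L) * px
  # nearest-seed assignment (anisotropy-aware, in um)
  n_s <- nrow(seed_um)
  best <- rep(1L, length(reg)); bestd <- rep(Inf, length(reg))
  for (s in seq_len(n_s)) {
    ds <- (rz - seed_um[s, 1L])^2 + (ry - seed_um[s, 2L])^2 +
      (rx - seed_um[s, 3L])^2
    take <- ds < bestd
    best[take] <- s; bestd[take] <- ds[take]
  }
  # cap assignment distance: voxels farther than one endothelial diameter
  # from every seed are background clutter
  ok <- bestd <= 15^2
  reg <- reg[ok]; best <- best[ok]
  rz <- rz[ok]; ry <- ry[ok]; rx <- rx[ok]
  out <- lapply(seq_len(n_s), function(s) {
    sel <- best == s
    nv <- sum(sel)
    if (nv < min_voxels) return(NULL)
    zc <- rz[sel]; yc <- ry[sel]; xc <- rx[sel]
    vol <- nv * px * px * zs
    # intensity-weighted moments with Sheppard correction for voxel size:
    # binary/discrete sampling otherwise understates roundness of small
    # nuclei. Shape moments trim the region to 1.25 equivalent radii
    # around its bright core's centroid, so voxels annexed from a
    # touching neighbour's blob cannot distort the axis ratio.
    w <- arr[reg[sel]]
    core <- w >= 0.6 * max(w)
    if (sum(core) < min_voxels) core <- rep(TRUE, nv)
    ctr <- c(sum(w[core] * zc[core]), sum(w[core] * yc[core]),
             sum(w[core] * xc[core])) / sum(w[core])
    r_eq <- (3 * vol / (4 * pi))^(1 / 3)
    trim <- core & ((zc - ctr[1L])^2 + (yc - ctr[2L])^2 +
                      (xc - ctr[3L])^2 <= (1.25 * r_eq)^2)
    if (sum(trim) < min_voxels) trim <- core
    wc <- w[trim]
    zk <- zc[trim]; yk <- yc[trim]; xk <- xc[trim]
    ctr <- c(sum(wc * zk), sum(wc * yk), sum(wc * xk)) / sum(wc)
    dzyx <- cbind(zk - ctr[1L], yk - ctr[2L], xk - ctr[3L])
    cov <- crossprod(dzyx * sqrt(wc)) / sum(wc) +
      diag(c(zs, px, px)^2 / 12)
    ev <- pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 1e-9)
    data.frame(x_um = ctr[3L], y_um = ctr[2L], z_um = ctr[1L],
               diameter_um = 2 * (3 * vol / (4 * pi))^(1 / 3),
               sphericity = sqrt(min(ev) / max(ev)),
               peak = max(w), n_voxels = nv)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Classify a detection as monocyte or endothelial
#'
#' Monocyte nuclei are recognised by their small size and rounded shape:
#' equivalent diameter at or below `diam_max_um` AND sphericity at or
#' above `min_sphericity`; anything else is called endothelial.
#'
#' @param detection one detection row (or a data.frame of them).
#' @param diam_max_um monocyte diameter ceiling (um, default 9).
#' @param min_sphericity monocyte roundness floor (default 0.8).
#' @return character vector `"monocyte"`/`"endothelial"`.
#' @export
classify_cell_type <- function(detection, diam_max_um = 9,
                               min_sphericity = 0.8) {
  ifelse(detection$diameter_um <= diam_max_um &
           detection$sphericity >= min_sphericity,
         "monocyte", "endothelial")
}

#' Classify a detection's position relative to the vessel wall
#'
#' The radial excess is the perpendicular distance of the centroid from
#' the vessel axis minus the radius; within `wall_tol_um` of zero the cell
#' sits at the wall (luminal-adherent), beyond it in the gel
#' (extravasated), below it inside the lumen (luminal-free).
#'
#' @param detection detection row(s) with `x_um`, `y_um`, `z_um`.
#' @param vessel list with `radius_um`, `axis_y_um`, `axis_z_um` (axis
#'   parallel to x).
#' @param wall_tol_um wall tolerance (um, default 5, about one endothelial
#'   cell thickness).
#' @param bounds_um optional `c(x, y, z)` stack extent; centroids outside
#'   it are an error.
#' @return data.frame with `position_class` and `radial_excess_um`.
#' @export
classify_position <- function(detection, vessel, wall_tol_um = 5,
                              bounds_um = NULL) {
  if (!is.null(bounds_um)) {
    if (any(detection$x_um < 0 | detection$x_um > bounds_um[1L] |
            detection$y_um < 0 | detection$y_um > bounds_um[2L] |
            detection$z_um < 0 | detection$z_um > bounds_um[3L]))
      stop("detection centroid outside stack bounds")
  }
  rho <- sqrt((detection$y_um - vessel$axis_y_um)^2 +
              (detection$z_um - vessel$axis_z_um)^2)
  excess <- rho - vessel$radius_um
  cls <- ifelse(excess > wall_tol_um, "extravasated",
                ifelse(excess < -wall_tol_um, "luminal_free",
                       "luminal_adherent"))
  data.frame(position_class = cls, radial_excess_um = excess)
}

#' Per-vessel extravasation summary
#'
#' Counts are restricted to monocytes; migration distances are the radial
#' excesses of extravasated monocytes.
#'
#' @param cells data.frame with `cell_type`, `position_class`,
#'   `radial_excess_um` (possibly zero rows).
#' @param vessel_id identifier carried into the summary.
#' @return an `ExtravasationSummary`: list with `vessel_id`, `n_adhered`,
#'   `n_extravasated`, `distances_um`, `mean_distance_um`,
#'   `median_distance_um`.
#' @export
summarize_vessel <- function(cells, vessel_id = 1L) {
  mono <- cells[!is.na(cells$cell_type) & cells$cell_type == "monocyte", ,
                drop = FALSE]
  adhered <- sum(mono$position_class == "luminal_adherent")
  extr <- mono[mono$position_class == "extravasated", , drop = FALSE]
  d <- extr$radial_excess_um
  structure(list(vessel_id = vessel_id, n_adhered = adhered,
                 n_extravasated = nrow(extr), distances_um = d,
                 mean_distance_um = if (length(d)) mean(d) else NA_real_,
                 median_distance_um = if (length(d)) stats::median(d)
                                      else NA_real_),
            class = "ExtravasationSummary")
}

#' Full extravasation pipeline on one z-stack
#'
#' @param stack a z-axis [image_stack()].
#' @param vessel list with `radius_um`, `axis_y_um`, `axis_z_um`.
#' @param diam_max_um,min_sphericity see [classify_cell_type()].
#' @param wall_tol_um see [classify_position()].
#' @param ... passed to [detect_nuclei()].
#' @return an `ExtravasationSummary` with the classified cell table
#'   attached as attribute `cells`.
#' @export
score_extravasation <- function(stack, vessel, diam_max_um = 9,
                                min_sphericity = 0.8, wall_tol_um = 5, ...) {
  det <- detect_nuclei(stack, ...)
  if (!nrow(det)) {
    s <- summarize_vessel(data.frame(cell_type = character(),
                                     position_class = character(),
                                     radial_excess_um = numeric()))
    attr(s, "cells") <- det
    return(s)
  }
  det$cell_type <- classify_cell_type(det, diam_max_um, min_sphericity)
  d <- dim(stack$data)
  bounds <- c(d[3L] * stack$pixel_size_um + stack$pixel_size_um,
              d[2L] * stack$pixel_size_um + stack$pixel_size_um,
              d[1L] * stack$step + stack$step)
  pos <- classify_position(det, vessel, wall_tol_um, bounds_um = bounds)
  det <- cbind(det, pos)
  s <- summarize_vessel(det)
  attr(s, "cells") <- det
  s
}

#' Match detections to a phantom truth table by nearest neighbour
#'
#' @param detections data.frame from [detect_nuclei()].
#' @param truth truth table from [simulate_cell_stack()].
#' @param radius_um maximum match distance (um, default 5).
#' @return list with `matched` (rows: truth id, detection row, distance),
#'   `missed` truth ids, `spurious` detection rows.
#' @export
match_detections <- function(detections, truth, radius_um = 5) {
  if (!nrow(detections) || !nrow(truth))
    return(list(matched = data.frame(), missed = truth$id,
                spurious = seq_len(nrow(detections))))
  dmat <- outer(truth$x_um, detections$x_um, `-`)^2 +
    outer(truth$y_um, detections$y_um, `-`)^2 +
    outer(truth$z_um, detections$z_um, `-`)^2
  dmat <- sqrt(dmat)
  matched <- data.frame()
  used_t <- logical(nrow(truth)); used_d <- logical(nrow(detections))
  repeat {
    i <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
    if (dmat[i[1L], i[2L]] > radius_um) break
    matched <- rbind(matched,
                     data.frame(truth_id = truth$id[i[1L]],
                                detection = i[2L],
                                dist_um = dmat[i[1L], i[2L]]))
    used_t[i[1L]] <- TRUE; used_d[i[2L]] <- TRUE
    dmat[i[1L], ] <- Inf; dmat[, i[2L]] <- Inf
    if (all(used_t) || all(used_d)) break
  }
  list(matched = matched, missed = truth$id[!used_t],
       spurious = which(!used_d))
}
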