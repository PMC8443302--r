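# Endothelial-monolayer geometry: junction segmentation, continuity of the
# junction lattice, vessel diameter/axis from wall projections, and lumen
# circle detection for the permeability pipeline.

#' Otsu threshold of a grayscale image
#'
#' Maximises between-class variance over a 256-bin histogram.
#'
#' @param img numeric matrix.
#' @return threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: no threshold separates fore/background")
  h <- tabulate(pmin(256L, 1L + floor((v - lo) / (hi - lo) * 256)), 256L)
  w <- h / sum(h)
  mids <- lo + (seq_len(256) - 0.5) / 256 * (hi - lo)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256L]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

# Connected-component labels of a logical mask (igraph-backed)
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- r + s[1L]; c2 <- cc + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges[[length(edges) + 1L]] <-
        cbind(id[cbind(r[ok], cc[ok])], id[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  lab <- matrix(0L, nr, nc)
  lab[idx] <- memb
  lab
}

#' Segment a junction network by thresholding
#'
#' Pixels at or above the threshold are foreground; objects smaller than
#' `speckle_px` pixels are removed before reporting so that isolated noise
#' blobs cannot defeat the single-object continuity check.
#'
#' @param image 2D numeric matrix (a maximum-intensity projection).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold when `method = "fixed"`.
#' @param speckle_px minimum retained object area (px, default 10; set 0 to
#'   disable despeckling).
#' @param connectivity 8 (default) or 4, used for despeckling.
#' @return a `SegmentationMask`: list with logical `mask`, `threshold`,
#'   `method`, `speckle_px`.
#' @export
segment_junctions <- function(image, method = c("otsu", "fixed"),
                              fixed_threshold = NULL, speckle_px = 10,
                              connectivity = 8) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  thr <- if (method == "otsu") otsu_threshold(image) else {
    if (is.null(fixed_threshold)) stop("fixed_threshold required")
    fixed_threshold
  }
  mask <- image >= thr
  if (!any(mask))
    stop("empty foreground after thresholding; review the threshold (",
         signif(thr, 4), ")")
  if (all(mask))
    stop("threshold selects the whole image; review the threshold (",
         signif(thr, 4), ")")
  if (speckle_px > 0) {
    lab <- label_components(mask, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    mask <- mask & matrix(sizes[pmax(lab, 1L)] >= speckle_px & lab > 0L,
                          nrow(mask), ncol(mask))
    if (!any(mask))
      stop("empty foreground after speckle removal; review the threshold")
  }
  structure(list(mask = mask, threshold = thr, method = method,
                 speckle_px = speckle_px),
            class = "SegmentationMask")
}

#' Monolayer continuity from a segmentation mask
#'
#' Counts connected components of the junction foreground. A continuous
#' endothelial monolayer shows up as a single 8-connected object; gaps
#' split the lattice.
#'
#' @param mask a `SegmentationMask` from [segment_junctions()] or a logical
#'   matrix.
#' @param connectivity 8 (default) or 4.
#' @return a `ContinuityReport`: list with `n_components`,
#'   `largest_component_fraction`, `is_single_object`, `component_sizes`.
#' @export
continuity_report <- function(mask, connectivity = 8) {
  m <- if (inherits(mask, "SegmentationMask")) mask$mask else mask
  stopifnot(is.matrix(m), is.logical(m))
  if (!any(m)) stop("empty mask: no foreground to analyse")
  lab <- label_components(m, connectivity)
  sizes <- sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
  structure(list(n_components = length(sizes),
                 largest_component_fraction = sizes[1L] / sum(sizes),
                 is_single_object = length(sizes) == 1L,
                 component_sizes = sizes),
            class = "ContinuityReport")
}

#' Vessel axis and diameter from a wall projection
#'
#' The axis is fit as a line through per-column intensity-weighted
#' centroids; per-column wall edges are the outermost half-maximum
#' crossings of the transverse intensity profile (subpixel, linear
#' interpolation), and the diameter is the wall separation corrected for
#' axis tilt, in micrometres. The summary diameter is the median over
#' valid columns.
#'
#' @param image 2D numeric matrix with both wall bands inside the field.
#' @param pixel_size_um pixel size (um).
#' @param min_columns minimum number of valid columns (default 10).
#' @param min_signal_frac columns whose peak is below this fraction of the
#'   global peak are skipped.
#' @return a `DiameterProfile`: list with `diameter_um` (median summary),
#'   per-column `profile_um`, `axis_angle_deg`, `wall_rows` (2-row matrix
#'   of subpixel wall positions), `columns` used.
#' @export
estimate_axis_and_diameter <- function(image, pixel_size_um,
                                       min_columns = 10,
                                       min_signal_frac = 0.3) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  nr <- nrow(image); nc <- ncol(image)
  peak <- max(image)
  if (peak <= 0) stop("blank image: no wall signal")
  cols <- seq_len(nc)
  top <- bottom <- rep(NA_real_, nc)
  centroid <- rep(NA_real_, nc)
  for (j in cols) {
    prof <- image[, j]
    pk <- max(prof)
    if (pk < min_signal_frac * peak) next
    h <- pk / 2
    above <- which(prof >= h)
    a <- above[1L]; b <- above[length(above)]
    if (a == 1L || b == nr) next    # wall touches the field edge
    # require two distinct wall bands: a single contiguous band (other
    # wall out of field) must not masquerade as a full vessel
    if (!any(diff(above) > 1L)) next
    # subpixel crossings around the outermost half-max samples
    top[j] <- (a - 1) + (h - prof[a - 1L]) / (prof[a] - prof[a - 1L])
    bottom[j] <- b + (prof[b] - h) / (prof[b] - prof[b + 1L])
    centroid[j] <- sum(prof * seq_len(nr)) / sum(prof)
  }
  ok <- which(!is.na(top))
  if (length(ok) < min_columns)
    stop("fewer than ", min_columns, " valid columns (",
         length(ok), "); are both walls inside the field?")
  fit <- ols_line(ok, centroid[ok])
  axis_angle_deg <- atan(fit$slope) * 180 / pi
  sep_px <- bottom[ok] - top[ok]
  prof_um <- sep_px * pixel_size_um * cos(axis_angle_deg * pi / 180)
  if (any(prof_um <= 0)) stop("non-positive wall separation encountered")
  structure(list(diameter_um = stats::median(prof_um),
                 profile_um = prof_um,
                 axis_angle_deg = axis_angle_deg,
                 wall_rows = rbind(top = top[ok], bottom = bottom[ok]),
                 columns = ok),
            class = "DiameterProfile")
}

#' Locate the lumen circle in the first frame of a permeability stack
#'
#' The bright lumen is thresholded (Otsu), the largest connected component
#' taken, and the circle reported as its centroid plus equivalent-area
#' radius.
#'
#' @param frame 2D numeric matrix (frame at t ~ 0) or an `ImageStack`
#'   (first frame used).
#' @param pixel_size_um pixel size (um).
#' @param min_area_px minimum bright-region area (px) to accept.
#' @return a `VesselCircle`: list with `center_px` (row, col),
#'   `radius_um`, `radius_px`.
#' @export
locate_lumen_circle <- function(frame, pixel_size_um = NULL,
                                min_area_px = 50) {
  if (inherits(frame, "ImageStack")) {
    pixel_size_um <- pixel_size_um %||% frame$pixel_size_um
    frame <- frame_of(frame, 1L)
  }
  stopifnot(is.matrix(frame), !is.null(pixel_size_um), pixel_size_um > 0)
  thr <- tryCatch(otsu_threshold(frame),
                  error = function(e) stop("dark/constant frame: ",
                                           conditionMessage(e)))
  mask <- frame >= thr
  lab <- label_components(mask, 8)
  sizes <- tabulate(lab[lab > 0L])
  if (!length(sizes) || max(sizes) < min_area_px)
    stop("no bright region exceeding ", min_area_px, " px found")
  big <- which.max(sizes)
  px <- which(lab == big, arr.ind = TRUE)
  center <- colMeans(px)
  radius_px <- sqrt(nrow(px) / pi)
  structure(list(center_px = c(row = unname(center[1L]),
                               col = unname(center[2L])),
                 radius_px = radius_px,
                 radius_um = radius_px * pixel_size_um),
            class = "VesselCircle")
}
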