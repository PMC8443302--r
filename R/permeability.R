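# Diffusive permeability P_d from a dextran time-lapse. The transported
# mass balance for a cylindrical vessel of radius r with lumen total
# intensity I0 (= C0 * pi r^2 per unit depth) leaking across its wall with
# permeability P_d into a sink-like exterior gives
#   dI_out/dt = 2 * P_d * I0 / r,
# hence the estimator P_d = (r / (2 I0)) * (dI_out/dt), the unique
# arrangement of the named quantities (r, I0, dI/dt) with velocity units
# that is exact for this balance.

#' Extract lumen/exterior intensity traces from a permeability stack
#'
#' The lumen ROI is the vessel circle eroded by `guard_px`; the exterior
#' ROI is the full frame minus the circle dilated by `guard_px` (the guard
#' band keeps the endothelium itself out of both ROIs). The background
#' (mean exterior intensity of frame 1 by default) is subtracted from both
#' traces, which are clipped at zero. The lumen total is reported as the
#' guard-banded mean times the full-disk pixel count, so the erosion does
#' not bias the mass-balance denominator.
#'
#' @param stack a time-axis [image_stack()].
#' @param circle a `VesselCircle` from [locate_lumen_circle()], or a list
#'   with `center_px` (row, col) and `radius_um`.
#' @param background `"first-frame-exterior"` (default) or `"fixed"`.
#' @param fixed_background background level when `background = "fixed"`.
#' @param guard_px wall guard band in pixels (default 2).
#' @return an `IntensityTrace`: list with `t` (s), `I_in_total`,
#'   `I_out_total`, `background`, `n_lumen_px`, `n_exterior_px`.
#' @export
extract_traces <- function(stack, circle,
                           background = c("first-frame-exterior", "fixed"),
                           fixed_background = 0, guard_px = 2) {
  background <- match.arg(background)
  stopifnot(inherits(stack, "ImageStack"))
  if (stack$axis_kind != "time")
    stop("permeability traces need a time-axis stack")
  nfr <- n_frames(stack)
  if (nfr < 3L) stop("time fit needs at least 3 frames; got ", nfr)
  d <- dim(stack$data)
  r_px <- circle$radius_um / stack$pixel_size_um
  rho <- radial_map(d[2L], d[3L], circle$center_px[1L], circle$center_px[2L])
  lumen <- rho <= r_px - guard_px
  disk <- rho <= r_px
  exterior <- rho >= r_px + guard_px
  if (!any(lumen)) stop("guard band consumes the lumen ROI")
  if (!any(exterior)) stop("guard band consumes the exterior ROI")
  I_in_raw <- I_out_raw <- numeric(nfr)
  for (f in seq_len(nfr)) {
    fr <- frame_of(stack, f)
    I_in_raw[f] <- mean(fr[lumen])
    I_out_raw[f] <- sum(fr[exterior])
  }
  bg <- if (background == "first-frame-exterior")
    mean(frame_of(stack, 1L)[exterior]) else fixed_background
  n_ext <- sum(exterior)
  n_disk <- sum(disk)
  I_in <- pmax((I_in_raw - bg) * n_disk, 0)
  I_out <- pmax(I_out_raw - bg * n_ext, 0)
  if (mean(I_in) == 0)
    stop("lumen trace is zero after background subtraction")
  structure(list(t = stack_times(stack), I_in_total = I_in,
                 I_out_total = I_out, background = bg,
                 n_lumen_px = n_disk, n_exterior_px = n_ext),
            class = "IntensityTrace")
}

#' Fit the early-time exterior leak rate
#'
#' Ordinary least squares of `I_out_total` against time on a fit window.
#' The automatic window is the longest initial span over which
#' `I_out_total` stays at or below 20% of its final value, provided it
#' holds at least 5 frames; otherwise the first half of the series is
#' used. Restricting to early times guards against the flattening of the
#' trace as the exterior approaches equilibration.
#'
#' @param trace an `IntensityTrace`.
#' @param window `"auto"` (default) or an integer `c(a, b)` of frame
#'   indices.
#' @return list with `slope` (intensity/s), `r2`, `window = c(a, b)`.
#' @export
fit_leak_rate <- function(trace, window = "auto") {
  stopifnot(inherits(trace, "IntensityTrace"))
  n <- length(trace$t)
  if (identical(window, "auto")) {
    final <- trace$I_out_total[n]
    below <- trace$I_out_total <= 0.2 * final
    run <- if (below[1L]) which.min(c(below, FALSE)) - 1L else 0L
    window <- if (run >= 5L) c(1L, run) else c(1L, max(3L, floor(n / 2)))
  }
  a <- window[1L]; b <- window[2L]
  if (b - a + 1L < 3L)
    stop("fit window [", a, ", ", b, "] holds fewer than 3 frames")
  fit <- ols_line(trace$t[a:b], trace$I_out_total[a:b])
  list(slope = fit$slope, r2 = fit$r2, window = c(a, b))
}

#' Diffusive permeability from the mass-balance relation
#'
#' `P_d = (r / (2 I0)) * slope` in um/s, with `r` in um, `I0` the lumen
#' total intensity and `slope` the exterior leak rate (intensity/s).
#' Negative slopes are clipped to `P_d = 0` with a warning flag.
#'
#' @param r_um vessel radius (um, > 0).
#' @param I0_ref reference lumen total intensity (> 0).
#' @param slope exterior intensity slope (intensity units / s).
#' @param r2,window optional fit diagnostics carried into the result.
#' @return a `PdResult`: list with `pd_um_s`, `r_um`, `I0_ref`, `slope`,
#'   `r2`, `window`, `clipped_negative`.
#' @export
compute_pd <- function(r_um, I0_ref, slope, r2 = NA_real_, window = c(NA, NA)) {
  stopifnot(r_um > 0)
  if (!is.finite(I0_ref) || I0_ref <= 0)
    stop("I0_ref must be positive; got ", I0_ref)
  pd <- r_um / (2 * I0_ref) * slope
  clipped <- pd < 0
  if (clipped) {
    warning("negative leak slope; P_d clipped to 0")
    pd <- 0
  }
  structure(list(pd_um_s = pd, r_um = r_um, I0_ref = I0_ref, slope = slope,
                 r2 = r2, window = window, clipped_negative = clipped),
            class = "PdResult")
}

#' Full diffusive-permeability pipeline on one stack
#'
#' Locates the lumen circle (unless supplied), extracts traces, fits the
#' early leak rate and applies the mass-balance estimator. `I0_ref` is the
#' mean of the lumen trace over the fit window (`i0 = "window-mean"`,
#' default) or the per-frame lumen trace averaged the same way after
#' normalising the exterior trace frame-by-frame (`i0 = "per-frame"`).
#'
#' @param stack a time-axis [image_stack()].
#' @param circle optional `VesselCircle`; located automatically if `NULL`.
#' @param window fit window (see [fit_leak_rate()]).
#' @param i0 `"window-mean"` or `"per-frame"`.
#' @param ... passed to [extract_traces()].
#' @return a `PdResult` (with the trace attached as attribute `trace`).
#' @export
measure_pd <- function(stack, circle = NULL, window = "auto",
                       i0 = c("window-mean", "per-frame"), ...) {
  i0 <- match.arg(i0)
  if (is.null(circle)) circle <- locate_lumen_circle(stack)
  trace <- extract_traces(stack, circle, ...)
  if (i0 == "per-frame") {
    scale <- mean(trace$I_in_total) / trace$I_in_total
    trace$I_out_total <- trace$I_out_total * scale
  }
  fit <- fit_leak_rate(trace, window)
  I0_ref <- mean(trace$I_in_total[fit$window[1L]:fit$window[2L]])
  res <- compute_pd(circle$radius_um, I0_ref, fit$slope,
                    r2 = fit$r2, window = fit$window)
  attr(res, "trace") <- trace
  res
}
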