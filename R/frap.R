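# Interstitial flow velocimetry: track a photobleached spot through a
# time-lapse and convert the advection velocity to Darcy hydraulic
# permeability k = v mu L / dP.

#' Detect the bleached-spot centre in one frame
#'
#' Candidate pixels are those below `background - 3 * noise_sd` within the
#' search radius of the prior centre. The centre is then refined by
#' least-squares fit of a radially symmetric dip model
#' `offset - amplitude * exp(-rho^2 / (2 sigma^2))` over a local window,
#' giving a subpixel position. Intensity gain/offset enter only through
#' the fitted offset/amplitude, so detection is invariant to affine
#' intensity rescaling.
#'
#' @param frame 2D numeric matrix.
#' @param prior_center optional `c(row, col)` from the previous frame.
#' @param search_radius_px search radius around the prior (px).
#' @param background background level; default: median of the frame.
#' @param noise_sd noise scale; default: robust MAD of the frame.
#' @return list with `center` (row, col), `sigma_px`, `residual` (RMS of
#'   the dip fit), or an error if no dip is found.
#' @export
detect_spot <- function(frame, prior_center = NULL, search_radius_px = 20,
                        background = NULL, noise_sd = NULL) {
  stopifnot(is.matrix(frame))
  bg <- background %||% stats::median(frame)
  ns <- noise_sd %||% max(stats::mad(frame), 1e-12)
  cand <- frame < bg - 3 * ns
  if (!is.null(prior_center)) {
    rho <- radial_map(nrow(frame), ncol(frame),
                      prior_center[1L], prior_center[2L])
    cand <- cand & rho <= search_radius_px
  }
  if (!any(cand))
    stop("spot detection failure: no pixels below background - 3*noise")
  # initial centre and width: deficit-weighted moments of candidate pixels
  px <- which(cand, arr.ind = TRUE)
  wts <- (bg - frame[cand])
  c0 <- c(sum(px[, 1L] * wts), sum(px[, 2L] * wts)) / sum(wts)
  m2 <- sum(((px[, 1L] - c0[1L])^2 + (px[, 2L] - c0[2L])^2) * wts) / sum(wts)
  sig0 <- max(2, sqrt(m2 / 2))
  # local window for the model fit
  half <- max(8L, ceiling(3 * sig0))
  rr <- max(1L, floor(c0[1L] - half)):min(nrow(frame), ceiling(c0[1L] + half))
  cc <- max(1L, floor(c0[2L] - half)):min(ncol(frame), ceiling(c0[2L] + half))
  sub <- frame[rr, cc]
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  amp0 <- max(bg - min(sub), 1e-12)
  obj <- function(p) {
    model <- p[3L] - abs(p[4L]) *
      exp(-((gr - p[1L])^2 + (gc - p[2L])^2) / (2 * p[5L]^2))
    sum((sub - model)^2)
  }
  fit <- stats::optim(c(c0, bg, amp0, sig0), obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  # Nelder-Mead can stall on a large window; a restart from the first
  # solution converges the centre to well below 0.1 px
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  center <- fit$par[1:2]
  list(center = c(row = center[1L], col = center[2L]),
       sigma_px = abs(fit$par[5L]),
       residual = sqrt(fit$value / length(sub)))
}

#' Track the bleached spot across a time-lapse
#'
#' Frame-by-frame [detect_spot()] with the previous centre as prior. The
#' track ends early after `fail_limit` consecutive detection failures
#' (diffusive recovery has erased the spot); failed frames are flagged,
#' never interpolated.
#'
#' @param stack a time-axis [image_stack()].
#' @param search_radius_px search radius passed to [detect_spot()].
#' @param fail_limit consecutive failures that end the track (default 3).
#' @param min_frames minimum successful detections (default 5).
#' @return a `SpotTrack`: list with `t` (s, successful frames), `centers`
#'   (matrix row/col, px), `residuals`, `failed_frames`.
#' @export
track_spot <- function(stack, search_radius_px = 20, fail_limit = 3,
                       min_frames = 5) {
  stopifnot(inherits(stack, "ImageStack"), stack$axis_kind == "time")
  nfr <- n_frames(stack)
  if (nfr < 5L) stop("spot tracking needs at least 5 frames; got ", nfr)
  t_all <- stack_times(stack)
  centers <- matrix(NA_real_, nfr, 2L)
  resid <- rep(NA_real_, nfr)
  failed <- integer()
  prior <- NULL
  consec <- 0L
  last <- nfr
  for (f in seq_len(nfr)) {
    det <- tryCatch(
      detect_spot(frame_of(stack, f), prior_center = prior,
                  search_radius_px = search_radius_px),
      error = function(e) NULL)
    if (is.null(det)) {
      failed <- c(failed, f)
      consec <- consec + 1L
      if (consec >= fail_limit) { last <- f; break }
    } else {
      centers[f, ] <- det$center
      resid[f] <- det$residual
      prior <- det$center
      consec <- 0L
    }
  }
  ok <- which(!is.na(centers[, 1L]))
  if (length(ok) < min_frames)
    stop("only ", length(ok), " frames with a detectable spot (need ",
         min_frames, ")")
  structure(list(t = t_all[ok], centers = centers[ok, , drop = FALSE],
                 residuals = resid[ok], failed_frames = failed,
                 pixel_size_um = stack$pixel_size_um),
            class = "SpotTrack")
}

#' Fit the interstitial flow velocity from a spot track
#'
#' Separate least-squares lines for row(t) and col(t); the speed is the
#' quadrature sum of the two slopes converted to um/s, and R^2 is computed
#' from the displacement projected on the fitted direction.
#'
#' @param track a `SpotTrack`.
#' @return a `VelocityResult`: list with `v_um_s`, `direction` (unit row/
#'   col vector), `r2`.
#' @export
fit_velocity <- function(track) {
  stopifnot(inherits(track, "SpotTrack"))
  if (length(track$t) < 5L) stop("need at least 5 retained centres")
  fr <- ols_line(track$t, track$centers[, 1L])
  fc <- ols_line(track$t, track$centers[, 2L])
  sl <- c(fr$slope, fc$slope)
  speed_px <- sqrt(sum(sl^2))
  dirv <- if (speed_px > 0) sl / speed_px else c(0, 0)
  # R^2 of displacement projected on the fitted direction
  proj <- track$centers %*% dirv
  r2 <- if (speed_px > 0) ols_line(track$t, as.numeric(proj))$r2 else 0
  structure(list(v_um_s = speed_px * track$pixel_size_um,
                 direction = c(row = dirv[1L], col = dirv[2L]), r2 = r2),
            class = "VelocityResult")
}

#' Hydraulic permeability from Darcy's law
#'
#' `k = v * mu * L / dP` with the spot velocity taken as the superficial
#' Darcy flux (porosity 1 by default). The applied head is given in
#' mmH2O as in the assay protocol (5, 10 or 20; other values allowed with
#' a warning) and converted at 9.80665 Pa per mmH2O.
#'
#' @param v_um_s measured flow speed (um/s, >= 0).
#' @param head_mmH2O applied hydrostatic head (mmH2O, > 0).
#' @param gap_L_um channel-to-channel gel gap L (um, > 0). No default:
#'   device geometry must be supplied explicitly.
#' @param mu_pa_s dynamic viscosity (Pa s; default 7e-4, aqueous buffer at
#'   37 C).
#' @param porosity superficial-to-interstitial velocity factor (default 1).
#' @return a `DarcyResult`: list with `k_m2`, `v_um_s`, `delta_p_pa`,
#'   `head_mmH2O`, `gap_L_um`, `mu_pa_s`, `zero_flow`.
#' @export
darcy_permeability <- function(v_um_s, head_mmH2O, gap_L_um,
                               mu_pa_s = 7e-4, porosity = 1) {
  if (missing(gap_L_um) || is.null(gap_L_um))
    stop("gap_L_um is required (channel-to-channel distance, um)")
  stopifnot(v_um_s >= 0, head_mmH2O > 0, gap_L_um > 0, mu_pa_s > 0,
            porosity > 0, porosity <= 1)
  if (!head_mmH2O %in% c(5, 10, 20))
    warning("head ", head_mmH2O, " mmH2O is outside the usual {5, 10, 20}")
  delta_p <- mmh2o_to_pa(head_mmH2O)
  v_m_s <- v_um_s * 1e-6 * porosity
  L_m <- gap_L_um * 1e-6
  k <- v_m_s * mu_pa_s * L_m / delta_p
  structure(list(k_m2 = k, v_um_s = v_um_s, delta_p_pa = delta_p,
                 head_mmH2O = head_mmH2O, gap_L_um = gap_L_um,
                 mu_pa_s = mu_pa_s, porosity = porosity,
                 zero_flow = v_um_s == 0),
            class = "DarcyResult")
}
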