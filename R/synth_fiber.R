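# Oriented fiber-texture phantom for the alignment-index module. Fiber
# orientations are axial data (theta and theta + 180 degrees are the same
# fiber), so angular dispersion is modelled on the doubled angle: with
# 2*(theta - axis) ~ von Mises(0, kappa), the population alignment index
# E[cos 2(theta - axis)] has the closed form I1(kappa)/I0(kappa).

#' Specification of an oriented fiber-field phantom
#'
#' @param n_fibers number of line segments.
#' @param axis_angle_deg vessel-axis angle (degrees; 0 = horizontal, i.e.
#'   along image columns, increasing toward +rows).
#' @param kappa von Mises concentration of the doubled fiber angle about the
#'   axis. `0` gives isotropic orientations, `Inf` perfectly parallel ones.
#' @param fiber_length_px,fiber_width_px segment geometry (px). Fibers
#'   default to long strands spanning several analysis patches, as actin
#'   stress fibers and junction strands span whole cells; short segments
#'   add isotropic end-cap energy to the spectrum that depresses the
#'   alignment index of even perfectly parallel textures.
#' @param field_px image size `c(rows, cols)`.
#' @param fiber_intensity additive intensity per fiber (a.u.).
#' @param noise_sd additive Gaussian noise SD (fraction of fiber intensity).
#' @return a validated `FiberPhantomSpec` list.
#' @export
fiber_phantom_spec <- function(n_fibers = 700, axis_angle_deg = 0, kappa = 2,
                               fiber_length_px = 200, fiber_width_px = 2,
                               field_px = c(640, 640), fiber_intensity = 1,
                               noise_sd = 0) {
  stopifnot(n_fibers >= 1, kappa >= 0, fiber_length_px > 0,
            fiber_width_px > 0, noise_sd >= 0, length(field_px) == 2L)
  structure(list(n_fibers = as.integer(n_fibers),
                 axis_angle_deg = axis_angle_deg, kappa = kappa,
                 fiber_length_px = fiber_length_px,
                 fiber_width_px = fiber_width_px,
                 field_px = as.integer(field_px),
                 fiber_intensity = fiber_intensity, noise_sd = noise_sd),
            class = "FiberPhantomSpec")
}

# von Mises(0, kappa) sampler (Best & Fisher rejection scheme); kappa = 0
# falls back to the uniform circle.
rvonmises0 <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa)) return(numeric(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + sum(ok))] <- th
      got <- got + sum(ok)
    }
  }
  out
}

#' Simulate an oriented fiber texture with known angular dispersion
#'
#' Anti-aliased line segments are rendered additively; each segment's angle
#' is `axis + delta/2` with `delta ~ von Mises(0, kappa)` (doubled-angle
#' convention).
#'
#' @param spec a [fiber_phantom_spec()].
#' @param seed integer seed.
#' @return `list(image = matrix, truth = list(...))`; truth records kappa,
#'   the axis, the drawn angles, their empirical alignment
#'   `mean(cos 2(theta - axis))`, and the closed-form expectation
#'   `besselI(kappa, 1) / besselI(kappa, 0)`.
#' @export
simulate_fiber_field <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "FiberPhantomSpec"))
  set.seed(stage_seed(seed, 31L))
  nr <- spec$field_px[1L]; nc <- spec$field_px[2L]
  axis_rad <- spec$axis_angle_deg * pi / 180
  theta <- axis_rad + rvonmises0(spec$n_fibers, spec$kappa) / 2
  img <- matrix(0, nr, nc)
  half <- spec$fiber_length_px / 2
  hw <- spec$fiber_width_px / 2
  cr <- stats::runif(spec$n_fibers, 1, nr)
  cc <- stats::runif(spec$n_fibers, 1, nc)
  for (i in seq_len(spec$n_fibers)) {
    # direction in (col, row) = (cos, sin): 0 deg runs along columns
    d <- c(sin(theta[i]), cos(theta[i]))            # (row, col)
    p0 <- c(cr[i], cc[i]) - half * d
    p1 <- c(cr[i], cc[i]) + half * d
    r_rng <- max(1L, floor(min(p0[1L], p1[1L]) - hw - 1)):
             min(nr, ceiling(max(p0[1L], p1[1L]) + hw + 1))
    c_rng <- max(1L, floor(min(p0[2L], p1[2L]) - hw - 1)):
             min(nc, ceiling(max(p0[2L], p1[2L]) + hw + 1))
    if (!length(r_rng) || !length(c_rng)) next
    rr <- matrix(r_rng, length(r_rng), length(c_rng))
    cc2 <- matrix(c_rng, length(r_rng), length(c_rng), byrow = TRUE)
    # distance from pixel centres to the segment
    vx <- p1[1L] - p0[1L]; vy <- p1[2L] - p0[2L]
    len2 <- vx^2 + vy^2
    tt <- ((rr - p0[1L]) * vx + (cc2 - p0[2L]) * vy) / len2
    tt <- pmin(1, pmax(0, tt))
    dist <- sqrt((rr - (p0[1L] + tt * vx))^2 + (cc2 - (p0[2L] + tt * vy))^2)
    cov <- clamp01(hw + 0.5 - dist)                # ~1 px anti-alias ramp
    img[r_rng, c_rng] <- img[r_rng, c_rng] + spec$fiber_intensity * cov
  }
  if (spec$noise_sd > 0)
    img <- pmax(img + stats::rnorm(length(img), 0,
                                   spec$noise_sd * spec$fiber_intensity), 0)
  kap <- spec$kappa
  closed_form <- if (is.finite(kap)) {
    if (kap == 0) 0 else besselI(kap, 1) / besselI(kap, 0)
  } else 1
  truth <- list(kappa = kap, axis_angle_deg = spec$axis_angle_deg,
                angles_rad = theta,
                empirical_alignment = mean(cos(2 * (theta - axis_rad))),
                expected_alignment = closed_form, seed = seed)
  list(image = img, truth = truth)
}
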