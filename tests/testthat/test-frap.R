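# Spot detection/tracking, velocity fitting, Darcy conversion.

test_that("detect_spot: subpixel recovery vs brute-force centroid oracle", {
  for (ctr in list(c(64, 64), c(64.5, 64.5), c(58.25, 71.75))) {
    sp <- frap_phantom_spec(velocity_um_s = 0, noise_sd = 0,
                            start_px = ctr, frames = 5)
    fr <- matrix(simulate_frap_timelapse(sp, 1)$stack$data[1, , ], 128, 128)
    det <- detect_spot(fr)
    expect_equal(unname(det$center), ctr, tolerance = 0.1 / 64)
    # independent oracle: centroid of (background - frame) deficit weights
    w <- pmax(max(fr) - fr - 1e-9, 0)
    oracle <- c(sum(row(fr) * w), sum(col(fr) * w)) / sum(w)
    expect_lt(sqrt(sum((det$center - oracle)^2)), 0.2)
  }
  expect_error(detect_spot(matrix(100, 64, 64)), "detection failure")
})

test_that("track_spot follows the dip and honours failure limits", {
  sp <- frap_phantom_spec(velocity_um_s = 1, dt = 1, pixel_size_um = 1,
                          noise_sd = 0.02)
  sim <- simulate_frap_timelapse(sp, seed = 4)
  tr <- track_spot(sim$stack)
  expect_equal(nrow(tr$centers), 30L)
  # successive steps ~ 1 px
  steps <- sqrt(rowSums(diff(tr$centers)^2))
  expect_equal(mean(steps), 1, tolerance = 0.05)
  # static spot, noise-free: all centres within 0.3 px of frame-0 centre
  sp0 <- frap_phantom_spec(velocity_um_s = 0, noise_sd = 0)
  tr0 <- track_spot(simulate_frap_timelapse(sp0, seed = 5)$stack)
  drift <- sqrt(rowSums((tr0$centers -
                           matrix(tr0$centers[1, ], 30, 2,
                                  byrow = TRUE))^2))
  expect_true(all(drift < 0.3))
  # with 2% noise the typical (median) drift stays below 0.3 px
  spn <- frap_phantom_spec(velocity_um_s = 0, noise_sd = 0.02)
  trn <- track_spot(simulate_frap_timelapse(spn, seed = 5)$stack)
  driftn <- sqrt(rowSums((trn$centers -
                            matrix(trn$centers[1, ], 30, 2,
                                   byrow = TRUE))^2))
  expect_lt(median(driftn), 0.3)
  # a spot fully recovered mid-movie ends the track early, no error
  spr <- frap_phantom_spec(velocity_um_s = 0.3,
                           diffusion_recovery_um2_s = 40, noise_sd = 0.02)
  trr <- track_spot(simulate_frap_timelapse(spr, seed = 6)$stack)
  expect_lt(nrow(trr$centers), 30L)
  expect_gte(nrow(trr$centers), 5L)
  short <- image_stack(sim$stack$data[1:4, , ], "time", 1, 1)
  expect_error(track_spot(short), "at least 5 frames")
})

test_that("fit_velocity: 3-4-5 identity and recovery from phantoms", {
  t <- 0:19
  centers <- cbind(10 + 0.6 * t, 20 + 0.8 * t)
  tr <- structure(list(t = t, centers = centers,
                       residuals = rep(0, 20), failed_frames = integer(),
                       pixel_size_um = 1),
                  class = "SpotTrack")
  v <- fit_velocity(tr)
  expect_equal(v$v_um_s, 1)
  expect_equal(unname(v$direction), c(0.6, 0.8))
  expect_equal(v$r2, 1)

  # recovery within 10% over 5 seeds at noise 0.02
  vs <- vapply(1:5, function(s) {
    sp <- frap_phantom_spec(velocity_um_s = 0.5, noise_sd = 0.02)
    fit_velocity(track_spot(simulate_frap_timelapse(sp, s)$stack))$v_um_s
  }, numeric(1))
  expect_true(all(abs(vs / 0.5 - 1) < 0.1))
  # static phantom: speed below 0.05 um/s
  sp0 <- frap_phantom_spec(velocity_um_s = 0, noise_sd = 0.02)
  v0 <- fit_velocity(track_spot(simulate_frap_timelapse(sp0, 9)$stack))
  expect_lt(v0$v_um_s, 0.05)
})

test_that("velocity is invariant under intensity gain and offset", {
  sp <- frap_phantom_spec(velocity_um_s = 0.8, noise_sd = 0.01)
  sim <- simulate_frap_timelapse(sp, seed = 7)
  v1 <- fit_velocity(track_spot(sim$stack))
  scaled <- image_stack(sim$stack$data * 3.7 + 250, "time", 1, 1)
  v2 <- fit_velocity(track_spot(scaled))
  expect_equal(v2$v_um_s, v1$v_um_s, tolerance = 0.005)
})

test_that("darcy_permeability arithmetic, units, and flags", {
  # v = 1 um/s, L = 1000 um, mu = 1e-3, head = 10 mmH2O
  res <- darcy_permeability(1, 10, 1000, mu_pa_s = 1e-3)
  expect_equal(res$k_m2, 1e-6 * 1e-3 * 1e-3 / 98.0665)
  expect_equal(res$delta_p_pa, 98.0665)
  z <- darcy_permeability(0, 5, 500)
  expect_equal(z$k_m2, 0)
  expect_true(z$zero_flow)
  expect_warning(darcy_permeability(1, 7, 500), "outside the usual")
  expect_error(darcy_permeability(1, 10, NULL), "gap_L_um")
  expect_error(darcy_permeability(1, -5, 500))
})

test_that("k is constant across heads when v scales with the head", {
  # phantoms generated with v = k dP / (mu L): recovered k has low CV
  k_true <- 5e-15                       # m^2 (v = 0.35-1.4 um/s over heads)
  mu <- 7e-4; L_um <- 1000
  ks <- vapply(c(5, 10, 20), function(head) {
    v_true <- k_true * mmh2o_to_pa(head) / (mu * L_um * 1e-6) * 1e6  # um/s
    sp <- frap_phantom_spec(velocity_um_s = v_true, noise_sd = 0.02,
                            field_px = c(160, 160))
    v <- fit_velocity(track_spot(simulate_frap_timelapse(sp, 11)$stack))
    darcy_permeability(v$v_um_s, head, L_um, mu)$k_m2
  }, numeric(1))
  expect_lt(stats::sd(ks) / mean(ks), 0.10)
  expect_equal(mean(ks), k_true, tolerance = 0.1)
})
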