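# Phantom generators: determinism, validation, and analytic oracles.

test_that("identical spec + seed gives bitwise-identical stacks", {
  a <- small_dextran(pd = 0.3, noise_sd = 0.02, seed = 5)
  b <- small_dextran(pd = 0.3, noise_sd = 0.02, seed = 5)
  expect_identical(a$stack$data, b$stack$data)
  d <- small_dextran(pd = 0.3, noise_sd = 0.02, seed = 6)
  expect_false(identical(a$stack$data, d$stack$data))

  f1 <- simulate_frap_timelapse(frap_phantom_spec(), seed = 3)
  f2 <- simulate_frap_timelapse(frap_phantom_spec(), seed = 3)
  expect_identical(f1$stack$data, f2$stack$data)
})

test_that("dextran spec validation enforces geometry and stability", {
  expect_error(vessel_phantom_spec(radius_um = 400, field_px = c(256, 256)),
               "exceeds field")
  expect_error(vessel_phantom_spec(radius_um = 100, field_px = c(640, 640),
                                   center_px = c(50, 320)),
               "outside the field")
  expect_error(vessel_phantom_spec(frames = 2), "frames")
  sp <- vessel_phantom_spec(frames = 5, field_px = c(256, 256),
                            radius_um = 50, D_um2_s = 5000)
  expect_error(simulate_dextran_timelapse(sp, max_substeps = 10),
               "substeps")
})

test_that("zero-permeability phantom keeps the exterior dark", {
  sim <- small_dextran(pd = 0, noise_sd = 0)
  circ <- list(center_px = c(80.5, 80.5), radius_um = 40)
  tr <- extract_traces(sim$stack, circ)
  expect_equal(tr$I_out_total, rep(0, 20))
  expect_equal(sim$truth$analytic_slope, 0)
})

test_that("noise-free exterior growth matches the analytic membrane flux", {
  # early-time mass balance: dI_out/dt = 2 pd I0 / r, pd = 0.5, r = 75
  sp <- vessel_phantom_spec(pd_true = 0.5, radius_um = 75, noise_sd = 0,
                            pixel_size_um = 1, field_px = c(512, 512),
                            frames = 12)
  sim <- simulate_dextran_timelapse(sp, seed = 1)
  rho <- sqrt(outer((1:512 - 256.5)^2, rep(1, 512)) +
              outer(rep(1, 512), (1:512 - 256.5)^2))
  ext <- rho > 75                        # no guard band: full exterior mass
  I_out <- apply(sim$stack$data, 1L, function(m) sum(m[ext]))
  secants <- diff(I_out) / 5
  expect_equal(mean(secants), sim$truth$analytic_slope,
               tolerance = 0.02)
  # and each interval individually stays within 2%
  expect_true(all(abs(secants / sim$truth$analytic_slope - 1) < 0.02))
})

test_that("series gel mode saturates the wall and bends the trace down", {
  sp_m <- vessel_phantom_spec(pd_true = 1.45, radius_um = 75, noise_sd = 0,
                              pixel_size_um = 1, field_px = c(400, 400),
                              frames = 15)
  sp_s <- vessel_phantom_spec(pd_true = 1.45, radius_um = 75, noise_sd = 0,
                              pixel_size_um = 1, field_px = c(400, 400),
                              frames = 15, gel_mode = "series")
  circ <- list(center_px = c(200.5, 200.5), radius_um = 75)
  tr_m <- extract_traces(simulate_dextran_timelapse(sp_m, 1)$stack, circ)
  tr_s <- extract_traces(simulate_dextran_timelapse(sp_s, 1)$stack, circ)
  # coupled boundary condition transports strictly less, increasingly so
  expect_true(all(tr_s$I_out_total[-1] < tr_m$I_out_total[-1]))
  ratio <- tr_s$I_out_total[-1] / tr_m$I_out_total[-1]
  expect_lt(ratio[14], 0.6)              # strong late-time saturation
})

test_that("FRAP phantom: kinematics identities and degenerate cases", {
  # v = 0: truth centres all equal
  sp0 <- frap_phantom_spec(velocity_um_s = 0)
  sim0 <- simulate_frap_timelapse(sp0, seed = 1)
  expect_equal(max(dist(sim0$truth$centers_px)), 0)
  # v = 1 um/s, dt = 1 s, 30 frames: 29 um end-to-end by construction,
  # and the rendered dip minimum moves accordingly (noise-free)
  sp1 <- frap_phantom_spec(velocity_um_s = 1, noise_sd = 0)
  sim1 <- simulate_frap_timelapse(sp1, seed = 1)
  tr <- sim1$truth$centers_px
  expect_equal(sqrt(sum((tr[30, ] - tr[1, ])^2)), 29)
  first <- which(sim1$stack$data[1, , ] == min(sim1$stack$data[1, , ]),
                 arr.ind = TRUE)
  expect_lt(sqrt(sum((first[1, ] - tr[1, ])^2)), 1)
  # spot_depth 0: flat stack, detection fails loudly
  spf <- frap_phantom_spec(spot_depth = 0, noise_sd = 0)
  simf <- simulate_frap_timelapse(spf, seed = 1)
  expect_equal(diff(range(simf$stack$data)), 0)
  expect_error(detect_spot(matrix(simf$stack$data[1, , ], 128, 128)),
               "detection failure")
  # spot escaping the field is refused up front
  expect_error(frap_phantom_spec(velocity_um_s = 10, frames = 30,
                                 field_px = c(128, 128)),
               "leaves the field")
})

test_that("fiber phantom: limit cases and the Bessel-ratio oracle", {
  al <- simulate_fiber_field(fiber_phantom_spec(kappa = Inf), seed = 1)
  expect_equal(al$truth$empirical_alignment, 1)
  expect_equal(al$truth$expected_alignment, 1)
  rnd <- simulate_fiber_field(fiber_phantom_spec(kappa = 0), seed = 1)
  expect_equal(rnd$truth$expected_alignment, 0)
  expect_lt(abs(rnd$truth$empirical_alignment), 0.1)
  # kappa = 2: empirical mean of cos 2(theta - axis) over drawn angles
  # matches I1(2)/I0(2) ~ 0.6978 (Monte-Carlo vs closed form)
  k2 <- simulate_fiber_field(fiber_phantom_spec(kappa = 2, n_fibers = 4000),
                             seed = 2)
  expect_equal(k2$truth$expected_alignment,
               besselI(2, 1) / besselI(2, 0))
  expect_equal(k2$truth$empirical_alignment, 0.6978, tolerance = 0.03)
})

test_that("von Mises sampler matches closed-form resultants over kappa", {
  set.seed(11)
  for (kap in c(0.5, 1, 5)) {
    th <- vesselquant:::rvonmises0(6000, kap)
    expect_equal(mean(cos(th)), besselI(kap, 1) / besselI(kap, 0),
                 tolerance = 0.03)
  }
})

test_that("cell phantom: truth table, boundary labels, empty case", {
  sim <- small_cells(n_endo = 5, n_adh = 0, n_ext = 0)
  expect_true(all(sim$truth$class == "endothelial"))
  v <- attr(sim$truth, "vessel")
  expect_equal(v$n_adhered, 0L)

  sim2 <- small_cells(n_endo = 6, n_adh = 2, n_ext = 3, seed = 2)
  tt <- sim2$truth
  expect_equal(sum(tt$position_class == "extravasated"), 3L)
  expect_true(all(tt$radial_excess_um[tt$position_class == "extravasated"] >=
                    5))
  # adhered monocytes sit within the wall tolerance by construction
  expect_true(all(abs(tt$radial_excess_um[tt$position_class ==
                                            "luminal_adherent"]) <= 5))
  # rendered intensities live in the stack, non-negative
  expect_true(all(sim2$stack$data >= 0))
  expect_equal(sim2$stack$axis_kind, "z")
})

test_that("migration preset draws truncated-normal distances near 20 um", {
  means <- vapply(1:5, function(s) {
    tt <- simulate_preset("migration-20um", seed = s)$truth
    mean(tt$radial_excess_um[tt$position_class == "extravasated"])
  }, numeric(1))
  expect_equal(mean(means), 20, tolerance = 2 / 20)
  expect_true(all(abs(means - 20) < 3))
})

test_that("presets encode the reported condition values", {
  expect_equal(get_preset("static-2.5mg")$truth$pd_um_s, 1.45)
  expect_equal(get_preset("flow-2.5mg")$truth$pd_um_s, 0.10)
  expect_equal(get_preset("flow-6mg")$truth$pd_um_s, 0.60)
  expect_equal(get_preset("migration-20um")$truth$migration_mean_um, 20)
  expect_equal(get_preset("counts-static")$truth$adhered_range, c(3, 10))
  expect_equal(get_preset("counts-flow")$truth$adhered_range, c(5, 20))
  expect_equal(get_preset("diam-hi")$truth$diameter_um, 250)
  expect_equal(get_preset("diam-lo")$truth$diameter_um, 125)
  expect_true(is.infinite(get_preset("aligned")$spec$kappa))
  expect_equal(get_preset("random")$spec$kappa, 0)
  expect_error(get_preset("does-not-exist"), "valid presets")
})
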