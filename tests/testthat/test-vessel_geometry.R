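# Junction segmentation, monolayer continuity, diameter/axis, lumen circle.

test_that("segment_junctions thresholds correctly and despeckles", {
  lat <- simulate_junction_lattice()
  seg <- segment_junctions(lat$image)        # Otsu on a two-level image
  expect_identical(seg$mask, lat$mask)
  # fixed threshold at 50% of max on a two-level image picks the top level
  seg2 <- segment_junctions(lat$image, method = "fixed",
                            fixed_threshold = 50)
  expect_identical(seg2$mask, lat$mask)
  # a lone 4-px speckle is removed, the lattice survives
  img <- lat$image
  img[5:6, 5:6] <- 100
  seg3 <- segment_junctions(img, method = "fixed", fixed_threshold = 50,
                            speckle_px = 10)
  expect_identical(seg3$mask, lat$mask)
  seg4 <- segment_junctions(img, method = "fixed", fixed_threshold = 50,
                            speckle_px = 0)
  expect_equal(sum(seg4$mask) - sum(lat$mask), 4)
  expect_error(segment_junctions(matrix(3, 32, 32)), "constant image")
  expect_error(segment_junctions(lat$image, method = "fixed",
                                 fixed_threshold = 1000),
               "empty foreground")
})

test_that("continuity_report counts objects and their area fractions", {
  lat <- simulate_junction_lattice()
  rep1 <- continuity_report(segment_junctions(lat$image))
  expect_equal(rep1$n_components, 1L)
  expect_true(rep1$is_single_object)
  expect_equal(rep1$largest_component_fraction, 1)

  cut <- simulate_junction_lattice(cut_columns = 3)
  rep2 <- continuity_report(segment_junctions(cut$image))
  expect_equal(rep2$n_components, 2L)
  expect_false(rep2$is_single_object)

  # two disjoint equal squares: fraction exactly one half
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE
  m[25:34, 25:34] <- TRUE
  rep3 <- continuity_report(m)
  expect_equal(rep3$n_components, 2L)
  expect_equal(rep3$largest_component_fraction, 0.5)
  expect_error(continuity_report(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("continuity is invariant under translation and 90-degree rotation", {
  cut <- simulate_junction_lattice(n_rows = 3, n_cols = 4, cut_columns = 2)
  base <- continuity_report(cut$mask)
  # embed with offsets (translation) and rotate
  for (tr in list(c(3, 5), c(10, 0))) {
    big <- matrix(FALSE, nrow(cut$mask) + 20, ncol(cut$mask) + 20)
    big[tr[1] + seq_len(nrow(cut$mask)), tr[2] + seq_len(ncol(cut$mask))] <-
      cut$mask
    r <- continuity_report(big)
    expect_equal(r$n_components, base$n_components)
    expect_equal(r$largest_component_fraction,
                 base$largest_component_fraction)
  }
  rot <- t(cut$mask)[ncol(cut$mask):1, ]
  r90 <- continuity_report(rot)
  expect_equal(r90$n_components, base$n_components)
  expect_equal(r90$largest_component_fraction,
               base$largest_component_fraction)
})

test_that("diagonal strands are one object at 8-connectivity, two at 4", {
  m <- matrix(FALSE, 10, 10)
  m[cbind(1:10, 1:10)] <- TRUE
  expect_equal(continuity_report(m, connectivity = 8)$n_components, 1L)
  expect_equal(continuity_report(m, connectivity = 4)$n_components, 10L)
})

test_that("diameter recovery across the physiological range, with rotation", {
  for (d in c(125, 200, 250)) {
    sim <- simulate_vessel_projection(d, field_px = c(192, 256),
                                      pixel_size_um = 2)
    prof <- estimate_axis_and_diameter(sim$image, pixel_size_um = 2)
    expect_equal(prof$diameter_um, d, tolerance = 2 / d)
    expect_equal(prof$axis_angle_deg, 0, tolerance = 0.01)
    expect_true(prof$diameter_um >= min(prof$profile_um) &&
                  prof$diameter_um <= max(prof$profile_um))
  }
  # monotone in the phantom diameter
  ds <- vapply(c(100, 150, 200, 250, 300), function(d)
    estimate_axis_and_diameter(
      simulate_vessel_projection(d, field_px = c(192, 256),
                                 pixel_size_um = 2)$image, 2)$diameter_um,
    numeric(1))
  expect_true(all(diff(ds) > 0))
  # 10-degree tilt changes the estimate by < 2%
  tilt <- simulate_vessel_projection(200, axis_angle_deg = 10,
                                     field_px = c(256, 256),
                                     pixel_size_um = 2)
  p10 <- estimate_axis_and_diameter(tilt$image, 2)
  expect_equal(p10$diameter_um, 200, tolerance = 0.02)
  expect_equal(p10$axis_angle_deg, 10, tolerance = 0.1)
})

test_that("diameter estimation fails loudly on bad fields", {
  # wall out of field: vessel larger than the frame rejects at generation,
  # so build a half-visible band by cropping
  sim <- simulate_vessel_projection(250, field_px = c(192, 256),
                                    pixel_size_um = 2)
  cropped <- sim$image[1:70, ]            # bottom wall gone
  expect_error(estimate_axis_and_diameter(cropped, 2), "valid columns")
  expect_error(estimate_axis_and_diameter(matrix(0, 64, 64), 2), "blank")
})

test_that("lumen circle: radius/centre recovery and degenerate frames", {
  sp <- vessel_phantom_spec(pd_true = 0.2, radius_um = 60, noise_sd = 0.02,
                            pixel_size_um = 1, field_px = c(200, 200),
                            center_px = c(90, 110), frames = 3)
  sim <- simulate_dextran_timelapse(sp, seed = 2)
  circ <- locate_lumen_circle(sim$stack)
  expect_equal(circ$radius_um, 60, tolerance = 1 / 60)      # within 1 px
  expect_equal(unname(circ$center_px), c(90, 110), tolerance = 1)
  expect_error(locate_lumen_circle(matrix(0, 64, 64), pixel_size_um = 1),
               "dark|constant")
})
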