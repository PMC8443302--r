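# 3D nucleus detection, classification, and migration scoring.

test_that("well-separated nuclei are all detected with accurate centroids", {
  sim <- small_cells(n_endo = 0, n_adh = 4, n_ext = 6, noise_sd = 0)
  det <- detect_nuclei(sim$stack)
  expect_equal(nrow(det), 10L)
  m <- match_detections(det, sim$truth, radius_um = 5)
  expect_equal(nrow(m$matched), 10L)
  expect_equal(length(m$spurious), 0L)
  expect_true(all(m$matched$dist_um < 1))
})

test_that("touching nuclei are split into two detections", {
  # two monocyte-sized spheres, centres 7 um apart (surfaces touching)
  spec <- cell_phantom_spec(radius_um = 30, n_endothelial = 0,
                            n_adhered = 0, n_extravasated = 0,
                            n_x = 48, n_y = 84, noise_sd = 0)
  sim <- simulate_cell_stack(spec, seed = 1)
  arr <- sim$stack$data
  # render manually: drop two spheres into the blank stack
  blob <- function(arr, ctr, d = 7) {
    dm <- dim(arr)
    zs <- seq_len(dm[1]) * 2; ys <- seq_len(dm[2]) * 2
    xs <- seq_len(dm[3]) * 2
    g <- expand.grid(z = zs, y = ys, x = xs)
    m <- sqrt((g$z - ctr[3])^2 + (g$y - ctr[2])^2 + (g$x - ctr[1])^2) /
      (d / 2)
    pmax(arr, array(vesselquant:::clamp01((1 - m) * (d / 2) / 1.5 + 0.5),
                    dm))
  }
  arr <- blob(arr, c(48, 80, 80))
  arr <- blob(arr, c(48, 87, 80))       # 7 um away along y
  st <- image_stack(arr, "z", pixel_size_um = 2, step = 2)
  det <- detect_nuclei(st)
  expect_equal(nrow(det), 2L)
  expect_equal(sort(det$y_um), c(80, 87), tolerance = 1.5 / 80)
})

test_that("blank stacks yield zero detections, not an error", {
  blank <- image_stack(array(0, c(10, 20, 20)), "z", 2, 2)
  expect_equal(nrow(detect_nuclei(blank)), 0L)
  noise <- image_stack(array(abs(rnorm(10 * 20 * 20, 0, 0.01)),
                             c(10, 20, 20)), "z", 2, 2)
  expect_equal(nrow(detect_nuclei(noise)), 0L)
})

test_that("cell-type thresholds follow size and roundness", {
  det <- data.frame(diameter_um = c(7, 12, 7, 12),
                    sphericity = c(0.9, 0.6, 0.7, 0.95))
  expect_equal(classify_cell_type(det),
               c("monocyte", "endothelial", "endothelial", "endothelial"))
  # phantom mixture: >= 95% agreement with truth
  sim <- small_cells(n_endo = 12, n_adh = 3, n_ext = 5, noise_sd = 0.02,
                     seed = 4)
  det2 <- detect_nuclei(sim$stack)
  det2$cell_type <- classify_cell_type(det2)
  m <- match_detections(det2, sim$truth, radius_um = 5)
  tm <- sim$truth[match(m$matched$truth_id, sim$truth$id), ]
  dm <- det2[m$matched$detection, ]
  agree <- mean((tm$class == "monocyte") == (dm$cell_type == "monocyte"))
  expect_gte(agree, 0.95)
})

test_that("position classes split on radial excess with the wall tolerance", {
  vessel <- list(radius_um = 40, axis_y_um = 100, axis_z_um = 100)
  det <- data.frame(x_um = c(10, 10, 10),
                    y_um = 100 + c(40, 60, 10),
                    z_um = c(100, 100, 100))
  pos <- classify_position(det, vessel)
  expect_equal(pos$position_class,
               c("luminal_adherent", "extravasated", "luminal_free"))
  expect_equal(pos$radial_excess_um, c(0, 20, -30))
  expect_error(classify_position(data.frame(x_um = -5, y_um = 1, z_um = 1),
                                 vessel, bounds_um = c(100, 100, 100)),
               "outside stack bounds")
})

test_that("classify_position is equivariant under axial translation", {
  vessel <- list(radius_um = 40, axis_y_um = 100, axis_z_um = 100)
  det <- data.frame(x_um = runif(20, 0, 50), y_um = runif(20, 40, 160),
                    z_um = runif(20, 40, 160))
  p1 <- classify_position(det, vessel)
  det2 <- det; det2$x_um <- det$x_um + 37.5   # slide along the axis
  p2 <- classify_position(det2, vessel)
  expect_identical(p1, p2)
})

test_that("summaries count monocytes only; empty input gives zeros", {
  cells <- data.frame(
    cell_type = c("monocyte", "monocyte", "monocyte", "endothelial"),
    position_class = c("luminal_adherent", "extravasated", "extravasated",
                       "extravasated"),
    radial_excess_um = c(0, 18, 22, 30))
  s <- summarize_vessel(cells)
  expect_equal(s$n_adhered, 1L)
  expect_equal(s$n_extravasated, 2L)
  expect_equal(s$mean_distance_um, 20)
  empty <- summarize_vessel(data.frame(cell_type = character(),
                                       position_class = character(),
                                       radial_excess_um = numeric()))
  expect_equal(empty$n_adhered, 0L)
  expect_equal(empty$n_extravasated, 0L)
  expect_length(empty$distances_um, 0L)
})

test_that("noise-free end-to-end counts are exact (6 adhered, 3 extravasated)", {
  sim <- small_cells(n_endo = 10, n_adh = 6, n_ext = 3, noise_sd = 0,
                     seed = 7)
  s <- score_extravasation(sim$stack, vessel_of(sim$truth))
  expect_equal(s$n_adhered, 6L)
  expect_equal(s$n_extravasated, 3L)
})

test_that("distances honour z anisotropy (1 um vs 3 um z-step)", {
  # migration distances must not depend on voxel anisotropy as long as the
  # z-step metadata is honoured. Measured on every detection's radial
  # excess: nuclei spanning only ~2 slices at a 3-um step lose shape
  # (sphericity) fidelity, but their positions — hence distances — do not.
  mk <- function(zstep) {
    spec <- cell_phantom_spec(radius_um = 30, n_endothelial = 0,
                              n_adhered = 0, n_extravasated = 8,
                              migration_mean_um = 15, migration_sd_um = 3,
                              n_x = 48, n_y = 84, z_step_um = zstep,
                              noise_sd = 0)
    sim <- simulate_cell_stack(spec, seed = 5)
    det <- detect_nuclei(sim$stack)
    pos <- classify_position(det, vessel_of(sim$truth))
    c(mean(pos$radial_excess_um), mean(sim$truth$radial_excess_um),
      nrow(det))
  }
  a <- mk(1); b <- mk(3)
  expect_equal(a[3], 8)                 # every nucleus found at both steps
  expect_equal(b[3], 8)
  expect_equal(a[1], a[2], tolerance = 0.05)
  expect_equal(b[1], b[2], tolerance = 0.05)
})

test_that("count recovery across a small grid: off by at most 1 per class", {
  ok <- 0L; n <- 0L
  for (seed in 1:3) for (cnt in c(0, 5, 12)) {
    sim <- small_cells(n_endo = 8, n_adh = cnt, n_ext = max(0, 10 - cnt),
                       noise_sd = 0.02, seed = seed)
    v <- attr(sim$truth, "vessel")
    s <- score_extravasation(sim$stack, vessel_of(sim$truth))
    n <- n + 1L
    if (abs(s$n_adhered - v$n_adhered) <= 1 &&
        abs(s$n_extravasated - v$n_extravasated) <= 1)
      ok <- ok + 1L
  }
  expect_gte(ok / n, 0.9)
})
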