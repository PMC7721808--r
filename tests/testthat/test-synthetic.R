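# Synthetic scene generator and the GLIM interference forward model.

test_that("empty scene has zero phase and all-false masks", {
  sc <- generate_scene(noiseless_params(size = 64, n_cells = 0))
  expect_true(all(sc$phase_truth == 0))
  expect_false(any(sc$cell_mask))
  expect_false(any(sc$nucleus_mask))
  expect_equal(nrow(sc$cells), 0)
})

test_that("scene generation is deterministic in the seed", {
  p <- noiseless_params(size = 96, n_cells = 5, seed = 11)
  expect_identical(generate_scene(p), generate_scene(p))
  p2 <- p; p2$seed <- 12L
  expect_false(identical(generate_scene(p)$cell_mask,
                         generate_scene(p2)$cell_mask))
})

test_that("rasterised disk area matches the analytic pixel-count oracle", {
  for (r in c(5.5, 9, 14.2)) {
    m <- pics:::ellipse_mask(c(64, 64), 32, 32, r, r, 0)
    # oracle: brute-force test of each pixel centre against the disk
    inside <- outer(1:64, 1:64,
                    function(i, j) (i - 32)^2 + (j - 32)^2 <= r^2)
    expect_identical(m, inside)
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("scene invariants hold across seeds", {
  for (seed in 1:4) {
    sc <- fixture_scene(96, 6, seed)
    expect_true(all(sc$phase_truth >= 0))
    expect_true(all(sc$cell_mask[sc$nucleus_mask]))          # nucleus in cell
    expect_true(all(sc$fluor_dapi >= 0), all(sc$fluor_dil >= 0))
    # DAPI is supported on the nucleus mask up to the optical blur
    expect_true(all(sc$fluor_dapi[sc$nucleus_mask] > 0))
    far_from_nuclei <- pics:::gaussian_blur(sc$nucleus_mask + 0, 2) < 1e-8
    expect_lt(max(sc$fluor_dapi[far_from_nuclei]), 1e-6)
  }
})

test_that("doubling the number of cells roughly doubles covered area when sparse", {
  a1 <- mean(generate_scene(noiseless_params(256, 4, seed = 7))$cell_mask)
  a2 <- mean(generate_scene(noiseless_params(256, 8, seed = 7))$cell_mask)
  expect_gt(a2 / a1, 1.5)
  expect_lt(a2 / a1, 2.5)
})

test_that("interference frames follow the closed-form four-phase model", {
  # flat phase difference 0: I_n = 2 + 2 cos(n pi/2) = 4, 2, 0, 2
  sc0 <- list(phase_truth = matrix(0, 64, 64))
  p <- noiseless_params(64, 0); p$shear_px <- 2
  fs <- simulate_glim_frames(sc0, p, beam_intensity = c(1, 1), noiseless = TRUE)
  for (k in 1:4) {
    expect_equal(fs$frames[[k]], matrix(c(4, 2, 0, 2)[k], 64, 64),
                 tolerance = 1e-12)
  }
  expect_equal(fs$modulation_phases, c(0, pi / 2, pi, 3 * pi / 2))
})

test_that("simulated fluorescence reduces to scaled masks without blur or noise", {
  sc <- fixture_scene(96, 6, 2)
  fl <- simulate_fluorescence(list(nucleus = sc$nucleus_mask,
                                   cell = sc$cell_mask))
  expect_equal(fl$dapi, sc$nucleus_mask + 0)
  expect_equal(fl$dil, sc$cell_mask + 0)
  # nucleus mask empty -> DAPI channel is pure background
  fl0 <- simulate_fluorescence(list(nucleus = sc$nucleus_mask & FALSE,
                                    cell = sc$cell_mask), background = 0.1)
  expect_true(all(fl0$dapi == 0.1))
})

test_that("Poisson shot noise has variance close to the mean on a flat field", {
  flat <- matrix(TRUE, 128, 128)
  withr::with_seed(42, {
    fl <- simulate_fluorescence(list(nucleus = flat, cell = flat),
                                noise_model = list(gaussian_sd = 0,
                                                   poisson_scale = 50),
                                gain = 2)
    counts <- fl$dapi * 50  # photon counts, mean 100
    expect_lt(abs(mean(counts) - 100) / 100, 0.02)
    expect_lt(abs(stats::var(as.vector(counts)) - mean(counts)) /
                mean(counts), 0.05)
  })
})

test_that("oversized cells are rejected at parameter construction", {
  expect_error(scene_params(field_size_px = c(64, 64), pixel_size_um = 0.3,
                            cell_radius_um = c(30, 0)),
               "radius")
  expect_error(scene_params(nucleus_fraction = 1.2))
})

test_that("time-lapse scales dry mass exponentially with fixed geometry", {
  tl <- generate_timelapse(noiseless_params(64, 3, seed = 9),
                           times_h = c(0, 12, 24), doubling_time_h = 24,
                           n_fov = 2)
  expect_length(tl, 2)
  for (fov in tl) {
    s0 <- sum(fov$phase_t[[1]])
    expect_equal(sum(fov$phase_t[[2]]) / s0, sqrt(2), tolerance = 1e-10)
    expect_equal(sum(fov$phase_t[[3]]) / s0, 2, tolerance = 1e-10)
  }
  # distinct FOVs get distinct geometry
  expect_false(identical(tl[[1]]$scene$cell_mask, tl[[2]]$scene$cell_mask))
})
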