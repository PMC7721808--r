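# Compartment masks, dry mass, confluence, counting and growth curves.

test_that("empty predicted channels give empty masks and zero confluence", {
  z <- matrix(0, 32, 32)
  m <- segment(z, z)
  expect_false(any(m$nucleus) || any(m$cell) || any(m$cytoplasm))
  expect_identical(confluence(m$cell), 0)
})

test_that("segmenting clean ground-truth channels recovers the true masks", {
  for (seed in c(2, 5)) {
    sc <- fixture_scene(128, 6, seed)
    m <- segment(pmin(sc$fluor_dapi, 1), pmin(sc$fluor_dil, 1))
    expect_jaccard_ge(m$nucleus, sc$nucleus_mask, 0.95)
    expect_jaccard_ge(m$cell, sc$cell_mask, 0.95)
    expect_identical(m$cytoplasm, m$cell & !m$nucleus)
    expect_true(all(m$cell[m$nucleus]))
  }
})

test_that("a nucleus blob outside the cell body is clipped away", {
  dapi <- matrix(0, 64, 64); dil <- matrix(0, 64, 64)
  dil[10:30, 10:30] <- 1
  dapi[15:25, 15:25] <- 1   # inside
  dapi[45:55, 45:55] <- 1   # stray blob outside any cell
  m <- segment(dapi, dil, thresholds = list(dapi = 0.5, dil = 0.5))
  expect_true(all(m$cell[m$nucleus]))
  expect_false(any(m$nucleus[45:55, 45:55]))
  raw_nucleus <- dapi > 0.5
  expect_lt(sum(m$nucleus & raw_nucleus) / sum(m$nucleus | raw_nucleus), 1)
})

test_that("dry mass matches the closed form and is additive and linear", {
  # 100 px of uniform phase 1 rad, pixel area 0.25 um^2, lambda 0.55 um,
  # gamma 0.2 ml/g: m = 0.55/(2*pi*0.2) * 100 * 0.25 = 10.9419... pg
  phi <- matrix(0, 20, 20); mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE; phi[mask] <- 1
  cfg <- dry_mass_config(wavelength_um = 0.55,
                         refractive_increment_ml_per_g = 0.2,
                         pixel_size_um = 0.5)
  expect_equal(dry_mass(phi, mask, cfg), 0.55 / (2 * pi * 0.2) * 25,
               tolerance = 1e-12)
  expect_identical(dry_mass(phi, mask & FALSE, cfg), 0)
  expect_equal(dry_mass(3 * phi, mask, cfg), 3 * dry_mass(phi, mask, cfg))
  # additivity over the nucleus/cytoplasm partition of a real scene
  sc <- fixture_scene(96, 5, 3)
  m <- segment(pmin(sc$fluor_dapi, 1), pmin(sc$fluor_dil, 1))
  expect_equal(dry_mass(sc$phase_truth, m$cell, cfg),
               dry_mass(sc$phase_truth, m$nucleus, cfg) +
                 dry_mass(sc$phase_truth, m$cytoplasm, cfg),
               tolerance = 1e-10)
  expect_error(dry_mass_config(wavelength_um = -1))
})

test_that("confluence is the occupied-pixel fraction", {
  expect_identical(confluence(matrix(TRUE, 5, 5)), 1)
  expect_identical(confluence(matrix(FALSE, 5, 5)), 0)
  withr::with_seed(20, m <- matrix(stats::runif(400) < 0.3, 20, 20))
  expect_identical(confluence(m), sum(m) / 400)
})

test_that("cell counting finds disjoint nuclei and merges touching ones", {
  expect_identical(count_cells(matrix(FALSE, 16, 16)), 0L)
  sc <- fixture_scene(256, 6, 8)
  k_true <- max(EBImage::bwlabel(EBImage::Image(sc$nucleus_mask + 0)))
  expect_identical(count_cells(sc$nucleus_mask), as.integer(k_true))
  two <- matrix(FALSE, 32, 32)
  two[5:12, 5:12] <- TRUE; two[12:19, 12:19] <- TRUE  # touching at a corner
  expect_identical(count_cells(two), 1L)
})

test_that("mask mass discrepancy matches brute-force ratios", {
  phi <- matrix(1, 20, 20)
  a <- matrix(FALSE, 20, 20); a[1:10, ] <- TRUE
  expect_identical(mask_mass_discrepancy(phi, a, a), 0)
  half <- a; half[1:5, ] <- FALSE      # half the pixels of a
  expect_equal(mask_mass_discrepancy(phi, half, a), 50)
  withr::with_seed(21, {
    ra <- matrix(stats::runif(400) < 0.4, 20, 20)
    rb <- matrix(stats::runif(400) < 0.4, 20, 20)
    phi2 <- matrix(stats::runif(400), 20, 20)
  })
  cfg <- dry_mass_config()
  brute <- abs(sum(phi2[ra]) - sum(phi2[rb])) / sum(phi2[rb]) * 100
  expect_equal(mask_mass_discrepancy(phi2, ra, rb, cfg), brute)
  expect_error(mask_mass_discrepancy(phi, a & FALSE, a & FALSE), "zero")
})

test_that("growth normalization uses the first-six-hour baseline", {
  t <- seq(0, 48, by = 2)
  rec <- do.call(rbind, lapply(t, function(tt) {
    data.frame(time_h = tt, fov_id = 1L, total_mass_pg = 100 * 2^(tt / 20))
  }))
  g <- growth_curves(rec, baseline_h = 6)
  base <- mean(100 * 2^(c(0, 2, 4, 6) / 20))
  expect_equal(g$per_fov$normalized, rec$total_mass_pg / base)
  expect_equal(unname(g$doubling_time_h), 20, tolerance = 0.01)
})

test_that("flat series has undefined (infinite) doubling time", {
  rec <- data.frame(time_h = 0:10, fov_id = 1L, total_mass_pg = 50)
  g <- growth_curves(rec)
  expect_true(all(g$per_fov$normalized == 1))
  expect_identical(unname(g$doubling_time_h), Inf)
})

test_that("median curve is the pointwise median across FOVs", {
  t <- 0:5
  c1 <- 1 + 0.1 * t
  rec <- rbind(data.frame(time_h = t, fov_id = 1L, total_mass_pg = c1),
               data.frame(time_h = t, fov_id = 2L, total_mass_pg = 3 - c1))
  g <- growth_curves(rec, baseline_h = 0)
  m1 <- c1 / c1[1]; m2 <- (3 - c1) / (3 - c1[1])
  expect_equal(g$median_curve$normalized,
               apply(rbind(m1, m2), 2, stats::median))
})

test_that("zero-baseline FOVs are dropped with a warning", {
  rec <- rbind(data.frame(time_h = 0:3, fov_id = 1L, total_mass_pg = 0),
               data.frame(time_h = 0:3, fov_id = 2L,
                          total_mass_pg = 2^(0:3)))
  expect_warning(g <- growth_curves(rec), "non-positive")
  expect_identical(unique(g$per_fov$fov_id), 2L)
})

test_that("mass records satisfy their accounting identities", {
  sc <- fixture_scene(128, 6, 2)
  masks <- segment(pmin(sc$fluor_dapi, 1), pmin(sc$fluor_dil, 1))
  cfg <- dry_mass_config(pixel_size_um = sc$params$pixel_size_um)
  rec <- mass_record(sc$phase_truth, masks, cfg, time_h = 3, fov_id = 7L)
  expect_equal(rec$total_mass_pg, rec$nuclear_mass_pg + rec$cyto_mass_pg)
  expect_gte(rec$confluence, 0); expect_lte(rec$confluence, 1)
  expect_equal(rec$confluence, mean(masks$cell))
  expect_equal(rec$ncr, rec$nuclear_mass_pg / rec$cyto_mass_pg)
  expect_equal(rec$cell_area_um2,
               sum(masks$cell) * sc$params$pixel_size_um^2)
})
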