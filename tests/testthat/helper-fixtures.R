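# Shared fixtures, generated in code. Scenes are memoised per test run so
# several test files can reuse the same simulated data cheaply.

.fixture_env <- new.env()

noiseless_params <- function(size = 128, n_cells = 6, seed = 3, ...) {
  scene_params(field_size_px = c(size, size), n_cells = n_cells, seed = seed,
               noise_model = list(gaussian_sd = 0, poisson_scale = 0), ...)
}

fixture_scene <- function(size = 128, n_cells = 6, seed = 3) {
  key <- paste("scene", size, n_cells, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_scene(noiseless_params(size, n_cells, seed))
  }
  .fixture_env[[key]]
}

# Reconstructed-phase / fluorescence training pairs for the virtual-staining
# benchmark: n scenes at 128 x 128, DAPI-like target, rebased phase input.
fixture_staining_pairs <- function(n = 24, size = 128, seed0 = 100) {
  key <- paste("pairs", n, size, seed0, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    phase <- vector("list", n); dapi <- vector("list", n)
    for (i in seq_len(n)) {
      p <- scene_params(field_size_px = c(size, size), n_cells = 8,
                        seed = seed0 + i)
      sc <- generate_scene(p)
      fs <- simulate_glim_frames(sc, p)
      pm <- rebase_phase(integrate_gradient(reconstruct_gradient(fs)))
      phase[[i]] <- pm$phi
      dapi[[i]] <- sc$fluor_dapi
    }
    n_train <- max(1, n - 4)
    rng_x <- compute_range(phase[seq_len(n_train)])
    rng_y <- compute_range(dapi[seq_len(n_train)])
    .fixture_env[[key]] <- list(
      pairs = lapply(seq_len(n), function(i) {
        list(x = normalize_image(phase[[i]], rng_x),
             y = normalize_image(dapi[[i]], rng_y))
      }),
      n_train = n_train)
  }
  .fixture_env[[key]]
}

expect_jaccard_ge <- function(a, b, lower) {
  j <- sum(a & b) / sum(a | b)
  expect_gte(j, lower)
  invisible(j)
}
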