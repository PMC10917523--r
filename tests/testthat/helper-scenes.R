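# Small scene factories used across tests. Sizes are kept at desk scale:
# a handful of cells on a field matched to ~15-20% area fill, so quantile
# seeding of the random walker behaves as in full-size scenes.

tiny_spec <- function(n_cells = 8, seed = 1, ...) {
  scene_spec(image_shape = c(6L, 128L, 128L), n_cells = n_cells,
             seed = seed, ...)
}

noiseless_spec <- function(n_cells = 8, seed = 1, ...) {
  tiny_spec(n_cells = n_cells, seed = seed, poisson_scale = 0,
            read_noise_sd = 0, ...)
}

# a one-cell rectangular label map for unit tests of per-cell statistics
rect_label_map <- function(ny = 20, nx = 20, y = 5:15, x = 5:15) {
  labels <- matrix(0L, ny, nx)
  labels[y, x] <- 1L
  cell_label_map(labels)
}
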