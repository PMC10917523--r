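test_that("identical spec and seed give bit-identical scenes", {
  s1 <- generate_scene(tiny_spec(n_cells = 5, seed = 7))
  s2 <- generate_scene(tiny_spec(n_cells = 5, seed = 7))
  expect_identical(s1, s2)
  s3 <- generate_scene(tiny_spec(n_cells = 5, seed = 8))
  expect_false(identical(s1$gfp_stack$voxels, s3$gfp_stack$voxels))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_scene(tiny_spec(n_cells = 3)))
  expect_identical(runif(1), before)
})

test_that("noiseless render reproduces designed compartment means", {
  sc <- generate_scene(noiseless_spec(n_cells = 6, seed = 2,
                                      reporter_mito_enrichment = 3,
                                      background_level = 0))
  gfp <- sum_project(sc$gfp_stack)$pixels
  mito <- sc$mito_truth > 0
  cytosol <- sc$cell_truth$labels > 0 & !mito
  ratio <- mean(gfp[mito]) / mean(gfp[cytosol])
  expect_equal(ratio, 3, tolerance = 0.01)
  # designed absolute levels, exact up to float accumulation
  expect_equal(mean(gfp[mito]), 300, tolerance = 1e-9)
  expect_equal(mean(gfp[cytosol]), 100, tolerance = 1e-9)
})

test_that("enrichment 1 with zero noise renders cells uniformly", {
  sc <- generate_scene(noiseless_spec(n_cells = 5, seed = 4,
                                      reporter_mito_enrichment = 1))
  gfp <- sum_project(sc$gfp_stack)$pixels
  inside <- gfp[sc$cell_truth$labels > 0]
  expect_lt(diff(range(inside)), 1e-9)
})

test_that("compartment truth masks lie inside their owning cells", {
  for (type in c("spgfp", "nc", "aggregate")) {
    sc <- generate_scene(tiny_spec(n_cells = 6, seed = 5, scene_type = type,
                                   aggregate_fraction_true = 0.5,
                                   nc_ratio_true = 2))
    lab <- sc$cell_truth$labels
    for (mask in list(sc$mito_truth, sc$nuclear_truth, sc$puncta_truth)) {
      on <- mask > 0
      expect_true(all(lab[on] == mask[on]))
    }
    expect_equal(nrow(sc$true_values), 6)
  }
})

test_that("cell placement failure raises a clear error", {
  expect_error(
    generate_scene(scene_spec(image_shape = c(4L, 64L, 64L), n_cells = 60,
                              seed = 1)),
    "placement")
})

test_that("scene spec validation rejects out-of-range parameters", {
  expect_error(tiny_spec(n_cells = 0), "count")
  expect_error(tiny_spec(mito_fraction = 1.2), "\\[0, 1\\]")
  expect_error(tiny_spec(reporter_mito_enrichment = -1), "non-negative")
  expect_error(scene_spec(image_shape = c(0, 10, 10)), "positive")
})

test_that("scenes round-trip through write_scene", {
  sc <- generate_scene(tiny_spec(n_cells = 4, seed = 9))
  dir <- file.path(tempdir(), "scene_rt")
  write_scene(sc, dir)
  gfp <- read_stack(file.path(dir, "gfp.tif"))
  expect_identical(dim(gfp$voxels), dim(sc$gfp_stack$voxels))
  expect_equal(gfp$voxels, round(sc$gfp_stack$voxels))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$cell_id, sc$true_values$cell_id)
  spec <- jsonlite::read_json(file.path(dir, "scene_spec.json"),
                              simplifyVector = TRUE)
  expect_equal(spec$seed, sc$spec$seed)
})

test_that("chase: zero decay and zero noise give flat curves", {
  tab <- generate_chase(chase_spec(n_cells = 4, decay_rate_per_min = 0,
                                   initial_mean = 700, background_mean = 50,
                                   cell_cv = 0, measurement_cv = 0))
  live <- tab[!tab$is_background, ]
  expect_true(all(live$intensity == 750))
  expect_true(all(tab$intensity[tab$is_background] == 50))
})

test_that("chase: half-life 20 min halves intensity at t = 20 exactly", {
  tab <- generate_chase(chase_spec(n_cells = 3,
                                   timepoints_min = c(0, 10, 20),
                                   decay_rate_per_min = log(2) / 20,
                                   background_mean = 0, cell_cv = 0,
                                   measurement_cv = 0))
  i0 <- tab$intensity[!tab$is_background & tab$time_min == 0]
  i20 <- tab$intensity[!tab$is_background & tab$time_min == 20]
  expect_equal(i20, i0 / 2, tolerance = 1e-12)
})

test_that("chase sample mean tracks the closed form within 2% at n = 5000", {
  k <- 0.05
  spec <- chase_spec(n_cells = 5000, decay_rate_per_min = k, cell_cv = 0.2,
                     initial_mean = 1000, background_mean = 50, seed = 1)
  tab <- generate_chase(spec)
  for (t in spec$timepoints_min) {
    got <- mean(tab$intensity[!tab$is_background & tab$time_min == t])
    want <- 50 + 1000 * exp(-k * t)
    expect_lt(abs(got / want - 1), 0.02)
  }
})

test_that("chase tables are deterministic and carry one background row per cell", {
  s <- chase_spec(n_cells = 10, seed = 3)
  expect_identical(generate_chase(s), generate_chase(s))
  tab <- generate_chase(s)
  expect_equal(sum(tab$is_background), 10)
  expect_true(all(is.na(tab$time_min[tab$is_background])))
})
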