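test_that("vector Otsu threshold classifies like the EBImage image oracle", {
  # Otsu's criterion is flat across an empty intensity gap, so the threshold
  # value is convention-dependent; the induced classification is not.
  set.seed(31)
  for (i in 1:5) {
    img <- matrix(c(runif(300, 0, 0.3), runif(100, 0.6, 1)), 20, 20)
    got <- otsu_threshold(as.vector(img))
    want <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
    expect_identical(img > got, img > want)
    # both separate the designed classes
    expect_gte(got, 0.3); expect_lte(got, 0.6)
  }
})

test_that("nuclear mask recovers the designed nucleus on noiseless scenes", {
  sc <- generate_scene(noiseless_spec(n_cells = 5, seed = 41,
                                      scene_type = "nc", nc_ratio_true = 2))
  seg <- segment_scene(sc$gfp_stack, sc$marker_stack)
  m <- match_labels(seg$labels, sc$cell_truth)
  m <- m[!is.na(m$pred_id), ]
  ious <- vapply(seq_len(nrow(m)), function(i) {
    nuc <- nuclear_mask(m$pred_id[i], seg$labels, seg$marker_proj)
    truth <- sc$nuclear_truth == m$true_id[i]
    sum(nuc & truth) / sum(nuc | truth)
  }, 1.0)
  expect_gte(min(ious), 0.9)
})

test_that("uniform RFP across the cell excludes it (no distinct nucleus)", {
  lab <- rect_label_map()
  rfp <- matrix(0, 20, 20); rfp[5:15, 5:15] <- 33
  nuc <- nuclear_mask(1L, lab, projection2d(rfp))
  expect_false(any(nuc))
  expect_match(attr(nuc, "reason"), "uniform")
})

test_that("the larger of two bright components is selected as the nucleus", {
  lab <- rect_label_map()
  rfp <- matrix(1, 20, 20)
  rfp[6:9, 6:9] <- 100    # 16 px blob
  rfp[12:13, 12:13] <- 100  # 4 px blob
  nuc <- nuclear_mask(1L, lab, projection2d(rfp))
  expect_true(all(nuc[6:9, 6:9]))
  expect_false(any(nuc[12:13, 12:13]))
})

test_that("cytoplasmic annulus matches the analytic disk difference", {
  cellpx <- matrix(TRUE, 41, 41)
  nuc <- matrix(FALSE, 41, 41)
  nuc[(row(nuc) - 21)^2 + (col(nuc) - 21)^2 <= 9] <- TRUE
  ann <- cytoplasm_mask(nuc, cellpx, dilation_radius_px = 4L)
  expect_false(any(ann & nuc))
  # analytic area pi*((3+4)^2 - 3^2) ~ 125.7, up to discretization
  expect_gt(sum(ann), 100)
  expect_lt(sum(ann), 155)
  # every annulus pixel lies within the dilation reach of the nucleus
  d <- sqrt((row(ann) - 21)^2 + (col(ann) - 21)^2)
  expect_true(all(d[ann] <= 3 + 4 + 1.5))
})

test_that("zero dilation gives an empty cytoplasm and an exclusion", {
  cellpx <- matrix(TRUE, 15, 15)
  nuc <- matrix(FALSE, 15, 15); nuc[7:9, 7:9] <- TRUE
  ann <- cytoplasm_mask(nuc, cellpx, dilation_radius_px = 0L)
  expect_false(any(ann))
  row <- nc_ratio_cell(1L, projection2d(matrix(1, 15, 15)), nuc, ann)
  expect_true(row$excluded)
  expect_match(row$reason, "annulus")
})

test_that("N/C ratio arithmetic: uniform reporter gives 1, 10/5 gives 2", {
  gfp <- matrix(7, 12, 12)
  nuc <- matrix(FALSE, 12, 12); nuc[5:7, 5:7] <- TRUE
  cyt <- matrix(FALSE, 12, 12); cyt[3, 3:8] <- TRUE
  expect_equal(nc_ratio_cell(1L, projection2d(gfp), nuc, cyt)$ratio, 1)
  gfp[nuc] <- 10; gfp[cyt] <- 5
  r <- nc_ratio_cell(1L, projection2d(gfp), nuc, cyt)
  expect_equal(r$ratio, 2)
  expect_equal(r$nuclear_mean, 10)
  expect_equal(r$cytoplasmic_mean, 5)
})

test_that("ratios are invariant to uniform intensity rescaling", {
  set.seed(55)
  gfp <- matrix(runif(144, 1, 10), 12, 12)
  nuc <- matrix(FALSE, 12, 12); nuc[5:7, 5:7] <- TRUE
  cyt <- matrix(FALSE, 12, 12); cyt[9:10, 4:9] <- TRUE
  r1 <- nc_ratio_cell(1L, projection2d(gfp), nuc, cyt)$ratio
  r2 <- nc_ratio_cell(1L, projection2d(gfp * 3.7), nuc, cyt)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("overlapping masks are rejected", {
  gfp <- projection2d(matrix(1, 8, 8))
  nuc <- matrix(FALSE, 8, 8); nuc[3:5, 3:5] <- TRUE
  expect_error(nc_ratio_cell(1L, gfp, nuc, nuc), "overlap")
})

test_that("the N/C pipeline recovers a designed ratio of 2.5", {
  sc <- generate_scene(scene_spec(image_shape = c(12L, 160L, 160L),
                                  n_cells = 12, scene_type = "nc",
                                  nc_ratio_true = 2.5, seed = 61))
  res <- measure_nc_ratio(sc$gfp_stack, sc$marker_stack)
  inc <- res$cells[!res$cells$excluded, ]
  expect_gte(nrow(inc), 9)
  expect_lt(abs(mean(inc$ratio) / 2.5 - 1), 0.10)
})

test_that("recovered ratio is monotone in the designed ratio", {
  rec <- vapply(c(1, 1.5, 2, 3), function(rt) {
    sc <- generate_scene(tiny_spec(n_cells = 6, seed = 71, scene_type = "nc",
                                   nc_ratio_true = rt))
    res <- measure_nc_ratio(sc$gfp_stack, sc$marker_stack)
    mean(res$cells$ratio[!res$cells$excluded])
  }, 1.0)
  expect_true(all(diff(rec) > 0))
})
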