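test_that("mito mask applies the 5%-of-maximum rule within the cell", {
  lab <- rect_label_map()
  marker <- matrix(0, 20, 20)
  marker[5:15, 5:15] <- 5
  marker[8, 8] <- 200          # per-cell max
  marker[10, 10:12] <- 50
  m <- mito_mask(1L, lab, projection2d(marker), threshold_frac = 0.05)
  # threshold = 0.05 * 200 = 10: the 5-valued cytosol is excluded
  expect_equal(attr(m, "threshold_value"), 10)
  expect_true(m[8, 8] && all(m[10, 10:12]))
  expect_false(any(m & marker < 10))
  # uniform positive marker: every cell pixel reaches the maximum
  u <- matrix(0, 20, 20); u[5:15, 5:15] <- 42
  mu <- mito_mask(1L, lab, projection2d(u))
  expect_identical(mu[5:15, 5:15], matrix(TRUE, 11, 11))
})

test_that("mito mask equals a brute-force pixel scan on random cells", {
  set.seed(101)
  for (i in 1:100) {
    lab <- rect_label_map(16, 16, 3:12, 4:13)
    marker <- matrix(runif(256, 0, 300), 16, 16)
    frac <- runif(1, 0.02, 0.5)
    m <- mito_mask(1L, lab, projection2d(marker), threshold_frac = frac)
    oracle <- matrix(FALSE, 16, 16)
    mx <- -Inf
    for (y in 3:12) for (x in 4:13) mx <- max(mx, marker[y, x])
    for (y in 3:12) for (x in 4:13) {
      oracle[y, x] <- marker[y, x] >= frac * mx
    }
    expect_identical(unname(which(m)), which(oracle))
  }
})

test_that("a cell with no marker signal is excluded, not zeroed", {
  lab <- rect_label_map()
  m <- mito_mask(1L, lab, projection2d(matrix(0, 20, 20)))
  expect_false(any(m))
  expect_equal(attr(m, "reason"), "no mitochondrial signal")
  row <- spgfp_per_cell(1L, lab, projection2d(matrix(5, 20, 20)), m)
  expect_true(row$excluded)
  expect_true(is.na(row$spgfp_median))
})

test_that("raising the threshold never grows the mito mask", {
  set.seed(5)
  lab <- rect_label_map()
  marker <- matrix(runif(400, 0, 100), 20, 20)
  areas <- vapply(c(0.05, 0.2, 0.5, 0.8), function(f) {
    sum(mito_mask(1L, lab, projection2d(marker), f))
  }, 1.0)
  expect_true(all(diff(areas) <= 0))
})

test_that("per-cell spGFP is the median GFP over the mito mask", {
  lab <- rect_label_map(8, 8, 2:4, 2:4)
  gfp <- matrix(0, 8, 8)
  gfp[2, 2:4] <- c(1, 2, 3)
  mito <- matrix(FALSE, 8, 8); mito[2, 2:4] <- TRUE
  expect_equal(spgfp_per_cell(1L, lab, projection2d(gfp), mito)$spgfp_median,
               2)
  # even count: mean of the two central order statistics
  mito[3, 2] <- TRUE; gfp[3, 2] <- 10
  expect_equal(spgfp_per_cell(1L, lab, projection2d(gfp), mito)$spgfp_median,
               (2 + 3) / 2)
})

test_that("spGFP depends only on pixels inside the cell's mito mask", {
  set.seed(9)
  lab <- rect_label_map()
  gfp <- matrix(runif(400, 0, 50), 20, 20)
  mito <- matrix(FALSE, 20, 20); mito[6:9, 6:9] <- TRUE
  base <- spgfp_per_cell(1L, lab, projection2d(gfp), mito)$spgfp_median
  gfp2 <- gfp
  gfp2[!mito] <- gfp2[!mito] + runif(sum(!mito), 0, 1000)
  expect_equal(spgfp_per_cell(1L, lab, projection2d(gfp2), mito)$spgfp_median,
               base)
  # shift equivariance inside the mask
  gfp3 <- gfp; gfp3[mito] <- gfp3[mito] + 13.5
  expect_equal(spgfp_per_cell(1L, lab, projection2d(gfp3), mito)$spgfp_median,
               base + 13.5)
})

test_that("spGFP medians equal a sort-and-pick oracle on random cells", {
  set.seed(202)
  lab <- rect_label_map()
  for (i in 1:100) {
    gfp <- matrix(runif(400, 0, 1000), 20, 20)
    mito <- matrix(FALSE, 20, 20)
    npx <- sample(1:50, 1)
    cellpx <- which(lab$labels == 1L)
    mito[sample(cellpx, npx)] <- TRUE
    got <- spgfp_per_cell(1L, lab, projection2d(gfp), mito)$spgfp_median
    v <- sort(gfp[mito])
    n <- length(v)
    want <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_identical(got, want)
  }
})

test_that("group summaries work on replicate means with SEM over replicates", {
  df <- data.frame(
    spgfp_median = c(10, 20, 30, 20, 30, 40),
    group = rep(c("a", "b"), each = 3),
    replicate = rep(1:3, 2))
  s <- summarize_groups(df)
  expect_equal(s$summary$grand_mean, c(20, 30))
  expect_equal(s$summary$n_replicates, c(3, 3))
  expect_equal(s$summary$sem, rep(sd(c(10, 20, 30)) / sqrt(3), 2))
  expect_equal(s$summary$relative, c(1, 1.5))
})

test_that("two identical groups give t = 0 and p = 1", {
  df <- data.frame(spgfp_median = rep(c(1, 2, 3), 2),
                   group = rep(c("a", "b"), each = 3),
                   replicate = rep(1:3, 2))
  s <- summarize_groups(df)
  expect_equal(s$tests$t, 0)
  expect_equal(s$tests$p, 1)
})

test_that("unpaired test matches the hand-computed Welch formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  df <- data.frame(spgfp_median = c(a, b),
                   group = rep(c("a", "b"), each = 3),
                   replicate = rep(1:3, 2))
  s <- summarize_groups(df, reference = "b")
  # textbook Welch: t = (ma - mb) / sqrt(va/na + vb/nb)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  dfw <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), dfw)
  expect_equal(s$tests$t, t_hand, tolerance = 1e-12)
  expect_equal(s$tests$df, dfw, tolerance = 1e-12)
  expect_equal(s$tests$p, p_hand, tolerance = 1e-12)
})

test_that("paired tests require matching replicate ids", {
  df <- data.frame(spgfp_median = 1:6,
                   group = rep(c("a", "b"), each = 3),
                   replicate = c(1, 2, 3, 4, 5, 6))
  expect_error(summarize_groups(df, test = "paired"), "do not match")
  df$replicate <- rep(1:3, 2)
  s <- summarize_groups(df, test = "paired")
  expect_equal(s$tests$p, 0)  # constant difference of 3, zero variance
})

test_that("excluded cells never enter replicate means", {
  df <- data.frame(spgfp_median = c(10, 10, 999, 20, 20, 999),
                   group = rep(c("a", "b"), each = 3),
                   replicate = 1,
                   excluded = rep(c(FALSE, FALSE, TRUE), 2))
  s <- summarize_groups(df)
  expect_equal(s$summary$grand_mean, c(10, 20))
})

test_that("the full spGFP pipeline recovers designed enrichment per cell", {
  sc <- generate_scene(tiny_spec(n_cells = 8, seed = 21,
                                 reporter_mito_enrichment = 2))
  res <- measure_spgfp(sc$gfp_stack, sc$marker_stack)
  inc <- res$cells[!res$cells$excluded, ]
  expect_gte(nrow(inc), 6)
  # background-subtracted medians near cytosol * enrichment = 200
  expect_lt(abs(median(inc$spgfp_median) / 200 - 1), 0.15)
})

test_that("recovered group mean is monotone in designed enrichment", {
  means <- vapply(c(1, 2, 3), function(e) {
    sc <- generate_scene(tiny_spec(n_cells = 6, seed = 33,
                                   reporter_mito_enrichment = e))
    res <- measure_spgfp(sc$gfp_stack, sc$marker_stack)
    mean(res$cells$spgfp_median[!res$cells$excluded])
  }, 1.0)
  expect_true(all(diff(means) > 0))
})
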