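test_that("curve building subtracts background then normalizes to t0", {
  cu <- build_curve(c(110, 60, 35), c(0, 10, 20), background = 10)
  expect_equal(cu$relative, c(1, 0.5, 0.25))
  cu2 <- build_curve(c(5, 5, 5, 5), c(0, 5, 10, 15), background = 0)
  expect_equal(cu2$relative, rep(1, 4))
})

test_that("t0 at or below background is a normalization error", {
  expect_error(build_curve(c(10, 5), c(0, 10), background = 10),
               "indistinguishable")
  expect_warning(cu <- build_curve(c(100, 5), c(0, 10), background = 20),
                 "clipped")
  expect_equal(cu$relative, c(1, 0))
})

test_that("curves are invariant to rescaling raw and background together", {
  raw <- c(200, 150, 90, 60)
  cu1 <- build_curve(raw, c(0, 10, 20, 30), background = 40)
  cu2 <- build_curve(raw * 3.2, c(0, 10, 20, 30), background = 40 * 3.2)
  expect_equal(cu1$relative, cu2$relative, tolerance = 1e-12)
})

test_that("relative intensity at t0 is exactly 1 for generated panels", {
  ch <- run_chase_experiment(rates = c(a = 0.05, b = 0.01), n_replicates = 2,
                             n_cells = 100, seed = 3)
  for (cu in ch$curves) expect_identical(cu$relative[1], 1)
})

test_that("decay fitting is exact on geometric series and flat curves", {
  f <- fit_decay(build_curve(c(1, 0.5, 0.25), c(0, 20, 40)))
  expect_equal(f$rate_per_min, log(2) / 20, tolerance = 1e-15)
  expect_equal(f$half_life_min, 20, tolerance = 1e-12)
  flat <- fit_decay(build_curve(c(3, 3, 3), c(0, 10, 20)))
  expect_equal(flat$rate_per_min, 0)
  expect_equal(flat$half_life_min, Inf)
})

test_that("noiseless synthetic chase recovers k to machine precision", {
  k <- 0.05
  tab <- generate_chase(chase_spec(n_cells = 20, decay_rate_per_min = k,
                                   cell_cv = 0, measurement_cv = 0))
  f <- fit_decay(chase_curves(tab)[[1]])
  expect_equal(f$rate_per_min, k, tolerance = 1e-13)
})

test_that("noisy chase recovers k within 10%", {
  for (cv in c(0.1, 0.2)) {
    tab <- generate_chase(chase_spec(n_cells = 2000,
                                     decay_rate_per_min = 0.05,
                                     cell_cv = cv, seed = 17))
    f <- fit_decay(chase_curves(tab)[[1]])
    expect_lt(abs(f$rate_per_min / 0.05 - 1), 0.10)
  }
})

test_that("fits require at least three usable points", {
  expect_error(fit_decay(build_curve(c(1, 0.5), c(0, 10))), ">= 3")
  suppressWarnings(
    cu <- build_curve(c(10, 0.5, 0.1), c(0, 10, 20), background = 5))
  # relative hits 0 at two points after clipping
  expect_error(fit_decay(cu), ">= 3")
})

test_that("identical groups compare with p = 1 at every time point", {
  mk <- function(g, r) build_curve(c(100, 60, 40), c(0, 10, 20),
                                   replicate = r, group = g)
  curves <- list(mk("a", 1), mk("a", 2), mk("b", 1), mk("b", 2))
  out <- compare_timepoints(curves)
  expect_equal(out$p, rep(1, 3))
})

test_that("per-timepoint t-statistics match the hand-computed formula", {
  mk <- function(g, r, v) build_curve(c(1, v), c(0, 10), replicate = r,
                                      group = g)
  curves <- list(mk("a", 1, 0.80), mk("a", 2, 0.78),
                 mk("b", 1, 0.42), mk("b", 2, 0.40))
  out <- compare_timepoints(curves)
  a <- c(0.80, 0.78); b <- c(0.42, 0.40)
  se <- sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(out$t[2], (mean(a) - mean(b)) / se, tolerance = 1e-12)
  expect_lt(out$p[2], 0.05)
})

test_that("group separation appears at late time points, not at t0", {
  ch <- run_chase_experiment(rates = c(slow = 0.02, fast = 0.06),
                             n_replicates = 4, n_cells = 1000, seed = 5,
                             cell_cv = 0.1, measurement_cv = 0.02)
  expect_equal(ch$tests$p[ch$tests$time_min == 0], 1)
  late <- ch$tests$p[ch$tests$time_min >= 20]
  expect_true(all(late < 0.05))
})

test_that("mismatched time grids raise an alignment error", {
  c1 <- build_curve(c(1, 0.5), c(0, 10), group = "a", replicate = 1)
  c2 <- build_curve(c(1, 0.5), c(0, 20), group = "b", replicate = 1)
  expect_error(compare_timepoints(list(c1, c1, c2, c2)), "alignment")
})

test_that("densitometry tables normalize to the loading control per lane", {
  tab <- data.frame(time_min = c(NA, 0, 20, 40),
                    intensity = c(20, 220, 120, 70),
                    loading_control = c(2, 2, 1, 1),
                    is_background = c(TRUE, FALSE, FALSE, FALSE))
  cu <- chase_curves(tab)[[1]]
  # normalized: bg 10, raw {110, 120, 70} -> relative {1, 1.1, 0.6}
  expect_equal(cu$relative, c(1, 1.1, 0.6), tolerance = 1e-12)
  raw <- chase_curves(tab, normalize_loading = FALSE)[[1]]
  expect_equal(raw$relative, c(1, 0.5, 0.25))
  tab$loading_control[2] <- 0
  expect_error(chase_curves(tab), "positive")
})
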