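#' Build a chase curve from raw mean intensities
#'
#' The pre-induction background is subtracted from the mean intensity at every
#' time point (negative differences clipped to 0 with a warning), and the
#' curve is normalized to the first time point, so `relative[t0] = 1` exactly.
#'
#' @param raw_means mean intensity per time point.
#' @param timepoints_min strictly increasing times (minutes).
#' @param background pre-induction background intensity.
#' @param replicate,group optional identifiers carried in the object.
#' @return object of class `chase_curve`: `timepoints_min`, `raw_means`,
#'   `background`, `relative`, `replicate`, `group`.
#' @export
#' @examples
#' build_curve(c(110, 60, 35), c(0, 10, 20), background = 10)$relative
build_curve <- function(raw_means, timepoints_min, background = 0,
                        replicate = NA, group = NA) {
  if (length(raw_means) != length(timepoints_min)) {
    stopf("raw_means and timepoints_min differ in length")
  }
  if (any(diff(timepoints_min) <= 0)) {
    stopf("timepoints_min must be strictly increasing")
  }
  if (raw_means[1] <= background) {
    stopf("normalization error: t0 signal (%.4g) %s background (%.4g)",
          raw_means[1], "is indistinguishable from", background)
  }
  sub <- raw_means - background
  if (any(sub < 0)) {
    warnf("%d background-subtracted value(s) below 0 clipped", sum(sub < 0))
    sub[sub < 0] <- 0
  }
  structure(list(timepoints_min = as.numeric(timepoints_min),
                 raw_means = as.numeric(raw_means),
                 background = background, relative = sub / sub[1],
                 replicate = replicate, group = group),
            class = "chase_curve")
}

#' @export
print.chase_curve <- function(x, ...) {
  cat(sprintf("<chase_curve> %s/%s: t = %s min, relative = %s\n",
              x$group, x$replicate,
              paste(x$timepoints_min, collapse = ","),
              paste(signif(x$relative, 3), collapse = ",")))
  invisible(x)
}

#' Chase curves from a long-format table
#'
#' For each (group, replicate), the background is the mean intensity of the
#' pre-induction rows (`is_background = TRUE`) and the raw curve the mean
#' intensity over rows at each time point. The same reader serves per-cell
#' flow-cytometry tables (thousands of rows per time point) and immunoblot
#' densitometry tables (one band intensity per lane); for the latter, a
#' `loading_control` column, when present and `normalize_loading = TRUE`,
#' divides each band by its lane's loading-control band first.
#'
#' @param df `data.frame` with columns `time_min`, `intensity`,
#'   `is_background`, and optionally `group`, `replicate`,
#'   `loading_control`.
#' @param normalize_loading divide `intensity` by `loading_control` when
#'   that column is present (default `TRUE`).
#' @return list of [build_curve] objects, one per (group, replicate).
#' @export
chase_curves <- function(df, normalize_loading = TRUE) {
  df <- as.data.frame(df)
  for (col in c("time_min", "intensity", "is_background")) {
    if (!col %in% names(df)) stopf("missing column '%s'", col)
  }
  if (normalize_loading && "loading_control" %in% names(df)) {
    if (any(df$loading_control <= 0)) {
      stopf("loading_control values must be positive")
    }
    df$intensity <- df$intensity / df$loading_control
  }
  if (!"group" %in% names(df)) df$group <- "all"
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  keys <- unique(df[c("group", "replicate")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$group == keys$group[i] & df$replicate == keys$replicate[i], ]
    bg <- mean(sub$intensity[sub$is_background])
    if (!is.finite(bg)) bg <- 0
    tp <- sort(unique(sub$time_min[!sub$is_background]))
    raw <- vapply(tp, function(t) {
      mean(sub$intensity[!sub$is_background & sub$time_min == t])
    }, 1.0)
    build_curve(raw, tp, background = bg,
                replicate = keys$replicate[i], group = keys$group[i])
  })
}

#' Fit a first-order decay rate to a chase curve
#'
#' Origin-constrained least squares of `log(relative) = -k t` over time
#' points with positive relative intensity; `k` is clipped at 0.
#'
#' @param curve a [build_curve] object.
#' @return object of class `decay_fit`: `rate_per_min`, `half_life_min`
#'   (`Inf` when the rate is 0), `rss` (residual sum of squares on the log
#'   scale), `n_points`.
#' @export
#' @examples
#' fit_decay(build_curve(c(1, 0.5, 0.25), c(0, 20, 40)))$half_life_min
fit_decay <- function(curve) {
  stopifnot(inherits(curve, "chase_curve"))
  usable <- curve$relative > 0
  if (length(curve$timepoints_min) < 3 || sum(usable) < 3) {
    stopf("fit_decay needs >= 3 time points with positive relative intensity")
  }
  t <- curve$timepoints_min[usable]
  lr <- log(curve$relative[usable])
  k <- if (sum(t^2) > 0) -sum(t * lr) / sum(t^2) else 0
  k <- max(0, k)
  structure(list(rate_per_min = k,
                 half_life_min = if (k > 0) log(2) / k else Inf,
                 rss = sum((lr + k * t)^2), n_points = sum(usable)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g /min (half-life %.3g min, rss %.3g, n = %d)\n",
              x$rate_per_min, x$half_life_min, x$rss, x$n_points))
  invisible(x)
}

#' Per-timepoint group comparison of chase curves
#'
#' One unpaired two-tailed t-test per time point on replicate-level relative
#' intensities; no multiplicity correction (per-timepoint reporting).
#'
#' @param curves list of [build_curve] objects carrying `group` and
#'   `replicate`; exactly two groups, identical time grids.
#' @param var_equal Student's pooled form instead of Welch.
#' @return `data.frame`: `time_min`, `mean_<groupA>`, `mean_<groupB>`, `t`,
#'   `df`, `p`.
#' @export
compare_timepoints <- function(curves, var_equal = FALSE) {
  stopifnot(is.list(curves), length(curves) >= 2)
  groups <- unique(vapply(curves, function(cu) as.character(cu$group), ""))
  if (length(groups) != 2) stopf("need exactly 2 groups; got %d",
                                 length(groups))
  grids <- lapply(curves, function(cu) cu$timepoints_min)
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1) {
    stopf("alignment error: curves have mismatched time grids")
  }
  tp <- grids[[1]]
  ga <- curves[vapply(curves, function(cu) cu$group == groups[1], TRUE)]
  gb <- curves[vapply(curves, function(cu) cu$group == groups[2], TRUE)]
  if (length(ga) < 2 || length(gb) < 2) {
    stopf("need >= 2 replicates per group")
  }
  out <- do.call(rbind, lapply(seq_along(tp), function(i) {
    va <- vapply(ga, function(cu) cu$relative[i], 1.0)
    vb <- vapply(gb, function(cu) cu$relative[i], 1.0)
    tt <- safe_t_test(va, vb, var.equal = var_equal)
    data.frame(time_min = tp[i], mean_a = mean(va), mean_b = mean(vb),
               t = tt$t, df = tt$df, p = tt$p)
  }))
  names(out)[2:3] <- paste0("mean_", groups)
  out
}
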