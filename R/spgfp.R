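#' Estimate scene background from non-cell pixels
#'
#' Median projection intensity over pixels outside every cell. Robust to the
#' bright minority of mislabeled pixels; used (by default) to
#' background-subtract per-cell statistics, since additive background biases
#' relative intensities and ratios toward 1.
#'
#' @param proj a [projection2d].
#' @param labels a [cell_label_map].
#' @return scalar background estimate.
#' @export
estimate_background <- function(proj, labels) {
  stopifnot(inherits(proj, "projection2d"), inherits(labels, "cell_label_map"))
  bgpx <- proj$pixels[labels$labels == 0L]
  if (!length(bgpx)) return(0)
  median(bgpx)
}

#' Mitochondrial mask of one cell
#'
#' Pixels of the cell whose marker (mCherry) z-sum intensity is at least
#' `threshold_frac` of the maximal marker value — by default the maximum
#' within that cell, at the canonical 5% fraction.
#'
#' @param cell_id cell id present in `labels`.
#' @param labels a [cell_label_map].
#' @param marker_proj marker-channel [projection2d].
#' @param threshold_frac fraction of the maximal value, in (0, 1); default
#'   0.05.
#' @param per_image_max threshold against the image-wide maximum instead of
#'   the per-cell maximum (off by default).
#' @return logical mask matrix with attribute `threshold_value`; all-`FALSE`
#'   with attribute `reason = "no mitochondrial signal"` when the marker is
#'   non-positive throughout the cell.
#' @export
mito_mask <- function(cell_id, labels, marker_proj, threshold_frac = 0.05,
                      per_image_max = FALSE) {
  stopifnot(inherits(labels, "cell_label_map"),
            inherits(marker_proj, "projection2d"))
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stopf("threshold_frac must be in (0, 1)")
  }
  if (!cell_id %in% labels$cell_ids) stopf("cell_id %s not in label map",
                                           cell_id)
  cellpx <- labels$labels == cell_id
  mx <- if (per_image_max) max(marker_proj$pixels) else
    max(marker_proj$pixels[cellpx])
  if (mx <= 0) {
    mask <- cellpx & FALSE
    attr(mask, "reason") <- "no mitochondrial signal"
    attr(mask, "threshold_value") <- NA_real_
    return(mask)
  }
  thr <- threshold_frac * mx
  mask <- cellpx & (marker_proj$pixels >= thr)
  attr(mask, "threshold_value") <- thr
  mask
}

#' Per-cell split-GFP measurement
#'
#' The central statistic: the median GFP z-sum intensity within the cell's
#' mitochondrial mask. An even pixel count yields the mean of the two central
#' order statistics. An empty mask propagates as an excluded measurement,
#' never a silent zero.
#'
#' @param cell_id cell id.
#' @param labels a [cell_label_map].
#' @param gfp_proj GFP-channel [projection2d].
#' @param mito logical mitochondrial mask from [mito_mask].
#' @param background scalar subtracted from the median (default 0).
#' @return one-row `data.frame`: `cell_id`, `mito_area_px`,
#'   `mito_threshold_value`, `spgfp_median`, `excluded`, `reason`.
#' @export
spgfp_per_cell <- function(cell_id, labels, gfp_proj, mito, background = 0) {
  stopifnot(inherits(labels, "cell_label_map"),
            inherits(gfp_proj, "projection2d"), is.logical(mito))
  thr <- attr(mito, "threshold_value") %||% NA_real_
  if (!any(mito)) {
    return(data.frame(cell_id = cell_id, mito_area_px = 0L,
                      mito_threshold_value = thr, spgfp_median = NA_real_,
                      excluded = TRUE,
                      reason = attr(mito, "reason") %||% "empty mitochondrial mask",
                      stringsAsFactors = FALSE))
  }
  if (any(mito & labels$labels != cell_id)) {
    stopf("mitochondrial mask extends outside cell %s", cell_id)
  }
  data.frame(cell_id = cell_id, mito_area_px = sum(mito),
             mito_threshold_value = thr,
             spgfp_median = median(gfp_proj$pixels[mito]) - background,
             excluded = FALSE, reason = "", stringsAsFactors = FALSE)
}

#' Full spGFP pipeline on a two-channel stack pair
#'
#' z-sum projection, segmentation, per-cell mitochondrial masking and median
#' GFP scoring. Border-touching cells and cells without mitochondrial signal
#' are reported with their exclusion reason rather than dropped.
#'
#' @param gfp_stack,marker_stack [image_stack] objects.
#' @param params a [segmentation_params].
#' @param threshold_frac mitochondrial threshold fraction (default 0.05).
#' @param background_subtract subtract the [estimate_background] scene
#'   background from each median (default `TRUE`).
#' @return list with `cells` (per-cell `data.frame`), `labels`
#'   ([cell_label_map]) and `background`.
#' @export
measure_spgfp <- function(gfp_stack, marker_stack,
                          params = segmentation_params(),
                          threshold_frac = 0.05,
                          background_subtract = TRUE) {
  seg <- segment_scene(gfp_stack, marker_stack, params)
  labels <- seg$labels
  bg <- 0
  marker_proj <- seg$marker_proj
  if (background_subtract) {
    bg <- estimate_background(seg$gfp_proj, labels)
    # the fractional mito threshold must act on marker signal, not on the
    # camera background offset common to every pixel
    marker_bg <- estimate_background(marker_proj, labels)
    marker_proj <- projection2d(marker_proj$pixels - marker_bg,
                                provenance = paste0(marker_proj$provenance,
                                                    ":bg-subtracted"))
  }
  rows <- lapply(labels$cell_ids, function(id) {
    qrow <- labels$qc[labels$qc$cell_id == id, ]
    if (isTRUE(qrow$excluded)) {
      return(data.frame(cell_id = id, mito_area_px = 0L,
                        mito_threshold_value = NA_real_,
                        spgfp_median = NA_real_, excluded = TRUE,
                        reason = qrow$reason, stringsAsFactors = FALSE))
    }
    m <- mito_mask(id, labels, marker_proj, threshold_frac)
    spgfp_per_cell(id, labels, seg$gfp_proj, m, background = bg)
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  list(cells = cells, labels = labels, background = bg)
}

#' Replicate-level group summaries and t-tests
#'
#' Replicate means are means of included cells' values within each biological
#' replicate; the grand mean and SEM are taken over replicate means (n =
#' replicates, not cells), and two-tailed t-tests run on replicate means —
#' paired across matching replicate ids, or unpaired (Welch by default).
#' Relative values divide each group's grand mean by the reference group's.
#'
#' @param measurements `data.frame` with at least the value column plus
#'   `group` and `replicate` columns. Rows with `excluded = TRUE` are
#'   dropped. One row per replicate (already-aggregated input) is allowed.
#' @param value value column name (default `"spgfp_median"`).
#' @param group,replicate grouping column names.
#' @param test `"unpaired"` or `"paired"`.
#' @param var_equal use Student's pooled-variance form for unpaired tests
#'   (default `FALSE` = Welch).
#' @param reference reference group for relative values and as the second
#'   member of each test (default: first group encountered).
#' @return list with `summary` (per-group `data.frame`: `group`,
#'   `n_replicates`, `grand_mean`, `sem`, `relative`) , `replicate_means`,
#'   and `tests` (one row per non-reference group: `t`, `df`, `p`).
#' @export
summarize_groups <- function(measurements, value = "spgfp_median",
                             group = "group", replicate = "replicate",
                             test = c("unpaired", "paired"),
                             var_equal = FALSE, reference = NULL) {
  test <- match.arg(test)
  df <- as.data.frame(measurements)
  for (col in c(value, group, replicate)) {
    if (!col %in% names(df)) stopf("missing column '%s'", col)
  }
  if ("excluded" %in% names(df)) df <- df[!df$excluded, , drop = FALSE]
  df <- df[is.finite(df[[value]]), , drop = FALSE]
  if (!nrow(df)) stopf("no included measurements to summarize")

  rep_means <- aggregate(df[[value]],
                         by = list(group = df[[group]],
                                   replicate = df[[replicate]]),
                         FUN = mean)
  names(rep_means)[3] <- "mean_value"
  groups <- unique(as.character(df[[group]]))
  reference <- reference %||% groups[1]
  if (!reference %in% groups) stopf("reference group '%s' absent", reference)

  summ <- do.call(rbind, lapply(groups, function(gname) {
    v <- rep_means$mean_value[rep_means$group == gname]
    data.frame(group = gname, n_replicates = length(v), grand_mean = mean(v),
               sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ref_mean <- summ$grand_mean[summ$group == reference]
  summ$relative <- summ$grand_mean / ref_mean

  tests <- do.call(rbind, lapply(setdiff(groups, reference), function(gname) {
    a <- rep_means[rep_means$group == gname, ]
    b <- rep_means[rep_means$group == reference, ]
    if (test == "paired") {
      common <- intersect(a$replicate, b$replicate)
      if (length(common) != nrow(a) || length(common) != nrow(b)) {
        stopf("paired test: replicates of '%s' and '%s' do not match",
              gname, reference)
      }
      va <- a$mean_value[match(common, a$replicate)]
      vb <- b$mean_value[match(common, b$replicate)]
      tt <- safe_t_test(va, vb, paired = TRUE)
    } else {
      tt <- safe_t_test(a$mean_value, b$mean_value, var.equal = var_equal)
    }
    data.frame(group = gname, reference = reference, test = test,
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }))
  list(summary = summ, replicate_means = rep_means, tests = tests)
}

# two-tailed t-test that degrades gracefully on zero-variance input:
# identical constant groups give t = 0, p = 1
safe_t_test <- function(a, b, paired = FALSE, var.equal = FALSE) {
  res <- tryCatch({
    tt <- t.test(a, b, paired = paired, var.equal = var.equal)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)
  d <- if (paired) mean(a - b) else mean(a) - mean(b)
  if (isTRUE(all.equal(d, 0)) || d == 0) {
    list(t = 0, df = length(a) + length(b) - 2, p = 1)
  } else {
    list(t = sign(d) * Inf, df = length(a) + length(b) - 2, p = 0)
  }
}
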