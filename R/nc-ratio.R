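#' Nuclear mask of one cell from the RFP marker
#'
#' Within the cell, the RFP z-sum is thresholded at Otsu's value computed per
#' cell, and the largest connected component above threshold is taken as the
#' nucleoplasmic mask.
#'
#' @param cell_id cell id.
#' @param labels a [cell_label_map].
#' @param rfp_proj RFP/marker [projection2d].
#' @param min_nuclear_area_px smallest acceptable nucleus (default 5 px).
#' @return logical mask; all-`FALSE` with attribute `reason` when no distinct
#'   nucleus exists (uniform RFP, or largest component under the minimum
#'   area).
#' @export
nuclear_mask <- function(cell_id, labels, rfp_proj, min_nuclear_area_px = 5L) {
  stopifnot(inherits(labels, "cell_label_map"),
            inherits(rfp_proj, "projection2d"))
  if (!cell_id %in% labels$cell_ids) stopf("cell_id %s not in label map",
                                           cell_id)
  cellpx <- labels$labels == cell_id
  v <- rfp_proj$pixels[cellpx]
  empty <- function(reason) {
    m <- cellpx & FALSE
    attr(m, "reason") <- reason
    m
  }
  if (diff(range(v)) <= .Machine$double.eps * max(abs(v), 1)) {
    return(empty("no distinct nucleus (uniform RFP)"))
  }
  thr <- otsu_threshold(v)
  cand <- cellpx & (rfp_proj$pixels > thr)
  if (!any(cand)) return(empty("no pixels above nuclear threshold"))
  comp <- EBImage::bwlabel(cand)
  areas <- tabulate(comp, max(comp))
  big <- which.max(areas)
  if (areas[big] < min_nuclear_area_px) {
    return(empty(sprintf("nucleus under minimum area (%d px)",
                         min_nuclear_area_px)))
  }
  mask <- as.matrix(comp) == big
  attr(mask, "threshold_value") <- thr
  mask
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance over a 256-bin histogram; returns the
#' threshold on the original intensity scale.
#'
#' @param v numeric vector.
#' @param levels histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (r[2] <= r[1]) return(r[1])
  h <- tabulate(pmin(floor((v - r[1]) / (r[2] - r[1]) * levels) + 1L, levels),
                levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  r[1] + k / levels * (r[2] - r[1])
}

#' Cytoplasmic annulus around the nucleus
#'
#' Cytoplasm is defined by the dilated nuclear mask: the nucleus dilated by a
#' disc of `dilation_radius_px`, clipped to the cell, minus the nucleus — an
#' annulus. (A whole-cell mode, cell minus nucleus, is available in
#' [measure_nc_ratio].)
#'
#' @param nuclear logical nuclear mask.
#' @param cellpx logical mask of the cell's pixels.
#' @param dilation_radius_px disc radius (default 3).
#' @return logical mask, disjoint from `nuclear`; all-`FALSE` with attribute
#'   `reason` when the annulus is empty.
#' @export
cytoplasm_mask <- function(nuclear, cellpx, dilation_radius_px = 3L) {
  stopifnot(is.logical(nuclear), is.logical(cellpx))
  if (!any(nuclear)) stopf("nuclear mask is empty")
  if (dilation_radius_px < 1) {
    m <- nuclear & FALSE
    attr(m, "reason") <- "empty cytoplasmic annulus (dilation radius 0)"
    return(m)
  }
  dil <- EBImage::dilate(nuclear, disc_brush(dilation_radius_px))
  ann <- dil & cellpx & !nuclear
  if (!any(ann)) {
    attr(ann, "reason") <- "empty cytoplasmic annulus (nucleus fills cell)"
  }
  ann
}

#' Nuclear/cytoplasmic ratio of one cell
#'
#' Mean GFP over the nuclear mask divided by mean GFP over the cytoplasmic
#' mask, optionally after subtracting a scene background from both.
#'
#' @param cell_id cell id.
#' @param gfp_proj GFP [projection2d].
#' @param nuclear,cytoplasm logical masks (disjoint).
#' @param background scalar background subtracted from both means.
#' @param dilation_radius_px recorded in the output row.
#' @return one-row `data.frame`: `cell_id`, `nuclear_mean`,
#'   `cytoplasmic_mean`, `ratio`, `dilation_radius_px`, `excluded`, `reason`.
#' @export
nc_ratio_cell <- function(cell_id, gfp_proj, nuclear, cytoplasm,
                          background = 0, dilation_radius_px = NA_integer_) {
  stopifnot(inherits(gfp_proj, "projection2d"))
  row <- data.frame(cell_id = cell_id, nuclear_mean = NA_real_,
                    cytoplasmic_mean = NA_real_, ratio = NA_real_,
                    dilation_radius_px = dilation_radius_px,
                    excluded = TRUE, reason = "", stringsAsFactors = FALSE)
  if (!any(nuclear)) {
    row$reason <- attr(nuclear, "reason") %||% "empty nuclear mask"
    return(row)
  }
  if (!any(cytoplasm)) {
    row$reason <- attr(cytoplasm, "reason") %||% "empty cytoplasmic mask"
    return(row)
  }
  if (any(nuclear & cytoplasm)) stopf("nuclear and cytoplasmic masks overlap")
  nm <- mean(gfp_proj$pixels[nuclear]) - background
  cm <- mean(gfp_proj$pixels[cytoplasm]) - background
  row$nuclear_mean <- nm
  row$cytoplasmic_mean <- cm
  if (cm <= 0) {
    row$reason <- "non-positive cytoplasmic mean"
    return(row)
  }
  row$ratio <- nm / cm
  row$excluded <- FALSE
  row
}

#' Full nucleocytoplasmic-ratio pipeline on a stack pair
#'
#' Segmentation from the combined projections, per-cell Otsu nuclear masking
#' from the RFP channel, cytoplasmic annulus by nuclear dilation, and the
#' mean-over-mean ratio per cell.
#'
#' @param gfp_stack,rfp_stack [image_stack] objects.
#' @param params a [segmentation_params].
#' @param dilation_radius_px annulus dilation radius (default 3).
#' @param background_subtract subtract the scene background estimate from
#'   both means (default `TRUE`).
#' @param whole_cell_cytoplasm use the whole non-nuclear cell instead of the
#'   annulus.
#' @param min_nuclear_area_px passed to [nuclear_mask].
#' @return list with `cells` (per-cell `data.frame`), `labels`, `background`.
#' @export
measure_nc_ratio <- function(gfp_stack, rfp_stack,
                             params = segmentation_params(),
                             dilation_radius_px = 3L,
                             background_subtract = TRUE,
                             whole_cell_cytoplasm = FALSE,
                             min_nuclear_area_px = 5L) {
  seg <- segment_scene(gfp_stack, rfp_stack, params)
  labels <- seg$labels
  bg <- if (background_subtract) {
    estimate_background(seg$gfp_proj, labels)
  } else 0
  rows <- lapply(labels$cell_ids, function(id) {
    qrow <- labels$qc[labels$qc$cell_id == id, ]
    if (isTRUE(qrow$excluded)) {
      r <- nc_ratio_cell(id, seg$gfp_proj,
                         matrix(FALSE, 1, 1), matrix(FALSE, 1, 1),
                         dilation_radius_px = dilation_radius_px)
      r$reason <- qrow$reason
      return(r)
    }
    cellpx <- labels$labels == id
    nuc <- nuclear_mask(id, labels, seg$marker_proj, min_nuclear_area_px)
    cyt <- if (!any(nuc)) {
      nuc
    } else if (whole_cell_cytoplasm) {
      cellpx & !nuc
    } else {
      cytoplasm_mask(nuc, cellpx, dilation_radius_px)
    }
    nc_ratio_cell(id, seg$gfp_proj, nuc, cyt, background = bg,
                  dilation_radius_px = dilation_radius_px)
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  list(cells = cells, labels = labels, background = bg)
}
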