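#' Segmentation parameters
#'
#' Parameters of the two-stage segmentation: random-walker separation of
#' background from foreground on the summed projection, then marker-based
#' watershed separation of adjoining cells on the distance transform.
#'
#' @param bg_seed_quantile intensity quantile at or below which pixels seed
#'   the background class (default 0.20).
#' @param fg_seed_quantile intensity quantile at or above which pixels seed
#'   the foreground class (default 0.90). Quantile seeding makes the
#'   foreground mask invariant to multiplying the image by any k > 0.
#' @param rw_beta random-walker edge-weight sharpness (> 0, default 130,
#'   applied to the min-max-normalized image).
#' @param min_cell_area_px components smaller than this are removed.
#' @param smoothing_sigma_px Gaussian pre-smoothing of the projection (0
#'   disables).
#' @param min_marker_separation_px minimum distance between watershed
#'   markers; defaults to the expected cell radius.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(bg_seed_quantile = 0.20,
                                fg_seed_quantile = 0.90,
                                rw_beta = 130,
                                min_cell_area_px = 80L,
                                smoothing_sigma_px = 1,
                                min_marker_separation_px = 9L) {
  if (!is_prob(bg_seed_quantile) || !is_prob(fg_seed_quantile) ||
      bg_seed_quantile >= fg_seed_quantile) {
    stopf("need 0 <= bg_seed_quantile < fg_seed_quantile <= 1")
  }
  if (rw_beta <= 0) stopf("rw_beta must be > 0")
  if (smoothing_sigma_px < 0) stopf("smoothing_sigma_px must be >= 0")
  structure(list(bg_seed_quantile = bg_seed_quantile,
                 fg_seed_quantile = fg_seed_quantile, rw_beta = rw_beta,
                 min_cell_area_px = as.integer(min_cell_area_px),
                 smoothing_sigma_px = smoothing_sigma_px,
                 min_marker_separation_px = as.integer(min_marker_separation_px)),
            class = "segmentation_params")
}

#' Construct a cell label map
#'
#' @param labels 2D integer matrix; 0 = background, 1..n = cells.
#' @param qc per-cell QC `data.frame` with columns `cell_id`, `area_px`,
#'   `border`, `excluded`, `reason`.
#' @return an object of class `cell_label_map`.
#' @export
cell_label_map <- function(labels, qc = NULL) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  storage.mode(labels) <- "integer"
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (is.null(qc)) {
    qc <- data.frame(cell_id = ids,
                     area_px = if (length(ids)) {
                       tabulate(labels, max(ids))[ids]
                     } else integer(0),
                     border = logical(length(ids)),
                     excluded = logical(length(ids)),
                     reason = character(length(ids)),
                     stringsAsFactors = FALSE)
  }
  structure(list(labels = labels, cell_ids = ids, qc = qc),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d cells on %d x %d px (%d excluded by QC)\n",
              length(x$cell_ids), nrow(x$labels), ncol(x$labels),
              sum(x$qc$excluded)))
  invisible(x)
}

#' Included (QC-passing) cell ids of a label map
#' @param labels a [cell_label_map].
#' @return integer vector of cell ids not excluded by QC.
#' @export
included_cells <- function(labels) {
  stopifnot(inherits(labels, "cell_label_map"))
  labels$qc$cell_id[!labels$qc$excluded]
}

#' Random-walker probability map
#'
#' Grady-style random-walker segmentation on the 4-neighbor pixel graph:
#' edge weights `exp(-beta * (g_i - g_j)^2)` on the min-max-normalized image,
#' seeded pixels fixed at probability 0/1, unseeded probabilities obtained by
#' solving the combinatorial Dirichlet problem (sparse SPD solve).
#'
#' @param img numeric matrix (any scale; normalized internally).
#' @param fg_seeds,bg_seeds logical matrices marking seed pixels.
#' @param beta edge-weight sharpness.
#' @return matrix of foreground probabilities in `[0, 1]`.
#' @export
random_walker <- function(img, fg_seeds, bg_seeds, beta = 130) {
  stopifnot(is.matrix(img), identical(dim(img), dim(fg_seeds)),
            identical(dim(img), dim(bg_seeds)))
  ny <- nrow(img); nx <- ncol(img); n <- ny * nx
  g <- minmax(img)
  idx <- matrix(seq_len(n), ny, nx)
  e1 <- c(as.vector(idx[, -nx]), as.vector(idx[-ny, ]))
  e2 <- c(as.vector(idx[, -1]),  as.vector(idx[-1, ]))
  w <- exp(-beta * (g[e1] - g[e2])^2) + 1e-10
  W <- Matrix::sparseMatrix(i = c(e1, e2), j = c(e2, e1), x = c(w, w),
                            dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W

  prob <- matrix(NA_real_, ny, nx)
  prob[bg_seeds] <- 0
  prob[fg_seeds] <- 1
  prob[fg_seeds & bg_seeds] <- 1   # fg wins a contradictory seed
  seeded <- !is.na(prob)
  if (all(seeded)) return(prob)
  uns <- which(!seeded)
  sv <- prob[seeded]
  b <- -L[uns, which(seeded), drop = FALSE] %*% sv
  x <- Matrix::solve(Matrix::forceSymmetric(L[uns, uns]), b)
  prob[uns] <- pmin(pmax(as.numeric(x), 0), 1)
  prob
}

#' Separate foreground (cells) from background
#'
#' Optionally Gaussian-smooths the projection, seeds pixels at or below the
#' `bg_seed_quantile` of intensity as background and at or above the
#' `fg_seed_quantile` as foreground, assigns all remaining pixels by the
#' random-walker solver, and fills holes in the resulting mask.
#'
#' @param proj a [projection2d] (typically [combine_projections] of the
#'   marker and reporter z-sums).
#' @param params a [segmentation_params].
#' @return logical foreground mask covering every pixel decision; all-`FALSE`
#'   (with a message) when no foreground seeds exist.
#' @export
segment_foreground <- function(proj, params = segmentation_params()) {
  stopifnot(inherits(proj, "projection2d"),
            inherits(params, "segmentation_params"))
  img <- proj$pixels
  if (diff(range(img)) == 0) {
    stopf("degenerate input: projection is constant, seed quantiles collapse")
  }
  if (params$smoothing_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = params$smoothing_sigma_px)
  }
  g <- minmax(img)
  qb <- quantile(g, params$bg_seed_quantile, names = FALSE)
  qf <- quantile(g, params$fg_seed_quantile, names = FALSE)
  if (qf <= qb) {
    stopf("degenerate input: seed quantiles collapse (q_bg = q_fg = %g)", qb)
  }
  bg <- g <= qb
  fg <- g >= qf
  if (!any(fg)) {
    message("segment_foreground: no foreground seeds; no cells detected")
    return(matrix(FALSE, nrow(g), ncol(g)))
  }
  prob <- random_walker(g, fg, bg, beta = params$rw_beta)
  mask <- prob >= 0.5
  as.matrix(EBImage::fillHull(mask)) > 0
}

#' Split a foreground mask into individual cells
#'
#' Markers are local maxima of the (lightly smoothed) Euclidean distance
#' transform, greedily suppressed within `min_marker_separation_px` in order
#' of decreasing distance value (ties broken in raster order); the mask is
#' then flooded in decreasing distance order from the markers — watershed on
#' the negative distance transform confined to the mask. Components under
#' `min_cell_area_px` are removed; cells touching the image border are kept
#' in the map but flagged `excluded` for downstream statistics. Labels are
#' dense, 1..n in raster order of cell centroid.
#'
#' @param foreground logical mask from [segment_foreground].
#' @param params a [segmentation_params].
#' @return a [cell_label_map].
#' @export
split_cells <- function(foreground, params = segmentation_params()) {
  stopifnot(is.matrix(foreground), is.logical(foreground))
  ny <- nrow(foreground); nx <- ncol(foreground)
  if (!any(foreground)) {
    message("split_cells: empty foreground mask; zero cells")
    return(cell_label_map(matrix(0L, ny, nx)))
  }
  D <- as.matrix(EBImage::distmap(foreground * 1))
  Ds <- EBImage::gblur(D, sigma = 1)
  Ds[!foreground] <- 0

  # candidate peaks: local maxima of smoothed EDT within the suppression
  # radius, interior to the mask
  r <- max(1L, params$min_marker_separation_px)
  maxf <- EBImage::dilate(Ds, disc_brush(r))
  cand <- which(foreground & D >= 1 & Ds >= maxf - 1e-9)
  if (length(cand) == 0) cand <- which.max(Ds)
  cy <- (cand - 1L) %% ny + 1L
  cx <- (cand - 1L) %/% ny + 1L
  ord <- order(-Ds[cand], cy, cx)
  keep_y <- keep_x <- numeric(0)
  marker_idx <- integer(0)
  for (k in ord) {
    if (length(keep_y) == 0 ||
        all((keep_y - cy[k])^2 + (keep_x - cx[k])^2 >= r^2)) {
      keep_y <- c(keep_y, cy[k]); keep_x <- c(keep_x, cx[k])
      marker_idx <- c(marker_idx, cand[k])
    }
  }

  labels <- matrix(0L, ny, nx)
  labels[marker_idx] <- seq_along(marker_idx)
  labels <- flood_basins(labels, Ds, foreground)

  # size filter
  areas <- tabulate(labels, max(labels))
  small <- which(areas > 0 & areas < params$min_cell_area_px)
  if (length(small)) labels[labels %in% small] <- 0L

  relabel_by_centroid(labels)
}

# ordered flood: assign each masked pixel, in decreasing order of the
# distance transform, the label of its highest-distance labeled 4-neighbor;
# repeated passes resolve pixels reached before their neighbors
flood_basins <- function(labels, D, mask) {
  ny <- nrow(D); nx <- ncol(D)
  todo <- which(mask & labels == 0L)
  if (!length(todo)) return(labels)
  ty <- (todo - 1L) %% ny + 1L
  tx <- (todo - 1L) %/% ny + 1L
  todo <- todo[order(-D[todo], ty, tx)]
  off <- c(-1L, 1L, -ny, ny)   # up, down, left, right in linear index
  for (pass in 1:50) {
    assigned <- FALSE
    remaining <- logical(length(todo))
    for (ii in seq_along(todo)) {
      p <- todo[ii]
      py <- (p - 1L) %% ny + 1L
      best <- 0L; bestd <- -1
      for (o in off) {
        q <- p + o
        if (o == -1L && py == 1L) next
        if (o == 1L && py == ny) next
        if (q < 1L || q > ny * nx) next
        lq <- labels[q]
        if (lq > 0L && D[q] > bestd) { bestd <- D[q]; best <- lq }
      }
      if (best > 0L) { labels[p] <- best; assigned <- TRUE }
      else remaining[ii] <- TRUE
    }
    todo <- todo[remaining]
    if (!length(todo) || !assigned) break
  }
  labels
}

# dense relabeling 1..n in raster order of centroid (y, then x); border
# cells flagged and excluded in the QC table
relabel_by_centroid <- function(labels) {
  ny <- nrow(labels); nx <- ncol(labels)
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids)) return(cell_label_map(labels))
  pix <- which(labels > 0L)
  lv <- labels[pix]
  py <- (pix - 1L) %% ny + 1L
  px <- (pix - 1L) %/% ny + 1L
  cy <- tapply(py, lv, mean)[as.character(ids)]
  cx <- tapply(px, lv, mean)[as.character(ids)]
  ord <- ids[order(round(cy), round(cx), ids)]
  newlab <- integer(max(ids))
  newlab[ord] <- seq_along(ord)
  out <- labels
  out[pix] <- newlab[lv]
  border <- vapply(seq_along(ord), function(i) {
    sel <- lv == ord[i]
    any(py[sel] == 1L | py[sel] == ny | px[sel] == 1L | px[sel] == nx)
  }, TRUE)
  qc <- data.frame(cell_id = seq_along(ord),
                   area_px = tabulate(out[pix], length(ord)),
                   border = border, excluded = border,
                   reason = ifelse(border, "border-touching", ""),
                   stringsAsFactors = FALSE)
  cell_label_map(out, qc = qc)
}

#' Segment a two-channel scene into cells
#'
#' Convenience wrapper: z-sum both stacks, combine them
#' ([combine_projections]), run [segment_foreground] and [split_cells].
#'
#' @param gfp_stack,marker_stack [image_stack] objects.
#' @param params a [segmentation_params].
#' @return list with `labels` ([cell_label_map]), `gfp_proj`, `marker_proj`.
#' @export
segment_scene <- function(gfp_stack, marker_stack,
                          params = segmentation_params()) {
  gfp_proj <- sum_project(gfp_stack)
  marker_proj <- sum_project(marker_stack)
  fg <- segment_foreground(combine_projections(marker_proj, gfp_proj), params)
  list(labels = split_cells(fg, params),
       gfp_proj = gfp_proj, marker_proj = marker_proj)
}

#' Match predicted labels to ground truth by intersection-over-union
#'
#' Greedy one-to-one matching by decreasing overlap.
#'
#' @param pred a [cell_label_map] (or integer matrix).
#' @param truth a [cell_label_map] (or integer matrix).
#' @return `data.frame` with `true_id`, `pred_id` (`NA` if unmatched), `iou`.
#' @export
match_labels <- function(pred, truth) {
  pl <- if (inherits(pred, "cell_label_map")) pred$labels else pred
  tl <- if (inherits(truth, "cell_label_map")) truth$labels else truth
  stopifnot(identical(dim(pl), dim(tl)))
  tp <- which(tl > 0L | pl > 0L)
  key <- paste(tl[tp], pl[tp])
  ov <- table(key)
  parts <- do.call(rbind, strsplit(names(ov), " "))
  inter <- data.frame(true_id = as.integer(parts[, 1]),
                      pred_id = as.integer(parts[, 2]),
                      n = as.integer(ov))
  ta <- tabulate(tl, max(tl, 1L))
  pa <- tabulate(pl, max(pl, 1L))
  inter <- inter[inter$true_id > 0L & inter$pred_id > 0L, , drop = FALSE]
  inter$iou <- inter$n / (ta[inter$true_id] + pa[inter$pred_id] - inter$n)
  inter <- inter[order(-inter$iou, inter$true_id, inter$pred_id), , drop = FALSE]
  used_t <- used_p <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(inter))) {
    if (inter$true_id[i] %in% used_t || inter$pred_id[i] %in% used_p) next
    used_t <- c(used_t, inter$true_id[i])
    used_p <- c(used_p, inter$pred_id[i])
    rows[[length(rows) + 1L]] <- inter[i, c("true_id", "pred_id", "iou")]
  }
  matched <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(true_id = integer(), pred_id = integer(), iou = numeric())
  }
  all_t <- sort(setdiff(unique(as.vector(tl)), 0L))
  un <- setdiff(all_t, matched$true_id)
  if (length(un)) {
    matched <- rbind(matched, data.frame(true_id = un, pred_id = NA_integer_,
                                         iou = 0))
  }
  matched <- matched[order(matched$true_id), , drop = FALSE]
  rownames(matched) <- NULL
  matched
}
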