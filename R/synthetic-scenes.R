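#' Specify a synthetic microscopy scene
#'
#' Defines a two-channel yeast-like field: elliptical non-overlapping cells
#' (optionally one designed touching pair to exercise watershed splitting),
#' tubular mitochondria drawn as dilated random-walk curves, a nuclear disk
#' for nucleocytoplasmic scenes, and bright puncta for aggregate scenes. The
#' reporter (GFP) channel carries a controllable enrichment in the designated
#' compartment; the marker (mCherry/RFP) channel carries the mitochondria or
#' the nucleus. Photon (Poisson) noise and Gaussian read noise follow the
#' standard fluorescence camera model. All intensity levels are in z-sum
#' arbitrary units: only the z-summed image is contractually meaningful, and
#' signal is spread over slices by a mid-stack Gaussian profile whose weights
#' sum to one.
#'
#' @param image_shape integer `(n_z, n_y, n_x)`.
#' @param n_cells number of cells (>= 1).
#' @param cell_radius_px mean cell radius in pixels.
#' @param cell_radius_sd_px spread (SD) of cell radii.
#' @param mito_fraction fraction of cell area covered by mitochondrial
#'   tubules, in `[0, 1]`.
#' @param nuclear_radius_px nuclear disk radius (used by `"nc"` scenes).
#' @param scene_type `"spgfp"` (mitochondrial marker + enrichment), `"nc"`
#'   (nuclear marker + N/C ratio) or `"aggregate"` (mitochondrial marker +
#'   GFP puncta).
#' @param reporter_mito_enrichment ratio of true mean reporter intensity in
#'   mitochondria to the cytosolic mean (>= 0); 1 means no effect.
#' @param nc_ratio_true true nuclear/cytoplasmic reporter ratio (>= 0).
#' @param aggregate_fraction_true fraction of cells carrying >= 1 punctum;
#'   realized as an exact count `round(fraction * n_cells)`.
#' @param cytosol_level true cytosolic reporter level (z-sum a.u.).
#' @param background_level extracellular background (z-sum a.u.).
#' @param marker_level marker intensity in its compartment (z-sum a.u.).
#' @param punctum_level punctum peak amplitude added to the reporter
#'   channel (z-sum a.u.).
#' @param punctum_sigma_px punctum Gaussian radius.
#' @param poisson_scale photons per intensity unit for shot noise; 0 disables
#'   Poisson noise.
#' @param read_noise_sd Gaussian read noise SD (intensity units); 0 disables.
#' @param touching_pair place one designed pair of circular cells sharing a
#'   neck, to exercise watershed splitting.
#' @param seed RNG seed; identical spec + seed gives bit-identical scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(12L, 192L, 192L),
                       n_cells = 20L,
                       cell_radius_px = 9,
                       cell_radius_sd_px = 1,
                       mito_fraction = 0.15,
                       nuclear_radius_px = 3,
                       scene_type = c("spgfp", "nc", "aggregate"),
                       reporter_mito_enrichment = 1,
                       nc_ratio_true = 1,
                       aggregate_fraction_true = 0,
                       cytosol_level = 100,
                       background_level = 20,
                       marker_level = 400,
                       punctum_level = 500,
                       punctum_sigma_px = 1.5,
                       poisson_scale = 1,
                       read_noise_sd = 2,
                       touching_pair = TRUE,
                       seed = 1L) {
  scene_type <- match.arg(scene_type)
  spec <- list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
               cell_radius_px = cell_radius_px, cell_radius_sd_px = cell_radius_sd_px,
               mito_fraction = mito_fraction, nuclear_radius_px = nuclear_radius_px,
               scene_type = scene_type,
               reporter_mito_enrichment = reporter_mito_enrichment,
               nc_ratio_true = nc_ratio_true,
               aggregate_fraction_true = aggregate_fraction_true,
               cytosol_level = cytosol_level, background_level = background_level,
               marker_level = marker_level, punctum_level = punctum_level,
               punctum_sigma_px = punctum_sigma_px,
               poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
               touching_pair = isTRUE(touching_pair), seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  s <- spec
  if (length(s$image_shape) != 3L || any(s$image_shape < 1L)) {
    stopf("image_shape must be three positive counts (n_z, n_y, n_x)")
  }
  if (!is_count(s$n_cells)) stopf("n_cells must be a count >= 1")
  for (f in c("mito_fraction", "aggregate_fraction_true")) {
    if (!is_prob(s[[f]])) stopf("%s must lie in [0, 1]", f)
  }
  for (f in c("reporter_mito_enrichment", "nc_ratio_true", "cytosol_level",
              "background_level", "marker_level", "poisson_scale",
              "read_noise_sd")) {
    if (!(is.numeric(s[[f]]) && length(s[[f]]) == 1 && is.finite(s[[f]]) &&
          s[[f]] >= 0)) stopf("%s must be a single non-negative number", f)
  }
  if (s$cell_radius_px < 3) stopf("cell_radius_px must be >= 3")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %s: %d cells, %dx%dx%d (z,y,x), r=%g px, seed=%d\n",
    x$scene_type, x$n_cells, x$image_shape[1], x$image_shape[2],
    x$image_shape[3], x$cell_radius_px, x$seed))
  invisible(x)
}

# pixel indices (cbind(y, x)) of an ellipse; theta in radians
ellipse_pixels <- function(cy, cx, a, b, theta, ny, nx) {
  ext <- ceiling(max(a, b)) + 1
  ys <- max(1, floor(cy - ext)):min(ny, ceiling(cy + ext))
  xs <- max(1, floor(cx - ext)):min(nx, ceiling(cx + ext))
  if (!length(ys) || !length(xs)) return(cbind(y = integer(), x = integer()))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(y = ys[keep[, 1]], x = xs[keep[, 2]])
}

px_lin <- function(px, ny) px[, 1] + (px[, 2] - 1L) * ny

#' Generate a synthetic scene with ground truth
#'
#' Renders the two channels specified by a [scene_spec] and returns them
#' together with per-pixel truth (cell label map; mitochondrial, nuclear and
#' punctum masks labeled by owning cell) and a per-cell table of true
#' compartment means, so that segmentation and every per-cell statistic can be
#' scored against a known answer.
#'
#' @param spec a [scene_spec].
#' @return an object of class `synthetic_scene` with elements `spec`,
#'   `gfp_stack`, `marker_stack` (both [image_stack]), `cell_truth`
#'   ([cell_label_map]), `mito_truth`, `nuclear_truth`, `puncta_truth`
#'   (integer matrices, 0 = none, otherwise owning cell id) and
#'   `true_values` (one row per cell).
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(n_cells = 4, image_shape = c(6, 96, 96),
#'                                 seed = 2))
#' sc$true_values$area_px
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_local_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  nz <- spec$image_shape[1]; ny <- spec$image_shape[2]; nx <- spec$image_shape[3]
  n <- spec$n_cells
  labels <- matrix(0L, ny, nx)
  geom <- vector("list", n)

  radii <- pmin(pmax(rnorm(n, spec$cell_radius_px, spec$cell_radius_sd_px),
                     0.6 * spec$cell_radius_px), 1.6 * spec$cell_radius_px)
  budget <- 300L * n
  margin <- 3
  place_one <- function(i, a, b, theta) {
    # returns pixel set or NULL on failed draw
    cy <- runif(1, margin + a + 1, ny - margin - a)
    cx <- runif(1, margin + a + 1, nx - margin - a)
    # keep >= ~3.5 px clearance between undesigned neighbors: ground truth
    # stays unambiguous (only the designed pair touches) even after the
    # foreground mask dilates cell outlines by a pixel or two
    halo <- ellipse_pixels(cy, cx, a + 3.5, b + 3.5, theta, ny, nx)
    if (any(labels[halo] != 0L)) return(NULL)
    list(cy = cy, cx = cx, px = ellipse_pixels(cy, cx, a, b, theta, ny, nx))
  }

  i <- 1L
  if (spec$touching_pair && n >= 2L) {
    # a designed pair of circles whose centers sit closer than the sum of
    # radii, producing a neck that watershed must split
    r1 <- radii[1]; r2 <- radii[2]
    repeat {
      budget <- budget - 1L
      if (budget <= 0L) stopf("cell placement failed: retry budget exhausted")
      phi <- runif(1, 0, 2 * pi)
      # barely-overlapping circles: a thin neck with a clear EDT saddle
      # (deeper overlap can merge the union into a single-maximum blob)
      d <- r1 + r2 - 1.5
      cy1 <- runif(1, margin + r1 + d + 1, ny - margin - r1 - d)
      cx1 <- runif(1, margin + r1 + d + 1, nx - margin - r1 - d)
      cy2 <- cy1 + d * sin(phi); cx2 <- cx1 + d * cos(phi)
      p1 <- ellipse_pixels(cy1, cx1, r1, r1, 0, ny, nx)
      p2 <- ellipse_pixels(cy2, cx2, r2, r2, 0, ny, nx)
      # shared pixels go to the nearer center
      l2 <- px_lin(p2, ny)
      shared <- px_lin(p1, ny) %in% l2
      d1 <- (p1[, 1] - cy1)^2 + (p1[, 2] - cx1)^2
      d2 <- (p1[, 1] - cy2)^2 + (p1[, 2] - cx2)^2
      drop1 <- shared & (d2 < d1)
      p2 <- p2[!(l2 %in% px_lin(p1[!drop1, , drop = FALSE], ny)), , drop = FALSE]
      p1 <- p1[!drop1, , drop = FALSE]
      if (nrow(p1) > 10 && nrow(p2) > 10) {
        labels[p1] <- 1L; labels[p2] <- 2L
        geom[[1]] <- list(cy = cy1, cx = cx1, a = r1, b = r1, theta = 0)
        geom[[2]] <- list(cy = cy2, cx = cx2, a = r2, b = r2, theta = 0)
        break
      }
    }
    i <- 3L
  }
  while (i <= n) {
    budget <- budget - 1L
    if (budget <= 0L) {
      stopf(paste0("cell placement failed after retry budget: ",
                   "%d of %d cells placed; reduce n_cells or radius"),
            i - 1L, n)
    }
    elong <- runif(1, 1, 1.25)
    a <- radii[i] * elong; b <- radii[i] / elong
    theta <- runif(1, 0, pi)
    cand <- place_one(i, a, b, theta)
    if (is.null(cand) || nrow(cand$px) < 10) next
    labels[cand$px] <- i
    geom[[i]] <- list(cy = cand$cy, cx = cand$cx, a = a, b = b, theta = theta)
    i <- i + 1L
  }

  mito <- matrix(0L, ny, nx)
  nucl <- matrix(0L, ny, nx)
  punc <- matrix(0L, ny, nx)
  draw_mito <- spec$scene_type %in% c("spgfp", "aggregate")
  draw_nucl <- spec$scene_type == "nc"

  agg_cells <- integer(0)
  if (spec$scene_type == "aggregate" && spec$aggregate_fraction_true > 0) {
    n_pos <- round(spec$aggregate_fraction_true * n)
    agg_cells <- sort(sample.int(n, n_pos))
  }
  n_puncta <- integer(n)
  gfp2d <- matrix(0, ny, nx)
  marker2d <- matrix(0, ny, nx)

  brush3 <- EBImage::makeBrush(3L, "disc")
  for (ci in seq_len(n)) {
    g <- geom[[ci]]
    cellmask <- labels == ci
    area <- sum(cellmask)
    gfp2d[cellmask] <- spec$cytosol_level

    if (draw_mito && spec$mito_fraction > 0) {
      target <- max(9L, round(spec$mito_fraction * area))
      path <- matrix(FALSE, ny, nx)
      pos <- c(g$cy, g$cx)
      th <- runif(1, 0, 2 * pi)
      steps <- 0L; cap <- 6L * area
      chunk <- max(8L, ceiling(target / 2.5))
      mmask <- NULL
      repeat {
        for (s in seq_len(chunk)) {
          th <- th + rnorm(1, 0, 0.6)
          cand <- pos + c(sin(th), cos(th))
          ok <- cand[1] >= 1 && cand[1] <= ny && cand[2] >= 1 &&
            cand[2] <= nx && cellmask[round(cand[1]), round(cand[2])]
          if (!ok) {
            # bounce: restart direction; if stuck, jump to a random cell px
            th <- runif(1, 0, 2 * pi)
            cand <- pos + c(sin(th), cos(th))
            ok <- cand[1] >= 1 && cand[1] <= ny && cand[2] >= 1 &&
              cand[2] <= nx && cellmask[round(cand[1]), round(cand[2])]
            if (!ok) {
              j <- which(cellmask)[sample.int(area, 1)]
              cand <- c((j - 1L) %% ny + 1L, (j - 1L) %/% ny + 1L)
            }
          }
          pos <- cand
          path[round(pos[1]), round(pos[2])] <- TRUE
        }
        steps <- steps + chunk
        mmask <- EBImage::dilate(path, brush3) & cellmask
        if (sum(mmask) >= target || steps >= cap) break
      }
      mito[mmask] <- ci
      gfp2d[mmask] <- spec$cytosol_level * spec$reporter_mito_enrichment
      marker2d[mmask] <- spec$marker_level
    }

    if (draw_nucl && spec$nuclear_radius_px > 0) {
      jmax <- max(0, g$b - spec$nuclear_radius_px - 2)
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, jmax)
      ncy <- g$cy + rad * sin(ang); ncx <- g$cx + rad * cos(ang)
      npx <- ellipse_pixels(ncy, ncx, spec$nuclear_radius_px,
                            spec$nuclear_radius_px, 0, ny, nx)
      keep <- cellmask[npx]
      npx <- npx[keep, , drop = FALSE]
      nucl[npx] <- ci
      gfp2d[npx] <- spec$cytosol_level * spec$nc_ratio_true
      marker2d[npx] <- spec$marker_level
    }

    if (ci %in% agg_cells) {
      k <- sample(1:2, 1)
      inner <- ellipse_pixels(g$cy, g$cx, max(1, g$a - 3), max(1, g$b - 3),
                              g$theta, ny, nx)
      inner <- inner[cellmask[inner], , drop = FALSE]
      if (nrow(inner) == 0) inner <- cbind(y = round(g$cy), x = round(g$cx))
      picks <- inner[sample.int(nrow(inner), min(k, nrow(inner))), ,
                     drop = FALSE]
      n_puncta[ci] <- nrow(picks)
      sig <- spec$punctum_sigma_px
      ext <- ceiling(3 * sig)
      for (p in seq_len(nrow(picks))) {
        py <- picks[p, 1]; px <- picks[p, 2]
        ys <- max(1, py - ext):min(ny, py + ext)
        xs <- max(1, px - ext):min(nx, px + ext)
        dd <- outer((ys - py)^2, rep(1, length(xs))) +
          outer(rep(1, length(ys)), (xs - px)^2)
        gfp2d[ys, xs] <- gfp2d[ys, xs] +
          spec$punctum_level * exp(-dd / (2 * sig^2))
        ppx <- ellipse_pixels(py, px, 2, 2, 0, ny, nx)
        ppx <- ppx[cellmask[ppx], , drop = FALSE]
        punc[ppx] <- ci
      }
    }
  }

  gfp_stack <- render_stack(gfp2d, spec, "GFP")
  marker_stack <- render_stack(marker2d, spec, "marker")

  tv <- scene_true_values(spec, labels, mito, nucl, n_puncta, geom)
  qc <- data.frame(cell_id = seq_len(n), area_px = tabulate(labels, n),
                   border = FALSE, excluded = FALSE, reason = "",
                   stringsAsFactors = FALSE)
  structure(list(spec = spec,
                 gfp_stack = gfp_stack, marker_stack = marker_stack,
                 cell_truth = cell_label_map(labels, qc = qc),
                 mito_truth = mito, nuclear_truth = nucl, puncta_truth = punc,
                 true_values = tv),
            class = "synthetic_scene")
}

# distribute a designed z-sum pattern over slices and apply camera noise
render_stack <- function(signal2d, spec, channel) {
  nz <- spec$image_shape[1]
  zc <- (nz + 1) / 2
  wz <- exp(-((seq_len(nz) - zc)^2) / (2 * (nz / 4)^2))
  wz <- wz / sum(wz)
  arr <- array(outer(wz, as.vector(signal2d)), dim = spec$image_shape)
  arr <- arr + spec$background_level / nz
  if (spec$poisson_scale > 0) {
    arr <- array(rpois(length(arr), arr * spec$poisson_scale) /
                   spec$poisson_scale, dim = dim(arr))
  }
  if (spec$read_noise_sd > 0) {
    arr <- arr + array(rnorm(length(arr), 0, spec$read_noise_sd),
                       dim = dim(arr))
  }
  arr[arr < 0] <- 0
  image_stack(arr, z_step_um = 0.5, pixel_size_um = 0.2, channel_name = channel)
}

scene_true_values <- function(spec, labels, mito, nucl, n_puncta, geom) {
  n <- spec$n_cells
  bg <- spec$background_level
  cyt <- spec$cytosol_level
  data.frame(
    cell_id = seq_len(n),
    cy = vapply(geom, function(g) g$cy, 1.0),
    cx = vapply(geom, function(g) g$cx, 1.0),
    area_px = tabulate(labels, n),
    mito_area_px = tabulate(mito, n),
    nuclear_area_px = tabulate(nucl, n),
    n_puncta = n_puncta,
    has_aggregate = n_puncta > 0,
    true_cytosol = bg + cyt,
    true_mito = if (spec$scene_type %in% c("spgfp", "aggregate")) {
      bg + cyt * spec$reporter_mito_enrichment
    } else NA_real_,
    true_nuclear = if (spec$scene_type == "nc") {
      bg + cyt * spec$nc_ratio_true
    } else NA_real_,
    enrichment_true = spec$reporter_mito_enrichment,
    nc_ratio_true = spec$nc_ratio_true,
    stringsAsFactors = FALSE)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  rendered channels: GFP + marker; %d true cells\n",
              nrow(x$true_values)))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' One multi-page TIFF per channel (rounded to integer ADU), the per-cell
#' ground-truth table as CSV, and the spec as a JSON sidecar.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$gfp_stack, file.path(dir, "gfp.tif"), round = TRUE)
  write_stack(scene$marker_stack, file.path(dir, "marker.tif"), round = TRUE)
  write.csv(scene$true_values, file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- scene$spec; class(sp) <- NULL
  jsonlite::write_json(sp, file.path(dir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
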