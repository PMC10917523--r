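#' Construct an ImageStack
#'
#' A single-channel 3D fluorescence stack. Voxels are stored as a numeric
#' array in `(z, y, x)` order, 0-based pixel semantics with pixel-centered
#' coordinates; intensities are carried as doubles regardless of the on-disk
#' integer type so that downstream sums and medians are exact.
#'
#' @param voxels numeric 3D array `(n_z, n_y, n_x)`, finite and non-negative.
#' @param z_step_um z spacing in micrometers (default 0.5, the standard
#'   yeast 3D imaging step for a 6 um stack of 12 slices).
#' @param pixel_size_um lateral pixel size in micrometers.
#' @param channel_name free-text channel label (e.g. "GFP", "mCherry").
#' @return an object of class `image_stack`.
#' @export
#' @examples
#' st <- image_stack(array(1, dim = c(12, 8, 8)), channel_name = "GFP")
#' dim(st$voxels)
image_stack <- function(voxels, z_step_um = 0.5, pixel_size_um = 0.2,
                        channel_name = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("voxels must be a 3D array (z, y, x); got dims [%s]",
          paste(dim(voxels), collapse = ", "))
  }
  if (any(!is.finite(voxels))) stopf("voxel intensities must be finite")
  if (any(voxels < 0)) stopf("voxel intensities must be >= 0")
  structure(
    list(voxels = voxels * 1.0, z_step_um = z_step_um,
         pixel_size_um = pixel_size_um, channel_name = channel_name),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s: %d z-slices of %d x %d px (z step %g um)\n",
              if (nzchar(x$channel_name)) x$channel_name else "unnamed",
              d[1], d[2], d[3], x$z_step_um))
  invisible(x)
}

#' Sum-project a stack along z
#'
#' The first step of every imaging assay here: intensities are summed along
#' the z axis, with no rescaling or clipping, producing the 2D image that
#' segmentation and all per-cell statistics operate on.
#'
#' @param stack an [image_stack].
#' @return an object of class `projection2d`: list with `pixels` (n_y x n_x
#'   matrix) and `provenance`.
#' @export
#' @examples
#' st <- image_stack(array(1:24, dim = c(2, 3, 4)))
#' sum_project(st)$pixels
sum_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  px <- colSums(stack$voxels)           # sums over z, the first dimension
  projection2d(px, provenance = paste0(stack$channel_name, ":z-sum"))
}

#' @rdname sum_project
#' @param pixels 2D numeric matrix.
#' @param provenance free-text provenance note.
#' @export
projection2d <- function(pixels, provenance = "") {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  structure(list(pixels = pixels * 1.0, provenance = provenance),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("<projection2d> %d x %d px (%s)\n", nrow(x$pixels),
              ncol(x$pixels), x$provenance))
  invisible(x)
}

#' Combine marker and reporter projections for segmentation
#'
#' When the marker channel is mitochondrial (sparse tubules), neither channel
#' alone outlines whole cells; the segmentation input is the sum of the two
#' min-max-normalized projections.
#'
#' @param marker_proj,gfp_proj [projection2d] objects of equal shape.
#' @return a [projection2d].
#' @export
combine_projections <- function(marker_proj, gfp_proj) {
  stopifnot(inherits(marker_proj, "projection2d"),
            inherits(gfp_proj, "projection2d"))
  if (!identical(dim(marker_proj$pixels), dim(gfp_proj$pixels))) {
    stopf("projections differ in shape")
  }
  projection2d(minmax(marker_proj$pixels) + minmax(gfp_proj$pixels),
               provenance = "combined:minmax(marker)+minmax(gfp)")
}

#' Read a single-channel multi-page TIFF as an ImageStack
#'
#' Pages map to ascending z. Pixel/z metadata are taken, in order of
#' preference, from a JSON sidecar (`<path>.json`, as written by
#' [write_stack]), from OME-XML or ImageJ description tags, or from defaults
#' (with a message).
#'
#' @param path TIFF file path.
#' @param channel_name channel label to attach.
#' @param as_is if `TRUE` (default) integer pixel data are returned as raw
#'   counts rather than rescaled to `[0, 1]`.
#' @return an [image_stack].
#' @export
read_stack <- function(path, channel_name = "", as_is = TRUE) {
  if (!file.exists(path)) stopf("TIFF not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                   as.is = as_is),
                    error = function(e) stopf("unreadable TIFF %s: %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (isTRUE(attr(pages[[1]], "bits.per.sample") == 32L) && as_is) {
    # float samples: raw bit patterns are meaningless, re-read scaled
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar0 <- paste0(path, ".json")
    if (file.exists(sidecar0)) {
      sc0 <- jsonlite::read_json(sidecar0, simplifyVector = TRUE)
      if (!is.null(sc0$intensity_scale)) {
        pages <- lapply(pages, function(p) {
          a <- attributes(p); p <- p * sc0$intensity_scale
          attributes(p) <- a; p
        })
      }
    }
  }
  shp <- lapply(pages, dim)
  if (any(vapply(shp, length, 1L) > 2L)) {
    bad <- which(vapply(shp, length, 1L) > 2L)[1]
    stopf("page %d of %s is multi-channel (interleaved samples); %s",
          bad, path, "split channels before reading")
  }
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L) {
    stopf("mixed page shapes in %s (page 1: %s)", path,
          paste(shp[[1]], collapse = "x"))
  }
  nz <- length(pages); ny <- shp[[1]][1]; nx <- shp[[1]][2]
  vox <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) vox[z, , ] <- pages[[z]]

  meta <- list(z_step_um = NULL, pixel_size_um = NULL)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta$z_step_um <- sc$z_step_um
    meta$pixel_size_um <- sc$pixel_size_um
    if (!nzchar(channel_name)) channel_name <- sc$channel_name %||% ""
  } else {
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc)) meta <- parse_tiff_description(desc)
  }
  if (is.null(meta$z_step_um)) {
    message("read_stack: no z-step metadata in ", basename(path),
            "; using default 0.5 um")
  }
  image_stack(vox,
              z_step_um = meta$z_step_um %||% 0.5,
              pixel_size_um = meta$pixel_size_um %||% 0.2,
              channel_name = channel_name)
}

#' Parse pixel metadata from a TIFF description tag
#'
#' Understands the OME-XML attributes `PhysicalSizeZ` / `PhysicalSizeX` and
#' ImageJ-style `spacing=` text. Returns `NULL` fields when absent.
#'
#' @param desc description tag text.
#' @return list with `z_step_um` and `pixel_size_um` (either may be `NULL`).
#' @export
parse_tiff_description <- function(desc) {
  out <- list(z_step_um = NULL, pixel_size_um = NULL)
  if (is.null(desc) || !nzchar(desc)) return(out)
  grab <- function(pattern) {
    m <- regmatches(desc, regexec(pattern, desc))[[1]]
    if (length(m) >= 2) as.numeric(m[2]) else NULL
  }
  out$z_step_um <- grab('PhysicalSizeZ="([0-9.eE+-]+)"') %||%
    grab("spacing=([0-9.eE+-]+)")
  out$pixel_size_um <- grab('PhysicalSizeX="([0-9.eE+-]+)"')
  out
}

#' Write an ImageStack to a multi-page TIFF with a JSON sidecar
#'
#' 16-bit unsigned integer storage by default (the native EMCCD ADU format);
#' values must then be integers in `[0, 65535]` unless `round = TRUE`.
#' Metadata go to `<path>.json` because baseline TIFF writers carry no
#' description tag.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @param bits 16 (integer) or 32 (float; values scaled by their maximum,
#'   recorded in the sidecar as `intensity_scale`).
#' @param round round non-integer values before 16-bit storage.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L, round = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  vox <- stack$voxels
  nz <- dim(vox)[1]
  scale <- 1.0
  if (bits == 16L) {
    if (round) vox <- round(vox)
    if (any(vox != round(vox)) || max(vox) > 65535) {
      stopf("16-bit storage needs integer values in [0, 65535]; %s",
            "use round = TRUE or bits = 32")
    }
    pages <- lapply(seq_len(nz), function(z) vox[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (bits == 32L) {
    scale <- max(vox, 1e-12)
    pages <- lapply(seq_len(nz), function(z) vox[z, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else stopf("bits must be 16 or 32")
  jsonlite::write_json(
    list(z_step_um = stack$z_step_um, pixel_size_um = stack$pixel_size_um,
         channel_name = stack$channel_name, bits = bits,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
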