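#' Kyte-Doolittle hydropathy scale
#'
#' The standard per-residue hydropathy values (Kyte & Doolittle 1982),
#' one-letter amino-acid codes.
#'
#' @format named numeric vector of length 20.
#' @export
kd_scale <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Sliding-window hydropathy profile
#'
#' ProtScale-style profile: the score at each position is the weighted mean
#' of scale values over a centered window. With the edge weight at 100% and
#' linear weight variation the weights are uniform and the score is the plain
#' window mean; the general linear edge-to-center weighting is implemented
#' and collapses to uniform at `edge_weight = 1`. No normalization is
#' applied: scores stay on the scale's own range.
#'
#' @param sequence amino-acid string (standard 20 one-letter codes only).
#' @param window odd window size >= 1 (default 5).
#' @param edge_weight relative weight of the window edges vs the center, in
#'   (0, 1]; default 1 (uniform).
#' @param scale named per-residue scale (default [kd_scale]); alternate
#'   scales may be loaded from CSV via [read_scale_csv].
#' @param id sequence identifier carried into the output.
#' @return `data.frame` of class `hydropathy_profile` with `position`
#'   (1-based index of the window's center residue), `residue`, `score`;
#'   length `L - window + 1`. Attributes: `id`, `window`, `edge_weight`.
#' @export
#' @examples
#' kd_profile("IIIII", window = 5)$score   # 4.5, the Ile scale value
kd_profile <- function(sequence, window = 5L, edge_weight = 1,
                       scale = kd_scale, id = "") {
  if (length(sequence) != 1 || !is.character(sequence)) {
    stopf("sequence must be a single string")
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stopf("window must be odd and >= 1")
  if (!(edge_weight > 0 && edge_weight <= 1)) {
    stopf("edge_weight must be in (0, 1]")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  L <- length(aa)
  bad <- which(!aa %in% names(scale))
  if (length(bad)) {
    stopf("non-standard residue(s) %s at position(s) %s",
          paste(unique(aa[bad]), collapse = ","),
          paste(head(bad, 10), collapse = ","))
  }
  if (L < window) stopf("sequence length %d shorter than window %d", L, window)
  v <- unname(scale[aa])
  half <- (window - 1L) / 2L
  w <- if (half == 0L) 1 else {
    edge_weight + (1 - edge_weight) * (1 - abs(-half:half) / half)
  }
  centers <- (half + 1L):(L - half)
  score <- vapply(centers, function(c0) {
    win <- v[(c0 - half):(c0 + half)]
    sum(w * win) / sum(w)
  }, 1.0)
  out <- data.frame(position = centers, residue = aa[centers], score = score,
                    stringsAsFactors = FALSE)
  attr(out, "id") <- id
  attr(out, "window") <- window
  attr(out, "edge_weight") <- edge_weight
  class(out) <- c("hydropathy_profile", "data.frame")
  out
}

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_aa <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stopf("reading FASTA requires the Biostrings package")
  }
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Load an alternate hydropathy scale from CSV
#'
#' Two columns: `residue` (one-letter code) and `value`.
#'
#' @param path CSV file.
#' @return named numeric vector.
#' @export
read_scale_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df))) {
    stopf("scale CSV needs columns 'residue' and 'value'")
  }
  setNames(df$value, toupper(df$residue))
}
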