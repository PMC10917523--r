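#' Specify a synthetic cycloheximide-chase experiment
#'
#' Emulates a copper-inducible reporter chase read on a flow cytometer: each
#' cell carries an initial reporter intensity (lognormal across cells with the
#' stated coefficient of variation) decaying exponentially at a common rate on
#' top of a constant cellular background; every measurement additionally
#' receives multiplicative lognormal instrument noise. One pre-induction
#' measurement per cell carries background only.
#'
#' @param n_cells cells measured per time point.
#' @param timepoints_min strictly increasing times in minutes (default the
#'   40-min chase sampled every 10 min).
#' @param decay_rate_per_min first-order decay rate `k` (>= 0), per minute.
#' @param initial_mean mean initial reporter intensity (a.u.).
#' @param background_mean pre-induction background intensity (a.u.).
#' @param cell_cv across-cell CV of initial intensities (lognormal).
#' @param measurement_cv per-measurement instrument CV (lognormal, mean 1);
#'   0 disables.
#' @param seed RNG seed.
#' @return an object of class `chase_spec`.
#' @export
chase_spec <- function(n_cells = 2000L,
                       timepoints_min = c(0, 10, 20, 30, 40),
                       decay_rate_per_min = 0.03,
                       initial_mean = 1000,
                       background_mean = 50,
                       cell_cv = 0.2,
                       measurement_cv = 0.05,
                       seed = 1L) {
  if (!is_count(n_cells)) stopf("n_cells must be a count >= 1")
  if (length(timepoints_min) < 2 || any(diff(timepoints_min) <= 0)) {
    stopf("timepoints_min must be strictly increasing with >= 2 points")
  }
  if (decay_rate_per_min < 0) stopf("decay_rate_per_min must be >= 0")
  if (cell_cv < 0 || measurement_cv < 0) stopf("CVs must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 timepoints_min = as.numeric(timepoints_min),
                 decay_rate_per_min = decay_rate_per_min,
                 initial_mean = initial_mean,
                 background_mean = background_mean,
                 cell_cv = cell_cv, measurement_cv = measurement_cv,
                 seed = as.integer(seed)),
            class = "chase_spec")
}

#' Generate per-cell chase intensities
#'
#' @param spec a [chase_spec].
#' @return long-format `data.frame` with columns `cell_id`, `time_min`
#'   (`NA` for the pre-induction background row), `intensity`,
#'   `is_background`.
#' @export
#' @examples
#' head(generate_chase(chase_spec(n_cells = 3, cell_cv = 0,
#'                                measurement_cv = 0)))
generate_chase <- function(spec) {
  stopifnot(inherits(spec, "chase_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_cells
    tt <- spec$timepoints_min
    init <- if (spec$cell_cv > 0) {
      sdl <- sqrt(log(1 + spec$cell_cv^2))
      rlnorm(n, meanlog = log(spec$initial_mean) - sdl^2 / 2, sdlog = sdl)
    } else rep(spec$initial_mean, n)
    noise <- function(m) {
      if (spec$measurement_cv > 0) {
        sdl <- sqrt(log(1 + spec$measurement_cv^2))
        m * rlnorm(length(m), meanlog = -sdl^2 / 2, sdlog = sdl)
      } else m
    }
    bg_rows <- data.frame(cell_id = seq_len(n), time_min = NA_real_,
                          intensity = noise(rep(spec$background_mean, n)),
                          is_background = TRUE)
    rows <- lapply(tt, function(t) {
      mu <- spec$background_mean + init * exp(-spec$decay_rate_per_min * t)
      data.frame(cell_id = seq_len(n), time_min = t,
                 intensity = noise(mu), is_background = FALSE)
    })
    out <- rbind(bg_rows, do.call(rbind, rows))
    rownames(out) <- NULL
    out
  })
}
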