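#' Segmentation configuration
#'
#' Rule for locating the first marine growth year on the stretched axis: a
#' column belongs to a "low-variance" stretch when the across-transect
#' variance of the peak bin is below `var_threshold`, and the marine phase is
#' delimited by the first and last runs of at least `run_length` consecutive
#' low-variance columns. The defaults (30 columns, variance 10 in
#' bin-index units) are the values used on the salmon archive.
#'
#' @param run_length Minimum run of consecutive low-variance columns.
#' @param var_threshold Variance bound, in squared frequency-bin indices.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(run_length = 30, var_threshold = 10) {
  stopifnot_scalar_(run_length, "run_length", lower = 1)
  stopifnot_scalar_(var_threshold, "var_threshold")
  if (var_threshold <= 0) abort("`var_threshold` must be > 0.")
  structure(list(run_length = as.integer(run_length),
                 var_threshold = var_threshold),
            class = "segmentation_config")
}

#' Dominant-frequency trace of an ensemble spectrogram
#'
#' For each stretched column, the frequency of the maximum-amplitude bin.
#' Ties are broken toward the lower frequency (the physically dominant
#' long-period circuli ridge rather than a harmonic); all-zero columns are
#' returned as `NA`.
#'
#' @param e An `ensemble_spectrogram`.
#' @return Numeric vector of peak frequencies in cycles/pixel, length
#'   `ncol(e$z)`, `NA` where undefined.
#' @export
extract_peak_trace <- function(e) {
  if (!inherits(e, "spectrogram")) abort("`e` must be a spectrogram.")
  if (ncol(e$z) == 0) abort("empty spectrogram.")
  bins <- peak_bins_(e$z)
  out <- rep(NA_real_, length(bins))
  out[!is.na(bins)] <- e$freqs[bins[!is.na(bins)]]
  out
}

#' Segment the first marine growth year
#'
#' Scans the per-column peak variance sequence left to right for the first
#' run of at least `run_length` consecutive values below `var_threshold`
#' (its first column is the marine start) and right to left for the first
#' such run (its last column is the marine end). Freshwater and return
#' phases carry poorly resolved, angle-inconsistent peaks and therefore high
#' variance; the marine year is the prolonged low-variance stretch between
#' them. Indices are 1-based column positions on the stretched axis.
#'
#' @param sigma2 Numeric variance sequence (`NA` treated as not low).
#' @param cfg A [segmentation_config()].
#' @return A list with integer `marine_start` and `marine_end` (both `NA`
#'   when no qualifying run exists, in which case the scale is flagged).
#' @export
segment_marine_phase <- function(sigma2, cfg = segmentation_config()) {
  low <- !is.na(sigma2) & sigma2 < cfg$var_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= cfg$run_length)
  if (length(qual) == 0) {
    return(list(marine_start = NA_integer_, marine_end = NA_integer_))
  }
  list(marine_start = starts[qual[1]], marine_end = ends[qual[length(qual)]])
}

#' Convert peak frequency to circuli spacing
#'
#' Inter-circuli spacing is the reciprocal of spatial frequency:
#' `spacing_mm = 1 / (f * pixels_per_mm)`. At the reference magnification of
#' 302 px/mm, a 0.05 cycles/pixel peak (20 px period) maps to ~0.0662 mm.
#'
#' @param peak_freq Peak frequencies in cycles/pixel (`NA` allowed).
#' @param pixels_per_mm Image magnification, must be > 0.
#' @return Spacings in millimeters; `NA` where the frequency is undefined or
#'   zero.
#' @export
frequency_to_spacing <- function(peak_freq, pixels_per_mm = 302) {
  stopifnot_scalar_(pixels_per_mm, "pixels_per_mm")
  if (pixels_per_mm <= 0) abort("`pixels_per_mm` must be > 0.")
  out <- rep(NA_real_, length(peak_freq))
  ok <- !is.na(peak_freq) & peak_freq > 0
  out[ok] <- 1 / (peak_freq[ok] * pixels_per_mm)
  out
}

#' Growth trace of one scale
#'
#' Assembles the user-facing result of the spectral pipeline for one scale:
#' per stretched position, the dominant frequency, its circuli-spacing
#' equivalent in millimeters, the across-transect peak variance, and whether
#' the position falls inside the segmented first marine year.
#'
#' @param e An `ensemble_spectrogram`.
#' @param pixels_per_mm Image magnification.
#' @param seg A [segmentation_config()].
#' @return A tibble of class `growth_trace` with columns `position` (0-1),
#'   `peak_freq` (cycles/pixel), `spacing_mm`, `sigma2`, `marine` (logical);
#'   attributes `marine_start`, `marine_end` (stretched column indices or
#'   `NA`) and `n_transects`.
#' @export
growth_trace <- function(e, pixels_per_mm = 302, seg = segmentation_config()) {
  pf <- extract_peak_trace(e)
  bounds <- segment_marine_phase(e$sigma2, seg)
  L <- length(pf)
  marine <- rep(FALSE, L)
  if (!is.na(bounds$marine_start)) {
    marine[bounds$marine_start:bounds$marine_end] <- TRUE
  }
  out <- tibble::tibble(
    position = e$positions,
    peak_freq = pf,
    spacing_mm = frequency_to_spacing(pf, pixels_per_mm),
    sigma2 = e$sigma2,
    marine = marine
  )
  structure(out,
            class = c("growth_trace", class(out)),
            marine_start = bounds$marine_start,
            marine_end = bounds$marine_end,
            n_transects = e$n_transects)
}

#' @rdname tidy_scalegram
#' @export
tidy.growth_trace <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname glance_scalegram
#' @export
glance.growth_trace <- function(x, ...) {
  ms <- attr(x, "marine_start"); me <- attr(x, "marine_end")
  mar <- !is.na(ms)
  tibble::tibble(
    n_positions = nrow(x),
    n_transects = attr(x, "n_transects"),
    marine_start = ms,
    marine_end = me,
    segmented = mar,
    mean_marine_spacing_mm = if (mar) mean(x$spacing_mm[ms:me], na.rm = TRUE) else NA_real_
  )
}

#' Plot a growth trace
#'
#' Spacing equivalents against stretched position with the segmented marine
#' year shaded.
#'
#' @param object A `growth_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$spacing_mm))
  ms <- attr(object, "marine_start"); me <- attr(object, "marine_end")
  if (!is.na(ms)) {
    p <- p + ggplot2::annotate("rect",
                               xmin = df$position[ms], xmax = df$position[me],
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "steelblue")
  }
  p + ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "stretched position (0 = focus, 1 = edge)",
                  y = "circuli spacing equivalent (mm)") +
    ggplot2::theme_minimal()
}
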