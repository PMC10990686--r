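#' Stretch a spectrogram to a common length
#'
#' Rescales the window-center positions of a spectrogram by its transect
#' length (`x' = x / xmax`, so `x'` lies in `[0, 1]`) and, independently for
#' every frequency row, linearly interpolates the amplitudes onto `L` evenly
#' spaced positions `x'' = 0, 1/(L-1), ..., 1`. The frequency content of each
#' column is unchanged; only the position axis is resampled, which is what
#' lets spectrograms from transects of different physical lengths (the
#' anisotropy problem) be averaged without biasing the spacing information.
#' Because window centers cannot reach the exact ends of the transect, the
#' outermost stretched columns repeat the nearest source column.
#'
#' @param s A `spectrogram` with at least 2 columns.
#' @param L Number of stretched columns; must be at least `ncol(s$z)` so that
#'   no spectral columns are lost.
#' @return An object of class `stretched_spectrogram` with `z` (`L` columns),
#'   `freqs`, `positions` (the `x''` grid in `[0, 1]`) and `theta`.
#' @export
stretch_spectrogram <- function(s, L = 1500) {
  if (!inherits(s, "spectrogram")) abort("`s` must be a spectrogram.")
  nc <- ncol(s$z)
  if (nc < 2) {
    abort("spectrogram has fewer than 2 columns; excluded from the ensemble.",
          class = "scalegram_short_transect")
  }
  if (L < nc) abort("`L` must be at least the number of source columns.")
  xp <- s$positions / s$xmax
  xq <- seq(0, 1, length.out = L)
  z <- stretch_matrix_(s$z, xp, xq)
  structure(
    list(z = z, freqs = s$freqs, positions = xq, theta = s$theta),
    class = c("stretched_spectrogram", "spectrogram")
  )
}

# Row-wise linear interpolation of z (rows = frequency) from source positions
# xp onto query positions xq, with nearest-value extension beyond the ends.
stretch_matrix_ <- function(z, xp, xq) {
  i0 <- findInterval(xq, xp, all.inside = TRUE)
  w <- (xq - xp[i0]) / (xp[i0 + 1L] - xp[i0])
  w <- pmin(pmax(w, 0), 1)
  nf <- nrow(z)
  z[, i0, drop = FALSE] * rep(1 - w, each = nf) +
    z[, i0 + 1L, drop = FALSE] * rep(w, each = nf)
}

#' Average a set of stretched spectrograms
#'
#' Cell-wise arithmetic mean over the retained transects of one scale, plus
#' the per-column variance, across transects, of each transect's own
#' peak-frequency bin. That variance sequence is what segments the first
#' marine year: where circuli are well resolved nearly all transects agree on
#' the peak bin and the variance collapses.
#'
#' @param stretched A list of `stretched_spectrogram` objects with identical
#'   shapes and axes.
#' @return An `ensemble_spectrogram`: `z` (mean amplitudes), `freqs`,
#'   `positions`, `sigma2` (per-column across-transect variance of the peak
#'   bin index), `n_transects`, `n_excluded`.
#' @export
average_spectrograms <- function(stretched) {
  stretched <- Filter(Negate(is.null), stretched)
  if (length(stretched) == 0) abort("empty spectrogram set.")
  dims <- vapply(stretched, function(s) dim(s$z), integer(2))
  if (any(dims != dims[, 1])) abort("stretched spectrograms have differing shapes.")
  acc <- ensemble_accumulator_(dims[1, 1], dims[2, 1],
                               stretched[[1]]$freqs, stretched[[1]]$positions)
  for (s in stretched) acc <- ensemble_add_(acc, s$z)
  ensemble_finalize_(acc, n_excluded = 0L)
}

# streaming accumulator: mean amplitude + Welford-free moment sums of the
# per-transect argmax bin, per stretched column
ensemble_accumulator_ <- function(nf, L, freqs, positions) {
  list(sum_z = matrix(0, nf, L), n = 0L,
       bin_sum = numeric(L), bin_sum2 = numeric(L), bin_n = integer(L),
       freqs = freqs, positions = positions)
}

ensemble_add_ <- function(acc, z) {
  acc$sum_z <- acc$sum_z + z
  acc$n <- acc$n + 1L
  bins <- peak_bins_(z)
  def <- !is.na(bins)
  b <- bins[def]
  acc$bin_sum[def] <- acc$bin_sum[def] + b
  acc$bin_sum2[def] <- acc$bin_sum2[def] + b^2
  acc$bin_n[def] <- acc$bin_n[def] + 1L
  acc
}

ensemble_finalize_ <- function(acc, n_excluded) {
  if (acc$n == 0L) abort("no retained transects to average.")
  n <- acc$bin_n
  sigma2 <- rep(NA_real_, length(n))
  ok <- n >= 2L
  sigma2[ok] <- (acc$bin_sum2[ok] - acc$bin_sum[ok]^2 / n[ok]) / (n[ok] - 1L)
  sigma2[ok] <- pmax(sigma2[ok], 0)
  structure(
    list(z = acc$sum_z / acc$n, freqs = acc$freqs, positions = acc$positions,
         sigma2 = sigma2, n_transects = acc$n, n_excluded = n_excluded),
    class = c("ensemble_spectrogram", "spectrogram")
  )
}

# argmax bin per column; ties go to the lower frequency (which.max takes the
# first maximum and rows are ordered by increasing frequency); all-zero
# columns are undefined
peak_bins_ <- function(z) {
  b <- max.col(t(z), ties.method = "first")
  b[colSums(z) == 0] <- NA_integer_   # amplitudes are >= 0
  b
}

#' Ensemble spectrogram of a whole scale
#'
#' Streams every transect of a set through spectrogram computation
#' ([transect_spectrogram()]), stretching ([stretch_spectrogram()]) and the
#' running ensemble average, without materializing all stretched spectrograms
#' at once. Transects shorter than one analysis window (or yielding a single
#' spectral column) are excluded and counted.
#'
#' @param tset A `transect_set` (edge-truncated; see [truncate_transects()]).
#' @param cfg A [spectral_config()].
#' @param L Common stretched length, columns.
#' @return An `ensemble_spectrogram`; see [average_spectrograms()].
#' @export
ensemble_spectrogram <- function(tset, cfg = spectral_config(), L = 1500) {
  if (!inherits(tset, "transect_set")) abort("`tset` must be a transect_set.")
  N <- cfg$window_px
  acc <- NULL
  excluded <- 0L
  xq <- seq(0, 1, length.out = L)
  for (i in seq_along(tset$angle_deg)) {
    n <- tset$xmax[i]
    if (n < N) { excluded <- excluded + 1L; next }
    s <- transect_spectrogram(tset$x[i, seq_len(n)], cfg,
                              theta = tset$angle_deg[i])
    if (ncol(s$z) < 2) { excluded <- excluded + 1L; next }
    z <- stretch_matrix_(s$z, s$positions / s$xmax, xq)
    if (is.null(acc)) {
      acc <- ensemble_accumulator_(nrow(z), L, s$freqs, xq)
    }
    acc <- ensemble_add_(acc, z)
  }
  if (is.null(acc)) {
    abort("no transect is long enough for the configured window; no ensemble.")
  }
  ensemble_finalize_(acc, n_excluded = excluded)
}

#' @export
print.ensemble_spectrogram <- function(x, ...) {
  cat(sprintf("<ensemble_spectrogram> %d freq bins x %d stretched columns; %d transects (%d excluded)\n",
              nrow(x$z), ncol(x$z), x$n_transects, x$n_excluded))
  invisible(x)
}

#' @rdname tidy_scalegram
#' @export
tidy.ensemble_spectrogram <- function(x, ...) {
  tibble::tibble(
    position = rep(x$positions, each = length(x$freqs)),
    freq_cpp = rep(x$freqs, times = ncol(x$z)),
    amplitude = as.vector(x$z)
  )
}
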