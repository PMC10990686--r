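#' Spectrogram configuration
#'
#' Parameters of the short-window Fourier analysis: an `N`-pixel window slid
#' along the transect in `step`-pixel increments, each window multiplied by a
#' taper before the transform. Defaults (200-px Hamming window, 5-px step)
#' match the analysis conditions for medium-resolution salmon scale images at
#' 302 px/mm, where a window spans roughly ten circuli cycles.
#'
#' @param window_px Window length `N` in pixels; must be even.
#' @param step_px Window increment in pixels; `0 < step_px <= window_px`.
#' @param taper `"hamming"` (default) or `"none"`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window_px = 200, step_px = 5, taper = "hamming") {
  stopifnot_scalar_(window_px, "window_px", lower = 4)
  stopifnot_scalar_(step_px, "step_px", lower = 1)
  if (window_px %% 2 != 0) abort("`window_px` must be even.")
  if (step_px > window_px) abort("`step_px` must not exceed `window_px`.")
  taper <- match.arg(taper, c("hamming", "none"))
  structure(
    list(window_px = as.integer(window_px), step_px = as.integer(step_px),
         taper = taper),
    class = "spectral_config"
  )
}

taper_vector_ <- function(cfg) {
  switch(cfg$taper,
         hamming = as.numeric(signal::hamming(cfg$window_px)),
         none = rep(1, cfg$window_px))
}

#' One-sided amplitude spectrum of a tapered window
#'
#' Computes `|X(k)|` of the discrete Fourier transform
#' `X(k) = sum_n x(n) exp(-i 2 pi k n / N)` for `k = 1 .. N/2` after removing
#' the window mean and multiplying by the taper. Bin `k` corresponds to
#' spatial frequency `k/N` cycles/pixel; the DC bin is dropped because the
#' saturation offset of the image carries no growth information, and
#' frequencies above Nyquist (0.5 cycles/pixel) are redundant for a real
#' signal.
#'
#' @param x_window Numeric series of length `N` (the taper length).
#' @param taper Numeric taper of the same length, or a [spectral_config()]
#'   whose `window_px` equals `length(x_window)`.
#' @return Numeric vector of `N/2` amplitudes; `attr(, "freqs")` holds the
#'   frequencies `k/N` in cycles/pixel.
#' @export
windowed_amplitude_spectrum <- function(x_window, taper = spectral_config()) {
  if (inherits(taper, "spectral_config")) {
    if (taper$window_px != length(x_window)) {
      abort("`x_window` length must equal the configured window length.")
    }
    taper <- taper_vector_(taper)
  }
  n <- length(x_window)
  if (length(taper) != n) abort("taper and window lengths differ.")
  if (any(!is.finite(x_window))) abort("window contains non-finite values.")
  xw <- (x_window - mean(x_window)) * taper
  amp <- Mod(fft(xw))[2:(n %/% 2 + 1L)]
  structure(amp, freqs = (1:(n %/% 2)) / n)
}

#' Spectrogram of one radial transect
#'
#' Slides the configured window along the saturation series and inserts each
#' window's one-sided amplitude spectrum as a column of the spectrogram
#' matrix. Window `j` starts at offset `(j-1) * step` from the focus and its
#' column is mapped to the window's center offset `(j-1) * step + N/2`.
#' A transect shorter than one window yields an empty (0-column) spectrogram
#' flagged `excluded`, the fate of short transects near the scale edges.
#'
#' @param x Numeric saturation series (an edge-truncated transect), or a
#'   single row taken from a `transect_set`.
#' @param cfg A [spectral_config()].
#' @param theta Source angle in degrees, recorded on the result.
#' @return An object of class `spectrogram`: `z` (amplitude matrix, one row
#'   per frequency bin, one column per window), `freqs` (cycles/pixel),
#'   `positions` (window-center offsets in pixels), `xmax`, `theta`,
#'   `excluded`.
#' @export
transect_spectrogram <- function(x, cfg = spectral_config(), theta = NA_real_) {
  x <- x[!is.na(x)]
  n <- length(x)
  N <- cfg$window_px
  freqs <- (1:(N %/% 2)) / N
  if (n < N) {
    return(structure(
      list(z = matrix(numeric(0), nrow = N %/% 2, ncol = 0), freqs = freqs,
           positions = numeric(0), xmax = n, theta = theta, excluded = TRUE),
      class = "spectrogram"
    ))
  }
  starts <- seq(1L, n - N + 1L, by = cfg$step_px)
  W <- matrix(x[outer(0:(N - 1L), starts, "+")], nrow = N)
  W <- W - rep(colMeans(W), each = N)
  W <- W * taper_vector_(cfg)
  z <- Mod(mvfft(W))[2:(N %/% 2 + 1L), , drop = FALSE]
  structure(
    list(z = z, freqs = freqs, positions = (starts - 1L) + N / 2,
         xmax = n, theta = theta, excluded = FALSE),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> theta = %s deg: %d freq bins x %d windows (xmax = %d px)%s\n",
              format(x$theta), length(x$freqs), ncol(x$z), x$xmax,
              if (x$excluded) " [excluded: shorter than one window]" else ""))
  invisible(x)
}

#' @rdname tidy_scalegram
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble::tibble(
    position = rep(x$positions, each = length(x$freqs)),
    freq_cpp = rep(x$freqs, times = ncol(x$z)),
    amplitude = as.vector(x$z)
  )
}

#' Plot a spectrogram
#'
#' @param object A `spectrogram`, `stretched_spectrogram` or
#'   `ensemble_spectrogram`.
#' @param ... Unused.
#' @return A ggplot heat map (position x frequency, fill = amplitude).
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidy(object)
  xlab <- names(df)[1]
  ggplot2::ggplot(df, ggplot2::aes(.data[[xlab]], .data$freq_cpp,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(y = "frequency (cycles/pixel)", fill = "amplitude") +
    ggplot2::theme_minimal()
}
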