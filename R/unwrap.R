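#' Radially unwrap a scale image into saturation transects
#'
#' Samples the saturation field along radial lines fanning out from the
#' annotated focus at `delta_theta`-degree intervals (3600 transects at the
#' 0.1-degree default), at unit radial steps, using bilinear interpolation of
#' the four neighboring pixels. Angles are measured counter-clockwise from
#' the +x (column) axis with the row index increasing downward. Each transect
#' runs from the focus to the image boundary; edge truncation is applied
#' separately by [truncate_transects()].
#'
#' @param img A [scale_image].
#' @param focus `(row, col)` of the scale focus in pixels, strictly inside the
#'   image.
#' @param delta_theta Angular interval in degrees; must divide 360 evenly.
#'
#' @return An object of class `transect_set`: a list with `x` (matrix, one row
#'   per angle, radial samples in columns, `NA` beyond each transect's
#'   length), `angle_deg`, `xmax` (samples per transect), `delta_theta`,
#'   `pixels_per_mm` and `sample_id`.
#' @export
extract_transects <- function(img, focus, delta_theta = 0.1) {
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  if (length(focus) != 2L || any(!is.finite(focus))) {
    abort("`focus` must be a (row, col) pair.")
  }
  r0 <- focus[1]; c0 <- focus[2]
  if (r0 <= 1 || r0 >= h || c0 <= 1 || c0 >= w) {
    abort("focus must lie strictly inside the image (not on the boundary).")
  }
  n_theta <- 360 / delta_theta
  if (abs(n_theta - round(n_theta)) > 1e-9) {
    abort("`delta_theta` must divide 360 evenly.")
  }
  n_theta <- as.integer(round(n_theta))
  th <- (seq_len(n_theta) - 1L) * delta_theta * pi / 180
  ux <- cos(th)          # column direction
  uy <- -sin(th)         # row direction (row grows downward; theta is CCW)

  # distance from the focus to the image boundary along each direction
  t_col <- ifelse(ux > 0, (w - c0) / ux, ifelse(ux < 0, (1 - c0) / ux, Inf))
  t_row <- ifelse(uy > 0, (h - r0) / uy, ifelse(uy < 0, (1 - r0) / uy, Inf))
  rmax <- pmax(0, floor(pmin(t_col, t_row) - 1e-9))
  xmax <- as.integer(rmax) + 1L                     # samples at r = 0..rmax

  n_rad <- max(xmax)
  radii <- 0:(n_rad - 1L)
  rr <- r0 + outer(uy, radii)                       # n_theta x n_rad
  cc <- c0 + outer(ux, radii)
  valid <- outer(xmax, seq_len(n_rad), ">=")

  fr <- pmin(pmax(floor(rr), 1), h - 1L)
  fc <- pmin(pmax(floor(cc), 1), w - 1L)
  ar <- rr - fr
  ac <- cc - fc
  i00 <- fr + (fc - 1L) * h
  v <- px[i00] * (1 - ar) * (1 - ac) + px[i00 + 1L] * ar * (1 - ac) +
    px[i00 + h] * (1 - ar) * ac + px[i00 + h + 1L] * ar * ac
  v[!valid] <- NA_real_

  structure(
    list(x = v, angle_deg = (seq_len(n_theta) - 1L) * delta_theta,
         xmax = xmax, delta_theta = delta_theta,
         pixels_per_mm = img$pixels_per_mm, sample_id = img$sample_id),
    class = "transect_set"
  )
}

#' @export
print.transect_set <- function(x, ...) {
  cat(sprintf("<transect_set> %s: %d transects at %.3g deg, lengths %d-%d px\n",
              x$sample_id, length(x$angle_deg), x$delta_theta,
              min(x$xmax), max(x$xmax)))
  invisible(x)
}

#' @rdname tidy_scalegram
#' @export
tidy.transect_set <- function(x, ...) {
  n_rad <- ncol(x$x)
  out <- tibble::tibble(
    angle_deg = rep(x$angle_deg, times = n_rad),
    radius_px = rep(0:(n_rad - 1L), each = length(x$angle_deg)),
    saturation = as.vector(x$x)
  )
  dplyr::filter(out, !is.na(.data$saturation))
}

#' Detect the scale edge on a single transect
#'
#' Slides a window of `window` samples outward along the saturation series
#' and reports the last sample before the first window that looks like
#' background: sample variance at most `var_tol` and mean within `level_tol`
#' of the background level. Returns the full series length when no window
#' qualifies (no falloff to background), and 0 for a series that is
#' background from the start.
#'
#' The returned edge index counts retained samples: the first qualifying
#' window starts at `edge + 1`.
#'
#' @param x Numeric saturation series.
#' @param background Background model from [estimate_background()] (a list
#'   with `level`, `sd`, `variance`).
#' @param window Sliding-window length, pixels.
#' @param var_mult,level_mult Tolerance multipliers: a window qualifies when
#'   its variance is `<= var_mult * background$variance` and its mean is
#'   within `level_mult * background$sd` of `background$level` (both with a
#'   1e-6 slack so noise-free backgrounds survive interpolation round-off).
#' @return Integer edge index in `0..length(x)`.
#' @export
detect_scale_edge <- function(x, background, window = 25,
                              var_mult = 3, level_mult = 3) {
  n <- length(x)
  if (n < window) {
    warn(sprintf("transect of %d px shorter than the %d px edge window; not truncated.",
                 n, window))
    return(n)
  }
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - window + 1L)
  s <- cs[i + window] - cs[i]
  s2 <- cs2[i + window] - cs2[i]
  m <- s / window
  v <- pmax(0, (s2 - s^2 / window) / (window - 1))
  ok <- v <= var_mult * background$variance + 1e-6 &
    abs(m - background$level) <= level_mult * background$sd + 1e-6
  first <- which(ok)
  if (length(first) == 0) n else first[1] - 1L
}

#' Truncate all transects at the detected scale edge
#'
#' Applies [detect_scale_edge()] to every transect of a set, discarding the
#' background tail (and with it artifacts such as the scale bar, which lies
#' beyond the rim along any radial line).
#'
#' @param tset A `transect_set` from [extract_transects()].
#' @param background Background model; estimated from the source image with
#'   [estimate_background()].
#' @param window,var_mult,level_mult Edge-rule parameters, see
#'   [detect_scale_edge()].
#' @return The `transect_set` with `xmax` updated and samples beyond each
#'   edge set to `NA`; the per-transect edge indices are kept in `edge`.
#' @export
truncate_transects <- function(tset, background, window = 25,
                               var_mult = 3, level_mult = 3) {
  n_theta <- length(tset$angle_deg)
  edge <- integer(n_theta)
  short <- 0L
  for (i in seq_len(n_theta)) {
    xi <- tset$x[i, seq_len(tset$xmax[i])]
    if (tset$xmax[i] < window) {
      short <- short + 1L
      edge[i] <- tset$xmax[i]
    } else {
      edge[i] <- detect_scale_edge_(xi, background, window, var_mult, level_mult)
    }
  }
  if (short > 0) {
    warn(sprintf("%d transect(s) shorter than the %d px edge window were not truncated.",
                 short, window))
  }
  n_rad <- ncol(tset$x)
  tset$x[outer(edge, seq_len(n_rad), "<")] <- NA_real_
  tset$xmax <- edge
  tset$edge <- edge
  tset
}

# detect_scale_edge without the short-series warning (batch path)
detect_scale_edge_ <- function(x, background, window, var_mult, level_mult) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - window + 1L)
  s <- cs[i + window] - cs[i]
  s2 <- cs2[i + window] - cs2[i]
  m <- s / window
  v <- pmax(0, (s2 - s^2 / window) / (window - 1))
  ok <- v <= var_mult * background$variance + 1e-6 &
    abs(m - background$level) <= level_mult * background$sd + 1e-6
  first <- which(ok)
  if (length(first) == 0) n else first[1] - 1L
}
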