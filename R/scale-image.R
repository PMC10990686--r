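#' Scale image container
#'
#' Wraps an 8-bit saturation grid together with its magnification and sample
#' metadata. Pixel values are stored as a numeric `height x width` matrix on
#' the 0-255 saturation scale.
#'
#' @param pixels Numeric matrix of saturations in `[0, 255]`.
#' @param pixels_per_mm Magnification, pixels per millimeter (must be > 0).
#' @param sample_id,year,sample_date,fork_length_cm Sample metadata.
#'
#' @return An object of class `scale_image`.
#' @export
scale_image <- function(pixels, pixels_per_mm = 302, sample_id = NA_character_,
                        year = NA, sample_date = NA, fork_length_cm = NA) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    abort("pixel saturations must be finite and within [0, 255].")
  }
  stopifnot_scalar_(pixels_per_mm, "pixels_per_mm")
  if (pixels_per_mm <= 0) abort("`pixels_per_mm` must be > 0.")
  structure(
    list(pixels = pixels, pixels_per_mm = pixels_per_mm,
         sample_id = sample_id, year = year, sample_date = sample_date,
         fork_length_cm = fork_length_cm),
    class = "scale_image"
  )
}

#' @export
print.scale_image <- function(x, ...) {
  cat(sprintf("<scale_image> %s: %d x %d px, %.0f px/mm\n",
              x$sample_id, nrow(x$pixels), ncol(x$pixels), x$pixels_per_mm))
  invisible(x)
}

#' @export
dim.scale_image <- function(x) dim(x$pixels)

#' Load a scale photograph
#'
#' Reads a PNG or TIFF raster, converts color inputs to luminance
#' (Rec. 709 weights), and rescales to the 0-255 saturation range.
#'
#' @param path Path to a PNG or TIFF file.
#' @param pixels_per_mm Magnification, pixels per millimeter.
#' @param sample_id,year,sample_date,fork_length_cm Metadata passed through.
#' @return A [scale_image].
#' @export
load_image <- function(path, pixels_per_mm = 302, sample_id = NA_character_,
                       year = NA, sample_date = NA, fork_length_cm = NA) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("cannot read image file '%s' (missing or empty).", path))
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          abort("reading TIFF requires the 'tiff' package.")
        }
        tiff::readTIFF(path)
      },
      abort(sprintf("unsupported image format '%s' (PNG or TIFF expected).", ext))
    ),
    error = function(e) abort(sprintf("failed to decode '%s': %s", path,
                                      conditionMessage(e)))
  )
  px <- luminance_(arr) * 255
  scale_image(px, pixels_per_mm = pixels_per_mm, sample_id = sample_id,
              year = year, sample_date = sample_date,
              fork_length_cm = fork_length_cm)
}

luminance_ <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  nc <- dim(arr)[3]
  if (nc == 2) return(arr[, , 1])                 # gray + alpha
  0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
}

#' Write a scale image as 8-bit grayscale PNG
#'
#' @param img A [scale_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale_image <- function(img, path) {
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

#' Estimate the image background model
#'
#' Robust location and scale of the pixel saturations in the image border
#' frame (median and MAD), used as the background model for scale-edge
#' detection. The median makes the estimate insensitive to dark artifacts
#' such as a scale bar intersecting the border region.
#'
#' @param img A [scale_image].
#' @param border Width of the border frame sampled, pixels.
#' @return A list with `level`, `sd` and `variance`.
#' @export
estimate_background <- function(img, border = 25) {
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  b <- min(border, floor(min(h, w) / 4))
  vals <- c(px[1:b, ], px[(h - b + 1):h, ],
            px[(b + 1):(h - b), 1:b], px[(b + 1):(h - b), (w - b + 1):w])
  level <- median(vals)
  s <- mad(vals)
  list(level = level, sd = s, variance = s^2)
}

#' @rdname tidy_scalegram
#' @export
tidy.scale_image <- function(x, ...) {
  px <- x$pixels
  tibble::tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    saturation = as.vector(px)
  )
}

#' Plot a scale image
#'
#' @param object A [scale_image].
#' @param ... Unused.
#' @return A ggplot raster of the saturation grid.
#' @export
autoplot.scale_image <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$saturation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "saturation") +
    ggplot2::theme_minimal()
}
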