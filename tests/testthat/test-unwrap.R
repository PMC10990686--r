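test_that("PNG round trip preserves 8-bit grayscale values", {
  px <- matrix(sample(0:255, 40 * 30, replace = TRUE), nrow = 40)
  img <- scale_image(px, pixels_per_mm = 302, sample_id = "io")
  path <- withr::local_tempfile(fileext = ".png")
  write_scale_image(img, path)
  back <- load_image(path, pixels_per_mm = 302)
  expect_equal(back$pixels, px)
})

test_that("gray RGB images collapse to their common channel value", {
  arr <- array(0, dim = c(10, 12, 3))
  arr[, , 1] <- arr[, , 2] <- arr[, , 3] <- 77 / 255
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  img <- load_image(path)
  expect_true(all(abs(img$pixels - 77) < 1e-6))
})

test_that("unreadable files raise input errors", {
  path <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", path)
  expect_error(load_image(path), "decode")
  expect_error(load_image(file.path(tempdir(), "nope_missing.png")), "cannot read")
})

test_that("transect count is 360 / delta_theta and constant fields stay constant", {
  img <- scale_image(matrix(120, 60, 60))
  ts <- extract_transects(img, c(30, 30), delta_theta = 1)
  expect_length(ts$angle_deg, 360)
  expect_true(all(abs(ts$x[!is.na(ts$x)] - 120) < 1e-9))
  ts2 <- extract_transects(img, c(30, 30), delta_theta = 0.5)
  expect_length(ts2$angle_deg, 720)
  expect_error(extract_transects(img, c(30, 30), delta_theta = 7), "divide")
  expect_error(extract_transects(img, c(1, 30), delta_theta = 1), "inside")
})

test_that("opposite transects agree on an isotropic synthetic scale", {
  img <- tiny_ring_image(spacing = 16)
  ctr <- attr(img, "spec")$center
  ts <- extract_transects(img, ctr, delta_theta = 90)
  n <- min(ts$xmax[ts$angle_deg %in% c(0, 180)])
  expect_lt(max(abs(ts$x[1, 1:n] - ts$x[3, 1:n])), 1.5)
})

test_that("edge detection matches a brute-force window scan", {
  brute_edge <- function(x, bg, window, vm = 3, lm = 3) {
    for (i in seq_len(length(x) - window + 1)) {
      win <- x[i:(i + window - 1)]
      if (var(win) <= vm * bg$variance + 1e-6 &&
          abs(mean(win) - bg$level) <= lm * bg$sd + 1e-6) return(i - 1L)
    }
    length(x)
  }
  bg <- list(level = 230, sd = 1, variance = 1)
  set.seed(42)
  osc <- 150 + 60 * cos(2 * pi * (0:399) / 18)
  cases <- list(
    c(osc, rep(230, 200)),
    c(osc, 230 + rnorm(200, sd = 0.5)),
    rep(230, 120),
    osc
  )
  for (x in cases) {
    expect_identical(detect_scale_edge(x, bg, window = 25),
                     brute_edge(x, bg, 25))
  }
  expect_equal(detect_scale_edge(c(osc, rep(230, 200)), bg, window = 25), 400)
  expect_equal(detect_scale_edge(rep(230, 120), bg, window = 25), 0)
  expect_equal(detect_scale_edge(osc, bg, window = 25), 400)
})

test_that("short transects are returned untruncated with a warning", {
  bg <- list(level = 230, sd = 1, variance = 1)
  expect_warning(e <- detect_scale_edge(rep(100, 10), bg, window = 25),
                 "shorter")
  expect_equal(e, 10)
})

test_that("background estimation is robust to a scale bar in the border", {
  img <- generate_scale_image(
    scale_spec(image_size = c(560, 560), max_radius = 200, axis_ratio = 1,
               posterior_arc = NULL, noise_sd = 2, imperfection_count = 0,
               scale_bar = TRUE, background_level = 230, seed = 3),
    const_spacing_profile(18))
  bg <- estimate_background(img)
  expect_lt(abs(bg$level - 230), 2)
  bg_wide <- estimate_background(img, border = 100)   # frame includes the bar
  expect_lt(abs(bg_wide$level - 230), 2)
  u <- scale_image(matrix(57, 50, 50))
  bgu <- estimate_background(u)
  expect_equal(bgu$level, 57)
  expect_equal(bgu$variance, 0)
})

test_that("edge truncation removes the scale-bar artifact from every transect", {
  # rim at 150 px leaves a background gap of > one edge window between the
  # scale rim and the bar region, as in the archive images
  spec <- scale_spec(image_size = c(560, 560), max_radius = 150, axis_ratio = 1,
                     posterior_arc = NULL, noise_sd = 1, imperfection_count = 0,
                     scale_bar = TRUE, seed = 4)
  img <- generate_scale_image(spec, const_spacing_profile(18))
  bg <- estimate_background(img)
  ts <- truncate_transects(extract_transects(img, spec$center, 1), bg)
  h <- 560; w <- 560
  bar_rows <- c(h - 80, h - 55); bar_cols <- c(w - 340, w - 90)
  th <- ts$angle_deg * pi / 180
  for (i in seq_along(th)) {
    r <- seq_len(ts$xmax[i]) - 1
    rows <- spec$center[1] - r * sin(th[i])
    cols <- spec$center[2] + r * cos(th[i])
    inside_bar <- rows >= bar_rows[1] & rows <= bar_rows[2] &
      cols >= bar_cols[1] & cols <= bar_cols[2]
    expect_false(any(inside_bar))
  }
})

test_that("edge indices are stable across angles on an isotropic clean scale", {
  img <- tiny_ring_image(spacing = 18)
  ctr <- attr(img, "spec")$center
  bg <- estimate_background(img)
  ts <- truncate_transects(extract_transects(img, ctr, 2), bg)
  expect_lte(diff(range(ts$xmax)), 2)
})
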