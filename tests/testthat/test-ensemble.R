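make_spectrogram <- function(z, xmax = 800, N = 200, step = 5, theta = 0) {
  structure(
    list(z = z, freqs = (1:nrow(z)) / (2 * nrow(z)),
         positions = (seq_len(ncol(z)) - 1) * step + N / 2,
         xmax = xmax, theta = theta, excluded = FALSE),
    class = "spectrogram"
  )
}

test_that("stretching a position-constant spectrogram replicates its column", {
  v <- runif(50)
  s <- make_spectrogram(matrix(v, nrow = 50, ncol = 8))
  st <- stretch_spectrogram(s, L = 100)
  expect_equal(ncol(st$z), 100)
  expect_true(all(abs(st$z - v) < 1e-12))
  expect_equal(range(st$positions), c(0, 1))
})

test_that("stretched values are linear interpolants with nearest-end extension", {
  s <- make_spectrogram(cbind(c(2, 0), c(4, 0)), xmax = 400)
  # two columns at x' = 100/400 and 105/400; midpoint of the grid between them
  st <- stretch_spectrogram(s, L = 3)
  xp <- s$positions / s$xmax
  mid_expected <- approx(xp, c(2, 4), xout = 0.5, rule = 2)$y
  expect_equal(st$z[1, 2], mid_expected)
  expect_equal(st$z[1, 1], 2)      # below first window center: clamped
  expect_equal(st$z[1, 3], 4)      # above last window center: clamped
})

test_that("stretching matches a per-row approx() oracle on random spectrograms", {
  set.seed(7)
  z <- matrix(runif(30 * 12), nrow = 30)
  s <- make_spectrogram(z, xmax = 300)
  L <- 200
  st <- stretch_spectrogram(s, L = L)
  xp <- s$positions / s$xmax
  xq <- seq(0, 1, length.out = L)
  for (r in c(1, 15, 30)) {
    expect_equal(st$z[r, ], approx(xp, z[r, ], xout = xq, rule = 2)$y)
  }
})

test_that("stretching preserves a single tone's argmax in every column", {
  set.seed(8)
  z <- matrix(runif(100 * 40, 0, 0.5), nrow = 100)
  z[10, ] <- 5 + runif(40)
  s <- make_spectrogram(z, xmax = 800)
  st <- stretch_spectrogram(s, L = 1500)
  expect_true(all(apply(st$z, 2, which.max) == 10))
})

test_that("degenerate stretch inputs error appropriately", {
  s1 <- make_spectrogram(matrix(1, 10, 1))
  expect_error(stretch_spectrogram(s1, 100), class = "scalegram_short_transect")
  s8 <- make_spectrogram(matrix(1, 10, 8))
  expect_error(stretch_spectrogram(s8, 4), "at least")
})

test_that("averaging is idempotent on identical inputs and exact on known pairs", {
  z <- matrix(runif(20 * 30), nrow = 20)
  s <- make_spectrogram(z, xmax = 400)
  st <- stretch_spectrogram(s, 100)
  avg <- average_spectrograms(list(st, st, st))
  expect_equal(avg$z, st$z)
  expect_equal(avg$n_transects, 3)
  a <- st; a$z[] <- 0
  b <- st; b$z[] <- 2
  avg2 <- average_spectrograms(list(a, b))
  expect_true(all(avg2$z == 1))
  expect_error(average_spectrograms(list()), "empty")
})

test_that("the ensemble mean lies within the cell-wise envelope of contributors", {
  set.seed(9)
  sts <- lapply(1:5, function(i) {
    s <- make_spectrogram(matrix(runif(20 * 30), nrow = 20), xmax = 400)
    stretch_spectrogram(s, 80)
  })
  avg <- average_spectrograms(sts)
  arr <- simplify2array(lapply(sts, function(s) s$z))
  expect_true(all(avg$z >= apply(arr, c(1, 2), min) - 1e-12))
  expect_true(all(avg$z <= apply(arr, c(1, 2), max) + 1e-12))
})

test_that("peak variance is zero across marine columns of an isotropic clean scale", {
  img <- tiny_ring_image(spacing = 18, size = 1300, max_radius = 610)
  ctr <- attr(img, "spec")$center
  bg <- estimate_background(img)
  ts <- truncate_transects(extract_transects(img, ctr, 5), bg)
  ens <- ensemble_spectrogram(ts, spectral_config(), L = 1500)
  expect_equal(ens$n_transects, 72)
  interior <- 300:1200
  expect_true(all(ens$sigma2[interior] == 0, na.rm = TRUE))
})

test_that("the streaming ensemble equals the explicit stretch-then-average path", {
  img <- tiny_ring_image(spacing = 16, size = 900, max_radius = 420, noise_sd = 2)
  ctr <- attr(img, "spec")$center
  bg <- estimate_background(img)
  ts <- truncate_transects(extract_transects(img, ctr, 30), bg)
  cfg <- spectral_config()
  ens <- ensemble_spectrogram(ts, cfg, L = 400)
  sts <- lapply(seq_along(ts$angle_deg), function(i) {
    s <- transect_spectrogram(ts$x[i, seq_len(ts$xmax[i])], cfg, ts$angle_deg[i])
    stretch_spectrogram(s, 400)
  })
  ref <- average_spectrograms(sts)
  expect_equal(ens$z, ref$z, tolerance = 1e-12)
  expect_equal(ens$sigma2, ref$sigma2, tolerance = 1e-12)
  expect_equal(ens$n_transects, ref$n_transects)
})

test_that("transects shorter than the window are excluded and counted", {
  x <- matrix(NA_real_, nrow = 2, ncol = 900)
  x[1, 1:800] <- cosine_transect(20, 800)
  x[2, 1:150] <- cosine_transect(20, 150)
  tset <- structure(list(x = x, angle_deg = c(0, 180), xmax = c(800L, 150L),
                         delta_theta = 180, pixels_per_mm = 302,
                         sample_id = "mix"),
                    class = "transect_set")
  ens <- ensemble_spectrogram(tset, spectral_config(), L = 300)
  expect_equal(ens$n_transects, 1)
  expect_equal(ens$n_excluded, 1)
})
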