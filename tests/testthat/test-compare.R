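test_that("equally spaced circuli interpolate to a constant profile", {
  prof <- interpolate_manual_profile(seq(5, 100, by = 5), L = 200)
  expect_true(all(abs(prof$spacing - 5) < 1e-12))
  expect_equal(range(prof$position), c(0, 1))
})

test_that("the standardized profile is the hand-computed linear interpolant", {
  # positions 2, 4, 7: spacings 2 at x' = 4/7 and 3 at x' = 1
  prof <- interpolate_manual_profile(c(2, 4, 7), L = 15)
  x <- prof$position
  expect_equal(prof$spacing[abs(x - 11 / 14) < 1e-9], 2.5)
  expect_true(all(abs(prof$spacing[x <= 4 / 7] - 2) < 1e-12))  # clamped head
  expect_equal(prof$spacing[15], 3)
})

test_that("interpolation is exact at measurement knots", {
  cum <- c(2, 4, 7, 9, 10)
  prof <- interpolate_manual_profile(cum, L = 101)
  knots_x <- cum[-1] / max(cum)
  spac <- diff(cum)
  for (i in seq_along(knots_x)) {
    got <- approx(prof$position, prof$spacing, xout = knots_x[i])$y
    expect_equal(got, spac[i], tolerance = 0.02)
  }
})

test_that("degenerate manual measurements are rejected", {
  expect_error(interpolate_manual_profile(5), "at least 2")
  expect_error(interpolate_manual_profile(c(3, 2, 5)), "strictly increasing")
})

test_that("group summaries give exact two-point and zero-spread results", {
  P <- profile_matrix(list(rep(1, 10), rep(3, 10)),
                      tibble::tibble(sample_id = c("a", "b"), year = 2005))
  gs <- group_summary(P)
  expect_true(all(gs$mean == 2))
  expect_true(all(abs(gs$sd - sqrt(2)) < 1e-12))
  expect_true(all(abs(gs$cv - sqrt(2) / 2) < 1e-12))
  P2 <- profile_matrix(list(rep(4, 10), rep(4, 10)),
                       tibble::tibble(sample_id = c("a", "b"), year = 2005))
  gs2 <- group_summary(P2)
  expect_true(all(gs2$sd == 0) && all(gs2$cv == 0))
})

test_that("CV approaches noise-to-mean ratio in a simulated cohort", {
  set.seed(20)
  base <- 10 + 3 * sin(seq(0, pi, length.out = 60))
  tau <- 0.5
  rows <- lapply(1:50, function(i) base + rnorm(60, sd = tau))
  P <- profile_matrix(rows, tibble::tibble(sample_id = as.character(1:50),
                                           year = 2010))
  gs <- group_summary(P)
  expect_lt(max(abs(gs$cv - tau / gs$mean)), 0.02)
})

test_that("rank-1 data loads entirely on the first component", {
  set.seed(21)
  v <- rnorm(40)
  rows <- lapply(1:12, function(i) 5 + i * v)
  P <- profile_matrix(rows, tibble::tibble(sample_id = as.character(1:12)))
  p <- pca_profiles(P)
  expect_gt(p$explained_variance[1], 1 - 1e-10)
})

test_that("PCA separates two clusters along PC1, matching a 2-D eigen oracle", {
  set.seed(22)
  # embed a two-cluster 2-D configuration in profile space
  n <- 20
  offsets <- c(rep(-4, n / 2), rep(4, n / 2)) + rnorm(n, sd = 0.3)
  jitter <- rnorm(n, sd = 0.3)
  e1 <- c(1, rep(0, 29)); e2 <- c(0, 1, rep(0, 28))
  rows <- lapply(1:n, function(i) 10 + offsets[i] * e1 + jitter[i] * e2)
  P <- profile_matrix(rows, tibble::tibble(sample_id = as.character(1:n)))
  p <- pca_profiles(P)
  grp <- rep(c(1, 2), each = n / 2)
  expect_true(max(p$scores$PC1[grp == 1]) < min(p$scores$PC1[grp == 2]) ||
                min(p$scores$PC1[grp == 1]) > max(p$scores$PC1[grp == 2]))
  # oracle: eigendecomposition of the 2x2 covariance of the embedded coords
  S <- stats::cov(cbind(offsets, jitter))
  ev <- eigen(S, symmetric = TRUE)$values
  expect_equal(p$explained_variance[1], ev[1] / sum(ev), tolerance = 1e-8)
})

test_that("explained-variance fractions are a non-increasing sub-unit sequence", {
  set.seed(23)
  rows <- lapply(1:15, function(i) rnorm(25))
  P <- profile_matrix(rows, tibble::tibble(sample_id = as.character(1:15)))
  p <- pca_profiles(P)
  expect_lte(sum(p$explained_variance), 1 + 1e-10)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_error(pca_profiles(profile_matrix(list(rep(1, 5), rep(1, 5)),
                                           tibble::tibble(sample_id = c("a", "b")))),
               "zero variance")
})

test_that("PCA scores are row-order invariant up to sign", {
  set.seed(24)
  rows <- lapply(1:10, function(i) rnorm(20))
  info <- tibble::tibble(sample_id = sprintf("s%02d", 1:10))
  p1 <- pca_profiles(profile_matrix(rows, info))
  perm <- sample(10)
  p2 <- pca_profiles(profile_matrix(rows[perm], info[perm, ]))
  s1 <- p1$scores[order(p1$scores$sample_id), ]
  s2 <- p2$scores[order(p2$scores$sample_id), ]
  same_or_flipped <- function(a, b) {
    isTRUE(all.equal(a, b, tolerance = 1e-8)) ||
      isTRUE(all.equal(a, -b, tolerance = 1e-8))
  }
  expect_true(same_or_flipped(s1$PC1, s2$PC1))
  expect_true(same_or_flipped(s1$PC2, s2$PC2))
})

test_that("well-separated cohorts get disjoint 95% ellipses in PC space", {
  set.seed(25)
  base_a <- 8 + 4 * sin(seq(0, 2 * pi, length.out = 50))
  base_b <- 8 + 4 * cos(seq(0, 2 * pi, length.out = 50))
  rows <- c(lapply(1:15, function(i) base_a + rnorm(50, sd = 0.2)),
            lapply(1:15, function(i) base_b + rnorm(50, sd = 0.2)))
  info <- tibble::tibble(sample_id = sprintf("f%02d", 1:30),
                         year = rep(c(2005, 2010), each = 15))
  p <- pca_profiles(profile_matrix(rows, info))
  sc <- p$scores
  ell <- lapply(split(sc[, c("PC1", "PC2")], sc$year), confidence_ellipse)
  ctr <- lapply(ell, function(e) c(mean(e$x), mean(e$y)))
  rad <- mapply(function(e, c) max(sqrt((e$x - c[1])^2 + (e$y - c[2])^2)),
                ell, ctr)
  d <- sqrt(sum((ctr[[1]] - ctr[[2]])^2))
  expect_gt(d, sum(rad))
})
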