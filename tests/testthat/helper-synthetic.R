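# Shared builders for synthetic fixtures. Everything is generated in code;
# sizes are kept small except where a check is explicitly about full-scale
# behavior.

# Direct-summation DFT oracle: |X(k)| for k = 1..N/2 of the mean-removed,
# taper-multiplied window. Deliberately naive (O(N^2)); the independent
# reference for the fast transform.
dft_oracle <- function(x, taper = rep(1, length(x))) {
  n <- length(x)
  xw <- (x - mean(x)) * taper
  ks <- 1:(n %/% 2)
  vapply(ks, function(k) {
    ang <- -2 * pi * k * (0:(n - 1)) / n
    sqrt(sum(xw * cos(ang))^2 + sum(xw * sin(ang))^2)
  }, numeric(1))
}

# Small isotropic ring scale with constant spacing; clean by default.
const_spacing_profile <- function(spacing = 20) {
  growth_profile(function(u) rep(spacing, length(u)),
                 fw_end = 0.1, marine_end = 0.95)
}

tiny_scale_spec <- function(size = 560, max_radius = 240, noise_sd = 0, ...) {
  scale_spec(image_size = c(size, size), max_radius = max_radius,
             axis_ratio = 1, posterior_arc = NULL, noise_sd = noise_sd,
             imperfection_count = 0, scale_bar = FALSE, ...)
}

tiny_ring_image <- function(spacing = 20, size = 560, max_radius = 240,
                            seed = 1, noise_sd = 0, ...) {
  generate_scale_image(tiny_scale_spec(size, max_radius, noise_sd = noise_sd,
                                       seed = seed, ...),
                       const_spacing_profile(spacing),
                       sample_id = "tiny")
}

# Salmon-like profile with a single smooth seasonal modulation in the marine
# phase; within-window frequency drift stays below one bin so spectral
# tracking is exact.
modulated_profile <- function(fw_end = 0.12, marine_end = 0.9,
                              fw_spacing = 5, return_spacing = 8,
                              mid = 17, amp = 5) {
  force(fw_end); force(marine_end)
  fn <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    ifelse(u < fw_end, fw_spacing,
           ifelse(u > marine_end, return_spacing,
                  mid - amp * cos(2 * pi * (u - fw_end) / (marine_end - fw_end))))
  }
  growth_profile(fn, fw_end = fw_end, marine_end = marine_end)
}

# Pure cosine transect: period in pixels, n samples, amplitude about a
# scale-like mean level.
cosine_transect <- function(period, n, amplitude = 60, level = 150) {
  level + amplitude * cos(2 * pi * (0:(n - 1)) / period)
}
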