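#' Specification of a synthetic scale image
#'
#' Collects the geometric and photometric parameters of a simulated scale
#' photograph. Defaults reproduce the acquisition conditions of the salmon
#' image archive the method was designed for: 2560 x 1920 px frames at
#' 302 px/mm with the whole scale in frame, a bright uniform background with
#' a scale-bar artifact in the lower-right corner, mild elliptical anisotropy,
#' a weakly patterned posterior arc, and a few localized imperfections.
#'
#' @param image_size `(height, width)` in pixels.
#' @param center `(row, col)` of the scale focus, pixels; defaults to the
#'   image center.
#' @param max_radius Rim radius along the reference (minor) axis, pixels.
#' @param axis_ratio Elliptical anisotropy `>= 1`; ring radii along the major
#'   (horizontal) axis are `axis_ratio` times those along the minor axis.
#' @param posterior_arc Angular interval in degrees `(from, to)` of the
#'   posterior exposed portion of the scale, or `NULL`.
#' @param posterior_attenuation Ridge-depth multiplier inside the posterior
#'   arc. The posterior field of a real scale lacks the crisp circuli
#'   patterning of the anterior field but is not optically featureless; the
#'   default 0.2 leaves weak, low-amplitude ridge energy there. Set 0 for a
#'   literally ridge-free arc.
#' @param noise_sd Gaussian pixel noise standard deviation, saturation units.
#' @param imperfection_count Number of localized ridge imperfections.
#' @param imperfection_amplitude Radial displacement amplitude of an
#'   imperfection, pixels.
#' @param flank_jitter_sd Standard deviation of the per-angle log spacing
#'   factor applied outside the marine phase (dimensionless; factors are
#'   clamped to `[0.5, 2]`). Each transect keeps a coherent freshwater/return
#'   tone but at an angle-specific frequency, emulating the broad
#'   across-transect peak distributions that poorly resolved narrow circuli
#'   produce in real images. 0 disables it.
#' @param background_level Background saturation, 0-255.
#' @param base_level Scale-interior saturation between circuli, 0-255.
#' @param ridge_depth Saturation drop at a circulus crest, 0-255.
#' @param scale_bar Draw a dark scale-bar artifact in the lower-right
#'   background corner?
#' @param angle_bin Angular resolution (degrees) at which per-angle ring
#'   perturbations (jitter, imperfections) and ground truth are discretized.
#' @param seed Integer seed making the rendered image reproducible.
#'
#' @return An object of class `scale_spec` (a validated list).
#' @export
scale_spec <- function(image_size = c(1920, 2560),
                       center = NULL,
                       max_radius = 680,
                       axis_ratio = 1.25,
                       posterior_arc = c(130, 230),
                       posterior_attenuation = 0.2,
                       noise_sd = 3,
                       imperfection_count = 3,
                       imperfection_amplitude = 4,
                       flank_jitter_sd = 0,
                       background_level = 235,
                       base_level = 185,
                       ridge_depth = 90,
                       scale_bar = TRUE,
                       angle_bin = 0.5,
                       seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 16)) {
    abort("`image_size` must be (height, width), both >= 16 px.")
  }
  if (is.null(center)) center <- (image_size + 1) / 2
  if (length(center) != 2L || any(center <= 1) || center[1] >= image_size[1] ||
      center[2] >= image_size[2]) {
    abort("`center` must lie strictly inside the image.")
  }
  stopifnot_scalar_(axis_ratio, "axis_ratio", lower = 1)
  stopifnot_scalar_(background_level, "background_level", 0, 255)
  stopifnot_scalar_(base_level, "base_level", 0, 255)
  stopifnot_scalar_(max_radius, "max_radius", lower = 8)
  if (center[1] - max_radius < 1 || center[1] + max_radius > image_size[1] ||
      center[2] - max_radius * axis_ratio < 1 ||
      center[2] + max_radius * axis_ratio > image_size[2]) {
    abort("scale does not fit: `max_radius * axis_ratio` exceeds the frame.")
  }
  stopifnot_scalar_(posterior_attenuation, "posterior_attenuation", 0, 1)
  if (!is.null(posterior_arc) && (length(posterior_arc) != 2L ||
      any(posterior_arc < 0) || any(posterior_arc > 360) ||
      posterior_arc[1] >= posterior_arc[2])) {
    abort("`posterior_arc` must be (from, to) degrees with from < to in [0, 360].")
  }
  structure(
    list(image_size = as.integer(image_size), center = as.numeric(center),
         max_radius = max_radius, axis_ratio = axis_ratio,
         posterior_arc = posterior_arc,
         posterior_attenuation = posterior_attenuation, noise_sd = noise_sd,
         imperfection_count = as.integer(imperfection_count),
         imperfection_amplitude = imperfection_amplitude,
         flank_jitter_sd = flank_jitter_sd,
         background_level = background_level, base_level = base_level,
         ridge_depth = ridge_depth, scale_bar = isTRUE(scale_bar),
         angle_bin = angle_bin, seed = as.integer(seed)),
    class = "scale_spec"
  )
}

# Elliptical direction factor: rings are ellipses with semi-major
# a * r along +x and semi-minor r along +y, so the radius of ring r at polar
# angle theta (radians, CCW from +x) is r * s(theta).
ellipse_factor_ <- function(theta, a) {
  a / sqrt(cos(theta)^2 + (a * sin(theta))^2)
}

#' Render a synthetic scale image with ground truth
#'
#' Draws concentric quasi-elliptical dark ridges whose radial positions
#' accumulate the profile's inter-circulus spacing, attenuates (or removes)
#' ridges in the posterior arc, applies localized imperfections and optional per-angle flank
#' jitter, adds Gaussian pixel noise, quantizes to 8 bits, and attaches the
#' exact ring radii per angle as ground truth.
#'
#' Each circulus is rendered as a dark band with a Gaussian radial
#' cross-section whose width tracks the local spacing, producing the
#' quasi-sinusoidal saturation waveform the spectral analysis assumes.
#'
#' @param spec A [scale_spec()].
#' @param profile A [growth_profile()].
#' @param pixels_per_mm Image magnification recorded on the result.
#' @param sample_id,year,sample_date,fork_length_cm Metadata recorded on the
#'   result.
#'
#' @return A [scale_image] whose `ground_truth` attribute is a tibble with
#'   columns `angle_deg` (bin center), `ring` (index from the focus),
#'   `radius_px` (exact radius along that angle) and `u` (normalized radius
#'   along the reference axis); the `phase_bounds` attribute carries the
#'   profile's normalized phase bounds.
#' @export
generate_scale_image <- function(spec, profile, pixels_per_mm = 302,
                                 sample_id = "synthetic", year = NA,
                                 sample_date = NA, fork_length_cm = NA) {
  if (!inherits(spec, "scale_spec")) abort("`spec` must be a scale_spec.")
  if (!inherits(profile, "growth_profile")) abort("`profile` must be a growth_profile.")

  h <- spec$image_size[1]; w <- spec$image_size[2]
  a <- spec$axis_ratio
  n_bin <- as.integer(round(360 / spec$angle_bin))
  bin_centers <- (seq_len(n_bin) - 0.5) * spec$angle_bin   # degrees
  s_b <- ellipse_factor_(bin_centers * pi / 180, a)
  R_b <- spec$max_radius * s_b                             # rim radius per angle

  # Ring positions per angle: the spacing law s(u) is the SAME function of
  # relative radial position u = r / R(theta) at every angle; longer axes
  # simply accumulate more rings before reaching their rim (circuli are
  # created/destroyed, not stretched). Flank jitter perturbs the apparent
  # flank spacing per angle (each transect keeps a coherent flank tone, but
  # at an angle-specific frequency), drawn before any other randomness.
  with_seed_(spec$seed, {
  g_fw <- rep(1, n_bin); g_ret <- rep(1, n_bin)
  if (spec$flank_jitter_sd > 0) {
    g_fw <- pmin(pmax(exp(rnorm(n_bin, sd = spec$flank_jitter_sd)), 0.5), 2)
    g_ret <- pmin(pmax(exp(rnorm(n_bin, sd = spec$flank_jitter_sd)), 0.5), 2)
  }
  cum <- spacing_cumulative_(profile)
  rings_by_bin <- lapply(seq_len(n_bin), function(b) {
    ring_u_positions_phased_(cum, R_b[b], profile$fw_end, profile$marine_end,
                             g_fw = g_fw[b], g_ret = g_ret[b])
  })
  K_b <- lengths(rings_by_bin)
  if (any(K_b < 2)) abort("profile yields fewer than 2 rings on some transects.")

  bin_id <- rep.int(seq_len(n_bin), K_b)
  ring_idx <- unlist(lapply(K_b, seq_len), use.names = FALSE)
  u_all <- unlist(rings_by_bin, use.names = FALSE)
  r_all <- u_all * R_b[bin_id]
  spacing_all <- profile$spacing_fn(u_all) *
    ifelse(u_all < profile$fw_end, g_fw[bin_id],
           ifelse(u_all > profile$marine_end, g_ret[bin_id], 1))
  width_all <- pmin(pmax(0.22 * spacing_all, 0.8), 3.5)

    delta <- numeric(length(r_all))
    if (spec$imperfection_count > 0) {
      phi <- stats::runif(spec$imperfection_count, 0, 360)
      uc <- stats::runif(spec$imperfection_count, 0.2, 0.9)
      amp <- stats::runif(spec$imperfection_count, 0.5, 1) *
        spec$imperfection_amplitude *
        sample(c(-1, 1), spec$imperfection_count, replace = TRUE)
      ang_all <- bin_centers[bin_id]
      for (i in seq_len(spec$imperfection_count)) {
        dang <- pmin(abs(ang_all - phi[i]), 360 - abs(ang_all - phi[i]))
        delta <- delta + amp[i] * exp(-0.5 * (dang / 3)^2) *   # ~6 deg sector
          exp(-0.5 * ((u_all - uc[i]) / 0.05)^2)
      }
    }
    centers_all <- r_all + delta

    # per-angle-bin saturation profile on a fine radius grid (physical px)
    in_posterior <- rep(FALSE, n_bin)
    if (!is.null(spec$posterior_arc)) {
      in_posterior <- bin_centers >= spec$posterior_arc[1] &
        bin_centers <= spec$posterior_arc[2]
    }
    depth_bin <- rep(spec$ridge_depth, n_bin)
    depth_bin[in_posterior] <- spec$ridge_depth * spec$posterior_attenuation
    depth_all <- depth_bin[bin_id]

    drho <- 0.25
    ngrid <- as.integer(ceiling((max(R_b) + 4) / drho)) + 1L
    keep <- depth_all > 0
    prof <- matrix(spec$base_level, nrow = n_bin, ncol = ngrid)
    if (any(keep)) {
      ctr <- centers_all[keep]; wd <- width_all[keep]; dp <- depth_all[keep]
      bi <- bin_id[keep]
      nsup <- 2L * as.integer(ceiling(4 * max(wd) / drho)) + 1L
      i0 <- pmax(1L, as.integer(floor((ctr - 4 * wd) / drho)) + 1L)
      idx <- outer(i0, 0:(nsup - 1L), "+")
      idx[idx > ngrid] <- ngrid
      rho <- (idx - 1) * drho
      bump <- dp * exp(-0.5 * ((rho - ctr) / wd)^2)
      lin <- bi + (idx - 1L) * n_bin                 # column-major into prof
      agg <- rowsum(as.vector(bump), as.vector(lin))
      at <- as.integer(rownames(agg))
      prof[at] <- prof[at] - agg[, 1]
      prof[prof < 0] <- 0
    }

    # evaluate per pixel: angle bin + physical radius, linear interp in radius
    rr <- seq_len(h) - spec$center[1]
    cc <- seq_len(w) - spec$center[2]
    dx <- matrix(cc, nrow = h, ncol = w, byrow = TRUE)
    dy <- matrix(-rr, nrow = h, ncol = w)            # +y is up (CCW from +x)
    rho_px <- sqrt(dx^2 + dy^2)
    theta <- (atan2(dy, dx) * 180 / pi) %% 360
    bin <- pmin(pmax(as.integer(floor(theta / spec$angle_bin)) + 1L, 1L), n_bin)

    img <- matrix(spec$background_level, nrow = h, ncol = w)
    inside <- rho_px <= R_b[bin]
    gi <- rho_px[inside] / drho
    i0p <- pmin(as.integer(floor(gi)) + 1L, ngrid - 1L)
    frac <- gi - (i0p - 1L)
    b <- bin[inside]
    img[inside] <- prof[cbind(b, i0p)] * (1 - frac) + prof[cbind(b, i0p + 1L)] * frac

    if (spec$scale_bar) {
      bar_rows <- max(1L, h - 80L):max(1L, h - 55L)
      bar_cols <- max(1L, w - 340L):max(1L, w - 90L)
      img[bar_rows, bar_cols] <- 25
    }

    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, sd = spec$noise_sd), nrow = h)
    }
    img <- round(pmin(pmax(img, 0), 255))

    gt <- tibble::tibble(
      angle_deg = bin_centers[bin_id],
      ring = ring_idx,
      radius_px = centers_all,
      u = u_all
    )

    out <- scale_image(img, pixels_per_mm = pixels_per_mm,
                       sample_id = sample_id, year = year,
                       sample_date = sample_date,
                       fork_length_cm = fork_length_cm)
    attr(out, "ground_truth") <- gt
    attr(out, "phase_bounds") <- c(fw_end = profile$fw_end,
                                   marine_end = profile$marine_end)
    attr(out, "spec") <- spec
    out
  })
}

#' Ground truth attached to a synthetic image
#'
#' @param img A synthetic [scale_image] from [generate_scale_image()].
#' @return The ground-truth tibble (`angle_deg`, `ring`, `radius_px`, `u`).
#' @export
ground_truth <- function(img) {
  gt <- attr(img, "ground_truth")
  if (is.null(gt)) abort("`img` carries no ground truth (not a synthetic image?).")
  gt
}

#' Simulated operator measurements along one transect
#'
#' Emulates the classical protocol in which an analyst records cumulative
#' circulus positions along a single radial line: the ground-truth ring radii
#' on the transect closest to `angle_deg` plus independent Gaussian operator
#' error. Noisy points that break monotonicity are re-drawn individually (up
#' to `max_attempts` times each) so the cumulative distances remain strictly
#' increasing, as a real measurement sequence must be.
#'
#' @param img A synthetic [scale_image] with ground truth.
#' @param angle_deg Transect angle, degrees.
#' @param operator_noise_sd Measurement error standard deviation, pixels.
#' @param seed Integer seed.
#' @param max_attempts Re-draws allowed per point before failing.
#'
#' @return A tibble with columns `circulus` and `cumulative_distance_px`,
#'   strictly increasing; the `units` attribute is `"px"`.
#' @export
generate_manual_measurements <- function(img, angle_deg = 0,
                                         operator_noise_sd = 1,
                                         seed = 1L, max_attempts = 100L) {
  gt <- ground_truth(img)
  bins <- unique(gt$angle_deg)
  nearest <- bins[which.min(pmin(abs(bins - angle_deg %% 360),
                                 360 - abs(bins - angle_deg %% 360)))]
  radii <- sort(gt$radius_px[gt$angle_deg == nearest])
  if (length(radii) < 2) abort("need at least 2 rings on the chosen transect.")
  with_seed_(seed, {
    meas <- radii + rnorm(length(radii), sd = operator_noise_sd)
    for (i in seq_along(meas)) {
      attempt <- 0L
      lower <- if (i > 1) meas[i - 1] else 0
      while (meas[i] <= lower && attempt < max_attempts) {
        meas[i] <- radii[i] + rnorm(1, sd = operator_noise_sd)
        attempt <- attempt + 1L
      }
      if (meas[i] <= lower) {
        abort("could not draw a monotone measurement sequence; reduce `operator_noise_sd`.")
      }
    }
    out <- tibble::tibble(circulus = seq_along(meas),
                          cumulative_distance_px = meas)
    attr(out, "units") <- "px"
    attr(out, "angle_deg") <- nearest
    out
  })
}
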