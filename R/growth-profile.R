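#' Radial growth profile for a synthetic scale
#'
#' A growth profile maps normalized radial position `u` (0 at the scale focus,
#' 1 at the rim along the reference axis) to the local inter-circulus spacing
#' in pixels, and carries the normalized positions that delimit the three
#' life-history phases read off a one-sea-winter salmon scale: freshwater
#' growth near the focus, the first marine year, and the return migration at
#' the rim.
#'
#' @param spacing_fn Function of one argument; `spacing_fn(u)` must return the
#'   inter-circulus spacing in pixels for `u` in `[0, 1]`, vectorized, and
#'   strictly greater than 2 px everywhere (two pixels is the Nyquist limit
#'   below which rings cannot be resolved).
#' @param fw_end,marine_end Normalized radial positions of the
#'   freshwater/marine and marine/return transitions, with
#'   `0 <= fw_end < marine_end <= 1`.
#'
#' @return An object of class `growth_profile`: a list with elements
#'   `spacing_fn`, `fw_end` and `marine_end`.
#' @seealso [salmon_growth_profile()] for a ready-made profile,
#'   [ring_radii()] to accumulate spacings into ring positions.
#' @export
growth_profile <- function(spacing_fn, fw_end, marine_end) {
  if (!is.function(spacing_fn)) abort("`spacing_fn` must be a function.")
  stopifnot_scalar_(fw_end, "fw_end", 0, 1)
  stopifnot_scalar_(marine_end, "marine_end", 0, 1)
  if (fw_end >= marine_end) abort("`fw_end` must be < `marine_end`.")
  u <- seq(0, 1, length.out = 512)
  s <- spacing_fn(u)
  if (length(s) != length(u) || any(!is.finite(s))) {
    abort("`spacing_fn` must be vectorized and finite on [0, 1].")
  }
  if (any(s <= 2)) {
    abort("`spacing_fn` must exceed 2 px everywhere: narrower rings are not resolvable.")
  }
  structure(
    list(spacing_fn = spacing_fn, fw_end = fw_end, marine_end = marine_end),
    class = "growth_profile"
  )
}

#' One-sea-winter salmon growth profile
#'
#' Default spacing profile emulating the circuli sequence of an Atlantic
#' salmon that spent one winter at sea: tightly spaced freshwater circuli near
#' the focus, a wide-spaced ocean summer, a narrow-spaced ocean winter band, a
#' short second spring widening, and narrow return-phase circuli at the rim.
#' Segments are joined by cosine ramps so the saturation waveform stays
#' quasi-sinusoidal in radius.
#'
#' @param fw_spacing Freshwater inter-circulus spacing, pixels.
#' @param summer_spacing Peak ocean-summer spacing, pixels.
#' @param winter_spacing Ocean-winter spacing, pixels.
#' @param return_spacing Return-phase spacing at the rim, pixels.
#' @param fw_end,marine_end Phase bounds as in [growth_profile()].
#'
#' @return A [growth_profile()] object.
#' @examples
#' p <- salmon_growth_profile()
#' p$spacing_fn(c(0.05, 0.4, 0.8, 0.95))
#' @export
salmon_growth_profile <- function(fw_spacing = 5,
                                  summer_spacing = 22,
                                  winter_spacing = 11,
                                  return_spacing = 8,
                                  fw_end = 0.12,
                                  marine_end = 0.9) {
  # knots (u, spacing): fw plateau, ramp to summer peak, dip to winter,
  # modest spring recovery, taper into the return phase
  m0 <- fw_end
  m1 <- marine_end
  knots_u <- c(0, m0 * 0.8, m0,
               m0 + 0.25 * (m1 - m0), m0 + 0.45 * (m1 - m0),
               m0 + 0.70 * (m1 - m0), m0 + 0.88 * (m1 - m0),
               m1, 1)
  knots_s <- c(fw_spacing, fw_spacing, fw_spacing + 0.25 * (summer_spacing - fw_spacing),
               summer_spacing, summer_spacing * 0.92,
               winter_spacing, winter_spacing + 0.5 * (summer_spacing - winter_spacing) * 0.6,
               return_spacing, return_spacing * 0.9)
  fn <- cosine_ramp_fn_(knots_u, knots_s)
  growth_profile(fn, fw_end = fw_end, marine_end = marine_end)
}

# Piecewise cosine-smoothed interpolation through (u, s) knots: C1 at knots,
# monotone within each segment, so local spacing drifts slowly on the scale of
# an analysis window.
cosine_ramp_fn_ <- function(ku, ks) {
  force(ku); force(ks)
  function(u) {
    u <- pmin(pmax(u, ku[1]), ku[length(ku)])
    i <- findInterval(u, ku, all.inside = TRUE)
    t <- (u - ku[i]) / (ku[i + 1] - ku[i])
    w <- (1 - cos(pi * t)) / 2
    ks[i] * (1 - w) + ks[i + 1] * w
  }
}

#' Ring radii implied by a growth profile
#'
#' Accumulates `spacing_fn` outward from the focus along the reference (minor)
#' axis: the first circulus sits one local spacing from the focus and each
#' subsequent circulus one local spacing beyond the previous, until
#' `max_radius` is reached.
#'
#' @param profile A [growth_profile()].
#' @param max_radius Rim radius along the reference axis, pixels.
#' @return Numeric vector of ring radii in pixels, strictly increasing,
#'   all `<= max_radius`.
#' @export
ring_radii <- function(profile, max_radius) {
  stopifnot_scalar_(max_radius, "max_radius", lower = 1)
  out <- ring_u_positions_(profile, max_radius) * max_radius
  if (length(out) < 2) abort("profile yields fewer than 2 rings inside `max_radius`.")
  out
}

# Relative ring positions u_k in (0, 1] for a transect whose rim lies at
# radius R: the cumulative ring count at relative position u is
# k(u) = R * integral_0^u du' / spacing(u'), so ring k sits at the position
# where that integral equals k / R. Inverted on a fine grid.
ring_u_positions_ <- function(profile, R) {
  cum <- spacing_cumulative_(profile)
  K <- floor(R * cum$g[length(cum$g)])
  if (K < 1) return(numeric(0))
  approx(cum$g, cum$u, xout = (1:K) / R)$y
}

spacing_cumulative_ <- function(profile) {
  u <- seq(0, 1, length.out = 2048L)
  inv <- 1 / profile$spacing_fn(u)
  list(u = u, g = c(0, cumsum((inv[-1] + inv[-length(inv)]) / 2) * diff(u)))
}

# Phase-wise ring positions: marine rings come from the unperturbed law (so
# they are identical for every transect with the same rim radius), while
# freshwater and return rings take per-angle spacing factors g_fw / g_ret.
ring_u_positions_phased_ <- function(cum, R, fw_end, marine_end,
                                     g_fw = 1, g_ret = 1) {
  ginv <- function(q) approx(cum$g, cum$u, xout = q)$y
  g_end <- cum$g[length(cum$g)]
  g_m1 <- approx(cum$u, cum$g, xout = marine_end)$y
  K <- max(1, floor(R * g_end))
  base <- ginv(pmin((1:K) / R, g_end))
  marine <- base[!is.na(base) & base >= fw_end & base <= marine_end]
  fw <- ginv(pmin(g_fw * (1:K) / R, g_end))
  fw <- fw[!is.na(fw) & fw < fw_end]
  # return rings continue from the last marine lattice point, so an
  # unjittered profile reproduces the base lattice with no seam
  g_anchor <- floor(R * g_m1) / R
  rt <- ginv(pmin(g_anchor + g_ret * (1:K) / R, g_end))
  rt <- rt[!is.na(rt) & rt > marine_end & rt < 1]
  sort(c(fw, marine, rt))
}

#' @export
print.growth_profile <- function(x, ...) {
  cat("<growth_profile>\n")
  cat(sprintf("  phases (normalized radius): freshwater [0, %.2f), marine [%.2f, %.2f), return [%.2f, 1]\n",
              x$fw_end, x$fw_end, x$marine_end, x$marine_end))
  u <- c(0.05, (x$fw_end + x$marine_end) / 2, 0.97)
  cat(sprintf("  spacing at u = %.2f / %.2f / %.2f: %.1f / %.1f / %.1f px\n",
              u[1], u[2], u[3],
              x$spacing_fn(u[1]), x$spacing_fn(u[2]), x$spacing_fn(u[3])))
  invisible(x)
}
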