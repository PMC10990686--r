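#' Interpolate manual inter-circuli measurements to a standard axis
#'
#' Classical scale reading records cumulative circulus positions along a
#' single transect, giving a nonlinear axis (e.g. 2-4-7-12-14-16 mm). The
#' successive differences are the inter-circuli spacings; the spacing between
#' circuli `i-1` and `i` is placed at the rescaled position of circulus `i`
#' (cumulative distance divided by the transect maximum) and linearly
#' interpolated onto `L` evenly spaced points of `[0, 1]`, the same
#' standardized axis the stretched spectrograms use. Beyond the first and
#' last spacing knots the nearest value is carried.
#'
#' @param measurements A tibble/data.frame with a `cumulative_distance_px` or
#'   `cumulative_distance` column (strictly increasing; at least 2 circuli),
#'   e.g. from [generate_manual_measurements()], or a bare numeric vector of
#'   cumulative distances.
#' @param L Number of standardized positions.
#' @return A tibble with columns `position` (0-1) and `spacing` (input
#'   units).
#' @export
interpolate_manual_profile <- function(measurements, L = 1500) {
  cum <- if (is.numeric(measurements)) {
    measurements
  } else {
    nm <- intersect(c("cumulative_distance_px", "cumulative_distance"),
                    names(measurements))
    if (length(nm) == 0) abort("no cumulative-distance column found.")
    measurements[[nm[1]]]
  }
  if (length(cum) < 2) abort("at least 2 circuli are required.")
  if (any(diff(cum) <= 0)) abort("cumulative distances must be strictly increasing.")
  spacing <- diff(cum)
  xp <- cum[-1] / cum[length(cum)]
  xq <- seq(0, 1, length.out = L)
  val <- if (length(spacing) == 1) {
    rep(spacing, L)
  } else {
    approx(xp, spacing, xout = xq, rule = 2)$y
  }
  tibble::tibble(position = xq, spacing = val)
}

#' Cohort profile matrix
#'
#' Stacks per-fish standardized spacing profiles (all of length `L`) into a
#' fish x position matrix with group labels and a sampling-date ordering
#' key, the container for cohort summaries and PCA.
#'
#' @param profiles A list of numeric vectors (one per fish, equal length) or
#'   of tibbles with a `spacing` column as returned by
#'   [interpolate_manual_profile()].
#' @param info A data.frame/tibble with one row per fish; columns `sample_id`
#'   and (optionally) `year` and `sample_date`.
#' @return An object of class `profile_matrix`: `values` (matrix), `info`
#'   (tibble, rows ordered by year then sample date) and `positions`.
#' @export
profile_matrix <- function(profiles, info) {
  rows <- lapply(profiles, function(p) {
    if (is.numeric(p)) p else p$spacing
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) abort("all profiles must have the same length.")
  if (length(rows) != nrow(info)) abort("`info` must have one row per profile.")
  values <- do.call(rbind, rows)
  info <- tibble::as_tibble(info)
  if (!"sample_id" %in% names(info)) abort("`info` must contain `sample_id`.")
  ord <- seq_len(nrow(info))
  if (all(c("year", "sample_date") %in% names(info))) {
    ord <- order(info$year, info$sample_date)
  } else if ("year" %in% names(info)) {
    ord <- order(info$year)
  }
  structure(
    list(values = values[ord, , drop = FALSE], info = info[ord, ],
         positions = seq(0, 1, length.out = ncol(values))),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d fish x %d positions\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname tidy_scalegram
#' @export
tidy.profile_matrix <- function(x, ...) {
  n <- nrow(x$values); L <- ncol(x$values)
  out <- tibble::tibble(
    sample_id = rep(x$info$sample_id, times = L),
    position = rep(x$positions, each = n),
    spacing = as.vector(x$values)
  )
  if ("year" %in% names(x$info)) out$year <- rep(x$info$year, times = L)
  out
}

#' Per-group mean, spread and coefficient of variation by position
#'
#' Column-wise mean, standard deviation and CV (= sd/mean) of the spacing
#' profiles within each group (year), the cohort summaries displayed as the
#' mean growth pattern with a 1-sd envelope and the CV-by-position curve.
#'
#' @param P A [profile_matrix()].
#' @param group Name of the grouping column in `P$info` (default `"year"`;
#'   a single pseudo-group is used when absent).
#' @return A tibble with columns `group`, `position`, `mean`, `sd`, `cv`
#'   (`cv` is `NA` where the mean is 0).
#' @export
group_summary <- function(P, group = "year") {
  g <- if (group %in% names(P$info)) P$info[[group]] else rep("all", nrow(P$values))
  purrr::map_dfr(unique(g), function(gi) {
    rows <- P$values[g == gi, , drop = FALSE]
    if (nrow(rows) < 2) {
      abort(sprintf("group '%s' has fewer than 2 fish.", format(gi)))
    }
    m <- colMeans(rows)
    s <- apply(rows, 2, sd)
    tibble::tibble(group = gi, position = P$positions, mean = m, sd = s,
                   cv = ifelse(m == 0, NA_real_, s / m))
  })
}

#' PCA of standardized growth profiles
#'
#' Mean-centered (unscaled) principal component analysis of the fish x
#' position spacing matrix, used to compare how much cohort structure each
#' measurement representation captures.
#'
#' @param P A [profile_matrix()].
#' @param n_components Number of components to keep in the scores.
#' @return An object of class `profile_pca`: `scores` (tibble with
#'   `sample_id`, group columns and `PC1..PCk`), `explained_variance`
#'   (fractions, all components), and the underlying `prcomp` fit.
#' @export
pca_profiles <- function(P, n_components = 2) {
  if (nrow(P$values) < 2) abort("PCA needs at least 2 fish.")
  total_var <- sum(apply(P$values, 2, var))
  if (total_var == 0) abort("profiles are constant: zero variance, no PCA.")
  fit <- prcomp(P$values, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(P$info[intersect(c("sample_id", "year", "sample_date"),
                                              names(P$info))],
                             scores)
  structure(list(scores = scores, explained_variance = ev, fit = fit),
            class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  cat(sprintf("<profile_pca> %d samples; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), 100 * sum(x$explained_variance[1:2])))
  invisible(x)
}

#' @rdname tidy_scalegram
#' @export
tidy.profile_pca <- function(x, ...) x$scores

#' @rdname glance_scalegram
#' @export
glance.profile_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$explained_variance),
    pc1_var = x$explained_variance[1],
    pc2_var = if (length(x$explained_variance) >= 2) x$explained_variance[2] else NA_real_,
    pc12_var = sum(x$explained_variance[seq_len(min(2, length(x$explained_variance)))])
  )
}

#' 95% bivariate-normal confidence ellipse
#'
#' Parameters of the 95% contour of a bivariate normal fitted to a point
#' cloud, via the chi-square(2) quantile of the Mahalanobis radius. Used for
#' drawing per-group ellipses on PC score scatter plots.
#'
#' @param xy Two-column matrix or data frame of points (at least 3).
#' @param level Coverage level.
#' @param n_points Number of polygon vertices returned.
#' @return A tibble of ellipse boundary points (`x`, `y`).
#' @export
confidence_ellipse <- function(xy, level = 0.95, n_points = 100) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) abort("need at least 3 points to fit an ellipse.")
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  r <- sqrt(qchisq(level, df = 2))
  eig <- eigen(S, symmetric = TRUE)
  t <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(t), sin(t)) * r
  pts <- t(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * circ) + ctr)
  tibble::tibble(x = pts[, 1], y = pts[, 2])
}

#' Plot PCA scores with per-group confidence ellipses
#'
#' @param object A `profile_pca`.
#' @param group Grouping column in the scores (default `"year"` if present).
#' @param ... Unused.
#' @return A ggplot scatter of PC1 vs PC2 with 95% normal ellipses.
#' @export
autoplot.profile_pca <- function(object, group = "year", ...) {
  sc <- object$scores
  ev <- object$explained_variance
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  if (group %in% names(sc)) {
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                          color = factor(.data[[group]]))) +
      ggplot2::stat_ellipse(type = "norm", level = 0.95) +
      ggplot2::labs(color = group)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
}

#' Cohort profile heat map
#'
#' Profiles as rows (sorted by year and sampling date), standardized
#' position as columns, spacing as fill — the cohort overview panel.
#'
#' @param P A [profile_matrix()].
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(P) {
  df <- tidy(P)
  df$sample_id <- factor(df$sample_id, levels = rev(P$info$sample_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$sample_id,
                                        fill = .data$spacing)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "standardized position", y = NULL,
                  fill = "spacing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if ("year" %in% names(df)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$year),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' Group mean and CV curves
#'
#' @param summaries Output of [group_summary()].
#' @return A ggplot object: mean spacing with a 1-sd ribbon and the CV
#'   curve, per group.
#' @export
plot_group_summary <- function(summaries) {
  long <- dplyr::bind_rows(
    dplyr::transmute(summaries, .data$group, .data$position,
                     panel = "mean spacing (±1 sd)", value = .data$mean,
                     lo = .data$mean - .data$sd, hi = .data$mean + .data$sd),
    dplyr::transmute(summaries, .data$group, .data$position,
                     panel = "coefficient of variation", value = .data$cv,
                     lo = NA_real_, hi = NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$value,
                                     color = factor(.data$group),
                                     fill = factor(.data$group))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, color = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "standardized position", y = NULL,
                  color = "group", fill = "group") +
    ggplot2::theme_minimal()
}
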