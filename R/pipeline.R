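#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end workflow in one validated list.
#' The defaults are exactly the analysis constants used on the salmon
#' archive: 0.1-degree angular interval (3600 transects), 200-px Hamming
#' window moved in 5-px steps, stretch length 1500, magnification 302 px/mm,
#' and marine-phase segmentation by runs of 30 columns with peak variance
#' below 10.
#'
#' @param delta_theta Angular interval between transects, degrees.
#' @param window_px,step_px,taper Spectral parameters, see
#'   [spectral_config()].
#' @param stretch_L Common stretched length, columns.
#' @param pixels_per_mm Image magnification.
#' @param run_length,var_threshold Segmentation parameters, see
#'   [segmentation_config()].
#' @param edge_window,edge_var_mult,edge_level_mult Edge-detection
#'   parameters, see [detect_scale_edge()].
#' @param truncation_fraction Standardized position at which manual-profile
#'   displays are truncated to the ocean window.
#' @param seed Integer seed for any stochastic step (e.g. simulation).
#' @return An object of class `pipeline_config`; `config_hash()` of it is
#'   embedded in every output file for provenance.
#' @export
pipeline_config <- function(delta_theta = 0.1,
                            window_px = 200, step_px = 5, taper = "hamming",
                            stretch_L = 1500,
                            pixels_per_mm = 302,
                            run_length = 30, var_threshold = 10,
                            edge_window = 25, edge_var_mult = 3,
                            edge_level_mult = 3,
                            truncation_fraction = 0.85,
                            seed = 1L) {
  spectral <- spectral_config(window_px, step_px, taper)
  seg <- segmentation_config(run_length, var_threshold)
  stopifnot_scalar_(stretch_L, "stretch_L", lower = 2)
  stopifnot_scalar_(truncation_fraction, "truncation_fraction", 0, 1)
  # scalars stored as double so the provenance hash is stable across
  # JSON round trips
  cfg <- list(delta_theta = as.numeric(delta_theta),
              window_px = spectral$window_px, step_px = spectral$step_px,
              taper = spectral$taper,
              stretch_L = as.integer(stretch_L),
              pixels_per_mm = as.numeric(pixels_per_mm),
              run_length = seg$run_length,
              var_threshold = as.numeric(seg$var_threshold),
              edge_window = as.numeric(edge_window),
              edge_var_mult = as.numeric(edge_var_mult),
              edge_level_mult = as.numeric(edge_level_mult),
              truncation_fraction = as.numeric(truncation_fraction),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  cat(sprintf("  hash: %s\n", config_hash(x)))
  invisible(x)
}

#' Configuration hash for provenance
#'
#' @param cfg A [pipeline_config()].
#' @return Character hash of the configuration values.
#' @export
config_hash <- function(cfg) {
  rlang::hash(unclass(cfg))
}

#' Read/write a pipeline configuration
#'
#' Key-value JSON serialization; keys are the [pipeline_config()] arguments,
#' unknown keys are rejected.
#'
#' @param path File path.
#' @param cfg A [pipeline_config()].
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort(sprintf("unknown config key(s): %s",
                                 paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read focus annotations
#'
#' Batch replacement for the interactive focus click: a CSV with columns
#' `sample_id`, `center_row`, `center_col`.
#'
#' @param path CSV path.
#' @return A tibble of annotations.
#' @export
read_focus_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "center_row", "center_col")
  if (!all(need %in% names(df))) {
    abort(sprintf("focus annotation file must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

# csv with a provenance comment line
write_output_csv_ <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scalegram config_hash: %s", config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Process one scale end to end
#'
#' The full per-scale workflow: estimate the background model, unwrap the
#' image into transects, truncate them at the detected scale edge, build the
#' stretched ensemble spectrogram, and extract the segmented growth trace.
#' Deterministic given the image, focus and configuration.
#'
#' @param img A [scale_image], or a path to one (loaded with [load_image()]).
#' @param focus `(row, col)` focus annotation in pixels.
#' @param cfg A [pipeline_config()].
#' @param output_dir If non-`NULL`, the trace, ensemble matrix and QC table
#'   are written there as CSV (each embedding the config hash).
#' @return A list with `trace` ([growth_trace()]), `ensemble`
#'   (`ensemble_spectrogram`) and `qc` (one-row tibble: transect counts,
#'   edge statistics, segmentation flag, config hash).
#' @export
run_scale <- function(img, focus, cfg = pipeline_config(), output_dir = NULL) {
  if (is.character(img)) img <- load_image(img, pixels_per_mm = cfg$pixels_per_mm)
  if (!inherits(img, "scale_image")) abort("`img` must be a scale_image or a path.")
  bg <- estimate_background(img)
  tset <- extract_transects(img, focus, cfg$delta_theta)
  tset <- truncate_transects(tset, bg, window = cfg$edge_window,
                             var_mult = cfg$edge_var_mult,
                             level_mult = cfg$edge_level_mult)
  scfg <- spectral_config(cfg$window_px, cfg$step_px, cfg$taper)
  ens <- ensemble_spectrogram(tset, scfg, L = cfg$stretch_L)
  tr <- growth_trace(ens, pixels_per_mm = cfg$pixels_per_mm,
                     seg = segmentation_config(cfg$run_length, cfg$var_threshold))
  qc <- tibble::tibble(
    sample_id = img$sample_id,
    n_transects = length(tset$angle_deg),
    n_retained = ens$n_transects,
    n_excluded = ens$n_excluded,
    edge_min_px = min(tset$xmax),
    edge_median_px = median(tset$xmax),
    edge_max_px = max(tset$xmax),
    background_level = bg$level,
    segmented = !is.na(attr(tr, "marine_start")),
    marine_start = attr(tr, "marine_start"),
    marine_end = attr(tr, "marine_end"),
    config_hash = config_hash(cfg)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    sid <- if (is.na(img$sample_id)) "scale" else img$sample_id
    write_output_csv_(tibble::as_tibble(tr),
                      file.path(output_dir, paste0(sid, "_trace.csv")), cfg)
    ens_df <- tidy(ens)
    write_output_csv_(ens_df,
                      file.path(output_dir, paste0(sid, "_ensemble.csv")), cfg)
    write_output_csv_(qc, file.path(output_dir, paste0(sid, "_qc.csv")), cfg)
  }
  list(trace = tr, ensemble = ens, qc = qc)
}

#' Process a cohort of scales
#'
#' Runs [run_scale()] for every row of a manifest, assembles the per-fish
#' marine-window spacing profiles into a [profile_matrix()] sorted by year
#' and sampling date, and computes the cohort comparison surface (group
#' summaries and PCA). Each fish's spacing trace is restricted to its
#' segmented first marine year, that window rescaled to `[0, 1]` and
#' interpolated to `stretch_L` points so profiles are comparable across fish
#' of different sizes and return dates. Scales whose segmentation fails are
#' excluded from the profile matrix and listed in the QC table.
#'
#' @param manifest A tibble/data.frame (or CSV path) with columns
#'   `sample_id`, `image_path`, `center_row`, `center_col` and optionally
#'   `year`, `sample_date`, `fork_length_cm`. Alternatively `image` may be a
#'   list-column of [scale_image] objects in place of `image_path`.
#' @param cfg A [pipeline_config()].
#' @param output_dir If non-`NULL`, profiles, summaries, PCA scores and QC
#'   are written there as CSV.
#' @return A list with `profiles` ([profile_matrix()] or `NULL`),
#'   `summaries` ([group_summary()] output, when groups allow), `pca`
#'   ([pca_profiles()] output or `NULL`), `traces` (named list of
#'   growth traces) and `qc` (tibble, one row per scale).
#' @export
run_cohort <- function(manifest, cfg = pipeline_config(), output_dir = NULL) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                                comment.char = "#")
  }
  manifest <- tibble::as_tibble(manifest)
  need <- c("sample_id", "center_row", "center_col")
  if (!all(need %in% names(manifest))) {
    abort(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  }
  has_paths <- "image_path" %in% names(manifest)
  if (!has_paths && !"image" %in% names(manifest)) {
    abort("manifest needs an `image_path` column (or an `image` list-column).")
  }
  traces <- list()
  qcs <- list()
  profiles <- list()
  keep <- logical(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- if (has_paths) {
      if (!file.exists(row$image_path)) {
        abort(sprintf("image for sample '%s' not found: %s",
                      row$sample_id, row$image_path))
      }
      load_image(row$image_path, pixels_per_mm = cfg$pixels_per_mm,
                 sample_id = row$sample_id,
                 year = row$year %||% NA,
                 sample_date = row$sample_date %||% NA,
                 fork_length_cm = row$fork_length_cm %||% NA)
    } else {
      row$image[[1]]
    }
    res <- run_scale(img, c(row$center_row, row$center_col), cfg)
    traces[[row$sample_id]] <- res$trace
    qcs[[i]] <- res$qc
    ms <- attr(res$trace, "marine_start"); me <- attr(res$trace, "marine_end")
    if (!is.na(ms)) {
      sp <- res$trace$spacing_mm[ms:me]
      pos <- seq(0, 1, length.out = length(sp))
      def <- !is.na(sp)
      profiles[[row$sample_id]] <-
        approx(pos[def], sp[def], xout = seq(0, 1, length.out = cfg$stretch_L),
               rule = 2)$y
      keep[i] <- TRUE
    }
  }
  qc <- dplyr::bind_rows(qcs)
  P <- NULL; summaries <- NULL; pca <- NULL
  if (sum(keep) >= 1) {
    info_cols <- intersect(c("sample_id", "year", "sample_date", "fork_length_cm"),
                           names(manifest))
    P <- profile_matrix(profiles, manifest[keep, info_cols])
    grp <- if ("year" %in% names(P$info)) P$info$year else NULL
    if (!is.null(grp) && all(table(grp) >= 2)) summaries <- group_summary(P)
    if (nrow(P$values) >= 2 && sum(apply(P$values, 2, var)) > 0) {
      pca <- pca_profiles(P)
    }
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_output_csv_(qc, file.path(output_dir, "cohort_qc.csv"), cfg)
    if (!is.null(P)) {
      write_output_csv_(tidy(P), file.path(output_dir, "cohort_profiles.csv"), cfg)
    }
    if (!is.null(summaries)) {
      write_output_csv_(summaries, file.path(output_dir, "cohort_summaries.csv"), cfg)
    }
    if (!is.null(pca)) {
      write_output_csv_(pca$scores, file.path(output_dir, "cohort_pca_scores.csv"), cfg)
    }
  }
  list(profiles = P, summaries = summaries, pca = pca, traces = traces, qc = qc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
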