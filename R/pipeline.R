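# End-to-end runs ------------------------------------------------------------
#
# run_profile() chains the stages for one cochlea (possibly in fragments):
# read annotations + axis per fragment, fit the axis spline, project cells,
# merge fragments base to apex, smooth, normalize, summarize and write.
# run_compare() runs two configurations and applies the default statistics.
# A run is fully determined by its config; every CSV output carries the
# package version and a digest of the config in header comments, and
# re-running the same config reproduces the CSVs byte-identically.

#' Assemble (or load) a run configuration
#'
#' A run configuration lists the per-fragment input files in explicit
#' base-to-apex order together with the analysis parameters. `run_config()`
#' builds one from arguments; `read_run_config()` loads one from a YAML
#' file with the same field names. Defaults: σ = 250 μm, grid step 10 μm,
#' projection gate 150 μm, boundary correction on, hair-cell reference
#' densities.
#'
#' @param annotations Character vector of annotation CSV/ROI paths, one per
#'   fragment, ordered base to apex.
#' @param axes Character vector of axis polyline paths, parallel to
#'   `annotations`.
#' @param pixel_size Calibration, μm per pixel.
#' @param sigma Gaussian window standard deviation (μm).
#' @param grid_step Profile grid spacing (μm).
#' @param max_distance Projection acceptance gate (μm).
#' @param boundary_correction Logical.
#' @param ref_densities Named vector, cells per 100 μm.
#' @param out_dir Output directory for [run_profile()] products.
#' @param id Identifier used in output file names and summaries.
#' @return A `run_config` list.
#' @export
run_config <- function(annotations, axes, pixel_size = 1, sigma = 250,
                       grid_step = 10, max_distance = 150,
                       boundary_correction = TRUE,
                       ref_densities = reference_densities(),
                       out_dir = NULL, id = "cochlea") {
  cfg <- list(annotations = as.character(annotations),
              axes = as.character(axes),
              pixel_size = pixel_size, sigma = sigma, grid_step = grid_step,
              max_distance = max_distance,
              boundary_correction = isTRUE(boundary_correction),
              ref_densities = ref_densities, out_dir = out_dir, id = id)
  .validate_config(cfg)
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  refs <- raw$ref_densities
  if (!is.null(refs)) refs <- unlist(refs)
  cfg <- run_config(
    annotations = raw$annotations,
    axes = raw$axes,
    pixel_size = raw$pixel_size %||% 1,
    sigma = raw$sigma %||% 250,
    grid_step = raw$grid_step %||% 10,
    max_distance = raw$max_distance %||% 150,
    boundary_correction = raw$boundary_correction %||% TRUE,
    ref_densities = refs %||% reference_densities(),
    out_dir = raw$out_dir,
    id = raw$id %||% "cochlea"
  )
  cfg
}

.validate_config <- function(cfg) {
  if (length(cfg$annotations) == 0 ||
      length(cfg$annotations) != length(cfg$axes)) {
    abort("Config needs equal-length `annotations` and `axes` path lists (one per fragment, base to apex).",
          class = "cochleogram_config_error")
  }
  for (p in c(cfg$annotations, cfg$axes)) {
    if (!file.exists(p)) {
      abort(sprintf("Input file does not exist: %s", p),
            class = "cochleogram_config_error")
    }
  }
  for (fld in c("sigma", "grid_step", "max_distance", "pixel_size")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("Config field `%s` must be a positive number.", fld),
            class = "cochleogram_config_error")
    }
  }
  structure(cfg, class = "run_config")
}

.config_header <- function(cfg) {
  flat <- cfg
  flat$ref_densities <- paste(sprintf("%s=%g", names(cfg$ref_densities),
                                      cfg$ref_densities), collapse = ",")
  c(sprintf("cochleogram version %s",
            as.character(utils::packageVersion("cochleogram"))),
    sprintf("config digest %s", rlang::hash(cfg[setdiff(names(cfg), "out_dir")])),
    sprintf("sigma=%g grid_step=%g max_distance=%g boundary_correction=%s pixel_size=%g",
            cfg$sigma, cfg$grid_step, cfg$max_distance,
            cfg$boundary_correction, cfg$pixel_size),
    sprintf("ref_densities %s", flat$ref_densities))
}

# Load, fit and project all fragments of one run; coordinates on the
# concatenated base-to-apex domain.
.run_coords <- function(cfg) {
  frags <- purrr::map2(cfg$annotations, cfg$axes, function(ann_path, axis_path) {
    cells <- read_annotations(ann_path, pixel_size = cfg$pixel_size)
    poly <- read_axis(axis_path, pixel_size = cfg$pixel_size)
    axis <- fit_axis(poly)
    proj <- project_annotations(axis, cells, max_distance = cfg$max_distance)
    list(coords = proj, length = axis_length(axis),
         rejected = attr(proj, "rejected"))
  })
  stacked <- stack_fragments(frags)
  rejected <- purrr::reduce(purrr::map(frags, "rejected"), function(a, b) {
    all_ct <- union(names(a), names(b))
    av <- stats::setNames(rep(0L, length(all_ct)), all_ct)
    av[names(a)] <- av[names(a)] + a
    av[names(b)] <- av[names(b)] + b
    av
  }, .init = integer())
  list(coords = stacked$coords, L = stacked$L,
       fragment_lengths = vapply(frags, function(f) f$length, numeric(1)),
       rejected = rejected)
}

#' Run the full profiling pipeline for one cochlea
#'
#' Reads every fragment's annotations and axis, fits the axis spline,
#' projects the cells, merges fragments base to apex, computes the
#' boundary-corrected cochleogram and the transduction-rate profile, and
#' summarizes the per-type peaks. When `out_dir` is set, writes
#' `<id>_profile.csv`, `<id>_peaks.csv` and a profile figure
#' `<id>_profile.pdf`; CSV headers carry the package version and config
#' digest.
#'
#' @param config A `run_config`, or the path to a YAML config file.
#' @return A `cochlea_run` list with `profile` (a `transduction_profile`),
#'   `cochleogram`, `peaks`, `L`, `fragment_lengths`, `rejected` (per-type
#'   rejection counts), `coords` (accepted projected coordinates) and the
#'   `config`.
#' @export
run_profile <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  run <- .run_coords(config)
  cg <- compute_cochleogram(run$coords, L = run$L, sigma = config$sigma,
                            grid_step = config$grid_step,
                            boundary_correction = config$boundary_correction,
                            types = names(config$ref_densities))
  profile <- to_fraction(cg, refs = config$ref_densities)
  peaks <- peak_summary(profile, cochlea_id = config$id)
  inform(sprintf(
    "%s: L = %.0f μm, %d cell(s) accepted, %d rejected; peak fractions: %s",
    config$id, run$L, nrow(run$coords), sum(run$rejected),
    paste(sprintf("%s %.2f", peaks$cell_type, peaks$peak_fraction),
          collapse = ", ")))
  result <- structure(list(profile = profile, cochleogram = cg, peaks = peaks,
                           L = run$L, fragment_lengths = run$fragment_lengths,
                           rejected = run$rejected, coords = run$coords,
                           config = config),
                      class = "cochlea_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    header <- .config_header(config)
    ppath <- file.path(config$out_dir, paste0(config$id, "_profile.csv"))
    write_profile(profile, ppath, comment = header)
    kpath <- file.path(config$out_dir, paste0(config$id, "_peaks.csv"))
    readr::write_lines(paste0("# ", header), kpath)
    readr::write_csv(peaks, kpath, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    fig <- file.path(config$out_dir, paste0(config$id, "_profile.pdf"))
    try(suppressWarnings(suppressMessages(
      ggplot2::ggsave(fig, autoplot(profile), width = 7, height = 4))),
      silent = TRUE)
    result$paths <- list(profile = ppath, peaks = kpath, figure = fig)
  }
  result
}

#' @export
print.cochlea_run <- function(x, ...) {
  cat(sprintf("<cochlea_run> %s: L = %.0f μm, %d fragment(s), %d accepted cell(s)\n",
              x$config$id, x$L, length(x$fragment_lengths), nrow(x$coords)))
  print(x$peaks)
  invisible(x)
}

#' @export
tidy.cochlea_run <- function(x, ...) tidy(x$profile)

#' @export
glance.cochlea_run <- function(x, ...) {
  tibble(id = x$config$id, length_um = x$L,
         n_fragments = length(x$fragment_lengths),
         n_accepted = nrow(x$coords), n_rejected = sum(x$rejected),
         max_fraction = if (nrow(x$profile$data)) max(x$profile$data$fraction) else NA_real_)
}

#' Compare two cochlea runs
#'
#' Runs the profiling pipeline on both configurations and applies the
#' requested comparison: `"ks"` (default) tests the pooled transduced-cell
#' longitudinal coordinates with the two-sample Kolmogorov-Smirnov test on
#' relative (length-normalized) coordinates; `"welch"` compares the
#' per-segment transduced-cell counts (three base/mid/apex segments) with
#' Welch's t-test. A tidy comparison CSV is written when `out_path` is set.
#'
#' @param config_a,config_b `run_config` objects (or YAML paths).
#' @param test `"ks"`, `"welch"`, or both.
#' @param n_segments Segments for the Welch comparison (default 3).
#' @param relative Use length-normalized coordinates for the KS test
#'   (default `TRUE`).
#' @param out_path Optional CSV output path.
#' @return A tibble of tidy comparison rows.
#' @export
run_compare <- function(config_a, config_b, test = c("ks", "welch"),
                        n_segments = 3, relative = TRUE, out_path = NULL) {
  test <- match.arg(test, several.ok = TRUE)
  if (is.character(config_a)) config_a <- read_run_config(config_a)
  if (is.character(config_b)) config_b <- read_run_config(config_b)
  a <- .run_coords(config_a)
  b <- .run_coords(config_b)
  rows <- list()
  if ("ks" %in% test) {
    rows$ks <- tidy(compare_profiles_ks(
      a$coords, b$coords, relative = relative, L_a = a$L, L_b = b$L,
      grouping = sprintf("%s vs %s, pooled cell coordinates%s",
                         config_a$id, config_b$id,
                         if (relative) " (relative position)" else "")))
  }
  if ("welch" %in% test) {
    ca <- segment_counts(a$coords, L = a$L, n_segments = n_segments)$count
    cb <- segment_counts(b$coords, L = b$L, n_segments = n_segments)$count
    rows$welch <- tidy(compare_means_welch(
      ca, cb,
      grouping = sprintf("%s vs %s, counts in %d segments",
                         config_a$id, config_b$id, n_segments)))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_path)) {
    readr::write_lines(paste0("# ", .config_header(config_a)), out_path)
    readr::write_csv(out, out_path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  out
}
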