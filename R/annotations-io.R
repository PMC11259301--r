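# Reading and writing annotations, axis polylines and profiles --------------
#
# Canonical interchange format is plain CSV (UTF-8, header row). ImageJ ROI
# files (.roi, .zip) are supported as a convenience reader because manual
# annotation is typically done with the Fiji multipoint and segmented-line
# tools. Coordinates are converted to micrometres at load time via the
# pixel-size calibration; everything downstream works in micrometres.

.check_pixel_size <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a single finite, strictly positive number (μm per pixel).")
  }
  pixel_size
}

.is_roi_path <- function(path) grepl("\\.(roi|zip)$", path, ignore.case = TRUE)

#' Read cell annotations
#'
#' Loads point annotations of transduced cells, either from a CSV file with
#' columns `x`, `y`, `cell_type` (and optional `fragment_id`), or from an
#' ImageJ ROI file (`.roi`) or ROI archive (`.zip`) containing multipoint
#' selections whose ROI names give the cell type. Pixel coordinates are
#' multiplied by `pixel_size` so that all downstream analysis is in
#' micrometres. Every label is validated against [cell_types()].
#'
#' @param path Path to a CSV file or ImageJ `.roi`/`.zip` file.
#' @param pixel_size Calibration in micrometres per pixel (isotropic).
#' @param label_map Optional named character vector mapping labels found in
#'   the file to registered cell-type labels, e.g.
#'   `c("inner hair cell" = "IHC")`.
#' @return A tibble with columns `x`, `y` (μm), `cell_type` and
#'   `fragment_id`.
#' @seealso [write_annotations()], [read_axis()]
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = c(10, 30), y = c(20, 40),
#'                      cell_type = c("IHC", "OHC2")),
#'           path, row.names = FALSE)
#' read_annotations(path, pixel_size = 1)
#' @export
read_annotations <- function(path, pixel_size = 1, label_map = NULL) {
  .check_pixel_size(pixel_size)
  if (.is_roi_path(path)) {
    df <- .annotations_from_roi(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                          progress = FALSE)
    missing <- setdiff(c("x", "y", "cell_type"), names(df))
    if (length(missing) > 0) {
      abort(sprintf("Annotation file %s is missing required column(s): %s",
                    path, paste(missing, collapse = ", ")),
            class = "cochleogram_format_error")
    }
  }
  if (!"fragment_id" %in% names(df)) df$fragment_id <- NA_character_
  df <- dplyr::select(df, "x", "y", "cell_type", "fragment_id")
  df$cell_type <- as.character(df$cell_type)
  df$fragment_id <- as.character(df$fragment_id)
  if (!is.null(label_map)) {
    hit <- df$cell_type %in% names(label_map)
    df$cell_type[hit] <- unname(label_map[df$cell_type[hit]])
  }
  .check_cell_types(df$cell_type)
  if (nrow(df) == 0) {
    df$x <- double(); df$y <- double()
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || !all(is.finite(df$x)) ||
      !all(is.finite(df$y))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
                 !is.finite(suppressWarnings(as.numeric(df$y))))
    abort(sprintf("Non-finite coordinate(s) in %s at row(s): %s",
                  path, paste(head(bad, 5), collapse = ", ")),
          class = "cochleogram_validation_error")
  }
  df$x <- df$x * pixel_size
  df$y <- df$y * pixel_size
  inform(sprintf("Loaded %d annotation(s) of %d cell type(s) from %s",
                 nrow(df), dplyr::n_distinct(df$cell_type), basename(path)))
  as_tibble(df)
}

.annotations_from_roi <- function(path) {
  rois <- read_imagej_roi(path)
  pts <- purrr::keep(rois, ~ .x$type == "point")
  if (length(pts) == 0) {
    abort(sprintf("No multipoint ROI found in %s", path),
          class = "cochleogram_format_error")
  }
  purrr::map_dfr(pts, function(r) {
    tibble(x = r$coords$x, y = r$coords$y, cell_type = r$name)
  })
}

#' Write cell annotations to CSV
#'
#' Writes the canonical annotation CSV (`x`, `y`, `cell_type`,
#' `fragment_id`). Coordinates are written as-is; if they are calibrated
#' micrometres, re-load with `pixel_size = 1`.
#'
#' @param cells A data frame of annotations as returned by
#'   [read_annotations()].
#' @param path Output file path.
#' @return The input `cells`, invisibly (so it can be used in a pipe).
#' @export
write_annotations <- function(cells, path) {
  stopifnot(all(c("x", "y", "cell_type") %in% names(cells)))
  out <- dplyr::select(as_tibble(cells), "x", "y", "cell_type",
                       dplyr::any_of("fragment_id"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(cells)
}

#' Read a cochlear-axis polyline
#'
#' Loads the ordered control points of an operator-delineated cochlear axis,
#' from a CSV with columns `x`, `y` (ordered base to apex; the first point is
#' the cochlear base) or from an ImageJ polyline/segmented-line ROI.
#' Consecutive duplicate points are dropped; point order is preserved.
#' Orientation is explicit metadata: the file is taken to start at the base,
#' and never reinterpreted.
#'
#' @inheritParams read_annotations
#' @return A tibble with columns `x`, `y` in micrometres, carrying a
#'   `fragment_id` attribute when the CSV provides one.
#' @export
read_axis <- function(path, pixel_size = 1) {
  .check_pixel_size(pixel_size)
  if (.is_roi_path(path)) {
    rois <- read_imagej_roi(path)
    lines <- purrr::keep(rois, ~ .x$type %in% c("polyline", "polygon", "freehand"))
    if (length(lines) == 0) {
      abort(sprintf("No polyline ROI found in %s", path),
            class = "cochleogram_format_error")
    }
    df <- tibble(x = lines[[1]]$coords$x, y = lines[[1]]$coords$y)
    fragment_id <- NA_character_
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                          progress = FALSE)
    missing <- setdiff(c("x", "y"), names(df))
    if (length(missing) > 0) {
      abort(sprintf("Axis file %s is missing required column(s): %s",
                    path, paste(missing, collapse = ", ")),
            class = "cochleogram_format_error")
    }
    fragment_id <- if ("fragment_id" %in% names(df)) as.character(df$fragment_id[1]) else NA_character_
  }
  as_axis_polyline(df$x * pixel_size, df$y * pixel_size, fragment_id = fragment_id)
}

#' Construct an axis polyline from coordinates
#'
#' Validates and normalizes an ordered base-to-apex polyline: coordinates
#' must be finite, consecutive duplicates are removed, and at least two
#' distinct points must remain.
#'
#' @param x,y Numeric coordinate vectors in micrometres, ordered from base
#'   to apex.
#' @param fragment_id Optional identifier of the cochlear fragment.
#' @return A tibble with columns `x`, `y` and attribute `fragment_id`.
#' @export
as_axis_polyline <- function(x, y, fragment_id = NA_character_) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Axis polyline contains non-finite coordinates.",
          class = "cochleogram_validation_error")
  }
  if (length(x) > 1) {
    dup <- c(FALSE, diff(x) == 0 & diff(y) == 0)
    x <- x[!dup]; y <- y[!dup]
  }
  if (length(x) < 2) {
    abort("An axis polyline needs at least 2 distinct points.",
          class = "cochleogram_validation_error")
  }
  out <- tibble(x = x, y = y)
  attr(out, "fragment_id") <- fragment_id
  class(out) <- c("axis_polyline", class(out))
  out
}

# Profile CSV ----------------------------------------------------------------

#' Write and read transduction profiles
#'
#' `write_profile()` serializes a [transduction profile][to_fraction] to a
#' tidy CSV with columns `position_um`, `cell_type`, `fraction` and
#' `density_cells_per_um`, grouped by cell type with the position grid
#' repeated per type. Optional `comment` lines are written first, prefixed
#' with `#`, and skipped on re-read. `read_profile()` restores the profile
#' object losslessly at full double precision.
#'
#' @param profile A `transduction_profile` object.
#' @param path File path.
#' @param comment Optional character vector of header comment lines.
#' @return `write_profile()` returns `profile` invisibly; `read_profile()`
#'   returns a `transduction_profile`.
#' @export
write_profile <- function(profile, path, comment = NULL) {
  stopifnot(inherits(profile, "transduction_profile"))
  out <- dplyr::arrange(tidy(profile), .data$cell_type, .data$position_um)
  out <- dplyr::select(out, "position_um", "cell_type", "fraction",
                       "density_cells_per_um")
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(sprintf("Cannot open %s for writing: %s", path, conditionMessage(e)),
          class = "cochleogram_io_error")
  })
  close(con)
  if (!is.null(comment) && length(comment) > 0) {
    readr::write_lines(paste0("# ", comment), path)
  }
  readr::write_csv(out, path, append = !is.null(comment) && length(comment) > 0,
                   col_names = TRUE, progress = FALSE)
  invisible(profile)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  needed <- c("position_um", "cell_type", "fraction", "density_cells_per_um")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Profile file %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "cochleogram_format_error")
  }
  grid <- sort(unique(df$position_um))
  new_transduction_profile(
    data = as_tibble(df[needed]),
    L = max(grid),
    sigma = NA_real_,
    grid_step = if (length(grid) > 1) grid[2] - grid[1] else NA_real_,
    refs = NULL
  )
}
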