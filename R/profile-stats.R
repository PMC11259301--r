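# Profile statistics ---------------------------------------------------------
#
# Longitudinal profiles are compared through the cell coordinates they are
# built from: a two-sample Kolmogorov-Smirnov test on the empirical
# distributions of transduced-cell longitudinal coordinates (KS on the
# smoothed, autocorrelated grid values would not be a valid test), and
# Welch's t-test for comparisons of mean values (counts, peak rates).
# Left/right comparisons default to relative (length-normalized)
# coordinates since cochlear lengths differ between specimens.

new_comparison <- function(test, statistic, p_value, n_a, n_b,
                           grouping = NA_character_) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n_a = n_a, n_b = n_b, grouping = grouping),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> %s: statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' @export
tidy.profile_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, grouping = x$grouping)
}

#' @export
glance.profile_comparison <- function(x, ...) tidy(x)

#' Compare two longitudinal profiles (two-sample Kolmogorov-Smirnov)
#'
#' Tests whether two sets of transduced-cell longitudinal coordinates are
#' drawn from the same distribution along the cochlea, using the two-sample
#' KS statistic `D` (the maximum distance between the empirical
#' distribution functions) with the asymptotic p-value. With
#' `relative = TRUE` each sample is first normalized by its own cochlear
#' length, so cochleas of different lengths are compared on a common
#' `[0, 1]` base-to-apex scale.
#'
#' @param coords_a,coords_b Numeric vectors of longitudinal coordinates
#'   (μm), or data frames with an `s` column (e.g. from
#'   [project_annotations()]), in which case all cell types are pooled.
#' @param relative Normalize each sample by its own cochlear length before
#'   testing (default `TRUE` when lengths are supplied).
#' @param L_a,L_b Cochlear lengths for the normalization; required when
#'   `relative = TRUE`.
#' @param grouping Free-text descriptor of what is being compared, carried
#'   into the result.
#' @return A `profile_comparison` object ([tidy()] gives a one-row tibble).
#' @export
compare_profiles_ks <- function(coords_a, coords_b, relative = !is.null(L_a),
                                L_a = NULL, L_b = NULL,
                                grouping = NA_character_) {
  a <- .as_coords(coords_a, "coords_a")
  b <- .as_coords(coords_b, "coords_b")
  if (relative) {
    if (is.null(L_a) || is.null(L_b)) {
      abort("`L_a` and `L_b` are required when `relative = TRUE`.",
            class = "cochleogram_config_error")
    }
    a <- a / L_a
    b <- b / L_b
  }
  ks <- suppressWarnings(ks.test(a, b, exact = FALSE))
  new_comparison("Kolmogorov-Smirnov (two-sample)",
                 statistic = unname(ks$statistic),
                 p_value = ks$p.value, n_a = length(a), n_b = length(b),
                 grouping = grouping)
}

.as_coords <- function(x, arg) {
  if (is.data.frame(x)) x <- x$s
  x <- as.numeric(x)
  if (length(x) == 0) {
    abort(sprintf("`%s` is empty; the KS test needs nonempty samples.", arg),
          class = "cochleogram_validation_error")
  }
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values.", arg))
  x
}

#' Compare two groups of mean values (Welch's t-test)
#'
#' Welch's unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, for comparing summary values between
#' groups of cochleas (e.g. per-cochlea transduced-cell counts or peak
#' transduction rates).
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values
#'   and nonzero variance.
#' @param grouping Free-text descriptor carried into the result.
#' @return A `profile_comparison` object.
#' @export
compare_means_welch <- function(values_a, values_b, grouping = NA_character_) {
  for (v in list(a = values_a, b = values_b)) {
    if (length(v) < 2 || !all(is.finite(v))) {
      abort("Welch's t-test needs at least 2 finite values per group.",
            class = "cochleogram_validation_error")
    }
  }
  if (sd(values_a) == 0 && sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    # degenerate but well-defined: identical constant groups differ by 0
    return(new_comparison("Welch's t-test", statistic = 0, p_value = 1,
                          n_a = length(values_a), n_b = length(values_b),
                          grouping = grouping))
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  new_comparison("Welch's t-test", statistic = unname(tt$statistic),
                 p_value = tt$p.value, n_a = length(values_a),
                 n_b = length(values_b), grouping = grouping)
}

#' Count cells in equal-length cochlear segments
#'
#' Splits `[0, L]` into `n_segments` equal-length half-open segments
#' `[kL/n, (k+1)L/n)` (the last segment closed, so a cell exactly at the
#' apex is counted) and counts coordinates per segment. With the default
#' three segments this gives the base/mid/apex counts used for
#' segment-wise comparisons between cochleas.
#'
#' @param coords Numeric vector of longitudinal coordinates in `[0, L]`,
#'   or a data frame with an `s` column.
#' @param L Axis length (μm).
#' @param n_segments Number of segments (≥ 1); default 3 (base/mid/apex).
#' @return A tibble with columns `segment` (1 = most basal), `start_um`,
#'   `end_um`, `count`.
#' @export
segment_counts <- function(coords, L, n_segments = 3) {
  if (is.data.frame(coords)) coords <- coords$s
  stopifnot(is.numeric(L), L > 0, n_segments >= 1)
  if (length(coords) > 0 && (any(coords < 0) || any(coords > L))) {
    abort(sprintf("Coordinates must lie in [0, %g].", L),
          class = "cochleogram_validation_error")
  }
  breaks <- seq(0, L, length.out = n_segments + 1)
  idx <- pmin(findInterval(coords, breaks, rightmost.closed = TRUE),
              n_segments)
  tibble(segment = seq_len(n_segments),
         start_um = breaks[-length(breaks)],
         end_um = breaks[-1],
         count = vapply(seq_len(n_segments),
                        function(k) sum(idx == k), integer(1)))
}

#' Per-cell-type peak of a transduction profile
#'
#' Finds, for each cell type, the maximum transduction fraction over the
#' profile grid and the position attaining it (the first-attaining grid
#' point on ties). Peaks from several cochleas can be aggregated with
#' [summarize_peaks()].
#'
#' @param profile A `transduction_profile`.
#' @param cochlea_id Optional identifier recorded with each peak.
#' @return A tibble with columns `cell_type`, `peak_fraction`,
#'   `peak_position_um`, `peak_position_rel` and `cochlea_id`.
#' @export
peak_summary <- function(profile, cochlea_id = NA_character_) {
  stopifnot(inherits(profile, "transduction_profile"))
  if (nrow(profile$data) == 0) {
    abort("Cannot summarize an empty profile (no cell types).",
          class = "cochleogram_validation_error")
  }
  profile$data |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      peak_fraction = max(.data$fraction),
      peak_position_um = .data$position_um[which.max(.data$fraction)],
      .groups = "drop"
    ) |>
    dplyr::mutate(peak_position_rel = .data$peak_position_um / profile$L,
                  cochlea_id = cochlea_id)
}

#' Aggregate peak summaries across cochleas
#'
#' Reduces a collection of per-cochlea [peak_summary()] rows to the
#' cross-cochlea mean ± standard error of the mean, per cell type.
#'
#' @param peaks A data frame of stacked [peak_summary()] results.
#' @return A tibble with columns `cell_type`, `n`, `mean_peak_fraction`,
#'   `sem_peak_fraction`, `mean_peak_position_um`.
#' @export
summarize_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("cell_type", "peak_fraction") %in% names(peaks)))
  peaks |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_peak_fraction = mean(.data$peak_fraction),
      sem_peak_fraction = sd(.data$peak_fraction) / sqrt(dplyr::n()),
      mean_peak_position_um = mean(.data$peak_position_um),
      .groups = "drop"
    )
}
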