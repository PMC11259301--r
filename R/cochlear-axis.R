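# Arc-length parameterized cochlear axis -------------------------------------
#
# The operator delineates the organ of Corti with an ordered base-to-apex
# polyline; a parametric cubic spline through those control points (chord
# -length parameterization) gives a smooth curve, and a dense arc-length
# table (cumulative chord length over <=1 um evaluation steps) turns any
# position on the curve into a longitudinal coordinate s in [0, L].

#' Fit an arc-length-parameterized curve to a cochlear-axis polyline
#'
#' Fits a parametric cubic spline (natural boundary conditions) through the
#' ordered control points of an axis polyline, using chord-length
#' parameterization. With `smoothing = 0` (default) the curve interpolates
#' every control point, honouring the operator's delineation; a positive
#' `smoothing` is passed as the `spar` argument of [stats::smooth.spline()]
#' for lightly smoothed fits. Arc length is accumulated by fine-step chord
#' summation over a dense evaluation table, so the cochlear base maps to
#' longitudinal coordinate 0 and the apex to the total length `L`.
#'
#' @param polyline An axis polyline: a data frame with ordered `x`, `y`
#'   columns in micrometres (see [as_axis_polyline()], [read_axis()]).
#' @param smoothing Non-negative smoothing parameter; 0 interpolates.
#' @param step Target spacing (μm) of the dense arc-length table.
#' @param tol Maximum tolerated distance (μm) between the fitted curve and
#'   any control point; exceeding it raises a warning.
#' @return A `cochlea_axis` object with the fitted curve, the dense
#'   arc-length table and total length `L` (also via [axis_length()]).
#' @examples
#' ax <- fit_axis(as_axis_polyline(c(0, 100, 200), c(0, 0, 0)))
#' axis_length(ax)
#' @export
fit_axis <- function(polyline, smoothing = 0, step = 1, tol = 2) {
  if (!is.data.frame(polyline) || !all(c("x", "y") %in% names(polyline))) {
    abort("`polyline` must be a data frame with columns `x` and `y`.")
  }
  polyline <- as_axis_polyline(polyline$x, polyline$y,
                               fragment_id = attr(polyline, "fragment_id") %||% NA_character_)
  stopifnot(is.numeric(smoothing), length(smoothing) == 1, smoothing >= 0,
            is.numeric(step), step > 0)
  x <- polyline$x; y <- polyline$y
  chord <- sqrt(diff(x)^2 + diff(y)^2)
  t <- c(0, cumsum(chord))
  if (max(t) <= 0) {
    abort("Degenerate polyline: zero total chord length.",
          class = "cochleogram_validation_error")
  }
  if (smoothing == 0 || length(x) < 4) {
    if (smoothing > 0) {
      warn("Fewer than 4 control points: smoothing ignored, interpolating instead.")
    }
    fx <- splinefun(t, x, method = "natural")
    fy <- splinefun(t, y, method = "natural")
  } else {
    sx <- smooth.spline(t, x, spar = smoothing)
    sy <- smooth.spline(t, y, spar = smoothing)
    fx <- function(tt) predict(sx, tt)$y
    fy <- function(tt) predict(sy, tt)$y
  }
  tt <- seq(0, max(t), by = step)
  if (tt[length(tt)] < max(t)) tt <- c(tt, max(t))
  dx <- fx(tt); dy <- fy(tt)
  s <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
  dev <- sqrt((fx(t) - x)^2 + (fy(t) - y)^2)
  if (max(dev) > tol) {
    warn(sprintf("Fitted axis deviates up to %.2f μm from control points (tol %.1f μm).",
                 max(dev), tol))
  }
  structure(list(
    polyline = polyline,
    fx = fx, fy = fy,
    table = tibble(t = tt, x = dx, y = dy, s = s),
    L = s[length(s)],
    smoothing = smoothing,
    step = step,
    max_deviation = max(dev),
    fragment_id = attr(polyline, "fragment_id")
  ), class = "cochlea_axis")
}

#' Total arc length of a fitted axis
#'
#' @param axis A `cochlea_axis` object.
#' @return Total length `L` in micrometres.
#' @export
axis_length <- function(axis) {
  stopifnot(inherits(axis, "cochlea_axis"))
  axis$L
}

#' Evaluate a fitted axis at given longitudinal coordinates
#'
#' @param axis A `cochlea_axis` object.
#' @param s Longitudinal coordinates in `[0, L]` (μm).
#' @return A tibble with columns `s`, `x`, `y`.
#' @export
axis_point <- function(axis, s) {
  stopifnot(inherits(axis, "cochlea_axis"))
  s <- pmin(pmax(s, 0), axis$L)
  t <- approx(axis$table$s, axis$table$t, xout = s, ties = "ordered")$y
  tibble(s = s, x = axis$fx(t), y = axis$fy(t))
}

#' @export
print.cochlea_axis <- function(x, ...) {
  cat(sprintf("<cochlea_axis> L = %.1f μm, %d control points, %s\n",
              x$L, nrow(x$polyline),
              if (x$smoothing == 0) "interpolating" else sprintf("smoothing spar = %g", x$smoothing)))
  invisible(x)
}

#' @export
tidy.cochlea_axis <- function(x, ...) {
  dplyr::select(x$table, "s", "x", "y")
}

#' @export
glance.cochlea_axis <- function(x, ...) {
  tibble(length_um = x$L, n_control_points = nrow(x$polyline),
         smoothing = x$smoothing, max_fit_deviation_um = x$max_deviation,
         table_step_um = x$step)
}

# Projection ------------------------------------------------------------------

#' Project planar points onto a fitted cochlear axis
#'
#' For each point, finds the longitudinal coordinate `s` of the globally
#' nearest position on the curve: a global search over the dense arc-length
#' table picks the nearest table entry, and the projection is refined on the
#' two chord segments adjacent to it. Points farther than `max_distance`
#' from the curve (e.g. mesenchymal cells, or cells belonging to an adjacent
#' spiral turn) are flagged `accepted = FALSE` rather than silently
#' misprojected. Ties between equidistant candidates resolve to the smaller
#' `s`; points projecting beyond the curve ends are clamped to `[0, L]`,
#' with `d` measured to the endpoint.
#'
#' @param axis A `cochlea_axis` object.
#' @param points A data frame with columns `x`, `y` (μm).
#' @param max_distance Acceptance gate (μm) on the point-to-curve distance.
#' @return A tibble with one row per point: `s` (μm), `d` (perpendicular
#'   distance, μm) and `accepted`.
#' @export
project_points <- function(axis, points, max_distance = 150) {
  stopifnot(inherits(axis, "cochlea_axis"))
  if (!is.data.frame(points)) points <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(points)))
  n <- nrow(points)
  if (n == 0) return(tibble(s = double(), d = double(), accepted = logical()))
  tx <- axis$table$x; ty <- axis$table$y; ts <- axis$table$s
  N <- length(tx)
  px <- points$x; py <- points$y
  idx <- integer(n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    j <- start:min(start + chunk - 1L, n)
    d2 <- outer(px[j], tx, "-")^2 + outer(py[j], ty, "-")^2
    idx[j] <- max.col(-d2, ties.method = "first")
  }
  s_best <- d_best <- numeric(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    segs <- unique(pmax(pmin(c(i - 1L, i), N - 1L), 1L))
    best_s <- ts[i]
    best_d <- sqrt((px[k] - tx[i])^2 + (py[k] - ty[i])^2)
    for (a in segs) {
      b <- a + 1L
      vx <- tx[b] - tx[a]; vy <- ty[b] - ty[a]
      vv <- vx * vx + vy * vy
      if (vv == 0) next
      tt <- ((px[k] - tx[a]) * vx + (py[k] - ty[a]) * vy) / vv
      tt <- min(max(tt, 0), 1)
      qx <- tx[a] + tt * vx; qy <- ty[a] + tt * vy
      d <- sqrt((px[k] - qx)^2 + (py[k] - qy)^2)
      s <- ts[a] + tt * (ts[b] - ts[a])
      if (d < best_d - 1e-12 || (abs(d - best_d) <= 1e-12 && s < best_s)) {
        best_d <- d; best_s <- s
      }
    }
    s_best[k] <- best_s; d_best[k] <- best_d
  }
  tibble(s = pmin(pmax(s_best, 0), axis$L), d = d_best,
         accepted = d_best <= max_distance)
}

#' Project annotated cells onto the axis, grouped by cell type
#'
#' Projects every annotation with [project_points()], drops rejected cells
#' (distance beyond `max_distance`), and reports per-type rejection counts
#' via a warning when any cell is rejected. The result is the per-cell-type
#' set of longitudinal coordinates feeding [compute_cochleogram()].
#'
#' @param axis A `cochlea_axis` object.
#' @param cells A data frame of annotations with columns `x`, `y`,
#'   `cell_type` (see [read_annotations()]).
#' @param max_distance Acceptance gate in micrometres.
#' @return A tibble with columns `cell_type`, `s`, `d` for accepted cells,
#'   carrying a named `rejected` attribute of per-type rejection counts.
#' @export
project_annotations <- function(axis, cells, max_distance = 150) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0) {
    out <- tibble(cell_type = character(), s = double(), d = double())
    attr(out, "rejected") <- integer()
    return(out)
  }
  stopifnot(all(c("x", "y", "cell_type") %in% names(cells)))
  proj <- project_points(axis, cells, max_distance = max_distance)
  res <- tibble(cell_type = as.character(cells$cell_type),
                s = proj$s, d = proj$d, accepted = proj$accepted)
  rejected <- res |>
    dplyr::filter(!.data$accepted) |>
    dplyr::count(.data$cell_type)
  rej <- stats::setNames(rejected$n, rejected$cell_type)
  if (sum(rej) > 0) {
    warn(sprintf("Rejected %d cell(s) beyond %.0f μm from the axis: %s",
                 sum(rej), max_distance,
                 paste(sprintf("%s=%d", names(rej), rej), collapse = ", ")))
  }
  out <- res |>
    dplyr::filter(.data$accepted) |>
    dplyr::select("cell_type", "s", "d")
  attr(out, "rejected") <- rej
  out
}
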