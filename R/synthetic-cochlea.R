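# Synthetic cochleas with known ground truth ---------------------------------
#
# Emulates the measured data model: an Archimedean-type spiral axis of
# target arc length ~5700 um (about two turns), parallel cell rows laid at
# small lateral offsets from the axis (1 IHC row, 3 OHC rows, optional
# supporting-cell rows) at specified longitudinal densities, and an
# independent Bernoulli transduction draw per cell with position-dependent
# probability p(s). Only transduced cells are emitted as annotations —
# untransduced cells are never "clicked" — while the full ground truth
# (every cell, its generative arc-length position and transduction flag)
# is returned separately so every pipeline stage can be validated.

#' Transduction-probability profile families
#'
#' Phenomenological position-dependent transduction probabilities
#' \eqn{p(s)}, parameterized in relative position \eqn{u = s/L} so the same
#' family applies to cochleas of any length, and clipped to `[0, 1]`:
#'
#' * `constant`: `level` everywhere (default 0.5).
#' * `linear`: straight line from `from` at the base to `to` at the apex
#'   (defaults 0.8 to 0.2).
#' * `logistic`: sigmoid step between `p_base` and `p_apex` with relative
#'   `midpoint` and `scale` (defaults 0.5 to 0 around u = 0.35, scale 0.1) —
#'   the basal-peaked decline typical of embryonic injections; swap
#'   `p_base`/`p_apex` for an apical-rising profile.
#' * `gaussian_bump`: `baseline` plus a Gaussian bump of `height` at
#'   relative `center` with relative `width` (defaults 0 + 0.9 at u = 0.5,
#'   width 0.1) — a mid-cochlea maximum.
#'
#' @param name One of `"constant"`, `"linear"`, `"logistic"`,
#'   `"gaussian_bump"`.
#' @param ... Family parameters (see above).
#' @return A function `p(s, L)` returning probabilities in `[0, 1]`, with
#'   class `profile_family` and attributes `name` and `params`.
#' @examples
#' p <- profile_family("linear", from = 0.8, to = 0.2)
#' p(2850, L = 5700)  # 0.5 at the midpoint
#' @export
profile_family <- function(name, ...) {
  params <- list(...)
  fam <- switch(
    name,
    constant = {
      level <- params$level %||% 0.5
      function(u) rep(level, length(u))
    },
    linear = {
      from <- params$from %||% 0.8; to <- params$to %||% 0.2
      function(u) from + (to - from) * u
    },
    logistic = {
      p_base <- params$p_base %||% 0.5
      p_apex <- params$p_apex %||% 0
      midpoint <- params$midpoint %||% 0.35
      scale <- params$scale %||% 0.1
      function(u) p_apex + (p_base - p_apex) / (1 + exp((u - midpoint) / scale))
    },
    gaussian_bump = {
      center <- params$center %||% 0.5
      width <- params$width %||% 0.1
      height <- params$height %||% 0.9
      baseline <- params$baseline %||% 0
      function(u) baseline + height * exp(-(u - center)^2 / (2 * width^2))
    },
    abort(sprintf("Unknown profile family \"%s\" (use constant, linear, logistic or gaussian_bump).",
                  name), class = "cochleogram_config_error")
  )
  f <- function(s, L) pmin(pmax(fam(s / L), 0), 1)
  structure(f, class = c("profile_family", "function"),
            name = name, params = params)
}

#' @export
print.profile_family <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<profile_family> %s(%s)\n", attr(x, "name"),
              paste(sprintf("%s = %g", names(p), unlist(p)), collapse = ", ")))
  invisible(x)
}

#' Specify a synthetic cochlea
#'
#' Collects and validates all parameters defining a synthetic dataset:
#' spiral geometry (an Archimedean spiral, constant radial pitch, scaled to
#' the target arc length), per-cell-type longitudinal densities and lateral
#' row offsets, positional jitter, per-type transduction-probability
#' profiles, placement mode, optional fragmentation cuts and the random
#' seed. Identical spec + seed yields bit-identical generated data.
#'
#' @param length Target axis arc length in micrometres (default 5700).
#' @param inner_radius,pitch,turns Spiral shape: starting radius, radial
#'   pitch per turn (μm, before rescaling to `length`) and number of turns.
#' @param densities Named vector of longitudinal densities in cells per
#'   100 μm; defaults to the hair-cell reference densities
#'   ([reference_densities()]).
#' @param row_offsets Named vector of lateral offsets (μm) of each cell row
#'   from the axis; defaults place the IHC row medially and OHC rows 1-3
#'   laterally at 8 μm spacing.
#' @param jitter Isotropic Gaussian positional jitter (μm, default 2).
#' @param profiles Either a single `p(s, L)` function (applied to all
#'   types) or a named list of functions per cell type; see
#'   [profile_family()].
#' @param placement `"equal"` for equally spaced cells along arc length, or
#'   `"poisson"` for a homogeneous Poisson point process at the same
#'   density.
#' @param cuts Optional increasing vector of arc-length positions (μm) at
#'   which the cochlea is cut into fragments.
#' @param axis_spacing Arc-length spacing (μm) of the emitted axis-polyline
#'   control points, mimicking an operator's clicks (default 50).
#' @param seed Integer random seed.
#' @return A validated `synthetic_cochlea_spec` list.
#' @export
synthetic_cochlea_spec <- function(length = 5700,
                                   inner_radius = 200, pitch = 300, turns = 2,
                                   densities = reference_densities(),
                                   row_offsets = NULL,
                                   jitter = 2,
                                   profiles = profile_family("logistic"),
                                   placement = c("equal", "poisson"),
                                   cuts = NULL,
                                   axis_spacing = 50,
                                   seed = 1) {
  placement <- match.arg(placement)
  stopifnot(is.numeric(length), length > 0, is.numeric(jitter), jitter >= 0,
            is.numeric(turns), turns > 0, is.numeric(inner_radius),
            inner_radius >= 0, is.numeric(pitch), pitch > 0,
            is.numeric(axis_spacing), axis_spacing > 0)
  if (inner_radius <= 0 && pitch <= 0) {
    abort("Spiral with zero radius and pitch cannot reach any target length.",
          class = "cochleogram_config_error")
  }
  if (is.null(names(densities)) || any(!nzchar(names(densities)))) {
    abort("`densities` must be a fully named vector (cells per 100 μm).")
  }
  if (any(!is.finite(densities) | densities <= 0)) {
    abort("All densities must be finite and strictly positive.")
  }
  if (is.null(row_offsets)) {
    defaults <- c(IHC = -10, OHC1 = 8, OHC2 = 16, OHC3 = 24)
    row_offsets <- defaults[names(densities)]
    extra <- is.na(row_offsets)
    row_offsets[extra] <- 32 + 8 * seq_len(sum(extra))  # synthetic-only rows
    names(row_offsets) <- names(densities)
  }
  missing_off <- setdiff(names(densities), names(row_offsets))
  if (base::length(missing_off) > 0) {
    abort(sprintf("Missing row offset(s) for: %s",
                  paste(missing_off, collapse = ", ")))
  }
  if (is.function(profiles)) {
    profiles <- stats::setNames(rep(list(profiles), base::length(densities)),
                                names(densities))
  }
  missing_p <- setdiff(names(densities), names(profiles))
  if (base::length(missing_p) > 0) {
    abort(sprintf("Missing transduction-probability profile(s) for: %s",
                  paste(missing_p, collapse = ", ")),
          class = "cochleogram_config_error")
  }
  if (!is.null(cuts)) {
    cuts <- sort(as.numeric(cuts))
    if (any(cuts <= 0) || any(cuts >= length) || anyDuplicated(cuts)) {
      abort("`cuts` must be distinct positions strictly inside (0, length).",
            class = "cochleogram_config_error")
    }
  }
  structure(list(length = length, inner_radius = inner_radius, pitch = pitch,
                 turns = turns, densities = densities,
                 row_offsets = row_offsets, jitter = jitter,
                 profiles = profiles, placement = placement, cuts = cuts,
                 axis_spacing = axis_spacing, seed = as.integer(seed)),
            class = "synthetic_cochlea_spec")
}

# Dense spiral geometry table: arc length s, position, unit tangent/normal.
.spiral_table <- function(spec, step = 0.5) {
  theta_max <- 2 * pi * spec$turns
  b <- spec$pitch / (2 * pi)
  theta <- seq(0, theta_max, length.out = 20000L)
  r <- spec$inner_radius + b * theta
  ds <- sqrt(r^2 + b^2)
  s_raw <- c(0, cumsum((head(ds, -1) + tail(ds, -1)) / 2 * diff(theta)))
  k <- spec$length / s_raw[base::length(s_raw)]  # scale geometry to target length
  r <- r * k
  s <- s_raw * k
  x <- r * cos(theta); y <- r * sin(theta)
  # unit tangent from derivatives wrt theta
  bk <- b * k
  dx <- bk * cos(theta) - r * sin(theta)
  dy <- bk * sin(theta) + r * cos(theta)
  nrm <- sqrt(dx^2 + dy^2)
  list(s = s, x = x, y = y, tx = dx / nrm, ty = dy / nrm)
}

.spiral_at <- function(tab, s) {
  x <- approx(tab$s, tab$x, xout = s, ties = "ordered")$y
  y <- approx(tab$s, tab$y, xout = s, ties = "ordered")$y
  tx <- approx(tab$s, tab$tx, xout = s, ties = "ordered")$y
  ty <- approx(tab$s, tab$ty, xout = s, ties = "ordered")$y
  list(x = x, y = y, nx = -ty, ny = tx)
}

#' Generate a synthetic annotated cochlea
#'
#' Realizes a [synthetic_cochlea_spec()]: builds the spiral axis, places
#' cell rows along it at the requested densities and lateral offsets (with
#' positional jitter), draws each cell's transduction state from an
#' independent Bernoulli with probability \eqn{p(s)}, and assigns cells and
#' axis pieces to fragments when cut positions are given. Only transduced
#' cells appear in the annotation output (`$cells`), mirroring manual
#' annotation of reporter-positive cells; `$truth` holds every generated
#' cell with its generative (pre-jitter) arc-length coordinate.
#'
#' @param spec A `synthetic_cochlea_spec`.
#' @return A `synthetic_cochlea` list with elements `cells` (annotation
#'   tibble of transduced cells: `x`, `y`, `cell_type`, `fragment_id`),
#'   `axes` (named list of per-fragment axis polylines),
#'   `fragment_lengths` (named, base-to-apex order), `truth` (all cells:
#'   `cell_type`, `s_true`, `x`, `y`, `transduced`, `fragment_id`), `L`,
#'   and the originating `spec`.
#' @export
generate_cochlea <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cochlea_spec"))
  withr::with_seed(spec$seed, .generate_impl(spec))
}

.generate_impl <- function(spec) {
  L <- spec$length
  tab <- .spiral_table(spec)
  # validate p on a grid before any draw
  sgrid <- seq(0, L, length.out = 256)
  for (ct in names(spec$profiles)) {
    pv <- spec$profiles[[ct]](sgrid, L)
    if (any(!is.finite(pv)) || any(pv < 0) || any(pv > 1)) {
      abort(sprintf("Transduction probability for %s leaves [0, 1].", ct),
            class = "cochleogram_config_error")
    }
  }
  cut_breaks <- c(0, spec$cuts, L)
  frag_ids <- paste0("frag", seq_len(base::length(cut_breaks) - 1))

  truth <- purrr::map_dfr(names(spec$densities), function(ct) {
    dens <- spec$densities[[ct]] / 100  # cells per um
    n <- if (spec$placement == "equal") {
      round(L * dens)
    } else {
      stats::rpois(1, L * dens)
    }
    if (n == 0) {
      return(tibble(cell_type = character(), s_true = double(), x = double(),
                    y = double(), transduced = logical()))
    }
    s <- if (spec$placement == "equal") (seq_len(n) - 0.5) / n * L else sort(runif(n, 0, L))
    at <- .spiral_at(tab, s)
    off <- spec$row_offsets[[ct]]
    x <- at$x + off * at$nx + stats::rnorm(n, sd = spec$jitter)
    y <- at$y + off * at$ny + stats::rnorm(n, sd = spec$jitter)
    p <- spec$profiles[[ct]](s, L)
    tibble(cell_type = ct, s_true = s, x = x, y = y,
           transduced = runif(n) < p)
  })
  truth$fragment_id <- frag_ids[pmin(findInterval(truth$s_true, cut_breaks,
                                                  rightmost.closed = TRUE),
                                     base::length(frag_ids))]
  axes <- purrr::map2(head(cut_breaks, -1), tail(cut_breaks, -1),
                      function(a, b) {
    sa <- seq(a, b, by = spec$axis_spacing)
    if (sa[base::length(sa)] < b) sa <- c(sa, b)
    at <- .spiral_at(tab, sa)
    as_axis_polyline(at$x, at$y)
  })
  names(axes) <- frag_ids
  cells <- truth |>
    dplyr::filter(.data$transduced) |>
    dplyr::select("x", "y", "cell_type", "fragment_id")
  structure(list(
    cells = cells,
    axes = axes,
    fragment_lengths = stats::setNames(diff(cut_breaks), frag_ids),
    truth = truth,
    L = L,
    spec = spec
  ), class = "synthetic_cochlea")
}

#' @export
print.synthetic_cochlea <- function(x, ...) {
  cat(sprintf("<synthetic_cochlea> L = %g μm, %d fragment(s), %d cells (%d transduced)\n",
              x$L, base::length(x$axes), nrow(x$truth), nrow(x$cells)))
  invisible(x)
}

#' Sample transduced-cell longitudinal coordinates from a profile
#'
#' Draws `n` longitudinal coordinates from the distribution of transduced
#' cells implied by a transduction-probability profile over a uniform cell
#' placement, i.e. from the density proportional to \eqn{p(s)} on
#' `[0, L]`, by rejection sampling. Useful for calibrating the profile
#' comparison tests without running the full generator.
#'
#' @param n Number of coordinates to draw.
#' @param profile A `p(s, L)` function (see [profile_family()]).
#' @param L Domain length (μm).
#' @return A numeric vector of `n` coordinates in `[0, L]`.
#' @export
sample_coordinates <- function(n, profile = profile_family("constant", level = 1),
                               L = 5700) {
  stopifnot(is.function(profile), n >= 0)
  pmax_bound <- max(profile(seq(0, L, length.out = 512), L))
  if (pmax_bound <= 0) abort("Profile is identically zero; nothing to sample.")
  out <- double(0)
  while (base::length(out) < n) {
    m <- max(2L * (n - base::length(out)), 16L)
    s <- runif(m, 0, L)
    keep <- runif(m) < profile(s, L) / pmax_bound
    out <- c(out, s[keep])
  }
  out[seq_len(n)]
}

#' Write a generated cochlea to annotation and axis CSV files
#'
#' Writes, per fragment, the transduced-cell annotation CSV and the axis
#' polyline CSV in the formats consumed by [read_annotations()] and
#' [read_axis()] (coordinates already in μm, so re-load with
#' `pixel_size = 1`), plus the full ground truth as
#' `truth_synthetic.csv`. File content is a pure function of spec + seed.
#'
#' @param cochlea A `synthetic_cochlea` from [generate_cochlea()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_cochlea <- function(cochlea, dir) {
  stopifnot(inherits(cochlea, "synthetic_cochlea"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (fid in names(cochlea$axes)) {
    ann <- dplyr::filter(cochlea$cells, .data$fragment_id == fid)
    pa <- file.path(dir, paste0("annotations_", fid, ".csv"))
    readr::write_csv(ann, pa, progress = FALSE)
    ax <- cochlea$axes[[fid]]
    px <- file.path(dir, paste0("axis_", fid, ".csv"))
    readr::write_csv(tibble(x = ax$x, y = ax$y), px, progress = FALSE)
    paths[[paste0("annotations_", fid)]] <- pa
    paths[[paste0("axis_", fid)]] <- px
  }
  pt <- file.path(dir, "truth_synthetic.csv")
  readr::write_csv(cochlea$truth, pt, progress = FALSE)
  paths$truth <- pt
  invisible(paths)
}
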