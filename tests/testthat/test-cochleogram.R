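test_that("degenerate inputs give the expected densities", {
  empty <- compute_cochleogram(tibble::tibble(cell_type = character(),
                                              s = double()),
                               L = 5700, types = "IHC")
  expect_true(all(tidy(empty)$density_cells_per_um == 0))
  expect_equal(empty$n_cells[["IHC"]], 0L)

  out_of_range <- tibble::tibble(cell_type = "IHC", s = 6000)
  expect_error(compute_cochleogram(out_of_range, L = 5700),
               class = "cochleogram_validation_error")
})

test_that("a single interior cell reproduces the Gaussian peak value", {
  one <- compute_cochleogram(tibble::tibble(cell_type = "IHC", s = 2850),
                             L = 5700, sigma = 250)
  peak <- tidy(one) |> dplyr::filter(position_um == 2850)
  expect_equal(peak$density_cells_per_um, 1 / (250 * sqrt(2 * pi)),
               tolerance = 1e-3)
})

test_that("equally spaced cells give a uniform density at the spacing rate", {
  n <- 673; L <- 5700
  coords <- tibble::tibble(cell_type = "IHC", s = (seq_len(n) - 0.5) / n * L)
  cg <- compute_cochleogram(coords, L = L, sigma = 250)
  lam <- tidy(cg)$density_cells_per_um
  expect_lt(max(abs(lam - n / L)) / (n / L), 0.03)
})

test_that("boundary-corrected density integrates to the cell count", {
  withr::with_seed(2, {
    s <- sample_coordinates(400, profile_family("logistic"), L = 5700)
  })
  for (correct in c(TRUE, FALSE)) {
    cg <- compute_cochleogram(tibble::tibble(cell_type = "IHC", s = s),
                              L = 5700, boundary_correction = correct)
    integral <- trapz(tidy(cg)$position_um, tidy(cg)$density_cells_per_um)
    if (correct) {
      expect_equal(integral, 400, tolerance = 0.005)
    } else {
      expect_lt(integral, 400)  # uncorrected estimate loses edge mass
    }
  }
})

test_that("the cochleogram is invariant under input permutation", {
  withr::with_seed(3, {
    coords <- tibble::tibble(
      cell_type = sample(c("IHC", "OHC1"), 100, replace = TRUE),
      s = runif(100, 0, 5700))
    shuffled <- coords[sample.int(100), ]
  })
  expect_identical(tidy(compute_cochleogram(coords, L = 5700)),
                   tidy(compute_cochleogram(shuffled, L = 5700)))
})

test_that("larger smoothing windows never sharpen the profile", {
  withr::with_seed(4, {
    s <- sample_coordinates(300, profile_family("gaussian_bump"), L = 5700)
  })
  coords <- tibble::tibble(cell_type = "IHC", s = s)
  max_grad <- vapply(c(100, 250, 500, 1000), function(sigma) {
    # bump-concentrated cells exceed the reference locally: expected here
    f <- suppressWarnings(
      tidy(to_fraction(compute_cochleogram(coords, L = 5700,
                                           sigma = sigma))))$fraction
    max(abs(diff(f))) / 10
  }, numeric(1))
  expect_true(all(diff(max_grad) <= 1e-12))
})

test_that("fraction conversion divides density by the reference rate", {
  coords <- tibble::tibble(cell_type = rep(c("IHC", "OHC1"), each = 50),
                           s = rep(seq(100, 5600, length.out = 50), 2))
  cg <- compute_cochleogram(coords, L = 5700)
  prof <- to_fraction(cg, refs = c(IHC = 11.8, OHC1 = 13.7))
  joined <- dplyr::left_join(tidy(cg), tidy(prof),
                             by = c("position_um", "cell_type"))
  refs <- c(IHC = 11.8, OHC1 = 13.7)
  expect_equal(joined$fraction,
               joined$density_cells_per_um.x / (refs[joined$cell_type] / 100),
               ignore_attr = TRUE)

  # IHCs at exactly the reference spacing read out as full transduction
  n <- round(5700 * 11.8 / 100)
  full <- to_fraction(compute_cochleogram(
    tibble::tibble(cell_type = "IHC", s = (seq_len(n) - 0.5) / n * 5700),
    L = 5700))
  expect_equal(mean(tidy(full)$fraction), 1, tolerance = 0.01)

  zero <- to_fraction(compute_cochleogram(
    tibble::tibble(cell_type = character(), s = double()),
    L = 5700, types = "IHC"))
  expect_true(all(tidy(zero)$fraction == 0))

  expect_error(to_fraction(cg, refs = c(IHC = 11.8)), "OHC1",
               class = "cochleogram_config_error")
  expect_error(to_fraction(cg, refs = c(IHC = -1, OHC1 = 13.7)),
               class = "cochleogram_config_error")
})

test_that("over-unity fractions are reported, not clamped", {
  # 200 cells piled at one point exceed the reference density locally
  coords <- tibble::tibble(cell_type = "IHC", s = rep(2850, 200))
  cg <- compute_cochleogram(coords, L = 5700)
  expect_warning(prof <- to_fraction(cg), "1.05")
  expect_gt(max(tidy(prof)$fraction), 1.05)
})

test_that("fragment stacking offsets coordinates by upstream lengths", {
  frag1 <- list(coords = tibble::tibble(cell_type = "IHC", s = c(0, 2999)),
                length = 3000)
  frag2 <- list(coords = tibble::tibble(cell_type = "IHC", s = c(100, 2600)),
                length = 2700)
  stacked <- stack_fragments(list(frag1, frag2))
  expect_equal(stacked$L, 5700)
  expect_equal(stacked$coords$s, c(0, 2999, 3100, 5600))

  expect_error(stack_fragments(list()), class = "cochleogram_config_error")
  expect_error(stack_fragments(list(list(coords = frag1$coords))),
               class = "cochleogram_config_error")
})

test_that("a single fragment reproduces the unfragmented pipeline", {
  withr::with_seed(5, {
    coords <- tibble::tibble(cell_type = "IHC", s = runif(200, 0, 5700))
  })
  whole <- to_fraction(compute_cochleogram(coords, L = 5700))
  combined <- combine_fragments(list(list(coords = coords, length = 5700)))
  expect_equal(tidy(combined), tidy(whole))
})

test_that("relative resampling preserves constants, grids and ramps", {
  L <- 5700
  grid <- seq(0, L, by = 10)
  const <- profile_from_values(grid, list(IHC = rep(0.4, length(grid))))
  rc <- resample_relative(const, n_points = 57)
  expect_true(all(abs(rc$fraction - 0.4) < 1e-12))

  ramp <- profile_from_values(grid, list(IHC = grid / L))
  rr <- resample_relative(ramp, n_points = 101)
  expect_equal(rr$fraction, rr$position_rel, tolerance = 1e-6)

  # resampling onto the original grid is the identity
  same <- resample_relative(ramp, n_points = length(grid))
  expect_equal(same$fraction, grid / L, tolerance = 1e-9)

  expect_error(resample_relative(ramp, n_points = 1), "at least 2")
})
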