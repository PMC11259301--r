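test_that("CSV annotations load with calibration, validation and label maps", {
  path <- write_csv_fixture(data.frame(x = c(10, 30), y = c(20, 40),
                                       cell_type = c("IHC", "OHC2")))
  ann <- suppressMessages(read_annotations(path, pixel_size = 1))
  expect_equal(nrow(ann), 2)
  expect_equal(ann$cell_type, c("IHC", "OHC2"))
  expect_equal(ann$x, c(10, 30))

  scaled <- suppressMessages(read_annotations(path, pixel_size = 0.5))
  expect_equal(scaled$x, c(5, 15))
  expect_equal(scaled$y, c(10, 20))

  mapped_path <- write_csv_fixture(data.frame(
    x = 1, y = 2, cell_type = "inner hair cell"))
  mapped <- suppressMessages(read_annotations(
    mapped_path, label_map = c("inner hair cell" = "IHC")))
  expect_equal(mapped$cell_type, "IHC")

  bad_label <- write_csv_fixture(data.frame(x = 1, y = 2, cell_type = "OHC4"))
  expect_error(read_annotations(bad_label), "OHC4",
               class = "cochleogram_validation_error")

  no_col <- write_csv_fixture(data.frame(x = 1, y = 2))
  expect_error(read_annotations(no_col), "cell_type",
               class = "cochleogram_format_error")

  non_finite <- write_csv_fixture(data.frame(x = "Inf", y = 2, cell_type = "IHC"))
  expect_error(read_annotations(non_finite), "[Nn]on-finite",
               class = "cochleogram_validation_error")

  expect_error(read_annotations(path, pixel_size = -1), "pixel_size")
})

test_that("annotation write then re-load is the identity", {
  withr::with_seed(42, {
    ann <- tibble::tibble(
      x = round(runif(50, 0, 5000), 6), y = round(runif(50, -100, 100), 6),
      cell_type = sample(cell_types(), 50, replace = TRUE),
      fragment_id = sample(c("frag1", "frag2"), 50, replace = TRUE))
  })
  path <- tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- suppressMessages(read_annotations(path))
  expect_equal(back$x, ann$x)
  expect_equal(back$y, ann$y)
  expect_identical(back$cell_type, ann$cell_type)
  expect_identical(back$fragment_id, ann$fragment_id)
})

test_that("cell-type registry rejects unknown labels until registered", {
  path <- write_csv_fixture(data.frame(x = 1, y = 2, cell_type = "HensenC"))
  expect_error(read_annotations(path), "HensenC")
  register_cell_types("HensenC")
  expect_no_error(suppressMessages(read_annotations(path)))
  reset_cell_types()
  expect_false("HensenC" %in% cell_types())
})

test_that("axis polylines load ordered, deduplicated and validated", {
  path <- write_csv_fixture(data.frame(x = c(0, 100, 100, 200),
                                       y = c(0, 0, 0, 0)))
  poly <- read_axis(path)
  expect_equal(nrow(poly), 3)
  expect_equal(poly$x, c(0, 100, 200))

  # order preserved, including non-monotone traces
  wiggly <- write_csv_fixture(data.frame(x = c(0, 50, 25), y = c(0, 10, 30)))
  expect_equal(read_axis(wiggly)$x, c(0, 50, 25))

  single <- write_csv_fixture(data.frame(x = 1, y = 1))
  expect_error(read_axis(single), "2 distinct",
               class = "cochleogram_validation_error")
  all_dup <- write_csv_fixture(data.frame(x = c(5, 5, 5), y = c(2, 2, 2)))
  expect_error(read_axis(all_dup), class = "cochleogram_validation_error")

  scaled <- read_axis(path, pixel_size = 2)
  expect_equal(scaled$x, c(0, 200, 400))
})

test_that("ImageJ ROI and CSV readers agree point for point", {
  x <- c(10, 250, 471, 903)
  y <- c(20, 80, 35, 310)

  roi <- write_imagej_roi_fixture(x, y, name = "OHC1", type = 10L)
  csv <- write_csv_fixture(data.frame(x = x, y = y, cell_type = "OHC1"))
  from_roi <- suppressMessages(read_annotations(roi))
  from_csv <- suppressMessages(read_annotations(csv))
  expect_equal(from_roi$x, from_csv$x)
  expect_equal(from_roi$y, from_csv$y)
  expect_identical(from_roi$cell_type, from_csv$cell_type)

  # segmented-line ROI versus the equivalent CSV polyline
  roi_line <- write_imagej_roi_fixture(x, y, name = "axis", type = 5L)
  csv_line <- write_csv_fixture(data.frame(x = x, y = y))
  expect_equal(read_axis(roi_line)$x, read_axis(csv_line)$x)
  expect_equal(read_axis(roi_line)$y, read_axis(csv_line)$y)

  # a zip archive with one multipoint ROI per cell type
  f1 <- write_imagej_roi_fixture(c(1, 2), c(3, 4), name = "IHC")
  f2 <- write_imagej_roi_fixture(c(7, 8), c(9, 10), name = "OHC2")
  zip_path <- write_zip_fixture(c("IHC.roi" = f1, "OHC2.roi" = f2))
  ann <- suppressMessages(read_annotations(zip_path))
  expect_setequal(ann$cell_type, c("IHC", "OHC2"))
  expect_equal(sort(ann$x), c(1, 2, 7, 8))

  expect_error(read_imagej_roi(write_csv_fixture(data.frame(x = 1))),
               "Iout", class = "cochleogram_format_error")
})

test_that("profile CSV round-trips losslessly and keeps the stated layout", {
  coords <- tibble::tibble(cell_type = rep(c("IHC", "OHC1"), c(5, 4)),
                           s = c(100, 900, 2850, 4000, 5000,
                                 200, 2850, 3000, 5500))
  prof <- to_fraction(compute_cochleogram(coords, L = 5700, grid_step = 100))
  path <- tempfile(fileext = ".csv")
  write_profile(prof, path, comment = c("demo header"))
  back <- read_profile(path)
  expect_equal(tidy(back)$fraction,
               dplyr::arrange(tidy(prof), cell_type, position_um)$fraction,
               tolerance = 1e-9)
  expect_equal(tidy(back)$position_um,
               dplyr::arrange(tidy(prof), cell_type, position_um)$position_um)

  # layout: rows grouped per cell type, grid repeated per type
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  expect_identical(names(raw),
                   c("position_um", "cell_type", "fraction",
                     "density_cells_per_um"))
  expect_identical(raw$cell_type, rep(c("IHC", "OHC1"), each = 58))
  expect_identical(raw$position_um[1:58], raw$position_um[59:116])

  # profile with no cells: header plus zero-fraction rows for declared types
  empty <- to_fraction(compute_cochleogram(
    tibble::tibble(cell_type = character(), s = double()),
    L = 1000, grid_step = 100, types = "IHC"))
  epath <- tempfile(fileext = ".csv")
  write_profile(empty, epath)
  eraw <- readr::read_csv(epath, show_col_types = FALSE)
  expect_equal(nrow(eraw), 11)
  expect_true(all(eraw$fraction == 0))
})
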