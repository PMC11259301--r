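test_that("profile families evaluate to their defining shapes", {
  const <- profile_family("constant", level = 0.5)
  expect_equal(const(seq(0, 5700, by = 100), 5700),
               rep(0.5, 58))

  lin <- profile_family("linear", from = 0.8, to = 0.2)
  expect_equal(lin(2850, 5700), 0.5)
  expect_equal(lin(0, 5700), 0.8)
  expect_equal(lin(5700, 5700), 0.2)

  bump <- profile_family("gaussian_bump", center = 0.5, width = 0.1,
                         height = 0.9)
  s <- seq(0, 5700, by = 10)
  expect_equal(s[which.max(bump(s, 5700))], 2850)
  expect_equal(max(bump(s, 5700)), 0.9)

  logi <- profile_family("logistic", p_base = 0.5, p_apex = 0)
  vals <- logi(s, 5700)
  expect_true(all(diff(vals) <= 0))  # basal-peaked decline
  expect_equal(vals[1], 0.5 / (1 + exp(-3.5)))  # sigmoid tail at the base
  expect_lt(vals[length(vals)], 0.01)

  # out-of-range parameters are clipped to [0, 1]
  hot <- profile_family("linear", from = 1.5, to = -0.5)
  expect_true(all(hot(s, 5700) >= 0 & hot(s, 5700) <= 1))

  expect_error(profile_family("sigmoid"), "Unknown profile family",
               class = "cochleogram_config_error")
})

test_that("zero and full transduction probabilities bound the annotations", {
  spec0 <- synthetic_cochlea_spec(profiles = profile_family("constant",
                                                            level = 0),
                                  seed = 21)
  gen0 <- generate_cochlea(spec0)
  expect_equal(nrow(gen0$cells), 0)
  expect_equal(nrow(gen0$truth),
               sum(round(5700 * reference_densities() / 100)))
  expect_true(all(!gen0$truth$transduced))

  spec1 <- synthetic_cochlea_spec(profiles = profile_family("constant",
                                                            level = 1),
                                  seed = 21)
  gen1 <- generate_cochlea(spec1)
  n_ihc <- sum(gen1$cells$cell_type == "IHC")
  expect_lte(abs(n_ihc - floor(5700 * 0.118)), 1)
  expect_true(all(gen1$truth$transduced))
})

test_that("identical spec and seed give byte-identical files", {
  spec <- synthetic_cochlea_spec(seed = 99, cuts = 2850)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cochlea(generate_cochlea(spec), d1)
  write_cochlea(generate_cochlea(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # and a different seed gives different annotations
  other <- write_cochlea(generate_cochlea(
    synthetic_cochlea_spec(seed = 100, cuts = 2850)), withr::local_tempdir())
  expect_false(identical(
    readr::read_file(file.path(d1, "annotations_frag1.csv")),
    readr::read_file(other$annotations_frag1)))
})

test_that("ground truth stores generative coordinates and fragment pieces", {
  spec <- synthetic_cochlea_spec(seed = 31, cuts = c(2000, 4000))
  gen <- generate_cochlea(spec)
  expect_named(gen$axes, c("frag1", "frag2", "frag3"))
  expect_equal(unname(gen$fragment_lengths), c(2000, 2000, 1700))
  # fragment assignment respects the cut positions
  by_frag <- split(gen$truth$s_true, gen$truth$fragment_id)
  expect_true(all(by_frag$frag1 < 2000))
  expect_true(all(by_frag$frag2 >= 2000 & by_frag$frag2 < 4000))
  expect_true(all(by_frag$frag3 >= 4000))
  # transduced annotations are a subset of the truth
  expect_equal(nrow(gen$cells), sum(gen$truth$transduced))

  expect_error(synthetic_cochlea_spec(cuts = c(2000, 2000)),
               class = "cochleogram_config_error")
  expect_error(synthetic_cochlea_spec(cuts = 6000),
               class = "cochleogram_config_error")
  bad_p <- synthetic_cochlea_spec(seed = 1)
  bad_p$profiles$IHC <- function(s, L) rep(1.2, length(s))
  expect_error(generate_cochlea(bad_p), "IHC",
               class = "cochleogram_config_error")
})

test_that("transduced counts stay binomial across seeds", {
  p <- profile_family("linear", from = 0.8, to = 0.2)
  dens <- c(IHC = 11.8, OHC1 = 13.7)
  n_by_type <- round(5700 * dens / 100)
  counts <- vapply(1:100, function(seed) {
    gen <- generate_cochlea(synthetic_cochlea_spec(
      densities = dens, profiles = p, seed = seed))
    c(sum(gen$cells$cell_type == "IHC"), sum(gen$cells$cell_type == "OHC1"))
  }, numeric(2))
  for (i in 1:2) {
    n <- n_by_type[i]
    s_equal <- (seq_len(n) - 0.5) / n * 5700
    pbar <- mean(p(s_equal, 5700))
    sd_bin <- sqrt(n * pbar * (1 - pbar))
    expect_true(all(abs(counts[i, ] - n * pbar) <= 4 * sd_bin))
  }
})

test_that("poisson placement draws counts around the target density", {
  counts <- vapply(1:30, function(seed) {
    nrow(generate_cochlea(synthetic_cochlea_spec(
      densities = c(IHC = 11.8), placement = "poisson",
      profiles = profile_family("constant", level = 1), seed = seed))$cells)
  }, numeric(1))
  lambda <- 5700 * 0.118
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 30))
  expect_gt(var(counts), 0)  # poisson, not deterministic, placement
})

test_that("coordinate sampler reproduces the target density shape", {
  withr::with_seed(6, {
    s_lin <- sample_coordinates(4000, profile_family("linear", from = 0.8,
                                                     to = 0.2), L = 5700)
    s_const <- sample_coordinates(4000, profile_family("constant"), L = 5700)
  })
  expect_true(all(s_lin >= 0 & s_lin <= 5700))
  # linear 0.8 -> 0.2: E[u] = (0.4 - 0.2) / 0.5 = 0.4
  expect_equal(mean(s_lin), 5700 * 0.4, tolerance = 0.03)
  expect_equal(mean(s_const), 2850, tolerance = 0.03)
})
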