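test_that("zero-noise phantoms are the exact piecewise-constant anatomy", {
  sp <- small_spec(speckle_sigma = 0, n_outliers = 0L)
  ph <- generate_phantom(sp)
  lv <- sort(unique(as.numeric(ph$image)))
  expect_identical(lv, sort(c(sp$background_intensity, sp$tendon_intensity,
                              sp$bursa_intensity, sp$cortex_intensity)))
  # with outliers a fifth level appears
  ph2 <- generate_phantom(small_spec(speckle_sigma = 0, n_outliers = 2L))
  expect_length(unique(as.numeric(ph2$image)), 5L)
  expect_identical(dim(ph$image), dim(ph$truth_mask))
})

test_that("identical specs give bit-identical phantoms", {
  sp <- small_spec(rng_seed = 7L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_mask, b$truth_mask)
  expect_identical(a$outlier_mask, b$outlier_mask)
})

test_that("band regions are brighter than background, by direct averaging", {
  ph <- generate_phantom(phantom_spec())  # canonical 421x580
  sp <- ph$spec
  rho <- tendonseg:::phantom_rho(sp)
  R <- sp$curvature_radius; hw <- sp$tendon_width / 2; t <- sp$band_thickness
  bands <- (rho > R - hw - t & rho <= R - hw) |
           (rho > R + hw & rho <= R + hw + t)
  background <- rho <= R - hw - t | rho > R + hw + t
  background <- background & !ph$outlier_mask
  expect_gt(mean(ph$image[bands]), mean(ph$image[background]))
  # hypoechoic tendon: bursa median above tendon median under speckle
  bursa <- rho > R - hw - t & rho <= R - hw
  tendon <- rho > R - hw & rho <= R + hw
  expect_gt(median(ph$image[bursa]), median(ph$image[tendon]))
})

test_that("the truth mask is a single 8-connected component", {
  for (seed in 1:3) {
    ph <- generate_phantom(small_spec(rng_seed = seed,
                                      curvature_radius = 150 + 40 * seed))
    comps <- label_components_8(ph$truth_mask)
    expect_identical(comps$n_components, 1L)
    expect_identical(sum(comps$areas), sum(ph$truth_mask))
  }
})

test_that("truth area is a deterministic function of the geometry", {
  a <- generate_phantom(small_spec(rng_seed = 1L))
  b <- generate_phantom(small_spec(rng_seed = 99L))  # only the speckle differs
  expect_identical(sum(a$truth_mask), sum(b$truth_mask))
})

test_that("spec validation names the offending field", {
  expect_error(phantom_spec(tendon_width = 0), "tendon_width")
  expect_error(phantom_spec(curvature_radius = 10), "curvature_radius")
  expect_error(phantom_spec(bursa_intensity = 0.1, tendon_intensity = 0.5),
               "bursa_intensity")
  expect_error(phantom_spec(speckle_sigma = -1), "speckle_sigma")
})

test_that("a degenerate-range cohort of one reproduces the base phantom", {
  base <- small_spec(rng_seed = 11L)
  ranges <- list(tendon_width = c(24, 24), curvature_radius = c(200, 200))
  co <- generate_cohort(1, base = base, variation_ranges = ranges, seed = 5L)
  ref <- generate_phantom(base)
  expect_identical(co[[1]]$image, ref$image)
  expect_identical(co[[1]]$truth_mask, ref$truth_mask)
})

test_that("cohort spec draws are seeded, in range, and reproducible", {
  ranges <- list(tendon_width = c(18, 30), tendon_center_row = c(0.42, 0.5))
  co1 <- generate_cohort(6, base = small_spec(), variation_ranges = ranges,
                         seed = 42L)
  co2 <- generate_cohort(6, base = small_spec(), variation_ranges = ranges,
                         seed = 42L)
  s1 <- cohort_specs(co1); s2 <- cohort_specs(co2)
  expect_identical(s1, s2)
  expect_true(all(s1$tendon_width >= 18 & s1$tendon_width <= 30))
  expect_true(all(s1$tendon_center_row >= 0.42 & s1$tendon_center_row <= 0.5))
  # unvaried fields stay at base values
  expect_true(all(s1$band_thickness == 6))
  expect_error(generate_cohort(0, base = small_spec()), "at least 1")
  expect_error(generate_cohort(2, base = small_spec(),
                               variation_ranges = list(tendon_width = c(30, 18))),
               "range")
})

test_that("cohorts round-trip through PNG on disk", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(2, base = small_spec(), seed = 1L)
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("phantom_001.png", "phantom_002.png",
                    "truth_001.png", "truth_002.png", "specs.json"))
  img <- read_gray(file.path(dir, "phantom_001.png"))
  expect_identical(dim(img), dim(co[[1]]$image))
  # 8-bit quantisation on write
  expect_lt(max(abs(img - co[[1]]$image)), 1 / 255)
  expect_identical(read_mask(file.path(dir, "truth_002.png")),
                   co[[2]]$truth_mask)
})
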