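test_that("forward/inverse is a tight frame on assorted sizes", {
  set.seed(21)
  for (dims in list(c(64, 64), c(65, 70), c(128, 96))) {
    for (rep in 1:3) {
      x <- matrix(runif(prod(dims)), dims[1], dims[2])
      d <- fdct_forward(x, n_scales = 2, orientations = 16)
      y <- fdct_inverse(d)
      expect_lt(sqrt(sum((y - x)^2) / sum(x^2)), 1e-6)
      # Parseval: coefficient energy equals pixel energy
      expect_lt(abs(curvelet_energy(d) - sum(x^2)) / sum(x^2), 1e-6)
    }
  }
  # deeper decomposition with more orientations
  x <- matrix(runif(96 * 96), 96, 96)
  d <- fdct_forward(x, n_scales = 3, orientations = 32)
  expect_lt(sqrt(sum((fdct_inverse(d) - x)^2) / sum(x^2)), 1e-6)
})

test_that("a constant image concentrates all energy in the coarse band", {
  x <- matrix(0.6, 64, 64)
  d <- fdct_forward(x, 2, 16)
  coarse <- sum(d$coeffs[[1]][[1]]^2)
  fine <- curvelet_energy(d) - coarse
  expect_lt(fine, 1e-10 * curvelet_energy(d))
})

test_that("the transform is linear", {
  set.seed(22)
  x1 <- matrix(runif(64 * 64), 64, 64)
  x2 <- matrix(runif(64 * 64), 64, 64)
  a <- 1.7; b <- -0.4
  d12 <- fdct_forward(a * x1 + b * x2, 2, 16)
  d1 <- fdct_forward(x1, 2, 16); d2 <- fdct_forward(x2, 2, 16)
  for (j in seq_along(d12$coeffs)) {
    for (w in seq_along(d12$coeffs[[j]])) {
      expect_lt(max(abs(d12$coeffs[[j]][[w]] -
                        (a * d1$coeffs[[j]][[w]] + b * d2$coeffs[[j]][[w]]))),
                1e-8)
    }
  }
  # inverse linearity: all-zero coefficients give the zero image
  dz <- d1
  for (j in seq_along(dz$coeffs)) {
    for (w in seq_along(dz$coeffs[[j]])) dz$coeffs[[j]][[w]][] <- 0
  }
  expect_equal(fdct_inverse(dz), matrix(0, 64, 64))
})

test_that("input validation rejects bad geometry", {
  expect_error(fdct_forward(matrix(0.1, 8, 64), n_scales = 4), "2\\^n_scales")
  expect_error(fdct_forward(matrix(0.1, 64, 64), orientations = 10),
               "multiple of 4")
  d <- fdct_forward(matrix(runif(64^2), 64, 64), 2, 16)
  d$coeffs[[2]][[3]] <- matrix(0, 2, 2)
  expect_error(fdct_inverse(d), "geometry mismatch")
})

test_that("retain_top_fraction keeps exactly the largest coefficients", {
  set.seed(23)
  x <- matrix(runif(64 * 64), 64, 64)
  d <- fdct_forward(x, 2, 16)
  # p = 1: decomposition unchanged, reconstruction exact
  d1 <- retain_top_fraction(d, 1)
  expect_identical(d1$coeffs, d$coeffs)
  # full-sort oracle for the retained count
  p <- 0.065
  dk <- retain_top_fraction(d, p)
  av <- abs(unlist(lapply(d$coeffs, function(s) lapply(s, as.numeric))))
  N <- length(av)
  thr <- sort(av, decreasing = TRUE)[ceiling(p * N)]
  kept <- sum(unlist(lapply(dk$coeffs, function(s) lapply(s, as.numeric))) != 0)
  expect_identical(kept, sum(av >= thr))
  expect_gte(kept, ceiling(p * N))
  # a decomposition with a single nonzero coefficient survives any p
  dz <- d
  for (j in seq_along(dz$coeffs)) {
    for (w in seq_along(dz$coeffs[[j]])) dz$coeffs[[j]][[w]][] <- 0
  }
  dz$coeffs[[2]][[5]][3, 4] <- 2.5
  ds <- retain_top_fraction(dz, 0.01)
  expect_identical(ds$coeffs[[2]][[5]][3, 4], 2.5)
  expect_error(retain_top_fraction(d, 0), "fraction")
  expect_error(retain_top_fraction(d, 1.2), "fraction")
})

test_that("retained-energy ratio tracks the Parseval prediction from below", {
  # thresholded coefficients of a redundant tight frame leave the analysis
  # range, so the reconstruction energy is bounded above by -- and close
  # to -- the retained coefficient energy
  ph <- generate_phantom(small_spec(rng_seed = 31L))
  d <- fdct_forward(ph$image, 2, 16)
  for (p in c(0.05, 0.1)) {
    dk <- retain_top_fraction(d, p)
    rec <- fdct_inverse(dk)
    img_ratio <- sum(rec^2) / sum(ph$image^2)
    coef_ratio <- curvelet_energy(dk) / curvelet_energy(d)
    expect_lte(img_ratio, coef_ratio + 1e-9)
    expect_lt(coef_ratio - img_ratio, 0.10)
  }
  # with full retention the two coincide exactly
  expect_equal(sum(fdct_inverse(retain_top_fraction(d, 1))^2),
               curvelet_energy(d), tolerance = 1e-9)
})

test_that("image_energy follows the squared-intensity convention", {
  img <- matrix(1, 3, 3)
  mask <- matrix(FALSE, 3, 3); mask[1:2, 1:2] <- TRUE
  er <- image_energy(img, mask)
  expect_equal(er$ratio, 4 / 9)
  expect_equal(er$region_energy, 4)
  expect_equal(image_energy(img)$ratio, 1)
  expect_equal(image_energy(img, matrix(TRUE, 3, 3))$ratio, 1)
  expect_equal(image_energy(img, matrix(FALSE, 3, 3))$ratio, 0)
  expect_error(image_energy(img, matrix(TRUE, 2, 2)), "shape")
  # absolute-value convention for sensitivity analysis
  expect_equal(image_energy(0.5 * img, mask, convention = "absolute")$ratio,
               4 / 9)
})

test_that("energy_scan cells are independent and saturate at p = 1", {
  ph <- generate_phantom(small_spec(rng_seed = 32L))
  img <- ph$image
  tab <- energy_scan(img, scales = 2:3, orientations = 16,
                     fractions = c(0.05, 0.075, 1))
  expect_identical(nrow(tab), 6L)
  # full retention reconstructs exactly
  expect_true(all(abs(tab$energy_ratio[tab$fraction == 1] - 1) < 1e-6))
  # ratio nondecreasing in p within each setting
  for (s in 2:3) {
    r <- tab$energy_ratio[tab$scale == s]
    expect_true(all(diff(r) >= -1e-12))
  }
  # no state leakage: each cell equals its standalone recomputation
  d <- fdct_forward(img, 3, 16)
  rec <- fdct_inverse(retain_top_fraction(d, 0.075))
  cell <- tab$energy_ratio[tab$scale == 3 & tab$fraction == 0.075]
  expect_identical(cell, sum(rec^2) / sum(img^2))
  expect_error(energy_scan(img, scales = integer(0)), "nonempty")
})
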