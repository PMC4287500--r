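test_that("rescale_to_levels maps endpoints and preserves order", {
  img <- matrix(c(0.2, 0.5, 0.8, 0.35), 2, 2)
  out <- rescale_to_levels(img)
  expect_identical(out[img == 0.8], 1)     # max -> level 255
  expect_identical(out[img == 0.2], 0)     # min -> level 0
  expect_identical(rescale_to_levels(matrix(0.4, 3, 3)), matrix(0, 3, 3))
  set.seed(41)
  img <- matrix(runif(80), 8, 10)
  out <- rescale_to_levels(img)
  # monotone: every pixel pair keeps its order (ties may be created by
  # quantisation but never inverted)
  o <- order(img)
  expect_true(all(diff(out[o]) >= 0))
  expect_true(all(out * 255 == round(out * 255)))  # quantised to levels
})

test_that("threshold_mu_alpha_sigma applies T = mu + alpha*sigma", {
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  mask <- threshold_mu_alpha_sigma(img, alpha = 0.5)
  # hand computation: mu = 1/25 = 0.04, sd = sqrt(0.96/24) = 0.2 exactly
  expect_equal(attr(mask, "threshold"), 0.14)
  expect_identical(sum(mask), 1L)
  expect_true(mask[3, 3])
  # constant image: empty mask with the sigma-zero flag
  cm <- threshold_mu_alpha_sigma(matrix(0.5, 4, 4), alpha = 0.5)
  expect_false(any(cm))
  expect_true(attr(cm, "sigma_zero"))
  # per-pixel loop oracle on a random image
  set.seed(42)
  img <- matrix(runif(15 * 13), 15, 13)
  mask <- threshold_mu_alpha_sigma(img, alpha = 0.3)
  thr <- mean(img) + 0.3 * sd(as.numeric(img))
  for (i in seq_len(15)) for (j in seq_len(13)) {
    expect_identical(mask[i, j], img[i, j] >= thr)
  }
  expect_error(threshold_mu_alpha_sigma(img, alpha = 1.5), "alpha")
})

test_that("label_components_8 agrees with a flood-fill oracle", {
  expect_identical(label_components_8(matrix(FALSE, 4, 4))$n_components, 0L)
  # diagonal touch is one component under 8-connectivity
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(label_components_8(diag2)$n_components, 1L)
  set.seed(43)
  for (rep in 1:20) {
    mask <- random_mask(32, 32, p = runif(1, 0.2, 0.6))
    got <- label_components_8(mask)
    ref <- flood_label_8(mask)
    expect_identical(got$labels, ref)
    expect_identical(got$n_components, max(ref))
    expect_identical(as.integer(got$areas),
                     as.integer(tabulate(ref[ref > 0], nbins = max(ref))))
    expect_identical(sum(got$areas), sum(mask))
  }
})

test_that("area_filter drops small blobs, with optional size scaling", {
  mask <- matrix(FALSE, 10, 10)
  mask[2:3, 2:5] <- TRUE            # 8 px blob
  mask[7:9, 8] <- TRUE              # 3 px blob
  comps <- label_components_8(mask)
  out <- area_filter(comps, 5)
  expect_identical(sum(out), 8L)
  expect_true(all(out[2:3, 2:5]))
  expect_identical(area_filter(comps, 1), matrix(TRUE, 10, 10) & mask,
                   ignore_attr = TRUE)
  expect_false(any(area_filter(comps, 50)))
  # threshold scales with image size relative to the reference
  scaled <- area_filter(comps, 5000, reference_shape = c(421L, 580L))
  expect_equal(attr(scaled, "min_area_scaled"), 5000 * 100 / (421 * 580))
  expect_identical(sum(scaled), 11L)  # both blobs clear the scaled bar
  # never merges or grows components
  expect_true(all(which(out) %in% which(mask)))
})

test_that("elementary geodesic operations match hand computations", {
  marker <- matrix(c(0, 0, 1, 0, 0, 0, 0), 1, 7)
  maskimg <- matrix(c(0, 1, 1, 1, 0, 1, 1), 1, 7)
  out <- geodesic_dilate(marker, maskimg, se = matrix(1, 1, 3))
  expect_equal(out, matrix(c(0, 1, 1, 1, 0, 0, 0), 1, 7))
  expect_equal(geodesic_dilate(maskimg, maskimg), maskimg)  # fixed point
  zero <- matrix(0, 1, 7)
  expect_equal(geodesic_dilate(zero, maskimg), zero)
  expect_error(geodesic_dilate(maskimg, marker), "exceed")
  ones <- matrix(1, 4, 4)
  expect_equal(geodesic_erode(ones, ones), ones)
  expect_error(geodesic_erode(matrix(0, 4, 4), ones), "below")
})

test_that("geodesic erosion is the complement dual of geodesic dilation", {
  set.seed(44)
  for (rep in 1:10) {
    u <- matrix(runif(100), 10, 10); v <- matrix(runif(100), 10, 10)
    g <- pmin(u, v); f <- pmax(u, v)  # f >= g
    lhs <- geodesic_erode(f, g)
    rhs <- 1 - geodesic_dilate(1 - f, 1 - g)
    expect_equal(lhs, rhs)
  }
})

test_that("binary reconstruction equals marker-constrained flood fill", {
  mask <- matrix(0, 12, 16)
  mask[2:5, 2:6] <- 1    # blob A
  mask[8:11, 10:15] <- 1 # blob B
  marker <- matrix(0, 12, 16); marker[3, 3] <- 1  # touches A only
  rec <- reconstruct_by_dilation(marker, mask)
  expect_equal(rec > 0.5, flood_reconstruct(marker > 0.5, mask > 0.5))
  expect_false(any(rec[8:11, 10:15] > 0))
  # idempotence / stability
  expect_equal(reconstruct_by_dilation(rec, mask), rec)
  expect_equal(reconstruct_by_dilation(mask, mask), mask)
  set.seed(45)
  for (rep in 1:15) {
    mk <- random_mask(16, 16, 0.45)
    sub <- mk & random_mask(16, 16, 0.3)
    rec <- reconstruct_by_dilation(matrix(as.numeric(sub), 16, 16),
                                   matrix(as.numeric(mk), 16, 16))
    expect_identical(rec > 0.5, flood_reconstruct(sub, mk))
  }
})

test_that("open_by_reconstruction is anti-extensive, increasing, idempotent", {
  set.seed(46)
  se <- disc_se(2)
  for (rep in 1:10) {
    g2 <- matrix(runif(30 * 30), 30, 30)
    g1 <- pmin(g2, matrix(runif(30 * 30), 30, 30))  # g1 <= g2
    o1 <- open_by_reconstruction(g1, se)
    o2 <- open_by_reconstruction(g2, se)
    expect_true(all(o1 <= g1 + 1e-12))              # anti-extensive
    expect_true(all(o1 <= o2 + 1e-12))              # increasing
    expect_equal(open_by_reconstruction(o2, se), o2) # idempotent
  }
})

test_that("opening by reconstruction keeps or kills whole structures", {
  se <- disc_se(3)
  big <- matrix(0, 30, 30); big[5:20, 5:25] <- 1      # SE fits inside
  small <- matrix(0, 30, 30); small[4:6, 9:11] <- 1   # SE never fits
  expect_equal(open_by_reconstruction(big, se), big)  # boundary untouched
  expect_equal(open_by_reconstruction(small, se), matrix(0, 30, 30))
})

test_that("morphological_cleanup consolidates and filters the mask", {
  # one big solid blob survives as a single component
  blob <- matrix(FALSE, 60, 60); blob[10:40, 5:55] <- TRUE
  out <- morphological_cleanup(blob, se = ellipse_se(5, 2),
                               final_min_area = 100,
                               reference_shape = c(60L, 60L))
  expect_identical(label_components_8(out)$n_components, 1L)
  expect_false(attr(out, "segmentation_failure"))
  # isolated satellite smaller than the SE is removed; a bridge-attached one
  # is regrown with its component (reconstruction semantics) and must be
  # handled by the area rules instead
  mask <- blob
  mask[25, 56:58] <- TRUE          # thin spur off the big blob
  iso <- matrix(FALSE, 60, 60); iso[50:52, 50:52] <- TRUE
  out2 <- morphological_cleanup(mask | iso, se = ellipse_se(5, 2),
                                final_min_area = 100,
                                reference_shape = c(60L, 60L))
  expect_false(any(out2[50:52, 50:52]))          # isolated satellite gone
  expect_true(all(out2[10:40, 5:55]))            # big blob intact
  # second application changes (almost) nothing
  out3 <- morphological_cleanup(out2, se = ellipse_se(5, 2),
                                final_min_area = 100,
                                reference_shape = c(60L, 60L))
  expect_lt(sum(out3 != out2) / length(out2), 0.01)
  # empty result is flagged, not silently returned
  tiny <- matrix(FALSE, 60, 60); tiny[1:2, 1:2] <- TRUE
  out4 <- morphological_cleanup(tiny, se = ellipse_se(5, 2),
                                final_min_area = 100,
                                reference_shape = c(60L, 60L))
  expect_true(attr(out4, "segmentation_failure"))
  expect_false(any(out4))
})
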