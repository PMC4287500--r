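# Candidate-mask generation from the curvelet reconstruction: gray-level
# rescale, mean-plus-scaled-deviation threshold, 8-connected component
# analysis with area filtering, and geodesic morphological reconstruction.
#
# The area rule is calibrated at the canonical 421x580 working size (blobs
# under ~5000 px are outliers there) and scales linearly with pixel count for
# other sizes. The structuring element is a wide-flat elliptical disc
# (17x6 semi-extents) matching the lateral band geometry of the tendon.

ebi_mat <- function(x) {
  # EBImage operations can return Image objects; keep plain matrices
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Rescale an image to 256 gray levels
#'
#' Linear min-to-0 / max-to-255 rescale, quantised to integer levels and
#' stored back normalised (level/255). A constant image maps to all zeros.
#' The rescale is monotone: pixel intensity order is preserved.
#'
#' @param image Numeric matrix.
#' @return Numeric matrix in `[0, 1]` taking values `k/255`.
#' @export
rescale_to_levels <- function(image) {
  image <- as_gray_image(image)
  rng <- range(image)
  # a numerically constant image (e.g. rounding ripple on a flat
  # reconstruction) must not have its noise amplified to full range
  if (rng[2] - rng[1] <= 1e-8 * max(1, abs(rng[2]))) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  q <- round((image - rng[1]) / (rng[2] - rng[1]) * 255)
  q / 255
}

#' Mean-plus-scaled-deviation threshold
#'
#' Thresholds at \eqn{T = \mu + \alpha\sigma} where \eqn{\mu} and
#' \eqn{\sigma} are the image mean and standard deviation; pixels with
#' \eqn{p(i,j) \ge T} become foreground. `alpha < 1` is chosen small enough
#' that the hyperechoic structures survive. The realised threshold is
#' attached as attribute `"threshold"`. A constant image (\eqn{\sigma = 0})
#' yields an empty mask flagged with attribute `"sigma_zero"`.
#'
#' @param image Numeric matrix.
#' @param alpha Deviation multiplier, in `(0, 1)` (default 0.5).
#' @return Logical mask with attributes `threshold` and `sigma_zero`.
#' @export
threshold_mu_alpha_sigma <- function(image, alpha = 0.5) {
  image <- as_gray_image(image)
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  mu <- mean(image)
  s <- stats::sd(as.numeric(image))
  if (s == 0) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "threshold") <- mu
    attr(mask, "sigma_zero") <- TRUE
    return(mask)
  }
  thr <- mu + alpha * s
  mask <- image >= thr
  attr(mask, "threshold") <- thr
  attr(mask, "sigma_zero") <- FALSE
  mask
}

#' 8-connected component labelling
#'
#' Partitions the foreground into maximal 8-connected components. Labels are
#' consecutive integers `1..n_components` in scan order of each component's
#' first pixel; per-label pixel counts are tabulated.
#'
#' @param mask Logical matrix.
#' @return An object of class `labeled_components`: list with `labels`
#'   (integer matrix, 0 = background), `n_components`, and `areas`.
#' @export
label_components_8 <- function(mask) {
  mask <- as_binary_mask(mask)
  m <- nrow(mask); n <- ncol(mask)
  lab <- ebi_mat(EBImage::bwlabel(matrix(as.numeric(mask), m, n)))
  maxlab <- max(lab)
  if (maxlab == 0) {
    return(structure(list(labels = matrix(0L, m, n), n_components = 0L,
                          areas = integer(0)), class = "labeled_components"))
  }
  # bwlabel is 4-connected; union labels that touch diagonally
  parent <- seq_len(maxlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (m > 1L && n > 1L) {
    a <- lab[-m, -n]; b <- lab[-1, -1]   # down-right diagonal
    c_ <- lab[-m, -1]; d <- lab[-1, -n]  # down-left diagonal
    s1 <- a > 0 & b > 0 & a != b
    s2 <- c_ > 0 & d > 0 & c_ != d
    edges <- unique(rbind(cbind(a[s1], b[s1]), cbind(c_[s2], d[s2])))
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  root <- vapply(seq_len(maxlab), find, numeric(1))
  # consecutive relabelling in scan order of first appearance
  first_px <- match(seq_len(maxlab), lab)
  root_first <- vapply(unique(root), function(r) {
    min(first_px[root == r])
  }, numeric(1))
  ordered_roots <- unique(root)[order(root_first)]
  new_id <- integer(maxlab)
  for (i in seq_along(ordered_roots)) new_id[root == ordered_roots[i]] <- i
  labels <- matrix(0L, m, n)
  fg <- lab > 0
  labels[fg] <- new_id[lab[fg]]
  structure(list(labels = labels, n_components = length(ordered_roots),
                 areas = tabulate(labels[fg], nbins = length(ordered_roots))),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d components, areas: %s\n",
              x$n_components,
              paste(utils::head(sort(x$areas, decreasing = TRUE), 8),
                    collapse = ", ")))
  invisible(x)
}

#' Remove small components by area
#'
#' Keeps components whose pixel count is at least `min_area`, scaled by image
#' size when a `reference_shape` is given:
#' `min_area * (m*n) / prod(reference_shape)`. The canonical calibration is
#' ~5000 px at 421x580.
#'
#' @param components A `labeled_components` object.
#' @param min_area Minimum component area in pixels at the reference size.
#' @param reference_shape Optional `c(rows, cols)` the threshold was
#'   calibrated at; `NULL` (default) applies `min_area` unscaled.
#' @return Logical mask of the surviving components.
#' @export
area_filter <- function(components, min_area, reference_shape = NULL) {
  stopifnot(inherits(components, "labeled_components"))
  if (min_area < 1) stop("min_area must be at least 1", call. = FALSE)
  dims <- dim(components$labels)
  scaled <- if (is.null(reference_shape)) {
    min_area
  } else {
    min_area * prod(dims) / prod(reference_shape)
  }
  keep <- which(components$areas >= scaled)
  mask <- matrix(components$labels %in% keep, dims[1], dims[2])
  attr(mask, "min_area_scaled") <- scaled
  attr(mask, "kept") <- keep
  mask
}

#' Elementary geodesic dilation and erosion
#'
#' One elementary step of geodesic morphology: `geodesic_dilate()` is the
#' pointwise minimum of the dilated marker and the mask image (marker must
#' not exceed the mask); `geodesic_erode()` is its dual, the pointwise
#' maximum of the eroded marker and the mask (marker must not fall below the
#' mask). Iterated to stability these yield morphological reconstruction.
#'
#' @param marker Numeric matrix, the image being grown/shrunk.
#' @param mask_img Numeric matrix constraining the marker pointwise.
#' @param se Flat structuring element (0/1 matrix, default elementary 3x3).
#' @return Numeric matrix of the same shape.
#' @export
geodesic_dilate <- function(marker, mask_img, se = se_3x3()) {
  marker <- as_gray_image(marker, arg = "marker")
  mask_img <- as_gray_image(mask_img, arg = "mask_img")
  if (!all(dim(marker) == dim(mask_img))) {
    stop("marker and mask_img must have identical dimensions", call. = FALSE)
  }
  if (any(marker > mask_img + 1e-12)) {
    stop("marker must not exceed mask_img pointwise", call. = FALSE)
  }
  pmin(ebi_mat(EBImage::dilate(marker, se)), mask_img)
}

#' @rdname geodesic_dilate
#' @export
geodesic_erode <- function(marker, mask_img, se = se_3x3()) {
  marker <- as_gray_image(marker, arg = "marker")
  mask_img <- as_gray_image(mask_img, arg = "mask_img")
  if (!all(dim(marker) == dim(mask_img))) {
    stop("marker and mask_img must have identical dimensions", call. = FALSE)
  }
  if (any(marker < mask_img - 1e-12)) {
    stop("marker must not fall below mask_img pointwise", call. = FALSE)
  }
  pmax(ebi_mat(EBImage::erode(marker, se)), mask_img)
}

#' Morphological reconstruction by dilation or erosion
#'
#' Iterates the elementary (3x3) geodesic step until no pixel changes. On
#' binary inputs, reconstruction by dilation equals a connectivity-
#' constrained flood fill from the marker; on quantised graylevel inputs
#' termination is guaranteed.
#'
#' @param marker,mask_img As in [geodesic_dilate()] /[geodesic_erode()].
#' @param max_iter Safety bound on iterations.
#' @return The stable reconstructed image.
#' @export
reconstruct_by_dilation <- function(marker, mask_img, max_iter = 10000L) {
  cur <- geodesic_dilate(marker, mask_img)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(ebi_mat(EBImage::dilate(cur, se_3x3())), mask_img)
    if (all(nxt == cur)) return(nxt)
    cur <- nxt
  }
  warning("reconstruction did not stabilise within ", max_iter, " iterations",
          call. = FALSE)
  cur
}

#' @rdname reconstruct_by_dilation
#' @export
reconstruct_by_erosion <- function(marker, mask_img, max_iter = 10000L) {
  cur <- geodesic_erode(marker, mask_img)
  for (i in seq_len(max_iter)) {
    nxt <- pmax(ebi_mat(EBImage::erode(cur, se_3x3())), mask_img)
    if (all(nxt == cur)) return(nxt)
    cur <- nxt
  }
  warning("reconstruction did not stabilise within ", max_iter, " iterations",
          call. = FALSE)
  cur
}

#' Opening and closing by reconstruction
#'
#' `open_by_reconstruction()` erodes by `se` and reconstructs by dilation
#' under the original image: structures the SE cannot fit are removed while
#' the boundaries of the survivors are left untouched (anti-extensive,
#' increasing, idempotent). `close_by_reconstruction()` is the dual --
#' dilation followed by reconstruction by erosion -- and fills holes and
#' gaps smaller than the SE.
#'
#' @param image Numeric matrix.
#' @param se Flat structuring element (default the 17x6 elliptical disc).
#' @return Numeric matrix of the same shape.
#' @export
open_by_reconstruction <- function(image, se = ellipse_se(17, 6)) {
  image <- as_gray_image(image)
  marker <- pmin(ebi_mat(EBImage::erode(image, se)), image)
  reconstruct_by_dilation(marker, image)
}

#' @rdname open_by_reconstruction
#' @export
close_by_reconstruction <- function(image, se = ellipse_se(17, 6)) {
  image <- as_gray_image(image)
  marker <- pmax(ebi_mat(EBImage::dilate(image, se)), image)
  reconstruct_by_erosion(marker, image)
}

#' Morphological cleanup of the candidate mask
#'
#' Consolidates the thresholded, area-filtered mask in three steps: closing
#' by reconstruction with the structuring element (dilation followed by
#' erosion, which fills holes and gaps the SE covers without distorting
#' surviving edges), then opening by reconstruction with the same SE (which
#' deletes every component the SE fits nowhere inside, while components in
#' which the SE fits somewhere -- such as a curved band whose apex
#' accommodates it -- are restored with their exact boundaries), then a
#' final area filter with the high threshold. Reconstruction operators act
#' on whole connected components by construction: debris *attached* to a
#' surviving structure is retained with it (and left to the area/width
#' rules), which is the price of never distorting the boundaries of curved
#' thin bands the way a conventional opening would. Several laterally
#' extended components may legitimately survive (the bursa and cortex bands
#' run in parallel), so every component whose bounding-box width is at least
#' `keep_width_frac` of the widest survivor is kept; compact leftovers are
#' dropped.
#'
#' @param mask Logical matrix (candidate mask).
#' @param se Structuring element (default 17x6 elliptical disc).
#' @param final_min_area High area threshold, at the reference size.
#' @param reference_shape Size the area threshold is calibrated at.
#' @param keep_width_frac Keep components at least this fraction as wide as
#'   the widest surviving component.
#' @return Logical mask with attribute `segmentation_failure` set when no
#'   component survives.
#' @export
morphological_cleanup <- function(mask, se = ellipse_se(17, 6),
                                  final_min_area = 6000,
                                  reference_shape = c(421L, 580L),
                                  keep_width_frac = 0.6) {
  mask <- as_binary_mask(mask)
  m <- nrow(mask); n <- ncol(mask)
  x <- matrix(as.numeric(mask), m, n)
  closed <- close_by_reconstruction(x, se)
  opened <- open_by_reconstruction(closed, se) > 0.5
  comps <- label_components_8(opened)
  filtered <- area_filter(comps, final_min_area, reference_shape)
  comps2 <- label_components_8(filtered)
  if (comps2$n_components == 0L) {
    out <- matrix(FALSE, m, n)
    attr(out, "segmentation_failure") <- TRUE
    return(out)
  }
  widths <- vapply(seq_len(comps2$n_components), function(k) {
    cols <- which(apply(comps2$labels == k, 2, any))
    diff(range(cols)) + 1L
  }, numeric(1))
  keep <- which(widths >= keep_width_frac * max(widths))
  out <- matrix(comps2$labels %in% keep, m, n)
  attr(out, "segmentation_failure") <- FALSE
  attr(out, "components_kept") <- length(keep)
  attr(out, "components_dropped") <- comps2$n_components - length(keep)
  out
}
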