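# Quadratic boundary smoothing.
#
# The candidate mask's upper and lower envelopes (per-column extreme rows)
# are each fitted with a least-squares quadratic; the final mask fills every
# column of the lateral extent between the two curves. Because the curves
# are evaluated over the full column range, columns where the candidate mask
# had gaps are bridged -- this is the boundary-point recovery that encloses
# bursa, tendon and cortex in one smooth region.
#
# Coordinates: row index grows downward, so the upper boundary has the
# smaller row values; columns are the independent variable x.

#' Extract per-column boundary points of a mask
#'
#' For every column intersecting the mask, the upper point is the smallest
#' foreground row and the lower point the largest; columns without
#' foreground are skipped.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return A list with tibbles `upper` and `lower`, each with columns
#'   `x` (column) and `y` (row).
#' @export
extract_boundary_points <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) {
    stop("mask is empty: segmentation failed upstream", call. = FALSE)
  }
  cols <- which(colSums(mask) > 0)
  upper <- vapply(cols, function(j) which(mask[, j])[1L], numeric(1))
  lower <- vapply(cols, function(j) {
    w <- which(mask[, j]); w[length(w)]
  }, numeric(1))
  list(upper = tibble(x = cols, y = upper),
       lower = tibble(x = cols, y = lower))
}

#' Least-squares quadratic fit
#'
#' Fits \eqn{y = a x^2 + b x + c} by least squares (QR). With fewer than
#' three distinct x values the fit falls back to the highest degree the data
#' support, flagged via attribute `"degree"`; missing coefficients are zero.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Numeric vector `c(a, b, c)` with attribute `degree`.
#' @export
fit_quadratic <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop("x and y must be equal-length, nonempty vectors", call. = FALSE)
  }
  ndist <- length(unique(x))
  degree <- min(2L, ndist - 1L)
  X <- switch(degree + 1L,
    cbind(rep(1, length(x))),
    cbind(1, x),
    cbind(1, x, x^2)
  )
  beta <- qr.coef(qr(X), y)
  coef <- c(a = 0, b = 0, c = 0)
  coef["c"] <- beta[1]
  if (degree >= 1L) coef["b"] <- beta[2]
  if (degree >= 2L) coef["a"] <- beta[3]
  out <- unname(coef[c("a", "b", "c")])
  names(out) <- c("a", "b", "c")
  attr(out, "degree") <- degree
  out
}

eval_quadratic <- function(coef, x) coef[1] * x^2 + coef[2] * x + coef[3]

#' Fit the two-quadratic boundary model of a candidate mask
#'
#' Fits one quadratic to the upper envelope and one to the lower envelope of
#' the mask, recording the lateral column range.
#'
#' @param mask Logical matrix (candidate tendon mask).
#' @param extend_px Extend the column range this many pixels on each side
#'   (clamped to the image; default 0 -- no extrapolation beyond the
#'   observed lateral extent).
#' @return An object of class `boundary_model`: list with `upper_coeffs`,
#'   `lower_coeffs` (each `c(a, b, c)`), and `column_range`.
#' @export
fit_boundary_model <- function(mask, extend_px = 0L) {
  pts <- extract_boundary_points(mask)
  up <- fit_quadratic(pts$upper$x, pts$upper$y)
  lo <- fit_quadratic(pts$lower$x, pts$lower$y)
  cr <- range(pts$upper$x)
  cr <- c(max(1L, cr[1] - extend_px), min(ncol(mask), cr[2] + extend_px))
  structure(list(upper_coeffs = up, lower_coeffs = lo,
                 column_range = as.integer(cr)),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf(
    "<boundary_model> upper y = %.3gx^2 + %.3gx + %.3g | lower y = %.3gx^2 + %.3gx + %.3g | cols [%d, %d]\n",
    x$upper_coeffs[1], x$upper_coeffs[2], x$upper_coeffs[3],
    x$lower_coeffs[1], x$lower_coeffs[2], x$lower_coeffs[3],
    x$column_range[1], x$column_range[2]))
  invisible(x)
}

#' @export
tidy.boundary_model <- function(x, ...) {
  tibble(
    boundary = rep(c("upper", "lower"), each = 3L),
    term = rep(c("x^2", "x", "1"), 2L),
    estimate = unname(c(unclass(x$upper_coeffs), unclass(x$lower_coeffs)))
  )
}

#' Rasterise the final smooth tendon mask from a boundary model
#'
#' Pixel `(r, x)` is foreground iff `x` lies in the column range and
#' `upper(x) <= r <= lower(x)` (rows clamped to the image). The curves are
#' evaluated over the whole column range even where the input mask had gaps.
#' Columns where the curves cross are clipped (left empty) and counted in
#' attribute `"clipped_columns"`.
#'
#' @param model A `boundary_model`.
#' @param shape `c(rows, cols)` of the output mask.
#' @return Logical mask.
#' @export
build_final_mask <- function(model, shape) {
  stopifnot(inherits(model, "boundary_model"))
  m <- shape[1]; n <- shape[2]
  mask <- matrix(FALSE, m, n)
  clipped <- 0L
  xs <- seq(max(1L, model$column_range[1]), min(n, model$column_range[2]))
  for (x in xs) {
    ru <- round(eval_quadratic(model$upper_coeffs, x))
    rl <- round(eval_quadratic(model$lower_coeffs, x))
    if (ru > rl) {
      clipped <- clipped + 1L
      next
    }
    ru <- max(1L, min(m, ru))
    rl <- max(1L, min(m, rl))
    mask[ru:rl, x] <- TRUE
  }
  attr(mask, "clipped_columns") <- clipped
  mask
}
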