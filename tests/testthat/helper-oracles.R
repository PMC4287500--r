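# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# 8-connected labelling by explicit stack-based flood fill, scanning in
# column-major order (so label numbering matches scan order of first pixels)
flood_label_8 <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  lab <- matrix(0L, m, n)
  cur <- 0L
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        lab[i, j] <- cur
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (di in -1:1) for (dj in -1:1) {
            ii <- p[1] + di; jj <- p[2] + dj
            if (ii >= 1 && ii <= m && jj >= 1 && jj <= n &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- cur
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# binary morphological reconstruction = union of the mask components that
# the marker touches
flood_reconstruct <- function(marker, mask) {
  lab <- flood_label_8(mask)
  touched <- unique(lab[marker & mask])
  touched <- touched[touched > 0]
  matrix(lab %in% touched, nrow(mask), ncol(mask))
}

# two-sided Kolmogorov-Smirnov distance of pixel values to Rayleigh(sigma)
ks_to_rayleigh <- function(image, sigma) {
  x <- sort(as.numeric(image))
  nn <- length(x)
  Fx <- 1 - exp(-x^2 / (2 * sigma^2))
  max(abs(Fx - seq_len(nn) / nn), abs(Fx - (seq_len(nn) - 1) / nn))
}

# total variation: L1 norm of horizontal plus vertical first differences
total_variation <- function(img) {
  sum(abs(img[-1, ] - img[-nrow(img), ])) +
    sum(abs(img[, -1] - img[, -ncol(img)]))
}

# quadratic least squares through the normal equations, independent of the
# QR route used by fit_quadratic()
normal_eq_quadratic <- function(x, y) {
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(a = beta[3], b = beta[2], c = beta[1])
}

# a reduced-size phantom spec for fast unit tests (defaults overridable)
small_spec <- function(...) {
  args <- list(height = 128L, width = 176L, tendon_width = 24,
               band_thickness = 6, curvature_radius = 200, n_outliers = 2L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

random_mask <- function(m, n, p = 0.4) matrix(runif(m * n) < p, m, n)

# anatomy variation intervals rescaled to the reduced phantom size
small_ranges <- function() {
  list(
    tendon_width = c(18, 30),
    tendon_center_row = c(0.4, 0.5),
    curvature_radius = c(150, 260),
    tendon_intensity = c(0.10, 0.20),
    bursa_intensity = c(0.70, 0.85),
    cortex_intensity = c(0.86, 0.97),
    background_intensity = c(0.22, 0.32)
  )
}
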