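# Real-valued fast discrete curvelet transform via spectrum wrapping.
#
# Construction: the 2-D FFT of the image is partitioned by smooth frequency
# windows whose squares sum to one everywhere (a Meyer-type radial partition
# into dyadic annuli times a raised-cosine angular partition into wedges, the
# count doubling every other scale toward finer scales). Each windowed wedge
# spectrum is wrapped (periodised) onto a rectangle just large enough to hold
# its support -- the wrapping is collision-free by construction, so the
# transform is an exact tight frame: inverse(forward(I)) reproduces I to
# machine precision and the coefficient energy equals the pixel energy
# (Parseval).
#
# Real coefficients: for a real image the spectra of antipodal wedges are
# complex conjugates, so only wedges of one half-plane are computed and each
# complex wedge-coefficient array is stored as sqrt(2)*Re and sqrt(2)*Im in
# the slots of the wedge and of its antipodal partner (the convention of the
# reference wrapping implementation). The coarse (lowpass) band is wrapped
# symmetrically about DC, which keeps it Hermitian and hence real. A
# sum-of-squares renormalisation of the angular partition absorbs the
# Nyquist-seam asymmetry of even-sized grids, so the tight-frame identity is
# exact on arbitrary (even or odd) image sizes.

# Meyer smooth step: nu(0)=0, nu(1)=1, nu(t)+nu(1-t)=1
meyer_nu <- function(t) t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)

# smooth radial lowpass: 1 for r <= s/2, cosine taper to 0 at r = s
radial_lowpass <- function(r, s) {
  out <- numeric(length(r))
  out[r <= s / 2] <- 1
  tr <- r > s / 2 & r < s
  out[tr] <- cos(pi / 2 * meyer_nu((r[tr] - s / 2) / (s / 2)))
  out
}

# next integer >= x with no prime factor beyond 5 (efficient FFT length)
nice_len <- function(x) {
  x <- max(1L, as.integer(x))
  repeat {
    y <- x
    for (f in c(2L, 3L, 5L)) while (y %% f == 0L) y <- y %/% f
    if (y == 1L) return(x)
    x <- x + 1L
  }
}

# minimal covering interval of a set of 0-based indices on a circle of the
# given size; returns the start and length
circ_interval <- function(p, size) {
  k <- length(p)
  if (k == size) return(list(a = 0L, len = size))
  gaps <- c(diff(p), p[1] + size - p[k])
  gi <- which.max(gaps)
  a <- if (gi == k) p[1] else p[gi + 1L]
  list(a = a, len = size - gaps[gi] + 1L)
}

wedge_counts <- function(n_scales, orientations) {
  if (n_scales < 2L) return(integer(0))
  vapply(2:n_scales, function(j) {
    as.integer(orientations * 2^ceiling((j - 2) / 2))
  }, integer(1))
}

.geom_cache <- new.env(parent = emptyenv())

# frequency-domain geometry (windows, supports, wrapping rectangles) for one
# (size, scales, orientations) combination; cached, since it is reused across
# every image of a cohort
fdct_geometry <- function(m, n, n_scales, orientations) {
  key <- paste(m, n, n_scales, orientations, sep = "x")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])

  k1 <- 0:(m - 1L); s1 <- ifelse(k1 > m / 2, k1 - m, k1)
  k2 <- 0:(n - 1L); s2 <- ifelse(k2 > n / 2, k2 - n, k2)
  rmat <- 2 * sqrt(outer((s1 / m)^2, (s2 / n)^2, `+`))
  thmat <- atan2(matrix(s2 / n, m, n, byrow = TRUE), matrix(s1 / m, m, n))

  negrow <- ((m - (0:(m - 1L))) %% m) + 1L
  negcol <- ((n - (0:(n - 1L))) %% n) + 1L
  neg_of <- function(idx) {
    r0 <- ((idx - 1L) %% m) + 1L
    c0 <- ((idx - 1L) %/% m) + 1L
    (negcol[c0] - 1L) * m + negrow[r0]
  }

  wrap_rect <- function(idx) {
    rows0 <- sort(unique((idx - 1L) %% m))
    cols0 <- sort(unique((idx - 1L) %/% m))
    ri <- circ_interval(rows0, m); ci <- circ_interval(cols0, n)
    L1 <- min(nice_len(ri$len), m); L2 <- min(nice_len(ci$len), n)
    u1 <- (((idx - 1L) %% m) - ri$a) %% m
    u2 <- ((((idx - 1L) %/% m)) - ci$a) %% n
    widx <- u1 + u2 * L1 + 1L
    stopifnot(!anyDuplicated(widx))
    list(L1 = L1, L2 = L2, widx = as.integer(widx))
  }

  J <- n_scales
  cuts <- sqrt(2) * 2^(-(J - seq_len(max(J - 1, 1))))  # lowpass cutoffs 1..J-1
  bands <- list()

  # coarse band: symmetric crop about DC keeps the wrapped array Hermitian
  phi <- radial_lowpass(rmat, cuts[1])
  idx <- as.integer(which(phi > 0))
  h1 <- max(abs(s1[((idx - 1L) %% m) + 1L]))
  h2 <- max(abs(s2[((idx - 1L) %/% m) + 1L]))
  L1 <- min(nice_len(2L * h1 + 1L), m); L2 <- min(nice_len(2L * h2 + 1L), n)
  u1 <- s1[((idx - 1L) %% m) + 1L] %% L1
  u2 <- s2[((idx - 1L) %/% m) + 1L] %% L2
  widx <- as.integer(u1 + u2 * L1 + 1L)
  stopifnot(!anyDuplicated(widx))
  bands[[1]] <- list(scale = 1L, wedge = 0L, idx = idx, win = phi[idx],
                     negidx = NULL, L1 = L1, L2 = L2, widx = widx)

  kcounts <- wedge_counts(J, orientations)
  lam_prev <- phi  # radial lowpass of the previous (coarser) scale
  for (j in seq_len(J - 1L) + 1L) {
    lam_j <- if (j == J) rep(1, length(rmat)) else radial_lowpass(rmat, cuts[j])
    ring <- sqrt(pmax(lam_j^2 - lam_prev^2, 0))
    lam_prev <- lam_j
    ring_idx <- as.integer(which(ring > 0))
    th <- thmat[ring_idx]
    K <- kcounts[j - 1L]; H <- K %/% 2L; w <- 2 * pi / K

    pos <- integer(m * n); pos[ring_idx] <- seq_along(ring_idx)
    refl <- pos[neg_of(ring_idx)]
    stopifnot(all(refl > 0L))

    Vs <- vector("list", H)
    Araw <- numeric(length(ring_idx))
    for (h in seq_len(H)) {
      d <- (th - 2 * pi * (h - 0.5) / K + pi) %% (2 * pi) - pi
      u <- abs(d) / w
      V <- numeric(length(u))
      inw <- u < 1
      V[inw] <- cos(pi / 2 * meyer_nu(u[inw]))
      Vs[[h]] <- V
      Araw <- Araw + V^2
    }
    A <- Araw + Araw[refl]  # frame sum incl. antipodal wedges; symmetric

    for (h in seq_len(H)) {
      winv <- ring[ring_idx] * Vs[[h]] / sqrt(A)
      keep <- winv > 0
      idx <- ring_idx[keep]
      if (length(idx) == 0L) {
        bands[[length(bands) + 1L]] <- list(scale = j, wedge = h,
          idx = integer(0), win = numeric(0), negidx = integer(0),
          L1 = 1L, L2 = 1L, widx = integer(0))
        next
      }
      wr <- wrap_rect(idx)
      bands[[length(bands) + 1L]] <- list(scale = j, wedge = h, idx = idx,
        win = winv[keep], negidx = as.integer(neg_of(idx)),
        L1 = wr$L1, L2 = wr$L2, widx = wr$widx)
    }
  }

  geom <- list(m = m, n = n, n_scales = J, orientations = orientations,
               wedge_counts = kcounts, bands = bands)
  .geom_cache[[key]] <- geom
  geom
}

#' Forward fast discrete curvelet transform (wrapping, real-valued)
#'
#' Decomposes an image into a coarse band plus directional wedge bands at
#' `n_scales - 1` detail scales, with `orientations` angular wedges at scale
#' 2 (doubling every other scale toward finer scales). The decomposition is a
#' normalised tight frame: coefficients are real, their total energy equals
#' the pixel energy, and [fdct_inverse()] reconstructs the image to machine
#' precision.
#'
#' @param image A finite numeric matrix (any real values; the pipeline feeds
#'   it `[0, 1]` images). Both dimensions must be at least `2^n_scales`.
#' @param n_scales Total number of scales counting the coarse level
#'   (default 2: coarse + one detail scale).
#' @param orientations Number of angular wedges at scale 2; a multiple of 4
#'   (default 16).
#' @return An object of class `curvelet_decomp`: a nested list of real
#'   coefficient matrices indexed by (scale, wedge).
#' @examples
#' x <- matrix(runif(64 * 64), 64, 64)
#' d <- fdct_forward(x, n_scales = 2, orientations = 16)
#' max(abs(fdct_inverse(d) - x)) < 1e-9
#' @export
fdct_forward <- function(image, n_scales = 2L, orientations = 16L) {
  image <- as_gray_image(image)
  m <- nrow(image); n <- ncol(image)
  n_scales <- as.integer(n_scales); orientations <- as.integer(orientations)
  if (n_scales < 2L) stop("n_scales must be at least 2", call. = FALSE)
  if (min(m, n) < 2^n_scales) {
    stop("image dimensions must be at least 2^n_scales (",
         2^n_scales, ")", call. = FALSE)
  }
  if (orientations < 8L || orientations %% 4L != 0L) {
    stop("orientations must be a multiple of 4 (and at least 8)",
         call. = FALSE)
  }
  geom <- fdct_geometry(m, n, n_scales, orientations)
  Fhat <- stats::fft(image)

  coeffs <- vector("list", n_scales)
  coeffs[[1]] <- vector("list", 1L)
  for (j in seq_len(n_scales - 1L) + 1L) {
    coeffs[[j]] <- vector("list", geom$wedge_counts[j - 1L])
  }
  for (band in geom$bands) {
    W <- matrix(0 + 0i, band$L1, band$L2)
    if (length(band$idx)) W[band$widx] <- Fhat[band$idx] * band$win
    cc <- stats::fft(W, inverse = TRUE) / sqrt(as.numeric(band$L1) * band$L2 * m * n)
    if (band$scale == 1L) {
      coeffs[[1]][[1]] <- Re(cc)
    } else {
      H <- geom$wedge_counts[band$scale - 1L] %/% 2L
      coeffs[[band$scale]][[band$wedge]] <- sqrt(2) * Re(cc)
      coeffs[[band$scale]][[band$wedge + H]] <- sqrt(2) * Im(cc)
    }
  }
  structure(list(coeffs = coeffs, m = m, n = n, n_scales = n_scales,
                 orientations = orientations,
                 wedge_counts = geom$wedge_counts),
            class = "curvelet_decomp")
}

#' Inverse fast discrete curvelet transform
#'
#' Exact inverse (adjoint) of [fdct_forward()]; linear in the coefficients,
#' so it can be applied to thresholded decompositions.
#'
#' @param decomp A `curvelet_decomp`.
#' @return Numeric matrix of the original image size.
#' @export
fdct_inverse <- function(decomp) {
  stopifnot(inherits(decomp, "curvelet_decomp"))
  m <- decomp$m; n <- decomp$n
  geom <- fdct_geometry(m, n, decomp$n_scales, decomp$orientations)
  S <- matrix(0 + 0i, m, n)
  for (band in geom$bands) {
    if (band$scale == 1L) {
      cc <- decomp$coeffs[[1]][[1]]
      if (is.null(cc) || !all(dim(cc) == c(band$L1, band$L2))) {
        stop("decomposition geometry mismatch in coarse band", call. = FALSE)
      }
      W <- stats::fft(cc) * sqrt(m * n / (as.numeric(band$L1) * band$L2))
      S[band$idx] <- S[band$idx] + W[band$widx] * band$win
    } else {
      H <- geom$wedge_counts[band$scale - 1L] %/% 2L
      A <- decomp$coeffs[[band$scale]][[band$wedge]]
      B <- decomp$coeffs[[band$scale]][[band$wedge + H]]
      if (is.null(A) || is.null(B) ||
          !all(dim(A) == c(band$L1, band$L2)) ||
          !all(dim(B) == c(band$L1, band$L2))) {
        stop("decomposition geometry mismatch at scale ", band$scale,
             ", wedge ", band$wedge, call. = FALSE)
      }
      if (!length(band$idx)) next
      cc <- matrix(complex(real = A, imaginary = B) / sqrt(2),
                   band$L1, band$L2)
      W <- stats::fft(cc) * sqrt(m * n / (as.numeric(band$L1) * band$L2))
      wv <- W[band$widx] * band$win
      S[band$idx] <- S[band$idx] + wv
      S[band$negidx] <- S[band$negidx] + Conj(wv)
    }
  }
  Re(stats::fft(S, inverse = TRUE)) / (m * n)
}

# flat vector of all coefficients (coarse first, then scale/wedge order)
cl_coef_vector <- function(decomp) {
  unlist(lapply(decomp$coeffs, function(sc) lapply(sc, as.numeric)),
         use.names = FALSE)
}

#' Number of coefficients and total energy of a decomposition
#'
#' @param decomp A `curvelet_decomp`.
#' @return `n_curvelet_coeffs()`: integer count. `curvelet_energy()`: sum of
#'   squared coefficients (equals the image's pixel energy, by Parseval).
#' @export
n_curvelet_coeffs <- function(decomp) length(cl_coef_vector(decomp))

#' @rdname n_curvelet_coeffs
#' @export
curvelet_energy <- function(decomp) sum(cl_coef_vector(decomp)^2)

#' Keep only the largest curvelet coefficients
#'
#' Retains the `ceiling(p * N)` coefficients of largest absolute value across
#' all bands (`N` = total coefficient count, coarse band included) and zeroes
#' the rest. Ties at the threshold magnitude are all kept.
#'
#' @param decomp A `curvelet_decomp`.
#' @param p Fraction of coefficients to keep, in `(0, 1]` (the pipeline
#'   default is 0.065).
#' @return A `curvelet_decomp` with the small coefficients zeroed.
#' @export
retain_top_fraction <- function(decomp, p) {
  stopifnot(inherits(decomp, "curvelet_decomp"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must be a fraction in (0, 1]", call. = FALSE)
  }
  av <- abs(cl_coef_vector(decomp))
  N <- length(av)
  k <- ceiling(p * N)
  thr <- if (k >= N) min(av) else sort(av, partial = N - k + 1L)[N - k + 1L]
  # magnitudes within floating-point rounding of the threshold are ties and
  # are all kept (an exactly-tied population, e.g. the coarse band of a
  # constant image, must never be split by 1-ulp noise)
  thr <- thr * (1 - 1e-9)
  out <- decomp
  for (j in seq_along(out$coeffs)) {
    for (wdg in seq_along(out$coeffs[[j]])) {
      cm <- out$coeffs[[j]][[wdg]]
      cm[abs(cm) < thr] <- 0
      out$coeffs[[j]][[wdg]] <- cm
    }
  }
  out
}

#' @export
print.curvelet_decomp <- function(x, ...) {
  nz <- sum(cl_coef_vector(x) != 0)
  cat(sprintf(
    "<curvelet_decomp %dx%d> %d scales, %s wedges/scale, %d coefficients (%d nonzero)\n",
    x$m, x$n, x$n_scales, paste(x$wedge_counts, collapse = "/"),
    n_curvelet_coeffs(x), nz))
  invisible(x)
}

#' Image energy inside a region
#'
#' Energy is the sum of squared pixel intensities. The report gives the
#' energy over `mask` (or the whole image when `mask` is `NULL`), the total
#' energy, and their ratio -- the quantity used to compare a reconstruction
#' (or a delineated region) against the full image.
#'
#' @param image Numeric matrix.
#' @param mask Optional logical matrix of the same shape.
#' @param convention `"squared"` (default, energy = sum p^2) or `"absolute"`
#'   (sum |p|) for sensitivity analysis.
#' @return A list of class `energy_report`: `region_energy`, `total_energy`,
#'   `ratio`.
#' @export
image_energy <- function(image, mask = NULL,
                         convention = c("squared", "absolute")) {
  image <- as_gray_image(image)
  convention <- match.arg(convention)
  e <- if (convention == "squared") image^2 else abs(image)
  total <- sum(e)
  region <- if (is.null(mask)) {
    total
  } else {
    mask <- as_binary_mask(mask)
    if (!all(dim(mask) == dim(image))) {
      stop("mask shape does not match image", call. = FALSE)
    }
    sum(e[mask])
  }
  structure(list(region_energy = region, total_energy = total,
                 ratio = if (total > 0) region / total else 0),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> region %.4g / total %.4g = ratio %.4f\n",
              x$region_energy, x$total_energy, x$ratio))
  invisible(x)
}

#' Energy-retention scan over scales, orientations and coefficient fractions
#'
#' For each combination of scale count, orientation count and retained
#' fraction `p`, reconstructs the image from its top-`p` curvelet
#' coefficients and reports the ratio of reconstruction energy to original
#' image energy. This is the analysis used to pick the working setting
#' (scale 2, 16 orientations, 6.5% of coefficients).
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param scales Integer vector of total scale counts (default `2:5`).
#' @param orientations Integer vector of wedge counts at scale 2
#'   (default `c(16, 32)`).
#' @param fractions Numeric vector of retained fractions (default 5% to 10%
#'   in 0.5% steps).
#' @return A tibble with columns `scale`, `orientations`, `fraction`,
#'   `energy_ratio`, sorted by (scale, orientations, fraction).
#' @export
energy_scan <- function(image, scales = 2:5, orientations = c(16L, 32L),
                        fractions = seq(0.05, 0.10, by = 0.005)) {
  image <- as_gray_image(image)
  if (length(scales) == 0L || length(orientations) == 0L ||
      length(fractions) == 0L) {
    stop("scales, orientations and fractions must be nonempty", call. = FALSE)
  }
  e_total <- sum(image^2)
  rows <- list()
  for (s in sort(scales)) {
    for (o in sort(orientations)) {
      d <- fdct_forward(image, n_scales = s, orientations = o)
      for (p in sort(fractions)) {
        rec <- fdct_inverse(retain_top_fraction(d, p))
        rows[[length(rows) + 1L]] <- tibble(
          scale = s, orientations = o, fraction = p,
          energy_ratio = sum(rec^2) / e_total)
      }
    }
  }
  do.call(rbind, rows)
}
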