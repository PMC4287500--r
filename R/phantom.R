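# Synthetic SSP-tendon ultrasound phantoms.
#
# The anatomy is an annulus sector: a circle centre placed above the image so
# the tendon band (a hypoechoic annulus of width tendon_width around radius
# curvature_radius) runs laterally across the image as a convex arc, bounded
# by a hyperechoic bursa band along its upper offset and a hyperechoic cortex
# band along its lower offset. Speckle is multiplicative Rayleigh. Ground
# truth follows the radiologist convention: the tendon region *including*
# bursa and cortex, delimited by the two band midlines.

#' Phantom specification
#'
#' Parameters of a synthetic tendon phantom. Defaults give the canonical
#' 421x580 working size with a 70 px tendon (about 7 mm at a typical
#' musculoskeletal depth setting), 14 px hyperechoic bands, a 600 px radius of
#' curvature and unit-mean multiplicative Rayleigh speckle
#' (`speckle_sigma = sqrt(2/pi)`). `speckle_sigma = 0` is the documented
#' no-noise switch: the returned image is the exact piecewise-constant
#' anatomy.
#'
#' @param height,width Image size in pixels.
#' @param tendon_center_row Tendon midline position at the central column, as
#'   a fraction of `height`.
#' @param tendon_width Tendon band width in pixels (hypoechoic gap between the
#'   two bright bands).
#' @param curvature_radius Radius of the convex arc in pixels; must exceed
#'   `width / 2` so the arc spans the image laterally.
#' @param band_thickness Thickness of the bursa and cortex bands in pixels.
#' @param bursa_intensity,cortex_intensity,tendon_intensity,background_intensity
#'   Noiseless intensity levels in `[0, 1]`; the bands must be brighter than
#'   the tendon (hyperechoic vs hypoechoic).
#' @param speckle_sigma Rayleigh scale of the multiplicative speckle field;
#'   `0` disables speckle.
#' @param n_outliers Number of bright elliptical outlier blobs (muscle-fat
#'   mixture mimics, each well under the 5000 px area rule) injected in the
#'   background to exercise the area filter.
#' @param outlier_intensity Noiseless intensity of the outlier blobs.
#' @param rng_seed Integer seed; identical specs give bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 421L, width = 580L,
                         tendon_center_row = 0.45,
                         tendon_width = 70,
                         curvature_radius = 600,
                         band_thickness = 14,
                         bursa_intensity = 0.78,
                         cortex_intensity = 0.92,
                         tendon_intensity = 0.15,
                         background_intensity = 0.28,
                         speckle_sigma = sqrt(2 / pi),
                         n_outliers = 3L,
                         outlier_intensity = 0.85,
                         rng_seed = 1L) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    tendon_center_row = tendon_center_row,
    tendon_width = tendon_width,
    curvature_radius = curvature_radius,
    band_thickness = band_thickness,
    bursa_intensity = bursa_intensity,
    cortex_intensity = cortex_intensity,
    tendon_intensity = tendon_intensity,
    background_intensity = background_intensity,
    speckle_sigma = speckle_sigma,
    n_outliers = as.integer(n_outliers),
    outlier_intensity = outlier_intensity,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid phantom spec: ", field, " ", why, call. = FALSE)
  }
  chk(spec$height >= 32L, "height", "must be at least 32 pixels")
  chk(spec$width >= 32L, "width", "must be at least 32 pixels")
  chk(spec$tendon_center_row > 0 && spec$tendon_center_row < 1,
      "tendon_center_row", "must be a fraction in (0, 1)")
  chk(spec$tendon_width > 0 && spec$tendon_width < spec$height,
      "tendon_width", "must lie in (0, height)")
  chk(spec$curvature_radius > spec$width / 2,
      "curvature_radius", "must exceed width/2 so the arc spans the image")
  chk(spec$band_thickness >= 1, "band_thickness", "must be at least 1 pixel")
  for (f in c("bursa_intensity", "cortex_intensity", "tendon_intensity",
              "background_intensity", "outlier_intensity")) {
    chk(spec[[f]] >= 0 && spec[[f]] <= 1, f, "must lie in [0, 1]")
  }
  chk(spec$bursa_intensity > spec$tendon_intensity,
      "bursa_intensity", "must exceed tendon_intensity (hyperechoic band)")
  chk(spec$cortex_intensity > spec$tendon_intensity,
      "cortex_intensity", "must exceed tendon_intensity (hyperechoic band)")
  chk(spec$speckle_sigma >= 0, "speckle_sigma", "must be non-negative")
  chk(spec$n_outliers >= 0L, "n_outliers", "must be non-negative")
  spec
}

# radial distance of every pixel from the arc centre (which lies above the
# image); the tendon midline at the central column sits at
# tendon_center_row * height
phantom_rho <- function(spec) {
  m <- spec$height; n <- spec$width
  xc <- (n + 1) / 2
  r0 <- spec$tendon_center_row * m - spec$curvature_radius
  dr <- (seq_len(m) - r0)^2
  dc <- (seq_len(n) - xc)^2
  sqrt(outer(dr, dc, `+`))
}

#' Generate a synthetic tendon phantom
#'
#' Draws the noiseless annulus-sector anatomy, injects the optional bright
#' outlier blobs in the background (kept clear of the tendon complex so the
#' area filter is what must remove them), applies multiplicative Rayleigh
#' speckle, and returns the image with its ground-truth mask.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `image` (matrix in
#'   `[0, 1]`), `truth_mask` (logical matrix: bursa midline to cortex
#'   midline), `outlier_mask` (logical matrix of the injected blobs), and
#'   `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 96,
#'   tendon_width = 12, band_thickness = 4, curvature_radius = 80,
#'   n_outliers = 0))
#' dim(ph$image)
#' @export
generate_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  m <- spec$height; n <- spec$width
  rho <- phantom_rho(spec)
  R <- spec$curvature_radius
  hw <- spec$tendon_width / 2
  t <- spec$band_thickness

  anatomy <- matrix(spec$background_intensity, m, n)
  anatomy[rho > R - hw - t & rho <= R - hw] <- spec$bursa_intensity
  anatomy[rho > R - hw & rho <= R + hw] <- spec$tendon_intensity
  anatomy[rho > R + hw & rho <= R + hw + t] <- spec$cortex_intensity
  truth <- rho > R - hw - t / 2 & rho <= R + hw + t / 2

  out <- withr_seed(spec$rng_seed, {
    outlier_mask <- place_outliers(spec, rho)
    anatomy[outlier_mask] <- spec$outlier_intensity
    image <- anatomy
    if (spec$speckle_sigma > 0) {
      u <- pmax(matrix(runif(m * n), m, n), .Machine$double.xmin)
      s <- spec$speckle_sigma * sqrt(-2 * log(u))
      image <- clip01(anatomy * s)
    }
    list(image = image, outlier_mask = outlier_mask)
  })

  structure(list(image = out$image, truth_mask = truth,
                 outlier_mask = out$outlier_mask, spec = spec),
            class = "phantom")
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# rejection-sample bright ellipses in the background, clear of the tendon
# complex and of the image border
place_outliers <- function(spec, rho) {
  m <- spec$height; n <- spec$width
  mask <- matrix(FALSE, m, n)
  if (spec$n_outliers == 0L) return(mask)
  R <- spec$curvature_radius
  hw <- spec$tendon_width / 2
  t <- spec$band_thickness
  clearance <- 25 * m / 421
  # truth band expanded by the clearance
  keepout <- rho > R - hw - t / 2 - clearance & rho <= R + hw + t / 2 + clearance
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  placed <- 0L
  for (k in seq_len(spec$n_outliers)) {
    for (try in seq_len(200L)) {
      a <- runif(1, 0.031, 0.055) * n   # column semi-axis
      b <- runif(1, 0.019, 0.033) * m   # row semi-axis
      cy <- runif(1, b + 2, m - b - 2)
      cx <- runif(1, a + 2, n - a - 2)
      ell <- ((rows - cy) / b)^2 + ((cols - cx) / a)^2 <= 1
      if (!any(ell & keepout)) {
        mask <- mask | ell
        placed <- placed + 1L
        break
      }
    }
  }
  if (placed < spec$n_outliers) {
    warning("placed only ", placed, " of ", spec$n_outliers,
            " outlier blobs (no background room)", call. = FALSE)
  }
  mask
}

#' Generate a cohort of phantoms with varied anatomy
#'
#' Draws `n` specs uniformly (seeded) from per-field intervals around `base`,
#' emulating inter/intra-operator variability in tendon width, location,
#' intensity level and radius of curvature. Phantom `i` uses
#' `base$rng_seed + i - 1` as its own speckle seed, so a cohort of one with
#' degenerate (point) ranges reproduces `generate_phantom(base)` exactly.
#'
#' @param n Number of phantoms (>= 1).
#' @param base A [phantom_spec()] supplying all non-varied fields.
#' @param variation_ranges Named list of `c(lo, hi)` intervals for numeric
#'   spec fields; see [default_variation_ranges()].
#' @param seed Integer seed for the spec draws.
#' @return A list of `phantom` objects (class `phantom_cohort`).
#' @export
generate_cohort <- function(n, base = phantom_spec(),
                            variation_ranges = default_variation_ranges(),
                            seed = 42L) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  base <- validate_phantom_spec(base)
  if (length(variation_ranges) > 0 &&
      is.null(names(variation_ranges))) {
    stop("variation_ranges must be a named list", call. = FALSE)
  }
  for (f in names(variation_ranges)) {
    rg <- variation_ranges[[f]]
    if (is.null(base[[f]]) || !is.numeric(base[[f]])) {
      stop("unknown or non-numeric spec field in variation_ranges: ", f,
           call. = FALSE)
    }
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[1] > rg[2]) {
      stop("empty or malformed range for field ", f, call. = FALSE)
    }
  }
  specs <- withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      sp <- base
      for (f in names(variation_ranges)) {
        rg <- variation_ranges[[f]]
        sp[[f]] <- if (rg[1] == rg[2]) rg[1] else runif(1, rg[1], rg[2])
      }
      sp$rng_seed <- base$rng_seed + i - 1L
      validate_phantom_spec(sp)
    })
  })
  structure(lapply(specs, generate_phantom), class = "phantom_cohort")
}

#' @rdname generate_cohort
#' @export
default_variation_ranges <- function() {
  list(
    tendon_width = c(50, 90),
    tendon_center_row = c(0.38, 0.52),
    curvature_radius = c(450, 900),
    tendon_intensity = c(0.10, 0.20),
    bursa_intensity = c(0.70, 0.85),
    cortex_intensity = c(0.86, 0.97),
    background_intensity = c(0.22, 0.32)
  )
}

#' Tabulate the specs of a phantom cohort
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @return A tibble with one row per phantom and one column per spec field.
#' @export
cohort_specs <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  as_tibble(do.call(rbind, lapply(cohort, function(p) {
    as.data.frame(unclass(p$spec))
  })))
}

#' Write a phantom cohort to disk
#'
#' Writes `phantom_XXX.png`, `truth_XXX.png` (0/255 masks) and `specs.json`
#' into `dir`.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort)) {
    tag <- sprintf("%03d", i)
    write_gray(cohort[[i]]$image, file.path(dir, paste0("phantom_", tag, ".png")))
    write_mask(cohort[[i]]$truth_mask, file.path(dir, paste0("truth_", tag, ".png")))
  }
  jsonlite::write_json(lapply(cohort, function(p) unclass(p$spec)),
                       file.path(dir, "specs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d> tendon width %.1f px, truth area %d px, %d outlier px\n",
              x$spec$height, x$spec$width, x$spec$tendon_width,
              sum(x$truth_mask), sum(x$outlier_mask)))
  invisible(x)
}

#' @export
plot.phantom <- function(x, which = c("image", "truth", "outliers"), ...) {
  which <- match.arg(which)
  z <- switch(which, image = x$image,
              truth = matrix(as.numeric(x$truth_mask), nrow(x$truth_mask)),
              outliers = matrix(as.numeric(x$outlier_mask), nrow(x$outlier_mask)))
  # flip so row 1 is displayed at the top, as on an ultrasound console
  graphics::image(t(z)[, nrow(z):1], col = gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(x)
}
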