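# Pipeline configuration: a nested named list that round-trips losslessly
# through YAML. Unknown keys are rejected so typos cannot silently fall back
# to defaults.

#' Default pipeline configuration
#'
#' All stage parameters with the working defaults: Rayleigh scale 0.4 and 10
#' diffusion iterations for enhancement; scale 2 with 16 orientations and
#' 6.5% retained coefficients for the curvelet stage; alpha = 0.5 threshold,
#' 5000 px first-pass and 6000 px final area filters (calibrated at 421x580)
#' and the 17x6 elliptical disc for mask generation; no lateral extrapolation
#' for the boundary fit.
#'
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    enhance = list(
      sigma = 0.4,
      epsilon = 1e-6,
      levels = 256L,
      diffusion = list(
        iterations = 10L,
        kappa = 0.1,
        lambda = 0.2,
        variant = "exponential"
      )
    ),
    curvelet = list(
      n_scales = 2L,
      orientations = 16L,
      fraction = 0.065
    ),
    maskgen = list(
      alpha = 0.5,
      min_area = 5000,
      final_min_area = 6000,
      se_width = 17L,
      se_height = 6L,
      reference_shape = c(421L, 580L),
      keep_width_frac = 0.6,
      skip_cleanup = FALSE
    ),
    boundary = list(
      extend_px = 0L,
      min_area_fraction = 0.8
    ),
    seed = 42L,
    dump_intermediates = FALSE
  ), class = "pipeline_config")
}

# recursive key check against the default template
check_config_keys <- function(cfg, template, path = character()) {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(cfg[[k]])) {
        stop("config key ", paste(c(path, k), collapse = "."),
             " must be a section", call. = FALSE)
      }
      check_config_keys(cfg[[k]], template[[k]], c(path, k))
    }
  }
  invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' Merges partial user settings over [default_config()], rejecting unknown
#' keys.
#'
#' @param config A (possibly partial) nested list of settings, or `NULL` for
#'   the defaults.
#' @return A complete `pipeline_config`.
#' @export
as_pipeline_config <- function(config = NULL) {
  template <- default_config()
  if (is.null(config)) return(template)
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  check_config_keys(config, template)
  merged <- modifyList(unclass(template), config)
  structure(merged, class = "pipeline_config")
}

#' Read and write pipeline configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` a complete `pipeline_config`;
#'   `write_config()` the path, invisibly.
#' @export
read_config <- function(path) {
  as_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `pipeline_config` (or partial list).
#' @export
write_config <- function(config, path) {
  config <- as_pipeline_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
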