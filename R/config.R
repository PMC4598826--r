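## Run configuration: a flat named list with dotted keys, JSON on disk,
## CLI flags win over the file, unknown keys rejected.

#' Default run configuration
#'
#' Every tunable of the pipeline with its default.  Keys follow
#' `module.parameter` naming; see the methods vignette for units and
#' rationale.
#'
#' @return named list of class `stackreg_config`.
#' @export
default_config <- function() {
  structure(list(
    normalize.p_low = 0.01,
    normalize.p_high = 0.01,
    stains.hematoxylin = c(0.650, 0.704, 0.286),
    stains.eosin = c(0.072, 0.990, 0.105),
    feature.channel = "eosin",
    coarse.model_class = "similarity",
    coarse.ratio = 0.8,
    coarse.inlier_tol = 3,
    coarse.max_iters = 2000,
    coarse.seed = 0,
    coarse.contrast = 0.015,
    coarse.max_keypoints = 5000,
    elastic.spacing_px = 16,
    elastic.pyramid_levels = 3,
    elastic.w_img = 1.0,
    elastic.w_div = 0.1,
    elastic.w_rot = 0.1,
    elastic.w_cons = 1.0,
    elastic.max_iters = 60,
    elastic.tol = 1e-5,
    elastic.cons_stride = 2,
    stack.reference = "middle",
    stack.alpha = 50,
    validate.scope = "total",
    metric.t = 200,
    metric.bg_tol = 0,
    metric.symmetric = FALSE,
    seed = 0,
    verbosity = 1
  ), class = "stackreg_config")
}

#' Coerce a named list into a validated configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param cfg named list of overrides (or an existing config).
#' @return a `stackreg_config`.
#' @export
as_config <- function(cfg) {
  if (inherits(cfg, "stackreg_config")) return(cfg)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0)
    stop_usage(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  structure(modifyList(unclass(base), cfg), class = "stackreg_config")
}

#' Load configuration from a JSON file with overrides
#'
#' @param path JSON file of config keys, or `NULL` for defaults.
#' @param overrides named list applied on top (flags win).
#' @return a `stackreg_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_usage(paste0("config file not found: ", path))
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  as_config(modifyList(cfg, overrides))
}

stain_matrix_from_config <- function(cfg) {
  build_stain_matrix(cfg$stains.hematoxylin, cfg$stains.eosin)
}
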