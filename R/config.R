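# YAML run configuration: one file holding the crop rectangle, grid division
# count, refinement / brightness / entropy parameters, method choice and
# seed, consumed by the command-line interface and by scripted runs.

#' Default run configuration
#'
#' @return Nested list of defaults: `crop` (NULL = no crop), `n_divisions`,
#'   `method`, `invert`, `seed`, and `refine` / `brightness` / `entropy`
#'   parameter blocks mirroring [refinement_params()],
#'   [brightness_params()], [entropy_params()].
#' @export
default_run_config <- function() {
  list(crop = NULL,
       n_divisions = 10,
       method = "patchdsa",
       invert = FALSE,
       seed = 1L,
       refine = list(enabled = TRUE, initial_step = 1.0, xtol = 0.01,
                     ftol = 1e-5, max_iter = 200, max_shift = NULL),
       brightness = list(exclusion_mode = "robust_sigma",
                         fixed_threshold = NULL, sigma_k = 2,
                         max_excluded_fraction = 0.9),
       entropy = list(bin_width = 1.0, log_base = "natural"))
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_run_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Configuration list with parsed parameter objects in
#'   `$refine_params`, `$brightness_params`, `$entropy_params` and, when a
#'   crop is given, `$crop_rect`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- utils::modifyList(cfg, user)
  }
  cfg$refine_params <- if (isTRUE(cfg$refine$enabled))
    refinement_params(initial_step = cfg$refine$initial_step,
                      xtol = cfg$refine$xtol, ftol = cfg$refine$ftol,
                      max_iter = cfg$refine$max_iter,
                      max_shift = cfg$refine$max_shift)
  cfg$brightness_params <- brightness_params(
    exclusion_mode = cfg$brightness$exclusion_mode,
    fixed_threshold = cfg$brightness$fixed_threshold,
    sigma_k = cfg$brightness$sigma_k,
    max_excluded_fraction = cfg$brightness$max_excluded_fraction)
  cfg$entropy_params <- entropy_params(bin_width = cfg$entropy$bin_width,
                                       log_base = cfg$entropy$log_base)
  if (!is.null(cfg$crop))
    cfg$crop_rect <- crop_rect(cfg$crop$top, cfg$crop$left,
                               cfg$crop$height, cfg$crop$width)
  cfg
}
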