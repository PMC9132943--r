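#' Pipeline configuration with documented defaults
#'
#' Builds the full configuration list for the pipeline stages, filling any
#' key absent from `config` with its default. Every tolerance and threshold
#' used by the package is surfaced here.
#'
#' Defaults: FRAP uses 1 pre-bleach frame, a centre window of half-width
#' 1 px, the fitted plateau as the "final fluorescence" of the
#' mobile-fraction equation (set `final_mode = "last_k"` for the mean of the
#' last `final_last_k` frames), and a diffusion-coefficient search over
#' `[1e-6, 1e-1]` um^2/s at relative tolerance 1e-3. Focus detection uses a
#' mean + 3 SD threshold, a 4 px minimum area and 2-frame persistence; the
#' concomitance window is 0 frames (same-frame events only).
#'
#' @param config Optional partial configuration (nested list), e.g. from
#'   [yaml::read_yaml()].
#' @return The resolved configuration list, of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (inherits(config, "run_config")) return(config)
  defaults <- list(
    random_seed = 1L,
    output_dir = ".",
    frap = list(
      prebleach_frames = 1L,
      window = 1L,
      estimator = "profiled",   # or "two_stage" (D conditional on plateau M)
      final_mode = "plateau",   # or "last_k"
      final_last_k = 5L,
      D_range = c(1e-6, 1e-1),  # um^2/s
      D_rel_tol = 1e-3
    ),
    events = list(
      threshold_k = 3,          # foci threshold: mean + k*SD
      min_area = 4L,            # px
      persistence = 2L,         # frames
      concomitance_window = 0L  # frames
    ),
    coloc = list(
      background_offset = 0
    )
  )
  merged <- utils::modifyList(defaults, config, keep.null = TRUE)
  class(merged) <- "run_config"
  merged
}

#' Load a configuration file
#'
#' Reads a YAML configuration and resolves it against the defaults of
#' [run_config()].
#'
#' @param path YAML file path.
#' @return A resolved `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  run_config(yaml::read_yaml(path))
}
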