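#' Default analysis configuration
#'
#' A nested list of every tunable default in the pipeline, round-trippable
#' through YAML with [read_config()] / [write_config()]. Structure-class
#' presets carry the outline/skeleton point mode, the per-structure
#' maximum measurement length (20/10/8 um for nuclei / mitochondria /
#' microtubules) and the B-spline penalty defaults.
#'
#' @return a named list of class `analysis_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(kind = "nuclei", field_size_nm = 51200,
                    pre = unclass(imaging_params()),
                    post = unclass(imaging_params(pixel_size_nm = 1500)),
                    deformation = list(scale = 15.6, shear = c(1, 0, 0, 1),
                                       nonrigid_amplitude_nm = 0,
                                       nonrigid_correlation_length_nm = 8000)),
    registration = list(pyramid_levels = 3L, grid_spacing_px = 32,
                        max_iterations = 80L, blur_sigma_px = 2,
                        despeckle = FALSE),
    distortion = list(bin_width_um = 0.5, max_pairs = 2e6,
                      max_points = 3000, aggregator = "mean_abs",
                      structure_presets = list(
                        nuclei = list(mode = "outline", max_length_um = 20,
                                      penalty_weight = 1e-1),
                        mitochondria = list(mode = "skeleton",
                                            max_length_um = 10,
                                            penalty_weight = 1e-2),
                        microtubules = list(mode = "skeleton",
                                            max_length_um = 8,
                                            penalty_weight = 1e-2))),
    scale = list(min_area_um2 = 20),
    morphometry = list(thickness_px = 10, prominence_frac = 0.1,
                       min_separation = 3L),
    signal = list(min_nucleus_px = 9L, split_touching = FALSE)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys (at the top level or within a section) are rejected by
#' name; missing keys fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- default_config()
  merge_checked <- function(d, r, prefix = "") {
    unknown <- setdiff(names(r), names(d))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", ": ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(r)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(r[[k]]))
        merge_checked(d[[k]], r[[k]], paste0(prefix, k, "."))
      else r[[k]]
    }
    d
  }
  structure(merge_checked(unclass(def), raw), class = "analysis_config")
}

#' Write an analysis configuration to YAML
#' @param config an `analysis_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Stable hash embedded in every pipeline artifact for provenance.
#' @param config an `analysis_config`.
#' @return character hash.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))
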