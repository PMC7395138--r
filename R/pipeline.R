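#' Run a pipeline command
#'
#' Programmatic equivalent of the command-line surface. Every artifact
#' (CSV/JSON) embeds the configuration hash and the seed used, and all
#' randomness flows from the single top-level seed via named substreams,
#' so runs are deterministic given the seed.
#'
#' Commands:
#' * `"simulate"` — build the configured scene, render the pre image,
#'   deform and render the post image; writes `pre.tif`, `post.tif`,
#'   `ground_truth.json`, `scene.yaml`.
#' * `"register"` — similarity + B-spline registration of `post` to
#'   `pre`; writes `transform.json`, `field.tif` (2-page 32-bit
#'   displacement), `registered.tif`.
#' * `"distortion"` — full [distortion_report()]; writes
#'   `rms_curve_similarity.csv`, `rms_curve_affine.csv`, `rms_curve.pdf`.
#' * `"expansion-factor"` — nuclear-area expansion factor from a pre and
#'   a post image; writes `expansion_factor.json`.
#' * `"morphometry"` — peak-spacing measurements for line profiles given
#'   in a CSV annotation file (`x0,y0,x1,y1`); writes
#'   `morphometry.csv` (per measurement) and `morphometry_summary.csv`.
#' * `"signal"` — per-cell total-signal quantification of one image;
#'   writes `field_measurement.json`.
#'
#' @param config an `analysis_config` (see [default_config()]).
#' @param command one of the commands above.
#' @param inputs named list of input paths / objects, command-specific:
#'   `pre`, `post` (TIFF paths or [raster_image()]s), `structure`,
#'   `profiles` (CSV path), `image`, `background_roi`, `n_cells`,
#'   `expansion_factor`, `exposure_ms`.
#' @param out_dir output directory (created if needed).
#' @param seed top-level seed; defaults to `config$seed`.
#' @return list of computed results, invisibly for write-only commands.
#' @export
run_pipeline <- function(config = default_config(), command, inputs = list(),
                         out_dir = ".", seed = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  command <- match.arg(command, c("simulate", "register", "distortion",
                                  "expansion-factor", "morphometry",
                                  "signal"))
  seed <- as.integer(seed %||% config$seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- list(config_hash = config_hash(config), seed = seed,
               package_version = as.character(utils::packageVersion("exmetry")))
  load_img <- function(key) {
    x <- inputs[[key]]
    if (is.null(x)) stop("command '", command, "' needs input '", key, "'")
    if (is_raster(x)) x
    else if (is.character(x)) read_image(x)
    else stop("input '", key, "' must be a path or raster_image")
  }
  res <- switch(
    command,
    simulate = {
      sc <- config$simulate
      scene <- make_scene(sc$kind, params = list(field_size_nm = sc$field_size_nm),
                          seed = sub_seed(seed, "scene"))
      imaging_pre <- do.call(imaging_params, sc$pre)
      imaging_post <- do.call(imaging_params, sc$post)
      d <- sc$deformation
      spec <- deformation_spec(scale = d$scale,
                               shear = matrix(unlist(d$shear), 2, 2),
                               nonrigid_amplitude_nm = d$nonrigid_amplitude_nm,
                               nonrigid_correlation_length_nm =
                                 d$nonrigid_correlation_length_nm,
                               seed = sub_seed(seed, "field"))
      pre <- render(scene, imaging_pre, seed = sub_seed(seed, "pre-noise"))
      def <- deform_scene(scene, spec, imaging_post, imaging_pre,
                          seed = sub_seed(seed, "post-noise"))
      write_image(pre, file.path(out_dir, "pre.tif"))
      write_image(def$post, file.path(out_dir, "post.tif"))
      jsonlite::write_json(
        c(meta, list(
          true_points_nm = scene$truth$points_nm,
          spacings_nm = scene$truth$spacings_nm,
          region_areas_um2 = scene$truth$region_areas_um2,
          field_ux_nm = def$field$ux, field_uy_nm = def$field$uy,
          field_pixel_size_nm = def$field$pixel_size_nm,
          scale = spec$scale, shear = spec$shear,
          nonrigid_amplitude_nm = spec$nonrigid_amplitude_nm)),
        file.path(out_dir, "ground_truth.json"), digits = NA,
        auto_unbox = TRUE)
      write_config(config, file.path(out_dir, "scene.yaml"))
      list(pre = pre, post = def$post, truth = def$truth)
    },
    register = {
      pre <- load_img("pre"); post <- load_img("post")
      rc <- config$registration
      cfg <- registration_config(pyramid_levels = rc$pyramid_levels,
                                 grid_spacing_px = rc$grid_spacing_px,
                                 max_iterations = rc$max_iterations)
      pre_p <- preprocess(pre, blur_sigma_px = 0)
      post_p <- preprocess(post, blur_sigma_px = rc$blur_sigma_px,
                           despeckle = rc$despeckle)
      lin <- fit_linear(pre_p, post_p, kind = inputs$kind %||% "similarity",
                        config = cfg)
      reg <- resample(post_p, lin, output_dim = dim(pre_p$data))
      bs <- fit_bspline(pre_p, reg, config = cfg)
      jsonlite::write_json(
        c(meta, list(kind = lin$kind, A = lin$A, t = lin$t,
                     expansion_scale = lin$expansion_scale,
                     final_metric = lin$metric)),
        file.path(out_dir, "transform.json"), digits = NA)
      write_field(bs$field, file.path(out_dir, "field.tif"))
      write_image(reg, file.path(out_dir, "registered.tif"))
      list(linear = lin, bspline = bs, registered = reg)
    },
    distortion = {
      pre <- load_img("pre"); post <- load_img("post")
      structure_class <- inputs$structure %||% "nuclei"
      rc <- config$registration
      cfg <- registration_config(pyramid_levels = rc$pyramid_levels,
                                 grid_spacing_px = rc$grid_spacing_px,
                                 max_iterations = rc$max_iterations)
      rep <- distortion_report(pre, post, structure_class, config = cfg,
                               blur_sigma_px = rc$blur_sigma_px,
                               despeckle = rc$despeckle,
                               max_points = config$distortion$max_points,
                               max_pairs = config$distortion$max_pairs,
                               bin_width_um = config$distortion$bin_width_um,
                               seed = sub_seed(seed, "pairs"))
      for (kind in c("similarity", "affine")) {
        cv <- rep[[kind]]$curve
        cv$config_hash <- meta$config_hash
        cv$seed <- seed
        utils::write.csv(cv, file.path(out_dir,
                                       sprintf("rms_curve_%s.csv", kind)),
                         row.names = FALSE)
      }
      grDevices::pdf(file.path(out_dir, "rms_curve.pdf"), width = 6,
                     height = 4)
      plot(rep$similarity$curve,
           main = sprintf("%s (similarity)", structure_class))
      plot(rep$affine$curve, main = sprintf("%s (affine)", structure_class))
      grDevices::dev.off()
      rep
    },
    `expansion-factor` = {
      pre <- load_img("pre"); post <- load_img("post")
      min_area <- config$scale$min_area_um2
      a_pre <- nuclear_areas(pre, min_area)
      # the same physical floor, expanded, for the post image
      a_post <- nuclear_areas(post, min_area)
      est <- expansion_factor(a_pre, a_post)
      jsonlite::write_json(
        c(meta, list(linear_factor = est$linear_factor,
                     method = est$method, n_objects = est$n_objects,
                     dispersion = est$dispersion)),
        file.path(out_dir, "expansion_factor.json"),
        auto_unbox = TRUE, digits = NA)
      est
    },
    morphometry = {
      img <- load_img("image")
      prof_tab <- utils::read.csv(inputs$profiles)
      fac <- inputs$expansion_factor %||% 1
      mc <- config$morphometry
      rows <- lapply(seq_len(nrow(prof_tab)), function(i) {
        pr <- thick_line_profile(img,
                                 c(prof_tab$x0[i], prof_tab$y0[i]),
                                 c(prof_tab$x1[i], prof_tab$y1[i]),
                                 thickness_px = mc$thickness_px)
        ps <- peak_spacing(pr, fac, prominence_frac = mc$prominence_frac,
                           min_separation = mc$min_separation)
        data.frame(profile = i, spacing_nm = ps$values_nm)
      })
      per <- do.call(rbind, rows)
      per$config_hash <- meta$config_hash; per$seed <- seed
      utils::write.csv(per, file.path(out_dir, "morphometry.csv"),
                       row.names = FALSE)
      sm <- data.frame(mean = mean(per$spacing_nm),
                       sd = stats::sd(per$spacing_nm),
                       median = stats::median(per$spacing_nm),
                       iqr = stats::IQR(per$spacing_nm),
                       n = nrow(per),
                       config_hash = meta$config_hash, seed = seed)
      utils::write.csv(sm, file.path(out_dir, "morphometry_summary.csv"),
                       row.names = FALSE)
      list(per_measurement = per, summary = sm)
    },
    signal = {
      img <- load_img("image")
      bg <- if (!is.null(inputs$background_roi))
        background_level(img, inputs$background_roi) else 0
      n_cells <- inputs$n_cells %||%
        count_nuclei(img, min_size = config$signal$min_nucleus_px,
                     split = config$signal$split_touching)
      fm <- total_signal(img, mode = "per_cell", background = bg,
                         n_cells = n_cells,
                         exposure_ms = inputs$exposure_ms %||% 1)
      jsonlite::write_json(c(meta, unclass(fm)),
                           file.path(out_dir, "field_measurement.json"),
                           auto_unbox = TRUE, digits = NA)
      fm
    })
  invisible(res)
}
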