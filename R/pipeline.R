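#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default:
#' DBSCAN radius and minimum points, segmentation threshold multiplier and
#' opening radii, NND co-localisation threshold, rendering precision,
#' length-model support and nm-to-monomer conversion, fibril-like
#' thresholds, STED filters, and the Beta prior. Validation rejects any
#' value outside its documented domain, naming the offending field.
#'
#' @param eps_nm DBSCAN neighbourhood radius (nm).
#' @param min_points DBSCAN minimum neighbourhood size.
#' @param k_sd segmentation threshold multiplier.
#' @param erosion_radius_px,dilation_radius_px opening radii (px).
#' @param min_area_px,max_area_px synaptosome size filter (px).
#' @param nnd_threshold_nm co-localisation distance threshold (nm).
#' @param render_precision_nm rendering Gaussian sigma (nm).
#' @param render_pixel_nm rendering pixel size (nm).
#' @param n_min,n_max length-model support (monomers).
#' @param conversion_factor monomers per nm.
#' @param fibril_length_nm,fibril_ecc fibril-like thresholds.
#' @param sted_intensity_min,sted_sigma_range_nm,sted_presynaptic_nm STED
#'   filter parameters.
#' @param a_prior,b_prior Beta prior shapes.
#' @param seed master seed for the synthetic scene and posterior draws.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(eps_nm = 75, min_points = 2L, k_sd = 2,
                            erosion_radius_px = 1L, dilation_radius_px = 1L,
                            min_area_px = 4L, max_area_px = Inf,
                            nnd_threshold_nm = 50,
                            render_precision_nm = 20, render_pixel_nm = 10,
                            n_min = 500L, n_max = 1200L,
                            conversion_factor = 4,
                            fibril_length_nm = 150, fibril_ecc = 0.9,
                            sted_intensity_min = 200,
                            sted_sigma_range_nm = c(80, 800),
                            sted_presynaptic_nm = 90,
                            a_prior = 1, b_prior = 1,
                            seed = 1L) {
  cfg <- as.list(environment())
  check_pos <- function(field) {
    if (!is.numeric(cfg[[field]]) || any(cfg[[field]] <= 0))
      stop("`", field, "` must be positive")
  }
  for (f in c("eps_nm", "min_points", "k_sd", "nnd_threshold_nm",
              "render_precision_nm", "render_pixel_nm", "conversion_factor",
              "fibril_length_nm", "a_prior", "b_prior",
              "sted_presynaptic_nm"))
    check_pos(f)
  if (cfg$fibril_ecc < 0 || cfg$fibril_ecc > 1)
    stop("`fibril_ecc` must lie in [0, 1]")
  if (cfg$n_min >= cfg$n_max) stop("`n_min` must be smaller than `n_max`")
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end synthetic-scene analysis pipeline
#'
#' Executes the full chain on a synthetic scene: scene generation,
#' aggregate detection (DBSCAN + morphometry), synaptosome segmentation,
#' compartment assignment, per-compartment length-model fits, the
#' removal-rate ratio when both compartments carry enough in-support
#' aggregates, and a comparison of every recovered quantity with the
#' planted ground truth. Re-running with the same spec and config
#' reproduces the result exactly.
#'
#' @param spec a [scene_spec()] describing the synthetic scene.
#' @param config a [pipeline_config()].
#' @param fit_lengths logical; fit the truncated-geometric length model to
#'   the recovered synaptic lengths?
#' @return list with `scene`, `aggregates` (compartment-labelled table),
#'   `regions`, `occupancy_fraction`, `aggregates_per_occupied`,
#'   `fibril_fraction_synaptic`, `length_fit` (or NULL), and `truth`
#'   (planted occupancy, fibril fraction, alpha when applicable).
#' @export
run_pipeline <- function(spec, config = pipeline_config(),
                         fit_lengths = TRUE) {
  stopifnot(inherits(spec, "scene_spec"), inherits(config, "pipeline_config"))
  scene <- generate_localisation_scene(spec)

  agg <- detect_aggregates(scene$localisations,
                           eps_nm = config$eps_nm,
                           min_points = config$min_points,
                           conversion_factor = config$conversion_factor,
                           length_threshold = config$fibril_length_nm,
                           ecc_threshold = config$fibril_ecc)
  regions <- segment_synaptosomes(scene$membrane_image,
                                  k_sd = config$k_sd,
                                  erosion_radius_px = config$erosion_radius_px,
                                  dilation_radius_px = config$dilation_radius_px,
                                  min_area_px = config$min_area_px,
                                  max_area_px = config$max_area_px,
                                  pixel_size_nm = spec$pixel_size_nm)
  asg <- assign_aggregates(agg, regions, pixel_size_nm = spec$pixel_size_nm)
  agg <- asg$aggregates
  syn <- agg[agg$compartment == "synaptic", , drop = FALSE]

  fit <- NULL
  if (fit_lengths && nrow(syn) >= 2L) {
    fit <- tryCatch(
      fit_alpha(syn$length_nm, n_min = config$n_min, n_max = config$n_max,
                conversion_factor = config$conversion_factor),
      error = function(e) NULL)
  }

  gt <- scene$ground_truth
  truth <- list(
    occupancy_fraction = if (nrow(gt$synaptosomes)) mean(gt$synaptosomes$occupied) else NA_real_,
    fibril_fraction = if (!is.null(gt$aggregates) && nrow(gt$aggregates))
      mean(gt$aggregates$fibril_like[gt$aggregates$compartment == "synaptic"]) else NA_real_,
    alpha = if (identical(spec$aggregate_length_law$type, "truncgeom"))
      spec$aggregate_length_law$alpha else NA_real_
  )

  list(scene = scene,
       aggregates = agg,
       regions = regions,
       occupancy_fraction = asg$occupancy_fraction,
       aggregates_per_occupied = asg$aggregates_per_occupied,
       fibril_fraction_synaptic = if (nrow(syn)) mean(syn$fibril_like) else NA_real_,
       length_fit = fit,
       truth = truth)
}
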