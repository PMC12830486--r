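#' Segment synaptosomes from a membrane-stain image
#'
#' Thresholds the field of view at `mean + k_sd * sd` of the whole image,
#' removes small noise-induced objects by morphological opening (erosion
#' followed by dilation with disc structuring elements), labels connected
#' components, and keeps components inside the configured area bounds.
#' A constant image (zero standard deviation) yields no regions.
#'
#' @param image numeric matrix (rows = y, cols = x) of counts.
#' @param k_sd threshold multiplier on the FoV standard deviation.
#' @param erosion_radius_px,dilation_radius_px opening radii in pixels
#'   (0 disables the corresponding step).
#' @param min_area_px,max_area_px inclusive area bounds (pixels) for a
#'   component to count as a synaptosome.
#' @param pixel_size_nm pixel size used to report centroids in nm.
#' @return object of class `synaptosome_regions`: list with `labels`
#'   (integer matrix, 0 = background) and `regions` (data frame
#'   `region_id`, `area_px`, `centroid_x_nm`, `centroid_y_nm`).
#' @export
segment_synaptosomes <- function(image, k_sd = 2,
                                 erosion_radius_px = 1L,
                                 dilation_radius_px = 1L,
                                 min_area_px = 4L, max_area_px = Inf,
                                 pixel_size_nm = 210) {
  if (length(image) == 0L) stop("`image` must be non-empty")
  s <- stats::sd(image)
  thr <- mean(image) + k_sd * s
  mask <- image > thr
  if (s == 0 || !any(mask))
    return(empty_regions(image))
  m <- EBImage::Image(t(mask) * 1)   # EBImage uses (x, y) storage
  if (erosion_radius_px > 0)
    m <- EBImage::erode(m, EBImage::makeBrush(2L * erosion_radius_px + 1L, "disc"))
  if (dilation_radius_px > 0)
    m <- EBImage::dilate(m, EBImage::makeBrush(2L * dilation_radius_px + 1L, "disc"))
  lab <- EBImage::bwlabel(m)
  labels <- t(EBImage::imageData(lab))  # back to (row = y, col = x)
  regions_from_labels(labels, min_area_px, max_area_px, pixel_size_nm)
}

empty_regions <- function(image) {
  structure(list(
    labels = matrix(0L, nrow(image), ncol(image)),
    regions = data.frame(region_id = integer(0), area_px = integer(0),
                         centroid_x_nm = numeric(0), centroid_y_nm = numeric(0))
  ), class = "synaptosome_regions")
}

regions_from_labels <- function(labels, min_area_px, max_area_px,
                                pixel_size_nm) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    return(structure(list(labels = labels,
                          regions = data.frame(region_id = integer(0),
                                               area_px = integer(0),
                                               centroid_x_nm = numeric(0),
                                               centroid_y_nm = numeric(0))),
                     class = "synaptosome_regions"))
  area <- tabulate(labels[labels > 0], nbins = max(ids))[ids]
  keep <- ids[area >= min_area_px & area <= max_area_px]
  out <- matrix(0L, nrow(labels), ncol(labels))
  rows <- integer(0)
  df <- data.frame(region_id = integer(0), area_px = integer(0),
                   centroid_x_nm = numeric(0), centroid_y_nm = numeric(0))
  new_id <- 0L
  for (k in keep) {
    new_id <- new_id + 1L
    sel <- which(labels == k, arr.ind = TRUE)
    out[sel] <- new_id
    # pixel (i, j) centre is at ((j - 0.5) p, (i - 0.5) p) nm
    df <- rbind(df, data.frame(
      region_id = new_id, area_px = nrow(sel),
      centroid_x_nm = (mean(sel[, 2]) - 0.5) * pixel_size_nm,
      centroid_y_nm = (mean(sel[, 1]) - 0.5) * pixel_size_nm))
  }
  structure(list(labels = out, regions = df), class = "synaptosome_regions")
}

#' @export
print.synaptosome_regions <- function(x, ...) {
  cat(sprintf("%d synaptosome region(s) in a %d x %d px field\n",
              nrow(x$regions), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# map nm coordinates to the integer pixel index (row, col) that contains them
nm_to_pixel <- function(x_nm, y_nm, pixel_size_nm, nr, nc) {
  j <- pmin(pmax(floor(x_nm / pixel_size_nm) + 1L, 1L), nc)
  i <- pmin(pmax(floor(y_nm / pixel_size_nm) + 1L, 1L), nr)
  cbind(i, j)
}

#' Assign aggregates to synaptic or extra-synaptic compartments
#'
#' An aggregate is synaptic when the pixel containing its centroid lies
#' inside a segmented synaptosome region mask; otherwise it is
#' extra-synaptic. Region occupancy metrics (fraction of regions holding
#' at least one aggregate, aggregates per occupied region) follow from the
#' per-region aggregate counts.
#'
#' @param aggregates aggregate table from [detect_aggregates()].
#' @param regions `synaptosome_regions` from [segment_synaptosomes()].
#' @param pixel_size_nm pixel size of the segmented image (nm).
#' @return list with `aggregates` (input table with `compartment` and
#'   `region_id` filled), `region_counts` (data frame `region_id`,
#'   `n_aggregates`), `occupancy_fraction` and `aggregates_per_occupied`.
#' @export
assign_aggregates <- function(aggregates, regions, pixel_size_nm = 210) {
  stopifnot(inherits(regions, "synaptosome_regions"))
  lab <- regions$labels
  n <- nrow(aggregates)
  region_id <- rep(NA_integer_, n)
  if (n > 0) {
    px <- nm_to_pixel(aggregates$centroid_x_nm, aggregates$centroid_y_nm,
                      pixel_size_nm, nrow(lab), ncol(lab))
    hit <- lab[px]
    region_id[hit > 0] <- hit[hit > 0]
  }
  aggregates$compartment <- ifelse(is.na(region_id), "extra_synaptic", "synaptic")
  aggregates$region_id <- region_id
  counts <- table(factor(region_id, levels = regions$regions$region_id))
  region_counts <- data.frame(region_id = regions$regions$region_id,
                              n_aggregates = as.integer(counts))
  n_regions <- nrow(regions$regions)
  occ <- if (n_regions) mean(region_counts$n_aggregates > 0) else NA_real_
  per_occ <- if (any(region_counts$n_aggregates > 0))
    mean(region_counts$n_aggregates[region_counts$n_aggregates > 0]) else NA_real_
  list(aggregates = aggregates, region_counts = region_counts,
       occupancy_fraction = occ, aggregates_per_occupied = per_occ)
}

#' Assign localisations to synaptosome region masks
#'
#' Mask-based spatial filtering of (projected) localisations: localisations
#' whose containing pixel falls inside a region mask are assigned to that
#' region, all others are excluded. For each region the centroid of its
#' assigned localisations (the aggregate centroid) is computed, and the 2D
#' Euclidean distances between aggregate centroids and their synaptosome
#' centroids are averaged over the field of view.
#'
#' @param localisations data frame with `x`, `y` in nm.
#' @param regions `synaptosome_regions` (e.g. from a thresholded averaged
#'   wide-field image).
#' @param pixel_size_nm pixel size of the region mask (nm).
#' @return list with `assignment` (integer region id per localisation, 0 =
#'   excluded), `per_region` (data frame `region_id`, `n_localisations`,
#'   `aggregate_x_nm`, `aggregate_y_nm`, `centroid_distance_nm`) and
#'   `mean_centroid_distance_nm`.
#' @export
filter_localisations_by_mask <- function(localisations, regions,
                                         pixel_size_nm = 210) {
  stopifnot(inherits(regions, "synaptosome_regions"))
  lab <- regions$labels
  n <- nrow(localisations)
  assignment <- integer(n)
  if (n > 0) {
    px <- nm_to_pixel(localisations$x, localisations$y, pixel_size_nm,
                      nrow(lab), ncol(lab))
    # points beyond the image bounds are excluded, not clamped in
    inside <- localisations$x >= 0 & localisations$y >= 0 &
      localisations$x < ncol(lab) * pixel_size_nm &
      localisations$y < nrow(lab) * pixel_size_nm
    assignment[inside] <- lab[px[inside, , drop = FALSE]]
  }
  reg <- regions$regions
  per <- lapply(seq_len(nrow(reg)), function(r) {
    idx <- which(assignment == reg$region_id[r])
    if (length(idx) == 0L)
      return(data.frame(region_id = reg$region_id[r], n_localisations = 0L,
                        aggregate_x_nm = NA_real_, aggregate_y_nm = NA_real_,
                        centroid_distance_nm = NA_real_))
    ax <- mean(localisations$x[idx]); ay <- mean(localisations$y[idx])
    data.frame(region_id = reg$region_id[r], n_localisations = length(idx),
               aggregate_x_nm = ax, aggregate_y_nm = ay,
               centroid_distance_nm = sqrt((ax - reg$centroid_x_nm[r])^2 +
                                           (ay - reg$centroid_y_nm[r])^2))
  })
  per <- do.call(rbind, per)
  if (is.null(per)) per <- data.frame(region_id = integer(0),
                                      n_localisations = integer(0),
                                      aggregate_x_nm = numeric(0),
                                      aggregate_y_nm = numeric(0),
                                      centroid_distance_nm = numeric(0))
  list(assignment = assignment, per_region = per,
       mean_centroid_distance_nm = if (nrow(per) && any(!is.na(per$centroid_distance_nm)))
         mean(per$centroid_distance_nm, na.rm = TRUE) else NA_real_)
}
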