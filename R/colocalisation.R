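#' Detect diffraction-limited puncta in a fluorescence image
#'
#' Finds local maxima above `mean + k_sd * sd` of the image, applies
#' non-maximum suppression so that no two puncta are closer than
#' `min_separation_px`, and refines each centroid by the intensity-weighted
#' mean position within a 3x3 window.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param k_sd threshold multiplier on the image standard deviation.
#' @param min_separation_px minimum centre-to-centre separation (pixels).
#' @param pixel_size_nm pixel size used to report centroids in nm.
#' @return data frame (`x`, `y` in nm, `peak_intensity`), possibly empty.
#' @export
detect_puncta <- function(image, k_sd = 3, min_separation_px = 3L,
                          pixel_size_nm = 210) {
  if (length(image) == 0L) stop("`image` must be non-empty")
  thr <- mean(image) + k_sd * stats::sd(image)
  nr <- nrow(image); nc <- ncol(image)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      peak_intensity = numeric(0))
  cand <- which(image > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # strict local maximum over the 8-neighbourhood (plateaus broken by
  # requiring >= all neighbours and > at least one)
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    win <- image[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    image[i, j] >= max(win)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  vals <- image[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (k == 1L) { keep[1] <- TRUE; next }
    prev <- which(keep[seq_len(k - 1L)])
    d2 <- (cand[prev, 1] - cand[k, 1])^2 + (cand[prev, 2] - cand[k, 2])^2
    keep[k] <- all(d2 >= min_separation_px^2)
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
  # centroid refinement: intensity-weighted mean over the 3x3 window
  cen <- t(vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    w <- image[ii, jj, drop = FALSE]
    c(sum(outer(ii, jj, function(a, b) a) * w) / sum(w),
      sum(outer(ii, jj, function(a, b) b) * w) / sum(w))
  }, numeric(2)))
  data.frame(x = (cen[, 2] - 0.5) * pixel_size_nm,
             y = (cen[, 1] - 0.5) * pixel_size_nm,
             peak_intensity = vals)
}

#' Nearest-neighbour-distance co-localisation between two channels
#'
#' For each punctum in `set_a`, computes the nearest-neighbour distance to
#' the puncta of `set_b` (in a common, registration-corrected coordinate
#' frame); a punctum is colocalised when its NND is less than or equal to
#' the distance threshold. With an empty `set_b` all NNDs are undefined and
#' nothing is colocalised.
#'
#' @param set_a,set_b data frames with `x`, `y` centroid coordinates (nm).
#' @param threshold_nm inclusive distance threshold (nm).
#' @return list with `nnd_nm` (per-`set_a` punctum; `NA` when `set_b` is
#'   empty), `colocalised` (logical), `n_colocalised` and `fraction`.
#' @export
nnd_colocalise <- function(set_a, set_b, threshold_nm = 50) {
  na <- nrow(set_a)
  if (na == 0L)
    return(list(nnd_nm = numeric(0), colocalised = logical(0),
                n_colocalised = 0L, fraction = NA_real_))
  if (nrow(set_b) == 0L)
    return(list(nnd_nm = rep(NA_real_, na), colocalised = rep(FALSE, na),
                n_colocalised = 0L, fraction = 0))
  d2 <- outer(set_a$x, set_b$x, `-`)^2 + outer(set_a$y, set_b$y, `-`)^2
  nnd <- sqrt(apply(d2, 1, min))
  flag <- nnd <= threshold_nm
  list(nnd_nm = nnd, colocalised = flag,
       n_colocalised = sum(flag), fraction = mean(flag))
}

#' Per-field co-occurrence metrics of a marker with AT8-positive tau
#'
#' From a per-synaptosome flag table, computes the four co-occurrence
#' parameters: the total signal count, the marginal percentage
#' (synaptosomes with signal / all synaptosomes x 100), the conditional
#' percentage (synaptosomes with signal and AT8 / synaptosomes with AT8
#' x 100) and the joint percentage (synaptosomes with signal and AT8 /
#' all synaptosomes x 100). When there are no AT8-positive synaptosomes
#' the conditional percentage is undefined (`NA`), not zero.
#'
#' @param table data frame with logical columns `at8` and `signal`, one
#'   row per synaptosome.
#' @return list with `counts` (`N_total`, `N_at8`, `n_signal_total`,
#'   `n_signal_and_at8`) and `total_signal`, `marginal_pct`,
#'   `conditional_pct`, `joint_pct`.
#' @export
cooccurrence_metrics <- function(table) {
  if (nrow(table) < 1L) stop("`table` must contain at least one synaptosome")
  N <- nrow(table)
  n_at8 <- sum(table$at8)
  n_sig <- sum(table$signal)
  n_both <- sum(table$at8 & table$signal)
  list(
    counts = list(N_total = N, N_at8 = n_at8, n_signal_total = n_sig,
                  n_signal_and_at8 = n_both),
    total_signal = n_sig,
    marginal_pct = n_sig / N * 100,
    conditional_pct = if (n_at8 > 0) n_both / n_at8 * 100 else NA_real_,
    joint_pct = n_both / N * 100
  )
}
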