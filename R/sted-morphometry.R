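# 1D convolution with mirror boundary handling, kernel taps at offsets
# `off` with weights `w` (used for the holey B3-spline filter)
conv1_mirror <- function(v, off, w) {
  n <- length(v)
  out <- numeric(n)
  idx <- seq_len(n)
  for (k in seq_along(off)) {
    j <- idx + off[k]
    # mirror: reflect about the edges (1 and n), repeatedly if needed
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    out <- out + w[k] * v[j]
  }
  out
}

# separable smoothing with the B3-spline kernel [1,4,6,4,1]/16 dilated by
# `step` (holes of step-1 zeros): one a-trous level
atrous_smooth <- function(img, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * step
  tmp <- apply(img, 2, conv1_mirror, off = off, w = w)       # along rows (y)
  t(apply(tmp, 1, conv1_mirror, off = off, w = w))           # along cols (x)
}

#' A-trous B3-spline wavelet decomposition
#'
#' Undecimated ("with holes") wavelet transform using the B3-spline kernel:
#' at each level the image is smoothed with the kernel dilated by
#' `2^(level-1)` and the wavelet plane is the difference between the input
#' and output of the smoothing. By construction the sum of all wavelet
#' planes plus the final smooth residual reproduces the input exactly.
#'
#' @param image numeric matrix.
#' @param levels number of wavelet planes.
#' @return list with `planes` (list of matrices) and `residual`.
#' @export
atrous_decompose <- function(image, levels = 3L) {
  min_size <- 4L * 2L^(levels - 1L) + 1L
  if (nrow(image) < min_size || ncol(image) < min_size)
    stop("image too small for ", levels, " a-trous levels")
  planes <- vector("list", levels)
  c_prev <- image
  for (j in seq_len(levels)) {
    c_next <- atrous_smooth(c_prev, 2L^(j - 1L))
    planes[[j]] <- c_prev - c_next
    c_prev <- c_next
  }
  list(planes = planes, residual = c_prev)
}

#' Detect spot candidates with the a-trous wavelet pipeline
#'
#' Thresholds the chosen wavelet plane at `threshold_factor` times its
#' standard deviation and returns the local maxima of that plane as
#' candidate spot positions (pixel indices).
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param levels number of decomposition levels.
#' @param threshold_factor multiplier on the detection plane's SD.
#' @param detection_level which wavelet plane to threshold (default 2,
#'   matching common single-molecule detection practice).
#' @return data frame with `row`, `col` (pixel indices) and `response`
#'   (wavelet coefficient), possibly empty.
#' @export
atrous_detect <- function(image, levels = 3L, threshold_factor = 3,
                          detection_level = 2L) {
  dec <- atrous_decompose(image, levels)
  plane <- dec$planes[[min(detection_level, levels)]]
  thr <- threshold_factor * stats::sd(plane)
  nr <- nrow(plane); nc <- ncol(plane)
  cand <- which(plane > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      response = numeric(0)))
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    win <- plane[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    plane[i, j] >= max(win)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  data.frame(row = cand[, 1], col = cand[, 2], response = plane[cand])
}

#' Fit an anisotropic 2D Gaussian around a candidate position
#'
#' Levenberg-Marquardt least-squares fit of an elliptical Gaussian
#' `offset + A exp(-(u^2 / (2 s_long^2) + v^2 / (2 s_short^2)))`, where
#' `(u, v)` are the centred coordinates rotated by the orientation, in a
#' square window around the candidate. Initial values come from image
#' moments in the window. The spot length is defined as `2.3 * sigma_long`.
#' The orientation is identifiable only modulo pi and is reported in
#' `[0, pi)`.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param row,col candidate position (pixel indices).
#' @param window_px half-width of the square fit window (pixels).
#' @param pixel_size_nm pixel size (nm).
#' @return data frame with one row: `x_nm`, `y_nm`, `sigma_long_nm`,
#'   `sigma_short_nm`, `orientation`, `amplitude`, `offset`, `length_nm`,
#'   `converged`; or `NULL` when the fit fails to converge.
#' @export
fit_anisotropic_gaussian <- function(image, row, col, window_px = 15L,
                                     pixel_size_nm = 20) {
  nr <- nrow(image); nc <- ncol(image)
  ii <- max(1L, row - window_px):min(nr, row + window_px)
  jj <- max(1L, col - window_px):min(nc, col + window_px)
  z <- image[ii, jj, drop = FALSE]
  ygrid <- (ii - 0.5) * pixel_size_nm
  xgrid <- (jj - 0.5) * pixel_size_nm
  X <- rep(xgrid, each = length(ygrid))
  Y <- rep(ygrid, length(xgrid))
  zv <- as.vector(z)

  # moment-based initial values
  off0 <- stats::quantile(zv, 0.2, names = FALSE)
  w <- pmax(zv - off0, 0)
  if (sum(w) <= 0) return(NULL)
  mx <- sum(w * X) / sum(w); my <- sum(w * Y) / sum(w)
  vxx <- sum(w * (X - mx)^2) / sum(w)
  vyy <- sum(w * (Y - my)^2) / sum(w)
  vxy <- sum(w * (X - mx) * (Y - my)) / sum(w)
  eig <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2, 2), symmetric = TRUE)
  s_long0 <- sqrt(max(eig$values[1], pixel_size_nm^2))
  s_short0 <- sqrt(max(eig$values[2], pixel_size_nm^2 / 4))
  th0 <- atan2(eig$vectors[2, 1], eig$vectors[1, 1]) %% pi
  amp0 <- max(zv) - off0

  model <- function(p) {
    ct <- cos(p[5]); st <- sin(p[5])
    u <- (X - p[2]) * ct + (Y - p[3]) * st
    v <- -(X - p[2]) * st + (Y - p[3]) * ct
    p[6] + p[1] * exp(-(u^2 / (2 * p[4]^2) + v^2 / (2 * exp(p[7])^2)))
  }
  # p = (A, x0, y0, s_long, theta, offset, log(s_short))
  p0 <- c(amp0, mx, my, s_long0, th0, off0, log(s_short0))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) zv - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5)) return(NULL)
  p <- fit$par
  s_long <- abs(p[4]); s_short <- exp(p[7])
  theta <- p[5] %% pi
  if (s_short > s_long) {   # enforce sigma_long >= sigma_short
    tmp <- s_long; s_long <- s_short; s_short <- tmp
    theta <- (theta + pi / 2) %% pi
  }
  data.frame(x_nm = p[2], y_nm = p[3],
             sigma_long_nm = s_long, sigma_short_nm = s_short,
             orientation = theta, amplitude = p[1], offset = p[6],
             length_nm = 2.3 * s_long, converged = TRUE)
}

#' Detect and fit spots in a STED image
#'
#' Runs [atrous_detect()] and fits each candidate with
#' [fit_anisotropic_gaussian()], discarding failed fits.
#'
#' @inheritParams atrous_detect
#' @inheritParams fit_anisotropic_gaussian
#' @return data frame of fitted spots (see [fit_anisotropic_gaussian()]).
#' @export
detect_sted_spots <- function(image, levels = 3L, threshold_factor = 3,
                              detection_level = 2L, window_px = 15L,
                              pixel_size_nm = 20) {
  cand <- atrous_detect(image, levels, threshold_factor, detection_level)
  fits <- lapply(seq_len(nrow(cand)), function(k)
    fit_anisotropic_gaussian(image, cand$row[k], cand$col[k],
                             window_px, pixel_size_nm))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      sigma_long_nm = numeric(0), sigma_short_nm = numeric(0),
                      orientation = numeric(0), amplitude = numeric(0),
                      offset = numeric(0), length_nm = numeric(0),
                      converged = logical(0)))
  do.call(rbind, fits)
}

#' Filter fitted spots to synapse candidates
#'
#' Keeps spots whose fitted amplitude exceeds `intensity_min` (strict) and
#' whose Gaussian standard deviation lies within `sigma_range_nm`
#' (inclusive). Because the fit is anisotropic while the filter specifies a
#' single sigma, the rotation-invariant geometric mean of the long and
#' short sigmas is used for the range test.
#'
#' @param spots data frame of fitted spots.
#' @param intensity_min amplitude threshold (ADU, strict >).
#' @param sigma_range_nm inclusive `c(min, max)` for the combined sigma.
#' @return the filtered data frame.
#' @export
filter_synapse_candidates <- function(spots, intensity_min = 200,
                                      sigma_range_nm = c(80, 800)) {
  if (nrow(spots) == 0L) return(spots)
  sig <- sqrt(spots$sigma_long_nm * spots$sigma_short_nm)
  spots[spots$amplitude > intensity_min &
          sig >= sigma_range_nm[1] & sig <= sigma_range_nm[2], , drop = FALSE]
}

#' Classify aggregates as presynaptic by proximity to synapses
#'
#' An aggregate is presynaptic when the centroid-to-centroid Euclidean
#' distance to its nearest pre-synapse is less than or equal to the
#' distance threshold. With no synapses, no aggregate is presynaptic.
#'
#' @param aggregates,synapses data frames with `x_nm`, `y_nm` centroids.
#' @param threshold_nm inclusive distance threshold (nm).
#' @return list with `aggregates` (input plus `presynaptic` and
#'   `nearest_synapse_nm`), `presynaptic_fraction` and
#'   `synapse_occupied_fraction` (fraction of synapses with at least one
#'   presynaptic aggregate within the threshold).
#' @export
classify_presynaptic <- function(aggregates, synapses, threshold_nm = 90) {
  n <- nrow(aggregates)
  if (n == 0L)
    return(list(aggregates = cbind(aggregates,
                                   presynaptic = logical(0),
                                   nearest_synapse_nm = numeric(0)),
                presynaptic_fraction = NA_real_,
                synapse_occupied_fraction = if (nrow(synapses)) 0 else NA_real_))
  if (nrow(synapses) == 0L) {
    aggregates$presynaptic <- FALSE
    aggregates$nearest_synapse_nm <- NA_real_
    return(list(aggregates = aggregates, presynaptic_fraction = 0,
                synapse_occupied_fraction = NA_real_))
  }
  d2 <- outer(aggregates$x_nm, synapses$x_nm, `-`)^2 +
    outer(aggregates$y_nm, synapses$y_nm, `-`)^2
  d <- sqrt(d2)
  nearest <- apply(d, 1, min)
  aggregates$presynaptic <- nearest <= threshold_nm
  aggregates$nearest_synapse_nm <- nearest
  occupied <- apply(d <= threshold_nm, 2, any)
  list(aggregates = aggregates,
       presynaptic_fraction = mean(aggregates$presynaptic),
       synapse_occupied_fraction = mean(occupied))
}
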