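#' 2D affine transform
#'
#' Constructor for an affine transform `x' = A x + t` in nm coordinates,
#' used to correct aberration-induced misalignment between imaging
#' channels.
#'
#' @param linear 2x2 matrix, must have nonzero determinant.
#' @param offset length-2 translation (nm).
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(2), offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < .Machine$double.eps)
    stop("linear part of the affine transform must be invertible")
  structure(list(linear = linear, offset = as.numeric(offset)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("2D affine transform\n  linear:\n")
  print(x$linear)
  cat(sprintf("  offset: (%.4f, %.4f) nm\n", x$offset[1], x$offset[2]))
  invisible(x)
}

#' Invert an affine transform
#'
#' @param t an `affine_transform`.
#' @return the inverse `affine_transform`.
#' @export
invert_affine <- function(t) {
  ainv <- solve(t$linear)
  affine_transform(ainv, -ainv %*% t$offset)
}

#' Fit an affine transform from matched bead coordinates
#'
#' Least-squares estimate of the affine transform mapping `reference` onto
#' `moving`, as used for bead-based channel registration (the same beads
#' imaged in both channels give matched pairs; no correspondence search is
#' performed). The fit solves the normal equations of the linear model
#' `moving ~ 1 + reference_x + reference_y` per output coordinate.
#'
#' @param reference,moving matrices with columns x, y (nm); same row count,
#'   at least 3 non-collinear pairs.
#' @return object of class `affine_fit`: the `affine_transform` plus
#'   per-bead `residuals` and `residual_rms` (nm).
#' @export
fit_affine_from_beads <- function(reference, moving) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (nrow(reference) != nrow(moving))
    stop("`reference` and `moving` must have the same number of beads")
  if (nrow(reference) < 3)
    stop("at least 3 bead pairs are required for an affine fit")
  X <- cbind(1, reference)
  if (qr(X)$rank < 3L)
    stop("bead configuration is collinear; affine fit is degenerate")
  coef <- qr.solve(X, moving)          # 3x2: (intercept, x, y) per output
  t <- affine_transform(t(coef[2:3, ]), coef[1, ])
  fitted <- X %*% coef
  res <- moving - fitted
  structure(list(transform = t, residuals = res,
                 residual_rms = sqrt(mean(res^2))),
            class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  print(x$transform)
  cat(sprintf("  residual RMS: %.4f nm (%d beads)\n",
              x$residual_rms, nrow(x$residuals)))
  invisible(x)
}

#' Apply an affine transform to points or an image
#'
#' Points are mapped exactly; images are resampled by bilinear
#' interpolation (the output pixel at centre `c` takes the input value at
#' `T^{-1}(c)`, pixels mapping outside the input get 0).
#'
#' @param t an `affine_transform` or `affine_fit`.
#' @param x a two-column matrix / data frame of nm coordinates, or a
#'   numeric image matrix (rows = y, cols = x).
#' @param pixel_size_nm pixel size, required when `x` is an image.
#' @return transformed points (same shape as input) or resampled image.
#' @export
apply_affine <- function(t, x, pixel_size_nm = NULL) {
  if (inherits(t, "affine_fit")) t <- t$transform
  if (!inherits(t, "affine_transform")) stop("`t` must be an affine transform")
  if (is.matrix(x) && !is.null(pixel_size_nm)) {
    return(warp_image_affine(t, x, pixel_size_nm))
  }
  pts <- as.matrix(x)[, 1:2, drop = FALSE]
  out <- pts %*% t(t$linear) +
    matrix(t$offset, nrow(pts), 2, byrow = TRUE)
  if (is.data.frame(x)) { x[[1]] <- out[, 1]; x[[2]] <- out[, 2]; x } else {
    colnames(out) <- colnames(pts); out
  }
}

warp_image_affine <- function(t, img, pixel_size_nm) {
  nr <- nrow(img); nc <- ncol(img)
  inv <- invert_affine(t)
  # output pixel centres in nm
  cx <- (seq_len(nc) - 0.5) * pixel_size_nm
  cy <- (seq_len(nr) - 0.5) * pixel_size_nm
  gx <- rep(cx, each = nr); gy <- rep(cy, nc)
  src <- cbind(gx, gy) %*% t(inv$linear) +
    matrix(inv$offset, nr * nc, 2, byrow = TRUE)
  # to fractional pixel indices (centre of pixel (i,j) is at ((j-.5)p,(i-.5)p))
  fj <- src[, 1] / pixel_size_nm + 0.5
  fi <- src[, 2] / pixel_size_nm + 0.5
  j0 <- floor(fj); i0 <- floor(fi)
  wj <- fj - j0; wi <- fi - i0
  val <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    v <- numeric(length(i))
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  out <- (1 - wi) * (1 - wj) * val(i0, j0) +
    (1 - wi) * wj * val(i0, j0 + 1) +
    wi * (1 - wj) * val(i0 + 1, j0) +
    wi * wj * val(i0 + 1, j0 + 1)
  matrix(out, nr, nc)
}
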