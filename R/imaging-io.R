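#' Read a localisation table (ThunderSTORM CSV dialect)
#'
#' Reads a CSV with header `frame,x [nm],y [nm],sigma [nm],intensity [photon]`
#' (bracketed units optional) into a validated localisation table. Rows that
#' violate the invariants (non-finite or negative coordinates, non-positive
#' precision, frame < 1) are rejected with their line numbers.
#'
#' @param path path to the CSV file.
#' @return data frame with columns `frame`, `x`, `y`, `sigma`, `intensity`
#'   (coordinates in nm), of class `localisation_table`.
#' @export
read_localisations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  names(df) <- sub("\\s*\\[.*\\]\\s*$", "", trimws(names(df)))
  required <- c("frame", "x", "y", "sigma", "intensity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad_parse <- Reduce(`|`, lapply(num, function(v) is.na(v) & TRUE))
  # distinguish empty file (header only) from malformed rows
  if (nrow(df) == 0L) {
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      sigma = numeric(0), intensity = numeric(0))
    class(out) <- c("localisation_table", "data.frame")
    return(out)
  }
  if (any(bad_parse))
    stop("non-numeric value(s) at data line(s): ",
         paste(which(bad_parse), collapse = ", "))
  out <- data.frame(frame = as.integer(num$frame), x = num$x, y = num$y,
                    sigma = num$sigma, intensity = num$intensity)
  bad <- !is.finite(out$x) | !is.finite(out$y) | out$x < 0 | out$y < 0 |
    out$sigma <= 0 | out$frame < 1
  if (any(bad))
    stop("invalid localisation(s) at data line(s): ",
         paste(which(bad), collapse = ", "))
  class(out) <- c("localisation_table", "data.frame")
  out
}

#' Write a localisation table in the ThunderSTORM CSV dialect
#'
#' @param table data frame with columns `frame`, `x`, `y`, `sigma`,
#'   `intensity` (extra columns are dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localisations <- function(table, path) {
  out <- table[c("frame", "x", "y", "sigma", "intensity")]
  # %.17g keeps the round trip lossless for doubles
  fmt <- function(v) if (is.double(v)) sprintf("%.17g", v) else as.character(v)
  out <- data.frame(lapply(out, fmt))
  names(out) <- c("frame", "x [nm]", "y [nm]", "sigma [nm]",
                  "intensity [photon]")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a greyscale TIFF image
#'
#' Reads a single-plane or multi-plane greyscale TIFF as a numeric matrix
#' in raw integer counts (8-bit: 0-255, 16-bit: 0-65535). Multi-plane
#' stacks are either averaged into a single frame or returned as a list.
#'
#' @param path path to the TIFF file.
#' @param average_stack logical; average a multi-plane stack into one image?
#' @return numeric matrix (rows = y, cols = x), or a list of matrices when
#'   `average_stack = FALSE` and the file holds a stack.
#' @export
read_image <- function(path, average_stack = TRUE) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
  if (length(planes) == 1L) return(planes[[1]])
  if (average_stack) Reduce(`+`, planes) / length(planes) else planes
}

#' Write a matrix as a 16-bit greyscale TIFF
#'
#' @param image numeric matrix of counts in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image16 <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Render a super-resolved image from localisations
#'
#' Superimposes one unit-mass isotropic Gaussian (sigma = `precision_nm`)
#' per localisation on a pixel grid. The Gaussian mass per pixel is
#' computed by exact integration of the normal density over the pixel
#' (separable in x and y), truncated at 4 sigma, so the image total equals
#' the number of localisations to better than 1e-3 per localisation and
#' rendering is exactly additive over subsets of the table.
#'
#' Pixel `(i, j)` (row i = y, column j = x, 1-based) covers the half-open
#' square `[(j-1) p, j p) x [(i-1) p, i p)` with `p = pixel_size_nm`.
#'
#' @param table localisation table with `x`, `y` in nm.
#' @param precision_nm rendering Gaussian sigma (nm).
#' @param pixel_size_nm rendering pixel size (nm).
#' @param fov_size_nm optional `c(width, height)`; defaults to the bounding
#'   box of the localisations.
#' @return numeric matrix (rows = y, cols = x).
#' @export
render_superres <- function(table, precision_nm = 20, pixel_size_nm = 10,
                            fov_size_nm = NULL) {
  if (pixel_size_nm <= 0) stop("`pixel_size_nm` must be positive")
  if (is.null(fov_size_nm)) {
    fov_size_nm <- if (nrow(table) == 0L) c(pixel_size_nm, pixel_size_nm) else
      c(max(table$x) + 4 * precision_nm, max(table$y) + 4 * precision_nm)
  }
  nc <- max(1L, ceiling(fov_size_nm[1] / pixel_size_nm))
  nr <- max(1L, ceiling(fov_size_nm[2] / pixel_size_nm))
  img <- matrix(0, nr, nc)
  if (nrow(table) == 0L) return(img)
  half <- 4 * precision_nm
  xb <- (0:nc) * pixel_size_nm
  yb <- (0:nr) * pixel_size_nm
  for (k in seq_len(nrow(table))) {
    x <- table$x[k]; y <- table$y[k]
    j0 <- max(1L, floor((x - half) / pixel_size_nm) + 1L)
    j1 <- min(nc, floor((x + half) / pixel_size_nm) + 1L)
    i0 <- max(1L, floor((y - half) / pixel_size_nm) + 1L)
    i1 <- min(nr, floor((y + half) / pixel_size_nm) + 1L)
    if (j0 > j1 || i0 > i1) next
    px <- diff(stats::pnorm(xb[j0:(j1 + 1L)], x, precision_nm))
    py <- diff(stats::pnorm(yb[i0:(i1 + 1L)], y, precision_nm))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + py %o% px
  }
  img
}
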