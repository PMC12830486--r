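# grid-accelerated fixed-radius neighbour search: returns a list of
# neighbour index vectors (excluding the point itself). Points are binned
# into eps-sized cells; candidates come from the 3x3 cell neighbourhood.
eps_neighbours <- function(x, y, eps) {
  n <- length(x)
  cxi <- floor(x / eps); cyi <- floor(y / eps)
  span <- max(cyi) - min(cyi) + 3
  key <- (cxi - min(cxi)) * span + (cyi - min(cyi))
  ukey <- sort(unique(key))
  cell_id <- match(key, ukey)
  cell_of <- split(seq_len(n), cell_id)
  # per point, ids of the 9 surrounding cells (NA when the cell is empty)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  ncell <- matrix(NA_integer_, n, 9)
  for (k in 1:9)
    ncell[, k] <- match(key + offs[k, 1] * span + offs[k, 2], ukey)
  nb <- vector("list", n)
  eps2 <- eps^2
  for (i in seq_len(n)) {
    cand <- unlist(cell_of[ncell[i, !is.na(ncell[i, ])]], use.names = FALSE)
    cand <- cand[cand != i]
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    nb[[i]] <- cand[d2 <= eps2]
  }
  nb
}

#' Cluster localisations into aggregates with DBSCAN
#'
#' Density-based clustering (DBSCAN) of super-resolution localisations with
#' the point-counting convention in which a point's own membership counts
#' towards `min_points`; with the defaults (eps 75 nm, 2 points) any
#' localisation with at least one neighbour within 75 nm is a core point,
#' so clusters are exactly the connected components of the 75 nm
#' neighbourhood graph and every isolated localisation is noise.
#' Border points (non-core points within eps of a core point) are assigned
#' to the cluster of their nearest core point, ties broken by lower cluster
#' id. Cluster ids are canonical: clusters are numbered by the
#' lexicographically smallest (x, y) member coordinate, making the result
#' invariant under permutation of the input rows.
#'
#' @param table localisation table (or any data frame with `x`, `y` in nm).
#' @param eps_nm neighbourhood radius (nm).
#' @param min_points minimum neighbourhood size (including the point
#'   itself) for a core point.
#' @return list with `cluster` (integer vector, 0 = noise) and `clusters`
#'   (list of member index vectors, one per cluster id).
#' @export
cluster_localisations <- function(table, eps_nm = 75, min_points = 2L) {
  if (eps_nm <= 0) stop("`eps_nm` must be positive")
  if (min_points < 1) stop("`min_points` must be at least 1")
  n <- nrow(table)
  if (n == 0L) return(list(cluster = integer(0), clusters = list()))
  x <- table$x; y <- table$y
  nb <- eps_neighbours(x, y, eps_nm)
  core <- vapply(nb, length, integer(1)) + 1L >= min_points
  lab <- integer(n)  # 0 = noise/unassigned

  # connected components of core points under the eps-graph (union-find
  # with path halving)
  parent <- seq_len(n)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(core)) {
    for (j in nb[[i]]) {
      if (core[j]) {
        ri <- uf_find(i); rj <- uf_find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(which(core), uf_find, integer(1))
  comp <- match(roots, unique(roots))
  lab[core] <- comp

  # border points: nearest core neighbour's cluster, ties -> lower id
  for (i in which(!core)) {
    cand <- nb[[i]][core[nb[[i]]]]
    if (length(cand) == 0L) next
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    best <- d2 == min(d2)
    lab[i] <- min(lab[cand[best]])
  }

  # canonical ids: order clusters by lexicographic min member coordinate
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    keys <- t(vapply(ids, function(k) {
      m <- lab == k
      mx <- min(x[m])
      c(mx, min(y[m][x[m] == mx]))
    }, numeric(2)))
    ord <- order(keys[, 1], keys[, 2])
    remap <- integer(max(ids))
    remap[ids[ord]] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  clusters <- split(seq_len(n), factor(lab, levels = seq_len(max(lab, 0))))
  list(cluster = lab, clusters = unname(clusters))
}

#' Measure the morphology of a localisation cluster
#'
#' Principal-component morphometry of a cluster's member coordinates:
#' the centroid is the coordinate mean; principal axes come from the
#' eigen-decomposition of the member-coordinate covariance; the length is
#' the full extent (max minus min) of the member projections onto the
#' major axis; the eccentricity is
#' `sqrt(1 - lambda_minor / lambda_major)` with `lambda` the covariance
#' eigenvalues, so 0 describes a perfect circle and 1 a flat line
#' (defined as 0 for a degenerate cluster with `lambda_major` = 0).
#'
#' @param coords two-column matrix or data frame of member coordinates (nm),
#'   at least 2 points.
#' @return list with `centroid` (nm), `length_nm`, `eccentricity`.
#' @export
measure_cluster <- function(coords) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (nrow(coords) < 2L) stop("a cluster needs at least 2 localisations")
  centroid <- colMeans(coords)
  cc <- sweep(coords, 2, centroid)
  cv <- crossprod(cc) / (nrow(coords) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  major <- eig$vectors[, 1]
  proj <- cc %*% major
  len <- max(proj) - min(proj)
  ecc <- if (lam[1] <= 0) 0 else sqrt(max(0, 1 - lam[2] / lam[1]))
  list(centroid = unname(centroid), length_nm = as.numeric(len),
       eccentricity = ecc)
}

#' Convert an aggregate length in nm to a monomer count
#'
#' Uses the double-stranded aggregate geometry (0.5 nm beta-sheet spacing,
#' two strands), i.e. 4 monomers per nm by default; the result is rounded
#' half-up to an integer.
#'
#' @param length_nm non-negative length(s) in nm.
#' @param factor monomers per nm.
#' @return integer monomer count(s).
#' @export
length_to_monomers <- function(length_nm, factor = 4) {
  if (any(length_nm < 0, na.rm = TRUE)) stop("lengths must be non-negative")
  as.integer(floor(factor * length_nm + 0.5))
}

#' Classify an aggregate as fibril-like
#'
#' An aggregate is fibril-like when it is both long and elongated:
#' length strictly above `length_threshold` and eccentricity strictly
#' above `ecc_threshold`.
#'
#' @param length_nm length(s) in nm.
#' @param eccentricity eccentricity value(s) in `[0, 1]`.
#' @param length_threshold length cut-off (nm).
#' @param ecc_threshold eccentricity cut-off.
#' @return logical vector.
#' @export
classify_fibril_like <- function(length_nm, eccentricity,
                                 length_threshold = 150, ecc_threshold = 0.9) {
  if (any(eccentricity < 0 | eccentricity > 1, na.rm = TRUE))
    stop("eccentricity must lie in [0, 1]")
  length_nm > length_threshold & eccentricity > ecc_threshold
}

#' Detect and measure aggregates in a localisation table
#'
#' Convenience wrapper running [cluster_localisations()] and
#' [measure_cluster()] over a whole field of view and assembling the
#' per-aggregate table (centroid, length, eccentricity, monomer count,
#' fibril-like flag). Compartment labels default to `"unassigned"` until
#' [assign_aggregates()] is run against segmented synaptosome regions.
#'
#' @param table localisation table.
#' @param eps_nm,min_points DBSCAN parameters, see [cluster_localisations()].
#' @param conversion_factor monomers per nm for [length_to_monomers()].
#' @param length_threshold,ecc_threshold fibril-like thresholds.
#' @return data frame with one row per aggregate: `cluster_id`,
#'   `centroid_x_nm`, `centroid_y_nm`, `n_locs`, `length_nm`,
#'   `eccentricity`, `monomers`, `compartment`, `fibril_like`; the cluster
#'   membership is attached as attribute `"members"`.
#' @export
detect_aggregates <- function(table, eps_nm = 75, min_points = 2L,
                              conversion_factor = 4,
                              length_threshold = 150, ecc_threshold = 0.9) {
  cl <- cluster_localisations(table, eps_nm, min_points)
  k <- length(cl$clusters)
  if (k == 0L) {
    out <- data.frame(cluster_id = integer(0), centroid_x_nm = numeric(0),
                      centroid_y_nm = numeric(0), n_locs = integer(0),
                      length_nm = numeric(0), eccentricity = numeric(0),
                      monomers = integer(0), compartment = character(0),
                      fibril_like = logical(0))
    attr(out, "members") <- list()
    return(out)
  }
  meas <- lapply(cl$clusters, function(idx)
    measure_cluster(cbind(table$x[idx], table$y[idx])))
  len <- vapply(meas, `[[`, numeric(1), "length_nm")
  ecc <- vapply(meas, `[[`, numeric(1), "eccentricity")
  cen <- t(vapply(meas, `[[`, numeric(2), "centroid"))
  out <- data.frame(
    cluster_id = seq_len(k),
    centroid_x_nm = cen[, 1], centroid_y_nm = cen[, 2],
    n_locs = vapply(cl$clusters, length, integer(1)),
    length_nm = len, eccentricity = ecc,
    monomers = length_to_monomers(len, conversion_factor),
    compartment = "unassigned",
    fibril_like = classify_fibril_like(len, ecc, length_threshold, ecc_threshold)
  )
  attr(out, "members") <- cl$clusters
  out
}
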