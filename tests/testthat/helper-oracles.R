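# Independent oracles used to cross-check the package implementation.
# These deliberately use naive algorithms or third-party code so that they
# share no code path with the functions under test.

# O(n^2) connected components of the eps-neighbourhood graph, via igraph;
# isolated points get component label 0. Returns membership sets (as a
# canonical list of sorted index vectors, ordered by smallest member).
oracle_eps_components <- function(x, y, eps) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d <= eps & upper.tri(d)
  edges <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= 2])
  sets <- lapply(keep, function(k) sort(which(comp == k)))
  sets[order(vapply(sets, min, numeric(1)))]
}

# canonicalise cluster membership from cluster_localisations() output
membership_sets <- function(clusters) {
  sets <- lapply(clusters, sort)
  sets[order(vapply(sets, min, numeric(1)))]
}

# brute-force nearest-neighbour distances, explicit double loop
oracle_nnd <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# brute-force point-in-mask assignment (per-point scan over region pixels)
oracle_mask_assignment <- function(localisations, labels, pixel_size_nm) {
  vapply(seq_len(nrow(localisations)), function(k) {
    j <- floor(localisations$x[k] / pixel_size_nm) + 1
    i <- floor(localisations$y[k] / pixel_size_nm) + 1
    if (i < 1 || i > nrow(labels) || j < 1 || j > ncol(labels)) return(0L)
    labels[i, j]
  }, integer(1))
}

# Beta-Bernoulli marginal likelihood of (n, N) by numerical integration of
# the ordered-sequence likelihood f^n (1-f)^(N-n) over f in (0, 1) with a
# uniform prior, midpoint rule
oracle_beta_marginal <- function(n, N, n_grid = 1e5) {
  f <- (seq_len(n_grid) - 0.5) / n_grid
  mean(exp(n * log(f) + (N - n) * log1p(-f)))
}

# truncated geometric pmf by direct normalisation over the support
# (independent of the closed-form log-space route in the package)
oracle_truncgeom_pmf <- function(alpha, n_min, n_max) {
  # powers relative to n_min so small alpha does not underflow the ratio
  w <- alpha^(0:(n_max - n_min))
  w / sum(w)
}

# chi-square goodness of fit of sampled monomer counts against a pmf on
# the full support, merging right-tail bins until expected counts >= 5
gof_pvalue <- function(m, support, pmf) {
  obs <- tabulate(m - support[1] + 1L, nbins = length(support))
  expd <- pmf * length(m)
  # merge adjacent low-expectation bins from the right
  while (length(expd) > 2 && expd[length(expd)] < 5) {
    k <- length(expd)
    expd[k - 1] <- expd[k - 1] + expd[k]; expd <- expd[-k]
    obs[k - 1] <- obs[k - 1] + obs[k]; obs <- obs[-k]
  }
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = length(expd) - 1, lower.tail = FALSE)
}

# synthetic disc image: constant background plus filled discs of the given
# amplitude (no noise unless sigma > 0)
disc_image <- function(nr, nc, centres, radius_px, background = 100,
                       amplitude = 200, noise_sd = 0) {
  img <- matrix(background, nr, nc)
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= radius_px^2)
        img[i, j] <- background + amplitude
    }
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  img
}

# synthetic STED-like image: anisotropic Gaussian spots on a flat offset
# with Gaussian readout noise; coordinates in nm, pixel grid 20 nm
sted_image <- function(nr, nc, spots, pixel_size_nm = 20, offset = 10,
                       noise_sd = 2) {
  xs <- (seq_len(nc) - 0.5) * pixel_size_nm
  ys <- (seq_len(nr) - 0.5) * pixel_size_nm
  img <- matrix(offset, nr, nc)
  for (k in seq_len(nrow(spots))) {
    th <- spots$theta[k]
    dx <- outer(rep(1, nr), xs - spots$x[k])
    dy <- outer(ys - spots$y[k], rep(1, nc))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    img <- img + spots$amp[k] *
      exp(-(u^2 / (2 * spots$sl[k]^2) + v^2 / (2 * spots$ss[k]^2)))
  }
  img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
}
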