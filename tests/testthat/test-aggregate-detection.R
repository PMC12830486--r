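test_that("DBSCAN handles the canonical pair and isolation cases", {
  pair <- data.frame(x = c(0, 0), y = c(0, 50))
  res <- cluster_localisations(pair, eps_nm = 75, min_points = 2)
  expect_equal(res$cluster, c(1L, 1L))

  apart <- data.frame(x = c(0, 0), y = c(0, 200))
  res2 <- cluster_localisations(apart, eps_nm = 75, min_points = 2)
  expect_equal(res2$cluster, c(0L, 0L))

  empty <- data.frame(x = numeric(0), y = numeric(0))
  expect_length(cluster_localisations(empty)$clusters, 0L)
  expect_error(cluster_localisations(pair, eps_nm = 0), "eps_nm")
})

test_that("DBSCAN with min_points = 2 equals eps-graph connected components", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    tab <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
    res <- cluster_localisations(tab, eps_nm = 75, min_points = 2)
    expect_identical(membership_sets(res$clusters),
                     oracle_eps_components(tab$x, tab$y, 75))
  }
})

test_that("cluster membership is invariant under input permutation", {
  set.seed(24)
  tab <- data.frame(x = runif(80, 0, 800), y = runif(80, 0, 800))
  res <- cluster_localisations(tab)
  perm <- sample(80)
  res_p <- cluster_localisations(tab[perm, ])
  # map permuted memberships back to original indices
  sets_p <- lapply(res_p$clusters, function(idx) sort(perm[idx]))
  sets_p <- sets_p[order(vapply(sets_p, min, numeric(1)))]
  expect_identical(membership_sets(res$clusters), sets_p)
  # canonical ids are assigned in the same order too
  expect_identical(res$cluster, res_p$cluster[order(perm)])
})

test_that("border points go to the nearest core point's cluster", {
  # two dense runs of five points with a sparse point in between: with
  # minPts = 5 the middle point at 76 has only 3 neighbours (40, 105, 115),
  # so it is a border point of both clusters; its nearest core is at 105
  tab <- data.frame(x = c(0, 10, 20, 30, 40, 105, 115, 125, 135, 145, 76),
                    y = rep(0, 11))
  res <- cluster_localisations(tab, eps_nm = 45, min_points = 5)
  expect_equal(length(res$clusters), 2L)
  expect_equal(res$cluster[11], res$cluster[6])
  expect_false(res$cluster[11] == res$cluster[1])
})

test_that("cluster morphometry matches closed forms", {
  m <- measure_cluster(rbind(c(0, 0), c(100, 0)))
  expect_equal(m$length_nm, 100)
  expect_equal(m$eccentricity, 1)
  expect_equal(m$centroid, c(50, 0))

  sq <- rbind(c(-50, -50), c(-50, 50), c(50, -50), c(50, 50))
  expect_equal(measure_cluster(sq)$eccentricity, 0)

  expect_error(measure_cluster(rbind(c(1, 1))), "at least 2")
})

test_that("eccentricity of a 2:1 anisotropic Gaussian cloud is sqrt(3)/2", {
  set.seed(25)
  for (rep in 1:5) {
    th <- runif(1, 0, pi)
    u <- rnorm(1000, 0, 60); v <- rnorm(1000, 0, 30)
    pts <- cbind(u * cos(th) - v * sin(th), u * sin(th) + v * cos(th))
    m <- measure_cluster(pts)
    expect_lt(abs(m$eccentricity - sqrt(1 - 1 / 4)), 0.05)
  }
})

test_that("morphometry is invariant under rotation and uniform scaling", {
  set.seed(26)
  pts <- cbind(rnorm(200, 0, 50), rnorm(200, 0, 20))
  base <- measure_cluster(pts)
  phi <- 1.1
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rot <- measure_cluster(pts %*% t(R))
  expect_equal(rot$eccentricity, base$eccentricity, tolerance = 1e-9)
  expect_equal(rot$length_nm, base$length_nm, tolerance = 1e-9)
  scl <- measure_cluster(3 * pts)
  expect_equal(scl$eccentricity, base$eccentricity, tolerance = 1e-9)
  expect_equal(scl$length_nm, 3 * base$length_nm, tolerance = 1e-9)
})

test_that("length never decreases when a point extends the major axis", {
  set.seed(27)
  pts <- cbind(rnorm(50, 0, 50), rnorm(50, 0, 10))
  len0 <- measure_cluster(pts)$length_nm
  ext <- rbind(pts, c(max(pts[, 1]) + 100, 0))
  expect_gte(measure_cluster(ext)$length_nm, len0)
})

test_that("nm-to-monomer conversion uses 4 per nm with round-half-up", {
  expect_equal(length_to_monomers(125), 500L)
  expect_equal(length_to_monomers(300), 1200L)
  expect_equal(length_to_monomers(0), 0L)
  expect_equal(length_to_monomers(100.125), 401L)  # 400.5 rounds up
  expect_error(length_to_monomers(-1), "non-negative")
})

test_that("fibril-like classification uses strict thresholds", {
  expect_true(classify_fibril_like(160, 0.95))
  expect_false(classify_fibril_like(150, 0.95))
  expect_false(classify_fibril_like(200, 0.5))
  expect_false(classify_fibril_like(200, 0.9))
  expect_error(classify_fibril_like(100, 1.2), "eccentricity")
})

test_that("detect_aggregates assembles a consistent per-aggregate table", {
  set.seed(28)
  spec <- scene_spec(n_synaptosomes = 15, seed = 29,
                     background_density = 0)
  scene <- generate_localisation_scene(spec)
  agg <- detect_aggregates(scene$localisations)
  expect_true(all(agg$n_locs >= 2))
  expect_equal(agg$monomers, length_to_monomers(agg$length_nm))
  expect_equal(agg$fibril_like,
               classify_fibril_like(agg$length_nm, agg$eccentricity))
  members <- attr(agg, "members")
  expect_equal(vapply(members, length, integer(1)), agg$n_locs)
})
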