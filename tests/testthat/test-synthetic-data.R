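test_that("length sampling is empty at count 0, deterministic, and unbiased", {
  expect_equal(nrow(generate_length_sample(0.995, count = 0)), 0L)

  a <- generate_length_sample(0.995, count = 500, seed = 7)
  b <- generate_length_sample(0.995, count = 500, seed = 7)
  expect_identical(a, b)

  s <- generate_length_sample(0.995, count = 1e5, seed = 8)
  expect_true(all(s$monomers >= 500 & s$monomers <= 1200))
  expect_equal(s$length_nm, s$monomers / 4)
  pmf <- dtruncgeom(500:1200, 0.995)
  mu <- sum((500:1200) * pmf)
  sdv <- sqrt(sum(((500:1200) - mu)^2 * pmf))
  expect_lt(abs(mean(s$monomers) - mu), 3 * sdv / sqrt(1e5))
})

test_that("length samples pass a chi-square goodness-of-fit against the pmf", {
  pmf <- dtruncgeom(500:1200, 0.995)
  pvals <- vapply(1:20, function(seed) {
    s <- generate_length_sample(0.995, count = 1e5, seed = 1000 + seed)
    gof_pvalue(s$monomers, 500:1200, pmf)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 19L)
})

test_that("scene generation is deterministic and respects the field bounds", {
  spec <- scene_spec(n_synaptosomes = 20, fov_size_nm = c(20000, 15000),
                     extra_synaptic_aggregate_count = 5, seed = 9)
  s1 <- generate_localisation_scene(spec)
  s2 <- generate_localisation_scene(spec)
  expect_identical(s1$localisations, s2$localisations)
  expect_identical(s1$membrane_image, s2$membrane_image)
  expect_identical(s1$ground_truth, s2$ground_truth)

  loc <- s1$localisations
  expect_true(all(loc$x >= 0 & loc$x <= 20000))
  expect_true(all(loc$y >= 0 & loc$y <= 15000))
  # traceability: every localisation maps to background or one aggregate
  expect_true(all(loc$source_id %in%
                    c(0L, s1$ground_truth$aggregates$id)))
  # synaptic aggregate centroids lie inside their parent disc
  agg <- s1$ground_truth$aggregates
  syn <- agg[agg$compartment == "synaptic", ]
  par <- s1$ground_truth$synaptosomes[syn$synaptosome_id, ]
  d <- sqrt((syn$centroid_x_nm - par$centre_x_nm)^2 +
              (syn$centroid_y_nm - par$centre_y_nm)^2)
  expect_true(all(d <= par$radius_nm))
})

test_that("an empty scene yields an empty localisation table", {
  spec <- scene_spec(n_synaptosomes = 0, background_density = 0,
                     extra_synaptic_aggregate_count = 0, seed = 1)
  s <- generate_localisation_scene(spec)
  expect_equal(nrow(s$localisations), 0L)
  expect_equal(nrow(s$ground_truth$synaptosomes), 0L)
})

test_that("scene spec validation rejects out-of-domain parameters", {
  expect_error(scene_spec(occupancy_fraction = 1.5), "occupancy_fraction")
  expect_error(scene_spec(fov_size_nm = c(-1, 100)), "fov_size_nm")
  expect_error(scene_spec(pixel_size_nm = 0), "pixel_size_nm")
  expect_error(scene_spec(background_density = -1), "background_density")
})

test_that("planted eccentricity is recovered by cluster morphometry", {
  set.seed(13)
  # elongated clouds: every single draw within +/- 0.05 of planted
  for (ecc in c(0.7, 0.9, 0.95)) {
    for (rep in 1:5) {
      pts <- synaptau:::sample_aggregate_cloud(2000, 0, 0, 200, ecc,
                                               runif(1, 0, pi))
      m <- measure_cluster(pts)
      expect_lt(abs(m$eccentricity - ecc), 0.05)
    }
  }
  # near-circular clouds: the estimator is unbiased but noisy (the
  # eigenvalue ratio fluctuates most when the axes are nearly equal), so
  # the +/- 0.05 recovery holds for the mean over replicates
  for (ecc in c(0.3, 0.5)) {
    m <- replicate(20, measure_cluster(
      synaptau:::sample_aggregate_cloud(2000, 0, 0, 200, ecc,
                                        runif(1, 0, pi)))$eccentricity)
    expect_lt(abs(mean(m) - ecc), 0.05)
  }
})

test_that("planted length is recovered as the major-axis extent", {
  set.seed(14)
  for (len in c(150, 250)) {
    pts <- synaptau:::sample_aggregate_cloud(5000, 0, 0, len, 0.9, 0.7)
    m <- measure_cluster(pts)
    expect_lt(abs(m$length_nm - len) / len, 0.03)
  }
})

test_that("bead pairs honour the planted transform, noise and seed", {
  ident <- cbind(diag(2), c(0, 0))
  bp <- generate_bead_pair(ident, 10, noise_sigma_nm = 0, seed = 3)
  expect_equal(bp$moving, bp$reference)

  bp2 <- generate_bead_pair(ident, 10, noise_sigma_nm = 0, seed = 3)
  expect_identical(bp, bp2)

  expect_error(generate_bead_pair(ident, 2), "at least 3")
  expect_error(generate_bead_pair(diag(2), 5), "2x3")
})

test_that("co-occurrence tables reproduce planted frequencies", {
  # degenerate frequencies force all-positive rows
  t1 <- generate_cooccurrence_table(10, 1, 1, 0, seed = 5)
  expect_true(all(t1$at8) && all(t1$signal))

  expect_identical(generate_cooccurrence_table(50, 0.4, 0.6, 0.2, seed = 6),
                   generate_cooccurrence_table(50, 0.4, 0.6, 0.2, seed = 6))
  expect_error(generate_cooccurrence_table(10, 1.2, 0.5, 0.5), "probabilities")

  # planted conditional frequency recovered by the Beta posterior
  tab <- generate_cooccurrence_table(1e4, 0.5, 0.6, 0.1, seed = 7)
  sub <- tab[tab$at8, ]
  post <- beta_posterior(sum(sub$signal), nrow(sub))
  ci <- post$credible_interval(0.95)
  expect_true(ci[1] <= 0.6 && 0.6 <= ci[2])
})
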