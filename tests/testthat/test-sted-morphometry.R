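test_that("a-trous planes plus residual reconstruct the image exactly", {
  set.seed(61)
  img <- matrix(runif(80 * 70, 0, 100), 80, 70)
  dec <- atrous_decompose(img, levels = 3)
  rec <- Reduce(`+`, dec$planes) + dec$residual
  expect_lt(max(abs(rec - img)) / max(abs(img)), 1e-6)
  expect_error(atrous_decompose(matrix(0, 5, 5), levels = 3), "too small")
})

test_that("wavelet detection finds planted spots and is monotone in threshold", {
  expect_equal(nrow(atrous_detect(matrix(7, 64, 64))), 0L)

  set.seed(62)
  spots <- data.frame(x = c(600, 2000, 3200, 1000, 2800),
                      y = c(700, 900, 2600, 2400, 1600),
                      sl = 150, ss = 150, amp = 200, theta = 0)
  img <- sted_image(180, 180, spots, noise_sd = 5)
  # detection plane 3 matches the ~150 nm spot scale at 20 nm pixels
  cand <- atrous_detect(img, levels = 3, threshold_factor = 3,
                        detection_level = 3)
  expect_equal(nrow(cand), 5L)
  # each planted spot matched by a candidate within 1 pixel
  for (k in 1:5) {
    ci <- spots$y[k] / 20 + 0.5; cj <- spots$x[k] / 20 + 0.5
    d <- sqrt((cand$row - ci)^2 + (cand$col - cj)^2)
    expect_lte(min(d), 1)
  }
  n_hi <- nrow(atrous_detect(img, levels = 3, threshold_factor = 6,
                             detection_level = 3))
  n_vhi <- nrow(atrous_detect(img, levels = 3, threshold_factor = 12,
                              detection_level = 3))
  expect_lte(n_hi, nrow(cand))
  expect_lte(n_vhi, n_hi)
})

test_that("anisotropic Gaussian fits recover planted spot shapes", {
  set.seed(63)
  # isotropic spot: both sigmas agree within 2%
  iso <- data.frame(x = 1500, y = 1500, sl = 160, ss = 160, amp = 300, theta = 0)
  img <- sted_image(150, 150, iso, noise_sd = 3)
  fit <- fit_anisotropic_gaussian(img, round(1500 / 20), round(1500 / 20),
                                  window_px = 25)
  expect_lt(abs(fit$sigma_long_nm / fit$sigma_short_nm - 1), 0.02)

  # planted 200/100 nm at SNR 20: sigmas within 5%, length = 2.3 sigma_long
  ani <- data.frame(x = 1500, y = 1400, sl = 200, ss = 100, amp = 200,
                    theta = 0.6)
  img2 <- sted_image(150, 150, ani, noise_sd = 10)
  fit2 <- fit_anisotropic_gaussian(img2, round(1400 / 20), round(1500 / 20),
                                   window_px = 25)
  expect_lt(abs(fit2$sigma_long_nm - 200) / 200, 0.05)
  expect_lt(abs(fit2$sigma_short_nm - 100) / 100, 0.05)
  expect_equal(fit2$length_nm, 2.3 * fit2$sigma_long_nm)
  expect_lt(abs(fit2$orientation - 0.6), 0.05)
  expect_true(fit2$orientation >= 0 && fit2$orientation < pi)
})

test_that("the 2.3 sigma length definition is exact", {
  set.seed(64)
  spot <- data.frame(x = 1000, y = 1000, sl = 100, ss = 80, amp = 400, theta = 0)
  img <- sted_image(100, 100, spot, noise_sd = 1)
  fit <- fit_anisotropic_gaussian(img, 50, 50, window_px = 20)
  expect_equal(fit$length_nm, 2.3 * fit$sigma_long_nm)
  expect_equal(fit$length_nm, 230, tolerance = 5)
})

test_that("synapse-candidate filtering applies the intensity and sigma rules", {
  spots <- data.frame(
    x_nm = 1:4, y_nm = 1:4,
    sigma_long_nm = c(500, 50, 500, 120),
    sigma_short_nm = c(500, 50, 500, 90),
    orientation = 0, amplitude = c(300, 300, 150, 250),
    offset = 0, length_nm = 0, converged = TRUE)
  kept <- filter_synapse_candidates(spots)
  # spot 1: amp 300, sigma 500 -> kept; spot 2: sigma 50 -> out;
  # spot 3: amp 150 -> out (strict >200); spot 4: geometric mean ~104 -> kept
  expect_equal(kept$x_nm, c(1, 4))
  # boundary amplitude exactly 200 is rejected
  spots$amplitude <- 200
  expect_equal(nrow(filter_synapse_candidates(spots)), 0L)
})

test_that("presynaptic classification uses an inclusive 90 nm rule", {
  syn <- data.frame(x_nm = c(0, 1000), y_nm = c(0, 0))
  agg <- data.frame(x_nm = c(90, 1091, 500), y_nm = c(0, 0, 0))
  res <- classify_presynaptic(agg, syn, threshold_nm = 90)
  expect_equal(res$aggregates$presynaptic, c(TRUE, FALSE, FALSE))

  # empty synapse list: nothing presynaptic
  res0 <- classify_presynaptic(agg, syn[0, ])
  expect_false(any(res0$aggregates$presynaptic))

  # random configurations equal the all-pairs brute force
  set.seed(65)
  for (rep in 1:10) {
    a <- data.frame(x_nm = runif(40, 0, 2000), y_nm = runif(40, 0, 2000))
    s <- data.frame(x_nm = runif(15, 0, 2000), y_nm = runif(15, 0, 2000))
    res <- classify_presynaptic(a, s, 90)
    ref <- vapply(seq_len(40), function(i) {
      any(sqrt((s$x_nm - a$x_nm[i])^2 + (s$y_nm - a$y_nm[i])^2) <= 90)
    }, logical(1))
    expect_equal(res$aggregates$presynaptic, ref)
  }
})

test_that("a planted presynaptic fraction is recovered on synthetic scenes", {
  set.seed(66)
  # 24 synapses on a grid; 100 aggregates, 17 planted next to synapses
  syn <- expand.grid(x_nm = seq(500, 5500, by = 1000),
                     y_nm = seq(500, 3500, by = 1000))
  n_pre <- 17
  near <- syn[sample(nrow(syn), n_pre, replace = TRUE), ]
  agg <- data.frame(
    x_nm = c(near$x_nm + runif(n_pre, -60, 60), runif(83, 0, 6000)),
    y_nm = c(near$y_nm + runif(n_pre, -60, 60), runif(83, 0, 6000)))
  res <- classify_presynaptic(agg, syn, 90)
  p_hat <- res$presynaptic_fraction
  # planted fraction 0.17 up to the background aggregates that land near a
  # synapse by chance; binomial interval around the realised truth
  truth <- mean(vapply(seq_len(100), function(i) {
    any(sqrt((syn$x_nm - agg$x_nm[i])^2 + (syn$y_nm - agg$y_nm[i])^2) <= 90)
  }, logical(1)))
  expect_equal(p_hat, truth)
  expect_lt(abs(p_hat - 0.17), 1.96 * sqrt(0.17 * 0.83 / 100) + 0.1)
})
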