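test_that("localisation tables round-trip losslessly through CSV", {
  spec <- scene_spec(n_synaptosomes = 5, seed = 2)
  tab <- generate_localisation_scene(spec)$localisations
  path <- withr::local_tempfile(fileext = ".csv")
  write_localisations(tab, path)
  back <- read_localisations(path)
  expect_identical(back$x, tab$x)
  expect_identical(back$y, tab$y)
  expect_identical(back$frame, tab$frame)
  expect_identical(back$sigma, tab$sigma)
})

test_that("localisation reader validates structure and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines("frame,x [nm],y [nm],sigma [nm],intensity [photon]", path)
  empty <- read_localisations(path)
  expect_equal(nrow(empty), 0L)

  writeLines(c("frame,x [nm],y [nm],sigma [nm],intensity [photon]",
               "1,100.0,200.0,20.0,500"), path)
  one <- read_localisations(path)
  expect_equal(one$x, 100)
  expect_equal(one$y, 200)

  writeLines(c("frame,x [nm],sigma [nm],intensity [photon]", "1,1,1,1"), path)
  expect_error(read_localisations(path), "missing mandatory column")

  writeLines(c("frame,x [nm],y [nm],sigma [nm],intensity [photon]",
               "1,100,200,20,500", "2,oops,200,20,500"), path)
  expect_error(read_localisations(path), "line\\(s\\): 2")

  writeLines(c("frame,x [nm],y [nm],sigma [nm],intensity [photon]",
               "1,-5,200,20,500"), path)
  expect_error(read_localisations(path), "invalid localisation")
})

test_that("16-bit TIFF images round-trip and stacks average", {
  img <- matrix(sample(0:65535, 30 * 20, replace = TRUE), 30, 20)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image16(img, path)
  back <- read_image(path)
  expect_equal(back, img)

  # two-plane stack averaged on request
  a <- matrix(100, 10, 10); b <- matrix(300, 10, 10)
  tiff::writeTIFF(list(a / 65535, b / 65535), path, bits.per.sample = 16L)
  expect_equal(read_image(path, average_stack = TRUE), matrix(200, 10, 10))
  expect_length(read_image(path, average_stack = FALSE), 2L)
})

test_that("rendering produces unit-mass Gaussians on the pixel grid", {
  empty <- data.frame(x = numeric(0), y = numeric(0))
  expect_true(all(render_superres(empty, 20, 10, c(100, 100)) == 0))

  one <- data.frame(x = 155, y = 75)
  img <- render_superres(one, 20, 10, c(300, 300))
  expect_equal(sum(img), 1, tolerance = 1e-3)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(8, 16))  # pixel containing (155, 75)

  # two well-separated localisations give two local maxima at their pixels
  two <- data.frame(x = c(100, 300), y = c(100, 100))
  img2 <- render_superres(two, 20, 10, c(400, 200))
  for (x in c(100, 300)) {
    i <- floor(100 / 10) + 1; j <- floor(x / 10) + 1
    win <- img2[(i - 1):(i + 1), (j - 1):(j + 1)]
    expect_equal(max(win), img2[i, j])
  }
})

test_that("rendering matches a brute-force two-Gaussian evaluation", {
  tab <- data.frame(x = c(120, 320), y = c(150, 170))
  p <- 10; sig <- 20
  img <- render_superres(tab, sig, p, c(500, 300))
  # independent route: full-grid pixel-integrated Gaussian sum, no truncation
  nr <- nrow(img); nc <- ncol(img)
  xb <- (0:nc) * p; yb <- (0:nr) * p
  ref <- matrix(0, nr, nc)
  for (k in 1:2) {
    px <- diff(pnorm(xb, tab$x[k], sig))
    py <- diff(pnorm(yb, tab$y[k], sig))
    ref <- ref + py %o% px
  }
  expect_equal(img, ref, tolerance = 1e-3)
})

test_that("rendering is additive over subsets of the table", {
  set.seed(15)
  a <- data.frame(x = runif(20, 0, 900), y = runif(20, 0, 900))
  b <- data.frame(x = runif(15, 0, 900), y = runif(15, 0, 900))
  fov <- c(1000, 1000)
  expect_equal(render_superres(rbind(a, b), 20, 10, fov),
               render_superres(a, 20, 10, fov) +
                 render_superres(b, 20, 10, fov),
               tolerance = 1e-12)
})

test_that("affine fit recovers planted transforms", {
  set.seed(16)
  ref <- cbind(runif(10, 0, 5e4), runif(10, 0, 5e4))
  # identity: zero residual
  f0 <- fit_affine_from_beads(ref, ref)
  expect_equal(f0$transform$linear, diag(2), tolerance = 1e-12)
  expect_equal(f0$residual_rms, 0, tolerance = 1e-9)

  # planted rotation + scale + shift, noise-free: < 1e-9 relative error
  th <- pi / 180
  A <- 1.001 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr <- c(30, -20)
  mov <- ref %*% t(A) + matrix(tr, 10, 2, byrow = TRUE)
  f <- fit_affine_from_beads(ref, mov)
  expect_equal(f$transform$linear, A, tolerance = 1e-9)
  expect_equal(f$transform$offset, tr, tolerance = 1e-6)

  expect_error(fit_affine_from_beads(ref[1:2, ], mov[1:2, ]), "at least 3")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine_from_beads(col, col), "collinear")
})

test_that("affine fit residual is equivariant under joint rotation", {
  set.seed(17)
  ref <- cbind(runif(12, 0, 1e4), runif(12, 0, 1e4))
  mov <- ref + matrix(rnorm(24, 0, 5), ncol = 2)
  rms1 <- fit_affine_from_beads(ref, mov)$residual_rms
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rms2 <- fit_affine_from_beads(ref %*% t(R), mov %*% t(R))$residual_rms
  expect_equal(rms1, rms2, tolerance = 1e-9)
})

test_that("affine application maps points exactly and inverts cleanly", {
  t <- affine_transform(matrix(c(1.002, 0.001, -0.001, 0.998), 2, 2), c(30, -20))
  pts <- cbind(c(0, 100, 5000), c(0, -50, 2000))
  shifted <- apply_affine(affine_transform(diag(2), c(30, -20)), pts)
  expect_equal(shifted, pts + matrix(c(30, -20), 3, 2, byrow = TRUE),
               tolerance = 1e-12)
  round_trip <- apply_affine(invert_affine(t), apply_affine(t, pts))
  expect_equal(round_trip, pts, tolerance = 1e-9)
  expect_error(affine_transform(matrix(0, 2, 2)), "invertible")
})

test_that("affine image warp matches the identity and pure shifts", {
  img <- matrix(runif(400), 20, 20)
  ident <- affine_transform()
  expect_equal(apply_affine(ident, img, pixel_size_nm = 10), img,
               tolerance = 1e-12)
  # shift by exactly one pixel: interior content moves one column right
  shift <- affine_transform(diag(2), c(10, 0))
  out <- apply_affine(shift, img, pixel_size_nm = 10)
  expect_equal(out[, 2:20], img[, 1:19], tolerance = 1e-12)
})
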