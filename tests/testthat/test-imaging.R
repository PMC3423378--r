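test_that("clot_image validates its invariants", {
  expect_error(clot_image(matrix(0, 10, 10), 57.6), "64 x 64")
  expect_error(clot_image(matrix(-1, 64, 64), 57.6), "finite")
  expect_error(clot_image(matrix(0, 64, 64), 0), "positive")
  img <- clot_image(matrix(5, 64, 128), 57.6, label = "ctrl")
  expect_identical(dim(img), c(64L, 128L))
  expect_equal(field_area_um2(img), 64 * 128 * 0.0576^2)
})

test_that("clot_stack enforces shared geometry and increasing z", {
  a <- clot_image(matrix(1, 64, 64), 57.6, z_position_um = 0)
  b <- clot_image(matrix(1, 64, 64), 57.6, z_position_um = 10)
  st <- clot_stack(list(a, b), 10)
  expect_equal(length(st), 2L)
  expect_error(clot_stack(list(a, clot_image(matrix(1, 64, 128), 57.6))),
               "dimensions")
  expect_error(clot_stack(list(b, a)), "increasing")
})

test_that("TIFF round trip is bit-exact for 8-bit rasters", {
  m <- matrix(sample(0:255, 128 * 128, replace = TRUE), 128, 128)
  img <- clot_image(m, 57.6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_clot_tiff(img, path)
  back <- read_clot_tiff(path, 57.6)
  expect_identical(back$pixels, m)
  expect_equal(back$pixel_size_nm, 57.6)
})

test_that("multi-page TIFF loads as a stack with stated z spacing", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:3, function(i) matrix((i * 37) %% 256, 64, 64) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  st <- read_clot_tiff(path, 57.6, slice_spacing_um = 10)
  expect_s3_class(st, "clot_stack")
  expect_equal(length(st), 3L)
  expect_equal(vapply(st$slices, `[[`, numeric(1), "z_position_um"),
               c(0, 10, 20))
})

test_that("RGB input is rejected with a channel message", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(64, 64, 3)), path)
  expect_error(read_clot_tiff(path, 57.6), "channel")
  expect_error(read_clot_tiff("/nonexistent/file.tif", 57.6), "exist")
})

test_that("preprocess subtracts background, normalizes to target, keeps dims", {
  m <- matrix(10, 128, 128)
  m[40, 50] <- 210  # single bright pixel over constant background 10
  img <- clot_image(m, 57.6)
  out <- preprocess(img)
  expect_identical(dim(out), dim(img))
  expect_equal(max(out$pixels), 255)
  expect_equal(out$pixels[1, 1], 0)
  # degenerate: uniform image equals its background estimate
  expect_error(preprocess(clot_image(matrix(10, 64, 64), 57.6)), "degenerate")
})

test_that("preprocess is idempotent on normalized background-free images", {
  img <- ridge_image(n_px = 101, peak_au = 255)
  once <- preprocess(img)
  twice <- preprocess(once)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-12)
})

test_that("preprocessing a constant offset leaves peak positions unchanged", {
  sc <- render_scene(scene_spec(n_fibers = 8, noise_sd_au = 0, seed = 31))
  shifted <- sc$image
  shifted$pixels <- shifted$pixels + 20
  pp0 <- preprocess(sc$image)
  pp1 <- preprocess(shifted)
  lines <- make_test_lines(pp0)
  for (r in lines$row_index) {
    expect_equal(which.max(extract_profile(pp1, r)),
                 which.max(extract_profile(pp0, r)))
  }
})

test_that("rolling-percentile background removes an illumination gradient", {
  base <- ridge_image(n_px = 151, peak_au = 150)
  grad <- outer(seq(0, 40, length.out = 151), rep(1, 151))
  img <- clot_image(base$pixels + grad, 57.6)
  out <- preprocess(img, preprocess_config(background_mode = "rolling_percentile"))
  # away from the ridge the gradient should be essentially gone
  corners <- c(out$pixels[5, 5], out$pixels[146, 5],
               out$pixels[5, 146], out$pixels[146, 146])
  expect_lt(max(corners), 15)
})

test_that("binarize is inclusive at the threshold and monotone", {
  img26 <- clot_image(matrix(26, 64, 64), 57.6)
  img27 <- clot_image(matrix(27, 64, 64), 57.6)
  expect_false(any(binarize(img26, 27)))
  expect_true(all(binarize(img27, 27)))
  m <- matrix(runif(64 * 64, 0, 255), 64, 64)
  img <- clot_image(m, 57.6)
  for (pair in list(c(10, 27), c(27, 100))) {
    lo <- binarize(img, pair[1]); hi <- binarize(img, pair[2])
    expect_true(all(lo | !hi))  # hi-threshold mask is a subset
  }
})

test_that("binarized footprint of a rendered scene matches the truth footprint", {
  sc <- default_scene()
  mask <- binarize(sc$image, 27)  # raw render: truth footprint is pre-noise
  expect_equal(fiber_area(mask) / 100, sc$truth$footprint_fraction,
               tolerance = 0.1)
})
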