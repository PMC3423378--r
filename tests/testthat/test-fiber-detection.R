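test_that("test lines are equally spaced at the standard rows", {
  img1024 <- clot_image(matrix(0, 1024, 1024), 57.6)
  rows <- make_test_lines(img1024, 5)$row_index
  # the classic five-line labels for a 1024-row image, within 1 px
  expect_true(all(abs(rows - c(171, 341, 512, 682, 853)) <= 1))
  expect_equal(make_test_lines(img1024, 1)$row_index, 512L)
  img100 <- clot_image(matrix(0, 100, 100), 57.6)
  expect_equal(make_test_lines(img100, 4)$row_index, c(20L, 40L, 60L, 80L))
  expect_equal(make_test_lines(img100, 4)$length_um[1], 100 * 57.6 / 1000)
  expect_error(make_test_lines(img100, 0), "n_lines")
  expect_error(make_test_lines(img100, 100), "n_lines")
})

test_that("extract_profile returns the image row", {
  img <- clot_image(matrix(7, 64, 96), 57.6)
  expect_equal(extract_profile(img, 10), rep(7, 96))
  img$pixels[11, ] <- 1:96
  expect_equal(extract_profile(img, 10), 1:96)
  expect_error(extract_profile(img, 64), "row_index")
})

test_that("peaks are detected at bump centres and numbered left to right", {
  x <- seq(0, 599)
  bumps <- 100 * exp(-(x - 100)^2 / 50) + 150 * exp(-(x - 300)^2 / 50) +
    200 * exp(-(x - 500)^2 / 50)
  hits <- detect_fibers_on_line(bumps, min_peak_au = 27)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$id, 1:3)
  expect_true(all(abs(hits$peak_col_px - c(100, 300, 500)) <= 1))
  expect_true(all(hits$peak_intensity_au >= 27))
})

test_that("flat and empty profiles yield no fibers, errors where specified", {
  expect_equal(nrow(detect_fibers_on_line(rep(0, 100))), 0L)
  expect_error(detect_fibers_on_line(numeric()), "non-empty")
  # below-threshold bump is ignored
  x <- 20 * exp(-(seq(0, 99) - 50)^2 / 20)
  expect_equal(nrow(detect_fibers_on_line(x)), 0L)
})

test_that("peaks closer than the separation merge to the higher one", {
  x <- seq(0, 199)
  two <- 100 * exp(-(x - 100)^2 / 4) + 140 * exp(-(x - 103)^2 / 4)
  hits <- detect_fibers_on_line(two, min_separation_px = 5)
  expect_equal(nrow(hits), 1L)
  expect_true(abs(hits$peak_col_px - 103) <= 1)
})

test_that("fiber density follows the fibers-per-100-um definition", {
  one_line <- tibble::tibble(row_index = 0L, length_px = 1024L, length_um = 59)
  five_lines <- tibble::tibble(row_index = 0:4, length_px = 1024L,
                               length_um = 59)
  fib <- function(n) tibble::tibble(id = seq_len(n), status = "auto")
  expect_equal(fiber_density(fib(0), one_line), 0)
  expect_equal(fiber_density(fib(17), one_line), 17 / 59 * 100,
               tolerance = 1e-12)
  expect_equal(round(fiber_density(fib(17), one_line), 1), 28.8)
  expect_equal(round(fiber_density(fib(15), five_lines), 2), 5.08)
  expect_error(fiber_density(fib(1), five_lines[0, ]), "test line")
})

test_that("editing updates status and the audit reports the PPV formula", {
  fibers <- tibble::tibble(id = 1:90, line_row = 0L, peak_col_px = 1:90,
                           peak_intensity_au = 50, status = "auto")
  ed <- edit_fibers(fibers, tibble::tibble(
    action = c(rep("confirm", 89), "reject"), id = 1:90))
  expect_equal(ed$audit$true_pos, 89)
  expect_equal(ed$audit$false_pos, 1)
  expect_equal(round(ed$audit$ppv_percent, 1), 98.9)

  all_ok <- edit_fibers(fibers, tibble::tibble(action = "confirm", id = 1))
  expect_equal(all_ok$audit$ppv_percent, 100)

  # no detections, two manual adds: PPV undefined, density counts the adds
  none <- fibers[0, ]
  added <- edit_fibers(none, tibble::tibble(
    action = "add", id = NA, line_row = c(10L, 20L), peak_col_px = c(5L, 9L)))
  expect_true(is.na(added$audit$ppv_percent))
  expect_equal(added$audit$false_neg, 2)
  lines <- tibble::tibble(row_index = 0L, length_px = 1024L, length_um = 59)
  expect_equal(fiber_density(added$fibers, lines), 2 / 59 * 100)

  expect_error(edit_fibers(fibers, tibble::tibble(action = "reject", id = 999)),
               "unknown fiber id")
  # rejected fibers no longer count toward density
  expect_equal(fiber_density(ed$fibers, lines), 89 / 59 * 100)
})

test_that("per-line detection matches ground truth within one fiber", {
  sc <- default_scene()
  lines <- make_test_lines(sc$pp)
  fb <- detect_fibers(sc$pp)
  tc <- truth_line_crossings(sc$truth$fibers, lines)
  det <- table(factor(fb$line_row, levels = lines$row_index))
  tru <- table(factor(tc$line_row, levels = lines$row_index))
  expect_true(all(abs(as.integer(det) - as.integer(tru)) <= 1))
})

test_that("density scales linearly with generator fiber count", {
  low <- render_scene(scene_spec(n_fibers = 10, seed = 7))
  high <- render_scene(scene_spec(n_fibers = 20, seed = 7))
  d <- function(sc) {
    pp <- preprocess(sc$image)
    fiber_density(detect_fibers(pp), make_test_lines(pp))
  }
  # ratio of measured densities tracks the 2x truth ratio within 10%,
  # using the truth crossing counts to remove placement randomness
  lines <- make_test_lines(preprocess(low$image))
  t_ratio <- nrow(truth_line_crossings(high$truth$fibers, lines)) /
    nrow(truth_line_crossings(low$truth$fibers, lines))
  expect_equal(d(high) / d(low), t_ratio, tolerance = 0.1)
})
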