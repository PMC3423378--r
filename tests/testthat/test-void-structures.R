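test_that("void and fiber area are exact complements", {
  all_black <- matrix(FALSE, 64, 64)
  expect_equal(void_area(all_black), 100)
  checker <- matrix(c(TRUE, FALSE), 64, 64)
  expect_equal(void_area(checker), 50)
  set.seed(2)
  for (i in 1:5) {
    m <- matrix(runif(64 * 64) > runif(1), 64, 64)
    expect_identical(void_area(m) + fiber_area(m), 100)
  }
})

test_that("projected void is the OR projection and bounded by every slice", {
  m <- matrix(FALSE, 64, 64)
  a <- m; a[1:10, ] <- TRUE
  expect_equal(projected_void(list(a, a, a))$percent, void_area(a))
  # three disjoint 10% fiber masks project to 70% void
  b <- m; b[11:20, ] <- TRUE
  d <- m; d[21:30, ] <- TRUE
  pv <- projected_void(list(a, b, d))
  expect_equal(pv$percent, 100 - 3 * fiber_area(a))
  expect_error(projected_void(list(a, matrix(FALSE, 32, 32))), "dimensions")
  set.seed(4)
  masks <- lapply(1:3, function(i) matrix(runif(64 * 64) > 0.6, 64, 64))
  expect_lte(projected_void(masks)$percent,
             min(vapply(masks, void_area, numeric(1))))
})

test_that("void volume is the equal-slab mean of slice voids", {
  mk <- function(p) matrix(seq_len(100 * 100) > p * 100 * 100, 100, 100)
  expect_equal(void_volume(list(mk(0.6), mk(0.7), mk(0.8))), 70)
  expect_equal(void_volume(list(matrix(FALSE, 64, 64),
                                matrix(FALSE, 64, 64))), 100)
  expect_error(void_volume(list(matrix(TRUE, 64, 64))), "at least 2")
})

test_that("stack void volume matches the truth-footprint arithmetic", {
  st <- render_stack(scene_spec(n_fibers = 10, noise_sd_au = 0, seed = 3), 3)
  masks <- lapply(st$stack$slices, binarize)
  f <- vapply(st$truths, `[[`, numeric(1), "footprint_fraction")
  expect_equal(void_volume(masks), 100 * (1 - mean(f)), tolerance = 1e-6)
  expect_equal(vapply(st$stack$slices, `[[`, numeric(1), "z_position_um"),
               c(40, 50, 60))
  expect_error(render_stack(scene_spec(), 1), "at least 2")
})

test_that("a cluster inside a network is found with its protrusion count", {
  sc <- cached_scene("cluster_scene", function() {
    render_scene(scene_spec(n_fibers = 15, n_clusters = 1, seed = 303))
  })
  cl <- detect_clusters(preprocess(sc$image))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_protruding_fibers, sc$truth$clusters$n_protrusions,
               tolerance = 2 / sc$truth$clusters$n_protrusions)
  expect_gte(cl$n_protruding_fibers, 8)
  expect_lt(cl$solidity, 0.9)
  expect_lt(cl$mean_protrusion_diameter_nm, 761.9)
  d <- sqrt((cl$core_row_px - sc$truth$clusters$row_px)^2 +
            (cl$core_col_px - sc$truth$clusters$col_px)^2)
  expect_lt(d, 5)
})

test_that("plain networks and bare beads yield no clusters", {
  for (sd in 1:3) {
    sc <- render_scene(scene_spec(n_fibers = 20, seed = 400 + sd))
    expect_equal(nrow(detect_clusters(preprocess(sc$image))), 0L)
  }
  # a bright round bead with no protrusions fails the definition
  n <- 201
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  bead <- clot_image(
    ifelse((rr - 100)^2 + (cc - 100)^2 <= 12^2, 240, 0), 57.6)
  expect_equal(nrow(detect_clusters(bead)), 0L)
})

test_that("agglomerate detection measures counts and long axes", {
  sc <- cached_scene("agg_scene", function() {
    render_scene(scene_spec(n_fibers = 0, n_agglomerates = 40, seed = 77))
  })
  pp <- preprocess(sc$image)
  ag <- detect_agglomerates(pp)
  tr <- sc$truth$agglomerates
  expect_equal(nrow(ag), nrow(tr), tolerance = 2 / nrow(tr))
  errs <- vapply(seq_len(nrow(tr)), function(i) {
    j <- which.min((ag$row_px - tr$row_px[i])^2 +
                   (ag$col_px - tr$col_px[i])^2)
    abs(ag$long_axis_um[j] - tr$long_axis_um[i])
  }, numeric(1))
  expect_lt(max(errs), 0.2)
  expect_true(all(ag$long_axis_um >= 0.3 & ag$long_axis_um <= 20))
})

test_that("a single 8 x 2 um ellipse is measured and classed irregular", {
  m <- matrix(0, 301, 301)
  img <- clot_image(m, 57.6)
  a_px <- 8000 / 57.6 / 2; b_px <- 2000 / 57.6 / 2
  rr <- matrix(0:300, 301, 301); cc <- t(rr)
  u <- (cc - 150) / a_px; v <- (rr - 150) / b_px
  img$pixels <- ifelse(u^2 + v^2 <= 1, 200, 0)
  ag <- detect_agglomerates(img)
  expect_equal(nrow(ag), 1L)
  expect_equal(ag$long_axis_um, 8, tolerance = 0.2 / 8)
  expect_equal(ag$shape_class, "irregular")

  # empty image: nothing detected
  expect_equal(nrow(detect_agglomerates(clot_image(matrix(0, 64, 64), 57.6))),
               0L)
})

test_that("agglomerate count is invariant under 90-degree rotation", {
  sc <- cached_scene("agg_scene", function() {
    render_scene(scene_spec(n_fibers = 0, n_agglomerates = 40, seed = 77))
  })
  pp <- preprocess(sc$image)
  rot <- pp
  rot$pixels <- t(pp$pixels)[ncol(pp$pixels):1, ]
  expect_equal(nrow(detect_agglomerates(rot)), nrow(detect_agglomerates(pp)))
})

test_that("agglomerate mode refuses images with a spanning network", {
  sc <- default_scene()
  expect_true(has_spanning_network(sc$pp))
  expect_error(detect_agglomerates(sc$pp), "spanning")
  agg <- cached_scene("agg_scene", function() {
    render_scene(scene_spec(n_fibers = 0, n_agglomerates = 40, seed = 77))
  })
  expect_false(has_spanning_network(preprocess(agg$image)))
})

test_that("agglomerate summaries follow the definitions", {
  s1 <- agglomerate_summary(c(2, 3, 4), capillary_diameter_um = 5)
  expect_equal(s1$mean_long_axis_um, 3)
  expect_equal(s1$fraction_above_percent, 0)
  s2 <- agglomerate_summary(c(1, 6), capillary_diameter_um = 5)
  expect_equal(s2$fraction_above_percent, 50)
  expect_equal(sum(s1$histogram$count), 3)
  expect_error(agglomerate_summary(numeric()), "at least one")
  # summary on a detected catalogue equals arithmetic on the truth list
  sc <- cached_scene("agg_scene", function() {
    render_scene(scene_spec(n_fibers = 0, n_agglomerates = 40, seed = 77))
  })
  tr <- sc$truth$agglomerates
  s3 <- agglomerate_summary(tr$long_axis_um)
  expect_equal(s3$mean_long_axis_um, mean(tr$long_axis_um))
  expect_equal(s3$fraction_above_percent, 100 * mean(tr$long_axis_um > 5))
})
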