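test_that("local maximum search finds an off-line maximum and breaks ties near", {
  img <- ridge_image(n_px = 101, angle_rad = pi / 2)
  m <- img$pixels
  m[47, 51] <- 200  # true maximum 3 px off the midline crossing (50, 50)
  img$pixels <- m
  hit <- local_max_intensity(img, 50, 50, 5)
  expect_equal(c(hit$row_px, hit$col_px), c(46, 50))
  expect_equal(hit$intensity_au, 200)
  # radius 0: the crossing itself
  at0 <- local_max_intensity(img, 50, 50, 0)
  expect_equal(c(at0$row_px, at0$col_px), c(50, 50))
  # uniform window: tie broken to the crossing point
  flat <- clot_image(matrix(80, 101, 101), 57.6)
  tie <- local_max_intensity(flat, 50, 50, 5)
  expect_equal(c(tie$row_px, tie$col_px), c(50, 50))
  expect_error(local_max_intensity(img, 2, 50, 5), "outside")
})

test_that("FWHM diameter recovers rendered widths at any orientation", {
  for (ang in c(pi / 2, pi / 4, 1.1)) {
    img <- ridge_image(n_px = 201, angle_rad = ang, fwhm_nm = 700)
    d <- measure_diameter(img, 100, 100, orientation_rad = ang)
    expect_equal(d$flag, "ok")
    expect_equal(d$diameter_nm, 700, tolerance = 30 / 700)
  }
  # and with the orientation estimated from the structure tensor
  img <- ridge_image(n_px = 201, angle_rad = pi / 4, fwhm_nm = 700)
  est <- measure_diameter(img, 100, 100)
  expect_equal(est$diameter_nm, 700, tolerance = 30 / 700)
})

test_that("structure-tensor orientation matches the rendered axis", {
  for (ang in c(-1, -0.4, 0.3, 1.2)) {
    img <- ridge_image(n_px = 121, angle_rad = ang)
    est <- fiber_orientation(img, 60, 60)
    dang <- abs(atan2(sin(est - ang), cos(est - ang)))
    expect_lt(min(dang, pi - dang), 0.05)
  }
})

test_that("two closely parallel fibers are flagged, not silently widened", {
  # two 450 nm fibers 400 nm apart: the combined profile must not be
  # reported as a single wide fiber
  sep_px <- 400 / 57.6
  sigma <- (450 / 57.6) / (2 * sqrt(2 * log(2)))
  n <- 161; ctr <- (n - 1) / 2
  cc <- matrix(0:(n - 1), n, n, byrow = TRUE)
  m <- 120 * exp(-(cc - ctr + sep_px / 2)^2 / (2 * sigma^2)) +
       120 * exp(-(cc - ctr - sep_px / 2)^2 / (2 * sigma^2))
  img <- clot_image(m, 57.6)
  d <- measure_diameter(img, 80, 80, orientation_rad = pi / 2)
  expect_true(d$flag %in% c("merged", "unresolved"))
  expect_true(is.na(d$diameter_nm))
})

test_that("profile that never falls to half maximum is unresolved", {
  img <- ridge_image(n_px = 201, fwhm_nm = 3000)
  d <- measure_diameter(img, 100, 100, orientation_rad = pi / 2,
                        max_halfwidth_px = 10)
  expect_equal(d$flag, "unresolved")
})

test_that("diameter-intensity relation detects the generator's linearity", {
  sc <- default_scene()
  mf <- cached_scene("measured_42_20", function() {
    measure_fibers(sc$pp, detect_fibers(sc$pp))
  })
  rel <- diameter_intensity_relation(mf)
  expect_gt(rel$slope, 0)
  expect_lt(rel$p_value, 0.05)
  td <- tidy(rel)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(glance(rel)$n, rel$n)
})

test_that("no relation is reported for constant diameters", {
  set.seed(1)
  fake <- tibble::tibble(diameter_nm = rep(700, 40),
                         local_max_intensity_au = runif(40, 50, 200))
  rel <- diameter_intensity_relation(fake)
  ci <- suppressWarnings(stats::confint(rel$fit))["local_max_intensity_au", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
  expect_error(diameter_intensity_relation(fake[1:2, ]), "at least 10")
})

test_that("normal samples get a normal fit with accurate mean", {
  set.seed(5)
  x <- rnorm(500, 800, 50)
  f <- fit_distribution(x)
  expect_equal(f$fit_kind, "normal")
  expect_equal(f$params$mu, 800, tolerance = 7 / 800)
  expect_true(is.na(f$local_min_nm))
})

test_that("bimodal samples are detected and the density minimum is located", {
  # brute-force interior minimum of the true mixture density
  truth_min <- optimize(
    function(x) 0.6 * dnorm(x, 650, 50) + 0.4 * dnorm(x, 880, 50),
    c(650, 880))$minimum
  set.seed(11)
  x <- c(rnorm(300, 650, 50), rnorm(200, 880, 50))
  f <- fit_distribution(x)
  expect_equal(f$fit_kind, "bimodal")
  expect_lt(f$normality_p, 0.05)
  expect_lt(f$params$mu1, f$local_min_nm)
  expect_gt(f$params$mu2, f$local_min_nm)
  expect_equal(f$local_min_nm, truth_min, tolerance = 25 / truth_min)
  expect_true(f$params$w > 0 && f$params$w < 1)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  set.seed(7)
  x <- c(rnorm(300, 650, 50), rnorm(200, 880, 50))
  f <- fit_distribution(x, force_bimodal = TRUE)
  withr::local_package("mclust")
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(c(f$params$mu1, f$params$mu2)),
               sort(as.numeric(mc$parameters$mean)), tolerance = 0.01)
})

test_that("degenerate and tiny samples fail loudly", {
  expect_error(fit_distribution(rep(700, 50)), "degenerate")
  expect_error(fit_distribution(c(1, 2)), "at least 3")
})

test_that("TTR follows its definition and properties", {
  d <- c(rep(700, 27), rep(800, 10))
  t1 <- compute_ttr(d)
  expect_equal(t1$n_thin, 27)
  expect_equal(t1$n_thick, 10)
  expect_equal(t1$ttr, 2.7)
  expect_equal(compute_ttr(c(rep(700, 7), rep(800, 10)))$ttr, 0.7)
  expect_equal(compute_ttr(c(700, 800))$ttr, 1)
  inf_case <- compute_ttr(rep(500, 5))
  expect_true(is.infinite(inf_case$ttr))
  expect_match(inf_case$note, "infinite")
  expect_error(compute_ttr(numeric()), "at least one")
  # scale-free: multiplying diameters and threshold by c leaves TTR fixed
  set.seed(3)
  x <- runif(200, 400, 1100)
  for (cc in c(0.5, 2, 10)) {
    expect_equal(compute_ttr(cc * x, cc * 761.9)$ttr,
                 compute_ttr(x, 761.9)$ttr)
  }
  # monotone: raising the threshold never decreases TTR
  ttrs <- vapply(seq(500, 1000, by = 50),
                 function(th) compute_ttr(x, th)$ttr, numeric(1))
  expect_true(all(diff(ttrs) >= 0))
})

test_that("percent change is signed, exact, and rounds as reported", {
  expect_equal(round(percent_change(2.7, 0.7)), -74)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(0.7, 1.3), 85.714286, tolerance = 1e-6)
  expect_error(percent_change(0, 1), "undefined")
})
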