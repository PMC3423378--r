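test_that("branch classification implements width conservation", {
  expect_equal(classify_branch(c(700, 400, 300))$call, "branch")
  expect_equal(classify_branch(c(700, 400, 300))$residual, 0)
  nb <- classify_branch(c(700, 100, 100))
  expect_equal(nb$call, "not_branch")
  expect_equal(nb$residual, 5 / 7, tolerance = 1e-12)
  expect_equal(classify_branch(c(700, 380, 320))$call, "branch")
  expect_error(classify_branch(c(700, -1, 300)), "positive")
  expect_error(classify_branch(c(700, 300)), "positive|three")
  # permutation invariance
  w <- c(640, 410, 250)
  perms <- list(w, w[c(2, 1, 3)], w[c(3, 2, 1)], w[c(2, 3, 1)])
  calls <- vapply(perms, function(p) classify_branch(p)$call, character(1))
  expect_true(length(unique(calls)) == 1L)
})

test_that("crossing classification uses the 40% proportional-increase rule", {
  base <- rep(100, 41)
  bump <- function(h) { p <- base; p[21] <- 100 + h; p }
  both50 <- classify_crossing(bump(50), bump(50), 21)
  expect_equal(both50$kind, "contact")
  expect_equal(both50$rel_increase_a, 0.5)
  one_low <- classify_crossing(bump(50), bump(5), 21)
  expect_equal(one_low$kind, "pass_over")
  # boundary: exactly 40% is strictly not a contact
  expect_equal(classify_crossing(bump(40), bump(40), 21)$kind, "pass_over")
  # scale invariance: the rule is proportional
  expect_equal(classify_crossing(3 * bump(50), 0.2 * bump(50), 21)$kind,
               "contact")
  expect_error(classify_crossing(rep(0, 41), bump(50), 21), "degenerate")
  expect_error(classify_crossing(bump(50)[1:12], bump(50), 6), "baseline")
  expect_error(classify_crossing(bump(50), bump(50), 99), "outside")
})

test_that("rendered additive crossings show ~100% increase and classify as contact", {
  sc <- render_scene(scene_spec(n_fibers = 0, n_crossings = 3, seed = 210))
  img <- sc$image
  for (i in seq_len(nrow(sc$truth$crossings))) {
    x <- sc$truth$crossings[i, ]
    prof_along <- function(phi) {
      s <- seq(-30, 30, by = 1)
      fibrinet:::sample_bilinear(img$pixels, x$row_px + s * sin(phi),
                                 x$col_px + s * cos(phi))
    }
    cl <- classify_crossing(prof_along(x$phi_a), prof_along(x$phi_b), 31)
    expect_equal(cl$kind, "contact")
    expect_gt(cl$rel_increase_a, 0.6)
    expect_gt(cl$rel_increase_b, 0.6)
  }
})

test_that("branch junctions measured in rendered scenes conserve width", {
  sc <- render_scene(scene_spec(n_fibers = 0, n_branches = 3, seed = 211))
  for (i in seq_len(nrow(sc$truth$branches))) {
    b <- sc$truth$branches[i, ]
    angles <- c(b$phi + pi, b$phi + 25 * pi / 180, b$phi - 25 * pi / 180)
    w <- vapply(angles, function(ang) {
      p <- c(b$row_px, b$col_px) + 20 * c(sin(ang), cos(ang))
      d <- measure_diameter(sc$image, p[1], p[2], orientation_rad = ang)
      if (d$flag == "ok") d$diameter_nm else NA_real_
    }, numeric(1))
    expect_true(all(is.finite(w)))
    expect_equal(classify_branch(w)$call, "branch")
    # truth triple satisfies F1 = F2 + F3 exactly
    expect_equal(b$f1_nm, b$f2_nm + b$f3_nm, tolerance = 1e-12)
  }
})

test_that("fiber tracing follows the axis and reads the ridge intensity", {
  img <- ridge_image(n_px = 201, angle_rad = pi / 3, fwhm_nm = 700,
                     peak_au = 150)
  tr <- trace_fiber(img, 100, 100, orientation_rad = pi / 3, max_steps = 60)
  expect_gt(nrow(tr), 100)
  expect_true(all(tr$intensity_au > 140))  # stays on the ridge
})

test_that("candidate meetings appear only at true crossings", {
  # isolated fiber: no candidates
  iso <- render_scene(scene_spec(n_fibers = 1, seed = 212))
  pp <- preprocess(iso$image)
  mf <- measure_fibers(pp, detect_fibers(pp))
  cand <- candidate_meetings(pp, mf)
  expect_equal(nrow(cand), 0L)

  # one true crossing of equal fibers: starting from measurement points on
  # each arm, tracing must flag a candidate at the crossing and pair the two
  sc <- render_scene(scene_spec(n_fibers = 0, n_crossings = 1, seed = 213))
  x <- sc$truth$crossings[1, ]
  arm_point <- function(phi) c(x$row_px, x$col_px) + 18 * c(sin(phi), cos(phi))
  pa <- arm_point(x$phi_a); pb <- arm_point(x$phi_b)
  fake_mf <- tibble::tibble(
    id = 1:2,
    max_row_px = round(c(pa[1], pb[1])), max_col_px = round(c(pa[2], pb[2])),
    orientation_rad = c(x$phi_a, x$phi_b), width_flag = "ok"
  )
  cand2 <- candidate_meetings(sc$image, fake_mf, max_steps = 40)
  expect_gt(nrow(cand2), 0L)
  d <- sqrt((cand2$row_px - x$row_px)^2 + (cand2$col_px - x$col_px)^2)
  expect_lte(min(d), 2.5)
  expect_true(any(!is.na(cand2$partner_id)))
})

test_that("topology_stats computes densities and count ratios", {
  st <- topology_stats(5, 7, 10, 59 * 59)
  expect_equal(st$density_branch_ratio, 2)
  expect_equal(st$density_crossing_ratio, 10 / 7)
  expect_equal(st$xbranch_per_fiber, 0.5)
  expect_equal(st$xbranch_per_field, 5)
  expect_equal(st$xbranch_per_mm2, 5 / (59 * 59 / 1e6))

  none <- topology_stats(0, 0, 10, 59 * 59)
  expect_equal(none$xbranch_per_fiber, 0)
  expect_true(is.na(none$density_branch_ratio))

  per_field <- topology_stats(48, 0, 30, 59 * 59)
  expect_equal(per_field$xbranch_per_field, 48)
  expect_error(topology_stats(1, 1, 1, 0), "positive")

  # tibble inputs: pass_over contacts and rejected fibers are excluded
  contacts <- tibble::tibble(kind = c("contact", "pass_over", "contact"))
  fibers <- tibble::tibble(status = c("auto", "rejected", "confirmed"))
  st2 <- topology_stats(tibble::tibble(x = 1:2), contacts, fibers, 100)
  expect_equal(st2$n_junctions, 2)
  expect_equal(st2$n_contacts, 2)
  expect_equal(st2$n_fibers, 2)
})
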