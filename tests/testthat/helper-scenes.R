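# shared fixtures, built in code at test time

# analytic Gaussian ridge through the image centre at a given axis angle;
# independent of the package's renderer (direct closed form)
ridge_image <- function(n_px = 201, angle_rad = pi / 2, fwhm_nm = 700,
                        peak_au = 120, pixel_size_nm = 57.6,
                        offset_au = 0) {
  sigma_px <- (fwhm_nm / pixel_size_nm) / (2 * sqrt(2 * log(2)))
  ctr <- (n_px - 1) / 2
  rr <- matrix(0:(n_px - 1), n_px, n_px)
  cc <- matrix(0:(n_px - 1), n_px, n_px, byrow = TRUE)
  # perpendicular distance to the line through (ctr, ctr) with direction
  # (sin a, cos a)
  d <- abs(-(rr - ctr) * cos(angle_rad) + (cc - ctr) * sin(angle_rad))
  clot_image(offset_au + peak_au * exp(-d^2 / (2 * sigma_px^2)),
             pixel_size_nm)
}

# a small cache so expensive rendered scenes are shared between tests
.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, builder) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, builder(), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

default_scene <- function(seed = 42, n_fibers = 20) {
  cached_scene(sprintf("scene_%d_%d", seed, n_fibers), function() {
    sc <- render_scene(scene_spec(n_fibers = n_fibers, seed = seed))
    sc$pp <- preprocess(sc$image)
    sc
  })
}

# nearest ground-truth diameter for a detected fiber on a test line
truth_diameter_at <- function(truth, line_row, col_px, lines) {
  tc <- truth_line_crossings(truth$fibers, lines)
  tc <- tc[tc$line_row == line_row, ]
  j <- which.min(abs(tc$col_px - col_px))
  truth$fibers$diameter_nm[truth$fibers$id == tc$fiber_id[j]]
}
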