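#' Clot void area of a binary mask
#'
#' White pixels are fibers, black pixels empty space; void area is the black
#' fraction in percent. `void_area(mask) + fiber_area(mask) = 100` exactly.
#'
#' @param mask Logical matrix from [binarize()].
#' @return Percent void (0-100).
#' @export
void_area <- function(mask) {
  stopifnot(is.logical(mask))
  100 * sum(!mask) / length(mask)
}

#' @rdname void_area
#' @export
fiber_area <- function(mask) {
  stopifnot(is.logical(mask))
  100 * sum(mask) / length(mask)
}

#' Projected void area over a slice stack
#'
#' The projected mask is the pixelwise OR of the fiber (white) pixels of all
#' slices; the projected void percentage is the void fraction of that
#' projection, and can never exceed the void of any single slice.
#'
#' @param stack_masks List of logical masks sharing dimensions (classically
#'   three slices, e.g. 40/50/60 um above the clot surface).
#' @return List with `mask` (the projection) and `percent`.
#' @export
projected_void <- function(stack_masks) {
  stopifnot(is.list(stack_masks), length(stack_masks) >= 1L)
  d <- dim(stack_masks[[1]])
  proj <- matrix(FALSE, d[1], d[2])
  for (m in stack_masks) {
    if (!identical(dim(m), d)) {
      stop("all masks must share dimensions", call. = FALSE)
    }
    proj <- proj | m
  }
  list(mask = proj, percent = void_area(proj))
}

#' Clot void volume over a slice stack
#'
#' Equal-slab model: the void volume percentage is the unweighted mean of the
#' per-slice void percentages.
#'
#' @param stack_masks List of at least two logical masks.
#' @return Percent void volume.
#' @export
void_volume <- function(stack_masks) {
  if (!is.list(stack_masks) || length(stack_masks) < 2L) {
    stop("void volume requires at least 2 slices", call. = FALSE)
  }
  mean(vapply(stack_masks, void_area, numeric(1)))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

component_solidity <- function(rows, cols) {
  if (length(rows) < 3L) return(1)
  # hull over pixel corners so solidity of convex pixel blobs stays <= 1
  px <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  py <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(px, py)
  hull_area <- shoelace_area(px[h], py[h])
  if (hull_area <= 0) return(1)
  min(length(rows) / hull_area, 1)
}

#' Detect abnormal fibrin clusters
#'
#' A fibrin cluster is an irregularly shaped high-intensity core with at
#' least 8 thin fibers protruding from its periphery. Cores are connected
#' components of pixels above the `core_percentile` intensity quantile with
#' area at least `min_core_area_um2` and solidity below `max_solidity`
#' (irregular outline). Protruding fibers are counted as angular intensity
#' peaks on a ring just outside the core boundary whose perpendicular FWHM is
#' below `thin_threshold_nm`.
#'
#' @param img A preprocessed [clot_image()].
#' @param thin_threshold_nm Thin-fiber diameter cut for protrusions
#'   (default 761.9 nm).
#' @param core_percentile Intensity quantile defining core pixels
#'   (default 0.99).
#' @param core_min_au Absolute intensity floor for core pixels (default
#'   180 au): cluster cores approach saturation, whereas single-fiber ridges
#'   stay well below it, so the effective cut is the larger of the quantile
#'   and this floor.
#' @param min_core_area_um2 Minimum core area (default 0.5 um^2).
#' @param max_solidity Solidity above which a core is too regular
#'   (default 0.9).
#' @param max_aspect Major/minor axis ratio above which a candidate core is
#'   an elongated ridge fragment, not a compact core (default 3).
#' @param min_protrusions Minimum protruding thin fibers (default 8).
#' @param ring_offset_px Ring distance outside the core boundary (default
#'   5 px, far enough out that neighbouring protrusions resolve); a second
#'   ring 5 px further out confirms
#'   that a peak is radial: a protrusion radiates from the core, so its
#'   angular position coincides across rings, whereas a network fiber
#'   passing the core crosses successive rings at different angles; peaks
#'   must persist on three rings (offsets +0, +5, +10 px) to count.
#' @return Tibble of clusters: `core_row_px`, `core_col_px` (0-based
#'   centroid), `core_area_um2`, `solidity`, `n_protruding_fibers`,
#'   `mean_protrusion_diameter_nm`.
#' @export
detect_clusters <- function(img, thin_threshold_nm = 761.9,
                            core_percentile = 0.99,
                            core_min_au = 180,
                            min_core_area_um2 = 0.5,
                            max_solidity = 0.9,
                            max_aspect = 3,
                            min_protrusions = 8L,
                            ring_offset_px = 5) {
  stopifnot(inherits(img, "clot_image"))
  m <- img$pixels
  px_um2 <- (img$pixel_size_nm / 1000)^2
  cut <- max(stats::quantile(m, core_percentile, names = FALSE), core_min_au)
  core_mask <- m >= cut
  lab <- EBImage::bwlabel(core_mask)
  n_comp <- max(lab)
  out <- list()
  for (k in seq_len(n_comp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area_um2 <- nrow(idx) * px_um2
    if (area_um2 < min_core_area_um2) next
    sol <- component_solidity(idx[, 1], idx[, 2])
    if (sol >= max_solidity) next
    cov_rc <- stats::cov(idx)
    ev <- eigen(cov_rc, symmetric = TRUE, only.values = TRUE)$values
    if (sqrt(max(ev[1], 1e-9) / max(ev[2], 1e-9)) >= max_aspect) next
    cen <- colMeans(idx) - 1  # 0-based centroid
    rad_px <- sqrt((idx[, 1] - 1 - cen[1])^2 + (idx[, 2] - 1 - cen[2])^2)
    r_core <- stats::quantile(rad_px, 0.98, names = FALSE)
    nb <- 180L
    theta <- (seq_len(nb) - 0.5) / nb * 2 * pi - pi
    ring_peaks <- function(offset) {
      rr <- cen[1] + (r_core + offset) * sin(theta)
      cc <- cen[2] + (r_core + offset) * cos(theta)
      ring <- sample_bilinear(m, rr, cc)
      ring[is.na(ring)] <- 0
      ext <- c(ring[(nb - 1):nb], ring, ring[1:2])
      sm <- moving_average3(ext)[3:(nb + 2)]
      prev <- c(sm[nb], sm[-nb]); nxt <- c(sm[-1], sm[1])
      peaks <- which(sm >= prev & sm > nxt & ring >= 27)
      if (length(peaks) > 1L) {
        # minimal angular separation (6 degrees), keeping higher peaks
        ord <- peaks[order(-sm[peaks])]
        kept <- integer()
        for (p in ord) {
          dtheta <- abs(p - kept)
          dtheta <- pmin(dtheta, nb - dtheta)
          if (!length(kept) || all(dtheta >= 3)) kept <- c(kept, p)
        }
        peaks <- sort(kept)
      }
      list(peaks = peaks, rr = rr, cc = cc)
    }
    inner <- ring_peaks(ring_offset_px)
    mid <- ring_peaks(ring_offset_px + 5)
    outer <- ring_peaks(ring_offset_px + 10)
    near <- function(p, set) {
      dtheta <- abs(set - p)
      length(set) && any(pmin(dtheta, nb - dtheta) <= 2)
    }
    radial <- inner$peaks[vapply(inner$peaks, function(p) {
      near(p, mid$peaks) || near(p, outer$peaks)
    }, logical(1))]
    diams <- purrr::map_dbl(radial, function(p) {
      # width at the innermost ring; fall back to the mid ring when a
      # passing fiber spoils the inner measurement
      for (ring in list(inner, mid)) {
        d <- measure_diameter(img, ring$rr[p], ring$cc[p],
                              orientation_rad = theta[p],
                              max_halfwidth_px = 12)
        if (d$flag == "ok") return(d$diameter_nm)
      }
      NA_real_
    })
    thin <- diams[is.finite(diams) & diams < thin_threshold_nm]
    if (length(thin) < min_protrusions) next
    out[[length(out) + 1L]] <- tibble::tibble(
      core_row_px = cen[1], core_col_px = cen[2],
      core_area_um2 = area_um2, solidity = sol,
      n_protruding_fibers = length(thin),
      mean_protrusion_diameter_nm = mean(thin)
    )
  }
  if (!length(out)) {
    return(tibble::tibble(core_row_px = numeric(), core_col_px = numeric(),
                          core_area_um2 = numeric(), solidity = numeric(),
                          n_protruding_fibers = integer(),
                          mean_protrusion_diameter_nm = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Test whether an image contains a spanning fibrin network
#'
#' Network fibers are long structures crossing a substantial part of the
#' field, whereas isolated agglomerates are at most a few um across. An
#' image is classed as containing a network when any connected component of
#' the binarized image has a major axis of at least `span_um` (well above
#' the agglomerate size range), capped at half the shorter field edge for
#' small fields.
#'
#' @param img A preprocessed [clot_image()].
#' @param threshold_au Binarization threshold (default 27 au).
#' @param span_um Physical span defining a network structure (default 20 um).
#' @return Logical.
#' @export
has_spanning_network <- function(img, threshold_au = 27, span_um = 20) {
  stopifnot(inherits(img, "clot_image"))
  mask <- binarize(img, threshold_au)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(FALSE)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  span_px <- min(span_um * 1000 / img$pixel_size_nm, 0.5 * min(dim(mask)))
  any(mom[, "m.majoraxis"] >= span_px)
}

#' Detect fibrin agglomerates in a network-free image
#'
#' Agglomerates are isolated fibrin particles (about 0.5-8 um) suspended in
#' plasma when network formation is fully inhibited. This detector refuses to
#' run when a spanning fibrin network is present: fibers detected on two or
#' more standard test lines indicate a network, and network analysis should
#' be used instead.
#'
#' @param img A preprocessed [clot_image()].
#' @param threshold_au Binarization threshold (default 27 au).
#' @param min_equiv_diameter_um Minimum equivalent (area-derived) diameter
#'   (default 0.3 um).
#' @param spherical_aspect_max Aspect ratio below which the shape class is
#'   `"spherical"` (default 1.3).
#' @return Tibble of agglomerates: `row_px`, `col_px` (0-based centroid),
#'   `area_um2`, `long_axis_um`, `aspect_ratio`, `shape_class`,
#'   `has_blunted_fibers` (irregular outline, solidity < 0.85).
#' @export
detect_agglomerates <- function(img, threshold_au = 27,
                                min_equiv_diameter_um = 0.3,
                                spherical_aspect_max = 1.3) {
  stopifnot(inherits(img, "clot_image"))
  if (has_spanning_network(img, threshold_au)) {
    stop("image contains a spanning fibrin network; use the network ",
         "analysis instead", call. = FALSE)
  }
  mask <- binarize(img, threshold_au)
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  empty <- tibble::tibble(row_px = numeric(), col_px = numeric(),
                          area_um2 = numeric(), long_axis_um = numeric(),
                          aspect_ratio = numeric(), shape_class = character(),
                          has_blunted_fibers = logical())
  if (n_comp == 0L) return(empty)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  px_um <- img$pixel_size_nm / 1000
  rows <- purrr::map(seq_len(n_comp), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    area_um2 <- nrow(idx) * px_um^2
    equiv_d <- 2 * sqrt(area_um2 / pi)
    if (equiv_d < min_equiv_diameter_um) return(NULL)
    major <- mom[k, "m.majoraxis"] * px_um
    ecc <- mom[k, "m.eccentricity"]
    minor <- major * sqrt(max(1 - ecc^2, 1e-12))
    aspect <- major / minor
    tibble::tibble(
      row_px = mean(idx[, 1]) - 1, col_px = mean(idx[, 2]) - 1,
      area_um2 = area_um2, long_axis_um = major, aspect_ratio = aspect,
      shape_class = if (aspect < spherical_aspect_max) "spherical" else "irregular",
      has_blunted_fibers = component_solidity(idx[, 1], idx[, 2]) < 0.85
    )
  })
  res <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(res)) empty else res
}

#' Summarise agglomerate long-axis morphometry
#'
#' @param aggs Agglomerate tibble from [detect_agglomerates()] (at least one
#'   row) or a numeric vector of long axes (um).
#' @param capillary_diameter_um Reference capillary diameter (default 5 um);
#'   agglomerates longer than this can obstruct capillary flow.
#' @param breaks_um Histogram bin edges (default 0.5 um bins over 0-10 um,
#'   extended if needed).
#' @return List with `mean_long_axis_um`, `fraction_above_percent`, and
#'   `histogram` (tibble of `bin_left_um`, `bin_right_um`, `count`).
#' @export
agglomerate_summary <- function(aggs, capillary_diameter_um = 5,
                                breaks_um = seq(0, 10, by = 0.5)) {
  lax <- if (is.numeric(aggs)) aggs else aggs$long_axis_um
  lax <- lax[is.finite(lax)]
  if (!length(lax)) stop("need at least one agglomerate", call. = FALSE)
  if (max(lax) > max(breaks_um)) {
    breaks_um <- c(breaks_um,
                   seq(max(breaks_um) + 0.5, ceiling(max(lax) * 2) / 2, by = 0.5))
  }
  h <- graphics::hist(lax, breaks = breaks_um, plot = FALSE)
  list(
    mean_long_axis_um = mean(lax),
    fraction_above_percent = 100 * mean(lax > capillary_diameter_um),
    histogram = tibble::tibble(
      bin_left_um = h$breaks[-length(h$breaks)],
      bin_right_um = h$breaks[-1],
      count = h$counts
    )
  )
}
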