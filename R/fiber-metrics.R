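#' @keywords internal
#' Bilinear interpolation at fractional 0-based (row, col) positions.
#' Positions outside the image return NA.
sample_bilinear <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(rows))
  ok <- rows >= 0 & rows <= nr - 1 & cols >= 0 & cols <= nc - 1
  if (!any(ok)) return(out)
  r <- rows[ok]; c <- cols[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  out[ok] <- (1 - fr) * ((1 - fc) * m[i00] + fc * m[i01]) +
             fr * ((1 - fc) * m[i10] + fc * m[i11])
  out
}

#' Local maximum fiber intensity near a test-line crossing
#'
#' Fiber intensity is proportional to the lateral aggregation of labelled
#' monomers, so each fiber is characterised at its locally brightest point.
#' The search window is a square of half-width `search_radius_px` centred on
#' the test-line crossing; ties break to the pixel nearest the crossing.
#'
#' @param img A [clot_image()].
#' @param row_px,col_px 0-based pixel coordinates of the crossing.
#' @param search_radius_px Half-width of the search window (default 5 px);
#'   0 returns the crossing pixel itself.
#' @return List with `row_px`, `col_px` (0-based position of the maximum) and
#'   `intensity_au`.
#' @export
local_max_intensity <- function(img, row_px, col_px, search_radius_px = 5L) {
  stopifnot(inherits(img, "clot_image"))
  m <- img$pixels
  r <- as.integer(row_px); c <- as.integer(col_px)
  s <- as.integer(search_radius_px)
  if (r - s < 0 || r + s > nrow(m) - 1 || c - s < 0 || c + s > ncol(m) - 1) {
    stop("search window extends outside the image", call. = FALSE)
  }
  rows <- (r - s):(r + s); cols <- (c - s):(c + s)
  win <- m[rows + 1L, cols + 1L, drop = FALSE]
  mx <- max(win)
  hit <- which(win == mx, arr.ind = TRUE)
  d2 <- (rows[hit[, 1]] - r)^2 + (cols[hit[, 2]] - c)^2
  best <- which.min(d2)
  list(row_px = rows[hit[best, 1]], col_px = cols[hit[best, 2]],
       intensity_au = mx)
}

#' Estimate local fiber axis orientation
#'
#' Intensity-weighted structure tensor in a square window: the dominant
#' gradient direction is perpendicular to the fiber, so the fiber axis is its
#' normal. Angle is measured in image coordinates; the axis direction vector
#' is `(d_col, d_row) = (cos a, sin a)`.
#'
#' @param img A [clot_image()].
#' @param row_px,col_px 0-based centre of the window.
#' @param window_px Window edge length (default 15 px).
#' @return Axis angle in radians, in `(-pi/2, pi/2]`.
#' @export
fiber_orientation <- function(img, row_px, col_px, window_px = 15L) {
  m <- img$pixels
  h <- (as.integer(window_px) - 1L) %/% 2L
  r0 <- max(1L, row_px + 1L - h); r1 <- min(nrow(m), row_px + 1L + h)
  c0 <- max(1L, col_px + 1L - h); c1 <- min(ncol(m), col_px + 1L + h)
  win <- m[r0:r1, c0:c1, drop = FALSE]
  if (nrow(win) < 3L || ncol(win) < 3L) return(0)
  gy <- (win[-c(1, 2), ] - win[-c(nrow(win) - 1, nrow(win)), ]) / 2
  gx <- (win[, -c(1, 2)] - win[, -c(ncol(win) - 1, ncol(win))]) / 2
  core_r <- 2:(nrow(win) - 1); core_c <- 2:(ncol(win) - 1)
  gy <- gy[, core_c]; gx <- gx[core_r, ]
  w <- win[core_r, core_c]
  jxx <- sum(w * gx * gx); jyy <- sum(w * gy * gy); jxy <- sum(w * gx * gy)
  if (jxx + jyy <= 0) return(0)
  grad_angle <- 0.5 * atan2(2 * jxy, jxx - jyy)
  a <- grad_angle + pi / 2
  if (a > pi / 2) a <- a - pi
  a
}

#' Measure fiber diameter as the FWHM of the perpendicular profile
#'
#' The intensity profile is sampled (bilinear interpolation, 0.5 px steps)
#' perpendicular to the fiber axis through the measurement point. The local
#' background is the minimum of the profile; the diameter is the full width
#' at half maximum above that background, with sub-pixel linear interpolation
#' at the two half-maximum crossings, converted to nm via the pixel size.
#'
#' Unresolvable widths are flagged rather than silently reported: if the
#' profile never falls to half maximum inside the window the result is
#' `NA` with flag `"unresolved"`; if the above-half region contains more than
#' one distinct peak (two closely parallel fibers) the flag is `"merged"`.
#'
#' @param img A [clot_image()].
#' @param row_px,col_px 0-based measurement position (fiber local maximum).
#' @param orientation_rad Local fiber axis angle; estimated with
#'   [fiber_orientation()] if `NULL`.
#' @param max_halfwidth_px Profile half-window (default 20 px, about 1.15 um
#'   at 57.6 nm/px).
#' @return List with `diameter_nm` (NA when flagged) and `flag`
#'   (`"ok"`, `"unresolved"` or `"merged"`).
#' @export
measure_diameter <- function(img, row_px, col_px, orientation_rad = NULL,
                             max_halfwidth_px = 20) {
  stopifnot(inherits(img, "clot_image"))
  if (is.null(orientation_rad)) {
    orientation_rad <- fiber_orientation(img, row_px, col_px)
  }
  perp <- orientation_rad + pi / 2
  step <- 0.5
  s <- seq(-max_halfwidth_px, max_halfwidth_px, by = step)
  raw <- sample_bilinear(img$pixels, row_px + s * sin(perp),
                         col_px + s * cos(perp))
  # a light smoothing before the half-maximum search: the raw maximum of a
  # noisy profile is biased upward, which would bias the FWHM downward
  prof <- moving_average3(raw)
  # peak: brightest sample within +/-2 px of the measurement point
  idx_near <- which(abs(s) <= 2)
  pk <- idx_near[which.max(prof[idx_near])]
  if (!length(pk) || is.na(prof[pk])) {
    return(list(diameter_nm = NA_real_, flag = "unresolved"))
  }
  bg <- min(prof, na.rm = TRUE)
  half <- bg + (prof[pk] - bg) / 2
  cross <- function(side) {
    ii <- if (side < 0) seq(pk, 1L) else seq(pk, length(prof))
    v <- prof[ii]
    below <- which(!is.na(v) & v <= half)
    below <- below[below > 1L]
    if (!length(below)) return(NA_real_)
    b <- below[1]
    a <- b - 1L
    # linear interpolation between the bracketing samples
    frac <- (v[a] - half) / (v[a] - v[b])
    s[ii[a]] + frac * (s[ii[b]] - s[ii[a]])
  }
  # if the window never approaches background the measurement is invalid:
  # a profile whose minimum sits above half the absolute peak cannot show a
  # credible half-maximum crossing
  if (bg >= 0.5 * prof[pk]) {
    return(list(diameter_nm = NA_real_, flag = "unresolved"))
  }
  s_left <- cross(-1); s_right <- cross(+1)
  if (is.na(s_left) || is.na(s_right)) {
    return(list(diameter_nm = NA_real_, flag = "unresolved"))
  }
  # flat-top check: for a single Gaussian cross-section the 80%-maximum
  # width is 0.567x the half-maximum width; two fused parallel fibers give
  # a markedly flatter top
  level80 <- bg + 0.8 * (prof[pk] - bg)
  cross_at <- function(side, level) {
    ii <- if (side < 0) seq(pk, 1L) else seq(pk, length(prof))
    v <- prof[ii]
    below <- which(!is.na(v) & v <= level)
    below <- below[below > 1L]
    if (!length(below)) return(NA_real_)
    b <- below[1]; a <- b - 1L
    frac <- (v[a] - level) / (v[a] - v[b])
    s[ii[a]] + frac * (s[ii[b]] - s[ii[a]])
  }
  w80_l <- cross_at(-1, level80); w80_r <- cross_at(+1, level80)
  if (!is.na(w80_l) && !is.na(w80_r)) {
    ratio <- (w80_r - w80_l) / (s_right - s_left)
    if (is.finite(ratio) && ratio > 0.70) {
      return(list(diameter_nm = NA_real_, flag = "merged"))
    }
  }
  # shoulder check: a second distinct peak above half max inside the width
  # betrays two closely parallel fibers. The dip prominence must clear the
  # profile's own noise level (estimated from first differences) so noisy
  # single fibers are not falsely flagged.
  inside <- which(s > s_left & s < s_right & !is.na(prof))
  if (length(inside) >= 5L) {
    v <- prof[inside]
    noise_sd <- stats::mad(diff(raw[!is.na(raw)])) / sqrt(2)
    prom_min <- max(4 * noise_sd, 0.04 * (prof[pk] - bg))
    locmax <- which(diff(sign(diff(v))) < 0) + 1L
    locmax <- locmax[v[locmax] > half]
    if (length(locmax) >= 2L) {
      main <- locmax[which.max(v[locmax])]
      merged <- any(vapply(setdiff(locmax, main), function(p) {
        dip <- min(v[min(p, main):max(p, main)])
        (v[p] - dip) > prom_min && abs(p - main) * step >= 2
      }, logical(1)))
      if (merged) return(list(diameter_nm = NA_real_, flag = "merged"))
    }
  }
  list(diameter_nm = (s_right - s_left) * img$pixel_size_nm, flag = "ok")
}

#' Measure local-maximum intensity and diameter for every detected fiber
#'
#' For each fiber the local intensity maximum is found near its test-line
#' crossing, the fiber axis is estimated there from the structure tensor, and
#' the FWHM diameter is measured perpendicular to the axis.
#'
#' @param img A preprocessed [clot_image()].
#' @param fibers Fiber tibble from [detect_fibers()] (rejected rows skipped).
#' @param search_radius_px Search radius for [local_max_intensity()].
#' @param max_halfwidth_px Passed to [measure_diameter()].
#' @return The fiber tibble with added columns `max_row_px`, `max_col_px`,
#'   `local_max_intensity_au`, `orientation_rad`, `diameter_nm`,
#'   `width_flag`.
#' @export
measure_fibers <- function(img, fibers, search_radius_px = 5L,
                           max_halfwidth_px = 20) {
  fb <- tibble::as_tibble(fibers)
  res <- purrr::pmap(list(fb$line_row, fb$peak_col_px, fb$status),
                     function(r, c, st) {
    if (identical(st, "rejected")) {
      return(list(max_row_px = NA_integer_, max_col_px = NA_integer_,
                  local_max_intensity_au = NA_real_,
                  orientation_rad = NA_real_,
                  diameter_nm = NA_real_, width_flag = "rejected"))
    }
    s <- min(search_radius_px,
             r, nrow(img$pixels) - 1L - r,
             c, ncol(img$pixels) - 1L - c)
    lm <- local_max_intensity(img, r, c, s)
    a <- fiber_orientation(img, lm$row_px, lm$col_px)
    d <- measure_diameter(img, lm$row_px, lm$col_px, a, max_halfwidth_px)
    list(max_row_px = lm$row_px, max_col_px = lm$col_px,
         local_max_intensity_au = lm$intensity_au,
         orientation_rad = a,
         diameter_nm = d$diameter_nm, width_flag = d$flag)
  })
  dplyr::bind_cols(fb, dplyr::bind_rows(res))
}

#' Regression of fiber diameter on fiber intensity
#'
#' Fiber diameter should be directly related to fluorescence intensity
#' (brighter fibers carry more laterally aggregated labelled monomers); a
#' significant positive slope is the standard internal consistency check of
#' an analysis run.
#'
#' @param fibers Measured fiber tibble with `diameter_nm` and
#'   `local_max_intensity_au`; at least 10 complete rows required.
#' @return Object of class `fiber_relation` wrapping the least-squares fit;
#'   supports [tidy()] and [glance()].
#' @export
diameter_intensity_relation <- function(fibers) {
  df <- dplyr::filter(tibble::as_tibble(fibers),
                      is.finite(.data$diameter_nm),
                      is.finite(.data$local_max_intensity_au))
  if (nrow(df) < 10L) {
    stop("at least 10 fibers with measured diameter and intensity required",
         call. = FALSE)
  }
  fit <- stats::lm(diameter_nm ~ local_max_intensity_au, data = df)
  sm <- suppressWarnings(summary(fit))
  structure(list(fit = fit, n = nrow(df),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = unname(sm$coefficients[2, 4]),
                 r_squared = sm$r.squared),
            class = "fiber_relation")
}

#' @export
print.fiber_relation <- function(x, ...) {
  cat(sprintf(
    "<fiber_relation> diameter ~ intensity: slope %.3f nm/au (p = %.3g), R^2 = %.3f, n = %d\n",
    x$slope, x$p_value, x$r_squared, x$n))
  invisible(x)
}

em_gmm2 <- function(x, w, mu1, s1, mu2, s2, tol = 1e-8, max_iter = 1000L) {
  n <- length(x)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(x, mu1, s1)
    d2 <- (1 - w) * stats::dnorm(x, mu2, s2)
    tot <- d1 + d2
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g <- d1 / tot
    w <- mean(g)
    if (w <= 1e-6 || w >= 1 - 1e-6) return(NULL)
    mu1 <- sum(g * x) / sum(g)
    mu2 <- sum((1 - g) * x) / sum(1 - g)
    s1 <- sqrt(sum(g * (x - mu1)^2) / sum(g))
    s2 <- sqrt(sum((1 - g) * (x - mu2)^2) / sum(1 - g))
    if (!is.finite(s1) || !is.finite(s2) || s1 < 1e-6 || s2 < 1e-6) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu1 > mu2) {
    tmp <- c(mu1, s1); mu1 <- mu2; s1 <- s2; mu2 <- tmp[1]; s2 <- tmp[2]
    w <- 1 - w
  }
  list(w = w, mu1 = mu1, sigma1 = s1, mu2 = mu2, sigma2 = s2, loglik = ll)
}

mixture_density <- function(x, p) {
  p$w * stats::dnorm(x, p$mu1, p$sigma1) +
    (1 - p$w) * stats::dnorm(x, p$mu2, p$sigma2)
}

#' Fit a normal or bimodal distribution to fiber diameters
#'
#' Diameters are first tested for normality (Shapiro-Wilk, alpha = 0.05). If
#' normality is not rejected a single Gaussian is fitted by maximum
#' likelihood. Otherwise a two-component Gaussian mixture is fitted by EM
#' (k-means initialisation plus random restarts, log-likelihood tolerance
#' 1e-8) and the interior local minimum of the fitted density between the two
#' component means — the thin/thick diameter threshold — is located by grid
#' search at 0.1 nm resolution.
#'
#' @param diameters_nm Numeric sample of fiber diameters (nm); `NA` dropped.
#' @param alpha Normality-test significance level (default 0.05).
#' @param n_restarts Random EM restarts beyond the k-means start (default 10).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param seed RNG seed for the restarts (default 1; the global RNG state is
#'   preserved).
#' @param force_bimodal Skip the normality gate and always fit the mixture.
#' @return Object of class `diameter_fit` with fields `fit_kind`
#'   (`"normal"` or `"bimodal"`), `params`, `local_min_nm` (bimodal only),
#'   `normality_p`, `loglik`, `n`. Supports [tidy()] and [glance()].
#' @export
fit_distribution <- function(diameters_nm, alpha = 0.05, n_restarts = 10L,
                             tol = 1e-8, seed = 1L, force_bimodal = FALSE) {
  x <- diameters_nm[is.finite(diameters_nm)]
  if (length(x) < 3L) stop("need at least 3 diameters", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("fit failure: degenerate sample (all diameters equal)", call. = FALSE)
  }
  sw <- stats::shapiro.test(if (length(x) > 5000) sample(x, 5000) else x)
  normality_p <- sw$p.value
  if (!force_bimodal && normality_p >= alpha) {
    params <- list(mu = mean(x), sigma = stats::sd(x))
    ll <- sum(stats::dnorm(x, params$mu, params$sigma, log = TRUE))
    return(structure(list(fit_kind = "normal", params = params,
                          local_min_nm = NA_real_,
                          normality_p = normality_p, loglik = ll,
                          n = length(x), diameters_nm = x),
                     class = "diameter_fit"))
  }
  if (length(x) < 30L) {
    stop("bimodal fitting requires at least 30 diameters", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(x, 2, nstart = 5)
  ord <- order(km$centers)
  inits <- list(list(
    w = mean(km$cluster == ord[1]),
    mu1 = min(km$centers), s1 = max(stats::sd(x[km$cluster == ord[1]]), 1),
    mu2 = max(km$centers), s2 = max(stats::sd(x[km$cluster == ord[2]]), 1)
  ))
  for (i in seq_len(n_restarts)) {
    q <- sort(stats::runif(2, 0.2, 0.8))
    inits[[i + 1L]] <- list(
      w = stats::runif(1, 0.3, 0.7),
      mu1 = stats::quantile(x, q[1], names = FALSE), s1 = stats::sd(x) / 2,
      mu2 = stats::quantile(x, q[2], names = FALSE), s2 = stats::sd(x) / 2
    )
  }
  fits <- purrr::map(inits, function(p) {
    tryCatch(em_gmm2(x, p$w, p$mu1, p$s1, p$mu2, p$s2, tol = tol),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    stop("fit failure: EM did not converge from any start (n = ", length(x),
         ", sd = ", signif(stats::sd(x), 4), ")", call. = FALSE)
  }
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  grid <- seq(best$mu1, best$mu2, by = 0.1)
  local_min <- NA_real_
  if (length(grid) > 2L) {
    dens <- mixture_density(grid, best)
    interior <- which.min(dens)
    if (interior > 1L && interior < length(grid)) {
      local_min <- grid[interior]
    }
  }
  structure(list(fit_kind = "bimodal",
                 params = best[c("w", "mu1", "sigma1", "mu2", "sigma2")],
                 local_min_nm = local_min,
                 normality_p = normality_p, loglik = best$loglik,
                 n = length(x), diameters_nm = x),
            class = "diameter_fit")
}

#' @export
print.diameter_fit <- function(x, ...) {
  if (x$fit_kind == "normal") {
    cat(sprintf("<diameter_fit> normal: mu = %.1f nm, sigma = %.1f nm (normality p = %.3g, n = %d)\n",
                x$params$mu, x$params$sigma, x$normality_p, x$n))
  } else {
    cat(sprintf(
      "<diameter_fit> bimodal: %.2f N(%.1f, %.1f) + %.2f N(%.1f, %.1f); local min %.1f nm (normality p = %.3g, n = %d)\n",
      x$params$w, x$params$mu1, x$params$sigma1,
      1 - x$params$w, x$params$mu2, x$params$sigma2,
      x$local_min_nm, x$normality_p, x$n))
  }
  invisible(x)
}

#' Plot a fitted diameter distribution
#' @param object A `diameter_fit`.
#' @param binwidth_nm Histogram bin width (default 25 nm).
#' @param ... Unused.
#' @return A ggplot: diameter histogram with fitted density and, for bimodal
#'   fits, the thin/thick threshold.
#' @export
autoplot.diameter_fit <- function(object, binwidth_nm = 25, ...) {
  df <- tibble::tibble(diameter_nm = object$diameters_nm)
  xs <- seq(min(df$diameter_nm), max(df$diameter_nm), length.out = 400)
  dens <- if (object$fit_kind == "normal") {
    stats::dnorm(xs, object$params$mu, object$params$sigma)
  } else {
    mixture_density(xs, object$params)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$diameter_nm)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth_nm, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_line(data = tibble::tibble(x = xs, y = dens),
                       ggplot2::aes(.data$x, .data$y), colour = "red") +
    ggplot2::labs(x = "fiber diameter (nm)", y = "density",
                  title = paste0(object$fit_kind, " fit"))
  if (is.finite(object$local_min_nm)) {
    p <- p + ggplot2::geom_vline(xintercept = object$local_min_nm,
                                 linetype = 2)
  }
  p
}

#' Thin-to-thick fiber ratio
#'
#' Fibers thinner than the threshold (default 761.9 nm, the interior local
#' minimum of the bimodal diameter distribution of control clots) count as
#' thin; fibers at or above it as thick. `TTR = n_thin / n_thick`, reported
#' as `Inf` (with a note) when no thick fibers exist.
#'
#' @param diameters_nm Numeric diameters (nm); `NA` dropped.
#' @param threshold_nm Thin/thick cut (default 761.9 nm).
#' @return One-row tibble: `n_thin`, `n_thick`, `threshold_nm`, `ttr`,
#'   `note`.
#' @export
compute_ttr <- function(diameters_nm, threshold_nm = 761.9) {
  x <- diameters_nm[is.finite(diameters_nm)]
  if (!length(x)) stop("need at least one diameter", call. = FALSE)
  n_thin <- sum(x < threshold_nm)
  n_thick <- sum(x >= threshold_nm)
  tibble::tibble(
    n_thin = n_thin, n_thick = n_thick, threshold_nm = threshold_nm,
    ttr = if (n_thick > 0) n_thin / n_thick else Inf,
    note = if (n_thick > 0) NA_character_ else "no thick fibers: TTR infinite"
  )
}

#' Signed percent change between two values
#'
#' `100 * (b - a) / a`; rounding is left to report time.
#'
#' @param a Reference value (nonzero).
#' @param b New value.
#' @return Signed percent change.
#' @examples
#' percent_change(2.7, 0.7) # about -74
#' @export
percent_change <- function(a, b) {
  if (any(a == 0)) stop("percent change undefined for reference 0", call. = FALSE)
  100 * (b - a) / a
}

#' @rdname tidy.diameter_fit
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy.diameter_fit
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidiers for fitted objects
#'
#' `tidy()` returns one row per parameter; `glance()` a one-row model
#' summary, in the style of broom.
#'
#' @param x A `diameter_fit` or `fiber_relation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.diameter_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @rdname tidy.diameter_fit
#' @export
glance.diameter_fit <- function(x, ...) {
  tibble::tibble(fit_kind = x$fit_kind, local_min_nm = x$local_min_nm,
                 normality_p = x$normality_p, loglik = x$loglik, n = x$n)
}

#' @rdname tidy.diameter_fit
#' @export
tidy.fiber_relation <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = sm[, 1], std_error = sm[, 2],
                 statistic = sm[, 3], p_value = sm[, 4])
}

#' @rdname tidy.diameter_fit
#' @export
glance.fiber_relation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 p_value = x$p_value, r_squared = x$r_squared, n = x$n)
}
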