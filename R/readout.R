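#' Consolidated per-clot read-out
#'
#' Assembles the standard clot parameter report from the module outputs:
#' fiber count and density, intensity (mean and CV), diameter summary (mean
#' for normal fits, median for bimodal fits, with CV), thin-to-thick ratio
#' (and its ratio to a control TTR when supplied), void area, per-fiber
#' branching and crossing rates, and cluster/agglomerate densities per mm^2.
#' Analyses not supplied are reported as `NA` with a reason in `notes`.
#'
#' @param fibers Measured fiber tibble (from [measure_fibers()]); required.
#'   An empty tibble is valid (e.g. an agglomerate-only image).
#' @param lines Test-line tibble from [make_test_lines()]; required.
#' @param field_area_um2 Imaged field area (um^2).
#' @param fit Optional [fit_distribution()] result.
#' @param ttr Optional [compute_ttr()] result.
#' @param control_ttr Optional control TTR for the vs-control ratio.
#' @param topology Optional [topology_stats()] row.
#' @param void_percent Optional void area percent.
#' @param clusters Optional [detect_clusters()] tibble.
#' @param agglomerates Optional [detect_agglomerates()] tibble.
#' @return One-row tibble of class `clot_readout`.
#' @export
build_readout <- function(fibers, lines, field_area_um2,
                          fit = NULL, ttr = NULL, control_ttr = NULL,
                          topology = NULL, void_percent = NULL,
                          clusters = NULL, agglomerates = NULL) {
  if (is.null(fibers) || is.null(lines)) {
    stop("fiber detection output is required to build a read-out",
         call. = FALSE)
  }
  fb <- dplyr::filter(tibble::as_tibble(fibers), .data$status != "rejected")
  notes <- character()
  n <- nrow(fb)
  dens <- fiber_density(fb, lines)
  has_int <- "local_max_intensity_au" %in% names(fb) &&
    any(is.finite(fb$local_max_intensity_au))
  int_mean <- if (has_int) mean(fb$local_max_intensity_au, na.rm = TRUE) else {
    notes <- c(notes, "intensity: no measured fibers"); NA_real_
  }
  int_cv <- if (has_int) {
    stats::sd(fb$local_max_intensity_au, na.rm = TRUE) / int_mean
  } else NA_real_
  diams <- if ("diameter_nm" %in% names(fb)) {
    fb$diameter_nm[is.finite(fb$diameter_nm)]
  } else numeric()
  if (length(diams)) {
    use_median <- !is.null(fit) && fit$fit_kind == "bimodal"
    diam_summary <- if (use_median) stats::median(diams) else mean(diams)
    diam_cv <- stats::sd(diams) / mean(diams)
    diam_stat <- if (use_median) "median" else "mean"
  } else {
    notes <- c(notes, "diameter: no measured fibers")
    diam_summary <- NA_real_; diam_cv <- NA_real_; diam_stat <- NA_character_
  }
  ttr_val <- if (!is.null(ttr)) ttr$ttr else {
    notes <- c(notes, "ttr: not computed"); NA_real_
  }
  ttr_ctrl <- if (!is.null(ttr) && !is.null(control_ttr) && control_ttr > 0) {
    ttr_val / control_ttr
  } else NA_real_
  xb <- xf <- NA_real_
  if (!is.null(topology)) {
    xb <- topology$xbranch_per_fiber
    xf <- topology$xfiber_per_fiber
  } else notes <- c(notes, "topology: not computed")
  if (is.null(void_percent)) {
    notes <- c(notes, "void: not computed"); void_percent <- NA_real_
  }
  mm2 <- field_area_um2 / 1e6
  cl_dens <- if (!is.null(clusters)) nrow(clusters) / mm2 else {
    notes <- c(notes, "clusters: not computed"); NA_real_
  }
  ag_dens <- if (!is.null(agglomerates)) nrow(agglomerates) / mm2 else {
    notes <- c(notes, "agglomerates: not analyzed"); NA_real_
  }
  out <- tibble::tibble(
    n_fibers = n,
    fiber_density_per_100um = dens,
    fiber_intensity_au = int_mean,
    fiber_intensity_cv = int_cv,
    diameter_nm = diam_summary,
    diameter_stat = diam_stat,
    diameter_cv = diam_cv,
    ttr = ttr_val,
    ttr_vs_control = ttr_ctrl,
    void_area_percent = void_percent,
    xbranching_per_fiber = xb,
    xfibers_per_fiber = xf,
    clusters_per_mm2 = cl_dens,
    agglomerates_per_mm2 = ag_dens,
    notes = paste(notes, collapse = "; ")
  )
  class(out) <- c("clot_readout", class(out))
  out
}

#' Full single-image analysis
#'
#' Runs the standard chain on one calibrated image: preprocess, detect
#' fibers on the test lines, measure intensities and diameters, fit the
#' diameter distribution (when enough fibers), compute the TTR and void
#' area, optionally detect clusters, and — when no spanning network exists —
#' switch to agglomerate mode. Returns all intermediates plus the read-out.
#'
#' @param img A [clot_image()] (raw; preprocessing is applied unless
#'   `preprocessed = TRUE`).
#' @param cfg [preprocess_config()].
#' @param n_lines Number of test lines (default 5).
#' @param ttr_threshold_nm Thin/thick cut (default 761.9 nm).
#' @param detect_structures Also run cluster detection (default TRUE).
#' @param control_ttr Optional control TTR for the vs-control field.
#' @param preprocessed Set TRUE if `img` is already preprocessed.
#' @return List with `image`, `lines`, `fibers`, `fit`, `ttr`, `void`,
#'   `clusters`, `agglomerates`, `mode` (`"network"` or
#'   `"agglomerate_only"`), `readout`.
#' @export
analyze_clot <- function(img, cfg = preprocess_config(), n_lines = 5L,
                         ttr_threshold_nm = 761.9, detect_structures = TRUE,
                         control_ttr = NULL, preprocessed = FALSE) {
  stopifnot(inherits(img, "clot_image"))
  if (max(img$pixels) < cfg$binarize_threshold_au && !preprocessed) {
    # nothing above the fiber threshold: an empty field. Normalizing would
    # only stretch detector noise to full range, so report an empty read-out.
    lines <- make_test_lines(img, n_lines)
    fibers <- detect_fibers(img, lines)[0, ]
    readout <- build_readout(
      fibers = fibers, lines = lines, field_area_um2 = field_area_um2(img),
      void_percent = 100, clusters = NULL,
      agglomerates = tibble::tibble(long_axis_um = numeric())[0, ])
    return(list(image = img, lines = lines, fibers = fibers, fit = NULL,
                ttr = NULL, void = 100, clusters = NULL,
                agglomerates = NULL, mode = "empty", readout = readout))
  }
  pp <- if (preprocessed) img else preprocess(img, cfg)
  lines <- make_test_lines(pp, n_lines)
  fibers <- detect_fibers(pp, lines, min_peak_au = cfg$binarize_threshold_au)
  mode <- if (has_spanning_network(pp, cfg$binarize_threshold_au)) "network"
    else "agglomerate_only"
  fit <- NULL; ttr <- NULL; clusters <- NULL; aggs <- NULL
  if (mode == "network") {
    fibers <- measure_fibers(pp, fibers)
    diams <- fibers$diameter_nm[is.finite(fibers$diameter_nm)]
    if (length(diams) >= 3L && stats::sd(diams) > 0) {
      fit <- tryCatch(fit_distribution(diams), error = function(e) NULL)
    }
    if (length(diams)) ttr <- compute_ttr(diams, ttr_threshold_nm)
    if (detect_structures) clusters <- detect_clusters(pp, ttr_threshold_nm)
  } else {
    # no spanning network: line detections are blob intercepts, not fibers
    fibers <- fibers[0, ]
    aggs <- tryCatch(detect_agglomerates(pp, cfg$binarize_threshold_au),
                     error = function(e) {
                       tibble::tibble(row_px = numeric(), col_px = numeric(),
                                      area_um2 = numeric(),
                                      long_axis_um = numeric(),
                                      aspect_ratio = numeric(),
                                      shape_class = character(),
                                      has_blunted_fibers = logical())
                     })
  }
  void_pct <- void_area(binarize(pp, cfg$binarize_threshold_au))
  readout <- build_readout(
    fibers = fibers, lines = lines, field_area_um2 = field_area_um2(pp),
    fit = fit, ttr = ttr, control_ttr = control_ttr,
    void_percent = void_pct, clusters = clusters, agglomerates = aggs
  )
  list(image = pp, lines = lines, fibers = fibers, fit = fit, ttr = ttr,
       void = void_pct, clusters = clusters, agglomerates = aggs,
       mode = mode, readout = readout)
}

#' Analyse a virtual dose series into a dose table
#'
#' Runs [analyze_clot()] on each element of a [render_dose_series()] result
#' and assembles the per-dose read-outs, with percent changes versus the
#' first (control) row computed from unrounded values.
#'
#' @param series List from [render_dose_series()].
#' @param ... Passed to [analyze_clot()].
#' @return Tibble: one row per dose with the read-out fields plus
#'   `density_change_percent` and `diameter_change_percent` versus control.
#' @export
analyze_dose_series <- function(series, ...) {
  rows <- purrr::map(series, function(el) {
    res <- analyze_clot(el$image, ...)
    out <- res$readout
    out$dose_mM <- el$dose_mM
    out$mode <- res$mode
    out
  })
  tab <- dplyr::bind_rows(rows)
  ctrl <- tab[1, ]
  tab$density_change_percent <- ifelse(
    ctrl$fiber_density_per_100um > 0,
    percent_change(ctrl$fiber_density_per_100um, tab$fiber_density_per_100um),
    NA_real_)
  tab$diameter_change_percent <- ifelse(
    rep(is.finite(ctrl$diameter_nm) && ctrl$diameter_nm > 0, nrow(tab)),
    100 * (tab$diameter_nm - ctrl$diameter_nm) / ctrl$diameter_nm,
    NA_real_)
  dplyr::relocate(tab, "dose_mM")
}

#' Linear regression of fiber density on fiber diameter
#'
#' Thicker fibers consume more fibrinogen, so across conditions density and
#' diameter should fall on a straight (descending) line; conditions with
#' abnormal structures break the relation. Rows whose standardized residual
#' exceeds 2 in absolute value are flagged as outliers.
#'
#' @param table Tibble with columns `fiber_density_per_100um` and
#'   `diameter_nm` (e.g. from [analyze_dose_series()]); at least 3 complete
#'   rows required.
#' @return Object of class `dd_regression` with the fit, `r`, `p_value`,
#'   and a `residuals` tibble flagging outliers. Supports [tidy()] and
#'   [glance()].
#' @export
density_diameter_regression <- function(table) {
  df <- dplyr::filter(tibble::as_tibble(table),
                      is.finite(.data$fiber_density_per_100um),
                      is.finite(.data$diameter_nm))
  if (nrow(df) < 3L) {
    stop("need at least 3 rows with density and diameter", call. = FALSE)
  }
  fit <- stats::lm(fiber_density_per_100um ~ diameter_nm, data = df)
  # perfectly collinear tables are legitimate input (r = -1 is the expected
  # healthy dose-response); silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  # deleted (externally studentized) residuals, computed explicitly so the
  # two degenerate cases resolve correctly: on a numerically perfect line
  # every deleted prediction error is ~0 (residual 0), while a gross
  # outlier against an otherwise perfect line gives an unbounded residual
  scale_y <- max(stats::sd(df$fiber_density_per_100um), 1e-12)
  res <- vapply(seq_len(nrow(df)), function(i) {
    f_i <- stats::lm(fiber_density_per_100um ~ diameter_nm, data = df[-i, ])
    # summary warns on numerically perfect deleted fits; that case is
    # handled explicitly below
    pred <- suppressWarnings(stats::predict(f_i, df[i, ], se.fit = TRUE))
    err <- df$fiber_density_per_100um[i] - pred$fit
    denom <- sqrt(suppressWarnings(summary(f_i))$sigma^2 + pred$se.fit^2)
    if (!is.finite(denom) || denom < 1e-8 * scale_y) {
      if (abs(err) < 1e-8 * scale_y) 0 else sign(err) * Inf
    } else {
      err / denom
    }
  }, numeric(1))
  structure(list(
    fit = fit,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(df$diameter_nm, df$fiber_density_per_100um),
    p_value = unname(sm$coefficients[2, 4]),
    n = nrow(df),
    residuals = tibble::tibble(
      row = seq_len(nrow(df)),
      diameter_nm = df$diameter_nm,
      fiber_density_per_100um = df$fiber_density_per_100um,
      std_residual = as.numeric(res),
      outlier = abs(as.numeric(res)) > 2
    )
  ), class = "dd_regression")
}

#' @export
print.dd_regression <- function(x, ...) {
  cat(sprintf(
    "<dd_regression> density ~ diameter: slope %.4f, r = %.3f (p = %.3g, n = %d); %d outlier(s)\n",
    x$slope, x$r, x$p_value, x$n, sum(x$residuals$outlier)))
  invisible(x)
}

#' @rdname tidy.diameter_fit
#' @export
tidy.dd_regression <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = sm[, 1], std_error = sm[, 2],
                 statistic = sm[, 3], p_value = sm[, 4])
}

#' @rdname tidy.diameter_fit
#' @export
glance.dd_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 p_value = x$p_value, n = x$n,
                 n_outliers = sum(x$residuals$outlier))
}

#' Plot a dose-series read-out table
#'
#' @param table Tibble from [analyze_dose_series()].
#' @return A ggplot of density, diameter and void area against dose.
#' @export
plot_dose_series <- function(table) {
  long <- tidyr::pivot_longer(
    dplyr::select(table, "dose_mM", "fiber_density_per_100um",
                  "diameter_nm", "void_area_percent"),
    -"dose_mM", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$dose_mM, .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "dose (mM)", y = NULL)
}

#' Run the full pipeline from a configuration and write artifacts
#'
#' Stages: synth (optional) -> detect -> measure -> fitdist/ttr -> void ->
#' structures -> readout. Every intermediate is written to `out_dir`
#' (fibers.csv, metrics.csv, void.json, structures.json, readout.json). A
#' failed stage is recorded in the returned log and downstream stages are
#' skipped with a reason.
#'
#' @param config List (or path to a YAML file) with fields: either `image`
#'   (TIFF path) plus `pixel_size_nm`, or `scene` (a list of [scene_spec()]
#'   arguments); optional `out_dir` (default `"."`), `n_lines`,
#'   `ttr_threshold_nm`, `threshold_au`.
#' @return Invisibly, a list with the analysis results, the paths written,
#'   and a `log` tibble of stage outcomes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$image) && is.null(config$scene)) {
    stop("config must name either `image` (a TIFF path) or `scene` ",
         "(generator parameters)", call. = FALSE)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, status, detail = "") {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage, status = status,
                                               detail = detail)
  }
  img <- if (!is.null(config$image)) {
    if (is.null(config$pixel_size_nm)) {
      stop("config field `pixel_size_nm` is required with `image`",
           call. = FALSE)
    }
    note("load", "ok", config$image)
    read_clot_tiff(config$image, config$pixel_size_nm)
  } else {
    spec <- do.call(scene_spec, config$scene)
    note("synth", "ok", sprintf("seed %d", spec$seed))
    render_scene(spec)$image
  }
  res <- tryCatch(
    analyze_clot(img,
                 n_lines = config$n_lines %||% 5L,
                 ttr_threshold_nm = config$ttr_threshold_nm %||% 761.9),
    error = function(e) e)
  if (inherits(res, "error")) {
    note("analyze", "failed", conditionMessage(res))
    return(invisible(list(log = dplyr::bind_rows(log))))
  }
  note("analyze", "ok", sprintf("%d fibers, mode %s", nrow(res$fibers),
                                res$mode))
  paths <- character()
  wr <- function(obj, file, writer) {
    p <- file.path(out_dir, file)
    writer(obj, p)
    paths[[length(paths) + 1L]] <<- p
  }
  wr(res$fibers[, intersect(c("id", "line_row", "peak_col_px",
                              "peak_intensity_au", "status"),
                            names(res$fibers))],
     "fibers.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(res$fibers, "metrics.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(list(void_area_percent = res$void), "void.json",
     function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
  wr(list(clusters = res$clusters, agglomerates = res$agglomerates),
     "structures.json",
     function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
  wr(res$readout, "readout.json",
     function(o, p) jsonlite::write_json(as.list(res$readout), p,
                                         auto_unbox = TRUE, digits = NA))
  note("write", "ok", paste(basename(paths), collapse = ", "))
  invisible(c(res, list(paths = paths, log = dplyr::bind_rows(log))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
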