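#' Build equally spaced horizontal test lines
#'
#' Fibers in a fibrin network are randomly oriented, so equally spaced
#' horizontal lines sample them without orientation bias (stereological
#' test-line counting). Rows are placed at `floor(height * k / (n + 1))` for
#' `k = 1..n` (0-based), which for a 1024-row image and the default 5 lines
#' gives rows 170, 341, 512, 682 and 853.
#'
#' @param img A [clot_image()].
#' @param n_lines Number of lines (default 5); must satisfy
#'   `1 <= n_lines < height`.
#' @return Tibble with one row per line: `row_index` (0-based pixel row),
#'   `length_px`, `length_um`.
#' @export
make_test_lines <- function(img, n_lines = 5L) {
  stopifnot(inherits(img, "clot_image"))
  h <- nrow(img$pixels)
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 1L ||
      n_lines >= h) {
    stop("`n_lines` must satisfy 1 <= n_lines < image height", call. = FALSE)
  }
  n_lines <- as.integer(n_lines)
  w <- ncol(img$pixels)
  tibble::tibble(
    row_index = as.integer(floor(h * seq_len(n_lines) / (n_lines + 1L))),
    length_px = w,
    length_um = w * img$pixel_size_nm / 1000
  )
}

#' Extract the intensity profile along a test line
#'
#' @param img A [clot_image()].
#' @param row_index 0-based pixel row of the line.
#' @return Numeric vector of length `width_px`: the image row's intensities.
#' @export
extract_profile <- function(img, row_index) {
  stopifnot(inherits(img, "clot_image"))
  h <- nrow(img$pixels)
  if (row_index < 0 || row_index >= h) {
    stop("`row_index` outside image (0-based)", call. = FALSE)
  }
  img$pixels[row_index + 1L, ]
}

moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  c(x[1], (x[-c(1, n)] + x[-c(n - 1, n)] + x[-c(1, 2)]) / 3, x[n])
}

#' Detect fibers along one intensity profile
#'
#' Peaks are local maxima of the 3-px moving-average-smoothed profile where
#' the first derivative changes sign from positive to negative and the peak
#' intensity reaches `min_peak_au`. Peaks closer than `min_separation_px`
#' are merged to the higher one. Fibers are numbered left to right.
#'
#' @param profile Numeric intensity profile (au per column).
#' @param min_peak_au Minimum peak intensity (default 27 au, the binarization
#'   threshold).
#' @param min_separation_px Minimum distance between distinct fibers
#'   (default 5 px, about 290 nm at 57.6 nm/px — below the thinnest fibers).
#' @param min_prominence_au Minimum peak prominence (rise above the higher of
#'   the valleys separating the peak from higher terrain). `NULL` (default)
#'   estimates it from the profile's own noise level (first differences), so
#'   ripple on top of a wide fiber plateau is not split into spurious fibers;
#'   clean constructed profiles are unaffected.
#' @return Tibble with `id`, `peak_col_px` (0-based column) and
#'   `peak_intensity_au` (unsmoothed profile value at the peak).
#' @export
detect_fibers_on_line <- function(profile, min_peak_au = 27,
                                  min_separation_px = 5L,
                                  min_prominence_au = NULL) {
  if (!is.numeric(profile) || length(profile) == 0L) {
    stop("`profile` must be a non-empty numeric vector", call. = FALSE)
  }
  empty <- tibble::tibble(id = integer(), peak_col_px = integer(),
                          peak_intensity_au = numeric())
  if (length(profile) < 3L) return(empty)
  sm <- moving_average3(profile)
  d1 <- diff(sm)
  # + to - sign change of the first derivative; plateaus (d1 == 0) belong to
  # the rising side so flat-topped peaks resolve to their last plateau pixel
  sgn <- sign(d1)
  nz <- sgn != 0
  carried <- sgn
  last <- 0
  for (i in seq_along(carried)) {
    if (carried[i] == 0) carried[i] <- last else last <- carried[i]
  }
  peak_at <- which(carried[-length(carried)] > 0 & carried[-1] < 0) + 1L
  peak_at <- peak_at[sm[peak_at] >= min_peak_au & profile[peak_at] >= min_peak_au]
  if (!length(peak_at)) return(empty)
  if (is.null(min_prominence_au)) {
    min_prominence_au <- min(4 * stats::mad(diff(profile)) / sqrt(2),
                             min_peak_au)
  }
  if (min_prominence_au > 0) {
    prom <- vapply(peak_at, function(p) {
      v <- sm[p]
      side <- function(idx) {
        higher <- idx[sm[idx] > v]
        stop_at <- if (length(higher)) higher[1] else idx[length(idx)]
        span <- idx[seq_len(match(stop_at, idx))]
        min(sm[span])
      }
      left <- if (p > 1L) side(seq(p - 1L, 1L)) else v
      right <- if (p < length(sm)) side(seq(p + 1L, length(sm))) else v
      v - max(left, right)
    }, numeric(1))
    peak_at <- peak_at[prom >= min_prominence_au]
    if (!length(peak_at)) return(empty)
  }
  # merge close peaks to the higher one
  keep <- peak_at
  repeat {
    gaps <- diff(keep)
    too_close <- which(gaps < min_separation_px)
    if (!length(too_close)) break
    i <- too_close[1]
    drop <- if (sm[keep[i]] >= sm[keep[i + 1]]) i + 1L else i
    keep <- keep[-drop]
  }
  tibble::tibble(
    id = seq_along(keep),
    peak_col_px = keep - 1L,
    peak_intensity_au = profile[keep]
  )
}

#' Detect and number fibers across all test lines of an image
#'
#' Runs [detect_fibers_on_line()] on every test line and assigns ids unique
#' across the whole analysis. A fiber crossing several test lines is counted
#' once per line: the density estimate is per-test-line sampling, not a
#' per-object census.
#'
#' @param img A preprocessed [clot_image()].
#' @param lines Tibble from [make_test_lines()]; built with defaults if
#'   omitted.
#' @param min_peak_au,min_separation_px Passed to [detect_fibers_on_line()].
#' @return Tibble of fibers: `id`, `line_row` (0-based), `peak_col_px`,
#'   `peak_intensity_au`, `status` (`"auto"`).
#' @export
detect_fibers <- function(img, lines = make_test_lines(img),
                          min_peak_au = 27, min_separation_px = 5L) {
  stopifnot(inherits(img, "clot_image"))
  per_line <- purrr::map(lines$row_index, function(r) {
    hits <- detect_fibers_on_line(extract_profile(img, r),
                                  min_peak_au, min_separation_px)
    hits$line_row <- r
    hits
  })
  out <- dplyr::bind_rows(per_line)
  if (!nrow(out)) {
    return(tibble::tibble(id = integer(), line_row = integer(),
                          peak_col_px = integer(),
                          peak_intensity_au = numeric(),
                          status = character()))
  }
  out$id <- seq_len(nrow(out))
  out$status <- "auto"
  out[, c("id", "line_row", "peak_col_px", "peak_intensity_au", "status")]
}

#' Fiber density in fibers per 100 um of test line
#'
#' @param fibers Fiber tibble (e.g. from [detect_fibers()]); rows with
#'   `status == "rejected"` are excluded.
#' @param lines Test-line tibble from [make_test_lines()].
#' @return Scalar density, fibers/100 um.
#' @export
fiber_density <- function(fibers, lines) {
  if (is.null(lines) || !nrow(lines)) {
    stop("at least one test line is required", call. = FALSE)
  }
  total_um <- sum(lines$length_um)
  if (total_um <= 0) stop("total test-line length must be positive", call. = FALSE)
  n <- if ("status" %in% names(fibers)) {
    sum(fibers$status != "rejected")
  } else {
    nrow(fibers)
  }
  n / total_um * 100
}

#' Apply reviewer edits to detected fibers and audit detection
#'
#' Automated detection is audited by an editor: confirmed detections are true
#' positives, rejected ones false positives, and manually added fibers false
#' negatives. The positive predictive value is
#' `PPV (%) = 100 * TP / (TP + FP)`, reported as `NA` when no automatic
#' detections exist.
#'
#' @param fibers Fiber tibble from [detect_fibers()].
#' @param edits Tibble/data frame with columns `action`
#'   (`"confirm"`, `"reject"` or `"add"`), `id` (for confirm/reject) and, for
#'   adds, `line_row` and `peak_col_px`. Unedited fibers keep status
#'   `"auto"` and count as confirmed.
#' @return List with `fibers` (post-edit tibble; rejected rows retained with
#'   status `"rejected"`) and `audit` (one-row tibble: `true_pos`,
#'   `false_pos`, `false_neg`, `ppv_percent`).
#' @export
edit_fibers <- function(fibers, edits) {
  edits <- tibble::as_tibble(edits)
  stopifnot("action" %in% names(edits))
  fb <- tibble::as_tibble(fibers)
  for (i in seq_len(nrow(edits))) {
    act <- edits$action[i]
    if (act %in% c("confirm", "reject")) {
      j <- match(edits$id[i], fb$id)
      if (is.na(j)) {
        stop("edit references unknown fiber id ", edits$id[i], call. = FALSE)
      }
      fb$status[j] <- if (act == "confirm") "confirmed" else "rejected"
    } else if (act == "add") {
      new_id <- if (nrow(fb)) max(fb$id) + 1L else 1L
      fb <- dplyr::bind_rows(fb, tibble::tibble(
        id = new_id,
        line_row = as.integer(edits$line_row[i]),
        peak_col_px = as.integer(edits$peak_col_px[i]),
        peak_intensity_au = if ("peak_intensity_au" %in% names(edits)) {
          edits$peak_intensity_au[i]
        } else NA_real_,
        status = "added"
      ))
    } else {
      stop("unknown edit action '", act, "'", call. = FALSE)
    }
  }
  tp <- sum(fb$status %in% c("confirmed", "auto"))
  fp <- sum(fb$status == "rejected")
  fn <- sum(fb$status == "added")
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  list(
    fibers = fb,
    audit = tibble::tibble(true_pos = tp, false_pos = fp, false_neg = fn,
                           ppv_percent = ppv)
  )
}

#' Plot a test-line intensity profile with detected fibers
#'
#' @param img A [clot_image()].
#' @param row_index 0-based row of the test line.
#' @param fibers Optional fiber tibble; detections on this line are marked.
#' @param min_peak_au Detection threshold drawn as a horizontal reference.
#' @return A ggplot object.
#' @export
plot_line_profile <- function(img, row_index, fibers = NULL,
                              min_peak_au = 27) {
  prof <- extract_profile(img, row_index)
  df <- tibble::tibble(col = seq_along(prof) - 1L, intensity = prof)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = min_peak_au, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "column (px)", y = "intensity (au)",
                  title = sprintf("test line at row %d", row_index))
  if (!is.null(fibers)) {
    hits <- dplyr::filter(fibers, .data$line_row == row_index,
                          .data$status != "rejected")
    if (nrow(hits)) {
      p <- p + ggplot2::geom_point(
        data = tibble::tibble(col = hits$peak_col_px,
                              intensity = hits$peak_intensity_au),
        colour = "red"
      )
    }
  }
  p
}
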