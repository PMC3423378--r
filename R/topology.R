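#' Trace a fiber axis through the image
#'
#' Steepest-ridge following from a start point: from the starting position
#' the tracer steps 1 px along the local fiber axis in both directions,
#' re-centring on the perpendicular intensity maximum at each step and
#' re-estimating the axis orientation every 5 steps. Tracing stops at the
#' image border, when intensity falls below `min_intensity_au`, or after
#' `max_steps` steps per direction.
#'
#' @param img A [clot_image()].
#' @param row_px,col_px 0-based start position (fiber local maximum).
#' @param orientation_rad Initial axis angle; estimated if `NULL`.
#' @param max_steps Maximum steps in each direction (default 200).
#' @param min_intensity_au Stop threshold (default 27 au).
#' @return Tibble ordered along the fiber: `s_px` (signed arc position),
#'   `row_px`, `col_px` (fractional), `intensity_au`. The start point is at
#'   `s_px = 0`.
#' @export
trace_fiber <- function(img, row_px, col_px, orientation_rad = NULL,
                        max_steps = 200L, min_intensity_au = 27) {
  stopifnot(inherits(img, "clot_image"))
  m <- img$pixels
  if (is.null(orientation_rad)) {
    orientation_rad <- fiber_orientation(img, row_px, col_px)
  }
  walk <- function(sign_dir) {
    a <- orientation_rad
    pos <- c(row_px, col_px)
    out <- vector("list", max_steps)
    for (k in seq_len(max_steps)) {
      dirv <- c(sin(a), cos(a)) * sign_dir
      cand <- pos + dirv
      # re-centre on the perpendicular ridge maximum
      perp <- c(cos(a), -sin(a))
      offs <- seq(-1, 1, by = 0.5)
      rr <- cand[1] + offs * perp[1]
      cc <- cand[2] + offs * perp[2]
      v <- sample_bilinear(m, rr, cc)
      if (all(is.na(v))) break
      b <- which.max(v)
      cand <- c(rr[b], cc[b])
      val <- v[b]
      if (is.na(val) || val < min_intensity_au) break
      pos <- cand
      out[[k]] <- c(k, pos, val)
      if (k %% 5L == 0L) {
        a_new <- fiber_orientation(img, round(pos[1]), round(pos[2]))
        # keep heading continuity: flip if the new axis points backwards
        if (cos(a_new - a) < 0) a_new <- a_new + pi
        a <- a_new
      }
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  fwd <- walk(+1)
  bwd <- walk(-1)
  rows <- rbind(
    if (!is.null(bwd)) cbind(-bwd[rev(seq_len(nrow(bwd))), 1, drop = FALSE],
                             bwd[rev(seq_len(nrow(bwd))), -1, drop = FALSE]),
    c(0, row_px, col_px, sample_bilinear(m, row_px, col_px)),
    fwd
  )
  tibble::tibble(s_px = rows[, 1], row_px = rows[, 2], col_px = rows[, 3],
                 intensity_au = rows[, 4])
}

#' Find candidate fiber-fiber meeting points
#'
#' Each measured fiber is traced along its axis; positions where the traced
#' intensity exceeds the fiber's own baseline (median along the trace) by
#' more than `rel_increase` are candidate meetings. A candidate is paired
#' with another fiber when that fiber's trace passes within `pair_radius_px`.
#'
#' @param img A preprocessed [clot_image()].
#' @param fibers Measured fiber tibble (from [measure_fibers()]); only rows
#'   with `width_flag == "ok"` are traced.
#' @param rel_increase Fractional intensity excess defining a candidate
#'   (default 0.40).
#' @param pair_radius_px Pairing distance (default 3 px).
#' @param ... Passed to [trace_fiber()].
#' @return Tibble of candidates: `fiber_id`, `row_px`, `col_px`,
#'   `intensity_au`, `baseline_au`, `partner_id` (`NA` when no second trace
#'   passes nearby).
#' @export
candidate_meetings <- function(img, fibers, rel_increase = 0.40,
                               pair_radius_px = 3, ...) {
  fb <- dplyr::filter(tibble::as_tibble(fibers), .data$width_flag == "ok")
  if (!nrow(fb)) {
    return(tibble::tibble(fiber_id = integer(), row_px = numeric(),
                          col_px = numeric(), intensity_au = numeric(),
                          baseline_au = numeric(), partner_id = integer()))
  }
  traces <- purrr::pmap(list(fb$max_row_px, fb$max_col_px, fb$orientation_rad),
                        function(r, c, a) trace_fiber(img, r, c, a, ...))
  names(traces) <- as.character(fb$id)
  cands <- purrr::imap(traces, function(tr, fid) {
    baseline <- stats::median(tr$intensity_au)
    if (baseline <= 0) return(NULL)
    hot <- tr$intensity_au > baseline * (1 + rel_increase)
    if (!any(hot)) return(NULL)
    # one candidate per contiguous hot run: its brightest point
    runs <- rle(hot)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hits <- purrr::map2(starts[runs$values], ends[runs$values], function(a, b) {
      i <- (a:b)[which.max(tr$intensity_au[a:b])]
      tibble::tibble(fiber_id = as.integer(fid), row_px = tr$row_px[i],
                     col_px = tr$col_px[i], intensity_au = tr$intensity_au[i],
                     baseline_au = baseline)
    })
    dplyr::bind_rows(hits)
  })
  cands <- dplyr::bind_rows(cands)
  if (!nrow(cands)) {
    return(tibble::tibble(fiber_id = integer(), row_px = numeric(),
                          col_px = numeric(), intensity_au = numeric(),
                          baseline_au = numeric(), partner_id = integer()))
  }
  cands$partner_id <- purrr::pmap_int(
    list(cands$fiber_id, cands$row_px, cands$col_px),
    function(fid, r, c) {
      for (other in setdiff(names(traces), as.character(fid))) {
        tr <- traces[[other]]
        if (any((tr$row_px - r)^2 + (tr$col_px - c)^2 <= pair_radius_px^2)) {
          return(as.integer(other))
        }
      }
      NA_integer_
    })
  cands
}

#' Classify a three-way fiber meeting by width conservation
#'
#' At a trifunctional branch junction the widest fiber splits into the other
#' two, so its width approximately equals their sum (F1 = F2 + F3). The
#' residual `|F1 - (F2 + F3)| / F1` (F1 the widest) must not exceed
#' `tolerance` for a branch call. Permutation-invariant in the three widths.
#'
#' @param widths_nm Numeric vector of three positive widths (nm).
#' @param tolerance Relative residual tolerance (default 0.15).
#' @return List with `call` (`"branch"` or `"not_branch"`) and `residual`.
#' @examples
#' classify_branch(c(700, 400, 300)) # exact conservation: branch
#' @export
classify_branch <- function(widths_nm, tolerance = 0.15) {
  if (length(widths_nm) != 3L || any(!is.finite(widths_nm)) ||
      any(widths_nm <= 0)) {
    stop("`widths_nm` must be three positive finite widths", call. = FALSE)
  }
  f1 <- max(widths_nm)
  rest <- sum(widths_nm) - f1
  residual <- abs(f1 - rest) / f1
  list(call = if (residual <= tolerance) "branch" else "not_branch",
       residual = residual)
}

#' Classify a two-fiber meeting as contact or pass-over
#'
#' Fluorophore content is additive where fibers touch, so a true contact
#' shows a proportional intensity increase greater than 40% on *both* fibers
#' relative to their own baselines; otherwise one fiber is simply passing
#' above or below the other. Baselines are the median along-fiber intensity
#' excluding a 7 px window around the meeting point. The rule is
#' scale-invariant: multiplying a profile by any c > 0 leaves the call
#' unchanged. The comparison is strict (an increase of exactly 40% is a
#' pass-over).
#'
#' @param profile_a,profile_b Along-fiber intensity profiles (au per px).
#' @param meeting_index Index of the meeting point in each profile (1-based);
#'   a length-2 vector gives per-profile indices.
#' @param threshold Fractional increase required on both fibers
#'   (default 0.40).
#' @param exclude_halfwidth_px Half-width of the window excluded from the
#'   baseline (default 3, i.e. a 7 px window).
#' @return One-row tibble: `rel_increase_a`, `rel_increase_b`, `kind`
#'   (`"contact"` or `"pass_over"`).
#' @export
classify_crossing <- function(profile_a, profile_b, meeting_index,
                              threshold = 0.40, exclude_halfwidth_px = 3L) {
  idx <- if (length(meeting_index) == 2L) meeting_index else
    rep(meeting_index, 2L)
  one <- function(prof, i) {
    if (i < 1L || i > length(prof)) {
      stop("meeting index outside profile", call. = FALSE)
    }
    keep <- setdiff(seq_along(prof),
                    max(1L, i - exclude_halfwidth_px):
                    min(length(prof), i + exclude_halfwidth_px))
    if (length(keep) < 10L) {
      stop("need at least 10 px of off-meeting baseline", call. = FALSE)
    }
    baseline <- stats::median(prof[keep])
    if (baseline <= 0) {
      stop("degenerate profile: baseline <= 0", call. = FALSE)
    }
    (prof[i] - baseline) / baseline
  }
  ra <- one(profile_a, idx[1])
  rb <- one(profile_b, idx[2])
  tibble::tibble(
    rel_increase_a = ra, rel_increase_b = rb,
    kind = if (ra > threshold && rb > threshold) "contact" else "pass_over"
  )
}

#' Summarise network topology counts into densities and ratios
#'
#' @param junctions Branch-junction tibble (or a count).
#' @param contacts Crossing-contact tibble (or a count); rows with
#'   `kind == "pass_over"` are excluded when a `kind` column exists.
#' @param fibers Fiber tibble (or a count); rejected rows excluded.
#' @param field_area_um2 Imaged field area (um^2); the classic multiphoton
#'   field is 59 x 59 = 3481 um^2.
#' @return One-row tibble with counts, per-field and per-mm^2 densities,
#'   per-fiber ratios and the fiber/branch and fiber/crossing count ratios
#'   (`NA` where the denominator is zero).
#' @export
topology_stats <- function(junctions, contacts, fibers, field_area_um2) {
  if (!is.numeric(field_area_um2) || field_area_um2 <= 0) {
    stop("`field_area_um2` must be positive", call. = FALSE)
  }
  count_of <- function(x, filter_col = NULL, drop = NULL) {
    if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
    x <- tibble::as_tibble(x)
    if (!is.null(filter_col) && filter_col %in% names(x)) {
      return(sum(x[[filter_col]] != drop))
    }
    nrow(x)
  }
  n_j <- count_of(junctions)
  n_c <- count_of(contacts, "kind", "pass_over")
  n_f <- count_of(fibers, "status", "rejected")
  mm2 <- field_area_um2 / 1e6
  tibble::tibble(
    n_fibers = n_f, n_junctions = n_j, n_contacts = n_c,
    xbranch_per_field = n_j, xfiber_per_field = n_c,
    xbranch_per_mm2 = n_j / mm2, xfiber_per_mm2 = n_c / mm2,
    xbranch_per_fiber = if (n_f > 0) n_j / n_f else NA_real_,
    xfiber_per_fiber = if (n_f > 0) n_c / n_f else NA_real_,
    density_branch_ratio = if (n_j > 0) n_f / n_j else NA_real_,
    density_crossing_ratio = if (n_c > 0) n_f / n_c else NA_real_
  )
}
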