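#' Calibrated clot image container
#'
#' A `clot_image` wraps a 2D intensity raster (arbitrary units, au) together
#' with its physical pixel-size calibration. Multiphoton acquisitions of
#' fibrin networks are typically 1024 x 1024 pixels over a 59 x 59 um^2 field
#' (about 57.6 nm/pixel), 8-bit depth; any single-channel grayscale raster of
#' at least 64 x 64 pixels is accepted.
#'
#' Pixel coordinates are row-major and 0-based throughout the package: the
#' top-left pixel is (row 0, col 0) and the physical position of a pixel
#' centre is `index * pixel_size_nm`.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities; rows are
#'   image rows (y), columns are image columns (x).
#' @param pixel_size_nm Physical edge length of one pixel in nanometres.
#' @param z_position_um Optional slice height above the clot surface (um).
#' @param label Free-text identifier (e.g. a treatment dose).
#' @return An object of class `clot_image`.
#' @examples
#' img <- clot_image(matrix(0, 64, 64), pixel_size_nm = 57.6)
#' dim(img)
#' @export
clot_image <- function(pixels, pixel_size_nm, z_position_um = NA_real_,
                       label = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 64L || ncol(pixels) < 64L) {
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = unname(pixels), pixel_size_nm = as.numeric(pixel_size_nm),
         z_position_um = as.numeric(z_position_um), label = as.character(label)),
    class = "clot_image"
  )
}

#' @export
dim.clot_image <- function(x) dim(x$pixels)

#' @export
print.clot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<clot_image> %d x %d px, %.1f nm/px (%.1f x %.1f um field)%s%s\n",
    d[2], d[1], x$pixel_size_nm,
    d[2] * x$pixel_size_nm / 1000, d[1] * x$pixel_size_nm / 1000,
    if (is.finite(x$z_position_um)) sprintf(", z = %g um", x$z_position_um) else "",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  cat(sprintf("  intensity range %.1f-%.1f au\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Field area of a clot image in square micrometres
#' @param img A [clot_image()].
#' @return Scalar area in um^2.
#' @export
field_area_um2 <- function(img) {
  stopifnot(inherits(img, "clot_image"))
  d <- dim(img$pixels)
  prod(d) * (img$pixel_size_nm / 1000)^2
}

#' Ordered stack of clot image slices
#'
#' Bundles co-registered slices acquired at increasing heights above the clot
#' surface (optical sectioning at regular intervals, e.g. every 10 um).
#'
#' @param slices List of [clot_image()] objects sharing dimensions and pixel
#'   size, with strictly increasing `z_position_um`.
#' @param slice_spacing_um Vertical spacing between consecutive slices (um).
#' @return An object of class `clot_stack`.
#' @export
clot_stack <- function(slices, slice_spacing_um = NA_real_) {
  if (!length(slices) || !all(vapply(slices, inherits, TRUE, "clot_image"))) {
    stop("`slices` must be a non-empty list of clot_image objects", call. = FALSE)
  }
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (length(slices) > 1L) {
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("all slices must share dimensions", call. = FALSE)
    }
    px <- vapply(slices, `[[`, numeric(1), "pixel_size_nm")
    if (any(abs(px - px[1]) > 1e-9)) {
      stop("all slices must share pixel_size_nm", call. = FALSE)
    }
    z <- vapply(slices, `[[`, numeric(1), "z_position_um")
    if (all(is.finite(z)) && any(diff(z) <= 0)) {
      stop("slice z positions must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(slices = slices,
                 slice_spacing_um = as.numeric(slice_spacing_um)),
            class = "clot_stack")
}

#' @export
length.clot_stack <- function(x) length(x$slices)

#' @export
print.clot_stack <- function(x, ...) {
  cat(sprintf("<clot_stack> %d slices, spacing %g um\n",
              length(x$slices), x$slice_spacing_um))
  invisible(x)
}

#' Read a clot image or stack from a TIFF file
#'
#' Single-page grayscale TIFFs load as a [clot_image()]; multi-page files
#' load as a [clot_stack()] with slices placed at
#' `z = 0, spacing, 2*spacing, ...` um. RGB / multi-channel input is rejected:
#' fibrin fluorescence images are single-channel.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_nm Pixel calibration (nm per pixel edge).
#' @param slice_spacing_um Slice spacing for multi-page files (um).
#' @param label Identifier attached to the image(s).
#' @return A `clot_image` or `clot_stack`.
#' @export
read_clot_tiff <- function(path, pixel_size_nm, slice_spacing_um = 10,
                           label = "") {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': file does not exist", call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop("cannot decode '", path, "' as TIFF: ",
                           conditionMessage(e), call. = FALSE)
                    })
  to_img <- function(arr, z) {
    if (length(dim(arr)) == 3L) {
      stop("multi-channel (", dim(arr)[3],
           "-channel) input is not supported; supply a single-channel ",
           "grayscale image", call. = FALSE)
    }
    clot_image(arr, pixel_size_nm, z_position_um = z, label = label)
  }
  if (length(pages) == 1L) return(to_img(pages[[1]], NA_real_))
  slices <- purrr::imap(pages, function(p, i) {
    to_img(p, (i - 1) * slice_spacing_um)
  })
  clot_stack(slices, slice_spacing_um)
}

#' Write a clot image or binary mask as an 8-bit TIFF
#'
#' Intensities are clamped to 0-255 au and written at 8-bit depth, so a
#' write/read round trip of integer-valued 8-bit data is bit-exact. Logical
#' masks are encoded as 0/255.
#'
#' @param img A [clot_image()] or logical matrix mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clot_tiff <- function(img, path) {
  m <- if (inherits(img, "clot_image")) img$pixels else img
  if (is.logical(m)) m <- m * 255
  m <- pmin(pmax(m, 0), 255)
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Preprocessing configuration
#'
#' Every image in an analysis receives the same background-subtraction,
#' normalization and thresholding chain. The background default is the modal
#' intensity of the image — fibrin micrographs are mostly dark void, so the
#' mode estimates the camera offset; a rolling-percentile estimator is
#' available for uneven illumination. Normalization rescales the maximum to a
#' fixed 0-255 au range so the binarization threshold (default 27 au, the
#' standard fiber/void cut for 8-bit clot images) is comparable across inputs.
#'
#' @param background_mode `"constant"` (modal intensity) or
#'   `"rolling_percentile"` (blockwise low-percentile surface, bilinearly
#'   interpolated).
#' @param normalize_to Target maximum intensity after rescaling (au).
#' @param binarize_threshold_au Global fiber/void threshold (au); must lie in
#'   `(0, normalize_to)`.
#' @param percentile Percentile for the rolling estimator (0-1).
#' @param block_px Block edge for the rolling estimator (pixels).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(background_mode = c("constant", "rolling_percentile"),
                              normalize_to = 255,
                              binarize_threshold_au = 27,
                              percentile = 0.1,
                              block_px = 64L) {
  background_mode <- match.arg(background_mode)
  if (binarize_threshold_au <= 0 || binarize_threshold_au >= normalize_to) {
    stop("`binarize_threshold_au` must lie in (0, normalize_to)", call. = FALSE)
  }
  structure(list(background_mode = background_mode,
                 normalize_to = normalize_to,
                 binarize_threshold_au = binarize_threshold_au,
                 percentile = percentile, block_px = as.integer(block_px)),
            class = "preprocess_config")
}

modal_intensity <- function(m) {
  tb <- tabulate(as.integer(round(m)) + 1L)
  which.max(tb) - 1L
}

rolling_percentile_background <- function(m, p, block) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- unique(c(seq(1L, nr, by = block), nr))
  ci <- unique(c(seq(1L, nc, by = block), nc))
  # low percentile in block-centred windows on a coarse grid, then
  # separable linear interpolation back to full resolution
  grid <- matrix(0, length(ri), length(ci))
  for (i in seq_along(ri)) {
    rr <- max(1L, ri[i] - block %/% 2):min(nr, ri[i] + block %/% 2)
    for (j in seq_along(ci)) {
      cc <- max(1L, ci[j] - block %/% 2):min(nc, ci[j] + block %/% 2)
      grid[i, j] <- stats::quantile(m[rr, cc], p, names = FALSE)
    }
  }
  if (length(ci) == 1L) {
    tmp <- matrix(grid[, 1], length(ri), nc)
  } else {
    tmp <- t(apply(grid, 1, function(v) {
      stats::approx(ci, v, xout = seq_len(nc), rule = 2)$y
    }))
  }
  if (length(ri) == 1L) {
    matrix(tmp[1, ], nr, nc, byrow = TRUE)
  } else {
    apply(tmp, 2, function(v) {
      stats::approx(ri, v, xout = seq_len(nr), rule = 2)$y
    })
  }
}

#' Preprocess a clot image
#'
#' Subtracts the background estimate (clipping at 0) and rescales so the image
#' maximum equals `cfg$normalize_to`. Deterministic for fixed configuration;
#' never changes image dimensions. Already-normalized, background-free images
#' pass through unchanged (idempotence).
#'
#' @param img A [clot_image()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed `clot_image`.
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "clot_image"), inherits(cfg, "preprocess_config"))
  m <- img$pixels
  bg <- switch(cfg$background_mode,
    constant = modal_intensity(m),
    rolling_percentile = rolling_percentile_background(m, cfg$percentile,
                                                       cfg$block_px)
  )
  m <- pmax(m - bg, 0)
  mx <- max(m)
  if (mx <= 0) {
    stop("degenerate image: all intensities equal the background estimate; ",
         "cannot normalize", call. = FALSE)
  }
  out <- img
  out$pixels <- m * (cfg$normalize_to / mx)
  out
}

#' Binarize a preprocessed clot image
#'
#' White (`TRUE`) pixels are fibers, black (`FALSE`) pixels empty space. The
#' comparison is inclusive: a pixel exactly at the threshold is fiber.
#'
#' @param img A [clot_image()] (or bare numeric matrix).
#' @param threshold_au Global intensity threshold in au (default 27).
#' @return Logical matrix of the same dimensions, attribute `pixel_size_nm`
#'   carried over when available.
#' @export
binarize <- function(img, threshold_au = 27) {
  stopifnot(is.numeric(threshold_au), length(threshold_au) == 1L)
  m <- if (inherits(img, "clot_image")) img$pixels else img
  mask <- m >= threshold_au
  if (inherits(img, "clot_image")) {
    attr(mask, "pixel_size_nm") <- img$pixel_size_nm
  }
  mask
}

#' Display a clot image with ggplot2
#'
#' @param object A [clot_image()].
#' @param ... Unused.
#' @return A ggplot raster of intensity with physical axes in um.
#' @export
autoplot.clot_image <- function(object, ...) {
  d <- dim(object$pixels)
  df <- tidyr::expand_grid(row = seq_len(d[1]) - 1L, col = seq_len(d[2]) - 1L)
  df$intensity <- as.vector(t(object$pixels))
  df$x_um <- df$col * object$pixel_size_nm / 1000
  df$y_um <- df$row * object$pixel_size_nm / 1000
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "au") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = object$label)
}
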