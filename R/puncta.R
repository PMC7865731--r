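#' Detect punctate local maxima with a prominence criterion
#'
#' Reimplements the "find maxima" idea used for cluster detection: a pixel
#' is reported as a punctum when it is a local maximum whose prominence over
#' the highest connecting saddle to any stronger maximum exceeds
#' `noise_tolerance`. Prominence is evaluated by descending flood-fill
#' region growing, plateau maxima are merged to their centroid, and peak
#' positions are refined to subpixel precision by a per-axis quadratic fit
#' in the 3x3 neighbourhood. Maxima within `exclude_border_px` of the image
#' border are dropped.
#'
#' @param image Numeric matrix (one frame) or an [image_stack()], in which
#'   case `channel`/`frame` select the frame.
#' @param noise_tolerance Minimum prominence. Defaults to 5x the robust
#'   background sd (median absolute deviation scaled by 1.4826), a
#'   scale-free choice that tracks the noise floor. The sd is estimated on
#'   the off-cell `bg_mask` when one is supplied; otherwise on the whole
#'   image, where structure inflates it (supplying `bg_mask` is
#'   recommended whenever a default tolerance is used).
#' @param within Optional logical mask; only maxima inside it are returned.
#' @param bg_mask Optional logical off-cell region used only for the
#'   default `noise_tolerance` estimate.
#' @param exclude_border_px Border margin in pixels (default 3).
#' @param subpixel Refine positions by quadratic interpolation?
#' @param background_subtract Optional radius (px) of a disc opening used to
#'   flatten large-scale background before detection (`NULL` = off).
#' @param channel,frame Frame selectors when `image` is a stack.
#' @return A tibble with columns `frame, row, col, peak, prominence`,
#'   one row per punctum.
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 100
#' find_maxima(img, noise_tolerance = 10)
find_maxima <- function(image, noise_tolerance = NULL, within = NULL,
                        bg_mask = NULL, exclude_border_px = 3,
                        subpixel = TRUE, background_subtract = NULL,
                        channel = 1L, frame = 1L) {
  if (inherits(image, "image_stack")) {
    image <- get_frame(image, channel, frame)
  }
  stopifnot(is.matrix(image))
  if (!is.null(background_subtract)) {
    image <- subtract_background(image, background_subtract)
  }
  if (is.null(noise_tolerance)) {
    ref <- if (!is.null(bg_mask)) image[bg_mask] else as.vector(image)
    noise_tolerance <- 5 * stats::mad(ref)
  }
  if (noise_tolerance < 0) rlang::abort("`noise_tolerance` must be >= 0.")
  res <- tibble::as_tibble(cpp_find_maxima(image, noise_tolerance))
  if (nrow(res) > 0 && exclude_border_px > 0) {
    b <- exclude_border_px
    res <- dplyr::filter(
      res,
      .data$row > b, .data$row <= nrow(image) - b,
      .data$col > b, .data$col <= ncol(image) - b)
  }
  if (nrow(res) > 0 && !is.null(within)) {
    keep <- within[cbind(pmin(pmax(round(res$row), 1L), nrow(within)),
                         pmin(pmax(round(res$col), 1L), ncol(within)))]
    res <- res[keep, , drop = FALSE]
  }
  if (subpixel && nrow(res) > 0) {
    ref <- refine_subpixel(image, res$row, res$col)
    res$row <- unname(ref[, 1L])
    res$col <- unname(ref[, 2L])
  }
  tibble::tibble(frame = as.integer(frame), res)
}

# Per-axis quadratic (parabolic) refinement around integer peaks.
refine_subpixel <- function(image, rows, cols) {
  nr <- nrow(image); nc <- ncol(image)
  out <- cbind(rows, cols)
  for (i in seq_along(rows)) {
    r <- round(rows[i]); c <- round(cols[i])
    if (r <= 1 || r >= nr || c <= 1 || c >= nc) next
    dr <- parabolic_offset(image[r - 1, c], image[r, c], image[r + 1, c])
    dc <- parabolic_offset(image[r, c - 1], image[r, c], image[r, c + 1])
    out[i, ] <- c(r + dr, c + dc)
  }
  out
}

parabolic_offset <- function(vm, v0, vp) {
  den <- vm - 2 * v0 + vp
  if (den >= 0) return(0)
  max(min(0.5 * (vm - vp) / den, 0.5), -0.5)
}

#' Flatten background by morphological opening
#'
#' Subtracts a disc-opening estimate of the smooth background (a white
#' top-hat), useful before detection when the field carries large-scale
#' intensity gradients.
#'
#' @param image Numeric matrix.
#' @param radius_px Disc radius in pixels.
#' @return Matrix of the same shape, background-flattened, clipped at 0.
#' @export
subtract_background <- function(image, radius_px) {
  size <- 2L * as.integer(radius_px) + 1L
  mx <- max(image)
  if (mx <= 0) return(image)
  opened <- EBImage::opening(EBImage::Image(image / mx),
                             EBImage::makeBrush(size, "disc"))
  pmax(image - EBImage::imageData(opened) * mx, 0)
}

#' Cluster density per membrane area
#'
#' Counts the detected puncta lying inside a cell mask and divides by the
#' mask area in square micrometres.
#'
#' @param puncta Tibble from [find_maxima()] (columns `row`, `col`).
#' @param cell_mask Logical matrix; must be non-empty.
#' @param pixel_size_nm Pixel pitch in nm.
#' @return Density in clusters per um^2 (a single number).
#' @export
cluster_density <- function(puncta, cell_mask, pixel_size_nm) {
  if (sum(cell_mask) == 0) {
    rlang::abort("cell mask is empty: density is undefined.")
  }
  area_um2 <- sum(cell_mask) * (pixel_size_nm / 1000)^2
  if (nrow(puncta) == 0) return(0)
  inside <- cell_mask[cbind(
    pmin(pmax(round(puncta$row), 1L), nrow(cell_mask)),
    pmin(pmax(round(puncta$col), 1L), ncol(cell_mask)))]
  sum(inside) / area_um2
}
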