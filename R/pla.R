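#' Maximum intensity projection of a z-stack
#'
#' Collapses the frame axis of a stack (or a list of matrices) to a single
#' plane by the per-pixel maximum.
#'
#' @param zstack An [image_stack()] (the frame axis is projected; one
#'   channel selected by `channel`), a list of matrices, or a 3-d array
#'   `(plane, row, col)`.
#' @param channel Channel index when `zstack` is an `image_stack`.
#' @return A numeric matrix.
#' @export
max_project <- function(zstack, channel = 1L) {
  if (inherits(zstack, "image_stack")) {
    planes <- lapply(seq_len(n_frames(zstack)),
                     function(fr) get_frame(zstack, channel, fr))
  } else if (is.list(zstack)) {
    planes <- zstack
  } else if (is.array(zstack) && length(dim(zstack)) == 3L) {
    planes <- lapply(seq_len(dim(zstack)[1L]), function(i) {
      matrix(zstack[i, , ], dim(zstack)[2L], dim(zstack)[3L])
    })
  } else if (is.matrix(zstack)) {
    return(zstack)
  } else {
    rlang::abort("unsupported z-stack representation.")
  }
  if (length(planes) == 0) rlang::abort("need at least one plane.")
  Reduce(pmax, planes)
}

#' Subtract an autofluorescence image
#'
#' Pixel-wise subtraction of an autofluorescence reference from an image,
#' clipped at zero.
#'
#' @param image,af_image Congruent numeric matrices.
#' @return Matrix `pmax(image - af_image, 0)`.
#' @export
subtract_autofluorescence <- function(image, af_image) {
  if (!identical(dim(image), dim(af_image))) {
    rlang::abort("image and autofluorescence image differ in shape.")
  }
  pmax(image - af_image, 0)
}

#' Clean an image with a white top-hat filter
#'
#' White top-hat (image minus its morphological opening) with a disc
#' structuring element of diameter `max_feature_px`: structures broader
#' than the element are suppressed while narrow dot signals are retained.
#' The element diameter is rounded up to the next odd integer.
#'
#' @param image Numeric matrix.
#' @param max_feature_px Structuring-element diameter in pixels
#'   (default 10): anything wider is removed.
#' @return Matrix of the same shape.
#' @export
tophat_clean <- function(image, max_feature_px = 10) {
  if (max_feature_px < 1) rlang::abort("`max_feature_px` must be >= 1.")
  size <- as.integer(max_feature_px)
  if (size %% 2L == 0L) size <- size + 1L
  mx <- max(image)
  if (mx <= 0) return(image * 0)
  th <- EBImage::whiteTopHat(EBImage::Image(image / mx),
                             EBImage::makeBrush(size, "disc"))
  EBImage::imageData(th) * mx
}

#' Define cell regions by expanding DAPI nuclei
#'
#' Nuclei are segmented from the DAPI channel (Otsu threshold, hole
#' filling, connected components, minimum-area filter) and every image
#' pixel within `expand_px` (Euclidean distance) of a nucleus is assigned
#' to its nearest nucleus, ties going to the lower label. Pixels beyond the
#' expansion are left unassigned, so objects outside the cell regions can
#' be removed at counting time.
#'
#' @param dapi Numeric matrix (DAPI frame).
#' @param expand_px Expansion distance in pixels (default 65).
#' @param min_nucleus_area Minimum nucleus area in px^2 (default 50).
#' @param threshold Optional absolute DAPI threshold; default is Otsu on
#'   the min-max normalized channel.
#' @return A list: `nuclei` (integer label matrix), `cells` (integer label
#'   matrix of expanded regions), `n_cells`.
#' @export
define_cells <- function(dapi, expand_px = 65, min_nucleus_area = 50,
                         threshold = NULL) {
  stopifnot(is.matrix(dapi))
  rng <- range(dapi)
  if (diff(rng) == 0) rlang::abort("no cells: DAPI channel is constant.")
  norm <- (dapi - rng[1L]) / diff(rng)
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(norm))
         else (threshold - rng[1L]) / diff(rng)
  bin <- EBImage::fillHull(EBImage::Image(norm > thr))
  lab <- EBImage::bwlabel(bin)
  labm <- EBImage::imageData(lab)
  areas <- table(labm[labm > 0])
  keep <- as.integer(names(areas)[areas >= min_nucleus_area])
  if (length(keep) == 0) rlang::abort("no cells: no nuclei found in DAPI.")
  nuclei <- matrix(match(labm, keep, nomatch = 0L), nrow(dapi), ncol(dapi))
  # nearest-nucleus assignment by per-label distance transforms;
  # iterating ascending labels makes ties resolve to the lower label
  best_d <- matrix(Inf, nrow(dapi), ncol(dapi))
  cells <- matrix(0L, nrow(dapi), ncol(dapi))
  for (l in seq_along(keep)) {
    fg <- matrix(1, nrow(dapi), ncol(dapi))
    fg[nuclei == l] <- 0
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg)))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    cells[upd] <- l
  }
  cells[best_d > expand_px] <- 0L
  list(nuclei = nuclei, cells = cells, n_cells = length(keep))
}

#' Count thresholded PLA signals per cell region
#'
#' Connected components of pixels above `intensity_threshold` are counted,
#' each component credited once to the cell region containing its centroid;
#' components whose centroid falls outside every region are removed. The
#' intensity threshold is interpreted on `[0, 1]`-normalized images: a
#' cleaned image whose maximum exceeds 1 raises an error unless
#' `auto_normalize` is set, in which case it is min-max normalized first.
#'
#' @param clean_image Numeric matrix (typically the top-hat cleaned PLA
#'   channel).
#' @param cell_regions Integer label matrix from [define_cells()]; must
#'   contain at least one region.
#' @param intensity_threshold Counting threshold on normalized intensity
#'   (default 0.08).
#' @param auto_normalize Min-max normalize images whose max exceeds 1?
#' @return An object of class `pla_report`: list with `n_cells`,
#'   `signals_total`, `per_cell_counts` (one entry per region label) and
#'   `signals_per_cell = signals_total / n_cells`. [generics::tidy()] gives
#'   per-cell rows, [generics::glance()] the one-row summary.
#' @export
count_signals <- function(clean_image, cell_regions,
                          intensity_threshold = 0.08,
                          auto_normalize = FALSE) {
  n_cells <- length(setdiff(unique(as.vector(cell_regions)), 0L))
  if (n_cells == 0) rlang::abort("no cell regions supplied.")
  if (max(clean_image) > 1) {
    if (!auto_normalize) {
      rlang::abort(paste0(
        "image is not normalized to [0, 1]; set `auto_normalize = TRUE` ",
        "to min-max normalize."))
    }
    rng <- range(clean_image)
    clean_image <- (clean_image - rng[1L]) / diff(rng)
  }
  lab <- EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(clean_image > intensity_threshold)))
  labels <- sort(unique(as.vector(cell_regions)))
  labels <- labels[labels != 0L]
  counts <- stats::setNames(rep(0L, n_cells), labels)
  n_comp <- max(lab)
  if (n_comp > 0) {
    idx <- which(lab > 0)
    comp <- lab[idx]
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    cen_r <- round(tapply(rows, comp, mean))
    cen_c <- round(tapply(cols, comp, mean))
    owner <- cell_regions[cbind(cen_r, cen_c)]
    tab <- table(owner[owner > 0])
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  structure(
    list(n_cells = n_cells, signals_total = total,
         per_cell_counts = counts,
         signals_per_cell = total / n_cells),
    class = "pla_report")
}

#' @export
print.pla_report <- function(x, ...) {
  cat(sprintf("<pla_report> %d signals in %d cells: %.2f signals per cell\n",
              x$signals_total, x$n_cells, x$signals_per_cell))
  invisible(x)
}

#' @method tidy pla_report
#' @export
tidy.pla_report <- function(x, ...) {
  tibble::tibble(cell = as.integer(names(x$per_cell_counts)),
                 count = as.integer(x$per_cell_counts))
}

#' @method glance pla_report
#' @export
glance.pla_report <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, signals_total = x$signals_total,
                 signals_per_cell = x$signals_per_cell)
}

#' Full PLA quantification chain
#'
#' Convenience wrapper running the whole counting pipeline on a PLA scene:
#' maximum projection (when given a z-stack), autofluorescence subtraction,
#' white top-hat cleaning, nuclei expansion into cell regions, and
#' thresholded counting. The cleaned image is normalized to `[0, 1]` by its
#' maximum before thresholding.
#'
#' @param stack An [image_stack()] with named channels `dapi` and `pla`
#'   (and optionally `af`), e.g. from [gen_pla_scene()]; or pass matrices.
#' @param dapi,pla,af Optional explicit matrices overriding the stack
#'   channels (`af = NULL` skips subtraction).
#' @param expand_px,max_feature_px,intensity_threshold Chain parameters,
#'   see [define_cells()], [tophat_clean()], [count_signals()].
#' @return A `pla_report` (with the `define_cells()` output attached as
#'   attribute `regions`).
#' @export
pla_signals_per_cell <- function(stack = NULL, dapi = NULL, pla = NULL,
                                 af = NULL, expand_px = 65,
                                 max_feature_px = 10,
                                 intensity_threshold = 0.08) {
  if (!is.null(stack)) {
    stopifnot(inherits(stack, "image_stack"))
    chn <- stack$channel_names
    if (is.null(dapi)) dapi <- max_project(stack, match("dapi", chn))
    if (is.null(pla)) pla <- max_project(stack, match("pla", chn))
    if (is.null(af) && "af" %in% chn) {
      af <- max_project(stack, match("af", chn))
    }
  }
  if (is.null(dapi) || is.null(pla)) {
    rlang::abort("need DAPI and PLA images (stack channels or matrices).")
  }
  if (!is.null(af)) pla <- subtract_autofluorescence(pla, af)
  clean <- tophat_clean(pla, max_feature_px)
  if (max(clean) > 0) clean <- clean / max(clean)
  regions <- define_cells(dapi, expand_px = expand_px)
  rep <- count_signals(clean, regions$cells,
                       intensity_threshold = intensity_threshold)
  attr(rep, "regions") <- regions
  rep
}
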