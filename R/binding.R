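#' Circle-annulus site measurement and the delta-F over S binding score
#'
#' At a punctate site, the mean pixel fluorescence is read in (1) a central
#' circle of `circle_diam_px` pixels diameter (default 3 px, about 0.5 um at
#' 160 nm/px), (2) the surrounding annulus out to `annulus_outer_diam_px`
#' (default 5 px, about 0.8 um), and (3) an off-cell background region. The
#' site-specific fluorescence is `deltaF = c - a`, the local unbound
#' fluorescence is `S = a - bg`, and their ratio `deltaF/S` scores binding
#' at the site independently of expression level: positive values indicate
#' enrichment (binding), negative values exclusion. Pixels belong to the
#' circle when their centre lies within `circle_diam_px / 2` of the site
#' centre, and to the annulus between that radius and
#' `annulus_outer_diam_px / 2`.
#'
#' @param image Numeric matrix (one frame).
#' @param center Numeric `(row, col)` site centre, possibly subpixel.
#' @param bg_mask Logical matrix marking an off-cell background region;
#'   must be non-empty.
#' @param circle_diam_px Central circle diameter, px.
#' @param annulus_outer_diam_px Annulus outer diameter, px.
#' @return A one-row tibble: `row, col, c, a, bg, delta_f, s, score,
#'   score_defined`. `score` is `NA` (and `score_defined` `FALSE`) when
#'   `S <= 0`.
#' @export
measure_site <- function(image, center, bg_mask,
                         circle_diam_px = 3, annulus_outer_diam_px = 5) {
  stopifnot(is.matrix(image), length(center) == 2L)
  if (sum(bg_mask) == 0) rlang::abort("background mask is empty.")
  r_in <- circle_diam_px / 2
  r_out <- annulus_outer_diam_px / 2
  if (center[1L] < 1 + r_out || center[1L] > nrow(image) - r_out ||
      center[2L] < 1 + r_out || center[2L] > ncol(image) - r_out) {
    rlang::abort("site is closer than the annulus radius to the border.")
  }
  w <- ceiling(r_out)
  rs <- max(1L, floor(center[1L]) - w):min(nrow(image), ceiling(center[1L]) + w)
  cs <- max(1L, floor(center[2L]) - w):min(ncol(image), ceiling(center[2L]) + w)
  d <- sqrt(outer((rs - center[1L])^2, (cs - center[2L])^2, "+"))
  vals <- image[rs, cs]
  c_mean <- mean(vals[d <= r_in])
  a_mean <- mean(vals[d > r_in & d <= r_out])
  bg <- mean(image[bg_mask])
  delta_f <- c_mean - a_mean
  s <- a_mean - bg
  defined <- s > 0
  tibble::tibble(
    row = center[1L], col = center[2L],
    c = c_mean, a = a_mean, bg = bg,
    delta_f = delta_f, s = s,
    score = ifelse(defined, delta_f / s, NA_real_),
    score_defined = defined)
}

#' Per-cell binding score: mean delta-F/S over well-separated sites
#'
#' Measures [measure_site()] at each supplied site and averages the defined
#' scores. Sites whose `S <= 0` are excluded from the mean and counted,
#' never imputed. At least `min_sites` sites with defined scores are
#' required (the conventional minimum is seven per cell) unless
#' `allow_fewer` is set.
#'
#' @param image Numeric matrix (one frame).
#' @param sites Tibble/data frame with columns `row`, `col` (e.g. from
#'   [find_maxima()]), or a two-column matrix.
#' @param bg_mask Logical off-cell background mask.
#' @param min_sites Minimum number of sites with defined scores (default 7).
#' @param allow_fewer Proceed below the minimum instead of erroring?
#' @inheritParams measure_site
#' @return An object of class `binding_score`: list with `mean_score`,
#'   `n_sites`, `n_undefined`, and the per-site tibble `sites`. Use
#'   [generics::tidy()] for the table and [generics::glance()] for the
#'   one-row summary.
#' @export
cell_binding_score <- function(image, sites, bg_mask, min_sites = 7L,
                               allow_fewer = FALSE,
                               circle_diam_px = 3,
                               annulus_outer_diam_px = 5) {
  if (is.matrix(sites)) {
    sites <- tibble::tibble(row = sites[, 1L], col = sites[, 2L])
  }
  tab <- purrr::pmap_dfr(list(sites$row, sites$col), function(r, c) {
    measure_site(image, c(r, c), bg_mask,
                 circle_diam_px = circle_diam_px,
                 annulus_outer_diam_px = annulus_outer_diam_px)
  })
  n_def <- sum(tab$score_defined)
  if (n_def < min_sites && !allow_fewer) {
    rlang::abort(sprintf(
      "only %d sites with defined scores (< %d required); set `allow_fewer = TRUE` to override.",
      n_def, min_sites))
  }
  structure(
    list(mean_score = mean(tab$score[tab$score_defined]),
         n_sites = nrow(tab),
         n_undefined = nrow(tab) - n_def,
         sites = tab),
    class = "binding_score")
}

#' @export
print.binding_score <- function(x, ...) {
  cat(sprintf(
    "<binding_score> mean deltaF/S = %.4f over %d sites (%d undefined)\n",
    x$mean_score, x$n_sites, x$n_undefined))
  invisible(x)
}

#' @method tidy binding_score
#' @export
tidy.binding_score <- function(x, ...) x$sites

#' @method glance binding_score
#' @export
glance.binding_score <- function(x, ...) {
  tibble::tibble(mean_score = x$mean_score, n_sites = x$n_sites,
                 n_undefined = x$n_undefined)
}

#' Co-localization percentage by centre distance
#'
#' The fraction of reference puncta that have a query-channel punctum
#' centre within `match_radius_px` of their own centre, expressed as a
#' percentage. This automates the observer-style cutout call: the
#' square cutout (default 11 um^2, about 21 x 21 px at 160 nm/px) bounds
#' the neighbourhood searched around each reference punctum, and the
#' yes/no decision is a one-pixel centre-distance criterion.
#'
#' @param reference_puncta,query_puncta Tibbles with columns `row`, `col`.
#'   The reference list must be non-empty.
#' @param match_radius_px Match radius, px (default 1).
#' @param cutout_um2 Cutout area bounding the search, um^2 (default 11).
#' @param pixel_size_nm Pixel pitch, nm.
#' @return Percentage in `[0, 100]`.
#' @export
colocalization_percent <- function(reference_puncta, query_puncta,
                                   match_radius_px = 1, cutout_um2 = 11,
                                   pixel_size_nm = 160) {
  if (nrow(reference_puncta) == 0) {
    rlang::abort("reference puncta list is empty: percentage undefined.")
  }
  half_w <- floor(sqrt(cutout_um2) / (pixel_size_nm / 1000) / 2)
  radius <- min(match_radius_px, half_w)
  if (nrow(query_puncta) == 0) return(0)
  qr <- query_puncta$row; qc <- query_puncta$col
  hits <- vapply(seq_len(nrow(reference_puncta)), function(i) {
    d2 <- (qr - reference_puncta$row[i])^2 + (qc - reference_puncta$col[i])^2
    any(d2 <= radius^2)
  }, logical(1))
  100 * mean(hits)
}

#' Interior of a cell mask, excluding an edge margin
#'
#' Erodes a cell mask by a disc of radius `margin_px`. Binding sites are
#' conventionally restricted to well-separated clusters far from the cell
#' edge; measuring a circle-annulus site whose annulus overlaps off-cell
#' pixels biases deltaF upward, so sites should be filtered to the interior
#' mask (a margin at least the annulus outer radius).
#'
#' @param cell_mask Logical matrix.
#' @param margin_px Erosion radius in pixels (default 4).
#' @return Logical matrix of interior pixels.
#' @export
interior_mask <- function(cell_mask, margin_px = 4) {
  EBImage::imageData(
    EBImage::erode(EBImage::Image(cell_mask + 0),
                   EBImage::makeBrush(2L * as.integer(margin_px) + 1L,
                                      "disc"))) > 0
}
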