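#' Calibrated multi-channel image stack
#'
#' Container for fluorescence image data indexed `(channel, frame, row, col)`
#' together with its physical calibration. All downstream stages (spot
#' detection, binding scores, traces, tracking, PLA counting) operate on
#' these stacks or on single frames extracted from them.
#'
#' Coordinates throughout the package are 1-based `(row, col)` with the
#' origin at the top-left pixel and pixel centres at integer coordinates.
#'
#' @param data Numeric array. Accepted layouts: a matrix (one channel, one
#'   frame), a 3-d array `(channel, row, col)`, or a 4-d array
#'   `(channel, frame, row, col)`.
#' @param pixel_size_nm Physical pixel pitch in nanometres (e.g. 160 for the
#'   TIRF set-up the defaults assume). Must be positive.
#' @param frame_interval_s Seconds between frames, or `NULL` for single
#'   frames / z-stacks without a time axis.
#' @param channel_names Optional character vector, one label per channel.
#'
#' @return An object of class `image_stack`: a list with elements `data`
#'   (4-d array), `pixel_size_nm`, `frame_interval_s`, `channel_names`.
#' @export
#' @examples
#' img <- matrix(rpois(64 * 64, 20), 64, 64)
#' stk <- image_stack(img, pixel_size_nm = 160)
#' n_frames(stk)
image_stack <- function(data, pixel_size_nm, frame_interval_s = NULL,
                        channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, 1L, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(data, dim = c(d[1L], 1L, d[2L], d[3L]))
  } else if (length(dim(data)) != 4L) {
    rlang::abort("`data` must be a matrix or a 3-d/4-d array.")
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    rlang::abort("all intensities must be finite and >= 0.")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    rlang::abort("`pixel_size_nm` must be a single positive number.")
  }
  if (!is.null(frame_interval_s) &&
      (!is.numeric(frame_interval_s) || frame_interval_s <= 0)) {
    rlang::abort("`frame_interval_s` must be positive when supplied.")
  }
  n_ch <- dim(data)[1L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch) {
    rlang::abort("`channel_names` length must equal the channel count.")
  }
  structure(
    list(data = data, pixel_size_nm = pixel_size_nm,
         frame_interval_s = frame_interval_s,
         channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d channel(s) x %d frame(s) x %d x %d px @ %g nm/px%s\n",
    d[1L], d[2L], d[3L], d[4L], x$pixel_size_nm,
    if (is.null(x$frame_interval_s)) ""
    else sprintf(", dt = %g s", x$frame_interval_s)))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname image_stack
#' @param stack An `image_stack`.
#' @export
n_channels <- function(stack) dim(stack$data)[1L]

#' @rdname image_stack
#' @export
n_frames <- function(stack) dim(stack$data)[2L]

#' Extract one frame of one channel as a matrix
#'
#' @param stack An `image_stack`.
#' @param channel,frame Indices (1-based).
#' @return A numeric matrix (rows x cols).
#' @export
get_frame <- function(stack, channel = 1L, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (channel < 1 || channel > d[1L]) rlang::abort("channel out of range.")
  if (frame < 1 || frame > d[2L]) rlang::abort("frame out of range.")
  matrix(stack$data[channel, frame, , ], d[3L], d[4L])
}

# Require a time axis; used by trace/tracking entry points.
assert_timelapse <- function(stack) {
  if (is.null(stack$frame_interval_s)) {
    rlang::abort(paste0(
      "stack has no time axis (`frame_interval_s` absent); ",
      "time-lapse operations are undefined for it."))
  }
  invisible(stack)
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered frame-major (all channels of frame 1, then frame 2,
#' ...). Because baseline TIFF stores values in `[0, 1]`, intensities are
#' written scaled and the scale factor is recorded in the sidecar
#' (`<path>.json`) together with the calibration. Stacks whose values are
#' all integers in `[0, 65535]` are stored as 16-bit words, which round-trips
#' bit-exactly; other data are stored as scaled 32-bit floats.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[1L] * d[2L])
  i <- 1L
  for (fr in seq_len(d[2L])) {
    for (ch in seq_len(d[1L])) {
      pages[[i]] <- matrix(stack$data[ch, fr, , ], d[3L], d[4L])
      i <- i + 1L
    }
  }
  mx <- max(stack$data)
  integral <- all(stack$data == round(stack$data)) && mx <= 65535
  if (integral) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- if (mx > 1) mx else 1
    bits <- 32L
  }
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = bits, compression = "none")
  sidecar <- list(
    pixel_size_nm = stack$pixel_size_nm,
    frame_interval_s = stack$frame_interval_s,
    channel_names = stack$channel_names,
    n_channels = d[1L], n_frames = d[2L],
    intensity_scale = scale, integral = integral)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a calibrated image stack from TIFF
#'
#' Reads a single- or multi-page TIFF written by [write_stack()] (or any
#' plain TIFF) and returns an [image_stack()]. Calibration is taken from the
#' JSON sidecar `<path>.json` when present; explicit arguments override the
#' sidecar. A stack without any pixel-size information cannot be calibrated
#' and loading fails.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,frame_interval_s,channel_names Optional overrides of
#'   the sidecar calibration.
#' @param n_channels Number of channels the pages cycle through
#'   (frame-major page order); defaults to the sidecar value or 1.
#' @return An `image_stack`.
#' @export
load_stack <- function(path, pixel_size_nm = NULL, frame_interval_s = NULL,
                       channel_names = NULL, n_channels = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("cannot read '%s'.", path))
  sidecar <- list()
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  }
  px <- pixel_size_nm %||% sidecar$pixel_size_nm
  if (is.null(px)) {
    rlang::abort(paste0(
      "no pixel size: supply `pixel_size_nm` or provide a JSON sidecar ",
      "with calibration."))
  }
  dt <- frame_interval_s %||% sidecar$frame_interval_s
  nch <- as.integer(n_channels %||% sidecar$n_channels %||% 1L)
  integral <- isTRUE(sidecar$integral)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = integral)
  if (!is.list(pages)) pages <- list(pages)
  scale <- sidecar$intensity_scale %||% 1
  if (integral) scale <- 1   # as.is = TRUE already returns raw integers
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey-stored-as-RGB
    p * scale
  })
  n_pages <- length(pages)
  if (n_pages %% nch != 0L) {
    rlang::abort("page count is not a multiple of the channel count.")
  }
  nfr <- n_pages %/% nch
  dimpg <- dim(pages[[1L]])
  data <- array(0, dim = c(nch, nfr, dimpg[1L], dimpg[2L]))
  i <- 1L
  for (fr in seq_len(nfr)) {
    for (ch in seq_len(nch)) {
      data[ch, fr, , ] <- pages[[i]]
      i <- i + 1L
    }
  }
  image_stack(data, pixel_size_nm = px, frame_interval_s = dt,
              channel_names = channel_names %||% sidecar$channel_names)
}

#' Read and write region masks
#'
#' Masks are single-page label images congruent with one frame: 0 marks
#' pixels outside every region and positive integers label regions (a
#' logical mask is stored as 0/1). Stored as 16-bit TIFF, which round-trips
#' labels up to 65535 exactly.
#'
#' @param mask Integer or logical matrix.
#' @param path TIFF path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns an
#'   integer matrix.
#' @export
write_mask <- function(mask, path) {
  m <- if (is.logical(mask)) mask + 0L else mask
  if (any(m != round(m)) || any(m < 0) || max(m) > 65535) {
    rlang::abort("mask must hold integer labels in [0, 65535].")
  }
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Correct translational misalignment between two colour channels
#'
#' Estimates the shift of one channel relative to a reference channel by
#' cross-correlation (computed over the first frame, FFT-based), refines the
#' correlation peak to subpixel precision by quadratic interpolation, and
#' translates every frame of the moving channel by the recovered shift
#' (bilinear interpolation, edges padded with the channel median). Rotation
#' and scale changes are out of scope; the correction is a pure translation.
#'
#' @param stack An `image_stack` with at least two channels.
#' @param reference_channel Channel the other is aligned to (default 1).
#' @param moving_channel Channel to translate (default 2).
#' @return A list: `stack` (aligned copy) and `shift`, the recovered
#'   `(drow, dcol)` displacement of the moving channel relative to the
#'   reference (the applied correction is its negation).
#' @export
align_channels <- function(stack, reference_channel = 1L,
                           moving_channel = 2L) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_channels(stack) < 2L) rlang::abort("need at least two channels.")
  ref <- get_frame(stack, reference_channel, 1L)
  mov <- get_frame(stack, moving_channel, 1L)
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    rlang::abort("alignment undetermined: a channel has no structure.")
  }
  shift <- estimate_shift(ref, mov)
  out <- stack
  for (fr in seq_len(n_frames(stack))) {
    frm <- get_frame(stack, moving_channel, fr)
    out$data[moving_channel, fr, , ] <-
      translate_bilinear(frm, -shift[1L], -shift[2L])
  }
  list(stack = out, shift = shift)
}

# Cross-correlation shift estimate (mov relative to ref), subpixel refined.
estimate_shift <- function(ref, mov) {
  a <- ref - mean(ref)
  b <- mov - mean(mov)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  # quadratic subpixel refinement along each axis, circular indexing
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  sub1 <- function(cm, cz, cp) {
    den <- cm - 2 * cz + cp
    if (den >= 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(min(d, 0.5), -0.5)
  }
  dr <- sub1(cc[wrap(pk[1L] - 1L, nr), pk[2L]], cc[pk[1L], pk[2L]],
             cc[wrap(pk[1L] + 1L, nr), pk[2L]])
  dc <- sub1(cc[pk[1L], wrap(pk[2L] - 1L, nc)], cc[pk[1L], pk[2L]],
             cc[pk[1L], wrap(pk[2L] + 1L, nc)])
  sr <- pk[1L] - 1L + dr
  sc <- pk[2L] - 1L + dc
  if (sr > nr / 2) sr <- sr - nr
  if (sc > nc / 2) sc <- sc - nc
  c(drow = sr, dcol = sc)
}

# Translate a matrix by (drow, dcol) with bilinear interpolation.
translate_bilinear <- function(img, drow, dcol) {
  nr <- nrow(img); nc <- ncol(img)
  fill <- stats::median(img)
  r <- seq_len(nr) - drow
  c <- seq_len(nc) - dcol
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  at <- function(i, j) {
    ok <- i >= 1L & i <= nr
    oj <- j >= 1L & j <= nc
    m <- matrix(fill, nr, nc)
    m[ok, oj] <- img[i[ok], j[oj], drop = FALSE]
    m
  }
  at(r0, c0) * outer(1 - fr, 1 - fc) +
    at(r0 + 1, c0) * outer(fr, 1 - fc) +
    at(r0, c0 + 1) * outer(1 - fr, fc) +
    at(r0 + 1, c0 + 1) * outer(fr, fc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
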