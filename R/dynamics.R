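#' Whole-cell fluorescence trace around a stimulation
#'
#' Per frame, the mean intensity inside the cell mask minus the mean inside
#' the off-cell background mask gives the background-corrected cell
#' fluorescence `f_raw`. It is normalized to the mean over all
#' pre-stimulation frames (`f_norm`), and the time axis is shifted so the
#' stimulation frame is t = 0. `f_norm` is by construction invariant to
#' camera gain, and `f_raw` to a constant offset applied to all pixels.
#'
#' @param stack A time-lapse [image_stack()].
#' @param cell_mask,bg_mask Logical masks; must be non-empty and disjoint.
#' @param stim_frame Index of the first stimulated frame (baseline = all
#'   earlier frames; at least `min_baseline` of them are required).
#' @param channel Channel index.
#' @param min_baseline Minimum number of baseline frames (default 5).
#' @return A tibble of class `fluorescence_trace` with columns
#'   `frame, time_s, f_raw, f_norm` and attributes `stim_frame` and
#'   `baseline_defined` (`FALSE` when the baseline mean is not positive, in
#'   which case `f_norm` is `NA`).
#' @export
cell_trace <- function(stack, cell_mask, bg_mask, stim_frame,
                       channel = 1L, min_baseline = 5L) {
  stopifnot(inherits(stack, "image_stack"))
  assert_timelapse(stack)
  nf <- n_frames(stack)
  if (stim_frame < 1 || stim_frame > nf) {
    rlang::abort("`stim_frame` outside the frame range.")
  }
  if (sum(cell_mask) == 0 || sum(bg_mask) == 0) {
    rlang::abort("cell and background masks must be non-empty.")
  }
  if (any(cell_mask & bg_mask)) {
    rlang::abort("cell and background masks must be disjoint.")
  }
  if (stim_frame - 1L < min_baseline) {
    rlang::abort(sprintf("need >= %d pre-stimulation frames.", min_baseline))
  }
  f_raw <- vapply(seq_len(nf), function(fr) {
    frm <- get_frame(stack, channel, fr)
    mean(frm[cell_mask]) - mean(frm[bg_mask])
  }, numeric(1))
  baseline <- mean(f_raw[seq_len(stim_frame - 1L)])
  defined <- is.finite(baseline) && baseline > 0
  out <- tibble::tibble(
    frame = seq_len(nf),
    time_s = (seq_len(nf) - stim_frame) * stack$frame_interval_s,
    f_raw = f_raw,
    f_norm = if (defined) f_raw / baseline else NA_real_)
  attr(out, "stim_frame") <- stim_frame
  attr(out, "baseline_defined") <- defined
  class(out) <- c("fluorescence_trace", class(out))
  out
}

#' Detect endocytosis events in per-punctum site traces
#'
#' An endocytosis event is the characteristic rapid loss of a punctum's
#' site-specific fluorescence within one or two frames. For each punctum a
#' per-frame `deltaF` trace is measured with [measure_site()] at a fixed
#' position, and an event is called at the first frame `e` where `deltaF`
#' has fallen by at least `drop_threshold` of its trailing 5-frame median
#' (the median of the 5 frames preceding the drop) within at most
#' `max_frames` frames, and stays at or below that level for at least
#' `persist_frames` frames (rejecting blinking).
#'
#' @param stack A time-lapse [image_stack()].
#' @param puncta Tibble with columns `row`, `col` and optionally
#'   `punctum_id` (default: row number); positions are held fixed over the
#'   movie.
#' @param bg_mask Logical off-cell background mask.
#' @param drop_threshold Fractional loss calling an event (default 0.5).
#' @param max_frames Maximum frames over which the loss may occur (1 or 2;
#'   default 2).
#' @param persist_frames Frames the trace must stay down (default 3).
#' @param channel Channel index.
#' @return A tibble `punctum_id, event_frame, drop_fraction,
#'   frames_to_loss` (0 rows when no events). Traces shorter than the
#'   baseline window are skipped with a warning.
#' @export
detect_endocytosis_events <- function(stack, puncta, bg_mask,
                                      drop_threshold = 0.5, max_frames = 2L,
                                      persist_frames = 3L, channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  window <- 5L
  if (nf < window + max_frames + persist_frames) {
    rlang::warn("movie shorter than the detection window: no traces scanned.")
    return(empty_events())
  }
  ids <- if ("punctum_id" %in% names(puncta)) puncta$punctum_id
         else seq_len(nrow(puncta))
  frames <- lapply(seq_len(nf), function(fr) get_frame(stack, channel, fr))
  out <- vector("list", nrow(puncta))
  for (i in seq_len(nrow(puncta))) {
    ctr <- c(puncta$row[i], puncta$col[i])
    df <- tryCatch(
      vapply(seq_len(nf), function(fr) {
        m <- measure_site(frames[[fr]], ctr, bg_mask)
        m$delta_f
      }, numeric(1)),
      error = function(e) NULL)
    if (is.null(df)) {
      rlang::warn(sprintf("punctum %s skipped (site unmeasurable).", ids[i]))
      next
    }
    ev <- scan_trace_for_event(df, drop_threshold, max_frames,
                               persist_frames, window)
    if (!is.null(ev)) {
      out[[i]] <- tibble::tibble(
        punctum_id = ids[i], event_frame = ev$frame,
        drop_fraction = ev$drop, frames_to_loss = ev$k)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_events() else res
}

empty_events <- function() {
  tibble::tibble(punctum_id = integer(0), event_frame = integer(0),
                 drop_fraction = numeric(0), frames_to_loss = integer(0))
}

# First frame satisfying the rapid-loss rule, or NULL.
scan_trace_for_event <- function(df, drop_threshold, max_frames,
                                 persist_frames, window = 5L) {
  nf <- length(df)
  for (e in (window + 1L):nf) {
    if (e + persist_frames - 1L > nf) break
    for (k in seq_len(min(max_frames, e - window))) {
      med <- stats::median(df[(e - k - window + 1L):(e - k)])
      if (med <= 0) next
      level <- (1 - drop_threshold) * med
      if (all(df[e:(e + persist_frames - 1L)] <= level)) {
        return(list(frame = e, drop = 1 - df[e] / med, k = k))
      }
    }
  }
  NULL
}

#' Cluster density before and after stimulation
#'
#' Runs [find_maxima()] on a window of frames on each side of the
#' stimulation, converts counts to [cluster_density()], and reports the
#' pre- and post-stimulation means and their ratio. The post window is
#' taken from the end of the movie so that step-wise losses triggered after
#' stimulation are complete.
#'
#' @param stack A time-lapse [image_stack()].
#' @param cell_mask Logical cell mask.
#' @param stim_frame Stimulation frame index; at least `window` frames are
#'   required on each side.
#' @param noise_tolerance Detection tolerance passed to [find_maxima()].
#' @param window Frames averaged on each side (default 3).
#' @param channel Channel index.
#' @return A one-row tibble: `density_pre, density_post, ratio`.
#' @export
density_before_after <- function(stack, cell_mask, stim_frame,
                                 noise_tolerance = NULL, window = 3L,
                                 channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- n_frames(stack)
  if (stim_frame - window < 1L || stim_frame + window > nf) {
    rlang::abort(sprintf("need >= %d frames on each side of `stim_frame`.",
                         window))
  }
  dens <- function(fr) {
    p <- find_maxima(stack, noise_tolerance = noise_tolerance,
                     within = cell_mask, channel = channel, frame = fr)
    cluster_density(p, cell_mask, stack$pixel_size_nm)
  }
  pre <- mean(vapply((stim_frame - window):(stim_frame - 1L), dens,
                     numeric(1)))
  post <- mean(vapply((nf - window + 1L):nf, dens, numeric(1)))
  tibble::tibble(density_pre = pre, density_post = post,
                 ratio = post / pre)
}
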