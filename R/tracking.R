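#' Link per-frame puncta into trajectories
#'
#' Frame-to-frame linking with a gating radius: candidate pairs between
#' consecutive frames within `max_step_px` are taken greedily in ascending
#' distance, each detection joining at most one track (global conflict
#' resolution). Unmatched detections start new tracks; there is no gap
#' closing, so consecutive points of a track always differ by exactly one
#' frame. Tracks with fewer than `min_length` points are discarded.
#'
#' @param puncta Tibble with columns `frame`, `row`, `col` (e.g. the
#'   row-bound output of [find_maxima()] over frames).
#' @param max_step_px Maximum frame-to-frame displacement, px (default 5,
#'   the conventional pixel cut-off).
#' @param min_length Minimum track length in points (default 3).
#' @return A tibble of class `track_table`: `track_id, frame, row, col`,
#'   ordered by track then frame.
#' @export
link_tracks <- function(puncta, max_step_px = 5, min_length = 3L) {
  stopifnot(all(c("frame", "row", "col") %in% names(puncta)))
  frames <- sort(unique(puncta$frame))
  if (length(frames) < 2L) {
    rlang::warn("fewer than two frames of detections: no links possible.")
  }
  puncta <- dplyr::arrange(puncta, .data$frame)
  # assign a track id to every detection
  puncta$track_id <- NA_integer_
  next_id <- 0L
  idx_by_frame <- split(seq_len(nrow(puncta)), puncta$frame)
  prev <- integer(0)
  for (fi in seq_along(frames)) {
    cur <- idx_by_frame[[as.character(frames[fi])]]
    linked_cur <- rep(FALSE, length(cur))
    if (fi > 1L && frames[fi] == frames[fi - 1L] + 1L &&
        length(prev) > 0 && length(cur) > 0) {
      d <- outer(puncta$row[prev], puncta$row[cur], "-")^2 +
        outer(puncta$col[prev], puncta$col[cur], "-")^2
      cand <- which(d <= max_step_px^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand])
        used_p <- rep(FALSE, length(prev))
        for (j in ord) {
          ip <- cand[j, 1L]; ic <- cand[j, 2L]
          if (used_p[ip] || linked_cur[ic]) next
          used_p[ip] <- TRUE
          linked_cur[ic] <- TRUE
          puncta$track_id[cur[ic]] <- puncta$track_id[prev[ip]]
        }
      }
    }
    for (ic in which(!linked_cur)) {
      next_id <- next_id + 1L
      puncta$track_id[cur[ic]] <- next_id
    }
    prev <- cur
  }
  out <- dplyr::arrange(puncta[, c("track_id", "frame", "row", "col")],
                        .data$track_id, .data$frame)
  keep <- dplyr::count(out, .data$track_id)
  keep <- keep$track_id[keep$n >= min_length]
  out <- out[out$track_id %in% keep, , drop = FALSE]
  out$track_id <- match(out$track_id, unique(out$track_id))
  class(out) <- c("track_table", class(out))
  out
}

# Per-step displacements of a track table.
track_steps <- function(tracks) {
  dplyr::reframe(
    dplyr::group_by(tibble::as_tibble(tracks), .data$track_id),
    frame = .data$frame[-1L],
    step_px = sqrt(diff(.data$row)^2 + diff(.data$col)^2))
}

#' Displacement histogram of tracked puncta
#'
#' Bins the per-frame step lengths of all tracks, and alongside them the
#' per-track total path lengths (the sum of a track's steps); both are
#' labelled by `kind` because either convention may be wanted when
#' comparing conditions. The count of minimum-displacement tracks (tracks
#' whose total falls in the lowest bin) is carried as an attribute and in
#' the summary.
#'
#' @param tracks A `track_table` from [link_tracks()].
#' @param bin_width_px Bin width in pixels; must be positive.
#' @return A tibble of class `displacement_histogram`:
#'   `kind (step | track_total), bin_left, bin_right, count`, with
#'   attribute `min_displacement_tracks`.
#' @export
displacement_histogram <- function(tracks, bin_width_px) {
  if (!is.numeric(bin_width_px) || bin_width_px <= 0) {
    rlang::abort("`bin_width_px` must be positive.")
  }
  if (nrow(tracks) == 0) rlang::abort("no tracks supplied.")
  steps <- track_steps(tracks)
  totals <- dplyr::summarise(dplyr::group_by(steps, .data$track_id),
                             total = sum(.data$step_px), .groups = "drop")
  bin_tab <- function(x, kind) {
    idx <- pmax(floor(x / bin_width_px), 0)
    tab <- table(idx)
    tibble::tibble(
      kind = kind,
      bin_left = as.numeric(names(tab)) * bin_width_px,
      bin_right = (as.numeric(names(tab)) + 1) * bin_width_px,
      count = as.integer(tab))
  }
  out <- dplyr::bind_rows(bin_tab(steps$step_px, "step"),
                          bin_tab(totals$total, "track_total"))
  attr(out, "min_displacement_tracks") <-
    sum(totals$total < bin_width_px)
  class(out) <- c("displacement_histogram", class(out))
  out
}

#' Average speed of tracked puncta
#'
#' Converts each track's mean step length to um/s using the pixel pitch and
#' frame interval, and pools across tracks (mean and SEM).
#'
#' @param tracks A `track_table` from [link_tracks()].
#' @param pixel_size_nm Pixel pitch, nm.
#' @param frame_interval_s Frame interval, s; required.
#' @return An object of class `speed_summary`: list with `per_track`
#'   (tibble `track_id, n_steps, mean_step_px, speed_um_s`), `pooled_mean`,
#'   `pooled_sem`, `n_tracks`. [generics::tidy()] returns the per-track
#'   table, [generics::glance()] the pooled one-row summary.
#' @export
average_speed <- function(tracks, pixel_size_nm, frame_interval_s) {
  if (is.null(frame_interval_s) || !is.finite(frame_interval_s) ||
      frame_interval_s <= 0) {
    rlang::abort("`frame_interval_s` is required for speeds.")
  }
  steps <- track_steps(tracks)
  per <- dplyr::summarise(
    dplyr::group_by(steps, .data$track_id),
    n_steps = dplyr::n(),
    mean_step_px = mean(.data$step_px), .groups = "drop")
  per$speed_um_s <- per$mean_step_px * (pixel_size_nm / 1000) /
    frame_interval_s
  structure(
    list(per_track = per,
         pooled_mean = mean(per$speed_um_s),
         pooled_sem = stats::sd(per$speed_um_s) /
           sqrt(max(nrow(per), 1L)),
         n_tracks = nrow(per)),
    class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  cat(sprintf("<speed_summary> %d tracks: %.4f +/- %.4f um/s (mean +/- SEM)\n",
              x$n_tracks, x$pooled_mean, x$pooled_sem))
  invisible(x)
}

#' @method tidy speed_summary
#' @export
tidy.speed_summary <- function(x, ...) x$per_track

#' @method glance speed_summary
#' @export
glance.speed_summary <- function(x, ...) {
  tibble::tibble(pooled_mean_um_s = x$pooled_mean,
                 pooled_sem_um_s = x$pooled_sem, n_tracks = x$n_tracks)
}
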