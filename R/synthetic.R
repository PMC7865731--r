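#' Scene parameters for the synthetic TIRF generator
#'
#' Bundles the knobs of the punctate-scene simulator. Defaults describe a
#' plausible TIRF field of diffraction-limited clusters on a diffuse
#' membrane: 160 nm pixels, a PSF sigma of 1.2 px (~192 nm), spot amplitude
#' 200 counts over a membrane background of 50 (off-cell 10), Poisson shot
#' noise plus Gaussian read noise of sd 2 counts.
#'
#' @param field_size_px Field edge length in pixels (square field).
#' @param density_per_um2 Expected spot density inside the cell, spots/um^2.
#' @param psf_sigma_px Isotropic Gaussian PSF sigma in pixels.
#' @param amplitude Peak amplitude of a spot above local background, counts.
#' @param membrane_background Diffuse background inside the cell, counts.
#' @param offcell_background Background outside the cell, counts.
#' @param gaussian_noise_sd Read-noise sd in counts (Gaussian, added after
#'   Poisson shot noise when `poisson_noise` is `TRUE`).
#' @param poisson_noise Apply Poisson shot noise to signal + background?
#' @param coloc_fraction Fraction of channel-1 spots duplicated into
#'   channel 2 at the same centres.
#' @param exclusion_radius_px When > 0, independent (non-duplicated)
#'   channel-2 spots are kept at least this far from every channel-1
#'   centre, producing exclusion rather than independence.
#' @param pixel_size_nm Pixel pitch, nm.
#' @param n_spots Optional exact spot count per channel, overriding the
#'   Poisson draw at `density_per_um2` (`NULL` = Poisson).
#' @param seed Integer seed fixing all randomness of a generator call.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(field_size_px = 80, density_per_um2 = 0.4,
                         psf_sigma_px = 1.2, amplitude = 200,
                         membrane_background = 50, offcell_background = 10,
                         gaussian_noise_sd = 2, poisson_noise = TRUE,
                         coloc_fraction = 0.5, exclusion_radius_px = 0,
                         pixel_size_nm = 160, n_spots = NULL, seed = 1L) {
  stopifnot(density_per_um2 >= 0, coloc_fraction >= 0, coloc_fraction <= 1,
            psf_sigma_px > 0, field_size_px >= 16, pixel_size_nm > 0)
  structure(as.list(environment()), class = "scene_params")
}

# Elliptical cell mask leaving a margin to the field border.
cell_ellipse_mask <- function(n, margin = 4) {
  ctr <- (n + 1) / 2
  a <- n / 2 - margin        # semi-axis, cols
  b <- n / 2 - margin - 2    # semi-axis, rows (slightly anisotropic)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  ((rr - ctr) / b)^2 + ((cc - ctr) / a)^2 <= 1
}

# Add isotropic Gaussian spots to an image; positions px, per-spot amplitude.
render_spots <- function(img, rows, cols, amps, sigma) {
  if (length(rows) == 0L) return(img)
  n_r <- nrow(img); n_c <- ncol(img)
  w <- ceiling(4 * sigma)
  for (i in seq_along(rows)) {
    r0 <- max(1L, floor(rows[i] - w)); r1 <- min(n_r, ceiling(rows[i] + w))
    c0 <- max(1L, floor(cols[i] - w)); c1 <- min(n_c, ceiling(cols[i] + w))
    rs <- r0:r1; cs <- c0:c1
    g <- exp(-outer((rs - rows[i])^2, (cs - cols[i])^2, "+") /
               (2 * sigma^2))
    img[rs, cs] <- img[rs, cs] + amps[i] * g
  }
  img
}

apply_noise <- function(img, params) {
  if (params$poisson_noise) {
    img <- matrix(stats::rpois(length(img), lambda = img),
                  nrow(img), ncol(img))
  }
  if (params$gaussian_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0,
                                     params$gaussian_noise_sd),
                        nrow(img), ncol(img))
  }
  pmax(img, 0)
}

# Uniform positions inside a mask (rejection sampling), optionally keeping
# a minimum distance to a set of forbidden centres.
sample_in_mask <- function(n, mask, margin = 0, avoid = NULL,
                           avoid_radius = 0) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- numeric(0); cols <- numeric(0)
  guard <- 0L
  while (length(rows) < n && guard < 200L) {
    m <- max(4L * (n - length(rows)), 32L)
    r <- stats::runif(m, 1 + margin, nr - margin)
    c <- stats::runif(m, 1 + margin, nc - margin)
    ok <- mask[cbind(round(r), round(c))]
    if (!is.null(avoid) && avoid_radius > 0 && nrow(avoid) > 0) {
      d2min <- apply(cbind(r, c), 1L, function(p) {
        min((avoid[, 1L] - p[1L])^2 + (avoid[, 2L] - p[2L])^2)
      })
      ok <- ok & d2min >= avoid_radius^2
    }
    rows <- c(rows, r[ok]); cols <- c(cols, c[ok])
    guard <- guard + 1L
  }
  if (length(rows) < n) {
    rlang::abort("could not place the requested spots in the mask.")
  }
  cbind(row = rows[seq_len(n)], col = cols[seq_len(n)])
}

#' Simulate a two-channel punctate TIRF frame with ground truth
#'
#' Places a Poisson number of diffraction-limited spots (isotropic Gaussian
#' PSF) at the stated density inside an elliptical cell, duplicates a
#' `coloc_fraction` subset into channel 2 at identical centres, tops
#' channel 2 up to its own Poisson draw with independent spots, adds the
#' diffuse membrane/off-cell backgrounds and noise, and reports every true
#' position. With `exclusion_radius_px > 0` the independent channel-2 spots
#' avoid channel-1 centres, producing an exclusion scene.
#'
#' @param params A [scene_params()] object.
#' @return A list with `stack` (2-channel [image_stack()]), `cell_mask`,
#'   `bg_mask` (logical matrices), and `truth`: a list holding per-channel
#'   spot tibbles (`frame, row, col, coloc`), the overcrowding flag, and the
#'   scene parameters.
#' @export
gen_two_channel_frame <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  n <- params$field_size_px
  px_um <- params$pixel_size_nm / 1000
  cell <- cell_ellipse_mask(n)
  bg_mask <- !EBImage::dilate(EBImage::Image(cell + 0),
                              EBImage::makeBrush(9, "disc")) > 0
  area_um2 <- sum(cell) * px_um^2
  if (is.null(params$n_spots)) {
    n1 <- stats::rpois(1L, params$density_per_um2 * area_um2)
    n2 <- stats::rpois(1L, params$density_per_um2 * area_um2)
  } else {
    n1 <- n2 <- as.integer(params$n_spots)
  }
  pos1 <- sample_in_mask(n1, cell, margin = 4)
  coloc <- if (n1 > 0) stats::runif(n1) < params$coloc_fraction else logical(0)
  n_dup <- sum(coloc)
  n_ind <- max(n2 - n_dup, 0L)
  pos2_ind <- sample_in_mask(n_ind, cell, margin = 4,
                             avoid = pos1, avoid_radius =
                               params$exclusion_radius_px)
  pos2 <- rbind(pos1[coloc, , drop = FALSE], pos2_ind)

  base <- function(pos) {
    img <- matrix(params$offcell_background, n, n)
    img[cell] <- params$membrane_background
    render_spots(img, pos[, 1L], pos[, 2L],
                 rep(params$amplitude, nrow(pos)), params$psf_sigma_px)
  }
  ch1 <- apply_noise(base(pos1), params)
  ch2 <- apply_noise(base(pos2), params)
  data <- array(0, dim = c(2L, 1L, n, n))
  data[1L, 1L, , ] <- ch1
  data[2L, 1L, , ] <- ch2
  # mean nearest-neighbour distance of a 2-D Poisson process: 0.5 / sqrt(lambda)
  lambda_px <- params$density_per_um2 * px_um^2
  overcrowded <- lambda_px > 0 &&
    0.5 / sqrt(lambda_px) < 2 * params$psf_sigma_px

  truth <- list(
    spots_ch1 = tibble::tibble(
      frame = 1L,
      row = pos1[, 1L], col = pos1[, 2L],
      coloc = as.logical(coloc)),
    spots_ch2 = tibble::tibble(
      frame = 1L,
      row = pos2[, 1L], col = pos2[, 2L],
      coloc = c(rep(TRUE, n_dup), rep(FALSE, n_ind))),
    overcrowded = overcrowded,
    params = params)
  if (overcrowded) {
    rlang::warn("expected spot spacing < 2 * psf sigma: scene overcrowded.")
  }
  list(
    stack = image_stack(data, pixel_size_nm = params$pixel_size_nm,
                        channel_names = c("ch1", "ch2")),
    cell_mask = cell, bg_mask = bg_mask, truth = truth)
}

#' Simulate a time-lapse with stimulated internalization events
#'
#' Spots perform 2-D Brownian motion (independent per-axis Gaussian steps of
#' variance `2 D dt`) and, after the stimulation frame, a designated
#' fraction lose their amplitude to zero linearly over one or two frames,
#' emulating single endocytosis events. The event frame of each
#' internalizing spot (the first frame at which loss is complete for
#' `loss_frames = 1`, or underway for `loss_frames = 2`) is recorded.
#'
#' @param params A [scene_params()]; channel-2 settings are ignored (the
#'   movie is single channel).
#' @param n_frames Number of frames.
#' @param stim_frame Index of the first stimulated frame.
#' @param internalized_fraction Fraction of spots that internalize.
#' @param loss_frames 1 or 2: frames over which the amplitude is lost.
#' @param diffusion_coeff_um2s Diffusion coefficient D (um^2/s), non-negative.
#' @param frame_interval_s Frame interval dt, seconds.
#' @param max_event_delay Events are placed uniformly in
#'   `stim_frame + 1 .. stim_frame + max_event_delay` (capped so that at
#'   least 3 post-event frames remain).
#' @param bleach_rate Optional global mono-exponential bleach factor per
#'   frame (0 = off, the default).
#' @return A list with `stack`, `cell_mask`, `bg_mask`, and `truth`: spot
#'   tracks (`id, frame, row, col, amplitude`), per-spot `event_frame`
#'   (`NA` for persistent spots), and the inputs.
#' @export
gen_timelapse <- function(params = scene_params(), n_frames = 30L,
                          stim_frame = 10L, internalized_fraction = 0.5,
                          loss_frames = 1L, diffusion_coeff_um2s = 0,
                          frame_interval_s = 0.1, max_event_delay = 10L,
                          bleach_rate = 0) {
  stopifnot(inherits(params, "scene_params"),
            internalized_fraction >= 0, internalized_fraction <= 1,
            stim_frame < n_frames, loss_frames %in% c(1L, 2L))
  if (diffusion_coeff_um2s < 0) rlang::abort("D must be >= 0.")
  set.seed(params$seed)
  n <- params$field_size_px
  px_um <- params$pixel_size_nm / 1000
  cell <- cell_ellipse_mask(n)
  bg_mask <- !EBImage::dilate(EBImage::Image(cell + 0),
                              EBImage::makeBrush(9, "disc")) > 0
  area_um2 <- sum(cell) * px_um^2
  n_spots <- if (is.null(params$n_spots)) {
    stats::rpois(1L, params$density_per_um2 * area_um2)
  } else {
    as.integer(params$n_spots)
  }
  pos0 <- sample_in_mask(n_spots, cell, margin = 6)

  n_events <- round(internalized_fraction * n_spots)
  internalizers <- if (n_spots > 0) sample.int(n_spots, n_events) else integer(0)
  max_delay <- max(1L, min(max_event_delay, n_frames - stim_frame - 3L))
  delays <- if (n_events > 0) sample.int(max_delay, n_events, replace = TRUE)
            else integer(0)
  event_frame <- rep(NA_integer_, n_spots)
  event_frame[internalizers] <- stim_frame + delays

  step_sd_px <- sqrt(2 * diffusion_coeff_um2s * frame_interval_s) / px_um
  rows <- matrix(0, n_spots, n_frames)
  cols <- matrix(0, n_spots, n_frames)
  if (n_spots > 0) {
    rows[, 1L] <- pos0[, 1L]; cols[, 1L] <- pos0[, 2L]
    for (fr in seq_len(n_frames)[-1L]) {
      rows[, fr] <- rows[, fr - 1L] + stats::rnorm(n_spots, 0, step_sd_px)
      cols[, fr] <- cols[, fr - 1L] + stats::rnorm(n_spots, 0, step_sd_px)
    }
    rows <- pmin(pmax(rows, 4), n - 3)
    cols <- pmin(pmax(cols, 4), n - 3)
  }
  amp_mult <- matrix(1, max(n_spots, 1L), n_frames)
  for (k in seq_along(internalizers)) {
    e <- event_frame[internalizers[k]]
    if (loss_frames == 1L) {
      amp_mult[internalizers[k], e:n_frames] <- 0
    } else {
      amp_mult[internalizers[k], e] <- 0.5
      if (e < n_frames) amp_mult[internalizers[k], (e + 1L):n_frames] <- 0
    }
  }
  data <- array(0, dim = c(1L, n_frames, n, n))
  tracks <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    img <- matrix(params$offcell_background, n, n)
    img[cell] <- params$membrane_background
    bleach <- if (bleach_rate > 0) exp(-bleach_rate * (fr - 1L)) else 1
    amps <- if (n_spots > 0) params$amplitude * amp_mult[seq_len(n_spots), fr] * bleach
            else numeric(0)
    img <- render_spots(img, rows[seq_len(n_spots), fr],
                        cols[seq_len(n_spots), fr], amps,
                        params$psf_sigma_px)
    data[1L, fr, , ] <- apply_noise(img, params)
    tracks[[fr]] <- tibble::tibble(
      id = seq_len(n_spots), frame = fr,
      row = rows[seq_len(n_spots), fr], col = cols[seq_len(n_spots), fr],
      amplitude = amps)
  }
  list(
    stack = image_stack(data, pixel_size_nm = params$pixel_size_nm,
                        frame_interval_s = frame_interval_s,
                        channel_names = "ch1"),
    cell_mask = cell, bg_mask = bg_mask,
    truth = list(
      tracks = dplyr::bind_rows(tracks),
      event_frame = event_frame,
      n_spots = n_spots, n_events = n_events,
      stim_frame = stim_frame, loss_frames = loss_frames,
      diffusion_coeff_um2s = diffusion_coeff_um2s,
      frame_interval_s = frame_interval_s, params = params))
}

#' Simulate a PLA scene: DAPI nuclei plus bright dot signals
#'
#' Nuclei are non-overlapping discs laid out on a jittered grid; each cell
#' receives a Poisson (or forced) number of small bright dots placed within
#' `placement_radius_px` of its nucleus. The scene carries a smooth
#' autofluorescence field that is also returned as its own channel, so the
#' full counting chain (autofluorescence subtraction, top-hat, nuclei
#' expansion, thresholded counting) can be exercised.
#'
#' @param n_cells Number of cells.
#' @param mean_signals_per_cell Poisson mean of dots per cell.
#' @param nucleus_radius_px Nucleus disc radius, px.
#' @param dot_amplitude Dot peak amplitude, counts.
#' @param dot_sigma_px Dot Gaussian sigma, px (amplified PLA dots are about one pixel wide at widefield sampling).
#' @param placement_radius_px Dots are placed within this distance of the
#'   owning nucleus disc (default 65 px, matching the expansion used to
#'   define cell regions at counting time).
#' @param forced_counts Optional integer vector (length `n_cells`) of exact
#'   per-cell dot counts, overriding the Poisson draw.
#' @param seed Integer seed.
#' @return A list with `stack` (channels `dapi`, `pla`, `af`), and `truth`:
#'   `pla_counts` (true per-cell counts), nucleus `centers`, dot positions,
#'   and inputs.
#' @export
gen_pla_scene <- function(n_cells, mean_signals_per_cell,
                          nucleus_radius_px = 12, dot_amplitude = 150,
                          dot_sigma_px = 0.45, placement_radius_px = 65,
                          forced_counts = NULL, seed = 1L) {
  stopifnot(n_cells >= 1, mean_signals_per_cell >= 0)
  set.seed(seed)
  pitch <- 2 * (nucleus_radius_px + placement_radius_px) %/% 2 + 110
  pitch <- max(pitch, ceiling(2.2 * nucleus_radius_px))
  n_col <- ceiling(sqrt(n_cells))
  n_row <- ceiling(n_cells / n_col)
  margin <- nucleus_radius_px + placement_radius_px + 6
  nr <- (n_row - 1L) * pitch + 2 * margin
  nc <- (n_col - 1L) * pitch + 2 * margin
  if (pitch < 2 * nucleus_radius_px + 4) {
    rlang::abort("cannot pack the requested nuclei without overlap.")
  }
  jit <- pitch / 2 - nucleus_radius_px - 4
  jit <- max(min(jit, 10), 0)
  centers <- do.call(rbind, lapply(seq_len(n_cells) - 1L, function(i) {
    r <- margin + (i %/% n_col) * pitch + stats::runif(1, -jit, jit)
    c <- margin + (i %% n_col) * pitch + stats::runif(1, -jit, jit)
    c(r, c)
  }))

  counts <- if (!is.null(forced_counts)) {
    stopifnot(length(forced_counts) == n_cells)
    as.integer(forced_counts)
  } else {
    stats::rpois(n_cells, mean_signals_per_cell)
  }

  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dapi <- matrix(5, nr, nc)
  for (i in seq_len(n_cells)) {
    disc <- (rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2 <=
      nucleus_radius_px^2
    dapi[disc] <- 120
  }
  # smooth autofluorescence: gentle large-scale gradient plus offset
  af <- 6 + 4 * (rr / nr) + 3 * (cc / nc)

  dots <- vector("list", n_cells)
  rmax <- nucleus_radius_px + placement_radius_px - 2
  for (i in seq_len(n_cells)) {
    k <- counts[i]
    if (k == 0L) { dots[[i]] <- NULL; next }
    # uniform over the disc of radius rmax around the nucleus centre
    rad <- rmax * sqrt(stats::runif(k))
    th <- stats::runif(k, 0, 2 * pi)
    dots[[i]] <- tibble::tibble(
      cell = i,
      row = pmin(pmax(centers[i, 1L] + rad * sin(th), 3), nr - 2),
      col = pmin(pmax(centers[i, 2L] + rad * cos(th), 3), nc - 2))
  }
  dots <- dplyr::bind_rows(dots)
  pla <- af
  if (nrow(dots) > 0) {
    pla <- render_spots(pla, dots$row, dots$col,
                        rep(dot_amplitude, nrow(dots)), dot_sigma_px)
  }
  noise <- function(img) pmax(img + matrix(stats::rnorm(length(img), 0, 1.5),
                                           nrow(img), ncol(img)), 0)
  data <- array(0, dim = c(3L, 1L, nr, nc))
  data[1L, 1L, , ] <- noise(dapi)
  data[2L, 1L, , ] <- noise(pla)
  data[3L, 1L, , ] <- af
  list(
    stack = image_stack(data, pixel_size_nm = 160,
                        channel_names = c("dapi", "pla", "af")),
    truth = list(pla_counts = counts, centers = centers, dots = dots,
                 nucleus_radius_px = nucleus_radius_px,
                 placement_radius_px = placement_radius_px, seed = seed))
}

#' Simulate a tidy qPCR Cq table with known fold changes
#'
#' Treated-condition Cq of each target gene is shifted by `-log2(true_fold)`
#' relative to untreated; reference genes are unshifted. Gaussian replicate
#' noise of sd `cq_noise_sd` is added to every reaction.
#'
#' @param genes Character vector of target gene names.
#' @param true_fold Numeric vector of true fold changes (treated /
#'   untreated), one per gene, all > 0.
#' @param reference_genes Character vector of reference (housekeeping)
#'   genes.
#' @param cq_noise_sd Replicate noise sd, cycles.
#' @param replicates Replicates per (gene, condition), >= 1.
#' @param base_cq Baseline untreated Cq (genes are offset slightly from it
#'   so the table looks plate-like).
#' @param seed Integer seed.
#' @return A tibble `(gene, condition, replicate, cq)` with attributes
#'   `reference_genes` and `true_fold`.
#' @export
gen_qpcr_table <- function(genes, true_fold, reference_genes,
                           cq_noise_sd = 0.2, replicates = 3L,
                           base_cq = 24, seed = 1L) {
  stopifnot(length(true_fold) == length(genes), replicates >= 1)
  if (any(true_fold <= 0)) rlang::abort("`true_fold` must be positive.")
  set.seed(seed)
  all_genes <- c(genes, reference_genes)
  base <- base_cq + (seq_along(all_genes) - 1) * 0.7
  names(base) <- all_genes
  shift <- c(-log2(true_fold), rep(0, length(reference_genes)))
  names(shift) <- all_genes
  grid <- tidyr::expand_grid(
    gene = all_genes,
    condition = c("untreated", "treated"),
    replicate = seq_len(replicates))
  grid$cq <- base[grid$gene] +
    ifelse(grid$condition == "treated", shift[grid$gene], 0) +
    stats::rnorm(nrow(grid), 0, cq_noise_sd)
  out <- tibble::as_tibble(grid)
  attr(out, "reference_genes") <- reference_genes
  attr(out, "true_fold") <- stats::setNames(true_fold, genes)
  out
}
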