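# Greedy one-to-one matching of detections to ground-truth positions.
match_detections <- function(det, truth, radius_px = 2) {
  if (nrow(det) == 0) {
    return(list(tp = 0, recall = 0, precision = NA_real_))
  }
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (det$row - truth$row[i])^2 + (det$col - truth$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius_px^2) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, recall = tp / nrow(truth), precision = tp / nrow(det))
}

# Brute-force circle/annulus site measurement: enumerate every pixel of the
# image and accumulate sums by distance from the centre.
oracle_site <- function(image, center, bg_mask, circle_diam = 3,
                        annulus_outer = 5) {
  r_in <- circle_diam / 2
  r_out <- annulus_outer / 2
  sc <- 0; nc_ <- 0; sa <- 0; na_ <- 0; sb <- 0; nb <- 0
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      d <- sqrt((r - center[1])^2 + (c - center[2])^2)
      if (d <= r_in) {
        sc <- sc + image[r, c]; nc_ <- nc_ + 1
      } else if (d <= r_out) {
        sa <- sa + image[r, c]; na_ <- na_ + 1
      }
      if (bg_mask[r, c]) {
        sb <- sb + image[r, c]; nb <- nb + 1
      }
    }
  }
  cm <- sc / nc_; am <- sa / na_; bg <- sb / nb
  list(c = cm, a = am, bg = bg, delta_f = cm - am, s = am - bg,
       score = (cm - am) / (am - bg))
}

# Exhaustive integer-shift cross-correlation (no FFT).
oracle_shift <- function(ref, mov, max_shift = 6) {
  best <- c(0, 0); best_v <- -Inf
  a <- ref - mean(ref)
  b <- mov - mean(mov)
  nr <- nrow(ref); nc <- ncol(ref)
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      v <- sum(a[rs - dr, cs - dc] * b[rs, cs])
      if (v > best_v) {
        best_v <- v
        best <- c(dr, dc)
      }
    }
  }
  best
}

# Brute-force 8-neighbourhood local-maximum test at an integer position.
oracle_is_local_max <- function(image, r, c) {
  v <- image[r, c]
  for (dr in -1:1) {
    for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(image) || cc < 1 || cc > ncol(image)) next
      if (image[rr, cc] > v) return(FALSE)
    }
  }
  TRUE
}

# Brute-force grey-scale opening (erode then dilate) with a disc of the
# given diameter, followed by top-hat. Slow; only for small images.
oracle_tophat <- function(image, diam) {
  size <- as.integer(diam)
  if (size %% 2L == 0L) size <- size + 1L
  rad <- (size - 1) / 2
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) <= rad + 1e-9, ]
  nr <- nrow(image); nc <- ncol(image)
  sweep_img <- function(img, f) {
    out <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        rr <- r + offs$dr; cc <- c + offs$dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        out[r, c] <- f(img[cbind(rr[ok], cc[ok])])
      }
    }
    out
  }
  opened <- sweep_img(sweep_img(image, min), max)
  image - opened
}

# Small single-spot frame used by several unit tests.
toy_spot_frame <- function(n = 41, amp = 120, sigma = 1.2, cell_bg = 40,
                           off_bg = 8, center = c(21, 21)) {
  img <- matrix(cell_bg, n, n)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  img <- img + amp * exp(-((rr - center[1])^2 + (cc - center[2])^2) /
                           (2 * sigma^2))
  bg_mask <- matrix(FALSE, n, n)
  bg_mask[1:5, 1:5] <- TRUE
  img[bg_mask] <- off_bg
  list(image = img, bg_mask = bg_mask, center = center)
}

# Integer translation with median padding (test fixture construction).
translate_shift_fixture <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(median(img), nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- img[rs - dr, cs - dc]
  out
}
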