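test_that("max projection equals the per-pixel maximum oracle", {
  set.seed(61)
  planes <- lapply(1:11, function(i) matrix(runif(24 * 24, 0, 100), 24, 24))
  proj <- max_project(planes)
  oracle <- matrix(0, 24, 24)
  for (r in 1:24) for (c in 1:24) {
    oracle[r, c] <- max(vapply(planes, function(p) p[r, c], numeric(1)))
  }
  expect_identical(proj, oracle)
  expect_identical(max_project(planes[1]), planes[[1]])
  expect_equal(max_project(list(matrix(0, 8, 8), matrix(7, 8, 8))),
               matrix(7, 8, 8))
})

test_that("autofluorescence subtraction clips at zero", {
  img <- matrix(1:20 * 1.0, 4, 5)
  expect_equal(subtract_autofluorescence(img, img), matrix(0, 4, 5))
  expect_equal(subtract_autofluorescence(img, img * 0), img)
  af <- img * 0 + 10
  out <- subtract_autofluorescence(img, af)
  expect_true(all(out >= 0))
  expect_equal(out, pmax(img - 10, 0))
  expect_error(subtract_autofluorescence(img, matrix(0, 5, 4)), "shape")
})

test_that("top-hat keeps narrow dots and suppresses broad blobs", {
  expect_equal(tophat_clean(matrix(5, 40, 40)), matrix(0, 40, 40))
  rr <- matrix(seq_len(64), 64, 64); cc <- t(rr)
  dot <- 100 * exp(-((rr - 32)^2 + (cc - 32)^2) / (2 * 0.8^2))   # ~3 px wide
  th_dot <- tophat_clean(dot, 10)
  expect_gte(max(th_dot), 0.9 * max(dot))
  blob <- 100 * exp(-((rr - 32)^2 + (cc - 32)^2) / (2 * 13^2))   # ~30 px wide
  th_blob <- tophat_clean(blob, 10)
  expect_lt(max(th_blob), 0.1 * max(blob))
  # agreement with a brute-force opening oracle on the small dot image
  small <- dot[20:44, 20:44]
  expect_equal(tophat_clean(small, 10), oracle_tophat(small, 10),
               tolerance = 1e-6)
})

test_that("define_cells expands an isolated nucleus by the stated radius", {
  dapi <- matrix(5, 120, 120)
  rr <- matrix(seq_len(120), 120, 120); cc <- t(rr)
  disc <- (rr - 60)^2 + (cc - 60)^2 <= 10^2
  dapi[disc] <- 120
  res <- define_cells(dapi, expand_px = 30)
  expect_equal(res$n_cells, 1)
  d_to_nuc <- sqrt((rr - 60)^2 + (cc - 60)^2)
  got <- res$cells == 1
  # region must lie within nucleus radius + expansion (+1 px segmentation slack)
  expect_true(all(d_to_nuc[got] <= 10 + 30 + 1))
  expect_true(all(got[d_to_nuc <= 10 + 30 - 1.5]))
  expect_error(define_cells(matrix(5, 40, 40)), "no cells")
})

test_that("two nuclei split their shared territory at the midline", {
  dapi <- matrix(5, 140, 180)
  rr <- matrix(seq_len(140), 140, 180); cc <- matrix(seq_len(180), 140, 180,
                                                     byrow = TRUE)
  c1 <- c(70, 70); c2 <- c(70, 110)   # 40 px apart
  dapi[(rr - c1[1])^2 + (cc - c1[2])^2 <= 64] <- 120
  dapi[(rr - c2[1])^2 + (cc - c2[2])^2 <= 64] <- 120
  res <- define_cells(dapi, expand_px = 65)
  expect_equal(res$n_cells, 2)
  # nearest-nucleus brute-force oracle on a pixel sample
  d1 <- sqrt((rr - c1[1])^2 + (cc - c1[2])^2)
  d2 <- sqrt((rr - c2[1])^2 + (cc - c2[2])^2)
  sample_px <- which(res$cells > 0 & abs(d1 - d2) > 1.5)
  expect_true(all((res$cells[sample_px] == 1) ==
                    (d1[sample_px] < d2[sample_px])))
  # regions are disjoint by construction and each contains its nucleus
  expect_true(all(res$cells[res$nuclei == 1] == 1))
  expect_true(all(res$cells[res$nuclei == 2] == 2))
})

test_that("count_signals counts components per region with exact identities", {
  cells <- matrix(0L, 60, 60)
  cells[10:50, 5:30] <- 1L
  img <- matrix(0, 60, 60)
  dot_at <- function(img, r, c) { img[r + (-1:1), c + (-1:1)] <- 0.9; img }
  for (p in list(c(15, 10), c(20, 20), c(30, 12), c(40, 25), c(45, 8))) {
    img <- dot_at(img, p[1], p[2])
  }
  img <- dot_at(img, 15, 50)   # outside every region
  img <- dot_at(img, 50, 55)
  rep <- count_signals(img, cells)
  expect_equal(rep$signals_total, 5)
  expect_equal(unname(rep$per_cell_counts), 5L)
  expect_equal(rep$signals_per_cell * rep$n_cells, rep$signals_total)
  expect_equal(sum(rep$per_cell_counts), rep$signals_total)
  expect_equal(glance(rep)$signals_per_cell, 5)
  # blank image
  rep0 <- count_signals(img * 0, cells)
  expect_equal(rep0$signals_per_cell, 0)
  # unnormalized input errors unless auto_normalize
  expect_error(count_signals(img * 300, cells), "normalize")
  expect_s3_class(count_signals(img * 300, cells, auto_normalize = TRUE),
                  "pla_report")
})

test_that("counting is monotone non-increasing in the threshold", {
  # isolated unimodal dots of graded peak intensity: raising the threshold
  # can only remove whole dots, never split one
  cells <- matrix(1L, 80, 80)
  rr <- matrix(seq_len(80), 80, 80); cc <- t(rr)
  img <- matrix(0, 80, 80)
  peaks <- seq(0.1, 0.9, by = 0.1)
  centres <- expand.grid(r = c(15, 40, 65), c = c(15, 40, 65))
  for (i in seq_len(9)) {
    img <- img + peaks[i] * exp(-((rr - centres$r[i])^2 +
                                    (cc - centres$c[i])^2) / (2 * 1.2^2))
  }
  totals <- vapply(c(0.05, 0.15, 0.35, 0.55, 0.85), function(thr) {
    count_signals(img, cells, thr)$signals_total
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
  expect_equal(totals[1], 9)
  expect_equal(totals[5], 1)
})

test_that("the full chain recovers the realized signals per cell", {
  for (m in c(5, 40)) {
    sc <- gen_pla_scene(15, m, seed = 63)
    est <- pla_signals_per_cell(sc$stack)$signals_per_cell
    truth <- mean(sc$truth$pla_counts)
    expect_lt(abs(est - truth) / max(truth, 1), 0.1)
  }
})
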