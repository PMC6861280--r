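# Nucleus segmentation, focus detection and the colocalization TIF rule:
# two foci colocalize when >= 5 supra-threshold pixels overlap within the
# same z-section, and a cell is positive with >= 1 TIF.

test_that("nucleus segmentation handles empty, single and simulated fields", {
  blank <- image_stack(array(0, c(64, 64, 2, 1)), "nuclear_stain")
  expect_identical(max(segment_nuclei(blank)), 0L)

  one <- matrix(0, 128, 128)
  one[disk_mask(128, 30) == 1L] <- 100
  lab1 <- segment_nuclei(image_stack(array(one, c(128, 128, 1, 1)),
                                     "nuclear_stain"))
  expect_identical(max(lab1), 1L)
  expect_lt(abs(sum(lab1 == 1) - pi * 30^2) / (pi * 30^2), 0.1)

  sim <- simulate_tif_stack(sim_config(seed = 11, n_nuclei = 5, width = 200,
                                       height = 200))
  lab <- segment_nuclei(sim$stack)
  expect_identical(max(lab), 5L)
  tl <- labels_at_true_centres(lab, sim$truth$nuclei)
  expect_true(all(tl > 0) && !anyDuplicated(tl))
  for (i in seq_len(5)) {
    got <- lab == tl[i]
    true <- sim$truth$mask == sim$truth$nuclei$id[i]
    iou <- sum(got & true) / sum(got | true)
    expect_gte(iou, 0.8)
  }
})

test_that("focus detection obeys threshold, size and centroid conventions", {
  flat <- image_stack(array(5, c(40, 40, 3, 1)), "ddr_marker")
  all_one <- matrix(1L, 40, 40)
  expect_identical(nrow(detect_foci(flat, "ddr_marker", all_one)$foci), 0L)

  # one 3x3 supra-threshold plateau above a fixed threshold -> 1 focus, 9 px
  img <- array(0, c(40, 40, 3, 1))
  img[10:12, 20:22, 2, 1] <- 100
  st <- image_stack(img, "ddr_marker")
  p <- coloc_params(threshold = "fixed", threshold_value = 50, min_size = 4,
                    smooth_sigma = 0)
  fs <- detect_foci(st, "ddr_marker", all_one, p)
  expect_identical(nrow(fs$foci), 1L)
  expect_identical(fs$foci$n_px, 9L)
  # raising min_size above the plateau removes it
  p2 <- coloc_params(threshold = "fixed", threshold_value = 50, min_size = 10,
                     smooth_sigma = 0)
  expect_identical(nrow(detect_foci(st, "ddr_marker", all_one, p2)$foci), 0L)

  expect_error(coloc_params(threshold = "nope"))
  expect_error(detect_foci(st, "telomere_marker", all_one), "not present")
})

test_that("the 5-pixel same-section overlap rule is exact at the boundary", {
  dim <- c(20L, 20L, 4L)
  mk <- function(px) focus_set(list(px), 1L, "ddr_marker", dim)
  mkt <- function(px) focus_set(list(px), 1L, "telomere_marker", dim)
  base <- data.frame(z = 3L, y = 5:9, x = 5L)       # 5 px column in z = 3

  five <- call_tifs(mk(base), mkt(base), coloc_params(min_overlap = 5))
  expect_identical(nrow(five$events), 1L)
  expect_identical(five$events$overlap, 5L)
  expect_identical(five$records$n_tif, 1L)
  expect_true(five$records$positive)

  four <- call_tifs(mk(base), mkt(data.frame(z = 3L, y = 5:8, x = 5L)),
                    coloc_params(min_overlap = 5))
  expect_identical(nrow(four$events), 0L)
  expect_false(any(four$records$positive))

  # 10 shared (y, x) pixels but in different sections: no TIF
  a <- data.frame(z = 2L, y = rep(5:9, 2), x = rep(5:6, each = 5))
  b <- transform(a, z = 3L)
  cross <- call_tifs(mk(a), mkt(b), coloc_params(min_overlap = 5))
  expect_identical(nrow(cross$events), 0L)

  # different nuclei never colocalize even with identical pixels
  other <- call_tifs(focus_set(list(base), 2L, "ddr_marker", dim), mkt(base))
  expect_identical(nrow(other$events), 0L)
})

test_that("TIF calling is symmetric, bounded, and monotone in min overlap", {
  set.seed(42)
  for (rep in 1:40) {
    pr <- random_focus_pair()
    ab <- call_tifs(pr$ddr, pr$telo, coloc_params())
    ba <- call_tifs(pr$telo, pr$ddr, coloc_params())
    expect_identical(ab$events$overlap, ba$events$overlap)
    expect_identical(ab$records$n_tif, ba$records$n_tif)
    expect_lte(max(ab$records$n_tif), 1L)  # <= min(#ddr, #telo) = 1
    n5 <- sum(call_tifs(pr$ddr, pr$telo,
                        coloc_params(min_overlap = 5))$records$n_tif)
    n8 <- sum(call_tifs(pr$ddr, pr$telo,
                        coloc_params(min_overlap = 8))$records$n_tif)
    expect_lte(n8, n5)
  }
})

test_that("event emission matches the brute-force intersection oracle", {
  set.seed(99)
  for (rep in 1:200) {
    pr <- random_focus_pair()
    got <- call_tifs(pr$ddr, pr$telo, coloc_params())$events
    oracle <- brute_tif_events(pr$ddr, pr$telo, 5L)
    expect_identical(nrow(got), nrow(oracle))
    if (nrow(got)) {
      ord <- order(got$ddr_id, got$telo_id, got$z)
      expect_identical(cbind(got$ddr_id, got$telo_id, got$z, got$overlap)[ord, ,
                                                                drop = FALSE],
                       matrix(as.integer(oracle), ncol = 4))
    }
  }
})

test_that("a simulated nucleus with planted pairs and extra DDR foci counts
          only the pairs", {
  sim <- simulate_tif_stack(sim_config(seed = 21, n_nuclei = 4, width = 200,
                                       height = 200, telo_foci = c(3, 3),
                                       nucleus_radius = c(15L, 16L),
                                       coloc_fraction = 1, ddr_extra = c(2, 2)))
  rec <- recover_tif_counts(sim)
  expect_true(all(rec$true == 3))
  expect_identical(rec$got, rec$true)
})

test_that("per-nucleus TIF recovery at SNR 8 meets the accuracy floor", {
  sim <- simulate_tif_stack(sim_config(seed = 101, telo_foci = c(0, 6),
                                       coloc_fraction = 1,
                                       ddr_extra = c(0, 2), snr = 8))
  rec <- recover_tif_counts(sim)
  expect_gte(mean(rec$got == rec$true), 0.95)
  expect_gte(mean((rec$got >= 1) == (rec$true >= 1)), 0.98)
})

test_that("focus-count error shrinks as SNR grows", {
  mae <- vapply(c(2, 4, 8, 16), function(snr) {
    sim <- simulate_tif_stack(sim_config(seed = 31, n_nuclei = 12, width = 260,
                                         height = 260, snr = snr,
                                         telo_foci = c(1, 5),
                                         coloc_fraction = 0))
    lab <- segment_nuclei(sim$stack)
    fs <- detect_foci(sim$stack, "telomere_marker", lab)
    tl <- labels_at_true_centres(lab, sim$truth$nuclei)
    got <- vapply(tl, function(l) sum(fs$foci$nucleus == l), numeric(1))
    true <- vapply(sim$truth$nuclei$id, function(i)
      sum(sim$truth$foci$nucleus == i &
            sim$truth$foci$channel == "telomere_marker"), numeric(1))
    mean(abs(got - true))
  }, numeric(1))
  expect_true(all(diff(mae) <= 0))   # monotone improvement...
  expect_lt(mae[4], mae[1])          # ...and strictly better at the extremes
})

test_that("RNAscope positivity uses the 3-dot minimum", {
  expect_identical(rnascope_positive(c(0, 2, 3, 7)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_true(rnascope_positive(2, min_dots = 2))
  expect_error(rnascope_positive(-1), "nonnegative")
})
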