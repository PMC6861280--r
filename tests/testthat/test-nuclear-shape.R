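# Lamin segmentation and the circularity index C = 4*pi*A/P^2 (1 = circle,
# 0 = straight-line limit).

test_that("lamin segmentation fills rims into nucleus regions", {
  blank <- image_stack(array(0, c(64, 64, 1, 1)), "lamin")
  expect_identical(max(segment_lamin(blank)), 0L)

  solid <- matrix(0, 120, 120)
  solid[outer(((1:120 - 60) / 40)^2, ((1:120 - 60) / 25)^2, `+`) <= 1] <- 80
  lab <- segment_lamin(image_stack(array(solid, c(120, 120, 1, 1)), "lamin"))
  expect_identical(max(lab), 1L)

  env <- simulate_nuclear_envelope(sim_config(seed = 13, width = 220,
                                              height = 220,
                                              n_envelope_nuclei = 3,
                                              shape_amplitude = 0.1))
  seg <- segment_lamin(env$stack)
  expect_identical(max(seg), 3L)
  tl <- labels_at_true_centres(seg, env$truth$nuclei)
  for (i in seq_len(3)) {
    got <- seg == tl[i]
    true <- env$truth$mask == env$truth$nuclei$id[i]
    expect_gte(sum(got & true) / sum(got | true), 0.9)
  }
})

test_that("circularity endpoints: rasterized circle scores 1, degenerate
          outline scores 0", {
  rec <- circularity_from_labels(disk_mask(256, 100))
  expect_equal(rec$circularity, 1, tolerance = 0.01)

  line <- nucleus_outline(cbind(c(0, 5, 10, 5, 0), c(0, 0, 0, 0, 0)))
  expect_identical(circularity_index(line)$circularity, 0)

  expect_error(nucleus_outline(cbind(c(0, 5, 10), c(0, 1, 0))), "closed")
})

test_that("a 2:1 ellipse matches the Ramanujan-perimeter closed form", {
  a <- 100; b <- 50
  m <- matrix(0L, 300, 300)
  m[outer(((1:300 - 150.5) / b)^2, ((1:300 - 150.5) / a)^2, `+`) <= 1] <- 1L
  got <- circularity_from_labels(m)$circularity
  oracle <- 4 * pi * (pi * a * b) / ram_perimeter(a, b)^2
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("circularity is scale invariant within discretization tolerance", {
  vals <- vapply(c(50, 100, 150), function(r)
    circularity_from_labels(disk_mask(2 * r + 56, r))$circularity, numeric(1))
  expect_lt(max(abs(vals - vals[1]) / vals[1]), 0.02)
  # area and perimeter scale as k^2 and k while C stays fixed
  r1 <- circularity_from_labels(disk_mask(156, 50))
  r2 <- circularity_from_labels(disk_mask(256, 100))
  expect_equal(r2$area_px / r1$area_px, 4, tolerance = 0.02)
  expect_equal(r2$perimeter_px / r1$perimeter_px, 2, tolerance = 0.02)
})

test_that("every emitted circularity lies in the unit interval", {
  for (a in c(0, 0.2, 0.45)) {
    env <- simulate_nuclear_envelope(sim_config(seed = 17, width = 220,
                                                height = 220,
                                                n_envelope_nuclei = 2,
                                                shape_amplitude = a,
                                                envelope_radius = c(24L, 30L)))
    rec <- circularity_from_labels(segment_lamin(env$stack))
    expect_true(all(rec$circularity >= 0 & rec$circularity <= 1))
  }
})

test_that("measured circularity decreases monotonically with boundary
          perturbation amplitude", {
  means <- vapply(c(0, 0.1, 0.2, 0.3), function(a) {
    env <- simulate_nuclear_envelope(sim_config(seed = 19, width = 300,
                                                height = 300,
                                                n_envelope_nuclei = 4,
                                                shape_amplitude = a))
    mean(circularity_from_labels(segment_lamin(env$stack))$circularity)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("group profiles recover a planted circularity gap", {
  rec <- data.frame(nucleus_label = 1:6, area_px = 1, perimeter_px = 1,
                    circularity = rep(0.9, 6))
  prof <- circularity_profile(rec, rep(c("a", "b"), each = 3))
  expect_equal(prof$sd, c(0, 0))
  expect_equal(prof$mean, c(0.9, 0.9))
  expect_identical(prof$n, c(3L, 3L))

  # two generated groups with a true mean gap of ~0.2
  gap_target <- 0.2
  amps <- seq(0.05, 0.4, by = 0.005)
  truths <- vapply(amps, function(a) {
    th <- seq(0, 2 * pi, length.out = 2049)[-2049]
    r <- 1 + a * sin(4 * th); dr <- 4 * a * cos(4 * th)
    P <- sum(sqrt(r^2 + dr^2)) * 2 * pi / 2048
    A <- sum(r^2 / 2) * 2 * pi / 2048
    4 * pi * A / P^2
  }, numeric(1))
  a_gap <- amps[which.min(abs((1 - truths) - gap_target))]
  measure <- function(a, seeds) {
    unlist(lapply(seeds, function(s) {
      env <- simulate_nuclear_envelope(sim_config(seed = s,
                                                  n_envelope_nuclei = 6,
                                                  shape_amplitude = a))
      circularity_from_labels(segment_lamin(env$stack))$circularity
    }))
  }
  circ0 <- measure(0, 41:48)        # 48 circles
  circ1 <- measure(a_gap, 51:58)    # 48 perturbed nuclei
  expect_gt(mean(circ0), mean(circ1))
  true_gap <- 1 - truths[which.min(abs((1 - truths) - gap_target))]
  expect_lt(abs((mean(circ0) - mean(circ1)) - true_gap), 0.05)
})
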