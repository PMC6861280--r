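# The generators must be deterministic under a seed, carry self-consistent
# ground truth, and invert cleanly at zero noise.

small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_nuclei = 6, width = 200, height = 200, ...)
}

test_that("identical seed and config give byte-identical simulations", {
  a <- simulate_tif_stack(small_cfg())
  b <- simulate_tif_stack(small_cfg())
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_qpcr(small_cfg()), simulate_qpcr(small_cfg()))
  expect_identical(simulate_histo(small_cfg()), simulate_histo(small_cfg()))
  expect_identical(simulate_survival(small_cfg()),
                   simulate_survival(small_cfg()))
  # a different seed must actually change the field
  c <- simulate_tif_stack(small_cfg(seed = 8))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("simulation leaves the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_qpcr(small_cfg()))
  expect_identical(before, .Random.seed)
})

test_that("colocalized fraction controls the planted pair structure", {
  none <- simulate_tif_stack(small_cfg(coloc_fraction = 0,
                                       telo_foci = c(3, 5)))
  expect_true(all(none$truth$tif_counts$n_tif == 0))
  expect_identical(nrow(none$truth$pairs), 0L)

  half <- simulate_tif_stack(small_cfg(coloc_fraction = 0.5,
                                       telo_foci = c(4, 4),
                                       ddr_extra = c(0, 0)))
  # deterministic per nucleus: round(0.5 * 4) = 2 pairs each
  expect_true(all(half$truth$tif_counts$n_tif == 2))
  expect_identical(nrow(half$truth$pairs), 2L * nrow(half$truth$nuclei))
})

test_that("ground truth is internally consistent", {
  sim <- simulate_tif_stack(small_cfg(coloc_fraction = 0.7,
                                      telo_foci = c(0, 6)))
  tr <- sim$truth
  for (i in tr$nuclei$id)
    expect_identical(tr$tif_counts$n_tif[tr$tif_counts$nucleus == i],
                     sum(tr$pairs$nucleus == i))
  # every pair references one focus per channel within the same nucleus
  for (k in seq_len(nrow(tr$pairs))) {
    tf <- tr$foci[tr$foci$id == tr$pairs$telo_id[k], ]
    df <- tr$foci[tr$foci$id == tr$pairs$ddr_id[k], ]
    expect_identical(tf$channel, "telomere_marker")
    expect_identical(df$channel, "ddr_marker")
    expect_identical(tf$nucleus, df$nucleus)
    expect_identical(tf$nucleus, tr$pairs$nucleus[k])
    expect_identical(tf$z, df$z)  # planted pairs share their z-section
  }
})

test_that("impossible geometry raises an explicit placement error", {
  expect_error(
    simulate_tif_stack(sim_config(seed = 1, n_nuclei = 50, width = 80,
                                  height = 80)),
    "could not place")
})

test_that("envelope ground truth matches analytic shape oracles", {
  env_cfg <- function(...) sim_config(seed = 7, ...)
  circles <- simulate_nuclear_envelope(env_cfg(shape_amplitude = 0,
                                               n_envelope_nuclei = 4))
  expect_true(all(circles$truth$nuclei$circularity == 1))

  ell <- simulate_nuclear_envelope(env_cfg(shape_kind = "ellipse",
                                           ellipse_ratio = 2,
                                           n_envelope_nuclei = 3))
  for (i in seq_len(3)) {
    R <- ell$truth$nuclei$r[i]
    a <- R * sqrt(2); b <- R / sqrt(2)
    oracle <- 4 * pi * (pi * a * b) / ram_perimeter(a, b)^2
    expect_equal(ell$truth$nuclei$circularity[i], oracle, tolerance = 1e-10)
  }

  # recorded sinusoid truth agrees with an independent dense-polygon oracle
  # and decreases with perturbation amplitude
  truths <- vapply(c(0.05, 0.15, 0.25), function(a) {
    env <- simulate_nuclear_envelope(env_cfg(shape_amplitude = a,
                                             n_envelope_nuclei = 2))
    tr <- env$truth$nuclei
    oracle <- vapply(tr$r, polygon_circularity, numeric(1), a = a, k = 4)
    expect_equal(tr$circularity, oracle, tolerance = 1e-4)
    mean(tr$circularity)
  }, numeric(1))
  expect_true(all(diff(truths) < 0))
})

test_that("qPCR generator inverts exactly at zero noise", {
  cfg <- small_cfg(qpcr_noise_sd = 0, qpcr_sample_sd = 0,
                   qpcr_targets = list(teloG = c(1, 4)))
  ct <- simulate_qpcr(cfg)
  expect_true(all(table(ct$sample_id, ct$target) == cfg$qpcr_replicates))
  re <- relative_expression(collapse_replicates(ct), "Rplp0", "laminA")
  expect_equal(re$fold[re$group == "progerin"], rep(4, 3), tolerance = 1e-12)
  expect_equal(re$fold[re$group == "laminA"], rep(1, 3), tolerance = 1e-12)
})

test_that("histology generator's recorded score equals direct recomputation", {
  ht <- simulate_histo(small_cfg(histo_n = 10))
  expect_true(all(ht$severity %in% 0:3) && all(ht$extent %in% 1:3))
  direct <- tapply(ht$severity * ht$extent, ht$sample_id, sum)
  truth <- attr(ht, "truth")
  expect_equal(as.vector(direct[truth$sample_id]), truth$cumulative)
})

test_that("survival generator hits the configured medians", {
  fx <- simulate_survival(small_cfg(surv_family = "fixed", surv_median = 8))
  expect_true(all(fx$day == 8) && all(fx$event == 1))
  km <- survival_analysis(fx, control = "HGPS_ctrlASO")
  expect_identical(km$curves[["HGPS_ctrlASO"]]$median, 8)

  wb <- simulate_survival(small_cfg(surv_family = "weibull",
                                    surv_median = c(8, 9.92), surv_n = 400))
  med <- tapply(wb$day, wb$group, median)
  expect_equal(unname(med["HGPS_ctrlASO"]), 8, tolerance = 0.15)
})

test_that("stacks survive a TIFF round trip", {
  sim <- simulate_tif_stack(sim_config(seed = 7, n_nuclei = 3, width = 96,
                                       height = 96))
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_identical(back$channels, sim$stack$channels)
  expect_equal(back$data, sim$stack$data, tolerance = 1e-5)
})
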