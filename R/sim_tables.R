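# Synthetic tabular inputs: Ct tables, histology ordinal scores, survival
# cohorts, and IHC fields, each with attached ground truth.

#' Simulate a replicate Ct table
#'
#' Ct values follow `baseline - log2(true fold) + sample shift + technical
#' noise`; the reference gene is generated with true fold 1 in every group,
#' and each reaction is measured as `qpcr_replicates` technical replicates
#' (triplicate by default). The per-sample shift models loading/RT
#' efficiency and hits every target of a sample equally, so it cancels in
#' the delta-Ct.
#'
#' @param config a [sim_config()]
#' @return a `data.frame` with columns `sample_id, group, target, strand,
#'   assay_class, replicate, ct` and an attribute `truth` (per-target,
#'   per-group true fold changes).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    groups <- config$qpcr_groups
    targets <- config$qpcr_targets
    ref <- config$qpcr_reference
    all_targets <- c(targets, stats::setNames(list(rep(1, length(groups))), ref))
    strand_of <- function(t) {
      if (grepl("G$", t)) "G-rich" else if (grepl("C$", t)) "C-rich" else "none"
    }
    class_of <- function(t) {
      if (t == ref) "mRNA"
      else if (grepl("^tDDRNA", t)) "small-RNA" else "dilncRNA"
    }
    rows <- list()
    truth <- list()
    for (gi in seq_along(groups)) {
      for (si in seq_len(config$qpcr_n)) {
        sample_id <- sprintf("%s_s%02d", groups[gi], si)
        shift <- stats::rnorm(1, 0, config$qpcr_sample_sd)
        for (tn in names(all_targets)) {
          fold <- rep(all_targets[[tn]], length.out = length(groups))[gi]
          baseline <- 26  # cycles, arbitrary but fixed per target class
          mu <- baseline - log2(fold) + shift
          ct <- mu + stats::rnorm(config$qpcr_replicates, 0, config$qpcr_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, group = groups[gi], target = tn,
            strand = strand_of(tn), assay_class = class_of(tn),
            replicate = seq_len(config$qpcr_replicates), ct = ct)
          truth[[paste(tn, groups[gi])]] <-
            data.frame(target = tn, group = groups[gi], true_fold = fold)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- do.call(rbind, unname(truth))
    out
  })
}

#' Simulate an ordinal histopathology score table
#'
#' Draws, for every sample and each of the five skin-damage variables
#' (epidermal hyperplasia, basal layer disarray, keratinocyte nuclear
#' atypia, keratinocyte apoptotic/necrotic figures, dermal stromal
#' remodeling), a severity in 0-3 and an extent in 1-3 from the per-group
#' ordinal distributions of the config.
#'
#' @param config a [sim_config()]
#' @return `data.frame(sample_id, group, variable, severity, extent)` with an
#'   attribute `truth` holding the per-sample cumulative score recomputed
#'   directly at generation time.
#' @export
simulate_histo <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    rows <- list()
    for (g in config$histo_groups) {
      psv <- config$histo_severity[[g]]; pex <- config$histo_extent[[g]]
      for (si in seq_len(config$histo_n)) {
        sample_id <- sprintf("%s_h%02d", g, si)
        sev <- sample(0:3, length(histo_variables), replace = TRUE, prob = psv)
        ext <- sample(1:3, length(histo_variables), replace = TRUE, prob = pex)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, group = g, variable = histo_variables,
          severity = sev, extent = ext)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    true_score <- tapply(out$severity * out$extent, out$sample_id, sum)
    attr(out, "truth") <- data.frame(sample_id = names(true_score),
                                     cumulative = as.vector(true_score))
    out
  })
}

#' Simulate a survival cohort
#'
#' Event times are drawn per group from the configured family with the
#' configured median matched exactly (Weibull scale `m / log(2)^(1/shape)`,
#' exponential rate `log(2) / m`, or all animals at the median for
#' `"fixed"`), optionally rounded to integer days — the resolution at which
#' short-lived progeria cohorts are followed — and optionally censored.
#'
#' @param config a [sim_config()]
#' @return `data.frame(animal_id, group, day, event)` with attribute `truth`
#'   (per-group configured median).
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    rows <- list()
    for (gi in seq_along(config$surv_groups)) {
      g <- config$surv_groups[gi]
      m <- rep(config$surv_median, length.out = length(config$surv_groups))[gi]
      n <- config$surv_n
      t <- switch(config$surv_family,
        fixed = rep(m, n),
        exponential = stats::rexp(n, rate = log(2) / m),
        weibull = stats::rweibull(n, shape = config$surv_shape,
                                  scale = m / log(2)^(1 / config$surv_shape)))
      if (config$round_days) t <- pmax(1, round(t))
      ev <- ifelse(stats::runif(n) < config$surv_censor_prob, 0L, 1L)
      rows[[gi]] <- data.frame(
        animal_id = sprintf("%s_a%02d", g, seq_len(n)),
        group = g, day = t, event = ev)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(group = config$surv_groups,
                                     true_median = rep(config$surv_median,
                                       length.out = length(config$surv_groups)))
    out
  })
}

#' Simulate one IHC high-power field
#'
#' Plants `n_nuclei` disk nuclei in a field, assigns a planted fraction a
#' high mean stain intensity (positive) and the rest a low one, and returns
#' the intensity image, nucleus label mask, an all-epidermis mask and the
#' planted positivity truth.
#'
#' @param n_nuclei nuclei in the field
#' @param frac_positive planted fraction of positive nuclei
#' @param seed integer seed
#' @param width,height field size (px)
#' @param mean_neg,mean_pos mean stain intensity of negative / positive nuclei
#' @param noise_sd pixelwise intensity noise sd
#' @return list with `intensity`, `nuclei` (label matrix), `epidermis`
#'   (logical matrix) and `truth` (`nucleus, positive`)
#' @export
simulate_ihc_field <- function(n_nuclei = 100, frac_positive = 0.3, seed = 1L,
                               width = 360L, height = 360L,
                               mean_neg = 20, mean_pos = 120, noise_sd = 8) {
  with_seed(seed, {
    nuc <- place_nuclei(n_nuclei, c(7L, 10L), height, width)
    img <- matrix(stats::rnorm(height * width, 5, noise_sd), height, width)
    lab <- matrix(0L, height, width)
    n_pos <- round(frac_positive * n_nuclei)
    positive <- seq_len(n_nuclei) %in% sample(n_nuclei, n_pos)
    for (i in seq_len(n_nuclei)) {
      d2 <- outer((seq_len(height) - nuc$y[i])^2, (seq_len(width) - nuc$x[i])^2, `+`)
      inside <- d2 <= nuc$r[i]^2
      lab[inside] <- i
      img[inside] <- img[inside] + if (positive[i]) mean_pos else mean_neg
    }
    list(intensity = pmax(img, 0), nuclei = lab,
         epidermis = matrix(TRUE, height, width),
         truth = data.frame(nucleus = seq_len(n_nuclei), positive = positive))
  })
}

#' The five skin-damage histology variables
#' @export
histo_variables <- c("epidermal_hyperplasia", "basal_layer_disarray",
                     "keratinocyte_nuclear_atypia",
                     "keratinocyte_apoptotic_necrotic_figures",
                     "dermal_stromal_remodeling")
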