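#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults encode
#' the study conditions the pipeline is meant to exercise: fields of ~25
#' fibroblast-like nuclei imaged as 5 optical sections, diffraction-limited
#' foci (sigma ~1.5 px) at SNR 8, qPCR designs with triplicate reactions and
#' a reference gene, ordinal skin-damage histology over five variables, and
#' short-lifespan progeria cohorts (control median survival 8 days).
#'
#' @param seed integer seed; each generator consumes one private stream.
#' @param width,height,n_z field geometry in pixels / optical sections.
#' @param n_nuclei nuclei per field.
#' @param nucleus_radius length-2 integer range of nucleus radii (px).
#' @param telo_foci length-2 range; per-nucleus telomere-marker focus count is
#'   drawn uniformly from this range.
#' @param ddr_extra length-2 range of additional non-colocalizing DDR foci.
#' @param coloc_fraction fraction of telomere foci with a colocalized DDR
#'   focus, applied deterministically per nucleus (`round(fraction * n)`).
#' @param spot_sigma Gaussian focus sigma (px).
#' @param snr peak spot amplitude divided by background standard deviation.
#' @param bg_level mean background photon count.
#' @param read_sd additive Gaussian read-noise sd (counts).
#' @param shape_amplitude nuclear-envelope boundary perturbation amplitude in
#'   `[0, 1)`; 0 gives perfect circles.
#' @param shape_lobes number of sinusoidal lobes of the boundary perturbation.
#' @param shape_kind `"sinusoidal"` or `"ellipse"` envelope model.
#' @param ellipse_ratio major/minor axis ratio for `shape_kind = "ellipse"`.
#' @param envelope_radius length-2 radius range (px) for envelope simulation
#'   (larger than TIF-field nuclei so perimeter discretization error is small).
#' @param n_envelope_nuclei nuclei per envelope field.
#' @param qpcr_groups character vector of group names; the first group is the
#'   calibrator.
#' @param qpcr_targets named list: per target, a numeric vector of true fold
#'   changes per group (recycled), e.g. `list(teloG = c(1, 4))`.
#' @param qpcr_reference reference gene name (true fold 1 everywhere).
#' @param qpcr_n samples per group.
#' @param qpcr_replicates technical replicates per reaction (triplicate).
#' @param qpcr_noise_sd technical Ct noise sd (cycles).
#' @param qpcr_sample_sd per-sample loading shift sd (cycles), applied to all
#'   targets of a sample including the reference.
#' @param histo_groups character vector of group names.
#' @param histo_n samples per group.
#' @param histo_severity named list: per group, probability vector over
#'   severity levels 0..3 (recycled over variables).
#' @param histo_extent named list: per group, probability vector over extent
#'   levels 1..3.
#' @param surv_groups character vector of group names; first is control.
#' @param surv_median numeric vector of per-group median survival (days).
#' @param surv_n per-group cohort size.
#' @param surv_family `"weibull"`, `"exponential"` or `"fixed"` event-time
#'   family (medians are matched exactly for all three).
#' @param surv_shape Weibull shape (larger = tighter around the median).
#' @param surv_censor_prob probability an animal is censored at its drawn time.
#' @param round_days round survival times to integer days (the study's
#'   resolution)?
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       width = 360L, height = 360L, n_z = 5L,
                       n_nuclei = 25L,
                       nucleus_radius = c(11L, 16L),
                       telo_foci = c(2L, 5L),
                       ddr_extra = c(0L, 2L),
                       coloc_fraction = 0.5,
                       spot_sigma = 1.5,
                       snr = 8,
                       bg_level = 10,
                       read_sd = 2,
                       shape_amplitude = 0.15,
                       shape_lobes = 4L,
                       shape_kind = c("sinusoidal", "ellipse"),
                       ellipse_ratio = 2,
                       envelope_radius = c(28L, 40L),
                       n_envelope_nuclei = 8L,
                       qpcr_groups = c("laminA", "progerin"),
                       qpcr_targets = list(teloG = c(1, 4), teloC = c(1, 4)),
                       qpcr_reference = "Rplp0",
                       qpcr_n = 3L,
                       qpcr_replicates = 3L,
                       qpcr_noise_sd = 0.2,
                       qpcr_sample_sd = 0.3,
                       histo_groups = c("WT", "HGPS", "HGPS_tASO"),
                       histo_n = 6L,
                       histo_severity = list(
                         WT        = c(0.70, 0.25, 0.05, 0.00),
                         HGPS      = c(0.05, 0.15, 0.40, 0.40),
                         HGPS_tASO = c(0.25, 0.40, 0.25, 0.10)),
                       histo_extent = list(
                         WT        = c(0.80, 0.15, 0.05),
                         HGPS      = c(0.10, 0.40, 0.50),
                         HGPS_tASO = c(0.40, 0.40, 0.20)),
                       surv_groups = c("HGPS_ctrlASO", "HGPS_antiTeloG"),
                       surv_median = c(8, 9.92),
                       surv_n = 13L,
                       surv_family = c("weibull", "exponential", "fixed"),
                       surv_shape = 4,
                       surv_censor_prob = 0,
                       round_days = TRUE) {
  shape_kind <- match.arg(shape_kind)
  surv_family <- match.arg(surv_family)
  stopifnot(
    coloc_fraction >= 0, coloc_fraction <= 1,
    snr > 0, bg_level >= 0, read_sd >= 0, spot_sigma > 0,
    shape_amplitude >= 0, shape_amplitude < 1,
    qpcr_replicates >= 1, qpcr_n >= 1,
    all(unlist(qpcr_targets) > 0),
    all(surv_median > 0), surv_n >= 1,
    length(nucleus_radius) == 2, nucleus_radius[1] <= nucleus_radius[2])
  for (g in histo_groups) {
    sv <- histo_severity[[g]]; ex <- histo_extent[[g]]
    if (is.null(sv) || length(sv) != 4 || any(sv < 0) || sum(sv) <= 0)
      stop("histo_severity[['", g, "']] must be 4 nonnegative weights (levels 0-3)")
    if (is.null(ex) || length(ex) != 3 || any(ex < 0) || sum(ex) <= 0)
      stop("histo_extent[['", g, "']] must be 3 nonnegative weights (levels 1-3)")
  }
  cfg <- mget(ls(environment()), envir = environment())
  cfg <- cfg[setdiff(names(cfg), c("g", "sv", "ex"))]
  structure(cfg, class = "sim_config")
}

# expected background sd under Poisson shot noise + Gaussian read noise
bg_sd <- function(config) sqrt(config$bg_level + config$read_sd^2)
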