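# Semiquantitative skin-damage scoring: each of five morphological variables
# is graded by severity (0 absent, 1 mild, 2 moderate, 3 severe) and extent
# (1 focal, 2 multifocal, 3 diffuse); the per-variable score is their
# product and the sample score the sum over the five variables (0..45).

#' Per-variable damage score
#'
#' @param severity integer in 0..3
#' @param extent integer in 1..3 (irrelevant when severity is 0: an absent
#'   lesion has no extent, the product is 0 regardless)
#' @return integer product score(s)
#' @export
variable_score <- function(severity, extent) {
  if (any(!severity %in% 0:3)) stop("severity must be in 0..3")
  if (any(!extent %in% 1:3)) stop("extent must be in 1..3")
  as.integer(severity) * as.integer(extent)
}

#' Cumulative damage score of one sample
#'
#' Requires exactly the five named variables, once each; the cumulative
#' score is the sum of the five severity-by-extent products (range 0-45).
#'
#' @param variables data.frame with columns `variable, severity, extent`
#' @return list with `per_variable` (data.frame with a `score` column) and
#'   `cumulative`
#' @export
sample_damage_score <- function(variables) {
  stopifnot(all(c("variable", "severity", "extent") %in% names(variables)))
  if (!identical(sort(as.character(variables$variable)),
                 sort(histo_variables)))
    stop("expected exactly the five damage variables once each: ",
         paste(histo_variables, collapse = ", "))
  variables$score <- variable_score(variables$severity, variables$extent)
  list(per_variable = variables, cumulative = sum(variables$score))
}

#' Cumulative damage scores for a whole histology table
#'
#' @param table data.frame `sample_id, group, variable, severity, extent`
#'   (one row per sample x variable, e.g. from [simulate_histo()])
#' @return data.frame `sample_id, group, cumulative`
#' @export
damage_score_table <- function(table) {
  stopifnot(all(c("sample_id", "variable", "severity", "extent") %in%
                  names(table)))
  counts <- table(table$sample_id, table$variable)
  if (!setequal(colnames(counts), histo_variables) || any(counts != 1L))
    stop("every sample must carry exactly the five damage variables once each")
  score <- variable_score(table$severity, table$extent)
  cum <- tapply(score, table$sample_id, sum)
  first <- !duplicated(table$sample_id)
  out <- data.frame(sample_id = table$sample_id[first],
                    group = if ("group" %in% names(table))
                      table$group[first] else NA,
                    cumulative = as.integer(cum[table$sample_id[first]]))
  rownames(out) <- NULL
  out
}

#' Automated nuclear IHC positivity for one high-power field
#'
#' Computes the mean stain intensity of every nucleus inside the (manually
#' segmented) epidermis mask, calls a nucleus positive when its mean exceeds
#' the threshold (Otsu over the per-nucleus means by default), and bins the
#' positive nuclei into low / intermediate / high staining intensity
#' (tertiles of the positive means by default, or fixed `bin_edges`).
#'
#' @param intensity numeric matrix, stain intensity (pre-unmixed DAB or
#'   grayscale)
#' @param nuclei integer nucleus label matrix aligned with `intensity`
#' @param epidermis logical matrix; nuclei whose centroid falls outside are
#'   ignored (empty mask yields a zero-nuclei result with a warning)
#' @param threshold `"otsu"` or a fixed numeric threshold on per-nucleus mean
#'   intensity
#' @param bin_edges optional two increasing edges splitting positives into
#'   low/intermediate/high; default tertiles of the positive means
#' @param field_id identifier carried into the result
#' @return data.frame `field_id, n_total, n_positive, percent_positive,
#'   n_low, n_intermediate, n_high`
#' @export
ihc_nuclear_positivity <- function(intensity, nuclei, epidermis,
                                   threshold = "otsu", bin_edges = NULL,
                                   field_id = 1L) {
  stopifnot(all(dim(intensity) == dim(nuclei)),
            all(dim(intensity) == dim(epidermis)))
  if (!any(epidermis)) {
    warning("empty epidermis mask: zero-nuclei result")
    return(data.frame(field_id = field_id, n_total = 0L, n_positive = 0L,
                      percent_positive = NA_real_, n_low = 0L,
                      n_intermediate = 0L, n_high = 0L))
  }
  labels <- sort(unique(nuclei[nuclei > 0]))
  inside <- vapply(labels, function(l) {
    idx <- which(nuclei == l, arr.ind = TRUE)
    c_y <- round(mean(idx[, 1])); c_x <- round(mean(idx[, 2]))
    isTRUE(epidermis[c_y, c_x])
  }, logical(1))
  labels <- labels[inside]
  n_total <- length(labels)
  if (!n_total)
    return(data.frame(field_id = field_id, n_total = 0L, n_positive = 0L,
                      percent_positive = NA_real_, n_low = 0L,
                      n_intermediate = 0L, n_high = 0L))
  means <- vapply(labels, function(l) mean(intensity[nuclei == l]), numeric(1))
  thr <- if (is.numeric(threshold)) threshold else otsu_threshold(means)
  pos <- means > thr
  pos_means <- means[pos]
  if (is.null(bin_edges))
    bin_edges <- if (length(pos_means) >= 2)
      stats::quantile(pos_means, c(1 / 3, 2 / 3), names = FALSE) else c(Inf, Inf)
  # 0 = low (<= edge1), 1 = intermediate (<= edge2), 2 = high
  bins <- findInterval(pos_means, sort(bin_edges), left.open = TRUE)
  data.frame(field_id = field_id, n_total = n_total, n_positive = sum(pos),
             percent_positive = 100 * sum(pos) / n_total,
             n_low = sum(bins == 0L),
             n_intermediate = sum(bins == 1L),
             n_high = sum(bins == 2L))
}
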