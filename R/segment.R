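# Nucleus segmentation from the DAPI or lamin A/C channel.
# EBImage provides the primitives (Otsu, labeling, hole filling); the glue
# here fixes the conventions: label 0 = background, labels consecutive,
# border-touching and sub-minimum-area regions removed.

# Otsu threshold of a numeric vector (values above it are foreground);
# returns Inf for degenerate (constant) input so nothing is called foreground
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(Inf)
  vn <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(vn, nrow = 1)), range = c(0, 1))
  thr * diff(rng) + rng[1]
}

resolve_threshold <- function(values, method, value = NULL) {
  if (is.numeric(method)) return(method)
  switch(method,
    otsu = otsu_threshold(values),
    # robust background model: median + k * MAD; suited to sparse punctate
    # signal whose histogram is long-tailed rather than bimodal
    robust = stats::median(values) + (value %||% 7) * stats::mad(values),
    percentile = stats::quantile(values, value %||% 0.99, names = FALSE),
    fixed = value %||% stop("threshold method 'fixed' needs a value"),
    stop("unknown threshold method '", method, "'"))
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so merge label
# pairs that touch diagonally with a union-find pass
label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # \ diagonal neighbours
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # / diagonal neighbours
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (!nrow(pairs)) return(lab)
  rep_of <- uf_components(n, pairs)
  new_id <- match(rep_of, sort(unique(rep_of)))
  lab[lab > 0] <- new_id[lab[lab > 0]]
  lab
}

# drop regions touching the image border or smaller than min_area,
# then relabel 1..k in raster order
clean_labels <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- union(border[border > 0], which(areas < min_area))
  if (length(drop)) lab[lab %in% drop] <- 0L
  keep <- sort(unique(lab[lab > 0]))
  if (length(keep)) lab[lab > 0] <- match(lab[lab > 0], keep)
  lab
}

# 2D working image from a 3D channel: maximum-intensity projection, or the
# single maximum-foreground z-section
flatten_channel <- function(arr, mode = c("max_projection", "best_section"),
                            threshold = "otsu") {
  mode <- match.arg(mode)
  if (length(dim(arr)) == 2L) return(arr)
  if (mode == "max_projection") return(apply(arr, c(1, 2), max))
  thr <- resolve_threshold(as.vector(arr), threshold)
  fg <- apply(arr > thr, 3, sum)
  arr[, , which.max(fg)]
}

#' Segment nuclei from the nuclear-stain (DAPI) channel
#'
#' Otsu-thresholds the maximum-intensity projection of the DAPI channel,
#' fills holes, labels connected regions, and removes border-touching and
#' sub-minimum-area regions. Deterministic.
#'
#' @param stack an [image_stack] with a `nuclear_stain` channel
#' @param min_area smallest admissible nucleus area (px)
#' @param threshold `"otsu"`, or a fixed numeric threshold
#' @return integer label matrix (0 = background, labels consecutive)
#' @export
segment_nuclei <- function(stack, min_area = 100, threshold = "otsu") {
  proj <- flatten_channel(stack_channel(stack, "nuclear_stain"))
  thr <- resolve_threshold(as.vector(proj), threshold)
  binary <- proj > thr
  if (!any(binary)) return(matrix(0L, nrow(proj), ncol(proj)))
  filled <- EBImage::fillHull(EBImage::Image(binary * 1)) > 0.5
  clean_labels(label8(matrix(filled, nrow(proj))), min_area)
}

#' Segment nuclei from the lamin A/C channel
#'
#' Intensity thresholding of the lamin rim followed by hole filling turns
#' each closed envelope outline into a filled nucleus region; border-touching
#' and sub-minimum-area regions are removed. The representative section is
#' the maximum-foreground z-section (configurable to the max projection).
#'
#' @param stack an [image_stack] with a `lamin` channel
#' @param min_area smallest admissible region (px); default excludes debris
#' @param threshold `"otsu"` or a fixed numeric threshold
#' @param section `"best_section"` or `"max_projection"`
#' @return integer label matrix
#' @export
segment_lamin <- function(stack, min_area = 100, threshold = "otsu",
                          section = c("best_section", "max_projection")) {
  section <- match.arg(section)
  img <- flatten_channel(stack_channel(stack, "lamin"), mode = section)
  thr <- resolve_threshold(as.vector(img), threshold)
  binary <- img > thr
  if (!any(binary)) return(matrix(0L, nrow(img), ncol(img)))
  filled <- EBImage::fillHull(EBImage::Image(binary * 1)) > 0.5
  clean_labels(label8(matrix(filled, nrow(img))), min_area)
}
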