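# TIF calling: a DDR-marker focus and a telomere-marker focus colocalize
# when five or more supra-threshold pixels overlap between the two channels
# within the same section of the stack; a cell is positive if it shows at
# least one TIF.

#' Call telomere dysfunction-induced foci (TIFs)
#'
#' Emits one colocalization event per (DDR focus, telomere focus, z-section)
#' whose per-section pixel intersection contains at least
#' `params$min_overlap` pixels (default 5) and whose foci share a nucleus.
#' Events that share a focus — including events of the same focus pair in
#' adjacent sections — are merged into a single TIF, so one physical focus
#' never counts twice. The relation is symmetric in the two channels.
#'
#' @param ddr_foci,telo_foci `focus_set`s from [detect_foci()] (order
#'   irrelevant)
#' @param params a [coloc_params()]
#' @param nuclei optional integer vector of nucleus labels to report (e.g.
#'   `seq_len(max(label_map))`), so nuclei without any focus appear with a
#'   TIF count of 0; defaults to the nuclei seen in either focus set
#' @return list with `events` (data.frame `ddr_id, telo_id, z, overlap,
#'   nucleus`) and `records` (data.frame `nucleus, n_tif, positive`; positive
#'   means at least one TIF)
#' @export
call_tifs <- function(ddr_foci, telo_foci, params = coloc_params(),
                      nuclei = NULL) {
  stopifnot(inherits(ddr_foci, "focus_set"), inherits(telo_foci, "focus_set"))
  dd <- ddr_foci$foci; tt <- telo_foci$foci
  events <- list()
  shared_nuclei <- intersect(dd$nucleus, tt$nucleus)
  for (nuc in shared_nuclei) {
    for (i in dd$id[dd$nucleus == nuc]) {
      pi_ <- ddr_foci$pixels[[i]]
      for (j in tt$id[tt$nucleus == nuc]) {
        pj <- telo_foci$pixels[[j]]
        for (z in intersect(unique(pi_$z), unique(pj$z))) {
          ov <- length(intersect(pi_$p[pi_$z == z], pj$p[pj$z == z]))
          if (ov >= params$min_overlap)
            events[[length(events) + 1L]] <- data.frame(
              ddr_id = i, telo_id = j, z = z, overlap = ov, nucleus = nuc)
        }
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(ddr_id = integer(0), telo_id = integer(0), z = integer(0),
               overlap = integer(0), nucleus = integer(0))

  # merge events sharing foci into TIFs: connected components of the
  # bipartite ddr/telo graph restricted to event edges
  tif_per_nucleus <- integer(0)
  if (nrow(events)) {
    edges <- unique(events[, c("ddr_id", "telo_id", "nucleus")])
    nd <- max(dd$id)
    comp <- uf_components(nd + max(tt$id),
                          cbind(edges$ddr_id, nd + edges$telo_id))
    rep_per_edge <- comp[edges$ddr_id]
    first <- !duplicated(rep_per_edge)   # one edge per merged TIF
    tif_per_nucleus <- table(edges$nucleus[first])
  }

  all_nuclei <- sort(unique(c(nuclei, dd$nucleus, tt$nucleus)))
  n_tif <- integer(length(all_nuclei))
  if (length(tif_per_nucleus))
    n_tif[match(as.integer(names(tif_per_nucleus)), all_nuclei)] <-
      as.integer(tif_per_nucleus)
  records <- data.frame(nucleus = all_nuclei, n_tif = n_tif,
                        positive = n_tif >= 1L)
  list(events = events, records = records)
}

#' RNAscope per-cell positivity
#'
#' A cell is positive when it shows at least `min_dots` hybridization dots
#' (default 3).
#'
#' @param dot_counts nonnegative integer vector of dots per cell
#' @param min_dots positivity threshold (dots)
#' @return logical vector, one flag per cell
#' @export
rnascope_positive <- function(dot_counts, min_dots = 3L) {
  if (any(dot_counts < 0)) stop("dot counts must be nonnegative")
  dot_counts >= min_dots
}
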