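# Nuclear morphometry: outline extraction and the circularity index
# C = 4*pi*A / P^2, which is 1.0 for a perfect circle and approaches 0 for a
# straight line (degenerate zero-area outlines score exactly 0).

#' Crofton boundary-length estimate of a binary region
#'
#' Counts foreground/background transitions along the horizontal, vertical
#' and the two diagonal scan directions and combines them with Crofton
#' weights. Nearly unbiased for smooth blob-like shapes (a rasterized disk
#' of radius r measures ~2*pi*r), unlike the naive boundary-pixel count.
#'
#' @param mask logical or 0/1 matrix of one region
#' @return estimated perimeter in pixels
#' @export
perimeter_crofton <- function(mask) {
  m <- (mask > 0) * 1L
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  nh <- sum(pad[, -1] != pad[, -(w + 2L)])
  nv <- sum(pad[-1, ] != pad[-(h + 2L), ])
  nd1 <- sum(pad[-1, -1] != pad[-(h + 2L), -(w + 2L)])
  nd2 <- sum(pad[-1, -(w + 2L)] != pad[-(h + 2L), -1])
  pi / 8 * (nh + nv + (nd1 + nd2) / sqrt(2))
}

# length of a closed polygonal chain
chain_perimeter <- function(pts) {
  d <- diff(pts)
  s <- sum(sqrt(rowSums(d^2)))
  if (!all(pts[1, ] == pts[nrow(pts), ]))
    s <- s + sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  s
}

# shoelace area of a polygon (rows are vertices; closure implicit)
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Construct a nucleus outline from an explicit boundary polygon
#'
#' The boundary must be closed (first vertex repeated as the last). Area is
#' the shoelace polygon area and perimeter the chain length; both can be
#' overridden when known from another estimator.
#'
#' @param boundary numeric matrix of boundary vertices (two columns), closed
#' @param label nucleus label
#' @param area,perimeter optional overrides
#' @return a `nucleus_outline`
#' @export
nucleus_outline <- function(boundary, label = 1L, area = NULL,
                            perimeter = NULL) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3L || !all(boundary[1, ] == boundary[nrow(boundary), ]))
    stop("boundary must be a closed polygon (first vertex == last vertex)")
  structure(list(label = label, boundary = boundary,
                 area = area %||% shoelace_area(boundary),
                 perimeter = perimeter %||% chain_perimeter(boundary)),
            class = "nucleus_outline")
}

#' Extract nucleus outlines from a label map
#'
#' Area is the region pixel count; perimeter uses the Crofton estimator by
#' default (configurable to the polygonal chain length of the traced
#' contour). The boundary vertex sequence comes from [EBImage::ocontour()].
#'
#' @param label_map integer label matrix from [segment_lamin()] or
#'   [segment_nuclei()]
#' @param perimeter_method `"crofton"` or `"chain"`
#' @return list of `nucleus_outline` objects
#' @export
nucleus_outlines <- function(label_map,
                             perimeter_method = c("crofton", "chain")) {
  perimeter_method <- match.arg(perimeter_method)
  labels <- sort(unique(label_map[label_map > 0]))
  contours <- if (length(labels))
    EBImage::ocontour(EBImage::Image(label_map)) else list()
  lapply(seq_along(labels), function(i) {
    l <- labels[i]
    mask <- label_map == l
    pts <- contours[[i]] + 1  # ocontour is 0-based
    pts <- rbind(pts, pts[1, , drop = FALSE])
    per <- if (perimeter_method == "crofton") perimeter_crofton(mask)
           else chain_perimeter(pts)
    nucleus_outline(pts, label = l, area = sum(mask), perimeter = per)
  })
}

#' Circularity index of one outline
#'
#' `C = 4*pi*A / P^2`, clamped to the unit interval; 1.0 for a perfect
#' circle, 0 for the degenerate straight-line limit (zero enclosed area
#' scores exactly 0 by convention).
#'
#' @param outline a [nucleus_outline()]
#' @return data.frame `nucleus_label, area_px, perimeter_px, circularity`
#' @export
circularity_index <- function(outline) {
  stopifnot(inherits(outline, "nucleus_outline"))
  C <- if (outline$area <= 0) 0 else
    min(1, max(0, 4 * pi * outline$area / outline$perimeter^2))
  data.frame(nucleus_label = outline$label, area_px = outline$area,
             perimeter_px = outline$perimeter, circularity = C)
}

#' Circularity of every nucleus in a label map
#'
#' @inheritParams nucleus_outlines
#' @return data.frame with one row per nucleus (see [circularity_index()])
#' @export
circularity_from_labels <- function(label_map,
                                    perimeter_method = c("crofton", "chain")) {
  outs <- nucleus_outlines(label_map, perimeter_method)
  if (!length(outs))
    return(data.frame(nucleus_label = integer(0), area_px = numeric(0),
                      perimeter_px = numeric(0), circularity = numeric(0)))
  do.call(rbind, lapply(outs, circularity_index))
}

#' Per-group circularity summary
#'
#' @param records data.frame from [circularity_from_labels()]
#' @param groups group label per record
#' @return data.frame `group, mean, sd, n`
#' @export
circularity_profile <- function(records, groups) {
  stopifnot(nrow(records) == length(groups), nrow(records) >= 1)
  agg <- split(records$circularity, groups)
  data.frame(group = names(agg),
             mean = vapply(agg, mean, numeric(1)),
             sd = vapply(agg, stats::sd, numeric(1)),
             n = lengths(agg), row.names = NULL)
}
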