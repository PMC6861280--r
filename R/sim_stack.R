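# Synthetic multi-channel fields with machine-readable ground truth.
#
# The spot model is an isotropic 2D Gaussian per optical section whose
# amplitude decays by half over +/-1 section, mimicking a deconvolved
# confocal-like focus while keeping the same-section colocalization rule
# exercisable. Noise is Poisson shot noise on (signal + background) plus
# additive Gaussian read noise; SNR = peak spot amplitude / background sd.

# rejection-sample non-overlapping nucleus centres; margin keeps nuclei off
# the field border so border-clearing during segmentation loses nothing
place_nuclei <- function(n, radius_range, height, width, extra_margin = 3,
                         gap = 4, max_tries = 5000L) {
  ys <- xs <- rs <- numeric(0)
  for (i in seq_len(n)) {
    r <- if (radius_range[1] == radius_range[2]) radius_range[1] else
      sample(seq(radius_range[1], radius_range[2]), 1)
    m <- r + extra_margin
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      y <- stats::runif(1, m + 1, height - m)
      x <- stats::runif(1, m + 1, width - m)
      if (!length(ys) || all((ys - y)^2 + (xs - x)^2 >= (rs + r + gap)^2)) {
        ys <- c(ys, y); xs <- c(xs, x); rs <- c(rs, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("geometry too small: could not place nucleus ", i, " of ", n,
           " without overlap; enlarge the field or reduce n_nuclei")
  }
  data.frame(id = seq_len(n), y = ys, x = xs, r = rs)
}

# soft-edged disk added in place into a 2D matrix
add_disk <- function(img, cy, cx, r, amp) {
  h <- nrow(img); w <- ncol(img)
  yy <- max(1, floor(cy - r - 2)):min(h, ceiling(cy + r + 2))
  xx <- max(1, floor(cx - r - 2)):min(w, ceiling(cx + r + 2))
  d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, `+`))
  img[yy, xx] <- img[yy, xx] + amp * pmin(1, pmax(0, r + 0.5 - d))
  img
}

# Gaussian spot added into a [y, x, z] array at (z0, y0, x0); amplitude
# decays by `decay` per section away from z0
add_spot <- function(arr, z0, y0, x0, sigma, amp, decay = 0.5) {
  h <- dim(arr)[1]; w <- dim(arr)[2]; nz <- dim(arr)[3]
  wd <- ceiling(3 * sigma)
  yy <- max(1, floor(y0 - wd)):min(h, ceiling(y0 + wd))
  xx <- max(1, floor(x0 - wd)):min(w, ceiling(x0 + wd))
  g <- amp * exp(-outer((yy - y0)^2, (xx - x0)^2, `+`) / (2 * sigma^2))
  for (dz in -1:1) {
    z <- z0 + dz
    if (z >= 1 && z <= nz)
      arr[yy, xx, z] <- arr[yy, xx, z] + g * decay^abs(dz)
  }
  arr
}

# sample a point uniformly in a disk, at least `min_sep` away from points
# (pys, pxs); returns c(y, x) or NULL on failure
sample_in_disk <- function(cy, cx, rmax, pys, pxs, min_sep, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    rho <- rmax * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    y <- cy + rho * sin(th); x <- cx + rho * cos(th)
    if (!length(pys) || all((pys - y)^2 + (pxs - x)^2 >= min_sep^2))
      return(c(y, x))
  }
  NULL
}

apply_noise <- function(arr, bg_level, read_sd) {
  n <- length(arr)
  noisy <- stats::rpois(n, lambda = as.vector(arr) + bg_level) +
    stats::rnorm(n, 0, read_sd)
  array(pmax(noisy, 0), dim(arr))
}

#' Simulate a TIF imaging field
#'
#' Generates a 3-channel 3D stack (DAPI nuclear stain, telomere marker, DDR
#' marker) in which a configurable fraction of telomere foci carry a
#' colocalized DDR focus — a planted telomere dysfunction-induced focus
#' (TIF). Planted pairs share their centroid (up to <=0.5 px jitter) and one
#' z-section, guaranteeing supra-threshold overlap of at least the
#' colocalization minimum; non-colocalizing DDR foci are kept at least
#' 3 sigma away from every telomere focus so ground truth is unambiguous.
#'
#' @param config a [sim_config()]
#' @return a list with elements `stack` ([image_stack]) and `truth`: nucleus
#'   table (`id, y, x, r`), 2D true label `mask`, focus table (`id, channel,
#'   nucleus, z, y, x, pair_id`), pair table (`pair_id, nucleus, telo_id,
#'   ddr_id`) and per-nucleus `tif_counts` (`nucleus, n_tif`).
#' @export
simulate_tif_stack <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    h <- config$height; w <- config$width; nz <- config$n_z
    nuc <- place_nuclei(config$n_nuclei, config$nucleus_radius, h, w)
    sd_bg <- bg_sd(config)
    amp_spot <- config$snr * sd_bg
    sigma <- config$spot_sigma

    dapi <- matrix(0, h, w)
    mask <- matrix(0L, h, w)
    for (i in seq_len(nrow(nuc))) {
      dapi <- add_disk(dapi, nuc$y[i], nuc$x[i], nuc$r[i], 12 * sd_bg)
      d2 <- outer((seq_len(h) - nuc$y[i])^2, (seq_len(w) - nuc$x[i])^2, `+`)
      mask[d2 <= nuc$r[i]^2] <- i
    }

    telo <- array(0, c(h, w, nz))
    ddr <- array(0, c(h, w, nz))
    foci <- list()
    pairs <- list()
    fid <- 0L; pid <- 0L
    for (i in seq_len(nrow(nuc))) {
      rmax <- nuc$r[i] - (3 * sigma + 1)
      n_t <- if (config$telo_foci[1] == config$telo_foci[2]) config$telo_foci[1]
             else sample(seq(config$telo_foci[1], config$telo_foci[2]), 1)
      n_x <- if (config$ddr_extra[1] == config$ddr_extra[2]) config$ddr_extra[1]
             else sample(seq(config$ddr_extra[1], config$ddr_extra[2]), 1)
      # telomere foci, mutually >= 5 sigma apart: closer spots are not
      # resolvable by any threshold detector once their tails sum, and the
      # planted ground truth must stay unambiguous
      tys <- txs <- tzs <- numeric(0)
      for (k in seq_len(n_t)) {
        p <- sample_in_disk(nuc$y[i], nuc$x[i], rmax, tys, txs, 5 * sigma)
        if (is.null(p)) break  # crowded nucleus: plant fewer, truth follows
        z <- sample(seq(2, max(2, nz - 1)), 1)
        tys <- c(tys, p[1]); txs <- c(txs, p[2]); tzs <- c(tzs, z)
      }
      n_t <- length(tys)
      n_pair <- round(config$coloc_fraction * n_t)
      telo_ids <- integer(n_t)
      for (k in seq_len(n_t)) {
        fid <- fid + 1L; telo_ids[k] <- fid
        telo <- add_spot(telo, tzs[k], tys[k], txs[k], sigma, amp_spot)
        foci[[fid]] <- data.frame(id = fid, channel = "telomere_marker",
                                  nucleus = i, z = tzs[k], y = tys[k],
                                  x = txs[k], pair_id = NA_integer_)
      }
      # colocalized DDR partners: same z-section, centroid jitter <= 0.5 px
      for (k in seq_len(n_pair)) {
        fid <- fid + 1L; pid <- pid + 1L
        jy <- tys[k] + stats::runif(1, -0.5, 0.5)
        jx <- txs[k] + stats::runif(1, -0.5, 0.5)
        ddr <- add_spot(ddr, tzs[k], jy, jx, sigma, amp_spot)
        foci[[fid]] <- data.frame(id = fid, channel = "ddr_marker",
                                  nucleus = i, z = tzs[k], y = jy, x = jx,
                                  pair_id = pid)
        foci[[telo_ids[k]]]$pair_id <- pid
        pairs[[pid]] <- data.frame(pair_id = pid, nucleus = i,
                                   telo_id = telo_ids[k], ddr_id = fid)
      }
      # isolated DDR foci: >= 3 sigma from every telomere focus
      dys <- dxs <- numeric(0)
      for (k in seq_len(n_x)) {
        p <- sample_in_disk(nuc$y[i], nuc$x[i], rmax, c(tys, dys), c(txs, dxs),
                            5 * sigma)
        if (is.null(p)) break
        z <- sample(seq(2, max(2, nz - 1)), 1)
        fid <- fid + 1L
        ddr <- add_spot(ddr, z, p[1], p[2], sigma, amp_spot)
        foci[[fid]] <- data.frame(id = fid, channel = "ddr_marker",
                                  nucleus = i, z = z, y = p[1], x = p[2],
                                  pair_id = NA_integer_)
        dys <- c(dys, p[1]); dxs <- c(dxs, p[2])
      }
    }

    dapi3 <- array(rep(dapi, nz), c(h, w, nz))
    arr <- array(0, c(h, w, nz, 3))
    arr[, , , 1] <- apply_noise(dapi3, config$bg_level, config$read_sd)
    arr[, , , 2] <- apply_noise(telo, config$bg_level, config$read_sd)
    arr[, , , 3] <- apply_noise(ddr, config$bg_level, config$read_sd)
    stack <- image_stack(arr, c("nuclear_stain", "telomere_marker",
                                "ddr_marker"))

    foci_df <- if (length(foci)) do.call(rbind, foci) else
      data.frame(id = integer(0), channel = character(0), nucleus = integer(0),
                 z = numeric(0), y = numeric(0), x = numeric(0),
                 pair_id = integer(0))
    pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(pair_id = integer(0), nucleus = integer(0),
                 telo_id = integer(0), ddr_id = integer(0))
    counts <- data.frame(nucleus = nuc$id,
                         n_tif = vapply(nuc$id, function(i)
                           sum(pairs_df$nucleus == i), integer(1)))
    list(stack = stack,
         truth = list(nuclei = nuc, mask = mask, foci = foci_df,
                      pairs = pairs_df, tif_counts = counts))
  })
}

# Ramanujan's closed-form perimeter approximation for an ellipse
ramanujan_perimeter <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))

# analytic circularity of r(theta) = R (1 + a sin(k theta + phi)) by
# numerical quadrature of perimeter and area
sinusoid_circularity <- function(R, a, k, n = 4096L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- R * (1 + a * sin(k * th))
  dr <- R * a * k * cos(k * th)
  P <- sum(sqrt(r^2 + dr^2)) * 2 * pi / n
  A <- sum(r^2 / 2) * 2 * pi / n
  4 * pi * A / P^2
}

#' Simulate nuclear-envelope (lamin A/C) fields
#'
#' Renders closed lamin rims around nuclei whose boundary is either a
#' sinusoidally perturbed circle `r(theta) = R (1 + a sin(k theta + phi))` or
#' an ellipse of configurable axis ratio. The analytic circularity
#' `4 pi A / P^2` of each true boundary is recorded in the ground truth
#' (numerical quadrature for sinusoids; Ramanujan's perimeter approximation
#' for ellipses). Amplitude 0 yields perfect circles (circularity exactly 1).
#'
#' @param config a [sim_config()]
#' @return a list with `stack` (single `lamin` channel) and `truth`: nucleus
#'   table (`id, y, x, r, circularity`) and true interior label `mask`.
#' @export
simulate_nuclear_envelope <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    h <- config$height; w <- config$width
    a <- config$shape_amplitude
    grow <- if (config$shape_kind == "ellipse") sqrt(config$ellipse_ratio) else 1 + a
    nuc <- place_nuclei(config$n_envelope_nuclei, config$envelope_radius, h, w,
                        extra_margin = max(config$envelope_radius) * (grow - 1) + 4,
                        gap = 2 * max(config$envelope_radius) * (grow - 1) + 6)
    nuc$y <- round(nuc$y); nuc$x <- round(nuc$x)
    sd_bg <- bg_sd(config)
    lamin <- matrix(0, h, w)
    mask <- matrix(0L, h, w)
    circ <- numeric(nrow(nuc))
    for (i in seq_len(nrow(nuc))) {
      R <- nuc$r[i]; phi <- stats::runif(1, 0, 2 * pi)
      ext <- ceiling(R * grow) + 2
      yy <- (nuc$y[i] - ext):(nuc$y[i] + ext)
      xx <- (nuc$x[i] - ext):(nuc$x[i] + ext)
      yy <- yy[yy >= 1 & yy <= h]; xx <- xx[xx >= 1 & xx <= w]
      dy <- outer(yy - nuc$y[i], rep(1, length(xx)))
      dx <- outer(rep(1, length(yy)), xx - nuc$x[i])
      rho <- sqrt(dy^2 + dx^2)
      th <- atan2(dy, dx)
      if (config$shape_kind == "ellipse") {
        ax <- R * sqrt(config$ellipse_ratio); bx <- R / sqrt(config$ellipse_ratio)
        rb <- ax * bx / sqrt((bx * cos(th - phi))^2 + (ax * sin(th - phi))^2)
        circ[i] <- 4 * pi * (pi * ax * bx) / ramanujan_perimeter(ax, bx)^2
      } else {
        rb <- R * (1 + a * sin(config$shape_lobes * th + phi))
        circ[i] <- if (a == 0) 1 else
          sinusoid_circularity(R, a, config$shape_lobes)
      }
      interior <- rho <= rb
      rim <- interior & rho >= rb - 3
      lamin[yy, xx] <- lamin[yy, xx] + 10 * sd_bg * rim
      sub <- mask[yy, xx]; sub[interior] <- i; mask[yy, xx] <- sub
    }
    arr <- apply_noise(array(lamin, c(h, w, 1)), config$bg_level, config$read_sd)
    stack <- image_stack(array(arr, c(h, w, 1, 1)), "lamin")
    nuc$circularity <- circ
    list(stack = stack, truth = list(nuclei = nuc, mask = mask))
  })
}
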