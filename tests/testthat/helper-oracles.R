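# Independent oracles and fixture builders shared across the suite.

# Ramanujan's ellipse perimeter, written out independently of the package
ram_perimeter <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))

# brute-force TIF event oracle: for every (ddr, telo) focus pair sharing a
# nucleus, count per-section pixel intersections directly
brute_tif_events <- function(ddr, telo, min_overlap = 5L) {
  ev <- list()
  for (i in seq_len(nrow(ddr$foci))) {
    for (j in seq_len(nrow(telo$foci))) {
      if (ddr$foci$nucleus[i] != telo$foci$nucleus[j]) next
      pi_ <- ddr$pixels[[ddr$foci$id[i]]]
      pj <- telo$pixels[[telo$foci$id[j]]]
      for (z in sort(unique(c(pi_$z, pj$z)))) {
        n_shared <- sum(pi_$p[pi_$z == z] %in% pj$p[pj$z == z])
        if (n_shared >= min_overlap)
          ev[[length(ev) + 1L]] <- c(ddr$foci$id[i], telo$foci$id[j], z, n_shared)
      }
    }
  }
  if (!length(ev)) return(matrix(numeric(0), ncol = 4))
  m <- do.call(rbind, ev)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# random focus pair in a small volume; overlap varies freely around the rule
# boundary so both emission outcomes occur
random_focus_pair <- function(dim = c(32L, 32L, 5L)) {
  blob <- function() {
    z <- sample(dim[3], 1)
    cy <- sample(5:(dim[1] - 5), 1); cx <- sample(5:(dim[2] - 5), 1)
    n <- sample(4:25, 1)
    off <- unique(cbind(sample(-3:3, n, TRUE), sample(-3:3, n, TRUE)))
    data.frame(z = z, y = cy + off[, 1], x = cx + off[, 2])
  }
  a <- blob()
  # second blob near the first so intersections straddle the threshold
  shift <- sample(-3:3, 2, TRUE)
  dz <- sample(c(0L, 0L, 0L, 1L), 1)
  b <- data.frame(z = pmin(dim[3], a$z + dz),
                  y = pmin(dim[1] - 1, pmax(2, a$y + shift[1])),
                  x = pmin(dim[2] - 1, pmax(2, a$x + shift[2])))
  b <- unique(b)
  list(ddr = focus_set(list(a), nucleus = 1L, channel = "ddr_marker", dim = dim),
       telo = focus_set(list(b), nucleus = 1L, channel = "telomere_marker",
                        dim = dim))
}

# segmentation label corresponding to each true nucleus (label under the
# true centre)
labels_at_true_centres <- function(label_map, truth_nuclei) {
  label_map[cbind(round(truth_nuclei$y), round(truth_nuclei$x))]
}

# per-nucleus recovery of TIF counts for one simulated field
recover_tif_counts <- function(sim, params = coloc_params()) {
  lab <- segment_nuclei(sim$stack)
  telo <- detect_foci(sim$stack, "telomere_marker", lab, params)
  ddr <- detect_foci(sim$stack, "ddr_marker", lab, params)
  res <- call_tifs(ddr, telo, params, nuclei = seq_len(max(lab)))
  tl <- labels_at_true_centres(lab, sim$truth$nuclei)
  data.frame(true = sim$truth$tif_counts$n_tif,
             got = res$records$n_tif[match(tl, res$records$nucleus)])
}

# dense-polygon circularity of r(theta) = R (1 + a sin(k theta + phi)):
# an oracle independent of the package's quadrature
polygon_circularity <- function(R, a, k, n = 20000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  r <- R * (1 + a * sin(k * th))
  x <- r * cos(th); y <- r * sin(th)
  A <- abs(sum(x[-1] * y[-(n + 1)] - x[-(n + 1)] * y[-1])) / 2
  P <- sum(sqrt(diff(x)^2 + diff(y)^2))
  4 * pi * A / P^2
}

# binary disk mask
disk_mask <- function(size, r, cy = (size + 1) / 2, cx = (size + 1) / 2) {
  m <- matrix(0L, size, size)
  m[outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`) <= r^2] <- 1L
  m
}
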