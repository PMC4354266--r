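# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature for arc lengths, O(n^3) agglomeration
# for UPGMA, BFS flood fill for connected components.

# Ellipse perimeter / partial arc length by fine Riemann quadrature of
# sqrt(a^2 sin^2 t + b^2 cos^2 t).
oracle_ellipse_perimeter <- function(a, b, n = 2e5) {
  t <- seq(0, 2 * pi, length.out = n)
  dt <- t[2] - t[1]
  sum(sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)) * dt
}

# Polyline length of a primitive tibble (single polyline).
polyline_length <- function(df) {
  sum(sqrt(diff(df$x)^2 + diff(df$y)^2))
}

# Shoelace polygon area.
polygon_area_oracle <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Brute-force UPGMA: returns sorted merge heights. Average linkage distance
# between clusters = mean pairwise distance, recomputed from scratch each
# merge (O(n^3)).
oracle_upgma_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# BFS flood-fill connected components (8-connectivity) over a logical
# matrix; returns a label matrix.
oracle_components <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(bw & lab == 0L)) {
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; cl <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (bw[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Brute-force 70%-rule classification: threshold, all components, keep the
# largest as core.
oracle_core_protrusion <- function(mask, channel, frac = 0.7) {
  thr <- frac * mean(channel[mask])
  above <- mask & channel > thr
  if (!any(above)) return(list(core = mask, rel = 0))
  lab <- oracle_components(above)
  sizes <- tabulate(lab[lab > 0])
  core <- lab == which.max(sizes)
  list(core = core, rel = sum(mask & !core) / sum(mask))
}

# A scaled single-row table for rendering tests.
scaled_row <- function(spec, values) {
  row <- tibble::as_tibble(as.list(stats::setNames(values,
                                                   spec$bindings$feature)))
  attr(row, "scaling") <- "scaled"
  row
}

# Map predicted labels to ground-truth labels by maximal overlap.
match_labels <- function(pred, truth) {
  ids <- sort(unique(pred[pred > 0]))
  vapply(ids, function(j) {
    ov <- table(truth[pred == j])
    ov <- ov[names(ov) != "0"]
    as.integer(names(which.max(ov)))
  }, integer(1))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Small two-plateau synthetic cell: n_core pixels at bright intensity,
# n_prot at dim, on an empty canvas. Returns mask + channel.
two_plateau_cell <- function(n_core = 80, n_prot = 20, bright = 100,
                             dim_int = 10, nr = 20, nc = 20) {
  stopifnot(n_core + n_prot <= nr * nc)
  mask <- matrix(FALSE, nr, nc)
  channel <- matrix(0, nr, nc)
  idx <- seq_len(n_core + n_prot)
  mask[idx] <- TRUE
  channel[idx[seq_len(n_core)]] <- bright
  channel[idx[n_core + seq_len(n_prot)]] <- dim_int
  list(mask = mask, channel = channel)
}
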