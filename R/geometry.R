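# Low-level ellipse geometry. All glyph encodings that claim proportionality
# to perimeter fraction are arc-length-proportional (not angle-proportional):
# on an eccentric ellipse a 25% value must cover 25% of the perimeter, which
# is not a 90-degree sweep. Arcs start at 12 o'clock and run clockwise.

# Dense clockwise parameterization of an ellipse starting at the top.
# Returns x, y and cumulative arc length s (s[1] = 0).
ellipse_arc_table <- function(a, b, n = 2048L) {
  t <- pi / 2 - seq(0, 2 * pi, length.out = n + 1L)
  x <- a * cos(t)
  y <- b * sin(t)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  list(x = x, y = y, s = c(0, cumsum(seg)))
}

# Perimeter of an ellipse by chord-sum quadrature.
ellipse_perimeter <- function(a, b, n = 2048L) {
  tab <- ellipse_arc_table(a, b, n)
  tab$s[length(tab$s)]
}

# Points along the ellipse between arc-length positions s0 and s1
# (clockwise from 12 o'clock). Endpoints are interpolated exactly.
ellipse_arc_points <- function(a, b, s0, s1, n = 2048L) {
  tab <- ellipse_arc_table(a, b, n)
  total <- tab$s[length(tab$s)]
  s0 <- max(0, min(s0, total)); s1 <- max(0, min(s1, total))
  if (s1 <= s0) return(list(x = numeric(0), y = numeric(0)))
  interp <- function(s) {
    i <- findInterval(s, tab$s, rightmost.closed = TRUE)
    w <- (s - tab$s[i]) / pmax(tab$s[i + 1] - tab$s[i], .Machine$double.eps)
    list(x = tab$x[i] + w * (tab$x[i + 1] - tab$x[i]),
         y = tab$y[i] + w * (tab$y[i + 1] - tab$y[i]))
  }
  inside <- which(tab$s > s0 & tab$s < s1)
  p0 <- interp(s0); p1 <- interp(s1)
  list(x = c(p0$x, tab$x[inside], p1$x),
       y = c(p0$y, tab$y[inside], p1$y))
}

# Point and outward unit normal at arc-length position s (clockwise from top).
ellipse_point_normal <- function(a, b, s, n = 2048L) {
  p <- ellipse_arc_points(a, b, max(0, s - 1e-9), s + 1e-9, n)
  if (!length(p$x)) {
    tab <- ellipse_arc_table(a, b, n)
    p <- list(x = tab$x[1], y = tab$y[1])
  }
  x <- p$x[length(p$x)]; y <- p$y[length(p$y)]
  # gradient of (x/a)^2 + (y/b)^2 points outward
  g <- c(2 * x / a^2, 2 * y / b^2)
  g <- g / sqrt(sum(g^2))
  list(x = x, y = y, nx = g[1], ny = g[2])
}

# Closed outline polygon of an ellipse (counter-clockwise, for fills).
ellipse_polygon <- function(a, b, cx = 0, cy = 0, n = 256L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + a * cos(t), y = cy + b * sin(t))
}

# Deterministic hexagonal lattice of points inside an ellipse (optionally
# offset to cx, cy). Pitch is chosen from the ellipse area so that the site
# count is close to `target_sites` regardless of ellipse size; sites are
# ordered bottom-up (then left-to-right) so that proportional fills grow
# upward from the region floor.
hex_lattice_in_ellipse <- function(a, b, cx = 0, cy = 0,
                                   target_sites = 140L, margin = 0.92) {
  area <- pi * a * b * margin^2
  pitch <- sqrt(area / (target_sites * sqrt(3) / 2))
  dy <- pitch * sqrt(3) / 2
  ys <- seq(-b * margin, b * margin, by = dy)
  pts_x <- numeric(0); pts_y <- numeric(0)
  for (i in seq_along(ys)) {
    off <- if (i %% 2L == 0L) pitch / 2 else 0
    xs <- seq(-a * margin - off, a * margin, by = pitch) + off
    keep <- (xs / (a * margin))^2 + (ys[i] / (b * margin))^2 <= 1
    pts_x <- c(pts_x, xs[keep]); pts_y <- c(pts_y, rep(ys[i], sum(keep)))
  }
  ord <- order(pts_y, pts_x)
  list(x = cx + pts_x[ord], y = cy + pts_y[ord], pitch = pitch)
}

# Shoelace polygon area (used by tests and by the ellipse-organelle fill).
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}
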