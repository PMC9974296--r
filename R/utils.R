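## Internal helpers shared across modules.

# Multivariate normal density (no mvtnorm dependency needed for this much).
.dmvnorm <- function(x, mu, sigma, log = FALSE) {
  x <- rbind(x)
  d <- length(mu)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
  if (log) ll else exp(ll)
}

# Even-odd ray casting; poly is a 2-column matrix of vertices (closed or open
# ring). Points on an edge count as inside often enough for raster cells.
.pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Separable Gaussian blur of a matrix, reflecting at the edges.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(min(r, length(v)))]), v,
                       rev(v[seq(length(v) - min(r, length(v)) + 1L, length(v))]))
  smooth1 <- function(v) {
    vp <- pad(v)
    out <- stats::filter(vp, k, sides = 2)
    as.numeric(out[(r + 1L):(r + length(v))])
  }
  m <- apply(m, 2L, smooth1)
  t(apply(m, 1L, smooth1))
}

# Evaluate an expression with a locally-set RNG seed, restoring global state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Linear interpolation of curve y(x) onto grid; NA outside the support -> 0.
.interpTo <- function(x, y, grid) {
  out <- approx(x, y, xout = grid, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

# Trapezoid integral on a (possibly non-uniform) grid.
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
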