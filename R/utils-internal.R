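# Small geometric helpers shared across modules. Not exported.

vnorm <- function(v) sqrt(sum(v * v))

unitVec <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# angle between two vectors, radians in [0, pi]
vecAngle <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na == 0 || nb == 0) return(NA_real_)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

deg <- function(rad) rad * 180 / pi
rad <- function(degr) degr * pi / 180

# population SD (divide by n), used for per-cell angle statistics
popSD <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# shoelace area (absolute) of a planar polygon given by vertex coordinates
polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygonPerimeter <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  j <- c(seq_len(n)[-1L], 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# centroid of a planar polygon (shoelace); falls back to vertex mean when degenerate
polygonCentroid <- function(x, y) {
  n <- length(x)
  j <- c(seq_len(n)[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# lateral surface and volume of one conical frustum (radii r1, r2; axial length L)
frustumLateral <- function(r1, r2, L) pi * (r1 + r2) * sqrt(L^2 + (r1 - r2)^2)
frustumVolume  <- function(r1, r2, L) pi * L / 3 * (r1^2 + r1 * r2 + r2^2)

# frusta surface/volume along a polyline with per-point radii; zero-length edges skipped
pathFrusta <- function(xyz, r) {
  n <- nrow(xyz)
  if (n < 2L) return(c(length = 0, surface = 0, volume = 0))
  d <- sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  keep <- d > 0
  r1 <- r[-n][keep]; r2 <- r[-1L][keep]; dd <- d[keep]
  c(length = sum(dd),
    surface = sum(pi * (r1 + r2) * sqrt(dd^2 + (r1 - r2)^2)),
    volume = sum(pi * dd / 3 * (r1^2 + r1 * r2 + r2^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
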