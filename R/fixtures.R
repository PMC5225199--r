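# Deterministic analytic fixtures with closed-form metric values.
#
# Closed forms used by the tests:
#   cylinder(r, L)        one segment; lateral surface 2*pi*r*L; volume pi*r^2*L
#   y_tree                stem + two daughters; centrifugal orders {1,2,2},
#                         central-shaft orders {1,1,2} (thicker daughter continues)
#   caterpillar(k)        k bifurcations, k+1 endings, 2k+1 segments
#   balanced_tree(depth)  2^depth - 1 nodes, 2^depth endings, 2^(depth+1)-1 segments
#   square_arbor          two identical square loops at mirrored depths
#   helix(pitch, radius, turns)  constant-curvature corkscrew, positive helicity
#   radial_ray(length)    straight ray from the origin along +x

#' Build a deterministic analytic fixture
#'
#' @param fixture one of \code{"cylinder"}, \code{"y_tree"},
#'   \code{"caterpillar"}, \code{"balanced_tree"}, \code{"square_arbor"},
#'   \code{"helix"}, \code{"radial_ray"}. (The formal is named
#'   \code{fixture} so that short fixture arguments like \code{n} passed by
#'   name cannot partially match it.)
#' @param ... fixture parameters, see Details in the source.
#' @return A \linkS4class{Morphology}.
#' @export
makeFixture <- function(fixture, ...) {
  f <- switch(fixture,
              cylinder = fixtureCylinder,
              y_tree = fixtureYTree,
              caterpillar = fixtureCaterpillar,
              balanced_tree = fixtureBalancedTree,
              square_arbor = fixtureSquareArbor,
              helix = fixtureHelix,
              radial_ray = fixtureRadialRay,
              stop("unknown fixture name: ", fixture))
  f(...)
}

pointsDF <- function(x, y, z, radius, parent, type = 0L) {
  data.frame(id = seq_along(x), type = as.integer(type), x = x, y = y, z = z,
             radius = radius, parent = as.integer(parent))
}

fixtureCylinder <- function(radius = 0.5, length = 10, n = 11L) {
  y <- seq(0, length, length.out = n)
  Morphology(pointsDF(rep(0, n), y, rep(0, n), rep(radius, n),
                      c(-1L, seq_len(n - 1L))),
             metadata = list(fixture = "cylinder"))
}

fixtureYTree <- function(stem = 5, daughter = 5, rStem = 0.5,
                         rThick = 0.4, rThin = 0.25) {
  s <- sqrt(2) / 2
  x <- c(0, 0, daughter * s, -daughter * s)
  y <- c(0, stem, stem + daughter * s, stem + daughter * s)
  r <- c(rStem, rStem, rThick, rThin)
  Morphology(pointsDF(x, y, c(0, 0, 0, 0), r, c(-1L, 1L, 2L, 2L)),
             metadata = list(fixture = "y_tree"))
}

# shaft along +y; at every micrometer a bifurcation emits one terminal side
# branch along +x while the shaft continues; k bifurcations in total
fixtureCaterpillar <- function(k = 5L, spacing = 2, side = 1.5,
                               rShaft = 0.4, rSide = 0.2) {
  x <- 0; y <- 0; z <- 0; r <- rShaft; parent <- -1L
  addP <- function(px, py, pz, pr, pp) {
    x <<- c(x, px); y <<- c(y, py); z <<- c(z, pz); r <<- c(r, pr)
    parent <<- c(parent, pp)
    length(x)
  }
  tip <- 1L
  for (i in seq_len(k)) {
    nodeId <- addP(0, i * spacing, 0, rShaft, tip)     # bifurcation point
    addP(side, i * spacing, 0, rSide, nodeId)          # terminal side branch
    tip <- nodeId
  }
  addP(0, k * spacing + spacing, 0, rShaft, tip)       # terminal shaft tip
  Morphology(pointsDF(x, y, z, r, parent),
             metadata = list(fixture = "caterpillar", k = k))
}

fixtureBalancedTree <- function(depth = 2L, stem = 4, branch = 3, r0 = 0.5) {
  x <- c(0, 0); y <- c(0, stem); z <- c(0, 0); r <- c(r0, r0)
  parent <- c(-1L, 1L)
  addP <- function(px, py, pz, pr, pp) {
    x <<- c(x, px); y <<- c(y, py); z <<- c(z, pz); r <<- c(r, pr)
    parent <<- c(parent, pp)
    length(x)
  }
  grow <- function(pid, level, xc, span) {
    if (level > depth) return(invisible(NULL))
    for (s in c(-1, 1)) {
      cid <- addP(xc + s * span, stem + level * branch, 0,
                  r0 * 0.8^level, pid)
      grow(cid, level + 1L, xc + s * span, span / 2)
    }
  }
  grow(2L, 1L, 0, 2^depth)
  Morphology(pointsDF(x, y, z, r, parent),
             metadata = list(fixture = "balanced_tree", depth = depth))
}

# vertical shaft carrying two identical square excursions at depths
# yMid - offset and yMid + offset; symmetric about yMid
fixtureSquareArbor <- function(side = 10, yLow = 10, yHigh = 30, r = 0.3) {
  x <- 0; y <- 0; z <- 0; rr <- r; parent <- -1L
  addP <- function(px, py, pz, pp) {
    x <<- c(x, px); y <<- c(y, py); z <<- c(z, pz); rr <<- c(rr, r)
    parent <<- c(parent, pp)
    length(x)
  }
  square <- function(atY, fromId) {
    h <- side / 2
    corners <- rbind(c(h, h), c(h, -h), c(-h, -h), c(-h, h))
    pid <- fromId
    for (i in seq_len(4)) pid <- addP(corners[i, 1], atY, corners[i, 2], pid)
    pid
  }
  n1 <- addP(0, yLow, 0, 1L)
  square(yLow, n1)
  n2 <- addP(0, yHigh, 0, n1)
  square(yHigh, n2)
  Morphology(pointsDF(x, y, z, rr, parent),
             metadata = list(fixture = "square_arbor"))
}

fixtureHelix <- function(pitch = 1, radius = 1, turns = 3, nPerTurn = 24L,
                         r = 0.2, handedness = 1) {
  t <- seq(0, 2 * pi * turns, length.out = turns * nPerTurn + 1L)
  x <- radius * cos(t)
  z <- -handedness * radius * sin(t)
  y <- pitch * t / (2 * pi)
  n <- length(t)
  Morphology(pointsDF(x, y, z, rep(r, n), c(-1L, seq_len(n - 1L))),
             metadata = list(fixture = "helix", pitch = pitch,
                             radius = radius, handedness = handedness))
}

fixtureRadialRay <- function(length = 10, n = 101L, r = 0.2) {
  x <- seq(0, length, length.out = n)
  Morphology(pointsDF(x, rep(0, n), rep(0, n), rep(r, n),
                      c(-1L, seq_len(n - 1L))),
             metadata = list(fixture = "radial_ray"))
}

# circular soma contour stack approximating a sphere of radius R centered at
# (cx, cy, cz); used by fixtures and the synthetic generator
sphericalSoma <- function(R = 4, center = c(0, -3, 0), nContours = 9L,
                          nVertices = 24L, margin = 0.98) {
  zs <- seq(-R * margin, R * margin, length.out = nContours)
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  lapply(zs, function(zz) {
    rc <- sqrt(max(R^2 - zz^2, 0))
    list(z = center[3] + zz,
         x = center[1] + rc * cos(th),
         y = center[2] + rc * sin(th))
  })
}
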