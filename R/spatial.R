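# Sholl-sphere analysis, laminar profiles, convex hulls (2D exact calipers,
# 3D incremental hull), dendritic-field metrics, density-territory scaling.

#' Sholl-sphere profile
#'
#' Nested concentric spheres at fixed radial separation are centered on the
#' soma centroid. For each sphere the number of geometric crossings by
#' dendritic edges is counted (an edge crossing k spheres contributes to each
#' of them; a tangent touch counts zero; a crossing exactly at a point shared
#' by two edges is counted once). For each shell between consecutive spheres,
#' edges are clipped exactly at the sphere boundaries and path length, frusta
#' surface and volume are accumulated; nodes, endings, varicosities and the
#' mean point diameter are binned by point distance, a point exactly on a
#' sphere belonging to the inner shell.
#'
#' @param m a \linkS4class{Morphology}.
#' @param step sphere separation in um (default 1).
#' @param varicosities optional varicosity table.
#' @param centroid optional centroid override.
#' @return list with \code{step}, \code{radii}, \code{crossings} (per
#'   sphere) and \code{shells} (data.frame per shell).
#' @export
shollProfile <- function(m, step = 1, varicosities = NULL,
                         centroid = somaCentroid(m)) {
  if (step <= 0) stop("step must be positive")
  p <- m@points
  pidx <- match(p$parent, p$id)
  dpt <- sqrt((p$x - centroid[1])^2 + (p$y - centroid[2])^2 +
                (p$z - centroid[3])^2)
  nShell <- max(1L, as.integer(ceiling(max(dpt) / step)))
  radii <- step * seq_len(nShell)
  crossings <- numeric(nShell)
  acc <- matrix(0, nShell, 3,
                dimnames = list(NULL, c("length", "surface", "volume")))
  shellOf <- function(d)
    as.integer(max(1L, min(nShell, as.integer(ceiling(d / step)))))
  for (i in which(!is.na(pidx))) {
    j <- pidx[i]
    a <- c(p$x[j], p$y[j], p$z[j]) - centroid
    b <- c(p$x[i], p$y[i], p$z[i]) - centroid
    r1 <- p$radius[j]; r2 <- p$radius[i]
    u <- b - a
    L <- vnorm(u)
    if (L == 0) next
    # |a + t u|^2 is quadratic in t; minimum at tstar
    A <- sum(u * u); B <- 2 * sum(a * u); C0 <- sum(a * a)
    tstar <- max(0, min(1, -B / (2 * A)))
    dfun <- function(t) sqrt(A * t^2 + B * t + C0)
    # monotone pieces [0, tstar] (decreasing) and [tstar, 1] (increasing)
    breaks <- c(0)
    pieces <- if (tstar > 0 && tstar < 1) list(c(0, tstar), c(tstar, 1))
    else list(c(0, 1))
    dmin <- dfun(tstar)
    for (pc in pieces) {
      d0 <- dfun(pc[1]); d1 <- dfun(pc[2])
      # crossed levels: strictly between the piece ends, plus the piece end
      # itself (a crossing at the end of an edge belongs to this edge); the
      # piece start is excluded (already counted upstream); a tangent touch
      # at the interior minimum counts zero
      ks <- if (d1 >= d0) which(radii > d0 & radii <= d1)
      else which(radii >= d1 & radii < d0)
      for (k in ks) {
        r <- radii[k]
        if (tstar > 0 && tstar < 1 && r == dmin) next   # tangent touch
        crossings[k] <- crossings[k] + 1
        disc <- B^2 - 4 * A * (C0 - r^2)
        if (disc < 0) disc <- 0
        tt <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
        tt <- tt[tt >= pc[1] - 1e-12 & tt <= pc[2] + 1e-12]
        if (length(tt)) breaks <- c(breaks, tt[1])
      }
    }
    breaks <- sort(unique(pmin(1, pmax(0, breaks))))
    breaks <- c(breaks, 1)
    breaks <- unique(breaks)
    for (q in seq_len(length(breaks) - 1L)) {
      t0 <- breaks[q]; t1 <- breaks[q + 1L]
      if (t1 <= t0) next
      mid <- dfun((t0 + t1) / 2)
      sh <- shellOf(mid)
      P0 <- a + t0 * u; P1 <- a + t1 * u
      rr0 <- r1 + t0 * (r2 - r1); rr1 <- r1 + t1 * (r2 - r1)
      ll <- vnorm(P1 - P0)
      acc[sh, "length"] <- acc[sh, "length"] + ll
      acc[sh, "surface"] <- acc[sh, "surface"] + frustumLateral(rr0, rr1, ll)
      acc[sh, "volume"] <- acc[sh, "volume"] + frustumVolume(rr0, rr1, ll)
    }
  }
  sg <- decomposeSegments(m)
  nodeRows <- match(sg$node_ids, p$id)
  endRows <- match(sg$ending_ids, p$id)
  shells <- data.frame(shell = seq_len(nShell), radius = radii)
  shells$length <- acc[, "length"]
  shells$surface <- acc[, "surface"]
  shells$volume <- acc[, "volume"]
  binCount <- function(rows) {
    out <- numeric(nShell)
    for (rr in rows) {
      s <- shellOf(dpt[rr])
      out[s] <- out[s] + 1
    }
    out
  }
  shells$n_nodes <- binCount(nodeRows)
  shells$n_endings <- binCount(endRows)
  if (!is.null(varicosities) && nrow(varicosities)) {
    dv <- sqrt((varicosities$x - centroid[1])^2 +
                 (varicosities$y - centroid[2])^2 +
                 (varicosities$z - centroid[3])^2)
    shells$n_varicosities <- vapply(seq_len(nShell), function(s)
      sum(vapply(dv, shellOf, integer(1)) == s), numeric(1))
  } else shells$n_varicosities <- 0
  shBin <- vapply(dpt, shellOf, integer(1))
  shells$mean_diameter <- vapply(seq_len(nShell), function(s) {
    dd <- 2 * p$radius[shBin == s]
    if (length(dd)) mean(dd) else NA_real_
  }, numeric(1))
  shells$crossings <- crossings
  list(step = step, radii = radii, crossings = crossings, shells = shells)
}

#' Laminar profile across retinal layers
#'
#' Path length is split by clipping every edge linearly at the layer/stratum
#' boundaries; nodes, endings and varicosities are binned by their depth
#' coordinate. Relative fractions per quantity sum to 1.
#'
#' @param m a \linkS4class{Morphology}.
#' @param layers a \linkS4class{LayerModel}.
#' @param varicosities optional varicosity table.
#' @return data.frame with one row per bin (INL, S1..S5, GCL): absolute
#'   \code{length}, \code{n_nodes}, \code{n_endings}, \code{n_varicosities}
#'   and the corresponding \code{*_fraction} columns.
#' @export
laminarProfile <- function(m, layers, varicosities = NULL) {
  p <- m@points
  pidx <- match(p$parent, p$id)
  y0 <- layers@yInlIpl; y1 <- layers@yIplGcl
  bounds <- y0 + (y1 - y0) * (0:5) / 5
  bins <- layerBins()
  binAt <- function(y) as.character(annotateLayers(y, layers))
  len <- stats::setNames(numeric(7), bins)
  for (i in which(!is.na(pidx))) {
    j <- pidx[i]
    a <- c(p$x[j], p$y[j], p$z[j]); b <- c(p$x[i], p$y[i], p$z[i])
    L <- vnorm(b - a)
    if (L == 0) next
    ya <- a[2]; yb <- b[2]
    if (ya == yb) {
      bn <- binAt(ya)
      len[bn] <- len[bn] + L
      next
    }
    ts <- (bounds - ya) / (yb - ya)
    ts <- sort(unique(c(0, ts[ts > 0 & ts < 1], 1)))
    for (q in seq_len(length(ts) - 1L)) {
      t0 <- ts[q]; t1 <- ts[q + 1L]
      ymid <- ya + (t0 + t1) / 2 * (yb - ya)
      bn <- binAt(ymid)
      len[bn] <- len[bn] + (t1 - t0) * L
    }
  }
  sg <- decomposeSegments(m)
  nodeBins <- binAt(p$y[match(sg$node_ids, p$id)])
  endBins <- binAt(p$y[match(sg$ending_ids, p$id)])
  cnt <- function(bb) vapply(bins, function(b) sum(bb == b), numeric(1))
  out <- data.frame(layer = bins, length = as.numeric(len),
                    n_nodes = cnt(nodeBins), n_endings = cnt(endBins))
  out$n_varicosities <- if (!is.null(varicosities) && nrow(varicosities))
    cnt(binAt(varicosities$y)) else 0
  frac <- function(v) if (sum(v) > 0) v / sum(v) else rep(NA_real_, length(v))
  out$length_fraction <- frac(out$length)
  out$node_fraction <- frac(out$n_nodes)
  out$varicosity_fraction <- frac(out$n_varicosities)
  rownames(out) <- NULL
  out
}

#' 2D convex hull with exact Feret calipers
#'
#' Projects 3D points onto the requested plane, takes the convex hull, and
#' reports area, perimeter, Feret maximum (largest pairwise distance between
#' hull vertices) and Feret minimum (smallest width over rotating calipers,
#' i.e. the minimum over hull edges of the largest vertex distance from the
#' edge line). Collinear input is a degenerate-hull error.
#'
#' @param points n x 3 matrix (or data.frame) of coordinates, or a
#'   \linkS4class{Morphology}.
#' @param projection \code{"xz"} (retinal surface, default), \code{"xy"}, or
#'   \code{"yz"}.
#' @return list with \code{vertices} (hull polygon, counter-clockwise),
#'   \code{area}, \code{perimeter}, \code{feret_max}, \code{feret_min}.
#' @export
convexHull2D <- function(points, projection = c("xz", "xy", "yz")) {
  projection <- match.arg(projection)
  if (is(points, "Morphology"))
    points <- cbind(points@points$x, points@points$y, points@points$z)
  points <- as.matrix(points)
  cols <- switch(projection, xz = c(1L, 3L), xy = c(1L, 2L), yz = c(2L, 3L))
  P <- points[, cols, drop = FALSE]
  P <- unique(P)
  if (nrow(P) < 3L) stop("degenerate hull: fewer than 3 distinct points")
  h <- grDevices::chull(P[, 1], P[, 2])
  if (length(h) < 3L) stop("degenerate hull: collinear points")
  V <- P[rev(h), , drop = FALSE]          # counter-clockwise
  area <- polygonArea(V[, 1], V[, 2])
  if (area < 1e-12) stop("degenerate hull: collinear points")
  per <- polygonPerimeter(V[, 1], V[, 2])
  D <- as.matrix(stats::dist(V))
  fmax <- max(D)
  nv <- nrow(V)
  widths <- vapply(seq_len(nv), function(i) {
    jn <- if (i == nv) 1L else i + 1L
    e <- V[jn, ] - V[i, ]
    en <- vnorm(e)
    if (en == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / en
    dd <- (V[, 1] - V[i, 1]) * nrm[1] + (V[, 2] - V[i, 2]) * nrm[2]
    max(abs(dd))
  }, numeric(1))
  list(vertices = V, area = area, perimeter = per,
       feret_max = fmax, feret_min = min(widths))
}

#' 3D convex hull volume and surface area
#'
#' Exact incremental convex hull over the point set; returns the enclosed
#' volume and the hull surface area. Requires at least four non-coplanar
#' points.
#'
#' @param points n x 3 matrix of coordinates.
#' @return list with \code{volume}, \code{surface}, and the hull
#'   \code{faces} (m x 3 matrix of point row indices).
#' @export
convexHull3D <- function(points) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  X <- unique(X)
  n <- nrow(X)
  if (n < 4L) stop("degenerate hull: need at least 4 distinct points")
  scale <- max(apply(X, 2, function(c) diff(range(c))))
  eps <- 1e-9 * max(scale, 1)
  # initial simplex: extreme point pair, then farthest from line, then plane
  i1 <- which.min(X[, 1])
  d1 <- sqrt(rowSums(sweep(X, 2, X[i1, ])^2))
  i2 <- which.max(d1)
  u <- X[i2, ] - X[i1, ]
  dl <- vapply(seq_len(n), function(i) {
    w <- X[i, ] - X[i1, ]
    vnorm(cross3(u, w)) / vnorm(u)
  }, numeric(1))
  i3 <- which.max(dl)
  if (dl[i3] < eps) stop("degenerate hull: collinear points")
  nrm <- cross3(u, X[i3, ] - X[i1, ])
  dp <- abs(as.numeric(sweep(X, 2, X[i1, ]) %*% nrm)) / vnorm(nrm)
  i4 <- which.max(dp)
  if (dp[i4] < eps) stop("degenerate hull: coplanar points")
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(X[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    a <- X[f[1], ]; b <- X[f[2], ]; c3 <- X[f[3], ]
    nn <- cross3(b - a, c3 - a)
    if (sum(nn * (ctr - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(faces, orient)
  faceNormal <- function(f) {
    a <- X[f[1], ]
    nn <- cross3(X[f[2], ] - a, X[f[3], ] - a)
    list(a = a, n = nn)
  }
  for (i in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(faces, function(f) {
      fn <- faceNormal(f)
      sum(fn$n * (X[i, ] - fn$a)) > eps * vnorm(fn$n)
    }, logical(1))
    if (!any(vis)) next
    visible <- faces[vis]
    faces <- faces[!vis]
    # horizon = edges of visible faces not shared by two visible faces
    edges <- do.call(rbind, lapply(visible, function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    keyFwd <- paste(edges[, 1], edges[, 2])
    keyRev <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(keyFwd %in% keyRev), , drop = FALSE]
    for (e in seq_len(nrow(horizon)))
      faces[[length(faces) + 1L]] <- c(horizon[e, 1], horizon[e, 2], i)
    # keep orientation consistent: new faces wind like the horizon edge
  }
  interior <- colMeans(X[unique(unlist(faces)), , drop = FALSE])
  vol <- 0; surf <- 0
  for (f in faces) {
    a <- X[f[1], ]; b <- X[f[2], ]; c3 <- X[f[3], ]
    nn <- cross3(b - a, c3 - a)
    surf <- surf + vnorm(nn) / 2
    vol <- vol + abs(sum((a - interior) * cross3(b - interior, c3 - interior))) / 6
  }
  list(volume = vol, surface = surf,
       faces = do.call(rbind, faces))
}

#' Arboreal and lobular dendritic-field hulls
#'
#' Splits the reconstruction at depth \code{ySplit} and computes the 2D
#' convex hull of each part projected onto the XZ plane (the retinal
#' surface): the proximal part gives the arboreal field, the distal part the
#' lobular field. A part with fewer than 3 distinct projected points yields
#' no hull.
#'
#' @param m a \linkS4class{Morphology}.
#' @param ySplit split-plane depth in um.
#' @param varicosities unused, accepted for interface symmetry.
#' @return list with \code{arboreal}, \code{lobular} (2D hulls or NULL),
#'   \code{split} (the \code{\link{splitDendriticFields}} result) and
#'   \code{arboreal_larger} (logical area comparison).
#' @export
fieldMetrics <- function(m, ySplit, varicosities = NULL) {
  fs <- splitDendriticFields(m, ySplit)
  p <- m@points
  mk <- function(sel) {
    if (sum(sel) < 3L) return(NULL)
    tryCatch(convexHull2D(cbind(p$x[sel], p$y[sel], p$z[sel]), "xz"),
             error = function(e) NULL)
  }
  arb <- mk(fs$side == "proximal")
  lob <- mk(fs$side == "distal")
  list(arboreal = arb, lobular = lob, split = fs,
       arboreal_larger = if (!is.null(arb) && !is.null(lob))
         arb$area > lob$area else NA)
}

#' Branch density versus territory volume scaling fit
#'
#' Branch density is total dendritic length divided by the 3D convex hull
#' (territory) volume. A straight line is fitted to log10(density) against
#' log10(volume); the reference line slope -0.55 / intercept 0.45 describes
#' the general neural-arbor scaling relation reported across many cell types
#' and is returned for comparison.
#'
#' @param hullVolume per-cell territory volumes (um^3), or a data.frame with
#'   columns \code{hull_volume} and \code{total_length}.
#' @param totalLength per-cell total dendritic lengths (um).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{data} (volume, length, density) and \code{reference}.
#' @export
densityScalingFit <- function(hullVolume, totalLength = NULL) {
  if (is.data.frame(hullVolume)) {
    totalLength <- hullVolume$total_length
    hullVolume <- hullVolume$hull_volume
  }
  if (length(hullVolume) < 2L) stop("need at least 2 cells")
  if (any(hullVolume <= 0) || any(totalLength <= 0))
    stop("volumes and lengths must be positive")
  density <- totalLength / hullVolume
  lx <- log10(hullVolume); ly <- log10(density)
  fit <- stats::lm(ly ~ lx)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       data = data.frame(hull_volume = hullVolume,
                         total_length = totalLength, density = density),
       reference = c(slope = -0.55, intercept = 0.45))
}
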