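# Layer annotation, major-axis alignment, soma centroid, dendritic-field split.

#' Bin reconstruction points into retinal layers
#'
#' Each point is assigned to INL, one of the five equal IPL strata S1..S5, or
#' GCL according to its depth coordinate. A point exactly on a stratum
#' boundary goes to the stratum nearer the INL (deterministic tie-break); a
#' point exactly on the INL/IPL boundary is binned INL, one exactly on the
#' IPL/GCL boundary is binned S5.
#'
#' @param m a \linkS4class{Morphology}, or a numeric vector of depths.
#' @param layers a \linkS4class{LayerModel}.
#' @return factor with levels \code{layerBins()}, one per point.
#' @export
annotateLayers <- function(m, layers) {
  y <- if (is(m, "Morphology")) m@points$y else as.numeric(m)
  validObject(layers)
  f <- (y - layers@yInlIpl) / (layers@yIplGcl - layers@yInlIpl)
  s <- ceiling(5 * f)           # 1..5 inside the IPL; 0 exactly at INL border
  bin <- ifelse(f <= 0, "INL", ifelse(f > 1, "GCL", paste0("S", pmin(s, 5))))
  factor(bin, levels = layerBins())
}

#' Soma centroid
#'
#' Volume-weighted centroid of the soma contour stack (contour-polygon
#' centroids weighted by area times local slab thickness). When no contours
#' are present, falls back to the mean position of the tree roots.
#'
#' @param m a \linkS4class{Morphology}.
#' @return numeric length-3 (x, y, z).
#' @export
somaCentroid <- function(m) {
  if (length(m@soma) == 0L) {
    r <- m@points[m@points$parent == -1L, , drop = FALSE]
    if (nrow(r) == 0L) stop("no soma contours and no tree roots")
    return(c(mean(r$x), mean(r$y), mean(r$z)))
  }
  zs <- vapply(m@soma, `[[`, numeric(1), "z")
  ord <- order(zs); zs <- zs[ord]; cts <- m@soma[ord]
  n <- length(cts)
  areas <- vapply(cts, function(ct) polygonArea(ct$x, ct$y), numeric(1))
  cents <- t(vapply(cts, function(ct) polygonCentroid(ct$x, ct$y), numeric(2)))
  thick <- if (n == 1L) 1 else {
    dz <- diff(zs)
    c(dz[1] / 2, (dz[-1] + dz[-length(dz)]) / 2, dz[length(dz)] / 2)
  }
  w <- areas * thick
  if (sum(w) == 0) w <- rep(1, n)
  c(sum(cents[, 1] * w), sum(cents[, 2] * w), sum(zs * w)) / sum(w)
}

#' Rotate a reconstruction so its major axis is vertical
#'
#' The principal axis of the reconstruction-point cloud is found by
#' eigen-decomposition of the coordinate covariance and the cell is rotated --
#' first in the XY plane (about z), then in the YZ plane (about x) -- until
#' that axis is parallel to the depth (y) axis. Soma contour vertices are
#' rotated along with the points; all pairwise distances are preserved.
#'
#' @param m a \linkS4class{Morphology} with at least 3 non-collinear points.
#' @return the rotated \linkS4class{Morphology}.
#' @export
alignMajorAxis <- function(m) {
  p <- m@points
  X <- cbind(p$x, p$y, p$z)
  if (nrow(X) < 3L) stop("need at least 3 points")
  ctr <- colMeans(X)
  cv <- stats::cov(X)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * ev$values[1])
    stop("degenerate (collinear) point cloud")
  v <- ev$vectors[, 1]
  if (v[2] < 0) v <- -v
  t1 <- atan2(v[1], v[2])                       # about z: zero the x component
  Rz <- rbind(c(cos(t1), -sin(t1), 0), c(sin(t1), cos(t1), 0), c(0, 0, 1))
  v1 <- as.numeric(Rz %*% v)
  t2 <- atan2(v1[3], v1[2])                     # about x: zero the z component
  Rx <- rbind(c(1, 0, 0), c(0, cos(t2), sin(t2)), c(0, -sin(t2), cos(t2)))
  R <- Rx %*% Rz
  rot <- function(M) sweep(t(R %*% t(sweep(M, 2, ctr))), 2, ctr, `+`)
  Xr <- rot(X)
  p$x <- Xr[, 1]; p$y <- Xr[, 2]; p$z <- Xr[, 3]
  soma <- lapply(m@soma, function(ct) {
    V <- rot(cbind(ct$x, ct$y, rep(ct$z, length(ct$x))))
    # contours stay associated with their (rotated mean) focal depth
    list(z = mean(V[, 3]), x = V[, 1], y = V[, 2])
  })
  new("Morphology", points = p, soma = soma, metadata = m@metadata)
}

#' Split a reconstruction into distal and proximal dendritic fields
#'
#' The arbor is cut by an XZ plane at depth \code{ySplit}: the distal part
#' (toward the INL: soma, apical trunk, lobular dendrites) and the proximal
#' part (toward the GCL: arboreal dendrites). Edges crossing the plane are
#' clipped by linear interpolation of position and radius; frusta surface
#' areas are accumulated per side and the soma surface is assigned to the
#' side containing the soma centroid. Fractions are percentages of the total
#' (soma + dendritic) surface area and sum to 100.
#'
#' @param m a \linkS4class{Morphology}.
#' @param ySplit depth of the splitting plane (um); must lie within the
#'   arbor's depth range.
#' @return list with \code{y_split}, \code{distal_area}, \code{proximal_area}
#'   (um^2), \code{distal_fraction}, \code{proximal_fraction} (percent), and
#'   \code{side}, a factor ("distal"/"proximal") assigning every point to
#'   exactly one part.
#' @export
splitDendriticFields <- function(m, ySplit) {
  p <- m@points
  yr <- range(p$y)
  if (ySplit <= yr[1] || ySplit >= yr[2])
    stop("ySplit must lie strictly within the arbor depth range [",
         signif(yr[1], 4), ", ", signif(yr[2], 4), "]")
  # distal = side of smaller depth (toward the INL) under the standard
  # orientation where depth increases from INL to GCL
  areas <- c(distal = 0, proximal = 0)
  pidx <- match(p$parent, p$id)
  sideOf <- function(y) if (y <= ySplit) "distal" else "proximal"
  for (i in which(!is.na(pidx))) {
    j <- pidx[i]
    y1 <- p$y[j]; y2 <- p$y[i]
    a1 <- c(p$x[j], p$y[j], p$z[j]); a2 <- c(p$x[i], p$y[i], p$z[i])
    r1 <- p$radius[j]; r2 <- p$radius[i]
    L <- vnorm(a2 - a1)
    if (L == 0) next
    if ((y1 - ySplit) * (y2 - ySplit) < 0) {
      t <- (ySplit - y1) / (y2 - y1)
      rm_ <- r1 + t * (r2 - r1)
      s1 <- sideOf(y1); s2 <- sideOf(y2)
      areas[s1] <- areas[s1] + frustumLateral(r1, rm_, L * t)
      areas[s2] <- areas[s2] + frustumLateral(rm_, r2, L * (1 - t))
    } else {
      s <- sideOf((y1 + y2) / 2)
      areas[s] <- areas[s] + frustumLateral(r1, r2, L)
    }
  }
  somaArea <- 0
  if (length(m@soma) >= 2L) {
    somaArea <- somaMetrics(m@soma)$surface_area
    sc <- somaCentroid(m)
    areas[sideOf(sc[2])] <- areas[sideOf(sc[2])] + somaArea
  }
  tot <- sum(areas)
  side <- factor(ifelse(p$y <= ySplit, "distal", "proximal"),
                 levels = c("distal", "proximal"))
  list(y_split = ySplit,
       distal_area = unname(areas["distal"]),
       proximal_area = unname(areas["proximal"]),
       distal_fraction = unname(100 * areas["distal"] / tot),
       proximal_fraction = unname(100 * areas["proximal"] / tot),
       soma_area = somaArea,
       side = side)
}

somaSideSign <- function(layers) sign(layers@yIplGcl - layers@yInlIpl)

#' Automatic split depth from the waist of the depth-density profile
#'
#' The split plane between lobular and arboreal fields is normally placed by
#' eye; as an automatic default, the length-density profile along depth is
#' binned (1 um), lightly smoothed, and the minimum between the two dominant
#' peaks of the bistratified profile is returned.
#'
#' @param m a \linkS4class{Morphology}.
#' @param bin bin width in um.
#' @return depth of the waist (um).
#' @export
autoSplitDepth <- function(m, bin = 1) {
  p <- m@points
  pidx <- match(p$parent, p$id)
  ii <- which(!is.na(pidx))
  jj <- pidx[ii]
  len <- sqrt((p$x[ii] - p$x[jj])^2 + (p$y[ii] - p$y[jj])^2 +
                (p$z[ii] - p$z[jj])^2)
  ym <- (p$y[ii] + p$y[jj]) / 2
  br <- seq(floor(min(ym)) - bin, ceiling(max(ym)) + bin, by = bin)
  h <- tapply(len, cut(ym, br), sum, default = 0)
  h[is.na(h)] <- 0
  k <- as.numeric(stats::filter(as.numeric(h), rep(1 / 5, 5), sides = 2))
  k[is.na(k)] <- 0
  mid <- (br[-1] + br[-length(br)]) / 2
  pk <- which.max(k)                 # dominant (arboreal) peak
  # second mode: the candidate with the deepest valley between it and the
  # dominant peak (a mere shoulder of the same band has no valley)
  sep <- ceiling(8 / bin)
  cand <- which(abs(seq_along(k) - pk) >= sep & k > 0)
  if (!length(cand)) return(mid[pk])
  score <- vapply(cand, function(cc) {
    lo <- min(pk, cc); hi <- max(pk, cc)
    valley <- min(k[lo:hi])
    min(k[pk], k[cc]) / max(valley, 1e-9)
  }, numeric(1))
  other <- cand[which.max(score)]
  lo <- min(pk, other); hi <- max(pk, other)
  if (hi - lo < 2) return(mean(mid[c(lo, hi)]))
  w <- lo + which.min(k[(lo + 1):(hi - 1)])
  mid[w]
}
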