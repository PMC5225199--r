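# Per-cell geometric and topological metrics.

#' Partition asymmetry per bifurcation
#'
#' For a bifurcation whose daughter subtrees carry n1 and n2 terminal tips,
#' the partition asymmetry is |n1 - n2| / (n1 + n2 - 2), defined as 0 for a
#' tip bifurcation (n1 = n2 = 1). A "stub" bifurcation (exactly one daughter
#' a single terminal branch, the other bifurcating further) scores 1. The
#' alternative \code{counts = "nodes"} mode uses daughter-subtree node counts
#' instead of tip counts. Bifurcations with more than two daughters
#' (trifurcations) are skipped and flagged.
#'
#' @param sg result of \code{\link{decomposeSegments}}.
#' @param counts \code{"tips"} (default) or \code{"nodes"}.
#' @return list with \code{per_bifurcation} (data.frame: node id, n1, n2,
#'   value), \code{mean}, and \code{n_skipped} (non-binary nodes). When the
#'   tree has no bifurcations the mean is \code{NA}.
#' @export
partitionAsymmetry <- function(sg, counts = c("tips", "nodes")) {
  counts <- match.arg(counts)
  df <- sg$segments
  ns <- nrow(df)
  children <- split(seq_len(ns), factor(df$parent_segment, levels = seq_len(ns)))
  tips <- as.integer(df$terminal)
  nodes <- integer(ns)
  for (i in rev(seq_len(ns))) {
    pp <- df$parent_segment[i]
    if (!is.na(pp)) {
      tips[pp] <- tips[pp] + tips[i]
      nodes[pp] <- nodes[pp] + nodes[i]
    }
    if (!df$terminal[i]) nodes[i] <- nodes[i] + 1L
  }
  w <- if (counts == "tips") tips else nodes
  rows <- list(); skipped <- 0L
  for (s in seq_len(ns)) {
    ch <- children[[s]]
    if (is.null(ch) || length(ch) < 2L) next
    if (length(ch) > 2L) { skipped <- skipped + 1L; next }
    n1 <- w[ch[1L]]; n2 <- w[ch[2L]]
    val <- if (n1 + n2 <= 2L) 0 else abs(n1 - n2) / (n1 + n2 - 2)
    rows[[length(rows) + 1L]] <- data.frame(node_id = df$end_id[s],
                                            n1 = n1, n2 = n2, value = val)
  }
  per <- if (length(rows)) do.call(rbind, rows)
  else data.frame(node_id = integer(0), n1 = integer(0), n2 = integer(0),
                  value = numeric(0))
  list(per_bifurcation = per,
       mean = if (nrow(per)) mean(per$value) else NA_real_,
       n_skipped = skipped)
}

# daughter chord vectors at each binary node: from the node point to the end
# point of each daughter segment
daughterChords <- function(sg, m) {
  p <- m@points
  df <- sg$segments
  ns <- nrow(df)
  children <- split(seq_len(ns), factor(df$parent_segment, levels = seq_len(ns)))
  out <- list()
  for (s in seq_len(ns)) {
    ch <- children[[s]]
    if (is.null(ch) || length(ch) != 2L) next
    nid <- match(df$end_id[s], p$id)
    node <- c(p$x[nid], p$y[nid], p$z[nid])
    chords <- lapply(ch, function(cc) {
      eid <- match(df$end_id[cc], p$id)
      c(p$x[eid], p$y[eid], p$z[eid]) - node
    })
    out[[length(out) + 1L]] <- list(segment = s, node_id = df$end_id[s],
                                    v1 = chords[[1L]], v2 = chords[[2L]])
  }
  out
}

#' Remote bifurcation angles
#'
#' The angle between the two daughter chord vectors (node point to daughter
#' segment end point) at every binary bifurcation; degrees in [0, 180].
#' Bifurcations with a zero-length daughter chord are skipped and flagged.
#' The per-cell SD is the population SD over that cell's bifurcations.
#'
#' @param sg result of \code{\link{decomposeSegments}}.
#' @param m the \linkS4class{Morphology}.
#' @return list with \code{angles} (degrees, named by node id), \code{mean},
#'   \code{sd}, \code{n_skipped}.
#' @export
bifurcationAngles <- function(sg, m) {
  ch <- daughterChords(sg, m)
  skipped <- 0L
  angs <- c()
  for (e in ch) {
    if (vnorm(e$v1) == 0 || vnorm(e$v2) == 0) { skipped <- skipped + 1L; next }
    a <- deg(vecAngle(e$v1, e$v2))
    angs <- c(angs, stats::setNames(a, e$node_id))
  }
  list(angles = angs,
       mean = if (length(angs)) mean(angs) else NA_real_,
       sd = popSD(angs),
       n_skipped = skipped)
}

#' Remote bifurcation tilts
#'
#' For each binary bifurcation, the tilt of a daughter is the angle between
#' its chord and the backward-pointing direction of the parent segment's last
#' edge: 180 degrees means the daughter continues straight ahead, 0 degrees
#' means it doubles back. The reported per-bifurcation value is the smaller
#' (most backward) of the two daughters' tilts. Bifurcations whose parent
#' segment has no usable final edge are skipped.
#'
#' @inheritParams bifurcationAngles
#' @return list with \code{tilts} (degrees), \code{mean}, \code{sd},
#'   \code{n_skipped}.
#' @export
bifurcationTilts <- function(sg, m) {
  p <- m@points
  df <- sg$segments
  ch <- daughterChords(sg, m)
  tilts <- c(); skipped <- 0L
  for (e in ch) {
    ids <- sg$paths[[e$segment]]
    rr <- match(ids[c(length(ids) - 1L, length(ids))], p$id)
    pdir <- c(p$x[rr[2]] - p$x[rr[1]], p$y[rr[2]] - p$y[rr[1]],
              p$z[rr[2]] - p$z[rr[1]])
    if (vnorm(pdir) == 0 || vnorm(e$v1) == 0 || vnorm(e$v2) == 0) {
      skipped <- skipped + 1L; next
    }
    back <- -pdir
    t1 <- deg(vecAngle(e$v1, back))
    t2 <- deg(vecAngle(e$v2, back))
    tilts <- c(tilts, stats::setNames(min(t1, t2), e$node_id))
  }
  list(tilts = tilts,
       mean = if (length(tilts)) mean(tilts) else NA_real_,
       sd = popSD(tilts),
       n_skipped = skipped)
}

#' Fractal dimension per branch
#'
#' Quantifies how much a branch resembles a fractal object (or random walk):
#' 1 for a branch steadily growing in one direction, 2 for a random walk.
#' For every segment with at least 3 points, mean Euclidean displacement is
#' computed over all windows of a given path-length lag; the slope of
#' log-displacement against log-lag, fitted over the monotone growth regime
#' (fitting stops once displacement saturates, as it does for tightly coiled
#' trajectories), is inverted to give D. Averaging over windows keeps the
#' estimate stable on long meandering branches. The cell value is the
#' unweighted mean over branches.
#'
#' @inheritParams bifurcationAngles
#' @return list with \code{per_branch} (one D per eligible segment),
#'   \code{mean}.
#' @export
fractalDimension <- function(sg, m) {
  p <- m@points
  ds <- c()
  for (k in seq_along(sg$paths)) {
    ids <- sg$paths[[k]]
    if (length(ids) < 3L) next
    rr <- match(ids, p$id)
    xyz <- cbind(p$x[rr], p$y[rr], p$z[rr])
    d <- branchFractalDimension(xyz)
    if (is.finite(d)) ds <- c(ds, d)
  }
  list(per_branch = unname(ds),
       mean = if (length(ds)) mean(ds) else NA_real_)
}

branchFractalDimension <- function(xyz) {
  n <- nrow(xyz)
  step <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                          xyz[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(step))
  if (cum[n] <= 0) return(NA_real_)
  lags <- unique(round(exp(seq(0, log(n - 1L), length.out = 24))))
  le <- lc <- numeric(0)
  for (k in lags) {
    i <- seq_len(n - k)
    eu <- sqrt(rowSums((xyz[i + k, , drop = FALSE] -
                          xyz[i, , drop = FALSE])^2))
    pl <- cum[i + k] - cum[i]
    if (mean(eu) > 0 && mean(pl) > 0) {
      le <- c(le, log(mean(eu)))
      lc <- c(lc, log(mean(pl)))
    }
  }
  if (length(le) < 2L) return(NA_real_)
  # saturation cut: drop lags after displacement falls below 90 percent of
  # its running maximum
  mx <- -Inf
  keep <- rep(TRUE, length(le))
  for (q in seq_along(le)) {
    mx <- max(mx, le[q])
    if (le[q] < mx + log(0.9)) { keep[q:length(le)] <- FALSE; break }
  }
  if (sum(keep) < 2L) return(NA_real_)
  s <- stats::lm.fit(cbind(1, lc[keep]), le[keep])$coefficients[2L]
  if (!is.finite(s) || s <= 0) return(NA_real_)
  unname(1 / s)
}

#' Helicity of dendritic trajectories
#'
#' For every sliding window of three consecutive edge vectors v1, v2, v3
#' along a segment path, the normalized triple product
#' (v1 x v2) . v3 / (|v1||v2||v3|). Positive values indicate right-handed
#' corkscrew growth, negative left-handed; planar trajectories give 0.
#' Windows containing a zero-length edge are skipped.
#'
#' @inheritParams bifurcationAngles
#' @return list with \code{per_window} values and their \code{mean}.
#' @export
helicity <- function(sg, m) {
  p <- m@points
  hs <- numeric(0)
  for (k in seq_along(sg$paths)) {
    ids <- sg$paths[[k]]
    if (length(ids) < 4L) next
    rr <- match(ids, p$id)
    xyz <- cbind(p$x[rr], p$y[rr], p$z[rr])
    E <- xyz[-1L, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE]
    for (i in seq_len(nrow(E) - 2L)) {
      v1 <- E[i, ]; v2 <- E[i + 1L, ]; v3 <- E[i + 2L, ]
      nn <- vnorm(v1) * vnorm(v2) * vnorm(v3)
      if (nn == 0) next
      hs <- c(hs, sum(cross3(v1, v2) * v3) / nn)
    }
  }
  list(per_window = hs, mean = if (length(hs)) mean(hs) else NA_real_)
}

#' Euclidean distance of reconstruction points from the soma centroid
#'
#' @param m a \linkS4class{Morphology}.
#' @param centroid optional centroid override (length-3).
#' @return list with \code{mean} (unweighted over all points), \code{max},
#'   and the per-point \code{distances}.
#' @export
euclideanDistanceStats <- function(m, centroid = somaCentroid(m)) {
  p <- m@points
  if (nrow(p) == 0L) stop("empty arbor")
  d <- sqrt((p$x - centroid[1])^2 + (p$y - centroid[2])^2 +
              (p$z - centroid[3])^2)
  list(mean = mean(d), max = max(d), distances = d)
}

#' Soma metrics from the contour stack
#'
#' Volume is the stack of slabs between consecutive contours (mean area times
#' spacing); lateral surface treats consecutive contour perimeters as frusta
#' of perimeter-equivalent circles, plus the two end-cap areas. Projection
#' metrics (area, perimeter, Feret max/min) are computed on the convex
#' outline of all contour vertices projected onto the XY plane. With a single
#' contour only the projection metrics are returned.
#'
#' @param soma a soma contour list (or a \linkS4class{Morphology}).
#' @return list with \code{volume}, \code{surface_area} (NA with fewer than
#'   2 contours), \code{projection_area}, \code{projection_perimeter},
#'   \code{feret_max}, \code{feret_min}.
#' @export
somaMetrics <- function(soma) {
  if (is(soma, "Morphology")) soma <- soma@soma
  if (length(soma) == 0L)
    return(list(volume = NA_real_, surface_area = NA_real_,
                projection_area = NA_real_, projection_perimeter = NA_real_,
                feret_max = NA_real_, feret_min = NA_real_))
  zs <- vapply(soma, `[[`, numeric(1), "z")
  ord <- order(zs); zs <- zs[ord]; soma <- soma[ord]
  A <- vapply(soma, function(ct) polygonArea(ct$x, ct$y), numeric(1))
  P <- vapply(soma, function(ct) polygonPerimeter(ct$x, ct$y), numeric(1))
  vol <- NA_real_; surf <- NA_real_
  if (length(soma) >= 2L) {
    dz <- diff(zs)
    vol <- sum((A[-1L] + A[-length(A)]) / 2 * dz)
    re <- P / (2 * pi)
    lat <- sum((P[-1L] + P[-length(P)]) / 2 *
                 sqrt(dz^2 + diff(re)^2))
    surf <- lat + A[1L] + A[length(A)]
  }
  V <- do.call(rbind, lapply(soma, function(ct) cbind(ct$x, ct$y)))
  hull <- convexHull2D(cbind(V, 0), projection = "xy")
  list(volume = vol, surface_area = surf,
       projection_area = hull$area, projection_perimeter = hull$perimeter,
       feret_max = hull$feret_max, feret_min = hull$feret_min)
}

#' Correct process diameters for the resolution limit
#'
#' The diameters of the 10 thinnest reconstruction points, taken on 10 unique
#' branch segments, are averaged; the difference between \code{target} and
#' this average is added to every process diameter so the post-correction
#' average equals \code{target} exactly. Soma contours are untouched. The
#' operation is idempotent: a second application yields a zero shift.
#'
#' @param m a \linkS4class{Morphology} with at least 10 branch segments.
#' @param target target mean diameter of the 10 thinnest points (um),
#'   default 0.23 (the thinnest-process caliber seen in electron-microscopic
#'   reconstructions of this cell type).
#' @return list with \code{morphology} (corrected) and \code{shift} (um,
#'   added to diameters).
#' @export
correctDiameters <- function(m, target = 0.23) {
  sg <- decomposeSegments(m)
  if (nrow(sg$segments) < 10L)
    stop("diameter correction needs at least 10 branch segments")
  thin10 <- sort(sg$segments$min_diameter)[1:10]
  shift <- target - mean(thin10)
  p <- m@points
  newR <- p$radius + shift / 2
  if (any(newR <= 0))
    stop("correction shift of ", signif(shift, 4),
         " um would produce non-positive diameters")
  p$radius <- newR
  list(morphology = new("Morphology", points = p, soma = m@soma,
                        metadata = m@metadata),
       shift = shift)
}

#' Expected membrane capacitance from surface area
#'
#' C = total surface area x specific membrane capacitance (default
#' 0.01 pF/um^2). Given a \linkS4class{Morphology}, the total area is the
#' soma surface (when contours are available) plus the dendritic frusta
#' surface; a plain number is treated as an area in um^2.
#'
#' @param x a \linkS4class{Morphology} or a total surface area (um^2).
#' @param specificCapacitance pF per um^2.
#' @return capacitance in pF.
#' @export
estimateCapacitance <- function(x, specificCapacitance = 0.01) {
  area <- if (is.numeric(x)) x else {
    sm <- somaMetrics(x)
    sa <- if (is.finite(sm$surface_area %||% NA_real_)) sm$surface_area else 0
    sg <- decomposeSegments(x)
    sa + sum(sg$segments$surface)
  }
  area * specificCapacitance
}

#' Per-branch-order profiles
#'
#' Totals of segment count, path length, surface, volume, and the numbers of
#' nodes and endings for each branch order under the chosen ordering scheme.
#' Sums across orders equal the whole-cell totals.
#'
#' @param sg result of \code{\link{decomposeSegments}}.
#' @param scheme \code{"central_shaft"} or \code{"centrifugal"}.
#' @param varicosities optional varicosity table (from
#'   \code{\link{detectVaricosities}}) to add per-order varicosity counts.
#' @return data.frame with one row per order.
#' @export
orderProfiles <- function(sg, scheme = c("central_shaft", "centrifugal"),
                          varicosities = NULL) {
  scheme <- match.arg(scheme)
  df <- sg$segments
  ord <- if (scheme == "centrifugal") df$order_centrifugal else df$order_shaft
  os <- sort(unique(ord))
  out <- data.frame(order = os)
  agg <- function(v, f = sum) vapply(os, function(o) f(v[ord == o]), numeric(1))
  out$n_segments <- agg(rep(1, nrow(df)))
  out$length <- agg(df$path_length)
  out$surface <- agg(df$surface)
  out$volume <- agg(df$volume)
  out$n_endings <- agg(as.numeric(df$terminal))
  out$n_nodes <- agg(as.numeric(!df$terminal))   # each non-terminal segment ends in a node
  if (!is.null(varicosities) && nrow(varicosities)) {
    vord <- if (scheme == "centrifugal") varicosities$order_centrifugal
    else varicosities$order_shaft
    out$n_varicosities <- vapply(os, function(o) sum(vord == o, na.rm = TRUE),
                                 numeric(1))
    out$varicosity_density <- ifelse(out$length > 0,
                                     out$n_varicosities / out$length, NA_real_)
  }
  out
}

#' Assemble the full per-cell metric table
#'
#' One row holding every per-cell metric: soma measures, stem counts, main
#' primary dendrite (the stem with the largest maximum diameter; its length
#' is the path length of its first-order segment), total dendritic length /
#' surface / volume, mean diameters, branch orders under both schemes,
#' partition asymmetry, node / ending / varicosity counts, 2D hulls of the
#' arboreal and lobular fields, the 3D hull, Euclidean distance statistics,
#' bifurcation angles and tilts, contraction, fractal dimension, and mean
#' helicity. Components whose inputs are unavailable (e.g. hulls without a
#' split depth) are reported as NA.
#'
#' @param m a \linkS4class{Morphology}.
#' @param layers optional \linkS4class{LayerModel} (defaults to metadata).
#' @param ySplit optional field-split depth; default
#'   \code{\link{autoSplitDepth}} when layers are available.
#' @param varicosities optional precomputed varicosity table.
#' @param cellId identifier stored in the first column.
#' @return one-row data.frame.
#' @export
cellSummary <- function(m, layers = NULL, ySplit = NULL, varicosities = NULL,
                        cellId = morphMetadata(m)$cell_id %||% "cell") {
  layers <- layers %||% m@metadata$layers
  sg <- decomposeSegments(m)
  df <- sg$segments
  p <- m@points
  sm <- somaMetrics(m)
  ctr <- somaCentroid(m)
  if (is.null(varicosities))
    varicosities <- detectVaricosities(m, layers = layers, segments = sg)
  ed <- euclideanDistanceStats(m, ctr)
  ba <- bifurcationAngles(sg, m)
  bt <- bifurcationTilts(sg, m)
  pa <- partitionAsymmetry(sg)
  fd <- fractalDimension(sg, m)
  hel <- helicity(sg, m)
  stems <- which(is.na(df$parent_segment))
  stemMaxDiam <- vapply(stems, function(s) {
    ids <- sg$paths[[s]][-1L]
    2 * max(p$radius[match(ids, p$id)])
  }, numeric(1))
  mainStem <- stems[which.max(stemMaxDiam)]
  hullA <- hullL <- NULL
  if (is.null(ySplit) && !is.null(layers))
    ySplit <- tryCatch(autoSplitDepth(m), error = function(e) NULL)
  if (!is.null(ySplit)) {
    fm <- tryCatch(fieldMetrics(m, ySplit), error = function(e) NULL)
    hullA <- fm$arboreal; hullL <- fm$lobular
  }
  h3 <- tryCatch(convexHull3D(cbind(p$x, p$y, p$z)), error = function(e) NULL)
  hv <- function(h, what) if (is.null(h)) NA_real_ else h[[what]]
  data.frame(
    cell_id = cellId,
    soma_volume = sm$volume,
    soma_surface_area = sm$surface_area,
    soma_projection_area = sm$projection_area,
    soma_projection_perimeter = sm$projection_perimeter,
    soma_feret_max = sm$feret_max,
    soma_feret_min = sm$feret_min,
    n_primary_dendrites = sg$n_stems,
    main_primary_length = df$path_length[mainStem],
    main_primary_max_diameter = stemMaxDiam[which.max(stemMaxDiam)],
    dendritic_length = sum(df$path_length),
    dendritic_surface_area = sum(df$surface),
    dendritic_volume = sum(df$volume),
    avg_diameter = mean(2 * p$radius),
    avg_segment_path_length = mean(df$path_length),
    max_order_shaft = max(df$order_shaft),
    max_order_centrifugal = max(df$order_centrifugal),
    avg_partition_asymmetry = pa$mean,
    n_nodes = sg$n_nodes,
    n_endings = sg$n_endings,
    n_segments = nrow(df),
    n_varicosities = nrow(varicosities),
    hull2d_area_arboreal = hv(hullA, "area"),
    hull2d_perimeter_arboreal = hv(hullA, "perimeter"),
    hull2d_feret_max_arboreal = hv(hullA, "feret_max"),
    hull2d_feret_min_arboreal = hv(hullA, "feret_min"),
    hull2d_area_lobular = hv(hullL, "area"),
    hull2d_perimeter_lobular = hv(hullL, "perimeter"),
    hull2d_feret_max_lobular = hv(hullL, "feret_max"),
    hull2d_feret_min_lobular = hv(hullL, "feret_min"),
    hull3d_volume = hv(h3, "volume"),
    hull3d_surface = hv(h3, "surface"),
    euclidean_distance_mean = ed$mean,
    euclidean_distance_max = ed$max,
    bifurcation_angle_mean = ba$mean,
    bifurcation_angle_sd = ba$sd,
    bifurcation_tilt_mean = bt$mean,
    bifurcation_tilt_sd = bt$sd,
    contraction = mean(df$contraction, na.rm = TRUE),
    fractal_dimension = fd$mean,
    helicity_mean = hel$mean,
    row.names = NULL)
}
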