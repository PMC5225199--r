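# Automated varicosity detection from reconstructed radius profiles, and the
# associated statistics.

#' Detect dendritic varicosities along radius profiles
#'
#' A varicosity is a spatially discrete swelling whose maximum diameter is at
#' least \code{ratio} times (default 1.8, i.e. a >= 80 percent increase) the
#' reference diameter immediately before and after the swelling. Candidates
#' are local diameter maxima along every root-to-tip path; the flank
#' reference on each side is the minimum diameter reached while the profile
#' keeps decreasing away from the peak, within a path-distance window capped
#' at \code{flankWindow} um. For terminal swellings (profile non-increasing
#' all the way to the tip) the distal flank requirement is waived. Adjacent
#' accepted peaks whose intervening profile never drops below the smaller
#' peak divided by \code{ratio} belong to one contiguous supra-threshold run
#' and only the larger peak is kept. The detector is scale-invariant:
#' multiplying all diameters by a constant leaves detections unchanged.
#'
#' @param m a \linkS4class{Morphology}.
#' @param ratio peak/flank diameter ratio threshold (default 1.8).
#' @param flankWindow cap on the flank search, um of path distance (default 5).
#' @param layers optional \linkS4class{LayerModel} for layer assignment.
#' @param segments optional precomputed \code{\link{decomposeSegments}} result.
#' @return data.frame: one row per varicosity with \code{point_id}, \code{x},
#'   \code{y}, \code{z}, \code{diameter}, \code{segment}, \code{order_centrifugal},
#'   \code{order_shaft}, \code{layer}, \code{terminal}.
#' @export
detectVaricosities <- function(m, ratio = 1.8, flankWindow = 5,
                               layers = NULL, segments = NULL) {
  p <- m@points
  sg <- segments %||% decomposeSegments(m)
  pidx <- match(p$parent, p$id)
  kids <- vector("list", nrow(p))
  for (i in seq_len(nrow(p)))
    if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  tips <- which(lengths(kids) == 0L & !is.na(pidx))
  # root-to-tip paths as row indices
  paths <- lapply(tips, function(tp) {
    path <- tp
    while (!is.na(pidx[path[1L]])) path <- c(pidx[path[1L]], path)
    path
  })
  hits <- new.env(parent = emptyenv())
  for (path in paths) {
    d <- 2 * p$radius[path]
    n <- length(d)
    if (n < 2L) next
    step <- sqrt(diff(p$x[path])^2 + diff(p$y[path])^2 + diff(p$z[path])^2)
    accepted <- list()
    i <- 2L
    while (i <= n) {
      leftLower  <- d[i] > d[i - 1L]
      # plateau: advance j to the end of a run of equal diameters
      j <- i
      while (j < n && d[j + 1L] == d[i]) j <- j + 1L
      rightLower <- j == n || d[j + 1L] < d[i]
      isTipPeak <- j == n
      if (leftLower && (rightLower || isTipPeak)) {
        # walk left while non-increasing away from the peak
        flankL <- Inf; dist <- 0; kk <- i
        while (kk > 1L && dist <= flankWindow && d[kk - 1L] <= d[kk]) {
          dist <- dist + step[kk - 1L]
          if (dist > flankWindow) break
          kk <- kk - 1L
          flankL <- min(flankL, d[kk])
        }
        # walk right
        flankR <- Inf; dist <- 0; kk <- j; reachedTip <- (j == n)
        while (kk < n && dist <= flankWindow && d[kk + 1L] <= d[kk]) {
          dist <- dist + step[kk]
          if (dist > flankWindow) break
          kk <- kk + 1L
          flankR <- min(flankR, d[kk])
          if (kk == n) reachedTip <- TRUE
        }
        tol <- 1 - 1e-9         # boundary-inclusive under floating point
        okL <- is.finite(flankL) && d[i] >= ratio * flankL * tol
        okR <- (is.finite(flankR) && d[i] >= ratio * flankR * tol) ||
          reachedTip
        if (okL && okR)
          accepted[[length(accepted) + 1L]] <- list(idx = i, peak = d[i])
      }
      i <- j + 1L
    }
    # merge peaks belonging to one contiguous supra-threshold run
    if (length(accepted) > 1L) {
      keep <- rep(TRUE, length(accepted))
      for (a in seq_len(length(accepted) - 1L)) {
        b <- a + 1L
        if (!keep[a]) next
        lo <- accepted[[a]]$idx; hi <- accepted[[b]]$idx
        valley <- min(d[lo:hi])
        small <- min(accepted[[a]]$peak, accepted[[b]]$peak)
        if (valley > small / ratio) {
          if (accepted[[a]]$peak >= accepted[[b]]$peak) keep[b] <- FALSE
          else keep[a] <- FALSE
        }
      }
      accepted <- accepted[keep]
    }
    for (a in accepted) {
      row <- path[a$idx]
      key <- as.character(p$id[row])
      if (is.null(hits[[key]]))
        hits[[key]] <- list(row = row, diameter = a$peak,
                            terminal = a$idx == n && path[n] == row)
    }
  }
  rows <- ls(hits)
  if (!length(rows))
    return(data.frame(point_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), diameter = numeric(0),
                      segment = integer(0), order_centrifugal = integer(0),
                      order_shaft = integer(0),
                      layer = factor(character(0), levels = layerBins()),
                      terminal = logical(0)))
  segOfPoint <- pointSegmentMap(sg, m)
  out <- do.call(rbind, lapply(rows, function(key) {
    h <- hits[[key]]
    r <- h$row
    seg <- segOfPoint[r]
    data.frame(point_id = p$id[r], x = p$x[r], y = p$y[r], z = p$z[r],
               diameter = h$diameter, segment = seg,
               order_centrifugal = sg$segments$order_centrifugal[seg],
               order_shaft = sg$segments$order_shaft[seg],
               terminal = h$terminal)
  }))
  out <- out[order(out$point_id), , drop = FALSE]
  rownames(out) <- NULL
  out$layer <- if (!is.null(layers)) annotateLayers(out$y, layers)
  else factor(rep(NA_character_, nrow(out)), levels = layerBins())
  out
}

# map point rows to owning segment; shared bifurcation/root start points
# belong to the upstream (parent) segment
pointSegmentMap <- function(sg, m) {
  p <- m@points
  owner <- rep(NA_integer_, nrow(p))
  for (k in seq_along(sg$paths)) {
    rr <- match(sg$paths[[k]], p$id)
    own <- rr[-1L]                       # exclusive ownership
    owner[own] <- k
  }
  # roots and bifurcation points: assign to the parent segment (the one they
  # terminate); roots get the first segment that starts there
  for (k in seq_along(sg$paths)) {
    rr <- match(sg$paths[[k]], p$id)
    if (is.na(owner[rr[1L]])) owner[rr[1L]] <- k
  }
  for (k in seq_along(sg$paths)) {
    endRow <- match(sg$segments$end_id[k], p$id)
    owner[endRow] <- k                   # nodes belong to the parent segment
  }
  owner
}

#' Summary statistics of a varicosity set
#'
#' Count, diameter mean / SD / range, and 3D nearest-neighbour distance
#' statistics (mean, min, max of the per-varicosity nearest distances).
#' Nearest-neighbour statistics require at least two varicosities and are
#' reported NA otherwise.
#'
#' @param v varicosity table from \code{\link{detectVaricosities}}.
#' @return list of scalars.
#' @export
varicosityStats <- function(v) {
  out <- list(count = nrow(v),
              diameter_mean = NA_real_, diameter_sd = NA_real_,
              diameter_min = NA_real_, diameter_max = NA_real_,
              nn_mean = NA_real_, nn_min = NA_real_, nn_max = NA_real_)
  if (nrow(v) == 0L) return(out)
  out$diameter_mean <- mean(v$diameter)
  out$diameter_sd <- stats::sd(v$diameter)
  out$diameter_min <- min(v$diameter)
  out$diameter_max <- max(v$diameter)
  if (nrow(v) >= 2L) {
    D <- as.matrix(stats::dist(cbind(v$x, v$y, v$z)))
    diag(D) <- Inf
    nn <- apply(D, 1L, min)
    out$nn_mean <- mean(nn)
    out$nn_min <- min(nn)
    out$nn_max <- max(nn)
  }
  out
}

#' Varicosity profiles by branch order, layer, and Sholl shell
#'
#' Per-order varicosity count, linear density (count divided by the total
#' path length of the segments of that order, in varicosities per um) and
#' mean diameter; per-layer counts and mean diameters; per-shell counts.
#' Each of the three groupings partitions the varicosity set, so the counts
#' in every table sum to the total.
#'
#' @param m a \linkS4class{Morphology}.
#' @param v varicosity table.
#' @param scheme branch-ordering scheme for the order profile.
#' @param layers optional \linkS4class{LayerModel}.
#' @param shollStep Sholl shell width in um (default 1).
#' @param segments optional precomputed segment decomposition.
#' @return list of data.frames \code{by_order}, \code{by_layer},
#'   \code{by_shell}.
#' @export
varicosityProfiles <- function(m, v, scheme = c("central_shaft", "centrifugal"),
                               layers = NULL, shollStep = 1, segments = NULL) {
  scheme <- match.arg(scheme)
  sg <- segments %||% decomposeSegments(m)
  df <- sg$segments
  ord <- if (scheme == "centrifugal") df$order_centrifugal else df$order_shaft
  vord <- if (scheme == "centrifugal") v$order_centrifugal else v$order_shaft
  os <- sort(unique(ord))
  byOrder <- data.frame(
    order = os,
    n = vapply(os, function(o) sum(vord == o), numeric(1)),
    segment_length = vapply(os, function(o) sum(df$path_length[ord == o]),
                            numeric(1)))
  byOrder$density <- ifelse(byOrder$segment_length > 0,
                            byOrder$n / byOrder$segment_length, NA_real_)
  byOrder$mean_diameter <- vapply(os, function(o) {
    dd <- v$diameter[vord == o]
    if (length(dd)) mean(dd) else NA_real_
  }, numeric(1))
  byLayer <- NULL
  if (!is.null(layers)) {
    lay <- annotateLayers(v$y, layers)
    byLayer <- data.frame(layer = layerBins(),
                          n = as.numeric(table(lay)[layerBins()]))
    byLayer$mean_diameter <- vapply(layerBins(), function(b) {
      dd <- v$diameter[lay == b]
      if (length(dd)) mean(dd) else NA_real_
    }, numeric(1))
  }
  ctr <- somaCentroid(m)
  dvc <- sqrt((v$x - ctr[1])^2 + (v$y - ctr[2])^2 + (v$z - ctr[3])^2)
  shell <- pmax(1, ceiling(dvc / shollStep))
  if (nrow(v)) {
    byShell <- data.frame(shell = sort(unique(shell)))
    byShell$radius <- byShell$shell * shollStep
    byShell$n <- vapply(byShell$shell, function(s) sum(shell == s), numeric(1))
  } else {
    byShell <- data.frame(shell = integer(0), radius = numeric(0),
                          n = numeric(0))
  }
  list(by_order = byOrder, by_layer = byLayer, by_shell = byShell)
}
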