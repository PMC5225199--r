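# Segment decomposition and branch ordering.
#
# A branch segment is the part of a branch between two nodes (bifurcation
# points) or between a node and a termination point; stems run from a tree
# root to the first node. Consequently n_segments = n_nodes + n_endings.
# A segment's point path includes its start point (the node or root it
# emanates from) so that geometry is continuous; for exclusive point
# accounting, the shared start point belongs to the upstream (parent)
# segment.

#' Decompose trees into branch segments
#'
#' @param m a \linkS4class{Morphology}.
#' @return list with
#'   \item{segments}{data.frame: one row per segment with \code{segment},
#'     \code{parent_segment} (NA for stems), \code{tree}, \code{terminal},
#'     \code{start_id}, \code{end_id}, \code{n_points}, \code{path_length},
#'     \code{euclidean}, \code{surface}, \code{volume}, \code{contraction},
#'     \code{min_diameter}, \code{first_radius}, \code{order_centrifugal},
#'     \code{order_shaft}}
#'   \item{paths}{list of integer point-id vectors, one per segment (start
#'     point included)}
#'   \item{n_nodes, n_endings, n_stems}{counts; nodes are non-root points
#'     with >= 2 children (trifurcations count as one node)}
#'   \item{node_ids, ending_ids}{point ids}
#' @export
decomposeSegments <- function(m) {
  p <- m@points
  n <- nrow(p)
  pidx <- match(p$parent, p$id)
  kids <- vector("list", n)
  for (i in seq_len(n))
    if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  nkids <- lengths(kids)
  isRoot <- is.na(pidx)
  isNode <- !isRoot & nkids >= 2L
  isEnd  <- nkids == 0L & !isRoot
  treeOf <- integer(n)
  tcount <- 0L
  segs <- list(); paths <- list()
  # stack entries: c(start row, first row of the path beyond start, parent segment)
  for (root in which(isRoot)) {
    tcount <- tcount + 1L
    stack <- lapply(kids[[root]], function(k) list(start = root, nxt = k,
                                                   parent = NA_integer_))
    while (length(stack)) {
      e <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      path <- c(e$start, e$nxt)
      cur <- e$nxt
      while (nkids[cur] == 1L && !isNode[cur]) {
        cur <- kids[[cur]][1L]
        path <- c(path, cur)
      }
      sid <- length(segs) + 1L
      segs[[sid]] <- list(path = path, parent = e$parent, tree = tcount,
                          terminal = isEnd[cur])
      if (isNode[cur])
        for (k in kids[[cur]])
          stack[[length(stack) + 1L]] <- list(start = cur, nxt = k, parent = sid)
    }
  }
  geo <- lapply(segs, function(s) {
    rows <- s$path
    xyz <- cbind(p$x[rows], p$y[rows], p$z[rows])
    g <- pathFrusta(xyz, p$radius[rows])
    eu <- vnorm(xyz[nrow(xyz), ] - xyz[1, ])
    c(g, euclidean = eu,
      contraction = if (g[["length"]] > 0) eu / g[["length"]] else NA_real_)
  })
  df <- data.frame(
    segment = seq_along(segs),
    parent_segment = vapply(segs, function(s) s$parent, integer(1)),
    tree = vapply(segs, function(s) s$tree, integer(1)),
    terminal = vapply(segs, function(s) s$terminal, logical(1)),
    start_id = vapply(segs, function(s) p$id[s$path[1L]], integer(1)),
    end_id = vapply(segs, function(s) p$id[s$path[length(s$path)]], integer(1)),
    n_points = vapply(segs, function(s) length(s$path), integer(1)),
    path_length = vapply(geo, `[[`, numeric(1), "length"),
    euclidean = vapply(geo, `[[`, numeric(1), "euclidean"),
    surface = vapply(geo, `[[`, numeric(1), "surface"),
    volume = vapply(geo, `[[`, numeric(1), "volume"),
    contraction = vapply(geo, `[[`, numeric(1), "contraction"),
    min_diameter = vapply(segs, function(s)
      2 * min(p$radius[s$path[-1L]]), numeric(1)),
    first_radius = vapply(segs, function(s)
      p$radius[s$path[2L]], numeric(1)))
  sg <- list(segments = df,
             paths = lapply(segs, function(s) p$id[s$path]),
             n_nodes = sum(isNode), n_endings = sum(isEnd),
             n_stems = sum(vapply(segs, function(s) is.na(s$parent), logical(1))),
             node_ids = p$id[isNode], ending_ids = p$id[isEnd])
  orders <- assignBranchOrders(sg, m, scheme = "both")
  sg$segments$order_centrifugal <- orders$centrifugal
  sg$segments$order_shaft <- orders$shaft
  sg
}

#' Assign branch orders to segments
#'
#' Two ordering schemes. \emph{Centrifugal}: stems are order 1 and every
#' bifurcation increments both daughters. \emph{Central shaft}: stems are
#' order 1; at each node the continuing daughter keeps the parent's order and
#' side daughters get the parent's order + 1. The continuing daughter is the
#' one with the larger radius at its first own point; ties are broken by the
#' smaller deviation angle from the parent's final direction, then by the
#' larger daughter-subtree total path length. Trifurcations are handled as a
#' single node (one continuing daughter, the rest increment).
#'
#' @param sg result of \code{\link{decomposeSegments}} (orders may be absent).
#' @param m the \linkS4class{Morphology} the segments came from.
#' @param scheme \code{"centrifugal"}, \code{"central_shaft"}, or
#'   \code{"both"}.
#' @return integer vector of per-segment orders, or a list with components
#'   \code{centrifugal} and \code{shaft} when \code{scheme = "both"}.
#' @export
assignBranchOrders <- function(sg, m, scheme = c("centrifugal",
                                                 "central_shaft", "both")) {
  scheme <- match.arg(scheme)
  df <- sg$segments
  ns <- nrow(df)
  children <- split(seq_len(ns), factor(df$parent_segment, levels = seq_len(ns)))
  cf <- integer(ns); sh <- integer(ns)
  # subtree total path length, computed bottom-up (rows are stack-ordered, so
  # sort by a DFS; simple reverse accumulation over parent pointers suffices)
  subLen <- df$path_length
  for (i in rev(seq_len(ns))) {
    pp <- df$parent_segment[i]
    if (!is.na(pp)) subLen[pp] <- subLen[pp] + subLen[i]
  }
  p <- m@points
  rowOf <- match(df$end_id, p$id)
  rowStart <- match(df$start_id, p$id)
  segDir <- function(i) {
    # direction of the final edge of segment i
    ids <- sg$paths[[i]]
    rr <- match(ids[c(length(ids) - 1L, length(ids))], p$id)
    d <- c(p$x[rr[2]] - p$x[rr[1]], p$y[rr[2]] - p$y[rr[1]],
           p$z[rr[2]] - p$z[rr[1]])
    if (vnorm(d) == 0) c(0, 0, 0) else unitVec(d)
  }
  firstDir <- function(i) {
    ids <- sg$paths[[i]]
    rr <- match(ids[c(1L, 2L)], p$id)
    d <- c(p$x[rr[2]] - p$x[rr[1]], p$y[rr[2]] - p$y[rr[1]],
           p$z[rr[2]] - p$z[rr[1]])
    if (vnorm(d) == 0) c(0, 0, 0) else unitVec(d)
  }
  ordSeq <- order(is.na(df$parent_segment), decreasing = TRUE)  # stems first
  # process in topological order over the segment tree
  done <- logical(ns)
  queue <- which(is.na(df$parent_segment))
  cf[queue] <- 1L; sh[queue] <- 1L; done[queue] <- TRUE
  while (length(queue)) {
    nxt <- integer(0)
    for (s in queue) {
      ch <- children[[s]]
      if (is.null(ch) || !length(ch)) next
      cf[ch] <- cf[s] + 1L
      # central shaft: pick the continuing daughter
      fr <- df$first_radius[ch]
      cand <- ch[fr == max(fr)]
      if (length(cand) > 1L) {
        pd <- segDir(s)
        devs <- vapply(cand, function(cc) {
          fd <- firstDir(cc)
          if (all(fd == 0) || all(pd == 0)) pi else vecAngle(pd, fd)
        }, numeric(1))
        cand <- cand[devs == min(devs)]
      }
      if (length(cand) > 1L) cand <- cand[which.max(subLen[cand])]
      cont <- cand[1L]
      sh[ch] <- sh[s] + 1L
      sh[cont] <- sh[s]
      nxt <- c(nxt, ch)
    }
    queue <- nxt
  }
  switch(scheme,
         centrifugal = cf,
         central_shaft = sh,
         both = list(centrifugal = cf, shaft = sh))
}

#' Geometry of a single segment path
#'
#' Path length, frusta lateral surface and volume, and contraction (ratio of
#' the Euclidean end-to-end distance to the path length, in (0, 1]).
#' Zero-length edges between coincident points are skipped.
#'
#' @param xyz n x 3 matrix of path coordinates (um).
#' @param r per-point radii (um).
#' @return list with \code{path_length}, \code{surface}, \code{volume},
#'   \code{contraction}.
#' @export
segmentGeometry <- function(xyz, r) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop("a segment needs at least 2 points")
  g <- pathFrusta(xyz, r)
  eu <- vnorm(xyz[nrow(xyz), ] - xyz[1, ])
  list(path_length = unname(g[["length"]]),
       surface = unname(g[["surface"]]),
       volume = unname(g[["volume"]]),
       contraction = if (g[["length"]] > 0) eu / g[["length"]] else NA_real_)
}
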