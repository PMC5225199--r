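# Stochastic generator of bistratified AII-like arbors with complete ground
# truth: inserted varicosities, per-segment branch orders under both ordering
# schemes, per-part surface areas, and (optionally) a planted density-volume
# scaling relation across a population.
#
# Growth model: a thick apical trunk descends from the soma through
# sublamina a, emitting lobular side chains in S1-S2, and branches into an
# arboreal subtree in S3-S5. Chains grow segment by segment; at each segment
# end an event is drawn: a stub bifurcation (one thick terminal daughter --
# varicose endings are thick, so the terminal daughter carries the larger
# first radius and is the central-shaft continuation), a side-chain spawn, or
# chain termination (plain ending or a tip bifurcation into two terminal
# daughters). Radii are constant within a segment and strictly decrease
# toward an asymptotic floor across bifurcations, which makes radius profiles
# monotone along every root-to-tip path; inserted varicosities are then the
# only local diameter maxima and satisfy the detection criterion with margin
# by construction.

#' Default parameters of the bistratified arbor generator
#'
#' The defaults emulate the reconstructed population: 1-9 stems, mean branch
#' segment path length near 3.2 um, node counts inside 46-311, varicosity
#' diameters in 0.39-2.7 um inserted at a rate matching roughly 125 per cell,
#' a bimodal depth profile with lobular mass in S1-S2 (peak S2) and arboreal
#' mass in S4-S5, an apical trunk of maximum diameter near 3 um, and a
#' distal/proximal surface split near 41/59 percent at the default split
#' depth of 20 um (the S2/S3 border of a 50 um IPL starting at depth 0).
#'
#' @param seed default seed used when \code{generateAII} is called without one.
#' @param ... overrides of any default listed in the function body.
#' @return named list of generator parameters.
#' @export
aiiGeneratorParams <- function(seed = 1, ...) {
  p <- list(
    seed = seed,
    # topology
    targetNodesMeanLog = log(165), targetNodesSdLog = 0.32,
    targetNodesRange = c(60, 280),
    extraStemsLambda = 2.2, maxStems = 9, lobularNodeShare = 0.18,
    backboneMinStubs = 12,            # guarantees shaft orders 1..>=13
    pStub = 0.25, pSide = 0.25, pEnd = 0.12, pTipBif = 0.90,
    # geometry
    stepLength = 0.9, meanSegmentLength = 2.9, segmentLengthSd = 1.1,
    minSegmentLength = 1.2, wander = 0.45,
    iplDepth = c(0, 50),              # INL/IPL and IPL/GCL boundaries (um)
    arborealRadius = 16, lobularRadius = 10,
    arborStartDepth = c(28, 34),      # apical trunk branches here
    lobularBand = c(10, 18), arborealBand = c(34, 49),
    maxDepthOvershoot = 3,
    # radii (um)
    rootRadius = 1.5, minRadius = 0.07,
    fApical = 0.90, fChain = 0.93, fTerminal = 0.95, fSide = 0.80,
    fApicalSide = 0.18,
    # soma
    somaRadius = 3.7, somaCenterY = -3, somaContours = 9, somaVertices = 24,
    # varicosities
    varicosityRate = 0.16,            # per um of lobular/arboreal path
    varicosityMeanLog = log(0.72), varicositySdLog = 0.30,
    varicosityRange = c(0.39, 2.7),
    lobularAppendageMeanLog = log(1.3), lobularAppendageSdLog = 0.25,
    terminalVaricosityProb = 0.6,
    insertionMargin = 2.1,            # peak >= margin x flank (criterion 1.8)
    minInsertGapPoints = 3,
    # field split
    ySplit = 20, distalFractionTarget = 41)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

# growable point store
newStore <- function(cap = 4096L) {
  env <- new.env(parent = emptyenv())
  env$x <- numeric(cap); env$y <- numeric(cap); env$z <- numeric(cap)
  env$r <- numeric(cap); env$type <- integer(cap); env$parent <- integer(cap)
  env$n <- 0L
  env
}

addPoint <- function(st, x, y, z, r, type, parentRow) {
  n <- st$n + 1L
  if (n > length(st$x)) {
    grow <- function(v) c(v, v)
    st$x <- grow(st$x); st$y <- grow(st$y); st$z <- grow(st$z)
    st$r <- grow(st$r); st$type <- grow(st$type); st$parent <- grow(st$parent)
  }
  st$x[n] <- x; st$y[n] <- y; st$z[n] <- z; st$r[n] <- r
  st$type[n] <- type
  st$parent[n] <- parentRow
  st$n <- n
  n
}

#' Generate one bistratified AII-like arbor with ground truth
#'
#' Reproducible: the same seed yields bit-identical output. The returned
#' ground truth lists every inserted varicosity, the per-segment branch
#' orders under both ordering schemes as constructed, the exact per-part
#' surface areas at the default split depth, and the topological counts.
#'
#' @param params parameter list from \code{\link{aiiGeneratorParams}}.
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @param cellId identifier stored in the metadata.
#' @return list with \code{morphology} (a \linkS4class{Morphology} whose
#'   metadata carries the \linkS4class{LayerModel}) and \code{truth}.
#' @export
generateAII <- function(params = aiiGeneratorParams(), seed = params$seed,
                        cellId = sprintf("synthetic_%d", seed)) {
  set.seed(seed)
  P <- params
  st <- newStore()
  segs <- list()          # each: rows (own points), startRow, cf, sh, kind, terminal
  nodeCount <- 0L
  targetN <- round(exp(stats::rnorm(1, P$targetNodesMeanLog, P$targetNodesSdLog)))
  targetN <- max(P$targetNodesRange[1], min(P$targetNodesRange[2], targetN))
  # reserved node budgets so both compartments always materialize
  kindBudget <- c(lobular = as.integer(round(P$lobularNodeShare * targetN)))
  kindBudget["arboreal"] <- targetN - kindBudget[["lobular"]]
  kindUsed <- c(lobular = 0L, arboreal = 0L)
  rmin <- P$minRadius
  shrink <- function(r, f) rmin + (r - rmin) * f

  soma <- sphericalSoma(R = P$somaRadius, center = c(0, P$somaCenterY, 0),
                        nContours = P$somaContours,
                        nVertices = P$somaVertices)

  stepTo <- function(pos, dir, band, radial, n, straightness = P$wander) {
    # n wandering unit steps biased toward the depth band and inward when
    # outside the lateral radius; returns matrix of positions
    out <- matrix(0, n, 3)
    for (q in seq_len(n)) {
      w <- stats::rnorm(3, 0, straightness)
      pull <- c(0, 0, 0)
      if (pos[2] < band[1]) pull[2] <- 0.5
      if (pos[2] > band[2]) pull[2] <- -0.5
      rad <- sqrt(pos[1]^2 + pos[3]^2)
      if (rad > radial) {
        pull[1] <- pull[1] - 0.8 * pos[1] / rad
        pull[3] <- pull[3] - 0.8 * pos[3] / rad
      }
      dir <- unitVec(dir + w + pull)
      pos <- pos + P$stepLength * dir
      out[q, ] <- pos
    }
    attr(out, "dir") <- dir
    out
  }

  emitSegment <- function(fromRow, dir, r, type, band, radial, lenOverride = NULL,
                          straightness = P$wander) {
    segLen <- lenOverride %||%
      max(P$minSegmentLength, stats::rnorm(1, P$meanSegmentLength, P$segmentLengthSd))
    nsteps <- max(2L, as.integer(round(segLen / P$stepLength)))
    pos <- c(st$x[fromRow], st$y[fromRow], st$z[fromRow])
    path <- stepTo(pos, dir, band, radial, nsteps, straightness = straightness)
    rows <- integer(nsteps)
    prev <- fromRow
    for (q in seq_len(nsteps)) {
      prev <- addPoint(st, path[q, 1], path[q, 2], path[q, 3], r, type, prev)
      rows[q] <- prev
    }
    list(rows = rows, dir = attr(path, "dir"))
  }

  # chain growth; returns nothing, appends to segs
  stack <- list()
  pushChain <- function(fromRow, dir, r, cf, sh, kind, minStubs = 0L,
                        maxSegs = 30L)
    stack[[length(stack) + 1L]] <<- list(fromRow = fromRow, dir = dir, r = r,
                                         cf = cf, sh = sh, kind = kind,
                                         minStubs = minStubs, maxSegs = maxSegs)
  bandOf <- function(kind) if (kind == "lobular") P$lobularBand else P$arborealBand
  radialOf <- function(kind) if (kind == "lobular") P$lobularRadius else P$arborealRadius

  runChain <- function(ch) {
    fromRow <- ch$fromRow; dir <- ch$dir; r <- ch$r
    cf <- ch$cf; sh <- ch$sh
    minStubs <- ch$minStubs
    typ <- if (ch$kind == "lobular") 3L else 4L
    for (si in seq_len(ch$maxSegs)) {
      sg <- emitSegment(fromRow, dir, r, typ, bandOf(ch$kind), radialOf(ch$kind))
      fromRow <- sg$rows[length(sg$rows)]
      dir <- sg$dir
      budget <- kindBudget[[ch$kind]] - kindUsed[[ch$kind]]
      ev <- if (minStubs > 0L && budget > 0L) "stub"
      else if (budget <= 0L || si == ch$maxSegs) "end"
      else sample(c("stub", "side", "end", "continue"), 1L,
                  prob = c(P$pStub, P$pSide, P$pEnd,
                           max(0, 1 - P$pStub - P$pSide - P$pEnd)))
      if (ev == "continue") {
        segs[[length(segs) + 1L]] <<- list(rows = sg$rows, cf = cf, sh = sh,
                                           kind = ch$kind, terminal = FALSE,
                                           continues = TRUE)
        next
      }
      if (ev == "stub") {
        minStubs <- minStubs - 1L
        nodeCount <<- nodeCount + 1L
        kindUsed[ch$kind] <<- kindUsed[ch$kind] + 1L
        segs[[length(segs) + 1L]] <<- list(rows = sg$rows, cf = cf, sh = sh,
                                           kind = ch$kind, terminal = FALSE)
        # thick terminal daughter keeps the shaft order
        rT <- shrink(r, P$fTerminal)
        dT <- unitVec(dir + stats::rnorm(3, 0, 1.0))
        tg <- emitSegment(fromRow, dT, rT, typ, bandOf(ch$kind),
                          radialOf(ch$kind),
                          lenOverride = stats::runif(1, 1.5, 3))
        segs[[length(segs) + 1L]] <<- list(rows = tg$rows, cf = cf + 1L,
                                           sh = sh, kind = ch$kind,
                                           terminal = TRUE)
        r <- shrink(r, P$fChain)
        cf <- cf + 1L
        sh <- sh + 1L
        next
      }
      if (ev == "side") {
        nodeCount <<- nodeCount + 1L
        kindUsed[ch$kind] <<- kindUsed[ch$kind] + 1L
        segs[[length(segs) + 1L]] <<- list(rows = sg$rows, cf = cf, sh = sh,
                                           kind = ch$kind, terminal = FALSE)
        dS <- unitVec(dir + stats::rnorm(3, 0, 1.2))
        pushChain(fromRow, dS, shrink(r, P$fSide), cf + 1L, sh + 1L, ch$kind,
                  maxSegs = 12L)
        r <- shrink(r, P$fChain)
        cf <- cf + 1L
        next
      }
      # ev == "end": either a tip bifurcation or a plain termination
      if (budget > 0L && stats::runif(1) < P$pTipBif) {
        nodeCount <<- nodeCount + 1L
        kindUsed[ch$kind] <<- kindUsed[ch$kind] + 1L
        segs[[length(segs) + 1L]] <<- list(rows = sg$rows, cf = cf, sh = sh,
                                           kind = ch$kind, terminal = FALSE)
        r1 <- shrink(r, P$fTerminal)
        r2 <- shrink(r, P$fChain)
        for (tb in 1:2) {
          dT <- unitVec(dir + stats::rnorm(3, 0, 1.0))
          tg <- emitSegment(fromRow, dT, if (tb == 1) r1 else r2, typ,
                            bandOf(ch$kind), radialOf(ch$kind),
                            lenOverride = stats::runif(1, 1.5, 3.5))
          segs[[length(segs) + 1L]] <<- list(rows = tg$rows, cf = cf + 1L,
                                             sh = if (tb == 1) sh else sh + 1L,
                                             kind = ch$kind, terminal = TRUE)
        }
      } else {
        segs[[length(segs) + 1L]] <<- list(rows = sg$rows, cf = cf, sh = sh,
                                           kind = ch$kind, terminal = TRUE)
      }
      return(invisible(NULL))
    }
  }

  # ---- apical trunk -----------------------------------------------------
  root <- addPoint(st, 0, 0.4, 0, P$rootRadius, 2L, -1L)
  arborStart <- stats::runif(1, P$arborStartDepth[1], P$arborStartDepth[2])
  rAp <- P$rootRadius
  cfAp <- 1L
  fromRow <- root
  dir <- c(0, 1, 0)
  apicalRows <- integer(0)
  repeat {
    sg <- emitSegment(fromRow, dir, rAp, 2L, c(0, arborStart), Inf,
                      lenOverride = stats::runif(1, 3, 6), straightness = 0.12)
    # keep the trunk nearly vertical
    dir <- unitVec(attr(stepTo(c(0, 0, 0), c(0, 1, 0), c(0, 50), Inf, 1L,
                               straightness = 0.1), "dir"))
    fromRow <- sg$rows[length(sg$rows)]
    yNow <- st$y[fromRow]
    if (yNow >= arborStart) {
      # trunk ends: branch into two arboreal chains; the thicker daughter is
      # the central-shaft continuation (order 1 backbone)
      nodeCount <- nodeCount + 1L
      kindUsed["arboreal"] <- kindUsed[["arboreal"]] + 1L
      segs[[length(segs) + 1L]] <- list(rows = sg$rows, cf = cfAp, sh = 1L,
                                        kind = "apical", terminal = FALSE)
      rB <- min(0.35, shrink(rAp, 0.85))
      rS <- min(0.28, shrink(rAp, 0.70))
      pushChain(fromRow, unitVec(c(stats::rnorm(1, 0, 0.6), 0.8,
                                   stats::rnorm(1, 0, 0.6))),
                rB, cfAp + 1L, 1L, "arboreal",
                minStubs = P$backboneMinStubs, maxSegs = 60L)
      pushChain(fromRow, unitVec(c(stats::rnorm(1, 0, 0.9), 0.6,
                                   stats::rnorm(1, 0, 0.9))),
                rS, cfAp + 1L, 2L, "arboreal", minStubs = 3L,
                maxSegs = 40L)
      break
    }
    # side spawn from the trunk: lobular in sublamina a, arboreal deeper
    nodeCount <- nodeCount + 1L
    kindUsed["arboreal"] <- kindUsed[["arboreal"]] + 1L
    segs[[length(segs) + 1L]] <- list(rows = sg$rows, cf = cfAp, sh = 1L,
                                      kind = "apical", terminal = FALSE)
    sideKind <- if (yNow < P$lobularBand[2]) "lobular" else "arboreal"
    az <- stats::runif(1, 0, 2 * pi)
    dS <- unitVec(c(cos(az), stats::rnorm(1, 0.1, 0.3), sin(az)))
    if (sideKind == "lobular" && stats::runif(1) < 0.45) {
      # short varicose branchlet instead of a full lobular chain
      tg <- emitSegment(fromRow, dS, shrink(rAp, P$fApicalSide), 3L,
                        P$lobularBand, P$lobularRadius,
                        lenOverride = stats::runif(1, 2, 4))
      segs[[length(segs) + 1L]] <- list(rows = tg$rows, cf = cfAp + 1L,
                                        sh = 2L, kind = "lobular",
                                        terminal = TRUE)
    } else {
      pushChain(fromRow, dS, shrink(rAp, P$fApicalSide), cfAp + 1L, 2L,
                sideKind, maxSegs = if (sideKind == "lobular") 6L else 10L)
    }
    rAp <- shrink(rAp, P$fApical)
    cfAp <- cfAp + 1L
  }

  # ---- extra stems (lobular dendrites arising from the soma) -----------
  nExtra <- min(P$maxStems - 1L, stats::rpois(1, P$extraStemsLambda))
  for (s in seq_len(nExtra)) {
    az <- stats::runif(1, 0, 2 * pi)
    sx <- P$somaRadius * 0.95 * cos(az)
    sz <- P$somaRadius * 0.95 * sin(az)
    sRoot <- addPoint(st, sx, P$somaCenterY + 1.5, sz, 0.32, 3L, -1L)
    dS <- unitVec(c(cos(az), 0.55, sin(az)))
    pushChain(sRoot, dS, 0.28, 1L, 1L, "lobular", maxSegs = 5L)
  }

  # ---- run all pending chains ------------------------------------------
  # arboreal chains (backbone first) get the node budget before lobular
  # chains, so the deep arboreal orders are guaranteed and the lobular mass
  # stays a modest share of the arbor
  while (length(stack)) {
    kinds <- vapply(stack, `[[`, character(1), "kind")
    pick <- if (any(kinds == "arboreal")) which(kinds == "arboreal")[1L] else 1L
    ch <- stack[[pick]]
    stack[[pick]] <- NULL
    runChain(ch)
  }

  # merge consecutive "continues" records with the following segment record:
  # a continue event draws no node, so the two pieces form one segment
  merged <- list()
  pending <- NULL
  for (sgr in segs) {
    if (!is.null(pending)) {
      sgr$rows <- c(pending$rows, sgr$rows)
      pending <- NULL
    }
    if (isTRUE(sgr$continues)) pending <- sgr
    else merged[[length(merged) + 1L]] <- sgr
  }
  if (!is.null(pending)) {   # chain exhausted maxSegs right after a continue
    pending$terminal <- TRUE
    pending$continues <- NULL
    merged[[length(merged) + 1L]] <- pending
  }
  segs <- merged

  # ---- varicosity insertion --------------------------------------------
  vrows <- integer(0); vdiam <- numeric(0); vterm <- logical(0)
  vkind <- character(0)
  drawDiam <- function(kind, terminal) {
    if (kind == "lobular" && terminal)
      d <- exp(stats::rnorm(1, P$lobularAppendageMeanLog, P$lobularAppendageSdLog))
    else
      d <- exp(stats::rnorm(1, P$varicosityMeanLog, P$varicositySdLog))
    max(P$varicosityRange[1], min(P$varicosityRange[2], d))
  }
  for (k in seq_along(segs)) {
    sgr <- segs[[k]]
    if (sgr$kind == "apical") next
    rows <- sgr$rows
    np <- length(rows)
    base <- 2 * st$r[rows[1L]]
    floorPeak <- P$insertionMargin * base
    if (floorPeak > P$varicosityRange[2]) next
    segLenUm <- np * P$stepLength
    taken <- integer(0)
    if (sgr$terminal && stats::runif(1) < P$terminalVaricosityProb) {
      d <- max(drawDiam(sgr$kind, TRUE), floorPeak)
      st$r[rows[np]] <- d / 2
      vrows <- c(vrows, rows[np]); vdiam <- c(vdiam, d)
      vterm <- c(vterm, TRUE); vkind <- c(vkind, sgr$kind)
      taken <- np
    }
    nIns <- stats::rpois(1, P$varicosityRate * segLenUm)
    if (nIns > 0 && np >= 4L) {
      elig <- setdiff(2:(np - 1L), unlist(lapply(taken, function(tk)
        (tk - P$minInsertGapPoints):(tk + P$minInsertGapPoints))))
      for (q in seq_len(nIns)) {
        if (!length(elig)) break
        pos <- if (length(elig) == 1L) elig else sample(elig, 1L)
        d <- max(drawDiam(sgr$kind, FALSE), floorPeak)
        st$r[rows[pos]] <- d / 2
        vrows <- c(vrows, rows[pos]); vdiam <- c(vdiam, d)
        vterm <- c(vterm, FALSE); vkind <- c(vkind, sgr$kind)
        elig <- setdiff(elig, (pos - P$minInsertGapPoints):(pos + P$minInsertGapPoints))
      }
    }
  }

  # ---- assemble ---------------------------------------------------------
  n <- st$n
  pts <- data.frame(id = seq_len(n), type = st$type[seq_len(n)],
                    x = st$x[seq_len(n)], y = st$y[seq_len(n)],
                    z = st$z[seq_len(n)], radius = st$r[seq_len(n)],
                    parent = st$parent[seq_len(n)])
  layers <- LayerModel(P$iplDepth[1], P$iplDepth[2])
  m <- Morphology(pts, soma = soma,
                  metadata = list(cell_id = cellId, seed = seed,
                                  generator = "generateAII", layers = layers))

  # ground truth per-part surface areas at the default split depth
  areas <- c(distal = 0, proximal = 0)
  for (i in seq_len(n)) {
    pr <- pts$parent[i]
    if (pr == -1L) next
    a <- c(pts$x[pr], pts$y[pr], pts$z[pr])
    b <- c(pts$x[i], pts$y[i], pts$z[i])
    L <- vnorm(b - a)
    if (L == 0) next
    r1 <- pts$radius[pr]; r2 <- pts$radius[i]
    y1 <- a[2]; y2 <- b[2]
    if ((y1 - P$ySplit) * (y2 - P$ySplit) < 0) {
      t <- (P$ySplit - y1) / (y2 - y1)
      rmid <- r1 + t * (r2 - r1)
      s1 <- if (y1 <= P$ySplit) "distal" else "proximal"
      s2 <- if (y2 <= P$ySplit) "distal" else "proximal"
      areas[s1] <- areas[s1] + frustumLateral(r1, rmid, L * t)
      areas[s2] <- areas[s2] + frustumLateral(rmid, r2, L * (1 - t))
    } else {
      s <- if ((y1 + y2) / 2 <= P$ySplit) "distal" else "proximal"
      areas[s] <- areas[s] + frustumLateral(r1, r2, L)
    }
  }
  somaSurf <- somaMetrics(soma)$surface_area
  areas["distal"] <- areas["distal"] + somaSurf
  truthOrders <- data.frame(
    end_id = vapply(segs, function(s) s$rows[length(s$rows)], integer(1)),
    order_centrifugal = vapply(segs, function(s) s$cf, integer(1)),
    order_shaft = vapply(segs, function(s) s$sh, integer(1)),
    kind = vapply(segs, function(s) s$kind, character(1)),
    terminal = vapply(segs, function(s) s$terminal, logical(1)))
  truth <- list(
    seed = seed, cell_id = cellId, target_nodes = targetN,
    n_nodes = nodeCount,
    n_stems = 1L + nExtra,
    varicosities = data.frame(point_id = vrows,
                              x = pts$x[vrows], y = pts$y[vrows],
                              z = pts$z[vrows], diameter = vdiam,
                              terminal = vterm, kind = vkind),
    n_varicosities = length(vrows),
    segment_orders = truthOrders,
    y_split = P$ySplit,
    distal_area = unname(areas["distal"]),
    proximal_area = unname(areas["proximal"]),
    soma_surface = somaSurf)
  truth$distal_fraction <- 100 * truth$distal_area /
    (truth$distal_area + truth$proximal_area)
  list(morphology = m, truth = truth)
}

#' Generate a population of synthetic arbors
#'
#' Cell sizes are spread laterally so that territory (3D hull) volumes cover
#' roughly a tenfold range. With \code{plantScaling}, total dendritic length
#' is adjusted (by extending terminal branches with interior meander, which
#' changes neither the topology nor the hull appreciably) so that the
#' population follows log10(density) = intercept + slope * log10(volume)
#' with lognormal scatter \code{sdLog10}; the planted relation is recorded in
#' each cell's ground truth.
#'
#' @param n number of cells (at least 2).
#' @param seed population seed; cell i uses seed * 1000 + i.
#' @param params generator parameters.
#' @param plantScaling optional list with \code{slope}, \code{intercept},
#'   \code{sdLog10} (defaults -0.37, 0.26, 0.015).
#' @return list of \code{generateAII} results.
#' @export
generatePopulation <- function(n, seed = 1, params = aiiGeneratorParams(),
                               plantScaling = NULL) {
  if (n < 2L) stop("a population needs at least 2 cells")
  if (!is.null(plantScaling)) {
    plantScaling$slope <- plantScaling$slope %||% -0.37
    plantScaling$intercept <- plantScaling$intercept %||% 0.26
    plantScaling$sdLog10 <- plantScaling$sdLog10 %||% 0.015
  }
  set.seed(seed)
  u <- stats::runif(n, -0.5, 0.5)        # ~10x volume spread (lateral scale)
  lapply(seq_len(n), function(i) {
    sc <- 10^(u[i] / 2)
    pi_ <- params
    pi_$arborealRadius <- params$arborealRadius * sc
    pi_$lobularRadius <- params$lobularRadius * sc
    # node budget scales with lateral area so density stays plausible; the
    # planted mode grows lean and lets the extension pass set the final length
    if (is.null(plantScaling)) {
      pi_$targetNodesMeanLog <- params$targetNodesMeanLog + log(sc^1.3)
    } else {
      pi_$targetNodesMeanLog <- params$targetNodesMeanLog + log(sc^1.3) - 0.55
      pi_$targetNodesSdLog <- 0.08   # controlled base size; extensions set L
      pi_$targetNodesRange <- c(30, 280)
    }
    cellSeed <- seed * 1000 + i
    if (is.null(plantScaling))
      return(generateAII(pi_, seed = cellSeed,
                         cellId = sprintf("synthetic_%d_%d", seed, i)))
    # planted mode: the base cell must come out shorter than the planted
    # length (length can only be added, not removed), so shrink the node
    # budget and regenerate when it overshoots
    for (attempt in 1:3) {
      g <- generateAII(pi_, seed = cellSeed + (attempt - 1L) * 101L,
                       cellId = sprintf("synthetic_%d_%d", seed, i))
      pp <- g$morphology@points
      V <- convexHull3D(cbind(pp$x, pp$y, pp$z))$volume
      L0 <- sum(decomposeSegments(g$morphology)$segments$path_length)
      set.seed(cellSeed + 500000L)
      eps <- stats::rnorm(1, 0, plantScaling$sdLog10)
      targetL <- 10^(plantScaling$intercept + eps +
                       (1 + plantScaling$slope) * log10(V))
      if (L0 <= 0.95 * targetL || attempt == 3) break
      pi_$targetNodesMeanLog <- pi_$targetNodesMeanLog +
        log(max(0.4, 0.75 * targetL / L0))
    }
    plantScalingTarget(g, plantScaling, cellSeed)
  })
}

# extend terminal branches with bounded meander until the total dendritic
# length matches the planted density-volume relation for the measured hull
plantScalingTarget <- function(g, plant, cellSeed) {
  set.seed(cellSeed + 500000L)
  eps <- stats::rnorm(1, 0, plant$sdLog10)
  # the hull can grow slightly while branches are extended, so re-measure and
  # top up until length and (current) territory volume sit on the planted line
  for (iter in 1:3) {
    g <- plantScalingPass(g, plant, eps)
    if (isTRUE(attr(g, "converged"))) break
  }
  V <- attr(g, "volume"); targetL <- attr(g, "target_length")
  g$truth$planted_scaling <- plant
  g$truth$hull_volume_at_plant <- V
  g$truth$target_length <- targetL
  g
}

plantScalingPass <- function(g, plant, eps) {
  m <- g$morphology
  p <- m@points
  hull <- convexHull3D(cbind(p$x, p$y, p$z))
  V <- hull$volume
  targetL <- 10^(plant$intercept + eps + (1 + plant$slope) * log10(V))
  sg <- decomposeSegments(m)
  L0 <- sum(sg$segments$path_length)
  add <- targetL - L0
  attr(g, "volume") <- V
  attr(g, "target_length") <- targetL
  if (add <= 1) {
    attr(g, "converged") <- TRUE
    return(g)
  }
  if (TRUE) {
    tips <- sg$segments[sg$segments$terminal, , drop = FALSE]
    tipIds <- tips$end_id
    if (length(tipIds) > 1L) tipIds <- sample(tipIds)
    per <- add / length(tipIds)
    ctrY <- mean(range(p$y))
    maxRad <- 0.7 * max(sqrt(p$x^2 + p$z^2))
    step <- 0.9
    nextId <- max(p$id)
    newRows <- list()
    for (tid in tipIds) {
      i <- match(tid, p$id)
      pos <- c(p$x[i], p$y[i], p$z[i])
      rr <- p$radius[i]
      # continue at the flank radius so the extension cannot create or mask
      # a diameter maximum (terminal varicosity peaks stay peaks)
      seg0 <- sg$segments[sg$segments$end_id == tid, ]
      firstRow <- match(sg$paths[[seg0$segment]][2L], p$id)
      rr <- min(rr, p$radius[firstRow])
      # aim the meander at an interior anchor so the extension loops inside
      # the existing territory instead of inflating the hull
      anchor <- c(0, min(max(pos[2], 30), 44), 0)
      dir <- unitVec(anchor - pos + stats::rnorm(3, 0, 2))
      remaining <- per
      parentId <- tid
      while (remaining > 1e-9) {
        h <- min(step, remaining)
        w <- stats::rnorm(3, 0, 0.5)
        toAnchor <- anchor - pos
        dist <- vnorm(toAnchor)
        pull <- if (dist > 0) 0.6 * toAnchor / dist else c(0, 0, 0)
        if (dist < 4) anchor <- c(stats::runif(1, -0.4, 0.4) * maxRad,
                                  stats::runif(1, 32, 44),
                                  stats::runif(1, -0.4, 0.4) * maxRad)
        dir <- unitVec(dir + w + pull)
        pos <- pos + h * dir
        nextId <- nextId + 1L
        newRows[[length(newRows) + 1L]] <-
          data.frame(id = nextId, type = p$type[i], x = pos[1], y = pos[2],
                     z = pos[3], radius = rr, parent = parentId)
        parentId <- nextId
        remaining <- remaining - h
      }
    }
    p2 <- rbind(p[, c("id", "type", "x", "y", "z", "radius", "parent")],
                do.call(rbind, newRows))
    g$morphology <- Morphology(p2, soma = m@soma, metadata = m@metadata)
    # formerly terminal varicosity peaks now sit mid-branch (extensions
    # continue at the flank radius, so the peaks remain valid detections)
    old <- g$truth$varicosities$point_id %in% tipIds &
      g$truth$varicosities$terminal
    g$truth$varicosities$terminal[old] <- FALSE
    g$truth$segment_orders <- NULL   # end ids changed; orders not re-derived
  }
  attr(g, "converged") <- FALSE
  g
}
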