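#' @import methods
NULL

# -- Morphology ---------------------------------------------------------------

#' Annotated single-neuron reconstruction
#'
#' A \code{Morphology} holds one reconstructed neuron: a table of
#' reconstruction points forming one or more rooted trees (SWC convention:
#' each point has an id, a parent id of -1 for a root, coordinates and a
#' radius in micrometers), an optional soma contour stack, and free-form
#' metadata (cell id, dye, pixel sizes, a \code{LayerModel}, ...).
#'
#' Coordinate convention: \code{x} is the lateral slice axis, \code{y} is
#' retinal depth increasing from the inner nuclear layer (INL) toward the
#' ganglion cell layer (GCL), and \code{z} is the optical axis. Soma contours
#' are closed polygons traced in the XY plane at a series of focal depths
#' along z, mirroring contour tracing at successive focal planes.
#'
#' @slot points data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent}, \code{label}; rows in
#'   topological order (parents precede children).
#' @slot soma list of contours; each contour is a list with scalar \code{z}
#'   (focal depth) and equal-length numeric vectors \code{x}, \code{y}
#'   (polygon vertices, at least 3, not closed explicitly).
#' @slot metadata named list.
#'
#' @aliases Morphology-class
#' @exportClass Morphology
setClass("Morphology",
         representation(points = "data.frame", soma = "list",
                        metadata = "list"))

setValidity("Morphology", function(object) {
  p <- object@points
  need <- c("id", "type", "x", "y", "z", "radius", "parent", "label")
  if (!all(need %in% names(p)))
    return(paste("points must contain columns:", paste(need, collapse = ", ")))
  for (ct in object@soma) {
    if (!all(c("z", "x", "y") %in% names(ct)))
      return("each soma contour needs z, x, y")
    if (length(ct$x) < 3L || length(ct$x) != length(ct$y))
      return("soma contours need at least 3 (x, y) vertex pairs")
  }
  TRUE
})

#' Construct a Morphology
#'
#' Builds a \linkS4class{Morphology} from an SWC-style point table. Points are
#' re-ordered topologically so every parent precedes its children; radii must
#' be strictly positive and every non-root parent id must exist.
#'
#' @param points data.frame with columns \code{id, type, x, y, z, radius,
#'   parent} (and optionally \code{label}).
#' @param soma list of soma contours (see \linkS4class{Morphology}).
#' @param metadata named list.
#' @return A \linkS4class{Morphology}.
#' @export
Morphology <- function(points, soma = list(), metadata = list()) {
  points <- as.data.frame(points)
  if (!"label" %in% names(points))
    points$label <- labelFromType(points$type)
  if (any(!is.finite(points$radius)) || any(points$radius <= 0))
    stop("validation error: all radii must be strictly positive")
  miss <- setdiff(points$parent[points$parent != -1L], points$id)
  if (length(miss))
    stop("parse error: parent id(s) not present: ", paste(miss, collapse = ", "))
  if (anyDuplicated(points$id))
    stop("parse error: duplicate point ids")
  points <- topoSortPoints(points)
  new("Morphology", points = points, soma = soma, metadata = metadata)
}

# order rows so parents precede children; detects cycles
topoSortPoints <- function(points, on_cycle = c("error", "keep")) {
  on_cycle <- match.arg(on_cycle)
  n <- nrow(points)
  pidx <- match(points$parent, points$id)  # row index of parent; NA for roots
  kids <- vector("list", n)
  for (i in seq_len(n))
    if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  placed <- logical(n)
  frontier <- which(is.na(pidx))
  placed[frontier] <- TRUE
  order_out <- frontier
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    nxt <- nxt[!placed[nxt]]
    placed[nxt] <- TRUE
    order_out <- c(order_out, nxt)
    frontier <- nxt
  }
  if (length(order_out) < n) {
    if (on_cycle == "error")
      stop("parse error: cycle or unreachable points in parent structure")
    order_out <- c(order_out, setdiff(seq_len(n), order_out))
  }
  rownames(points) <- NULL
  points[order_out, , drop = FALSE]
}

labelFromType <- function(type) {
  lab <- rep("unspecified", length(type))
  lab[type == 1L] <- "soma"
  lab[type == 2L] <- "apical"
  lab[type == 3L] <- "lobular"
  lab[type == 4L] <- "arboreal"
  lab
}

typeFromLabel <- function(label) {
  code <- rep(0L, length(label))
  code[label == "soma"] <- 1L
  code[label == "apical"] <- 2L
  code[label == "lobular"] <- 3L
  code[label == "arboreal"] <- 4L
  code
}

#' @describeIn Morphology point table accessor
#' @param m,object a \code{Morphology}
#' @export
morphPoints <- function(m) m@points

#' @describeIn Morphology soma contour accessor
#' @export
somaContours <- function(m) m@soma

#' @describeIn Morphology metadata accessor
#' @export
morphMetadata <- function(m) m@metadata

#' @describeIn Morphology number of reconstruction points
#' @export
nPoints <- function(m) nrow(m@points)

#' @describeIn Morphology number of rooted trees
#' @export
nTrees <- function(m) sum(m@points$parent == -1L)

setMethod("show", "Morphology", function(object) {
  p <- object@points
  cat("Morphology:", nrow(p), "points,", sum(p$parent == -1L), "tree(s),",
      length(object@soma), "soma contour(s)\n")
  if (nrow(p)) {
    cat(sprintf("  extent x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] um\n",
                min(p$x), max(p$x), min(p$y), max(p$y), min(p$z), max(p$z)))
    cat(sprintf("  radii [%.3f, %.3f] um\n", min(p$radius), max(p$radius)))
  }
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})

# -- LayerModel ---------------------------------------------------------------

#' Retinal layer model
#'
#' Two boundary depths delimit the inner plexiform layer (IPL): the INL/IPL
#' border and the IPL/GCL border. The IPL is divided into five equally thick
#' strata S1..S5, with S1 adjacent to the INL. Depth increases from INL toward
#' GCL when \code{yIplGcl > yInlIpl} and decreases otherwise.
#'
#' @slot yInlIpl depth of the INL/IPL boundary (um)
#' @slot yIplGcl depth of the IPL/GCL boundary (um)
#' @aliases LayerModel-class
#' @exportClass LayerModel
setClass("LayerModel",
         representation(yInlIpl = "numeric", yIplGcl = "numeric"))

setValidity("LayerModel", function(object) {
  if (length(object@yInlIpl) != 1L || length(object@yIplGcl) != 1L)
    return("boundaries must be scalars")
  if (!is.finite(object@yInlIpl) || !is.finite(object@yIplGcl))
    return("boundaries must be finite")
  if (object@yInlIpl == object@yIplGcl)
    return("degenerate layer model: boundaries are equal")
  TRUE
})

#' Construct a LayerModel
#' @param yInlIpl,yIplGcl boundary depths in um (must differ)
#' @return A \linkS4class{LayerModel}
#' @export
LayerModel <- function(yInlIpl, yIplGcl)
  new("LayerModel", yInlIpl = as.numeric(yInlIpl), yIplGcl = as.numeric(yIplGcl))

setMethod("show", "LayerModel", function(object) {
  cat(sprintf("LayerModel: INL/IPL at y = %.2f, IPL/GCL at y = %.2f um (S1..S5 equal strata)\n",
              object@yInlIpl, object@yIplGcl))
  invisible(NULL)
})

#' Layer bin names in anatomical order
#' @export
layerBins <- function() c("INL", "S1", "S2", "S3", "S4", "S5", "GCL")
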