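# SWC + annotation-sidecar I/O.
#
# SWC: standard 7 columns (id, type, x, y, z, radius, parent), 1-based ids,
# micrometers, '#' comments. Sidecar: JSON with layer boundaries and soma
# contour vertex lists. Writers emit UTF-8 with LF endings and full double
# precision so a write -> read round trip is bit-exact.

#' Read an SWC reconstruction file
#'
#' @param path path to an SWC file.
#' @return data.frame with columns \code{id, type, x, y, z, radius, parent}.
#' @export
readSWC <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"),
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  if (nrow(raw) == 0L) stop("parse error: empty SWC file: ", path)
  raw
}

#' Read a reconstruction with optional annotation sidecar
#'
#' The sidecar is a JSON file that may contain \code{layers} (fields
#' \code{y_inl_ipl}, \code{y_ipl_gcl}) and \code{soma} (list of contours with
#' scalar \code{z} and vertex vectors \code{x}, \code{y}). Layer information
#' is stored in the metadata as a \linkS4class{LayerModel}.
#'
#' @param swcPath path to the SWC file.
#' @param annotationPath optional path to the JSON sidecar.
#' @return A \linkS4class{Morphology}.
#' @export
readMorphology <- function(swcPath, annotationPath = NULL) {
  pts <- readSWC(swcPath)
  soma <- list()
  meta <- list(source = swcPath)
  if (!is.null(annotationPath)) {
    ann <- jsonlite::read_json(annotationPath, simplifyVector = TRUE)
    if (!is.null(ann$layers))
      meta$layers <- LayerModel(ann$layers$y_inl_ipl, ann$layers$y_ipl_gcl)
    if (!is.null(ann$soma)) {
      pick <- function(v, i) if (is.matrix(v)) as.numeric(v[i, ])
      else as.numeric(v[[i]])
      zs <- unlist(ann$soma$z)
      soma <- lapply(seq_along(zs), function(i)
        list(z = zs[[i]], x = pick(ann$soma$x, i), y = pick(ann$soma$y, i)))
      soma <- soma[order(vapply(soma, `[[`, numeric(1), "z"))]
    }
    if (!is.null(ann$metadata)) meta <- c(meta, ann$metadata)
  }
  Morphology(pts, soma = soma, metadata = meta)
}

#' Write a point table or Morphology to SWC
#'
#' Coordinates and radii are written with 17 significant digits so that
#' reading the file back reproduces the doubles bit-exactly.
#'
#' @param m a \linkS4class{Morphology} or an SWC-style data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSWC <- function(m, path) {
  p <- if (is(m, "Morphology")) m@points else m
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con, sep = "\n")
  writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                     p$id, p$type, p$x, p$y, p$z, p$radius, p$parent),
             con, sep = "\n")
  invisible(path)
}

#' Write the annotation sidecar (layers + soma contours) as JSON
#'
#' @param m a \linkS4class{Morphology}.
#' @param path output path.
#' @param layers optional \linkS4class{LayerModel}; defaults to
#'   \code{morphMetadata(m)$layers}.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(m, path, layers = NULL) {
  layers <- layers %||% m@metadata$layers
  out <- list()
  if (!is.null(layers))
    out$layers <- list(y_inl_ipl = layers@yInlIpl, y_ipl_gcl = layers@yIplGcl)
  if (length(m@soma))
    out$soma <- list(z = lapply(m@soma, `[[`, "z"),
                     x = lapply(m@soma, `[[`, "x"),
                     y = lapply(m@soma, `[[`, "y"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a reconstruction and report structural issues
#'
#' Reporting operation: never errors. Flags non-positive radii, trees whose
#' root lies farther than \code{somaAttachTol} from every soma contour
#' (detached trees), cycles in the parent structure, and points with multiple
#' roots inside one connected component.
#'
#' @param m a \linkS4class{Morphology}.
#' @param somaAttachTol attachment tolerance in um (default 2).
#' @return data.frame with columns \code{issue}, \code{id}, \code{detail};
#'   zero rows when the reconstruction is clean.
#' @export
validateMorphology <- function(m, somaAttachTol = 2) {
  p <- m@points
  issues <- list()
  add <- function(issue, id, detail)
    issues[[length(issues) + 1L]] <<- data.frame(issue = issue, id = id,
                                                 detail = detail)
  bad <- which(!is.finite(p$radius) | p$radius <= 0)
  for (i in bad) add("nonpositive_radius", p$id[i],
                     sprintf("radius %.4g", p$radius[i]))
  # cycles / unreachable points
  pidx <- match(p$parent, p$id)
  reach <- logical(nrow(p))
  frontier <- which(is.na(pidx))
  reach[frontier] <- TRUE
  kids <- vector("list", nrow(p))
  for (i in seq_len(nrow(p)))
    if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  while (length(frontier)) {
    nxt <- setdiff(unlist(kids[frontier], use.names = FALSE), which(reach))
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  for (i in which(!reach)) add("cycle", p$id[i], "point unreachable from any root")
  # detached trees: root farther than tolerance from every soma contour vertex
  if (length(m@soma)) {
    sv <- do.call(rbind, lapply(m@soma, function(ct)
      cbind(ct$x, ct$y, rep(ct$z, length(ct$x)))))
    for (i in which(is.na(pidx))) {
      d <- sqrt((sv[, 1] - p$x[i])^2 + (sv[, 2] - p$y[i])^2 +
                  (sv[, 3] - p$z[i])^2)
      if (min(d) > somaAttachTol)
        add("detached_tree", p$id[i],
            sprintf("root %.2f um from nearest soma contour", min(d)))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(issue = character(0), id = integer(0), detail = character(0))
}
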