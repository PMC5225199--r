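# Population analysis: metric matrix, normalization and redundancy exclusion,
# correlation-matrix PCA with two eigenvalue significance procedures,
# bootstrap coefficient z-scores with sign correction, regressions of
# excluded metrics, Ward clustering, and the random-branching baselines.

#' Default inclusion set of per-cell metrics for PCA (27 metrics)
#'
#' The metrics retained after redundancy exclusion: soma surface and Feret
#' maximum, stem counts and main-primary measures, per-layer dendritic
#' lengths (INL, S1..S5, GCL), dendritic surface area, mean diameter and
#' segment path length, maximum central-shaft order, partition asymmetry,
#' node count, the four field Feret calipers, 3D hull volume, Euclidean
#' distance statistics, contraction and fractal dimension.
#'
#' @return character vector of 27 column names.
#' @export
defaultInclusionMetrics <- function() {
  c("soma_surface_area", "soma_feret_max", "n_primary_dendrites",
    "main_primary_length", "main_primary_max_diameter",
    "length_INL", "length_S1", "length_S2", "length_S3", "length_S4",
    "length_S5", "length_GCL",
    "dendritic_surface_area", "avg_diameter", "avg_segment_path_length",
    "max_order_shaft", "avg_partition_asymmetry", "n_nodes",
    "hull2d_feret_max_arboreal", "hull2d_feret_min_arboreal",
    "hull2d_feret_max_lobular", "hull2d_feret_min_lobular",
    "hull3d_volume", "euclidean_distance_mean", "euclidean_distance_max",
    "contraction", "fractal_dimension")
}

#' Build the cells x metrics matrix
#'
#' Combines per-cell metric rows (from \code{\link{cellSummary}}) with
#' per-layer totals (dendritic length per layer/stratum and node counts from
#' \code{\link{laminarProfile}}), centers every column on its mean and
#' normalizes to unit SD. Cells with missing values are dropped with a
#' warning; constant columns are flagged near-constant.
#'
#' @param metrics data.frame of per-cell metric rows (non-numeric columns
#'   such as \code{cell_id} are carried as row names).
#' @param laminar optional data.frame of per-cell laminar totals with columns
#'   \code{length_INL}..\code{length_GCL} (and optionally \code{nodes_*}).
#' @return list of class \code{"MetricMatrix"}: \code{raw}, \code{scaled},
#'   \code{center}, \code{scale}, \code{near_constant} (logical per column),
#'   \code{n_cells}.
#' @export
buildMetricMatrix <- function(metrics, laminar = NULL) {
  if (!is.null(laminar)) metrics <- cbind(metrics, laminar)
  ids <- if ("cell_id" %in% names(metrics)) as.character(metrics$cell_id)
  else rownames(metrics)
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  X <- as.matrix(num)
  rownames(X) <- ids
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    warning(sum(!keep), " cell(s) excluded for missing metric values")
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X) < 3L) stop("need at least 3 complete cells")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  nearConst <- !is.finite(scl) | scl == 0 |
    (abs(ctr) > 0 & scl / pmax(abs(ctr), .Machine$double.eps) < 1e-3)
  sclSafe <- ifelse(scl > 0, scl, 1)
  S <- sweep(sweep(X, 2, ctr), 2, sclSafe, `/`)
  structure(list(raw = X, scaled = S, center = ctr, scale = scl,
                 near_constant = nearConst, n_cells = nrow(X)),
            class = "MetricMatrix")
}

#' Exclude redundant and near-constant metrics
#'
#' A metric is excluded when it is strongly correlated (|Pearson r| above
#' \code{rThreshold}) with a retained metric \emph{and} is listed as
#' geometrically related to it (the \code{candidates} list; by default every
#' metric outside \code{\link{defaultInclusionMetrics}}). Effective
#' duplicates (|r| >= 0.999) are excluded regardless of listing.
#' Near-constant metrics (coefficient of variation below 1e-3) are excluded
#' to avoid injecting noise. An exclusion log records the reason and the
#' correlated partner for every column.
#'
#' @param mm a \code{MetricMatrix} from \code{\link{buildMetricMatrix}}.
#' @param rThreshold correlation magnitude defining a strong correlation
#'   (default 0.80).
#' @param candidates metrics eligible for redundancy exclusion; default all
#'   columns not in the shipped 27-metric inclusion set.
#' @return the \code{MetricMatrix} with added \code{included} (character),
#'   \code{excluded} (character) and \code{exclusion_log} (data.frame).
#' @export
normalizeAndExclude <- function(mm, rThreshold = 0.80, candidates = NULL) {
  X <- mm$scaled
  cols <- colnames(X)
  candidates <- candidates %||% setdiff(cols, defaultInclusionMetrics())
  reason <- stats::setNames(rep("none", length(cols)), cols)
  partner <- stats::setNames(rep(NA_character_, length(cols)), cols)
  rval <- stats::setNames(rep(NA_real_, length(cols)), cols)
  reason[mm$near_constant] <- "near_constant"
  active <- cols[reason == "none"]
  C <- suppressWarnings(stats::cor(X[, active, drop = FALSE]))
  C[!is.finite(C)] <- 0
  # pass 1: effective duplicates always go (the later column yields);
  # pass 2: listed candidates strongly correlated with a retained metric
  for (pass in 1:2) {
    thr <- if (pass == 1) 0.999 else rThreshold
    for (j in active) {
      if (reason[j] != "none") next
      if (pass == 2 && !(j %in% candidates)) next
      retained <- active[reason[active] == "none"]
      retained <- setdiff(retained, j)
      if (pass == 1)    # a duplicate pair: only the later column is dropped
        retained <- retained[match(retained, cols) < match(j, cols)]
      if (!length(retained)) next
      rr <- abs(C[j, retained])
      hit <- retained[if (pass == 1) rr >= thr else rr > thr]
      if (length(hit)) {
        k <- hit[which.max(abs(C[j, hit]))]
        reason[j] <- "redundant"
        partner[j] <- k
        rval[j] <- C[j, k]
      }
    }
  }
  included <- cols[reason == "none"]
  if (!length(included)) stop("all metrics excluded")
  mm$included <- included
  mm$excluded <- setdiff(cols, included)
  mm$exclusion_log <- data.frame(metric = cols, reason = unname(reason),
                                 partner = unname(partner), r = unname(rval))
  mm$r_threshold <- rThreshold
  mm
}

#' Principal component analysis of the metric matrix
#'
#' Eigen-decomposition of the correlation matrix of the included metrics.
#' The variance fraction of a component is its eigenvalue divided by the
#' number of included metrics (the eigenvalues of a correlation matrix sum
#' to that number, so the fractions sum to 1). Scores are the projections of
#' the normalized data onto the components. Component signs are fixed so the
#' largest-magnitude coefficient is positive.
#'
#' @param mm a \code{MetricMatrix}, ideally after
#'   \code{\link{normalizeAndExclude}}.
#' @return list of class \code{"PCAResult"}: \code{eigenvalues},
#'   \code{fractions}, \code{components} (metrics x PCs), \code{scores}
#'   (cells x PCs), \code{n_metrics}, \code{metrics}.
#' @export
runPCA <- function(mm) {
  metrics <- mm$included %||% colnames(mm$scaled)
  S <- mm$scaled[, metrics, drop = FALSE]
  if (nrow(S) < 2L || ncol(S) < 2L) stop("need at least 2 cells and 2 metrics")
  C <- stats::cor(S)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  lam <- pmax(eg$values, 0)
  dimnames(V) <- list(metrics, paste0("PC", seq_along(lam)))
  scores <- S %*% V
  structure(list(eigenvalues = lam, fractions = lam / length(metrics),
                 components = V, scores = scores,
                 n_metrics = length(metrics), metrics = metrics),
            class = "PCAResult")
}

#' Eigenvalue significance of principal components
#'
#' Two procedures. \code{"random_data_mc"}: the observed k-th eigenvalue is
#' compared with the (1 - alpha) quantile of the k-th eigenvalue over
#' \code{nNull} datasets of independent standard-normal values of the same
#' shape. \code{"broken_stick"}: the k-th eigenvalue must exceed the
#' broken-stick expectation sum(1/i, i = k..p).
#'
#' @param pca a \code{PCAResult}.
#' @param nCells number of cells (rows) behind the PCA; required for the MC
#'   null.
#' @param method \code{"random_data_mc"} (default) or \code{"broken_stick"}.
#' @param nNull Monte-Carlo replicates (at least 100).
#' @param alpha significance level for the MC null.
#' @param seed optional RNG seed.
#' @return list with logical \code{significant}, the \code{thresholds}, and
#'   \code{n_significant} (leading run of significant components).
#' @export
significantComponents <- function(pca, nCells = nrow(pca$scores),
                                  method = c("random_data_mc", "broken_stick"),
                                  nNull = 1000, alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  p <- pca$n_metrics
  lam <- pca$eigenvalues
  if (method == "broken_stick") {
    thr <- rev(cumsum(1 / rev(seq_len(p))))
  } else {
    if (nNull < 100) stop("nNull must be at least 100")
    if (!is.null(seed)) set.seed(seed)
    null <- matrix(NA_real_, nNull, p)
    for (b in seq_len(nNull)) {
      Z <- matrix(stats::rnorm(nCells * p), nCells, p)
      null[b, ] <- eigen(stats::cor(Z), symmetric = TRUE, only.values = TRUE)$values
    }
    thr <- apply(null, 2, stats::quantile, probs = 1 - alpha)
  }
  exceeds <- lam > thr
  # sequential rule: a component is retained only when all earlier ones are
  # (the usual stopping criterion; prevents isolated late-k false positives)
  lead <- which(!exceeds)
  nsig <- if (length(lead)) lead[1L] - 1L else length(exceeds)
  sig <- exceeds & (seq_along(exceeds) <= nsig)
  list(significant = sig, exceeds_threshold = exceeds, thresholds = thr,
       method = method, n_significant = nsig)
}

#' Bootstrap z-scores for component coefficients
#'
#' PCA is repeated on datasets resampled from the cells with replacement.
#' Every bootstrapped component's sign is corrected by multiplying with the
#' sign of its scalar product with the original component, so all corrected
#' scalar products are non-negative; replicates whose leading eigenvalue
#' order swaps PC1/PC2 are counted (not reordered). The z-score of a
#' coefficient is its original magnitude divided by its bootstrap SD;
#' coefficients with z > 2 are conventionally significant (p < 0.05 without
#' multiplicity correction).
#'
#' @param mm a \code{MetricMatrix} (after exclusion).
#' @param pca the original \code{PCAResult}; computed when NULL.
#' @param nBoot bootstrap replicates (default 10000).
#' @param nComponents how many leading components to track (default 2).
#' @param seed optional RNG seed.
#' @return list with \code{z} (metrics x PCs), \code{boot_sd},
#'   \code{n_order_swapped}, \code{n_degenerate}, \code{nBoot}.
#' @export
bootstrapCoefficients <- function(mm, pca = NULL, nBoot = 10000,
                                  nComponents = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pca <- pca %||% runPCA(mm)
  metrics <- pca$metrics
  S <- mm$scaled[, metrics, drop = FALSE]
  n <- nrow(S)
  k <- min(nComponents, pca$n_metrics)
  V0 <- pca$components[, seq_len(k), drop = FALSE]
  sums <- matrix(0, nrow(V0), k)
  sums2 <- matrix(0, nrow(V0), k)
  used <- 0L; swapped <- 0L; degen <- 0L
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Sb <- S[idx, , drop = FALSE]
    sdv <- apply(Sb, 2, stats::sd)
    if (any(sdv == 0)) { degen <- degen + 1L; next }
    Cb <- stats::cor(Sb)
    eg <- eigen(Cb, symmetric = TRUE)
    Vb <- eg$vectors[, seq_len(k), drop = FALSE]
    # sign correction against the original components
    dots <- crossprod(Vb, V0)              # k x k scalar products
    for (j in seq_len(k)) {
      if (dots[j, j] < 0) { Vb[, j] <- -Vb[, j]; dots[j, ] <- -dots[j, ] }
    }
    if (k >= 2 && abs(dots[1, 2]) > abs(dots[1, 1])) swapped <- swapped + 1L
    used <- used + 1L
    sums <- sums + Vb
    sums2 <- sums2 + Vb^2
  }
  if (used < 2L) stop("too few usable bootstrap replicates")
  vmean <- sums / used
  vvar <- pmax(sums2 / used - vmean^2, 0) * used / (used - 1)
  bsd <- sqrt(vvar)
  z <- abs(V0) / bsd
  dimnames(z) <- dimnames(V0)
  list(z = z, boot_sd = bsd, n_order_swapped = swapped,
       n_degenerate = degen, n_used = used, nBoot = nBoot)
}

#' Regress excluded metrics on component scores
#'
#' Each excluded metric (raw values) is regressed on each selected
#' component's scores by simple linear regression; the slope and R^2 are
#' reported and entries with R^2 > 0.4 are flagged.
#'
#' @param mm a \code{MetricMatrix} after \code{\link{normalizeAndExclude}}.
#' @param pca the \code{PCAResult}.
#' @param components which PCs to use (default 1:2).
#' @param r2Flag flagging threshold (default 0.4).
#' @return data.frame with \code{metric}, \code{component},
#'   \code{coefficient}, \code{r_squared}, \code{flagged}.
#' @export
regressExcluded <- function(mm, pca, components = 1:2, r2Flag = 0.4) {
  exm <- mm$excluded %||% character(0)
  rows <- list()
  for (me in exm) {
    yv <- mm$raw[, me]
    for (cp in components) {
      sc <- pca$scores[, cp]
      fit <- stats::lm(yv ~ sc)
      # duplicates of included metrics fit essentially perfectly; that is the
      # expected outcome, not a numerical concern
      r2 <- suppressWarnings(summary(fit)$r.squared)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = me, component = paste0("PC", cp),
        coefficient = unname(stats::coef(fit)[2]),
        r_squared = r2, flagged = r2 > r2Flag)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(metric = character(0), component = character(0),
                  coefficient = numeric(0), r_squared = numeric(0),
                  flagged = logical(0))
}

#' Ward clustering with a separability assessment
#'
#' Hierarchical clustering of the normalized metric matrix with Ward's
#' method (Euclidean distances, \code{ward.D2}). Separability is judged by
#' the largest relative gap between successive linkage heights near the top
#' of the dendrogram: when the merge completing k clusters is at least
#' \code{gapThreshold} times higher than the preceding merge, k separable
#' clusters are reported; otherwise there is no evidence for separable
#' clusters.
#'
#' @param mm a \code{MetricMatrix}.
#' @param gapThreshold linkage-height ratio required to call clusters
#'   (default 2).
#' @param maxK largest cluster count examined (default 6).
#' @return list with \code{hclust}, \code{k} (1 when not separable),
#'   \code{separable}, \code{gap_ratios}, \code{membership}.
#' @export
wardClustering <- function(mm, gapThreshold = 2, maxK = 6) {
  S <- mm$scaled[, mm$included %||% colnames(mm$scaled), drop = FALSE]
  if (nrow(S) < 3L) stop("need at least 3 cells")
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")
  h <- hc$height
  nh <- length(h)
  ks <- 2:min(maxK, nh)
  ratios <- vapply(ks, function(k) h[nh - k + 2L] / h[nh - k + 1L], numeric(1))
  names(ratios) <- paste0("k", ks)
  best <- ks[which.max(ratios)]
  separable <- max(ratios) >= gapThreshold
  k <- if (separable) best else 1L
  list(hclust = hc, k = k, separable = separable, gap_ratios = ratios,
       membership = stats::cutree(hc, k = max(k, 1L)))
}

#' Export a linkage tree in Newick format
#'
#' @param hc an \code{hclust} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeLinkageNewick <- function(hc, path) {
  ph <- ape::as.phylo(hc)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Random-branching angle baselines
#'
#' For bifurcation directions distributed uniformly over the sphere: the
#' angle between two independent random directions has mean pi/2 and SD
#' sqrt(pi^2/4 - 2) (90.0 and 39.2 degrees); the smaller of two independent
#' axis angles (the most backward daughter, as used by the tilt metric) has
#' mean 3 pi/8 and SD sqrt(3 pi^2/8 - 2 - (3 pi/8)^2) (67.5 and 32.0
#' degrees). The Monte-Carlo mode estimates the same quantities from sampled
#' directions and agrees with the closed forms to within sampling error.
#'
#' @param mode \code{"analytic"} or \code{"monte_carlo"}.
#' @param nSamples Monte-Carlo sample count (at least 1000).
#' @param seed optional RNG seed for the MC mode.
#' @return list with \code{pair_angle_mean}, \code{pair_angle_sd},
#'   \code{tilt_mean}, \code{tilt_sd} (degrees), \code{mode}, and for MC the
#'   standard errors \code{pair_angle_se}, \code{tilt_se}.
#' @export
randomBranchingBaselines <- function(mode = c("analytic", "monte_carlo"),
                                     nSamples = 1e6, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    return(list(pair_angle_mean = 90,
                pair_angle_sd = deg(sqrt(pi^2 / 4 - 2)),
                tilt_mean = deg(3 * pi / 8),
                tilt_sd = deg(sqrt(3 * pi^2 / 8 - 2 - (3 * pi / 8)^2)),
                mode = mode))
  }
  if (nSamples < 1e3) stop("nSamples must be at least 1000 for Monte Carlo")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nSamples)
  # uniform directions: z ~ U(-1,1), azimuth ~ U(0, 2pi)
  rdir <- function(n) {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    cbind(s * cos(th), s * sin(th), z)
  }
  u1 <- rdir(n); u2 <- rdir(n)
  pair <- deg(acos(pmax(-1, pmin(1, rowSums(u1 * u2)))))
  # tilt: angle of each daughter to a fixed axis, take the smaller
  a1 <- deg(acos(pmax(-1, pmin(1, u1[, 3]))))
  a2 <- deg(acos(pmax(-1, pmin(1, u2[, 3]))))
  tilt <- pmin(a1, a2)
  list(pair_angle_mean = mean(pair), pair_angle_sd = stats::sd(pair),
       pair_angle_se = stats::sd(pair) / sqrt(n),
       tilt_mean = mean(tilt), tilt_sd = stats::sd(tilt),
       tilt_se = stats::sd(tilt) / sqrt(n),
       mode = mode, n_samples = n)
}

#' Simulate a metric matrix with planted latent factors
#'
#' Generates a cells x metrics matrix X = F L' + E with \code{nFactors}
#' orthogonal standard-normal factors, each loading on its own block of
#' metrics with the given strength, plus unit-variance noise. Used to verify
#' that the PCA significance machinery recovers the planted dimensionality.
#'
#' @param nCells rows (default 43).
#' @param nMetrics columns (default 27).
#' @param nFactors planted factors (default 2); 0 gives pure noise.
#' @param loadingStrength per-factor loading magnitudes (recycled).
#' @param blockSize metrics loaded per factor (default nMetrics %/% 3).
#' @param seed RNG seed.
#' @return numeric matrix with planted structure in the leading blocks.
#' @export
simulateMetricMatrix <- function(nCells = 43, nMetrics = 27, nFactors = 2,
                                 loadingStrength = c(1.5, 1.2),
                                 blockSize = nMetrics %/% 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(nCells * nMetrics), nCells, nMetrics)
  if (nFactors > 0) {
    loadingStrength <- rep_len(loadingStrength, nFactors)
    for (f in seq_len(nFactors)) {
      fac <- stats::rnorm(nCells)
      cols <- ((f - 1L) * blockSize + 1L):min(f * blockSize, nMetrics)
      X[, cols] <- X[, cols] + fac %o% rep(loadingStrength[f], length(cols))
    }
  }
  colnames(X) <- sprintf("m%02d", seq_len(nMetrics))
  rownames(X) <- sprintf("cell%02d", seq_len(nCells))
  X
}
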