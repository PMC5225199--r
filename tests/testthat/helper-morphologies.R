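# Shared builders for the test suite. All fixtures are constructed in code.

# straight path along +x with a prescribed per-point diameter profile,
# points 1 um apart; used to exercise the varicosity detector
profileMorphology <- function(diameters, spacing = 1) {
  n <- length(diameters)
  Morphology(data.frame(id = seq_len(n), type = 0L,
                        x = (seq_len(n) - 1) * spacing,
                        y = 0, z = 0,
                        radius = diameters / 2,
                        parent = c(-1L, seq_len(n - 1L))))
}

# tree from an explicit parent/coordinate table
treeMorphology <- function(x, y, z, r, parent, type = 0L) {
  Morphology(data.frame(id = seq_along(x), type = type, x = x, y = y, z = z,
                        radius = r, parent = as.integer(parent)))
}

# a "stub" tree: root bifurcation has one terminal daughter and one daughter
# subtree that bifurcates further (partition asymmetry 1 at the root node)
stubTree <- function() {
  treeMorphology(
    x = c(0, 0, 2, 0, 1, 0.5, 1.5),
    y = c(0, 2, 3, 4, 5, 6, 6),
    z = rep(0, 7),
    r = c(0.5, 0.5, 0.2, 0.4, 0.3, 0.2, 0.2),
    parent = c(-1, 1, 2, 2, 4, 4, 5))
}

# chain of 3 stub bifurcations ending in a tip bifurcation, plus a side tip
# bifurcation: 2 tips (PA 0) + 3 stubs (PA 1) -> mean 0.6
mixedTree <- function() {
  pts <- rbind(
    c(1, 0, 0, -1),      # 1 root
    c(2, 0, 1, 1),       # 2 = node A (stub): daughters 3 (terminal), 4
    c(3, 1, 1.5, 2),
    c(4, 0, 2, 2),       # 4 = node B (stub): daughters 5 (terminal), 6
    c(5, -1, 2.5, 4),
    c(6, 0, 3, 4),       # 6 = node C (stub): daughters 7 (terminal), 8
    c(7, 1, 3.5, 6),
    c(8, 0, 4, 6),       # 8 = node D (tip bif): daughters 9, 10 terminal
    c(9, 0.5, 5, 8),
    c(10, -0.5, 5, 8))
  # plus a second stem ending in its own tip bifurcation
  df <- data.frame(id = pts[, 1], x = pts[, 2], y = pts[, 3],
                   parent = pts[, 4])
  extra <- data.frame(id = 11:14, x = c(5, 5, 5.5, 4.5),
                      y = c(0.5, 1.5, 2.5, 2.5),
                      parent = c(-1, 11, 12, 12))
  all <- rbind(df, extra)
  Morphology(data.frame(id = as.integer(all$id), type = 0L, x = all$x,
                        y = all$y, z = 0, radius = 0.3,
                        parent = as.integer(all$parent)))
}

# small generated cell cached per test session (generation is the expensive
# step shared by many tests)
cachedCell <- local({
  cell <- NULL
  function() {
    if (is.null(cell)) cell <<- generateAII(seed = 1)
    cell
  }
})
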