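# Shared fixtures, all generated in code.

# small fast grid for unit tests (same 4 mm vertical pitch as the default)
tinyGrid <- function() Grid3D(c(64L, 64L, 24L), c(6, 6, 12))

# a mid-size phantom that fits the tiny grid comfortably
tinySpec <- function(offset = 0, ...) {
  phantomSpec(bodySemiAxisAP = 100, bodySemiAxisLat = 120, bodyLength = 240,
              tableHeightOffset = offset, ...)
}

# render + project in one go
renderCase <- function(spec, grid = defaultGrid(), mode = "divergent") {
  vol <- renderVolume(spec, grid)
  list(volume = vol, localizer = projectLocalizer(vol, mode = mode))
}

# brute-force voxel bounding-box midpoint of an analytic ellipsoid mask,
# independent of the rendering/segmentation path
voxelEllipsoidMid <- function(grid, centre, semi, zRange = NULL) {
  y <- axisCoords(grid, 1); x <- axisCoords(grid, 2); z <- axisCoords(grid, 3)
  keepZ <- if (is.null(zRange)) seq_along(z) else
    which(z >= zRange[1] & z <= zRange[2])
  f <- outer(outer(((y - centre[1]) / semi[1])^2,
                   ((x - centre[2]) / semi[2])^2, "+"),
             ((z[keepZ] - centre[3]) / semi[3])^2, "+")
  rows <- which(apply(f < 1, 1, any))
  (max(y[rows]) + min(y[rows])) / 2
}

# independent Mann-Whitney oracle: enumerate every label assignment and
# count pairwise wins (0.5 per tie) -- a different route than the rank-sum
# implementation
enumMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  uOf <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  sel <- utils::combn(length(pooled), na)
  uPerm <- apply(sel, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  u <- uOf(a, b)
  uLo <- min(u, na * length(b) - u)
  mean(pmin(uPerm, na * length(b) - uPerm) <= uLo)
}
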