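# Shared fixtures, built in code at test time.

# A straight vertical tube phantom whose axis passes through voxel
# centers (x = y = 16.5), radius 3, spanning z = 8..88.
straightTubeSpec <- function(shape = c(96, 33, 33), radius = 3) {
  phantomSpec(shape = shape,
              roots = list(list(type = "straight",
                                from = c(16.5, 16.5, 8),
                                to = c(16.5, 16.5, shape[1] - 8),
                                radius = radius, intensity = 255L)))
}

# The default gently wavy helical root (radius 8 voxels, pitch 64,
# 1.5 turns, tube radius 3) with optional salt noise.
helixSpec <- function(saltFraction = 0, seed = 1) {
  phantomSpec(saltFraction = saltFraction, seed = seed)
}

# A random polyline with n vertices, drifting downward.
randomPolyline <- function(n, lim = 60) {
  pts <- cbind(x = runif(n, 5, lim), y = runif(n, 5, lim),
               z = sort(runif(n, 5, lim)))
  pts
}

# A random valid RSATree with polylines cached on some roots.
randomTree <- function(nRootsMax = 5) {
  tree <- RSATree(base = runif(3, 0, 50), resolution = runif(1, 0.1, 0.5),
                  annotations = list(cultivar = "synthetic", das = "26"))
  for (k in seq_len(sample.int(nRootsMax, 1))) {
    nr <- sample(2:6, 1)
    tree <- addRoot(tree, randomPolyline(nr),
                    interpolation = sample(c("straight", "spline", "cog"), 1))
    id <- rootIds(tree)[nRoots(tree)]
    if (runif(1) < 0.7)
      tree <- vectorizeRoot(tree, id, "straight")
  }
  tree
}

expect_polyline_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
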