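test_that("straight interpolation keeps exactly the registered nodes", {
  pl <- straightInterpolate(c(0, 0, 0), c(3, 4, 0))
  expect_equal(nrow(pl), 2L)
  expect_equal(unname(rootvec:::polylineLengthVoxels(pl)), 5)

  relays <- rbind(c(1, 1, 2), c(2, 0, 5), c(4, 4, 9))
  pl <- straightInterpolate(c(0, 0, 0), relays)
  expect_equal(nrow(pl), 4L)
  expect_equal(unname(pl[2:4, ]), unname(relays))

  # brute-force pairwise-distance oracle for the length
  acc <- 0
  for (i in 1:(nrow(pl) - 1))
    acc <- acc + sqrt(sum((pl[i + 1, ] - pl[i, ])^2))
  expect_equal(rootvec:::polylineLengthVoxels(pl), acc)

  expect_warning(straightInterpolate(c(0, 0, 0),
                                     rbind(c(0, 0, 0), c(1, 1, 1))),
                 "duplicate")
})

test_that("spline interpolation degenerates to straight for two nodes and reproduces lines", {
  a <- c(1, 2, 3); b <- c(7, 5, 11)
  expect_polyline_equal(splineInterpolate(a, rbind(b)),
                        straightInterpolate(a, rbind(b)))

  # 4 collinear nodes: every sampled vertex on the line
  dirv <- c(2, 1, 3) / sqrt(14)
  nodes <- t(sapply(c(0, 3, 7, 12), function(s) c(1, 1, 1) + s * dirv))
  sp <- splineInterpolate(nodes[1, ], nodes[-1, ])
  rel <- sweep(sp, 2, c(1, 1, 1))
  resid <- rel - outer(rel %*% dirv, dirv)[, 1, ]
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("spline through quarter-circle nodes stays within half a voxel of the circle", {
  th <- seq(0, pi / 2, length.out = 5)
  nodes <- cbind(50 * cos(th) + 5, 50 * sin(th) + 5, rep(10, 5))
  sp <- splineInterpolate(nodes[1, ], nodes[-1, ])
  radial <- sqrt((sp[, 1] - 5)^2 + (sp[, 2] - 5)^2)
  expect_lt(max(abs(radial - 50)), 0.5)
  expect_lt(max(abs(sp[, 3] - 10)), 1e-9)
  # registered nodes appear among the vertices
  for (i in seq_len(nrow(nodes)))
    expect_lt(min(sqrt(colSums((t(sp) - nodes[i, ])^2))), 1e-9)
})

test_that("COG tracking follows a straight centered tube within 0.5 voxels RMS", {
  ras <- rasterizePhantom(straightTubeSpec())
  trk <- cogTrack(ras$volume, c(16.5, 16.5, 8), c(16.5, 16.5, 88))
  dev <- sqrt((trk[, 1] - 16.5)^2 + (trk[, 2] - 16.5)^2)
  expect_lt(sqrt(mean(dev^2)), 0.5)
  expect_gt(nrow(trk), 2L)  # interpolated nodes were added
})

test_that("COG tracking on an all-zero volume equals straight interpolation exactly", {
  zv <- RootVolume(array(0L, c(32, 32, 32)), 0.3)
  base <- c(5, 5, 5)
  relays <- rbind(c(10, 10, 10), c(20, 20, 25))
  expect_identical(cogTrack(zv, base, relays),
                   straightInterpolate(base, relays))
})

test_that("COG tracking recovers helix arc length from endpoint-only nodes under salt noise", {
  ras <- rasterizePhantom(helixSpec(saltFraction = 0.10, seed = 42))
  pl <- ras$polylines[[1]]
  base <- pl[1, ]; tip <- pl[nrow(pl), ]
  trk <- cogTrack(ras$volume, base, rbind(tip))
  len <- rootvec:::polylineLengthVoxels(trk)
  expect_lt(abs(len / ras$arcLengths - 1), 0.05)
  expect_gt(len, sqrt(sum((tip - base)^2)))  # strictly beats the chord
})

test_that("every method preserves endpoints, registered nodes, and the chord lower bound", {
  set.seed(202)
  ras <- rasterizePhantom(helixSpec())
  gt <- ras$polylines[[1]]
  base <- gt[1, ]
  mid <- gt[round(nrow(gt) / 2), ]
  tip <- gt[nrow(gt), ]
  relays <- rbind(mid, tip)
  cfg <- trackingConfig()
  polys <- list(straight = straightInterpolate(base, relays),
                spline = splineInterpolate(base, relays),
                cog = cogTrack(ras$volume, base, relays, cfg))
  for (nm in names(polys)) {
    pl <- polys[[nm]]
    expect_lt(max(abs(pl[1, ] - base)), 1e-6)
    expect_lt(max(abs(pl[nrow(pl), ] - tip)), 1e-6)
    for (i in seq_len(nrow(relays)))   # registered-node containment
      expect_lt(min(sqrt(colSums((t(pl) - relays[i, ])^2))), 1e-9)
    expect_gte(rootvec:::polylineLengthVoxels(pl),
               sqrt(sum((tip - base)^2)) - 1e-9)  # chord lower bound
  }
  # chord bound also on random inputs, straight/spline
  for (rep in 1:25) {
    nodes <- randomPolyline(sample(2:6, 1))
    for (f in list(straightInterpolate, splineInterpolate)) {
      pl <- f(nodes[1, ], nodes[-1, , drop = FALSE])
      chord <- sqrt(sum((pl[nrow(pl), ] - pl[1, ])^2))
      expect_gte(rootvec:::polylineLengthVoxels(pl), chord - 1e-9)
    }
  }
})

test_that("vectorizeRoot dispatches, caches, and is deterministic", {
  ras <- rasterizePhantom(helixSpec())
  gt <- ras$polylines[[1]]
  tree <- RSATree(base = gt[1, ], resolution = 0.3)
  tree <- addRoot(tree, rbind(gt[nrow(gt), ]))
  expect_error(vectorizeRoot(tree, 1, "cog"), "requires a volume")
  t1 <- vectorizeRoot(tree, 1, "cog", volume = ras$volume)
  t2 <- vectorizeRoot(tree, 1, "cog", volume = ras$volume)
  expect_identical(rootPolyline(t1, 1), rootPolyline(t2, 1))
  expect_equal(getRoot(t1, 1)@interpolation, "cog")
  # all three methods share endpoints
  ts <- vectorizeRoot(tree, 1, "straight")
  tp <- vectorizeRoot(tree, 1, "spline")
  for (tr in list(t1, ts, tp)) {
    pl <- rootPolyline(tr, 1)
    expect_lt(max(abs(pl[1, ] - gt[1, ])), 1e-6)
    expect_lt(max(abs(pl[nrow(pl), ] - gt[nrow(gt), ])), 1e-6)
  }
})

test_that("tracking starts from the relay farthest from the base", {
  # register relays out of distance order; the tip (farthest) must still
  # be the polyline's last vertex after the base->tip reversal
  ras <- rasterizePhantom(helixSpec())
  gt <- ras$polylines[[1]]
  base <- gt[1, ]
  relays <- rbind(gt[nrow(gt), ], gt[round(nrow(gt) / 2), ])  # tip first
  trk <- cogTrack(ras$volume, base, relays)
  expect_lt(max(abs(trk[nrow(trk), ] - gt[nrow(gt), ])), 1e-9)
  expect_lt(max(abs(trk[1, ] - base)), 1e-9)
})

test_that("COG tracking beats straight interpolation on noisy curved tubes", {
  set.seed(7)
  rmsToCurve <- function(poly, gt) {
    rs <- resamplePolyline(poly)
    d <- apply(rs, 1, function(p) min(sqrt(colSums((t(gt) - p)^2))))
    sqrt(mean(d^2))
  }
  nPhantom <- 20
  rmsCog <- rmsStraight <- numeric(nPhantom)
  for (k in seq_len(nPhantom)) {
    amp <- runif(1, 4, 7)
    cyc <- runif(1, 0.7, 1.3)
    spec <- phantomSpec(shape = c(96, 40, 40),
                        roots = list(list(type = "sine", center = c(20, 20),
                                          amplitude = amp, cycles = cyc,
                                          phase = 0, z0 = 8, length = 80,
                                          radius = 3, intensity = 255L)),
                        saltFraction = runif(1, 0.02, 0.10), seed = k)
    ras <- rasterizePhantom(spec)
    gt <- ras$polylines[[1]]
    b <- gt[1, ]; tp <- gt[nrow(gt), ]
    rmsCog[k] <- rmsToCurve(cogTrack(ras$volume, b, rbind(tp)), gt)
    rmsStraight[k] <- rmsToCurve(straightInterpolate(b, rbind(tp)), gt)
  }
  expect_lt(mean(rmsCog), mean(rmsStraight))
})

test_that("COG correction leaves a straight centered tube essentially unmoved", {
  ras <- rasterizePhantom(straightTubeSpec())
  trk <- cogTrack(ras$volume, c(16.5, 16.5, 8), c(16.5, 16.5, 88))
  # versus the pure geometric step: every node within 0.5 voxels of the axis
  expect_lt(max(sqrt((trk[, 1] - 16.5)^2 + (trk[, 2] - 16.5)^2)), 0.5)
})
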