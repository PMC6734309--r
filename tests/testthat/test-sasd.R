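# Euclidean and solvent-accessible-surface distance engine.

# hand-made grid helper: empty (all-solvent) box with given dims/spacing
emptyGrid <- function(dims, spacing = 1) {
  occ <- array(FALSE, dim = dims)
  new("SolventGrid", origin = c(0, 0, 0), spacing = spacing,
      dims = as.integer(dims), occupied = occ, probeRadius = 1.4,
      atomRadius = 1.7)
}

test_that("euclideanDistance is the plain norm", {
  expect_equal(euclideanDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclideanDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10)
    expect_equal(euclideanDistance(a, b), sqrt(sum((a - b)^2)),
                 tolerance = 1e-12)
    expect_equal(euclideanDistance(a, b), euclideanDistance(b, a))
  }
})

test_that("buildGrid marks exactly the voxels within atom+probe radius", {
  one <- new("XLStructure",
             atoms = data.frame(chain = "A", resno = 1L, icode = "",
                                resid = "ALA", elety = "CA",
                                x = 0, y = 0, z = 0),
             chains = "A")
  g <- buildGrid(one, spacing = 1, probeRadius = 1.4, atomRadius = 1.7)
  # brute-force: a voxel is occupied iff its center is within 3.1 A of origin
  d <- g@dims
  idx <- expand.grid(ix = seq_len(d[1]), iy = seq_len(d[2]),
                     iz = seq_len(d[3]))
  centers <- cbind(g@origin[1] + (idx$ix - 1) * g@spacing,
                   g@origin[2] + (idx$iy - 1) * g@spacing,
                   g@origin[3] + (idx$iz - 1) * g@spacing)
  expected <- sqrt(rowSums(centers^2)) <= 3.1
  expect_identical(as.logical(g@occupied), expected)
  # margin region is solvent on every face
  expect_false(any(g@occupied[1, , ])); expect_false(any(g@occupied[d[1], , ]))
  expect_false(any(g@occupied[, 1, ])); expect_false(any(g@occupied[, , 1]))

  expect_error(buildGrid(one, spacing = 0), "positive")

  # two distant atoms give two disjoint occupied components
  two <- new("XLStructure",
             atoms = data.frame(chain = "A", resno = 1:2, icode = "",
                                resid = "ALA", elety = "CA",
                                x = c(0, 20), y = 0, z = 0),
             chains = "A")
  g2 <- buildGrid(two)
  occIdx <- which(g2@occupied, arr.ind = TRUE)
  # cluster occupied voxels by which atom they are near; both exist, no overlap
  cx <- g2@origin[1] + (occIdx[, 1] - 1) * g2@spacing
  expect_true(any(cx < 10) && any(cx > 10))
  expect_false(any(abs(cx - 10) < 5))          # gap between the blobs
})

test_that("endpoint accessibility finds anchors and detects burial", {
  one <- new("XLStructure",
             atoms = data.frame(chain = "A", resno = 1L, icode = "",
                                resid = "LYS", elety = "CA",
                                x = 0, y = 0, z = 0),
             chains = "A")
  g <- buildGrid(one)
  ea <- endpointAccessible(g, c(0, 0, 0), accessRadius = 4)
  expect_true(ea$accessible)    # surface of an isolated atom
  expect_true(ea$anchorDist > 3.1 && ea$anchorDist <= 4)

  # monotone in accessRadius
  expect_false(endpointAccessible(g, c(0, 0, 0), accessRadius = 3)$accessible)
  expect_true(endpointAccessible(g, c(0, 0, 0), accessRadius = 6)$accessible)

  # fully occupied neighbourhood -> buried
  gb <- emptyGrid(c(21, 21, 21))
  gb@occupied[] <- TRUE
  expect_false(endpointAccessible(gb, c(10, 10, 10), 4)$accessible)
})

test_that("open-path SASD stays near the Euclidean distance", {
  d <- makeToyDimer(seed = 6)
  g <- buildGrid(d)
  lys <- lysineCalpha(d)
  # two exposed residues far apart on the same face
  p1 <- as.numeric(lys[2, c("x", "y", "z")])
  p2 <- as.numeric(lys[3, c("x", "y", "z")])
  r <- sasdDistance(g, p1, p2)
  expect_true(is.finite(r$distance))
  expect_gte(r$distance, euclideanDistance(p1, p2) - 2 * g@spacing * sqrt(3))
  expect_lte(r$distance,
             euclideanDistance(p1, p2) + 2 * g@spacing * sqrt(3) + 2 * 4 +
               30)   # loose sanity bound: detour around a small protein
})

test_that("SASD equals the independent graph shortest-path oracle on a
           walled box with one hole", {
  g <- emptyGrid(c(31, 31, 31))
  g@occupied[16, , ] <- TRUE          # solid wall at x index 16
  g@occupied[16, 24:26, 24:26] <- FALSE  # 3x3 hole, off the straight line
  pa <- c(5, 15, 15); pb <- c(25, 15, 15)
  r <- sasdDistance(g, pa, pb, accessRadius = 2)
  oracle <- gridGraphOracle(g@occupied, g@dims, g@spacing)
  ea <- endpointAccessible(g, pa, 2); eb <- endpointAccessible(g, pb, 2)
  od <- ea$anchorDist + eb$anchorDist +
    oracle$dist(xlambig:::voxelLinear(g, ea$anchor),
                xlambig:::voxelLinear(g, eb$anchor))
  expect_equal(r$distance, od, tolerance = 1e-9)
  # the wall forces a detour beyond the straight line
  expect_gt(r$distance, euclideanDistance(pa, pb) + 2)

  # same check in strict 6-connected mode: never shorter than 26-connected
  r6 <- sasdDistance(g, pa, pb, accessRadius = 2, connectivity = 6)
  o6 <- gridGraphOracle(g@occupied, g@dims, g@spacing, connectivity = 6)
  od6 <- ea$anchorDist + eb$anchorDist +
    o6$dist(xlambig:::voxelLinear(g, ea$anchor),
            xlambig:::voxelLinear(g, eb$anchor))
  expect_equal(r6$distance, od6, tolerance = 1e-9)
  expect_gte(r6$distance, r$distance - 1e-9)

  # sealed wall -> disconnected components -> non-accessible
  g@occupied[16, , ] <- TRUE
  rs <- sasdDistance(g, pa, pb, accessRadius = 2)
  expect_true(is.na(rs$distance))
  expect_true(rs$accessibleA && rs$accessibleB)
})

test_that("buried endpoints yield NON_ACCESSIBLE and SASD is symmetric", {
  d <- makeToyDimer(seed = 1)
  g <- buildGrid(d)
  lys <- lysineCalpha(d)
  buried <- as.numeric(lys[1, c("x", "y", "z")])  # first lysine is buried
  open <- as.numeric(lys[3, c("x", "y", "z")])
  rb <- sasdDistance(g, buried, open)
  expect_true(is.na(rb$distance))
  expect_false(rb$accessibleA)

  r12 <- sasdDistance(g, open, as.numeric(lys[4, c("x", "y", "z")]))
  r21 <- sasdDistance(g, as.numeric(lys[4, c("x", "y", "z")]), open)
  expect_identical(r12$distance, r21$distance)
})

test_that("SASD is bounded below by EUC minus the discretization tolerance
           on many random accessible pairs", {
  d <- makeToyDimer(seed = 9)
  g <- buildGrid(d)
  set.seed(33)
  # random points in a shell near the protein surface
  a <- atoms(d); xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- 0; checked <- 0
  pts <- list()
  while (length(pts) < 30 && n < 2000) {
    n <- n + 1
    p <- xyz[sample(nrow(xyz), 1), ] + rnorm(3, sd = 3)
    if (endpointAccessible(g, p, 4)$accessible) pts[[length(pts) + 1]] <- p
  }
  src <- do.call(rbind, pts[1:15]); tgt <- do.call(rbind, pts[16:30])
  D <- xlambig:::sasdMatrix(g, src, tgt)
  tol <- 2 * g@spacing * sqrt(3)
  for (i in 1:15) for (j in 1:15) {
    if (is.na(D[i, j])) next
    checked <- checked + 1
    expect_gte(D[i, j], euclideanDistance(src[i, ], tgt[j, ]) - tol)
  }
  expect_gt(checked, 100)
})

test_that("removing obstacles never increases SASD and halving the spacing
           is consistent on a convex-path fixture", {
  d <- makeToyDimer(seed = 2)
  lys <- lysineCalpha(d)
  p1 <- as.numeric(lys[2, c("x", "y", "z")])
  p2 <- as.numeric(lys[5, c("x", "y", "z")])
  g <- buildGrid(d)
  full <- sasdDistance(g, p1, p2)$distance
  # drop chain B's occupancy on the same grid: fewer obstacles
  aA <- atoms(d)[atoms(d)$chain == "A", ]
  occA <- xlambig:::cpp_occupancy(as.matrix(aA[, c("x", "y", "z")]),
                                  g@origin, g@dims, g@spacing,
                                  g@atomRadius + g@probeRadius)
  gA <- g
  dim(occA) <- g@dims
  gA@occupied <- occA
  less <- sasdDistance(gA, p1, p2)$distance
  tol <- 2 * g@spacing * sqrt(3)
  expect_true(is.finite(full) && is.finite(less))
  expect_lte(less, full + tol)

  # refinement: halving the spacing moves the distance by < 4*spacing*sqrt(3)
  gh <- buildGrid(d, spacing = 0.5)
  dh <- sasdDistance(gh, p1, p2)$distance
  if (!is.na(dh) && !is.na(full))
    expect_lt(abs(dh - full), 4 * 1 * sqrt(3))
})
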