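# Euclidean and solvent-accessible-surface distance (SASD) engine.
#
# SASD places the protein on a regular grid, marks voxels within
# atomRadius + probeRadius of any heavy atom as occupied, and measures the
# shortest path between two C-alpha endpoints through solvent voxels:
#   SASD = |CA_a -> anchor_a| + path(anchor_a, anchor_b) + |anchor_b -> CA_b|
# where each anchor is the nearest solvent voxel center within accessRadius
# of the endpoint. An endpoint with no such voxel is non-accessible, as is a
# pair whose anchors lie in disconnected solvent components.

#' Euclidean C-alpha distance
#'
#' Straight-line distance between two positions, ignoring solvent
#' accessibility and protein-occupied space.
#'
#' @param posA,posB length-3 numeric positions (Angstrom).
#' @return distance in Angstrom.
#' @export
euclideanDistance <- function(posA, posB) {
  sqrt(sum((as.numeric(posA) - as.numeric(posB))^2))
}

#' Build a solvent occupancy grid for a structure
#'
#' @param structure an [XLStructure-class] (hydrogens are ignored; all other
#'   atoms count as heavy atoms with a uniform radius).
#' @param spacing lattice spacing in Angstrom (default 1.0).
#' @param probeRadius solvent probe radius in Angstrom (default 1.4).
#' @param atomRadius uniform heavy-atom radius in Angstrom (default 1.7).
#' @param margin extra margin beyond the occupancy radius added around the
#'   atom bounding box; the total margin is at least the probe diameter plus
#'   two voxels.
#' @return a [SolventGrid-class].
#' @export
buildGrid <- function(structure, spacing = 1.0, probeRadius = 1.4,
                      atomRadius = 1.7, margin = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  a <- atoms(structure)
  a <- a[!grepl("^H", a$elety), , drop = FALSE]   # drop hydrogens
  if (nrow(a) == 0L) stop("structure has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radius <- atomRadius + probeRadius
  if (is.null(margin)) margin <- 2 * probeRadius + 2 * spacing
  pad <- radius + margin
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  occ <- cpp_occupancy(xyz, lo, dims, spacing, radius)
  dim(occ) <- dims
  new("SolventGrid", origin = as.numeric(lo), spacing = spacing,
      dims = dims, occupied = occ, probeRadius = probeRadius,
      atomRadius = atomRadius)
}

setMethod("show", "SolventGrid", function(object) {
  cat(sprintf("SolventGrid: %d x %d x %d voxels, spacing %.2f A, %.1f%% occupied\n",
              object@dims[1], object@dims[2], object@dims[3], object@spacing,
              100 * mean(object@occupied)))
})

# voxel (1-based ix,iy,iz) -> center coordinates
voxelCenter <- function(grid, ijk) {
  grid@origin + (as.numeric(ijk) - 1) * grid@spacing
}

# 1-based (ix,iy,iz) -> 0-based linear index for the C++ kernels
voxelLinear <- function(grid, ijk) {
  d <- grid@dims
  (ijk[1] - 1L) + d[1] * ((ijk[2] - 1L) + d[2] * (ijk[3] - 1L))
}

#' Endpoint solvent accessibility and anchor voxel
#'
#' An endpoint is accessible iff a solvent voxel center exists within
#' `accessRadius` of its C-alpha. The anchor is the nearest such voxel; ties
#' are broken by lexicographic voxel index (x fastest) for determinism.
#'
#' @param grid a [SolventGrid-class].
#' @param position C-alpha position (length-3 numeric, Angstrom).
#' @param accessRadius search radius in Angstrom (default 4.0).
#' @return list with `accessible` (logical), `anchor` (1-based voxel index
#'   triple or NULL), `anchorDist` (Angstrom or NA).
#' @export
endpointAccessible <- function(grid, position, accessRadius = 4.0) {
  d <- grid@dims
  p <- as.numeric(position)
  lo <- pmax(1L, as.integer(ceiling((p - accessRadius - grid@origin) /
                                      grid@spacing)) + 1L)
  hi <- pmin(d, as.integer(floor((p + accessRadius - grid@origin) /
                                   grid@spacing)) + 1L)
  if (any(lo > hi))
    return(list(accessible = FALSE, anchor = NULL, anchorDist = NA_real_))
  idx <- expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
  centers <- cbind(grid@origin[1] + (idx$ix - 1) * grid@spacing,
                   grid@origin[2] + (idx$iy - 1) * grid@spacing,
                   grid@origin[3] + (idx$iz - 1) * grid@spacing)
  dist <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
                 (centers[, 3] - p[3])^2)
  solv <- !grid@occupied[cbind(idx$ix, idx$iy, idx$iz)]
  ok <- solv & dist <= accessRadius
  if (!any(ok))
    return(list(accessible = FALSE, anchor = NULL, anchorDist = NA_real_))
  # nearest solvent voxel; ties by lexicographic (ix, iy, iz)
  cand <- which(ok)
  ordKey <- order(dist[cand], idx$ix[cand], idx$iy[cand], idx$iz[cand])
  best <- cand[ordKey[1]]
  list(accessible = TRUE,
       anchor = c(idx$ix[best], idx$iy[best], idx$iz[best]),
       anchorDist = dist[best])
}

#' Solvent accessible surface distance between two endpoints
#'
#' @param grid a [SolventGrid-class] built from the structure the endpoints
#'   belong to.
#' @param posA,posB C-alpha positions (Angstrom).
#' @param accessRadius endpoint accessibility radius (Angstrom, default 4.0).
#' @param connectivity 26 (default; Euclidean edge weights, Dijkstra) or 6
#'   (strict uniform-cost breadth-first mode).
#' @param cutoff stop the search beyond this path length (Angstrom); distances
#'   above it are reported as `Inf`. Default `Inf` (exact).
#' @return list with `distance` (Angstrom; `NA` if either endpoint is
#'   non-accessible or the anchors are disconnected; `Inf` if beyond
#'   `cutoff`), `accessibleA`, `accessibleB`.
#' @export
sasdDistance <- function(grid, posA, posB, accessRadius = 4.0,
                         connectivity = 26, cutoff = Inf) {
  ea <- endpointAccessible(grid, posA, accessRadius)
  eb <- endpointAccessible(grid, posB, accessRadius)
  if (!ea$accessible || !eb$accessible)
    return(list(distance = NA_real_, accessibleA = ea$accessible,
                accessibleB = eb$accessible))
  src <- voxelLinear(grid, ea$anchor)
  tgt <- voxelLinear(grid, eb$anchor)
  res <- cpp_grid_shortest(as.logical(grid@occupied), grid@dims, grid@spacing,
                           as.integer(src), as.integer(tgt),
                           as.integer(connectivity), cutoff, FALSE)
  path <- res$target_dist[1]
  if (is.infinite(path)) {
    d <- if (is.finite(cutoff)) Inf else NA_real_   # cutoff vs disconnected
  } else {
    d <- ea$anchorDist + path + eb$anchorDist
  }
  list(distance = d, accessibleA = TRUE, accessibleB = TRUE)
}

# Batched SASD: one shortest-path run per source endpoint against all target
# endpoints. sources/targets: n x 3 coordinate matrices. Returns a matrix of
# distances (NA non-accessible, Inf beyond cutoff). With a finite cutoff,
# pairs whose straight-line distance already exceeds it are pruned without a
# path search: a grid path can never be shorter than the straight line, so
# SASD >= EUC and the result is Inf exactly.
sasdMatrix <- function(grid, sources, targets, accessRadius = 4.0,
                       connectivity = 26, cutoff = Inf) {
  sources <- rbind(sources); targets <- rbind(targets)
  aS <- lapply(seq_len(nrow(sources)), function(i)
    endpointAccessible(grid, sources[i, ], accessRadius))
  aT <- lapply(seq_len(nrow(targets)), function(i)
    endpointAccessible(grid, targets[i, ], accessRadius))
  out <- matrix(NA_real_, nrow(sources), nrow(targets))
  tgtOk <- which(vapply(aT, `[[`, TRUE, "accessible"))
  if (length(tgtOk) == 0L) return(out)
  tgtLin <- vapply(aT[tgtOk], function(e) voxelLinear(grid, e$anchor), 0)
  tgtHop <- vapply(aT[tgtOk], `[[`, 0, "anchorDist")
  for (i in seq_len(nrow(sources))) {
    if (!aS[[i]]$accessible) next
    keep <- tgtOk
    if (is.finite(cutoff)) {
      euc <- sqrt(colSums((t(targets[tgtOk, , drop = FALSE]) -
                             as.numeric(sources[i, ]))^2))
      out[i, tgtOk[euc > cutoff]] <- Inf
      keep <- tgtOk[euc <= cutoff]
      if (length(keep) == 0L) next
    }
    sel <- match(keep, tgtOk)
    res <- cpp_grid_shortest(as.logical(grid@occupied), grid@dims,
                             grid@spacing,
                             as.integer(voxelLinear(grid, aS[[i]]$anchor)),
                             as.integer(tgtLin[sel]), as.integer(connectivity),
                             cutoff, FALSE)
    path <- res$target_dist
    d <- aS[[i]]$anchorDist + path + tgtHop[sel]
    d[is.infinite(path)] <- if (is.finite(cutoff)) Inf else NA_real_
    out[i, keep] <- d
  }
  out
}

#' Export a grid as a plain-text voxel dump
#'
#' One line per voxel: `ix iy iz occupied`, 1-based indices. Intended for
#' debugging and for independent shortest-path oracles on small grids.
#'
#' @param grid a [SolventGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportGrid <- function(grid, path) {
  d <- grid@dims
  idx <- expand.grid(ix = seq_len(d[1]), iy = seq_len(d[2]),
                     iz = seq_len(d[3]))
  df <- data.frame(idx, occupied = as.integer(grid@occupied))
  write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
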