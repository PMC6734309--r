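# Simulation of cross-link datasets, synthetic C2 homo-dimers and rigid-body
# decoy ensembles.
#
# The toy dimer emulates what the benchmark needs from a real C2 homo-dimer:
# two rigid identical subunits related by an exact two-fold rotation, a
# compact fold (helical hairpin C-alpha trace with pseudo side-chain atoms),
# surface-exposed lysines and one deliberately buried lysine. Decoys stand in
# for rigid-body docking output: chain 1 fixed, chain 2 re-placed by a rigid
# transform, with a guaranteed near-native share.

# Evaluate code under a temporary RNG state so callers' streams are untouched.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# uniform random rotation matrix (quaternion method)
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation by angle (radians) about unit axis
axisRotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

#' Generate a synthetic C2-symmetric toy homo-dimer
#'
#' Builds a compact single chain as an idealized helical-hairpin C-alpha
#' trace (1.5 A rise, 100 degrees per residue, 2.3 A helix radius) with one
#' pseudo side-chain atom (CB) per residue, then duplicates it into an exact
#' C2-symmetric dimer by a two-fold rotation about an axis between the
#' chains. Lysine positions are seeded-random but reproducible; the first
#' lysine is buried under a shell of pseudo side-chain atoms so that, for
#' `nResidues >= 20`, the structure contains at least one exposed and one
#' buried lysine.
#'
#' @param nResidues residues per chain (>= 8, default 40).
#' @param nLysines lysines per chain (>= 2, <= nResidues - 2, default 6).
#' @param interfaceOffset gap between the chain bounding boxes across the
#'   two-fold axis, in Angstrom (default 4, a snug contact interface).
#' @param seed integer seed.
#' @return an [XLStructure-class] with chains "A" and "B".
#' @export
makeToyDimer <- function(nResidues = 40, nLysines = 6, interfaceOffset = 4,
                         seed = 1) {
  if (nResidues < 8) stop("nResidues must be >= 8")
  if (nLysines < 2) stop("nLysines must be >= 2")
  if (nLysines > nResidues - 2) stop("too many lysines for chain length")
  withSeed(seed, {
    half <- ceiling(nResidues / 2)
    build <- function(i) {
      # helical segment 1 ascends in z; segment 2 descends, offset in x
      seg2 <- i > half
      j <- if (seg2) i - half else i
      phase <- j * 100 * pi / 180
      axis_x <- if (seg2) 10 else 0
      zpos <- if (seg2) (half - j + 0.75) * 1.5 else j * 1.5
      c(axis_x + 2.3 * cos(phase), 2.3 * sin(phase), zpos)
    }
    ca <- t(vapply(seq_len(nResidues), build, numeric(3)))
    # pseudo side chain: push radially out from the local helix axis
    axis_x <- ifelse(seq_len(nResidues) > half, 10, 0)
    rad <- cbind(ca[, 1] - axis_x, ca[, 2], 0)
    rad <- rad / sqrt(rowSums(rad^2))
    cb <- ca + 1.8 * rad

    lysAt <- sort(sample(2:(nResidues - 1), nLysines))
    resid <- rep("ALA", nResidues)
    resid[lysAt] <- "LYS"

    rows <- function(chain, caM, cbM, extra = NULL) {
      df <- data.frame(
        chain = chain,
        resno = rep(seq_len(nResidues), each = 2),
        icode = "",
        resid = rep(resid, each = 2),
        elety = rep(c("CA", "CB"), nResidues),
        x = as.numeric(t(cbind(caM[, 1], cbM[, 1]))),
        y = as.numeric(t(cbind(caM[, 2], cbM[, 2]))),
        z = as.numeric(t(cbind(caM[, 3], cbM[, 3]))),
        stringsAsFactors = FALSE)
      if (!is.null(extra)) df <- rbind(df, extra)
      df
    }
    # bury the first lysine under a dense shell of pseudo atoms
    shell <- NULL
    if (nResidues >= 20) {
      p <- ca[lysAt[1], ]
      dirs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
      dirs <- as.matrix(dirs[rowSums(abs(dirs)) > 0, ])
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- sweep(3.0 * dirs, 2, p, "+")
      shell <- data.frame(chain = "A", resno = lysAt[1], icode = "",
                          resid = "LYS", elety = "SD1",
                          x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          stringsAsFactors = FALSE)
      shell$elety <- sprintf("S%02d", seq_len(nrow(shell)))
    }
    chainA <- rows("A", ca, cb, shell)

    # exact two-fold rotation about a z-parallel axis beyond the chain
    cx <- max(chainA$x) + interfaceOffset / 2
    chainB <- chainA
    chainB$chain <- "B"
    chainB$x <- 2 * cx - chainA$x
    chainB$y <- -chainA$y
    new("XLStructure", atoms = rbind(chainA, chainB), chains = c("A", "B"))
  })
}

#' Simulate a cross-link dataset from a recreated reference
#'
#' Enumerates non-redundant lysine candidates on the reference with SASD
#' distances and keeps every pair whose intra- or inter-subunit SASD is at or
#' below the threshold. The retained residue-number pairs mimic the
#' chain-ambiguous output of an XL-MS experiment on a homo-oligomer.
#'
#' @param reference recreated reference dimer ([XLStructure-class]).
#' @param threshold linker threshold in Angstrom (default 33).
#' @param candidateSet optional pre-computed SASD [XLCandidateSet-class] of
#'   the reference (skips recomputation).
#' @param ... further arguments to [enumerateCandidates()].
#' @return data.frame with columns `res_i`, `res_j`, `label` (the reference
#'   assignment from [classifyPair()]), carrying attributes `threshold` and
#'   `method`. Zero rows (with a warning) when no pair qualifies.
#' @export
simulateCrosslinks <- function(reference, threshold = 33,
                               candidateSet = NULL, ...) {
  if (is.null(candidateSet))
    candidateSet <- enumerateCandidates(reference, method = "SASD",
                                        threshold = threshold, ...)
  d <- candidateSet@data
  keep <- isMatched(d$intra, threshold) | isMatched(d$shortest_inter, threshold)
  out <- d[keep, c("res_i", "res_j"), drop = FALSE]
  out$label <- classifyPair(d$intra[keep], d$shortest_inter[keep], threshold)
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no simulated cross-links at threshold ", threshold, " A")
  attr(out, "threshold") <- threshold
  attr(out, "method") <- candidateSet@method
  out
}

#' Generate a rigid-body decoy ensemble for a dimer reference
#'
#' Chain 1 stays fixed; each model applies a rigid transform to chain 2. A
#' `nearNativeFraction` share of models are small perturbations guaranteed
#' (by rejection) to keep the complex C-alpha RMSD to the reference at or
#' below 10 A; the remainder are random orientations and placements of chain
#' 2 around chain 1, rejected if any inter-chain C-alpha pair comes closer
#' than 2 A.
#'
#' @param reference recreated reference dimer ([XLStructure-class]).
#' @param nModels number of decoys.
#' @param nearNativeFraction share in `[0, 1]` of near-native decoys
#'   (default 0.1).
#' @param maxPerturbation translation scale (Angstrom) of the near-native
#'   perturbations (default 3).
#' @param separationRange range (Angstrom) of centroid separations for the
#'   random placements; default `c(0.8 * s, s + 12)` where `s` is the
#'   reference separation, keeping random decoys in surface contact as
#'   rigid-body docking output would be.
#' @param seed integer seed.
#' @return a [DecoyEnsemble-class]; model ids are `1:nModels` with the
#'   near-native block first.
#' @export
generateDecoys <- function(reference, nModels = 200, nearNativeFraction = 0.1,
                           maxPerturbation = 3, separationRange = NULL,
                           seed = 1) {
  if (nearNativeFraction < 0 || nearNativeFraction > 1)
    stop("nearNativeFraction must be in [0, 1]")
  ch <- chainIds(reference)
  if (length(ch) != 2L) stop("dimer reference required")
  ca <- calpha(reference)
  ca2 <- as.matrix(ca[ca$chain == ch[2], c("x", "y", "z")])
  cen1 <- colMeans(as.matrix(ca[ca$chain == ch[1], c("x", "y", "z")]))
  cen2 <- colMeans(ca2)
  sep <- sqrt(sum((cen2 - cen1)^2))
  if (is.null(separationRange)) separationRange <- c(0.8 * sep, sep + 12)
  nNear <- round(nearNativeFraction * nModels)
  withSeed(seed, {
    transforms <- vector("list", nModels)
    for (i in seq_len(nModels)) {
      if (i <= nNear) {
        for (try in 1:200) {
          ang <- runif(1, 0, 15) * pi / 180
          R <- axisRotation(rnorm(3), ang)
          tr <- rnorm(3); tr <- tr / sqrt(sum(tr^2)) *
            runif(1, 0, maxPerturbation)
          # rotate about the chain-2 centroid, then translate
          t0 <- as.numeric(cen2 - R %*% cen2 + tr)
          trf <- new("RigidTransform", rotation = R, translation = t0)
          moved <- transformCoords(ca2, trf)
          rmsd <- sqrt(mean(rowSums((moved - ca2)^2)))
          if (rmsd <= 10) { transforms[[i]] <- trf; break }
        }
        if (is.null(transforms[[i]]))
          stop("could not generate a near-native decoy within RMSD 10 A")
      } else {
        placed <- FALSE
        for (try in 1:500) {
          R <- randomRotation()
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          dist <- runif(1, separationRange[1], separationRange[2])
          newCen <- cen1 + dir * dist
          t0 <- as.numeric(newCen - R %*% cen2)
          trf <- new("RigidTransform", rotation = R, translation = t0)
          moved <- transformCoords(ca2, trf)
          ca1 <- as.matrix(ca[ca$chain == ch[1], c("x", "y", "z")])
          d2 <- outer(rowSums(ca1^2), rowSums(moved^2), "+") -
            2 * ca1 %*% t(moved)
          if (min(d2) >= 4) { transforms[[i]] <- trf; placed <- TRUE; break }
        }
        if (!placed) stop("could not place a clash-free random decoy")
      }
    }
    new("DecoyEnsemble", reference = reference, transforms = transforms,
        modelIds = seq_len(nModels), seed = as.integer(seed))
  })
}

#' Materialize one decoy model
#'
#' @param ensemble a [DecoyEnsemble-class].
#' @param modelId model identifier.
#' @return the decoy [XLStructure-class] (reference with chain 2 moved).
#' @export
getModel <- function(ensemble, modelId) {
  k <- match(modelId, ensemble@modelIds)
  if (is.na(k)) stop("unknown model id: ", modelId)
  ch <- chainIds(ensemble@reference)
  applyTransform(ensemble@reference, ch[2], ensemble@transforms[[k]])
}

setMethod("show", "DecoyEnsemble", function(object) {
  cat("DecoyEnsemble:", length(object@modelIds), "model(s), seed",
      object@seed, "\n")
})

#' @describeIn DecoyEnsemble-accessors number of models.
#' @export
nModels <- function(ensemble) length(ensemble@modelIds)

#' Accessors for DecoyEnsemble
#' @param ensemble a [DecoyEnsemble-class].
#' @name DecoyEnsemble-accessors
NULL

#' Subsample a cross-link set at fixed coverage
#'
#' Draws `nReplicates` random subsets of the cross-link set, each of size
#' `round(fraction * n)`, sampled without replacement within a replicate, to
#' emulate partial experimental coverage of the possible cross-links.
#'
#' @param xlSet data.frame of cross-links ([simulateCrosslinks()] output).
#' @param fraction coverage in `(0, 1]`.
#' @param nReplicates number of replicate subsets (default 1000).
#' @param seed integer seed.
#' @return list of data.frames, one per replicate.
#' @export
bootstrapCoverage <- function(xlSet, fraction, nReplicates = 1000, seed = 1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- nrow(xlSet)
  size <- round(fraction * n)
  if (size == 0L) stop("coverage fraction yields an empty subset")
  withSeed(seed, {
    lapply(seq_len(nReplicates), function(i) {
      idx <- sort(sample.int(n, size, replace = FALSE))
      out <- xlSet[idx, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
  })
}

#' Write / read a cross-link list as TSV
#'
#' Two columns `res_i`, `res_j` (residue numbers only; chain-ambiguous by
#' design, mirroring real XL-MS output for homo-oligomers).
#'
#' @param xlSet data.frame with columns `res_i`, `res_j`.
#' @param path file path.
#' @return `writeCrossLinks`: `path` invisibly; `readCrossLinks`: data.frame.
#' @export
writeCrossLinks <- function(xlSet, path) {
  write.table(xlSet[, c("res_i", "res_j")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCrossLinks
#' @export
readCrossLinks <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("res_i", "res_j") %in% names(df)))
    stop("cross-link file must have columns res_i and res_j")
  df
}
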