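# Independent oracles and fixture builders shared across the test files.

# --- Horn quaternion superposition oracle ------------------------------------
# Closed-form least-squares rigid superposition via the quaternion eigenvector
# method; independent of the SVD-based implementation under test.
hornRmsd <- function(mobile, target) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(target), 2, colMeans(target))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE)$values)
  ss <- sum(P^2) + sum(Q^2) - 2 * lambda
  sqrt(max(0, ss) / nrow(P))
}

# --- igraph shortest-path oracle on a voxel grid -----------------------------
# Builds the solvent-voxel graph (26- or 6-connectivity, Euclidean weights)
# and returns exact shortest path lengths between 0-based linear voxel
# indices. Used only on small grids.
gridGraphOracle <- function(occupied, dims, spacing, connectivity = 26) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  solvent <- which(!as.logical(occupied))          # 1-based linear
  id <- integer(length(occupied)); id[solvent] <- seq_along(solvent)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  ix <- (solvent - 1L) %% nx
  iy <- ((solvent - 1L) %/% nx) %% ny
  iz <- (solvent - 1L) %/% (nx * ny)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    jx <- ix + offs$dx[k]; jy <- iy + offs$dy[k]; jz <- iz + offs$dz[k]
    ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
    lin <- jx[ok] + nx * (jy[ok] + ny * jz[ok]) + 1L
    ok2 <- id[lin] > 0L
    from <- c(from, id[solvent[ok]][ok2])
    to <- c(to, id[lin][ok2])
    w <- c(w, rep(spacing * sqrt(sum(abs(offs[k, ]))), sum(ok2)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  list(
    dist = function(src0, tgt0) {     # 0-based linear voxel indices
      s <- id[src0 + 1L]; t <- id[tgt0 + 1L]
      if (s == 0L || t == 0L) return(Inf)
      as.numeric(igraph::distances(g, v = s, to = t))
    })
}

# --- literal transcription of the scoring-function rules ---------------------
# Applies the published rules of each scoring-function variant directly, as
# written, without sharing code with crosslinkContribution().
ruleOracle <- function(intra, ab, ba, inclusion, symmetry, orientation,
                       ambiguity, T = 33, mu = 18.62, s2 = 35.94,
                       pen = -0.1, symCut = 5) {
  mn <- function(d) {
    if (is.na(d) || d > T) pen else dnorm(d, mu, sqrt(s2))
  }
  matched <- function(d) !is.na(d) && d <= T
  consider <- switch(inclusion,
                     ALL = TRUE,
                     ONLY_BEST = max(mn(ab), mn(ba)) >= mn(intra),
                     NON_INTRA = !matched(intra))
  if (consider && symmetry == "SYMMETRY_MATCHED")
    consider <- matched(ab) && matched(ba)
  if (consider && symmetry == "SYMMETRY_DIFFERENCE")
    consider <- (matched(ab) || matched(ba)) &&
      !is.na(ab) && !is.na(ba) && is.finite(ab) && is.finite(ba) &&
      abs(ab - ba) < symCut
  if (!consider) return(0)
  alt <- function(d) {
    s <- mn(d)
    if (ambiguity == "NORMAL" && identical(s, pen) && matched(intra)) 0 else s
  }
  if (orientation == "ORIENTED") alt(ab) + alt(ba) else max(alt(ab), alt(ba))
}

allScoringConfigs <- function(method = "SASD") {
  grid <- expand.grid(
    inclusion = c("ALL", "ONLY_BEST", "NON_INTRA"),
    ambiguity = c("OBLIVIOUS", "NORMAL"),
    orientation = c("ORIENTED", "STRINGENT"),
    symmetry = c("NONE", "SYMMETRY_MATCHED", "SYMMETRY_DIFFERENCE"),
    stringsAsFactors = FALSE)
  grid
}

# canonical distance scenarios (intra, interAB, interBA); NA = non-accessible
canonicalScenarios <- function() {
  list(
    allMatched     = c(20, 19, 21),
    intraOnly      = c(12, 45, 60),
    interOnly      = c(50, 25, 26),
    asymmetricInter = c(NA, 19, 30),
    intraWithPenalties = c(20, 40, 41),
    selfPair       = c(NA, 28, 28))
}

randomScenario <- function() {
  d <- function() {
    u <- runif(1)
    if (u < 0.2) NA_real_ else runif(1, 0, 60)
  }
  c(d(), d(), d())
}

# --- PDB text fixture builder ------------------------------------------------
pdbLine <- function(serial, elety, resid, chain, resno, x, y, z,
                    altloc = " ", icode = " ", record = "ATOM") {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resid, chain, resno, icode,
          x, y, z, 1, 0, substr(elety, 1, 1))
}

# two-chain toy PDB text: nres residues per chain, CA + CB per residue
toyPdbText <- function(nres = 12, lysAt = c(3, 7)) {
  lines <- character(0); serial <- 0
  for (chain in c("A", "B")) {
    xoff <- if (chain == "A") 0 else 20
    for (r in seq_len(nres)) {
      resid <- if (r %in% lysAt) "LYS" else "ALA"
      for (at in c("CA", "CB")) {
        serial <- serial + 1
        zoff <- if (at == "CB") 0.8 else 0
        lines <- c(lines, pdbLine(serial, at, resid, chain, r,
                                  xoff + r * 1.9, (r %% 3) * 1.2, zoff))
      }
    }
  }
  c(lines, "END")
}

writeTempPdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
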