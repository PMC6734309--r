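# Structure I/O, lysine extraction, superposition and rigid-body transforms.

#' Read a PDB file into an XLStructure
#'
#' Parses ATOM records (HETATM and waters are excluded) of the first MODEL of
#' a PDB file. For alternate locations only the first-listed altloc of each
#' atom is kept. Chain order is file order and residue identity uses author
#' numbering with insertion codes carried verbatim.
#'
#' @param path path to a PDB-format file.
#' @return an [XLStructure-class].
#' @examples
#' dimer <- makeToyDimer(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(dimer, f)
#' s <- readStructure(f)
#' chainIds(s)
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$resid != "HOH", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in '", path, "'")
  a$icode <- ifelse(is.na(a$insert), "", a$insert)
  # first-listed altloc: keep the first record per (chain, resno, icode, atom)
  key <- paste(a$chain, a$resno, a$icode, a$elety, sep = "\r")
  a <- a[!duplicated(key), , drop = FALSE]
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      icode = a$icode, resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  st <- new("XLStructure", atoms = atoms, chains = unique(atoms$chain))
  if (nrow(calpha(st)) == 0L)
    stop("structure in '", path, "' has no C-alpha atoms")
  st
}

#' Write an XLStructure to a PDB file
#'
#' @param structure an [XLStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path) {
  a <- atoms(structure)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' @describeIn XLStructure-accessors atom table (data.frame).
#' @export
atoms <- function(structure) structure@atoms

#' Accessors for XLStructure
#'
#' @param structure an [XLStructure-class].
#' @name XLStructure-accessors
#' @return `atoms()` the atom data.frame; `chainIds()` chain identifiers in
#'   file order; `calpha()` the C-alpha subset of the atom table;
#'   `coords()` the n x 3 coordinate matrix.
NULL

#' @describeIn XLStructure-accessors chain identifiers in file order.
#' @export
chainIds <- function(structure) structure@chains

#' @describeIn XLStructure-accessors C-alpha atom records.
#' @export
calpha <- function(structure) {
  a <- structure@atoms
  a[a$elety == "CA", , drop = FALSE]
}

#' @describeIn XLStructure-accessors coordinate matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure@atoms[, c("x", "y", "z")])
}

setMethod("show", "XLStructure", function(object) {
  a <- object@atoms
  ca <- calpha(object)
  cat("XLStructure:", nrow(a), "atoms,", length(object@chains), "chain(s) [",
      paste(object@chains, collapse = ", "), "],",
      nrow(ca), "residues with C-alpha\n")
  nlys <- sum(ca$resid == "LYS")
  cat("  lysines with C-alpha:", nlys, "\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3]))
})

#' Lysine C-alpha positions
#'
#' One entry per LYS residue possessing a C-alpha atom, ordered by chain (file
#' order) then residue number. Lysines lacking a C-alpha (truncated records)
#' are omitted with a warning.
#'
#' @param structure an [XLStructure-class].
#' @return data.frame with columns `chain`, `resno`, `icode`, `x`, `y`, `z`.
#' @export
lysineCalpha <- function(structure) {
  a <- structure@atoms
  lys <- a[a$resid == "LYS", , drop = FALSE]
  key <- unique(lys[, c("chain", "resno", "icode")])
  ca <- lys[lys$elety == "CA", c("chain", "resno", "icode", "x", "y", "z"),
            drop = FALSE]
  if (nrow(ca) < nrow(key))
    warning(nrow(key) - nrow(ca), " lysine(s) lack a C-alpha atom; omitted")
  ord <- order(match(ca$chain, structure@chains), ca$resno, ca$icode)
  ca <- ca[ord, , drop = FALSE]
  rownames(ca) <- NULL
  ca
}

# Resolve (chain, resno[, icode]) to a single C-alpha coordinate.
calphaPosition <- function(structure, chain, resno, icode = "") {
  a <- structure@atoms
  hit <- a$chain == chain & a$resno == resno & a$icode == icode &
    a$elety == "CA"
  if (sum(hit) != 1L)
    stop("residue ", chain, ":", resno, icode,
         " does not resolve to exactly one C-alpha")
  as.numeric(a[hit, c("x", "y", "z")])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `target`.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3, non-collinear.
#' @return list with `transform` (a [RigidTransform-class]) and `rmsd`
#'   (Angstrom) after applying the transform to `mobile`.
#' @export
kabschSuperpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)))
    stop("mobile and target must have identical dimensions")
  if (nrow(mobile) < 3L) stop("at least 3 points required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  if (min(svd(P)$d) < 1e-10 && min(svd(Q)$d) < 1e-10)
    stop("point sets are collinear; superposition is degenerate")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)          # maps centered mobile onto centered target
  tr <- new("RigidTransform", rotation = R,
            translation = as.numeric(ct - R %*% cm))
  fitted <- transformCoords(mobile, tr)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

# Apply a RigidTransform to an n x 3 coordinate matrix.
transformCoords <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform@rotation), 2,
        transform@translation, "+")
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  R <- t(transform@rotation)
  new("RigidTransform", rotation = R,
      translation = as.numeric(-R %*% transform@translation))
}

#' Recreate a homo-dimer reference with identical chains
#'
#' Replaces the second chain (file order) by a copy of the first chain rigidly
#' superposed onto it, using C-alpha atoms common to both chains matched by
#' residue number + insertion code. After recreation both chains have
#' identical internal geometry and residue content, matching the chain
#' composition of rigid-body docking models built from the first subunit.
#'
#' @param structure a two-chain [XLStructure-class] whose chains share at
#'   least three common C-alpha residues.
#' @return an [XLStructure-class] with chain 2 replaced.
#' @export
recreateReference <- function(structure) {
  ch <- structure@chains
  if (length(ch) != 2L)
    stop("recreateReference requires exactly two chains, got ", length(ch))
  a <- structure@atoms
  ca <- calpha(structure)
  ca1 <- ca[ca$chain == ch[1], , drop = FALSE]
  ca2 <- ca[ca$chain == ch[2], , drop = FALSE]
  k1 <- paste(ca1$resno, ca1$icode)
  k2 <- paste(ca2$resno, ca2$icode)
  common <- intersect(k1, k2)
  if (length(common) < 3L)
    stop("chains share fewer than 3 common C-alpha residues")
  m1 <- as.matrix(ca1[match(common, k1), c("x", "y", "z")])
  m2 <- as.matrix(ca2[match(common, k2), c("x", "y", "z")])
  fit <- kabschSuperpose(m1, m2)
  chain1 <- a[a$chain == ch[1], , drop = FALSE]
  moved <- chain1
  moved[, c("x", "y", "z")] <- transformCoords(
    as.matrix(chain1[, c("x", "y", "z")]), fit$transform)
  moved$chain <- ch[2]
  keep <- a[a$chain != ch[2], , drop = FALSE]
  out <- rbind(keep, moved)
  ord <- order(match(out$chain, ch))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  new("XLStructure", atoms = out, chains = ch)
}

#' Apply a rigid transform to one chain of a structure
#'
#' Moves all atoms of `chainId` by `transform`; other chains are untouched,
#' so chain-internal geometry is preserved exactly up to floating point.
#'
#' @param structure an [XLStructure-class].
#' @param chainId chain to move.
#' @param transform a [RigidTransform-class].
#' @return the transformed [XLStructure-class].
#' @export
applyTransform <- function(structure, chainId, transform) {
  if (!chainId %in% structure@chains)
    stop("unknown chain: ", chainId)
  a <- structure@atoms
  sel <- a$chain == chainId
  a[sel, c("x", "y", "z")] <- transformCoords(
    as.matrix(a[sel, c("x", "y", "z")]), transform)
  new("XLStructure", atoms = a, chains = structure@chains)
}

# Subset a structure to one chain (internal).
chainSubset <- function(structure, chainId) {
  a <- structure@atoms
  new("XLStructure", atoms = a[a$chain == chainId, , drop = FALSE],
      chains = chainId)
}
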