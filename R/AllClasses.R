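#' @import methods
#' @importFrom stats dnorm sd runif rnorm
#' @importFrom utils head write.table read.table
#' @useDynLib xlambig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Protein structure as a flat atom table
#'
#' An `XLStructure` holds the atoms of one (possibly multi-chain) protein
#' structure in author numbering. Chain order is the order in which chains
#' first appear in the source file, so "first chain" is well defined; all
#' coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (integer, author
#'   numbering), `icode` (insertion code, `""` if none), `resid` (3-letter
#'   residue name), `elety` (atom name), `x`, `y`, `z`.
#' @slot chains character vector of chain identifiers in file order.
#'
#' @seealso [readStructure()], [makeToyDimer()]
#' @export
setClass("XLStructure",
  representation(atoms = "data.frame", chains = "character"))

setValidity("XLStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "icode", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0L && !all(unique(a$chain) %in% object@chains))
    return("every atom chain must be listed in @chains")
  if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z))
    return("atom coordinates must be finite")
  TRUE
})

#' Rigid-body transform (proper rotation + translation)
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector in Angstrom. The transform maps a
#'   coordinate row vector `x` to `x %*% t(rotation) + translation`.
#'
#' @seealso [kabschSuperpose()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (tolerance 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det = +1)")
  TRUE
})

#' Solvent occupancy grid for surface-distance calculations
#'
#' A regular cubic lattice enclosing a structure plus a margin. A voxel is
#' protein-occupied iff its center lies within `atomRadius + probeRadius` of
#' any heavy atom; solvent voxels are the complement within bounds.
#'
#' @slot origin center of the voxel with index (1,1,1), in Angstrom.
#' @slot spacing lattice spacing in Angstrom.
#' @slot dims integer vector (nx, ny, nz).
#' @slot occupied logical array of dimension `dims`; TRUE = protein-occupied.
#' @slot probeRadius,atomRadius radii (Angstrom) used to build the occupancy.
#'
#' @seealso [buildGrid()], [sasdDistance()]
#' @export
setClass("SolventGrid",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 occupied = "array", probeRadius = "numeric",
                 atomRadius = "numeric"))

setValidity("SolventGrid", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  if (!identical(dim(object@occupied), as.integer(object@dims)))
    return("occupied array dimension must equal dims")
  if (object@spacing <= 0) return("spacing must be positive")
  TRUE
})

#' Set of candidate cross-links with intra/inter distance alternatives
#'
#' One row per unordered lysine residue-number pair with at least one endpoint
#' in the first chain (the non-redundancy rule for homo-oligomers). Distances
#' are in Angstrom; `NA` marks a non-accessible alternative (buried endpoint or
#' disconnected solvent path for SASD, undefined intra for self pairs).
#'
#' @slot data data.frame with columns `res_i`, `res_j` (residue numbers,
#'   `res_i <= res_j`), `intra`, `inter_ab`, `inter_ba` (oriented alternatives,
#'   dimers only), `shortest_inter`.
#' @slot method `"EUC"` or `"SASD"`.
#' @slot threshold linker threshold (Angstrom) the set was built for.
#'
#' @seealso [enumerateCandidates()], [classifyCandidates()]
#' @export
setClass("XLCandidateSet",
  representation(data = "data.frame", method = "character",
                 threshold = "numeric"))

setValidity("XLCandidateSet", function(object) {
  need <- c("res_i", "res_j", "intra", "inter_ab", "inter_ba", "shortest_inter")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (!object@method %in% c("EUC", "SASD"))
    return("method must be 'EUC' or 'SASD'")
  d <- object@data
  if (nrow(d) > 0L && any(d$res_i > d$res_j))
    return("pairs must be stored with res_i <= res_j")
  TRUE
})

#' MNXL scoring configuration
#'
#' The four axes of the scoring-function family plus all numeric constants of
#' the MNXL (Matched and Non-accessible cross-link) score. A distance is
#' *matched* when it is finite, its endpoints accessible, and it is at or
#' below `threshold`; matched distances score the density of
#' Normal(`mu`, `sigma2`), everything else the fixed `penalty`.
#'
#' @slot method distance method, `"EUC"` or `"SASD"`.
#' @slot ambiguity `"OBLIVIOUS"` (penalties applied verbatim) or `"NORMAL"`
#'   (an inter penalty is replaced by `neutral` when the intra alternative is
#'   matched).
#' @slot orientation `"ORIENTED"` (both chain-assignment readings summed) or
#'   `"STRINGENT"` (only the higher-scoring reading).
#' @slot inclusion `"ALL"`, `"ONLY_BEST"` (inter considered only if its best
#'   MNXL score beats the intra score) or `"NON_INTRA"` (only if the intra
#'   alternative is non-accessible).
#' @slot symmetry `"NONE"`, `"SYMMETRY_MATCHED"` (both oriented readings must
#'   be matched) or `"SYMMETRY_DIFFERENCE"` (at least one matched and the two
#'   readings within `symDiffCutoff` of each other).
#' @slot mu,sigma2 mean (Angstrom) and variance (Angstrom^2) of the matched
#'   score density; defaults 18.62 and 35.94.
#' @slot threshold linker threshold (Angstrom), default 33.
#' @slot penalty score of a non-accessible alternative, default -0.1.
#' @slot neutral replacement score under NORMAL ambiguity, default 0.
#' @slot symDiffCutoff symmetry-difference cutoff (Angstrom), default 5.
#'
#' @seealso [scoringConfig()], [mnxl()], [crosslinkContribution()]
#' @export
setClass("ScoringConfig",
  representation(method = "character", ambiguity = "character",
                 orientation = "character", inclusion = "character",
                 symmetry = "character", mu = "numeric", sigma2 = "numeric",
                 threshold = "numeric", penalty = "numeric",
                 neutral = "numeric", symDiffCutoff = "numeric"))

setValidity("ScoringConfig", function(object) {
  ok <- function(x, vals) length(x) == 1L && x %in% vals
  if (!ok(object@method, c("EUC", "SASD"))) return("bad method")
  if (!ok(object@ambiguity, c("OBLIVIOUS", "NORMAL"))) return("bad ambiguity")
  if (!ok(object@orientation, c("ORIENTED", "STRINGENT")))
    return("bad orientation")
  if (!ok(object@inclusion, c("ALL", "ONLY_BEST", "NON_INTRA")))
    return("bad inclusion")
  if (!ok(object@symmetry, c("NONE", "SYMMETRY_MATCHED", "SYMMETRY_DIFFERENCE")))
    return("bad symmetry")
  if (object@sigma2 <= 0) return("sigma2 must be positive")
  if (object@threshold <= 0) return("threshold must be positive")
  if (object@penalty >= 0) return("penalty must be negative")
  if (object@neutral < object@penalty) return("neutral must be >= penalty")
  TRUE
})

#' Rigid-body decoy ensemble for a homo-dimer reference
#'
#' Chain 1 is fixed; each model is the reference with a rigid transform
#' applied to chain 2, so subunit-internal geometry is identical across all
#' models by construction.
#'
#' @slot reference the recreated reference [XLStructure-class].
#' @slot transforms list of [RigidTransform-class], one per model.
#' @slot modelIds integer model identifiers.
#' @slot seed integer seed used for generation.
#'
#' @seealso [generateDecoys()], [getModel()]
#' @export
setClass("DecoyEnsemble",
  representation(reference = "XLStructure", transforms = "list",
                 modelIds = "integer", seed = "integer"))

setValidity("DecoyEnsemble", function(object) {
  if (length(object@transforms) != length(object@modelIds))
    return("one transform per model id required")
  if (anyDuplicated(object@modelIds)) return("model ids must be unique")
  TRUE
})
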