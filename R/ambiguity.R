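# Intra- vs inter-subunit ambiguity of lysine cross-links in homo-oligomers.
#
# In a homo-oligomer a cross-link identified between residue numbers (r_i,
# r_j) cannot be assigned to subunits from peptide evidence alone: it may be
# intra-subunit or any inter-subunit chain combination. Candidates are
# enumerated non-redundantly (at least one endpoint in the first chain), all
# chain combinations of the inter alternative are computed and reduced to the
# shortest one, and each pair is classified at the linker threshold.

xlLabels <- c("INTRA", "INTER", "AMBIGUOUS", "NON_ACCESSIBLE")

# matched = finite, accessible and at or below threshold
isMatched <- function(d, threshold) !is.na(d) & d <= threshold

#' Enumerate non-redundant cross-link candidates of a homo-oligomer
#'
#' Builds one candidate per unordered lysine residue-number pair (including
#' self pairs, which are inter-only) with at least one endpoint in the first
#' chain, and computes the intra-subunit distance (within the first chain)
#' plus all inter-subunit chain combinations, reduced to `shortest_inter`.
#' For dimers both oriented alternatives are also kept: `inter_ab` places
#' `res_i` on chain 1 and `res_j` on chain 2, `inter_ba` the reverse.
#'
#' @param structure a homo-oligomeric [XLStructure-class] with at least two
#'   chains of identical lysine content (use [recreateReference()] first for
#'   experimental dimers).
#' @param method `"EUC"` or `"SASD"`.
#' @param threshold linker threshold in Angstrom recorded in the set
#'   (default 33).
#' @param grid optional pre-built [SolventGrid-class] (SASD only); built from
#'   `structure` when missing.
#' @param accessRadius,connectivity,cutoff SASD parameters, see
#'   [sasdDistance()].
#' @param ... further arguments to [buildGrid()].
#' @return an [XLCandidateSet-class]. For structures with more than two
#'   chains `inter_ab`/`inter_ba` are `NA` and only `shortest_inter` is
#'   meaningful.
#' @export
enumerateCandidates <- function(structure, method = c("EUC", "SASD"),
                                threshold = 33, grid = NULL,
                                accessRadius = 4.0, connectivity = 26,
                                cutoff = Inf, ...) {
  method <- match.arg(method)
  ch <- chainIds(structure)
  if (length(ch) < 2L) stop("homo-oligomer with >= 2 chains required")
  lys <- lysineCalpha(structure)
  perChain <- split(lys, lys$chain)[ch]
  resnos <- sort(unique(perChain[[1]]$resno))
  for (c2 in ch[-1]) {
    if (!identical(sort(unique(perChain[[c2]]$resno)), resnos))
      stop("chains differ in lysine content; recreate the reference first")
  }
  if (length(resnos) == 0L)
    return(new("XLCandidateSet",
               data = data.frame(res_i = integer(), res_j = integer(),
                                 intra = numeric(), inter_ab = numeric(),
                                 inter_ba = numeric(),
                                 shortest_inter = numeric()),
               method = method, threshold = threshold))

  # endpoint coordinates: sources = chain-1 lysines; targets = all lysines
  pos <- function(c, r) {
    row <- perChain[[c]][perChain[[c]]$resno == r, , drop = FALSE]
    as.numeric(row[1, c("x", "y", "z")])
  }
  src <- t(vapply(resnos, function(r) pos(ch[1], r), numeric(3)))
  tgtKey <- expand.grid(resno = resnos, chain = ch,
                        stringsAsFactors = FALSE)
  tgt <- t(vapply(seq_len(nrow(tgtKey)),
                  function(i) pos(tgtKey$chain[i], tgtKey$resno[i]),
                  numeric(3)))
  if (method == "EUC") {
    D2 <- outer(rowSums(src^2), rowSums(tgt^2), "+") - 2 * src %*% t(tgt)
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
  } else {
    if (is.null(grid)) grid <- buildGrid(structure, ...)
    D <- sasdMatrix(grid, src, tgt, accessRadius = accessRadius,
                    connectivity = connectivity, cutoff = cutoff)
  }
  lookup <- function(rSrc, chainTgt, rTgt) {
    D[match(rSrc, resnos),
      which(tgtKey$chain == chainTgt & tgtKey$resno == rTgt)]
  }

  pairs <- expand.grid(res_i = resnos, res_j = resnos)
  pairs <- pairs[pairs$res_i <= pairs$res_j, , drop = FALSE]
  n <- nrow(pairs)
  intra <- inter_ab <- inter_ba <- shortest <- rep(NA_real_, n)
  others <- ch[-1]
  for (k in seq_len(n)) {
    ri <- pairs$res_i[k]; rj <- pairs$res_j[k]
    if (ri != rj) intra[k] <- lookup(ri, ch[1], rj)
    # all inter chain combinations with >= 1 endpoint in chain 1
    alts <- c(vapply(others, function(c2) lookup(ri, c2, rj), 0),
              vapply(others, function(c2) lookup(rj, c2, ri), 0))
    fin <- alts[!is.na(alts)]
    shortest[k] <- if (length(fin)) min(fin) else NA_real_
    if (length(ch) == 2L) {
      inter_ab[k] <- alts[1]
      inter_ba[k] <- alts[2]
    }
  }
  dat <- data.frame(res_i = pairs$res_i, res_j = pairs$res_j, intra = intra,
                    inter_ab = inter_ab, inter_ba = inter_ba,
                    shortest_inter = shortest)
  rownames(dat) <- NULL
  new("XLCandidateSet", data = dat, method = method, threshold = threshold)
}

#' @describeIn XLCandidateSet-accessors candidate table (data.frame).
#' @export
candidates <- function(x) x@data

#' Accessors for XLCandidateSet
#' @param x an [XLCandidateSet-class].
#' @name XLCandidateSet-accessors
NULL

setMethod("show", "XLCandidateSet", function(object) {
  cat("XLCandidateSet:", nrow(object@data), "candidate pair(s), method",
      object@method, ", threshold", object@threshold, "A\n")
  if (nrow(object@data)) {
    lab <- classifyCandidates(object)
    print(table(lab))
  }
})

#' Classify one candidate pair
#'
#' Four-way rule at the linker threshold: `INTRA` if only the intra
#' alternative is at or below the threshold, `INTER` if only the (shortest)
#' inter alternative is, `AMBIGUOUS` if both are, `NON_ACCESSIBLE` otherwise.
#' A non-accessible distance (`NA`) never satisfies the threshold.
#'
#' @param intra,inter distances in Angstrom (`NA` = non-accessible).
#' @param threshold linker threshold in Angstrom (default 33).
#' @return one of `"INTRA"`, `"INTER"`, `"AMBIGUOUS"`, `"NON_ACCESSIBLE"`.
#' @export
classifyPair <- function(intra, inter, threshold = 33) {
  mi <- isMatched(intra, threshold)
  me <- isMatched(inter, threshold)
  ifelse(mi & me, "AMBIGUOUS",
         ifelse(mi, "INTRA", ifelse(me, "INTER", "NON_ACCESSIBLE")))
}

#' Classify all candidates of a set
#'
#' @param candset an [XLCandidateSet-class].
#' @param threshold linker threshold; defaults to the set's own.
#' @return factor with levels INTRA, INTER, AMBIGUOUS, NON_ACCESSIBLE, one
#'   label per candidate.
#' @export
classifyCandidates <- function(candset, threshold = candset@threshold) {
  d <- candset@data
  factor(classifyPair(d$intra, d$shortest_inter, threshold),
         levels = xlLabels)
}

#' Cross-tabulate EUC vs SASD assignments
#'
#' Joint and marginal fractions of the 4 x 4 assignment table of the same
#' candidate set classified with Euclidean and with solvent-accessible-surface
#' distances, plus EUC marginals across a threshold sweep. By default only
#' pairs with the intra or inter EUC alternative matched at `filterThreshold`
#' and with both alternatives calculable are counted (the comparison filter);
#' set `applyFilter = FALSE` to keep every pair.
#'
#' @param candEuc,candSasd [XLCandidateSet-class] objects over the same
#'   residue pairs, methods EUC and SASD.
#' @param thresholds thresholds (Angstrom) for the EUC sweep,
#'   default `c(33, 30, 27, 25)`.
#' @param applyFilter apply the EUC-matched + both-calculable filter.
#' @param filterThreshold threshold used by the filter (default 33).
#' @return list with `joint` (4 x 4 fraction matrix, EUC rows, SASD columns),
#'   `eucMarginal`, `sasdMarginal`, `sweep` (threshold x label fraction
#'   matrix), and `n` (pairs counted).
#' @export
assignmentStatistics <- function(candEuc, candSasd,
                                 thresholds = c(33, 30, 27, 25),
                                 applyFilter = TRUE, filterThreshold = 33) {
  de <- candEuc@data; ds <- candSasd@data
  if (!identical(de[, c("res_i", "res_j")], ds[, c("res_i", "res_j")]))
    stop("candidate sets cover different residue pairs")
  keep <- rep(TRUE, nrow(de))
  if (applyFilter) {
    keep <- (isMatched(de$intra, filterThreshold) |
               isMatched(de$shortest_inter, filterThreshold)) &
      !is.na(de$intra) & !is.na(de$shortest_inter)
  }
  n <- sum(keep)
  if (n == 0L) stop("no candidate pairs pass the comparison filter")
  le <- factor(classifyPair(de$intra[keep], de$shortest_inter[keep],
                            filterThreshold), levels = xlLabels)
  ls <- factor(classifyPair(ds$intra[keep], ds$shortest_inter[keep],
                            filterThreshold), levels = xlLabels)
  joint <- table(EUC = le, SASD = ls) / n
  sweepTab <- t(vapply(thresholds, function(th) {
    lab <- factor(classifyPair(de$intra[keep], de$shortest_inter[keep], th),
                  levels = xlLabels)
    as.numeric(table(lab)) / n
  }, numeric(4)))
  dimnames(sweepTab) <- list(threshold = thresholds, label = xlLabels)
  list(joint = unclass(joint),
       eucMarginal = rowSums(joint), sasdMarginal = colSums(joint),
       sweep = sweepTab, n = n)
}

#' Differences between the two oriented inter-subunit alternatives
#'
#' For each dimer candidate with both oriented inter alternatives finite,
#' returns |inter_AB - inter_BA| in Angstrom. On an exactly C2-symmetric
#' structure all differences vanish; on asymmetric decoys they measure how
#' far the model departs from symmetry at each cross-link.
#'
#' @param candset an [XLCandidateSet-class] from a two-chain structure.
#' @return numeric vector of nonnegative differences.
#' @export
symmetryDifferences <- function(candset) {
  d <- candset@data
  ok <- !is.na(d$inter_ab) & !is.na(d$inter_ba) &
    is.finite(d$inter_ab) & is.finite(d$inter_ba)
  abs(d$inter_ab[ok] - d$inter_ba[ok])
}
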