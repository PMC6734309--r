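# The MNXL (Matched and Non-accessible cross-link) score and its family of
# scoring-function variants for homo-dimer models.
#
# A distance is "matched" when finite, accessible and at or below the linker
# threshold; matched distances score the Gaussian density N(mu, sigma2)
# evaluated at the distance, everything else the fixed penalty. A model's
# total is the sum over cross-links of inter-subunit contributions, shaped by
# four axes evaluated in a fixed order:
#   inclusion -> symmetry -> orientation -> ambiguity
# Cross-links gated out by inclusion or symmetry contribute exactly 0.0.

#' Construct a scoring configuration
#'
#' @param method distance method, `"EUC"` or `"SASD"`.
#' @param ambiguity `"NORMAL"` or `"OBLIVIOUS"`.
#' @param orientation `"ORIENTED"` or `"STRINGENT"`.
#' @param inclusion `"ALL"`, `"ONLY_BEST"` or `"NON_INTRA"`.
#' @param symmetry `"NONE"`, `"SYMMETRY_MATCHED"` or `"SYMMETRY_DIFFERENCE"`.
#' @param mu,sigma2 matched-score Gaussian mean (Angstrom) and variance
#'   (Angstrom^2); defaults 18.62 and 35.94, fitted on an experimental
#'   cross-link database.
#' @param threshold linker threshold (Angstrom, default 33).
#' @param penalty non-accessible penalty (default -0.1).
#' @param neutral neutral replacement value (default 0).
#' @param symDiffCutoff symmetry-difference cutoff (Angstrom, default 5).
#' @return a [ScoringConfig-class].
#' @seealso [scoringPreset()] for the named variants.
#' @export
scoringConfig <- function(method = c("SASD", "EUC"),
                          ambiguity = c("NORMAL", "OBLIVIOUS"),
                          orientation = c("ORIENTED", "STRINGENT"),
                          inclusion = c("ALL", "ONLY_BEST", "NON_INTRA"),
                          symmetry = c("NONE", "SYMMETRY_MATCHED",
                                       "SYMMETRY_DIFFERENCE"),
                          mu = 18.62, sigma2 = 35.94, threshold = 33,
                          penalty = -0.1, neutral = 0, symDiffCutoff = 5) {
  new("ScoringConfig", method = match.arg(method),
      ambiguity = match.arg(ambiguity), orientation = match.arg(orientation),
      inclusion = match.arg(inclusion), symmetry = match.arg(symmetry),
      mu = mu, sigma2 = sigma2, threshold = threshold, penalty = penalty,
      neutral = neutral, symDiffCutoff = symDiffCutoff)
}

#' Named scoring-function presets
#'
#' The named variants of the scoring-function family:
#' `oblivious-oriented`, `oblivious-stringent`, `normal-oriented`,
#' `normal-stringent` (inclusion ALL), the inclusion options
#' `normal-oriented-only-best`, `normal-oriented-non-intra`,
#' `normal-stringent-only-best`, `normal-stringent-non-intra`, and the
#' symmetry-imposing `symmetry-matched` and `symmetry-difference` (Normal
#' ambiguity, oriented aggregation, inclusion ALL).
#'
#' @param name preset name (see above).
#' @param method distance method, `"SASD"` (default) or `"EUC"`.
#' @param ... overrides passed to [scoringConfig()].
#' @return a [ScoringConfig-class].
#' @export
scoringPreset <- function(name, method = "SASD", ...) {
  presets <- list(
    "oblivious-oriented"         = c("OBLIVIOUS", "ORIENTED", "ALL", "NONE"),
    "oblivious-stringent"        = c("OBLIVIOUS", "STRINGENT", "ALL", "NONE"),
    "normal-oriented"            = c("NORMAL", "ORIENTED", "ALL", "NONE"),
    "normal-stringent"           = c("NORMAL", "STRINGENT", "ALL", "NONE"),
    "normal-oriented-only-best"  = c("NORMAL", "ORIENTED", "ONLY_BEST", "NONE"),
    "normal-oriented-non-intra"  = c("NORMAL", "ORIENTED", "NON_INTRA", "NONE"),
    "normal-stringent-only-best" = c("NORMAL", "STRINGENT", "ONLY_BEST", "NONE"),
    "normal-stringent-non-intra" = c("NORMAL", "STRINGENT", "NON_INTRA", "NONE"),
    "symmetry-matched"    = c("NORMAL", "ORIENTED", "ALL", "SYMMETRY_MATCHED"),
    "symmetry-difference" = c("NORMAL", "ORIENTED", "ALL",
                              "SYMMETRY_DIFFERENCE"))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  scoringConfig(method = method, ambiguity = p[1], orientation = p[2],
                inclusion = p[3], symmetry = p[4], ...)
}

setMethod("show", "ScoringConfig", function(object) {
  cat(sprintf("ScoringConfig: %s | %s-%s | inclusion %s | symmetry %s\n",
              object@method, object@ambiguity, object@orientation,
              object@inclusion, object@symmetry))
  cat(sprintf("  N(%.2f, %.2f), threshold %.1f A, penalty %.2f, sym cutoff %.1f A\n",
              object@mu, object@sigma2, object@threshold, object@penalty,
              object@symDiffCutoff))
})

#' The MNXL score of a single distance
#'
#' Matched distances (at or below the threshold, accessible) score the
#' density of Normal(`mu`, `sigma2`) at the distance; greater distances and
#' non-accessible alternatives (`NA`) score the penalty.
#'
#' @param distance distance in Angstrom, `Inf` for beyond-cutoff, or `NA` for
#'   a non-accessible alternative. Vectorized.
#' @param config a [ScoringConfig-class] (only the numeric constants are
#'   used).
#' @return numeric score(s).
#' @export
mnxl <- function(distance, config = scoringConfig()) {
  if (any(!is.na(distance) & distance < 0))
    stop("distances must be nonnegative")
  matched <- isMatched(distance, config@threshold)
  out <- rep(config@penalty, length(distance))
  out[matched] <- dnorm(distance[matched], mean = config@mu,
                        sd = sqrt(config@sigma2))
  out
}

#' Inter-subunit contribution of one cross-link to a model's total
#'
#' Applies the four configuration axes in fixed order to the cross-link's
#' distances in one model (intra-subunit alternative plus the two oriented
#' inter-subunit alternatives A-B and B-A):
#' 1. *inclusion* gates whether the inter alternatives are considered at all
#'    (`ALL`; `ONLY_BEST`: only if the better inter MNXL score beats the intra
#'    score; `NON_INTRA`: only if the intra alternative is non-accessible);
#' 2. *symmetry* gates on the oriented pair (`SYMMETRY_MATCHED`: both matched;
#'    `SYMMETRY_DIFFERENCE`: at least one matched and the two distances within
#'    the cutoff of each other);
#' 3. *orientation* aggregates the two oriented alternatives (`ORIENTED`:
#'    both scored separately and summed; `STRINGENT`: only the higher score);
#' 4. *ambiguity* governs penalties (`OBLIVIOUS`: verbatim; `NORMAL`: an inter
#'    penalty is replaced by the neutral 0.0 when the intra alternative is
#'    matched — substitution happens before the STRINGENT max).
#' A cross-link gated out at step 1 or 2 contributes exactly 0.0.
#'
#' @param intra intra-subunit distance (Angstrom; `NA` = non-accessible,
#'   including undefined self-pair intra).
#' @param interAB,interBA the two oriented inter-subunit distances.
#' @param config a [ScoringConfig-class].
#' @return list with `score` and an audit `record` (gating decision and the
#'   per-alternative scores entering the total).
#' @export
crosslinkContribution <- function(intra, interAB, interBA, config) {
  T <- config@threshold
  intraMatched <- isMatched(intra, T)
  sIntra <- mnxl(intra, config)
  rawAB <- mnxl(interAB, config)
  rawBA <- mnxl(interBA, config)

  # ONLY_BEST compares the better oriented inter score against the intra
  # score; ties (possible only when both are the penalty) are included, so
  # the gated-in sets nest: NON_INTRA <= ONLY_BEST <= ALL.
  included <- switch(config@inclusion,
    ALL = TRUE,
    ONLY_BEST = max(rawAB, rawBA) >= sIntra,
    NON_INTRA = !intraMatched)
  gate <- if (included) "included" else "excluded-inclusion"

  if (included && config@symmetry != "NONE") {
    mAB <- isMatched(interAB, T)
    mBA <- isMatched(interBA, T)
    symOk <- switch(config@symmetry,
      SYMMETRY_MATCHED = mAB && mBA,
      SYMMETRY_DIFFERENCE = (mAB || mBA) &&
        !is.na(interAB) && !is.na(interBA) &&
        is.finite(interAB) && is.finite(interBA) &&
        abs(interAB - interBA) < config@symDiffCutoff)
    if (!symOk) { included <- FALSE; gate <- "excluded-symmetry" }
  }

  if (!included)
    return(list(score = 0.0,
                record = list(gate = gate, scoreAB = NA_real_,
                              scoreBA = NA_real_)))

  substitute <- function(s) {
    if (config@ambiguity == "NORMAL" && s == config@penalty && intraMatched)
      config@neutral else s
  }
  sAB <- substitute(rawAB)
  sBA <- substitute(rawBA)
  score <- switch(config@orientation,
    ORIENTED = sAB + sBA,
    STRINGENT = max(sAB, sBA))
  list(score = score,
       record = list(gate = gate, scoreAB = sAB, scoreBA = sBA))
}

# Per-model distance table for a cross-link set: intra (reference, rigid
# subunits) and both oriented inter alternatives computed on the model.
# Returns data.frame res_i, res_j, intra, inter_ab, inter_ba.
modelDistanceTable <- function(model, xlSet, method, intraTable = NULL,
                               accessRadius = 4.0, connectivity = 26,
                               cutoff = Inf, ...) {
  ch <- chainIds(model)
  if (length(ch) != 2L) stop("dimer model required")
  lys <- lysineCalpha(model)
  l1 <- lys[lys$chain == ch[1], , drop = FALSE]
  l2 <- lys[lys$chain == ch[2], , drop = FALSE]
  need <- sort(unique(c(xlSet$res_i, xlSet$res_j)))
  missing <- setdiff(need, l1$resno)
  if (length(missing))
    stop("cross-link residues absent from the model: ",
         paste(missing, collapse = ", "))
  p1 <- as.matrix(l1[match(need, l1$resno), c("x", "y", "z")])
  p2 <- as.matrix(l2[match(need, l2$resno), c("x", "y", "z")])
  if (method == "EUC") {
    eucMat <- function(a, b) {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
      d2[d2 < 0] <- 0
      sqrt(d2)
    }
    interD <- eucMat(p1, p2)
    intraD <- eucMat(p1, p1)
  } else {
    grid <- buildGrid(model, ...)
    interD <- sasdMatrix(grid, p1, p2, accessRadius = accessRadius,
                         connectivity = connectivity, cutoff = cutoff)
    intraD <- if (is.null(intraTable))
      sasdMatrix(grid, p1, p1, accessRadius = accessRadius,
                 connectivity = connectivity, cutoff = cutoff)
    else NULL
  }
  idx <- function(r) match(r, need)
  intra <- numeric(nrow(xlSet))
  for (k in seq_len(nrow(xlSet))) {
    ri <- xlSet$res_i[k]; rj <- xlSet$res_j[k]
    intra[k] <- if (ri == rj) NA_real_
    else if (!is.null(intraTable)) {
      m <- intraTable$intra[(intraTable$res_i == min(ri, rj)) &
                              (intraTable$res_j == max(ri, rj))]
      if (length(m) == 1L) m else NA_real_
    } else intraD[idx(ri), idx(rj)]
  }
  data.frame(res_i = xlSet$res_i, res_j = xlSet$res_j, intra = intra,
             inter_ab = interD[cbind(idx(xlSet$res_i), idx(xlSet$res_j))],
             inter_ba = interD[cbind(idx(xlSet$res_j), idx(xlSet$res_i))])
}

#' Score a model against a cross-link set
#'
#' Computes the cross-links' intra and oriented inter distances on the model
#' with the configuration's method and totals the per-cross-link
#' inter-subunit contributions.
#'
#' @param xlSet cross-link data.frame (`res_i`, `res_j`), e.g. from
#'   [simulateCrosslinks()].
#' @param model a dimer [XLStructure-class].
#' @param config a [ScoringConfig-class].
#' @param intraTable optional data.frame (`res_i`, `res_j`, `intra`) of
#'   intra-subunit distances precomputed on the reference; with rigid
#'   subunits these are identical across decoys and need not be recomputed.
#' @param distances optional precomputed per-model distance table (internal
#'   reuse across configurations sharing a method).
#' @param modelId identifier stored in the result (default 1).
#' @param ... SASD parameters passed through (see [sasdDistance()],
#'   [buildGrid()]).
#' @return list with `modelId`, `total`, and `breakdown` (per-cross-link
#'   contributions and gating records).
#' @export
scoreModel <- function(xlSet, model, config, intraTable = NULL,
                       distances = NULL, modelId = 1L, ...) {
  if (nrow(xlSet) == 0L) stop("empty cross-link set")
  if (is.null(distances))
    distances <- modelDistanceTable(model, xlSet, config@method,
                                    intraTable = intraTable, ...)
  contribs <- lapply(seq_len(nrow(distances)), function(k)
    crosslinkContribution(distances$intra[k], distances$inter_ab[k],
                          distances$inter_ba[k], config))
  scores <- vapply(contribs, `[[`, 0, "score")
  breakdown <- data.frame(res_i = distances$res_i, res_j = distances$res_j,
                          contribution = scores,
                          gate = vapply(contribs, function(x) x$record$gate,
                                        ""))
  list(modelId = modelId, total = sum(scores), breakdown = breakdown)
}

#' Rank models by total score
#'
#' Descending by total; ties broken by ascending model id for determinism.
#'
#' @param modelScores list of [scoreModel()] results, or a data.frame with
#'   columns `modelId` and `total`.
#' @return data.frame with columns `rank`, `modelId`, `total`.
#' @export
rankModels <- function(modelScores) {
  if (is.data.frame(modelScores)) df <- modelScores
  else df <- data.frame(
    modelId = vapply(modelScores, function(m) as.numeric(m$modelId), 0),
    total = vapply(modelScores, function(m) as.numeric(m$total), 0))
  if (nrow(df) == 0L) stop("no model scores to rank")
  ord <- order(-df$total, df$modelId)
  out <- data.frame(rank = seq_len(nrow(df)), modelId = df$modelId[ord],
                    total = df$total[ord])
  rownames(out) <- NULL
  out
}
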