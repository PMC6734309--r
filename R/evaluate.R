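# Model evaluation: C-alpha RMSD against the recreated reference, top-k
# near-native precision and the benchmark harness across scoring
# configurations.

#' C-alpha RMSD of a dimer model against a reference
#'
#' Whole-complex C-alpha RMSD after optimal rigid superposition, minimized
#' over the two homo-dimer chain mappings (1-1/2-2 and 1-2/2-1): both chains
#' of a recreated reference are identical, so their labels are arbitrary.
#'
#' @param model,reference two-chain [XLStructure-class] objects sharing
#'   chain/residue composition.
#' @return RMSD in Angstrom.
#' @export
caRMSD <- function(model, reference) {
  chM <- chainIds(model); chR <- chainIds(reference)
  if (length(chM) != 2L || length(chR) != 2L)
    stop("both structures must have exactly two chains")
  caM <- calpha(model); caR <- calpha(reference)
  key <- function(df) paste(df$resno, df$icode)
  one <- function(mapping) {
    pieces <- lapply(1:2, function(i) {
      m <- caM[caM$chain == chM[i], , drop = FALSE]
      r <- caR[caR$chain == chR[mapping[i]], , drop = FALSE]
      common <- intersect(key(m), key(r))
      if (length(common) == 0L) return(NULL)
      list(m = as.matrix(m[match(common, key(m)), c("x", "y", "z")]),
           r = as.matrix(r[match(common, key(r)), c("x", "y", "z")]))
    })
    if (any(vapply(pieces, is.null, TRUE)))
      stop("model and reference share no residues under a chain mapping")
    M <- do.call(rbind, lapply(pieces, `[[`, "m"))
    R <- do.call(rbind, lapply(pieces, `[[`, "r"))
    if (nrow(M) != nrow(caM))
      stop("model and reference differ in C-alpha composition")
    kabschSuperpose(M, R)$rmsd
  }
  min(one(c(1L, 2L)), one(c(2L, 1L)))
}

#' Top-k near-native precision of a ranked ensemble
#'
#' Precision = 100 x (near-native models among the top k) / min(k, n), where
#' a model is near-native when its C-alpha RMSD to the recreated reference is
#' at or below `cutoff`.
#'
#' @param ranking data.frame from [rankModels()].
#' @param rmsd named numeric vector of per-model RMSD (names = model ids), or
#'   a function `modelId -> RMSD`.
#' @param k number of top models (default 10).
#' @param cutoff near-native RMSD cutoff in Angstrom (default 10).
#' @return list with `precision` (percent), `k`, `cutoff`, and `perModel`
#'   (rank, model id, total score, rmsd, near-native flag).
#' @export
precisionAtK <- function(ranking, rmsd, k = 10, cutoff = 10) {
  if (nrow(ranking) == 0L) stop("empty ranking")
  r <- if (is.function(rmsd))
    vapply(ranking$modelId, rmsd, 0)
  else as.numeric(rmsd[as.character(ranking$modelId)])
  if (anyNA(r)) stop("missing RMSD for some ranked models")
  per <- data.frame(rank = ranking$rank, modelId = ranking$modelId,
                    total = ranking$total, rmsd = r,
                    nearNative = r <= cutoff)
  kEff <- min(k, nrow(per))
  list(precision = 100 * sum(per$nearNative[seq_len(kEff)]) / kEff,
       k = k, cutoff = cutoff, perModel = per)
}

#' Run the precision benchmark across scoring configurations
#'
#' For each reference: recreate the dimer, simulate cross-links (SASD at the
#' linker threshold), generate a rigid-body decoy ensemble, score every decoy
#' under every configuration, rank, and measure top-k near-native precision.
#' References without simulated cross-links or with fewer than `minNearNative`
#' decoys at or below the RMSD cutoff are excluded (logged), mirroring the
#' usual benchmark filter. Fully seeded and reproducible.
#'
#' @param references list of two-chain [XLStructure-class] objects (e.g. from
#'   [makeToyDimer()]).
#' @param configs named list of [ScoringConfig-class] objects.
#' @param nModels,nearNativeFraction,maxPerturbation decoy-generation
#'   parameters, see [generateDecoys()].
#' @param seed integer master seed; per-structure seeds are derived from it.
#' @param k,cutoff precision parameters (defaults 10 and 10 A).
#' @param threshold linker threshold (Angstrom, default 33).
#' @param minNearNative exclusion rule: a reference with fewer near-native
#'   decoys than this is skipped (default 10).
#' @param sasdCutoff distance cutoff (Angstrom) for the per-model SASD path
#'   search. Any distance above `threshold + symDiffCutoff` behaves
#'   identically in every scoring function (it scores the penalty, and a
#'   symmetry-difference gate with a matched partner cannot be satisfied), so
#'   the default `threshold + 5.1` leaves every score and gate unchanged
#'   while bounding the search.
#' @param verbose print progress.
#' @return list with `perStructure` (data.frame: structure, config,
#'   precision, nModels, nNearNative), `summary` (config, mean, sem, n) and
#'   `excluded` (structure ids with reasons). SEM is the sample standard
#'   deviation over structures divided by sqrt(n).
#' @export
runBenchmark <- function(references, configs, nModels = 200,
                         nearNativeFraction = 0.1, maxPerturbation = 3,
                         seed = 1, k = 10, cutoff = 10, threshold = 33,
                         minNearNative = 10, sasdCutoff = threshold + 5.1,
                         verbose = FALSE) {
  if (length(references) < 1L) stop("at least one reference required")
  if (length(configs) < 1L) stop("at least one configuration required")
  if (is.null(names(configs)))
    names(configs) <- paste0("config", seq_along(configs))
  methods <- unique(vapply(configs, function(cf) cf@method, ""))
  rows <- list(); excluded <- list()
  for (s in seq_along(references)) {
    sid <- if (!is.null(names(references))) names(references)[s]
    else paste0("structure", s)
    ref <- recreateReference(references[[s]])
    refCand <- enumerateCandidates(ref, method = "SASD",
                                   threshold = threshold)
    xls <- withCallingHandlers(
      simulateCrosslinks(ref, threshold, candidateSet = refCand),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(xls) == 0L) {
      excluded[[sid]] <- "no simulated cross-links"
      next
    }
    decoys <- generateDecoys(ref, nModels = nModels,
                             nearNativeFraction = nearNativeFraction,
                             maxPerturbation = maxPerturbation,
                             seed = (seed * 1000L + s) %% .Machine$integer.max)
    models <- lapply(decoys@modelIds, function(id) getModel(decoys, id))
    rmsd <- vapply(models, caRMSD, 0, reference = ref)
    names(rmsd) <- decoys@modelIds
    if (sum(rmsd <= cutoff) < minNearNative) {
      excluded[[sid]] <- sprintf("fewer than %d near-native decoys",
                                 minNearNative)
      next
    }
    # intra distances once per reference (rigid subunits)
    intraTables <- lapply(methods, function(m) {
      cand <- if (m == "SASD") refCand
      else enumerateCandidates(ref, method = "EUC", threshold = threshold)
      cand@data[, c("res_i", "res_j", "intra")]
    })
    names(intraTables) <- methods
    # distance tables once per (model, method); shared across configs
    distTables <- lapply(methods, function(m) {
      lapply(models, function(mod)
        modelDistanceTable(mod, xls, m, intraTable = intraTables[[m]],
                           cutoff = if (m == "SASD") sasdCutoff else Inf))
    })
    names(distTables) <- methods
    for (cn in names(configs)) {
      cf <- configs[[cn]]
      scores <- lapply(seq_along(models), function(i)
        scoreModel(xls, models[[i]], cf,
                   distances = distTables[[cf@method]][[i]],
                   modelId = decoys@modelIds[i]))
      pr <- precisionAtK(rankModels(scores), rmsd, k = k, cutoff = cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = sid, config = cn, precision = pr$precision,
        nModels = length(models), nNearNative = sum(rmsd <= cutoff))
    }
    if (verbose)
      message(sid, ": ", sum(rmsd <= cutoff), "/", length(models),
              " near-native decoys")
  }
  if (length(rows) == 0L)
    stop("every reference was excluded from the benchmark")
  perStructure <- do.call(rbind, rows)
  rownames(perStructure) <- NULL
  summ <- do.call(rbind, lapply(split(perStructure, perStructure$config),
                                function(d) data.frame(
                                  config = d$config[1],
                                  mean = mean(d$precision),
                                  sem = stats::sd(d$precision) /
                                    sqrt(nrow(d)),
                                  n = nrow(d))))
  summ <- summ[match(names(configs)[names(configs) %in% summ$config],
                     summ$config), ]
  rownames(summ) <- NULL
  list(perStructure = perStructure, summary = summ,
       excluded = excluded)
}
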