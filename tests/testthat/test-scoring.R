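# The MNXL score and the scoring-function family.

test_that("mnxl rewards matched distances with the Gaussian density and
           penalizes everything else", {
  cfg <- scoringConfig()
  # density oracle computed from the explicit formula
  dens <- function(d) exp(-(d - 18.62)^2 / (2 * 35.94)) / sqrt(2 * pi * 35.94)

  expect_equal(mnxl(40, cfg), -0.1)
  expect_equal(mnxl(NA_real_, cfg), -0.1)
  expect_equal(mnxl(Inf, cfg), -0.1)
  expect_equal(mnxl(18.62, cfg), dens(18.62), tolerance = 1e-12)
  expect_equal(mnxl(18.62, cfg), 0.0665458, tolerance = 1e-6)
  expect_equal(mnxl(33, cfg), dens(33), tolerance = 1e-12)
  expect_equal(mnxl(33, cfg), 0.0037475, tolerance = 1e-5)
  # boundary: 33 is matched, barely above is not
  expect_gt(mnxl(33, cfg), 0)
  expect_equal(mnxl(33.0001, cfg), -0.1)
  expect_error(mnxl(-1, cfg), "nonnegative")

  # strictly positive on [0, T], unimodal with mode at mu
  ds <- seq(0, 33, by = 0.25)
  vals <- mnxl(ds, cfg)
  expect_true(all(vals > 0))
  expect_equal(ds[which.max(vals)], 18.5)   # grid point nearest the mode
  expect_true(all(diff(vals[ds <= 18.5]) > 0))
  expect_true(all(diff(vals[ds >= 18.75]) < 0))
})

test_that("crosslinkContribution follows the documented axis rules", {
  cfg <- function(...) scoringConfig(...)
  # intra matched, both inter penalized: NORMAL neutralizes, OBLIVIOUS stacks
  expect_equal(crosslinkContribution(20, 40, 41,
                                     cfg(ambiguity = "NORMAL"))$score, 0)
  expect_equal(crosslinkContribution(20, 40, 41,
                                     cfg(ambiguity = "OBLIVIOUS"))$score, -0.2)
  # NON_INTRA excludes when intra is matched even if inter is good
  expect_equal(crosslinkContribution(20, 25, 25,
                                     cfg(inclusion = "NON_INTRA"))$score, 0)
  # symmetry-difference gate: 19 vs 30 differ by >= 5 -> excluded
  expect_equal(crosslinkContribution(NA, 19, 30,
                                     cfg(symmetry = "SYMMETRY_DIFFERENCE"))$score,
               0)
  # symmetry-matched needs both alternatives matched
  expect_equal(crosslinkContribution(NA, 19, 40,
                                     cfg(symmetry = "SYMMETRY_MATCHED"))$score,
               0)
  expect_gt(crosslinkContribution(NA, 19, 20,
                                  cfg(symmetry = "SYMMETRY_MATCHED"))$score, 0)
  # STRINGENT takes the better alternative only
  st <- crosslinkContribution(NA, 19, 25, cfg(orientation = "STRINGENT"))
  expect_equal(st$score, mnxl(19, cfg()), tolerance = 1e-12)
})

test_that("every configuration matches the literal rule oracle on canonical
           and random scenarios", {
  grid <- allScoringConfigs()
  scenarios <- canonicalScenarios()
  set.seed(99)
  for (i in 1:100) scenarios[[length(scenarios) + 1]] <- randomScenario()
  for (k in seq_len(nrow(grid))) {
    cfg <- scoringConfig(ambiguity = grid$ambiguity[k],
                         orientation = grid$orientation[k],
                         inclusion = grid$inclusion[k],
                         symmetry = grid$symmetry[k])
    for (sc in scenarios) {
      got <- crosslinkContribution(sc[1], sc[2], sc[3], cfg)$score
      want <- ruleOracle(sc[1], sc[2], sc[3], grid$inclusion[k],
                         grid$symmetry[k], grid$orientation[k],
                         grid$ambiguity[k])
      expect_equal(got, want, tolerance = 1e-12,
                   info = paste(unlist(grid[k, ]), collapse = "-"))
    }
  }
})

test_that("NORMAL dominates OBLIVIOUS and inclusion options nest", {
  set.seed(123)
  for (i in 1:100) {
    sc <- randomScenario()
    for (orient in c("ORIENTED", "STRINGENT")) {
      n <- crosslinkContribution(sc[1], sc[2], sc[3],
                                 scoringConfig(ambiguity = "NORMAL",
                                               orientation = orient))$score
      o <- crosslinkContribution(sc[1], sc[2], sc[3],
                                 scoringConfig(ambiguity = "OBLIVIOUS",
                                               orientation = orient))$score
      expect_gte(n, o - 1e-12)
    }
    # gated-in indicator: NON_INTRA subset of ONLY_BEST subset of ALL
    gated <- vapply(c("NON_INTRA", "ONLY_BEST", "ALL"), function(inc)
      crosslinkContribution(sc[1], sc[2], sc[3],
                            scoringConfig(inclusion = inc))$record$gate ==
        "included", TRUE)
    expect_true(!gated["NON_INTRA"] || gated["ONLY_BEST"])
    expect_true(!gated["ONLY_BEST"] || gated["ALL"])
  }
})

test_that("scoreModel totals per-cross-link contributions and respects the
           simulation guarantee", {
  ref <- recreateReference(makeToyDimer(seed = 1))
  cand <- enumerateCandidates(ref, "SASD")
  xl <- simulateCrosslinks(ref, candidateSet = cand)
  intraT <- candidates(cand)[, c("res_i", "res_j", "intra")]
  cfg <- scoringPreset("normal-oriented", "SASD")
  sc <- scoreModel(xl, ref, cfg, intraTable = intraT)
  expect_equal(sc$total, sum(sc$breakdown$contribution), tolerance = 1e-12)
  # reference scored against its own simulated set, NORMAL ambiguity:
  # no negative contributions (every pair is matched intra or inter)
  expect_true(all(sc$breakdown$contribution > -1e-12))

  # gating everything out gives exactly zero
  far <- xl[1, , drop = FALSE]
  cfgSym <- scoringConfig(symmetry = "SYMMETRY_MATCHED")
  scFar <- scoreModel(far, ref, cfgSym, intraTable = intraT,
                      distances = data.frame(res_i = far$res_i,
                                             res_j = far$res_j,
                                             intra = 20, inter_ab = 50,
                                             inter_ba = NA))
  expect_identical(scFar$total, 0)

  # total is invariant under cross-link reordering
  sc2 <- scoreModel(xl[rev(seq_len(nrow(xl))), ], ref, cfg,
                    intraTable = intraT)
  expect_equal(sc2$total, sc$total, tolerance = 1e-12)

  expect_error(scoreModel(xl[0, ], ref, cfg), "empty")
  bad <- data.frame(res_i = 9999, res_j = 1)
  expect_error(scoreModel(bad, ref, cfg), "absent")
})

test_that("rankModels sorts by score with deterministic tie-breaks", {
  ms <- list(list(modelId = 1L, total = 0.2), list(modelId = 2L, total = 0.5),
             list(modelId = 3L, total = -0.1))
  r <- rankModels(ms)
  expect_equal(r$modelId, c(2, 1, 3))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(modelId = c(5, 2, 9), total = c(1, 1, 1))
  expect_equal(rankModels(tie)$modelId, c(2, 5, 9))

  set.seed(8)
  df <- data.frame(modelId = 1:50, total = round(runif(50), 2))
  got <- rankModels(df)$modelId
  want <- df$modelId[order(-df$total, df$modelId)]
  expect_equal(got, want)
})

test_that("on an exact C2 model ORIENTED totals twice STRINGENT when all
           gated alternatives are matched", {
  ref <- recreateReference(makeToyDimer(seed = 4))
  cand <- enumerateCandidates(ref, "EUC")
  dd <- candidates(cand)
  # keep only cross-links whose inter alternatives are both matched
  sel <- !is.na(dd$inter_ab) & dd$inter_ab <= 33 &
    !is.na(dd$inter_ba) & dd$inter_ba <= 33
  xl <- dd[sel, c("res_i", "res_j")]
  intraT <- dd[, c("res_i", "res_j", "intra")]
  orient <- scoringPreset("oblivious-oriented", "EUC")
  string <- scoringPreset("oblivious-stringent", "EUC")
  so <- scoreModel(xl, ref, orient, intraTable = intraT)
  ss <- scoreModel(xl, ref, string, intraTable = intraT)
  expect_gt(so$total, 0)
  expect_equal(so$total, 2 * ss$total, tolerance = 1e-9)
})
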