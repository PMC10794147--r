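## uniform worked system: 2x2 block, Gmc = 5, Gse = 3
sq2sys <- buildUniqueDesign(list(sq = matrix(TRUE, 2, 2)))
sq2 <- layouts(sq2sys)$sq
sq2pat <- uniformPattern(sq2sys, concGmc5)

test_that("greedy paths reproduce the closed-form 2x2 and 1x4 barriers", {
  ## every start site and seed gives the trimer barrier 9 = 3*5 - 2*3
  for (s in 1:4) {
    start <- layoutCells(sq2)[s, ]
    for (seed in 1:3) {
      pth <- sgmSamplePath(sq2, sq2pat, fixParams,
                           c(start$row, start$col), seed = seed)
      expect_equal(pth$barrier, 9)
      expect_equal(pth$barrierSize, 3L)
      expect_equal(pth$G[length(pth$G)], 8)   # full block
    }
  }
  ## 1x4 line: no 2-bond sites exist, G strictly increases to 4*5 - 3*3 = 11
  lnsys <- buildUniqueDesign(list(ln = matrix(TRUE, 1, 4)))
  pth <- sgmSamplePath(layouts(lnsys)$ln, uniformPattern(lnsys, concGmc5),
                       fixParams, c(1, 2), seed = 1)
  expect_true(all(diff(pth$G) > 0))
  expect_equal(pth$barrier, 11)
  ## single-tile layout: the monomer path, barrier -ln(c/u0)
  solo <- buildUniqueDesign(list(dot = matrix(TRUE, 1, 1)))
  pth <- sgmSamplePath(layouts(solo)$dot, uniformPattern(solo, concGmc5),
                       fixParams, c(1, 1))
  expect_equal(nrow(pth$cells), 1L)
  expect_equal(pth$barrier, 5)
  expect_error(sgmSamplePath(sq2, sq2pat, fixParams, c(9, 9)), "start")
})

test_that("SGM barriers agree with the exhaustive minimax oracle (<= 9 tiles)", {
  set.seed(23)
  shapes <- list(sq2 = matrix(TRUE, 2, 2),
                 line = matrix(TRUE, 1, 5),
                 rect = matrix(TRUE, 3, 3),
                 ell = rbind(c(TRUE, FALSE, FALSE),
                             c(TRUE, FALSE, FALSE),
                             c(TRUE, TRUE, TRUE)),
                 tee = rbind(c(TRUE, TRUE, TRUE),
                             c(FALSE, TRUE, FALSE),
                             c(FALSE, TRUE, FALSE)))
  for (nm in names(shapes)) {
    sys <- buildUniqueDesign(shapes[nm])
    ly <- layouts(sys)[[1]]
    pats <- list(uniform = uniformPattern(sys, concGmc5),
                 random = stats::setNames(exp(runif(nTiles(sys), -1.5, 1.5)) * 60,
                                          tileNames(sys)))
    for (pat in pats) {
      oracle <- oracleMinBarrier(ly, pat, fixParams)
      est <- sgmEstimateRate(ly, pat, fixParams, nPaths = 200, seed = 17)
      ## sampling reaches the optimum and never beats it
      expect_equal(min(est$barriers), oracle, tolerance = 1e-9)
      expect_gte(min(est$barriers), oracle - 1e-9)
    }
  }
})

test_that("doubling all concentrations multiplies the 2x2 rate by exactly 16", {
  est1 <- sgmEstimateRate(sq2, sq2pat, fixParams, nPaths = 30, seed = 4)
  est2 <- sgmEstimateRate(sq2, 2 * sq2pat, fixParams, nPaths = 30, seed = 4)
  ## e^{3 ln 2} from the trimer barrier times 2 from the forward kinetics
  expect_equal(est2$rate / est1$rate, 16, tolerance = 1e-9)
  expect_equal(est1$nDistinctBarriers, 4L)   # the four L-shaped trimers
  expect_equal(est1$K, 3)
})

test_that("identical disjoint layouts with identical patterns get equal rates", {
  m <- letterMask("smallU")
  sys <- buildUniqueDesign(list(u1 = m, u2 = m))
  pat <- uniformPattern(sys, concGmc5)
  e1 <- sgmEstimateRate(layouts(sys)$u1, pat, fixParams, nPaths = 15, seed = 8)
  e2 <- sgmEstimateRate(layouts(sys)$u2, pat, fixParams, nPaths = 15, seed = 8)
  expect_equal(e1$logRate, e2$logRate, tolerance = 1e-12)
})

test_that("participation maps are frequencies and flag regions participate most", {
  fl <- makeFlag(checkerHAM, "H", flagCenters$H, window = 3)
  est <- sgmEstimateRate(layouts(checkerHAM)$H, fl$pattern, flagParams,
                         nPaths = 5, seed = 2)
  part <- est$participation
  expect_true(all(part >= 0 & part <= 1))
  ## barrier states concentrate around the enhanced window
  win <- part[3:5, 2:4]
  expect_gt(mean(win), mean(part[!is.na(layoutGrid(layouts(checkerHAM)$H))]))
})

test_that("WNM closed forms hold and scores are monotone in concentrations", {
  sys <- buildUniqueDesign(list(b = matrix(TRUE, 3, 3)))
  ly <- layouts(sys)$b
  pat <- uniformPattern(sys, 60)
  ## k = 1: sum of c/u0 over the shape
  expect_equal(as.numeric(wnmScore(ly, pat, fixParams, k = 1)),
               sum(pat * 1e-9), tolerance = 1e-12)
  ## 3x3 uniform, k = 2: 4 windows x (c/u0)^4 e^{4 Gse}
  expect_equal(as.numeric(wnmScore(ly, pat, fixParams, k = 2)),
               4 * (60e-9)^4 * exp(4 * 3), tolerance = 1e-9)
  ## permuting concentrations within one window leaves its weight unchanged
  pat2 <- pat
  g <- layoutGrid(ly)
  pat2[c(g[1, 1], g[1, 2])] <- pat2[c(g[1, 2], g[1, 1])]
  expect_equal(as.numeric(wnmScore(ly, pat2, fixParams, k = 2)),
               as.numeric(wnmScore(ly, pat, fixParams, k = 2)),
               tolerance = 1e-12)
  ## raising any single concentration raises (never lowers) the score
  set.seed(5)
  for (rep in 1:5) {
    tn <- sample(tileNames(sys), 1)
    pat3 <- pat; pat3[tn] <- pat3[tn] * 3
    expect_gt(as.numeric(wnmScore(ly, pat3, fixParams, k = 2)),
              as.numeric(wnmScore(ly, pat, fixParams, k = 2)))
  }
  expect_error(wnmScore(ly, pat, fixParams, k = 4), "window")
})

test_that("raising one concentration never lowers the SGM rate", {
  set.seed(9)
  sys <- buildUniqueDesign(list(b = matrix(TRUE, 3, 3)))
  ly <- layouts(sys)$b
  pat <- stats::setNames(exp(runif(9, -1, 1)) * 60, tileNames(sys))
  base <- sgmEstimateRate(ly, pat, fixParams, nPaths = 120, seed = 31)$logRate
  for (tn in sample(tileNames(sys), 3)) {
    pat2 <- pat; pat2[tn] <- pat2[tn] * 4
    up <- sgmEstimateRate(ly, pat2, fixParams, nPaths = 120, seed = 31)$logRate
    expect_gte(up, base - 1e-6)
  }
})

test_that("free-energy profiles match enumerated small cases", {
  prof <- freeEnergyProfile(sq2, sq2pat, fixParams, nPaths = 30, seed = 6)
  expect_equal(prof$minG, c(5, 7, 9, 8), tolerance = 1e-9)
  expect_equal(prof$size, 1:4)
  ## minG at each size is <= every sampled state's G there (min property) and
  ## the 1x4 line profile is monotone increasing
  lnsys <- buildUniqueDesign(list(ln = matrix(TRUE, 1, 4)))
  prof2 <- freeEnergyProfile(layouts(lnsys)$ln, uniformPattern(lnsys, concGmc5),
                             fixParams, nPaths = 10, seed = 6)
  expect_true(all(diff(prof2$minG) > 0))
  expect_equal(prof2$minG, c(5, 7, 9, 11), tolerance = 1e-9)
  expect_true(all(prof$minG <= prof$macroG + 1e-9 + log(prof$nStates)))
})

test_that("classification reports ties honestly and prefers colocalization", {
  ## two identical disjoint shapes, uniform pattern: a declared tie
  m <- letterMask("smallU")
  twin <- buildUniqueDesign(list(u1 = m, u2 = m))
  cl <- classifyPattern(uniformPattern(twin, concGmc5), twin, fixParams,
                        method = "sgm", nPaths = 10, seed = 3)
  expect_true(cl$tie)
  expect_true(is.na(cl$predicted))
  ## colocalized high-concentration patch: that shape wins under both models
  fl <- makeFlag(checkerHAM, "M", flagCenters$M, window = 3)
  cw <- classifyPattern(fl$pattern, checkerHAM, flagParams, method = "wnm")
  cs <- classifyPattern(fl$pattern, checkerHAM, flagParams, method = "sgm",
                        nPaths = 10, seed = 3)
  expect_equal(cw$predicted, "M")
  expect_equal(cs$predicted, "M")
  expect_gt(cw$margin, 0)
  expect_gt(cs$margin, 0)
})

test_that("stronger bonds (lower temperature) shrink the critical seed size K", {
  fl <- makeFlag(checkerHAM, "H", flagCenters$H, window = 3)
  ly <- layouts(checkerHAM)$H
  Kwarm <- sgmEstimateRate(ly, fl$pattern, energyParams(Gse = 10),
                           nPaths = 10, seed = 12)$K
  Kcold <- sgmEstimateRate(ly, fl$pattern, energyParams(Gse = 16),
                           nPaths = 10, seed = 12)$K
  expect_lte(Kcold, Kwarm)
})
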