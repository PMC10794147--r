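test_that("proposals respect null-side eligibility and are seed-deterministic", {
  ## an edge tile (null on N) and a corner-free interior tile have different
  ## null signatures and are never proposed together; interior tiles in
  ## different shapes are eligible
  p1 <- proposeMerge(uniqSmall, phase = "global", seed = 1)
  expect_s3_class(p1, "MergeProposal")
  nullSides <- function(tn) {
    tl <- tiles(uniqSmall)
    r <- tl[tl$name == tn, ]
    paste(c("N", "E", "S", "W")[c(r$N, r$E, r$S, r$W) == ""], collapse = "")
  }
  expect_equal(nullSides(p1$tileA), nullSides(p1$tileB))
  ## fixed seed: identical proposal sequence
  seq1 <- vapply(1:5, function(i) proposeMerge(uniqSmall, seed = i)$key,
                 character(1))
  seq2 <- vapply(1:5, function(i) proposeMerge(uniqSmall, seed = i)$key,
                 character(1))
  expect_identical(seq1, seq2)
  ## chequerboard phase only draws from one parity
  pc <- proposeMerge(uniqSmall, phase = "chequerboard", parity = 0L, seed = 2)
  occ <- do.call(rbind, lapply(layouts(uniqSmall), layoutCells))
  par <- (occ$row + occ$col) %% 2
  expect_true(all(par[occ$tile %in% c(pc$tileA, pc$tileB)] == 0))
})

test_that("applyMerge unifies glues system-wide and keeps layouts valid", {
  prop <- proposeMerge(uniqSmall, phase = "global", seed = 4)
  merged <- applyMerge(uniqSmall, prop)
  expect_lt(nTiles(merged), nTiles(uniqSmall))
  expect_true(all(vapply(validateSystem(merged), nrow, integer(1)) == 0L))
  ## merging two tiles that already share all four glues changes nothing
  again <- applyMerge(merged, list(tileA = prop$tileA, tileB = prop$tileA))
  expect_equal(tiles(again), tiles(merged))
})

test_that("unification forcing a glue to equal its own complement is rejected", {
  ## two 1x3 shapes whose middle tiles present g2/g1* and g1*/g2* on E/W:
  ## unifying them requires both g2 ~ g1* and g1 ~ g2, i.e. g1 ~ g1*
  tl <- data.frame(name = c("a1", "a2", "a3", "b1", "b2", "b3"),
                   N = "", S = "",
                   E = c("g1", "g2", "", "g2", "g1*", ""),
                   W = c("", "g1*", "g2*", "", "g2*", "g1"),
                   stringsAsFactors = FALSE)
  sys <- tileSystem(tl, layouts = list(
    A = shapeLayout("A", matrix(c("a1", "a2", "a3"), 1, 3)),
    B = shapeLayout("B", matrix(c("b1", "b2", "b3"), 1, 3))))
  expect_equal(vapply(validateSystem(sys), nrow, integer(1)),
               c(A = 0L, B = 0L))
  expect_error(applyMerge(sys, list(tileA = "a2", tileB = "b2")),
               "own complement", class = "mfsaMergeError")
})

test_that("proofreading criteria hold trivially for fully unique designs", {
  sh <- checkSelfHealing(uniqSmall)
  so <- checkSecondOrder(uniqSmall)
  expect_true(sh$pass)
  expect_true(so$pass)
  expect_equal(nrow(sh$witnesses), 0L)
  ## wrong tiles match zero constraints in a unique design
  expect_equal(length(oracleSelfHealing(uniqSmall)), 0L)
})

test_that("self-healing detects a wrong tile with two matching glues", {
  ## shape A is a 2x2 block [a b; c d]; the wrong tile w carries the N and W
  ## glues that location (2,2) expects from its neighbours b and c, so w can
  ## attach there by two bonds in place of the correct tile d
  tl <- data.frame(
    name = c("a", "b", "c", "d", "w"),
    N = c("", "", "v1*", "v2*", "v2*"),
    E = c("h1", "", "h2", "", ""),
    S = c("v1", "v2", "", "", ""),
    W = c("", "h1*", "", "h2*", "h2*"),
    stringsAsFactors = FALSE)
  sys <- tileSystem(tl, layouts = list(
    A = shapeLayout("A", matrix(c("a", "c", "b", "d"), 2, 2)),
    W = shapeLayout("W", matrix("w", 1, 1))))
  sh <- checkSelfHealing(sys)
  orc <- oracleSelfHealing(sys)
  expect_false(sh$pass)
  expect_equal(nrow(sh$witnesses), length(orc))
  expect_true("w" %in% sh$witnesses$tile)
  wit <- sh$witnesses[sh$witnesses$tile == "w", ]
  expect_equal(c(wit$row, wit$col), c(2L, 2L))
})

test_that("both criteria agree with exhaustive enumeration on random merges", {
  set.seed(31)
  for (rep in 1:4) {
    sys <- uniqSmall
    ## apply a few random merges without any acceptance filtering, which
    ## typically breaks the criteria in interesting ways
    for (k in 1:3) {
      prop <- proposeMerge(sys, phase = "global")
      if (is.null(prop)) break
      cand <- tryCatch(applyMerge(sys, prop), mfsaMergeError = function(e) NULL)
      if (!is.null(cand)) sys <- cand
    }
    sh <- checkSelfHealing(sys)
    so <- checkSecondOrder(sys)
    orcSH <- oracleSelfHealing(sys)
    orcSO <- oracleSecondOrder(sys)
    expect_equal(sh$pass, length(orcSH) == 0L)
    expect_equal(nrow(sh$witnesses), length(orcSH))
    expect_equal(so$pass, length(orcSO) == 0L)
    if (!so$pass) {
      gotChains <- unique(with(so$witnesses,
        paste(shape, row, col, tile, row2, col2, tile2)))
      orcChains <- unique(vapply(orcSO, paste, collapse = " ", character(1)))
      expect_setequal(gotChains, orcChains)
    }
  }
})

test_that("runMerging compresses the design while preserving all criteria", {
  res <- runMerging(uniqSmall, restarts = 2, seed = 99)
  expect_lt(nTiles(res$system), nTiles(uniqSmall))
  expect_true(all(vapply(validateSystem(res$system), nrow, integer(1)) == 0L))
  expect_true(checkSelfHealing(res$system)$pass)
  expect_true(checkSecondOrder(res$system)$pass)
  ## tile count is non-increasing along the accepted-merge sequence
  acc <- res$log[res$log$accepted, ]
  expect_true(all(diff(acc$tilesAfter) <= 0 | diff(acc$restart) > 0))
  ## a fixed point stays fixed: re-running on the merged system with the
  ## same criteria cannot accept fewer tiles than an exhausted run
  res2 <- runMerging(res$system, restarts = 1, seed = 7)
  expect_lte(nTiles(res2$system), nTiles(res$system))
  ## determinism
  resA <- runMerging(uniqSmall, restarts = 1, seed = 5)
  resB <- runMerging(uniqSmall, restarts = 1, seed = 5)
  expect_identical(tiles(resA$system), tiles(resB$system))
})

test_that("every accepted merge leaves a system passing both criteria", {
  ## replay the accepted proposals one by one and assert safety continuously
  res <- runMerging(uniqSmall, restarts = 1, seed = 13)
  acc <- res$log[res$log$accepted, ]
  sys <- uniqSmall
  for (i in seq_len(nrow(acc))) {
    sys <- applyMerge(sys, list(tileA = acc$tileA[i], tileB = acc$tileB[i]))
    expect_true(all(vapply(validateSystem(sys), nrow, integer(1)) == 0L))
    expect_true(checkSelfHealing(sys)$pass)
    expect_true(checkSecondOrder(sys)$pass)
  }
  expect_equal(nTiles(sys), nTiles(res$system))
})
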