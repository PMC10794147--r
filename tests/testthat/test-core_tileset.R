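test_that("glue complementation follows the star convention", {
  expect_equal(glueComplement("708"), "708*")
  expect_equal(glueComplement("708*"), "708")
  expect_equal(glueComplement(glueComplement("9")), "9")
  expect_true(gluesMatch("708", "708*"))
  expect_false(gluesMatch("708", "709*"))
  ## the null glue matches nothing, including itself
  expect_true(isNullGlue(""))
  expect_false(gluesMatch("", ""))
  expect_false(gluesMatch("", "708*"))
})

test_that("layout text grids round trip and reject malformed input", {
  f <- tempfile(fileext = ".layout")
  writeLines("t0", f)
  ly <- readLayout(f, name = "one")
  expect_equal(dim(layoutGrid(ly)), c(1L, 1L))
  expect_equal(layoutGrid(ly)[1, 1], "t0")

  writeLines(c("a b", ". c"), f)
  ly <- readLayout(f, name = "three")
  expect_equal(nrow(layoutCells(ly)), 3L)
  expect_true(is.na(layoutGrid(ly)[2, 1]))

  ## round trip of a fixture L-shape layout
  lyL <- layouts(uniqSmall)$smallL
  writeLayout(lyL, f)
  expect_equal(layoutGrid(readLayout(f, name = "smallL")), layoutGrid(lyL))

  writeLines(c("a b c", "d e"), f)
  expect_error(readLayout(f), "ragged")
  expect_error(shapeLayout("x", matrix(c("a", "a"), 1, 2)), "repeated")
})

test_that("tile-system JSON round trips on canonical form", {
  f <- tempfile(fileext = ".json")
  one <- tileSystem(data.frame(name = "t0", N = "", E = "", S = "", W = "",
                               stringsAsFactors = FALSE),
                    layouts = list(solo = shapeLayout("solo",
                                                     matrix("t0", 1, 1))))
  writeTileSystem(one, f)
  back <- readTileSystem(f)
  expect_equal(tiles(back), tiles(one))
  expect_equal(layoutGrid(layouts(back)$solo), layoutGrid(layouts(one)$solo))

  ## mini fixture: sharing stats identical after a round trip
  writeTileSystem(checkerSmall, f)
  back <- readTileSystem(f)
  expect_equal(sharingStats(back)$counts, sharingStats(checkerSmall)$counts)
  expect_equal(sort(tileNames(back)), sort(tileNames(checkerSmall)))
  expect_equal(nGlues(back), nGlues(checkerSmall))
})

test_that("strict JSON reading rejects undeclared glues and unknown fields", {
  f <- tempfile(fileext = ".json")
  doc <- list(format = "mfsa-tilesystem", version = 1L, glues = list("9"),
              tiles = data.frame(name = "t", N = "9*", E = "", S = "", W = "",
                                 stringsAsFactors = FALSE))
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_silent(readTileSystem(f))       # 9* declares base 9: fine
  doc$tiles$N <- "10*"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(readTileSystem(f), "not declared")
  expect_s4_class(readTileSystem(f, strict = FALSE), "TileSystem")
  doc$tiles$N <- "9*"
  doc$surprise <- "x"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(readTileSystem(f), "unknown field")
})

test_that("validateLayout flags exactly the mutated edges", {
  sys <- buildUniqueDesign(list(sq = matrix(TRUE, 2, 2)))
  expect_equal(nrow(validateLayout(sys, layouts(sys)$sq)), 0L)

  ## flip one internal glue to a non-complementary label: exactly one
  ## violated edge (reported from the tile whose side no longer matches)
  tl <- tiles(sys)
  i <- which(tl$E != "")[1]
  tl$E[i] <- "mismatch"
  bad <- tileSystem(tl, glues = c(glueAlphabet(sys), "mismatch"),
                    layouts = layouts(sys))
  v <- validateLayout(bad, layouts(bad)$sq)
  expect_equal(nrow(v), 1L)
  expect_equal(v$rule, "internal-edge-mismatch")

  ## non-null glue on a boundary edge
  tl <- tiles(sys)
  j <- which(tl$N == "")[1]
  tl$N[j] <- "stray"
  bad2 <- tileSystem(tl, glues = c(glueAlphabet(sys), "stray"),
                     layouts = layouts(sys))
  v2 <- validateLayout(bad2, layouts(bad2)$sq)
  expect_equal(v2$rule, "boundary-not-null")

  expect_error(validateLayout(sys, shapeLayout("x", matrix("ghost", 1, 1))),
               "unknown tile")
})

test_that("buildUniqueDesign counts tiles and domains as internal edges", {
  s1 <- buildUniqueDesign(list(dot = matrix(TRUE, 1, 1)))
  expect_equal(nTiles(s1), 1L)
  expect_equal(nGlues(s1), 0L)

  s4 <- buildUniqueDesign(list(sq = matrix(TRUE, 2, 2)))
  expect_equal(nTiles(s4), 4L)
  expect_equal(nGlues(s4), 4L)   # 4 internal edges counted by hand

  expect_error(buildUniqueDesign(list(no = matrix(FALSE, 2, 2))), "empty")
})

test_that("unique designs validate and match adjacency counts on random masks", {
  set.seed(7)
  for (rep in 1:8) {
    ## random connected mask grown from a seed cell
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    m <- matrix(FALSE, nr, nc)
    m[sample(nr, 1), sample(nc, 1)] <- TRUE
    for (k in seq_len(nr * nc)) {
      frontier <- which(!m & (rbind(m[-1, , drop = FALSE], FALSE) |
                              rbind(FALSE, m[-nr, , drop = FALSE]) |
                              cbind(m[, -1, drop = FALSE], FALSE) |
                              cbind(FALSE, m[, -nc, drop = FALSE])))
      if (!length(frontier) || runif(1) < 0.2) break
      m[sample(frontier, 1)] <- TRUE
    }
    sys <- buildUniqueDesign(list(rnd = m))
    expect_equal(nrow(validateLayout(sys, layouts(sys)$rnd)), 0L)
    ## oracle: count adjacent occupied pairs directly
    hEdges <- sum(m[, -ncol(m), drop = FALSE] & m[, -1, drop = FALSE])
    vEdges <- sum(m[-nrow(m), , drop = FALSE] & m[-1, , drop = FALSE])
    expect_equal(nGlues(sys), hEdges + vEdges)
    expect_equal(nTiles(sys), sum(m))
  }
})

test_that("sharingStats matches a direct set scan and unique designs share nothing", {
  st <- sharingStats(uniqSmall)
  expect_equal(unname(st$counts), c(nTiles(uniqSmall), 0L))
  expect_equal(sum(st$counts), st$totalTiles)

  st2 <- sharingStats(checkerSmall)
  expect_equal(unname(st2$counts), oracleSharing(checkerSmall))
  expect_equal(sum(st2$counts), st2$totalTiles)
  expect_gt(st2$sharedAtLeast2, 0L)
})

test_that("fixture systems are deterministic and merged variants are smaller", {
  a <- makeFixtureSystem(5, shapes = c("smallL", "smallT"), variant = "checker")
  b <- makeFixtureSystem(5, shapes = c("smallL", "smallT"), variant = "checker")
  expect_identical(tiles(a), tiles(b))
  expect_identical(layoutGrid(layouts(a)[[1]]), layoutGrid(layouts(b)[[1]]))

  merged <- makeFixtureSystem(3, shapes = c("smallL", "smallT"),
                              variant = "merged", mergeRestarts = 1)
  expect_lt(nTiles(merged), nTiles(uniqSmall))
  expect_true(all(vapply(validateSystem(merged), nrow, integer(1)) == 0L))
})
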