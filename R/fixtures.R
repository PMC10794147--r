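## Built-in miniature letter masks used by the fixture generator ("X" =
## occupied). The capital letters are chunky 12 x 12 forms (stroke width 4,
## like the mostly-filled published canvases, so they contain sizeable
## interior regions); the "small*" letters are 6 x 6 stroke-2 forms for
## tests that need very few tiles; "block" is a solid 8 x 8 square.
.LETTER_SPECS <- list(
  H = c("XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX"),
  A = c("..XXXXXXXX..",
        "..XXXXXXXX..",
        "..XXXXXXXX..",
        "..XXXXXXXX..",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX"),
  M = c("XXXX....XXXX",
        "XXXX....XXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX",
        "XXXX....XXXX"),
  L = c("XXXX........",
        "XXXX........",
        "XXXX........",
        "XXXX........",
        "XXXX........",
        "XXXX........",
        "XXXX........",
        "XXXX........",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX",
        "XXXXXXXXXXXX"),
  smallH = c("XX..XX",
             "XX..XX",
             "XXXXXX",
             "XXXXXX",
             "XX..XX",
             "XX..XX"),
  smallL = c("XX....",
             "XX....",
             "XX....",
             "XX....",
             "XXXXXX",
             "XXXXXX"),
  smallT = c("XXXXXX",
             "XXXXXX",
             "..XX..",
             "..XX..",
             "..XX..",
             "..XX.."),
  smallU = c("XX..XX",
             "XX..XX",
             "XX..XX",
             "XX..XX",
             "XXXXXX",
             "XXXXXX"),
  block = c("XXXXXXXX",
            "XXXXXXXX",
            "XXXXXXXX",
            "XXXXXXXX",
            "XXXXXXXX",
            "XXXXXXXX",
            "XXXXXXXX",
            "XXXXXXXX"))

#' Miniature letter occupancy masks
#'
#' Letter-like occupancy grids used to build test-scale analogues of large
#' molecular canvases: chunky 12 x 12 letters (\code{"H", "A", "M", "L"},
#' stroke width 4, with sizeable interiors like the mostly-filled published
#' canvases), tiny 6 x 6 letters (\code{"smallH", "smallL", "smallT",
#' "smallU"}) for tests needing very few tiles, and a solid 8 x 8
#' \code{"block"}.
#'
#' @param letter a built-in mask name (see above).
#' @return logical occupancy matrix.
#' @examples
#' sum(letterMask("H"))
#' @export
letterMask <- function(letter) {
  spec <- .LETTER_SPECS[[letter]]
  if (is.null(spec)) stop("no built-in mask for letter '", letter, "'")
  do.call(rbind, lapply(spec, function(l) strsplit(l, "")[[1]] == "X"))
}

## Internal: interior cells of a mask (all four neighbours occupied).
.interiorCells <- function(m) {
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  n <- nrow(m); p <- ncol(m)
  core <- pad[2:(n + 1), 2:(p + 1)] &
    pad[1:n, 2:(p + 1)] & pad[3:(n + 2), 2:(p + 1)] &
    pad[2:(n + 1), 1:p] & pad[2:(n + 1), 3:(p + 2)]
  core
}

## Internal: the two-sublattice multifarious construction.
## Shared tiles occupy interior locations of one chequerboard parity and are
## reused (randomly permuted) across shapes; the opposite sublattice and all
## boundary locations get shape-unique tiles whose glues mediate the
## interactions.
.checkerConstruct <- function(masks, parity = 0L) {
  nshape <- length(masks)
  sharedCellsL <- lapply(masks, function(m) {
    core <- .interiorCells(m)
    par <- (row(m) + col(m)) %% 2L == parity
    which(core & par, arr.ind = TRUE)
  })
  poolSize <- max(vapply(sharedCellsL, nrow, integer(1)))
  sharedNames <- sprintf("S%d", seq_len(poolSize))
  ## fixed glues of each shared tile (one fresh domain per side)
  sGlue <- matrix(sprintf("s%d%s", rep(seq_len(poolSize), each = 4L),
                          rep(c("N", "E", "S", "W"), poolSize)),
                  ncol = 4L, byrow = TRUE,
                  dimnames = list(sharedNames, .SIDES))
  gcount <- 0L
  tilerows <- list(data.frame(name = sharedNames,
                              N = sGlue[, "N"], E = sGlue[, "E"],
                              S = sGlue[, "S"], W = sGlue[, "W"],
                              stringsAsFactors = FALSE))
  layoutsL <- list()
  for (sname in names(masks)) {
    m <- masks[[sname]]
    grid <- matrix(NA_character_, nrow(m), ncol(m))
    sc <- sharedCellsL[[sname]]
    pick <- sample(sharedNames, nrow(sc))
    grid[sc] <- pick
    uniq <- m & is.na(grid)
    grid[uniq] <- sprintf("%s_%d_%d", sname, row(m)[uniq], col(m)[uniq])
    isShared <- matrix(FALSE, nrow(m), ncol(m)); isShared[sc] <- TRUE
    glues <- array("", dim = c(nrow(m), ncol(m), 4L),
                   dimnames = list(NULL, NULL, .SIDES))
    for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
      if (!m[r, cc] || isShared[r, cc]) next
      for (s in .SIDES) {
        r2 <- r + .SIDE_DROW[[s]]; c2 <- cc + .SIDE_DCOL[[s]]
        inside <- r2 >= 1L && r2 <= nrow(m) && c2 >= 1L && c2 <= ncol(m)
        if (!inside || !m[r2, c2]) next
        if (isShared[r2, c2]) {
          glues[r, cc, s] <- glueComplement(sGlue[grid[r2, c2], .OPPOSITE[[s]]])
        } else if (glues[r, cc, s] == "") {
          gcount <- gcount + 1L
          lab <- sprintf("%s_e%d", sname, gcount)
          glues[r, cc, s] <- lab
          glues[r2, c2, .OPPOSITE[[s]]] <- paste0(lab, "*")
        }
      }
    }
    tilerows[[length(tilerows) + 1L]] <- data.frame(
      name = grid[uniq],
      N = glues[, , "N"][uniq], E = glues[, , "E"][uniq],
      S = glues[, , "S"][uniq], W = glues[, , "W"][uniq],
      stringsAsFactors = FALSE)
    layoutsL[[sname]] <- shapeLayout(sname, grid)
  }
  tl <- do.call(rbind, tilerows)
  ## drop shared tiles that ended up unused (smaller shapes may not use all)
  used <- unique(unlist(lapply(layoutsL, function(l) l@grid[!is.na(l@grid)])))
  tl <- tl[tl$name %in% used, , drop = FALSE]
  tileSystem(tl, layouts = layoutsL)
}

#' Generate miniature multifarious fixture systems
#'
#' Builds small, deterministic analogues of a large multi-shape tile system
#' so that every operation is testable at toy scale. Three variants are
#' available: \code{"unique"} (one fresh tile per location, the initial fully
#' unique design), \code{"checker"} (the two-sublattice architecture in
#' which shared tiles occupy interior locations of one chequerboard parity
#' and are reused across shapes in permuted arrangements, while
#' shape-unique interaction tiles mediate their binding), and
#' \code{"merged"} (the unique design compressed by
#' \code{\link{runMerging}} under both proofreading criteria).
#'
#' @param seed integer seed; the same seed always returns the same system.
#' @param shapes character vector of built-in mask names (see
#'   \code{\link{letterMask}}), or a named list of logical masks.
#' @param variant "unique", "checker" or "merged".
#' @param parity chequerboard parity for the checker/merged variants.
#' @param mergeRestarts restarts for the merged variant.
#' @return a \linkS4class{TileSystem} whose layouts validate.
#' @examples
#' sys <- makeFixtureSystem(1, shapes = c("H", "L"), variant = "checker")
#' sharingStats(sys)$sharedAtLeast2
#' @export
makeFixtureSystem <- function(seed = 1, shapes = c("H", "A", "M"),
                              variant = c("unique", "checker", "merged"),
                              parity = 0L, mergeRestarts = 2) {
  variant <- match.arg(variant)
  masks <- if (is.list(shapes)) shapes
           else stats::setNames(lapply(shapes, letterMask), shapes)
  withSeed(seed, {
    switch(variant,
      unique = buildUniqueDesign(masks),
      checker = .checkerConstruct(masks, parity = parity),
      merged = runMerging(buildUniqueDesign(masks),
                          restarts = mergeRestarts, parity = parity)$system)
  })
}

#' Paired study systems for winner-take-all anneal simulations
#'
#' Builds the two contrasting systems of the competitive-nucleation study:
#' a "shared" system in which two shapes assemble from the same tile set in
#' different spatial arrangements, and a "disjoint" system in which the
#' second shape uses its own separate tiles. A concentration pattern
#' enhances the chequerboard tiles of a central window of shape S1; those
#' tiles are contiguous in S1 but placed on a stride-separated sublattice in
#' S2, so the on-target shape nucleates at a higher temperature. The tile
#' sets here are abstract (no glue structure): only arrangements and
#' concentrations matter to the window-model kinetics.
#'
#' @param n canvas side (square shapes of n x n tiles).
#' @param window odd flag window side.
#' @param base,enhanced concentrations in nM.
#' @param seed integer seed for the arrangement of non-flag tiles in S2.
#' @return list with \code{shared} and \code{disjoint}
#'   (\linkS4class{TileSystem}s, shapes "S1" and "S2"), \code{pattern}
#'   (named concentrations for the shared system), \code{patternDisjoint},
#'   and \code{enhancedTiles}.
#' @export
wtaStudySystems <- function(n = 12, window = 5, base = 50, enhanced = 880,
                            seed = 1) {
  tilesA <- sprintf("t%d", seq_len(n * n))
  g1 <- matrix(tilesA, n, n)
  ctr <- (n + 1L) %/% 2L
  h <- window %/% 2L
  rr <- (ctr - h):(ctr + h); cc <- (ctr - h):(ctr + h)
  wr <- rep(rr, times = window); wc <- rep(cc, each = window)
  onPar <- (wr + wc) %% 2L == (ctr + ctr) %% 2L
  flag <- g1[cbind(wr[onPar], wc[onPar])]
  ## S2: flag tiles on a stride-3 sublattice (no two in one 3x3 window),
  ## everything else shuffled into the remaining positions
  stride <- as.matrix(expand.grid(r = seq(1L, n, by = 3L),
                                  c = seq(1L, n, by = 3L)))
  if (nrow(stride) < length(flag))
    stop("canvas too small to spread the flag tiles")
  g2 <- matrix(NA_character_, n, n)
  g2[stride[seq_along(flag), , drop = FALSE]] <- flag
  rest <- setdiff(tilesA, flag)
  withSeed(seed, {
    g2[is.na(g2)] <- sample(rest)
  })
  mk <- function(tl, lys) tileSystem(
    data.frame(name = tl, N = "", E = "", S = "", W = "",
               stringsAsFactors = FALSE),
    layouts = lys)
  shared <- mk(tilesA, list(S1 = shapeLayout("S1", g1),
                            S2 = shapeLayout("S2", g2)))
  tilesB <- sprintf("u%d", seq_len(n * n))
  disjoint <- mk(c(tilesA, tilesB),
                 list(S1 = shapeLayout("S1", g1),
                      S2 = shapeLayout("S2", matrix(tilesB, n, n))))
  pat <- stats::setNames(rep(base, length(tilesA)), tilesA)
  pat[flag] <- enhanced
  patD <- stats::setNames(rep(base, 2 * n * n), c(tilesA, tilesB))
  patD[flag] <- enhanced
  list(shared = shared, disjoint = disjoint, pattern = pat,
       patternDisjoint = patD, enhancedTiles = flag)
}
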