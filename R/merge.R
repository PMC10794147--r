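## ---- signed union-find over base domain labels -------------------------
## Each base domain has a parent and a relative sign (+1 same sense as
## parent, -1 complemented). Unifying a glue with another glue unifies their
## base domains with the appropriate relative sign; a domain forced to equal
## its own complement is a conflict.

.ufNew <- function(bases) {
  list(parent = stats::setNames(bases, bases),
       sign = stats::setNames(rep(1L, length(bases)), bases))
}

.ufFind <- function(uf, b) {
  s <- 1L
  while (uf$parent[[b]] != b) {
    s <- s * uf$sign[[b]]
    b <- uf$parent[[b]]
  }
  list(root = b, sign = s)
}

## union base a (sense sa) with base b (sense sb): a^sa == b^sb.
## Returns updated uf, or NULL on a self-complementarity conflict.
.ufUnion <- function(uf, a, sa, b, sb) {
  fa <- .ufFind(uf, a); fb <- .ufFind(uf, b)
  rel <- sa * fa$sign * sb * fb$sign   # sign between roots
  if (fa$root == fb$root) {
    if (rel != 1L) return(NULL)        # root would equal its own complement
    return(uf)
  }
  uf$parent[[fb$root]] <- fa$root
  uf$sign[[fb$root]] <- rel
  uf
}

## Internal: decompose glue labels into (base, sign); sign -1 for starred.
.glueSign <- function(label) ifelse(endsWith(label, "*"), -1L, 1L)

## ---- merge proposals ----------------------------------------------------

## Internal: occurrence table of tiles across layouts (tile, shape, row, col).
.tileOccurrences <- function(system) {
  do.call(rbind, lapply(system@layouts, function(ly) {
    cells <- layoutCells(ly)
    data.frame(tile = cells$tile, shape = ly@name,
               row = cells$row, col = cells$col, stringsAsFactors = FALSE)
  }))
}

## Internal: all eligible unordered tile pairs for merging.
## Eligible: the two tiles occur in (at least one pair of) different shapes,
## have null glues on exactly the same sides, and in the chequerboard phase
## every occurrence of both tiles has (row + col) parity == parity.
.eligiblePairs <- function(system, phase = c("global", "chequerboard"),
                           parity = 0L) {
  phase <- match.arg(phase)
  occ <- .tileOccurrences(system)
  gm <- .glueMatrix(system)
  nullSig <- apply(gm == "", 1L, function(z) paste(which(z), collapse = ","))
  shapesOf <- split(occ$shape, occ$tile)
  tilesOk <- tileNames(system)
  if (phase == "chequerboard") {
    par <- split((occ$row + occ$col) %% 2L, occ$tile)
    good <- names(par)[vapply(par, function(p) all(p == parity), logical(1))]
    tilesOk <- intersect(tilesOk, good)
  }
  ## group by null signature; only same-signature tiles can merge
  pairs <- list()
  for (sig in unique(nullSig[tilesOk])) {
    grp <- tilesOk[nullSig[tilesOk] == sig]
    if (length(grp) < 2L) next
    cmb <- utils::combn(grp, 2L)
    keep <- vapply(seq_len(ncol(cmb)), function(i) {
      ## a cross-shape pair of occurrences must exist
      length(unique(c(shapesOf[[cmb[1L, i]]], shapesOf[[cmb[2L, i]]]))) >= 2L
    }, logical(1))
    if (any(keep)) pairs[[length(pairs) + 1L]] <- cmb[, keep, drop = FALSE]
  }
  if (!length(pairs))
    return(matrix(character(), nrow = 2L))
  do.call(cbind, pairs)
}

#' Propose a random tile merge
#'
#' Draws a uniformly random eligible pair of tiles occurring in different
#' shapes with null glues on the same sides of each tile. In the
#' "chequerboard" phase only tiles all of whose occurrences lie on the
#' configured (row + col) parity sublattice are considered; the "global"
#' phase draws from all tiles.
#'
#' @param system a \linkS4class{TileSystem}.
#' @param phase "chequerboard" or "global".
#' @param parity 0 or 1, the (row + col) %% 2 value of the chequerboard
#'   sublattice.
#' @param exclude character vector of already-tried pair keys
#'   (\code{"tileA|tileB"}, names sorted) to skip.
#' @param seed optional integer seed.
#' @return object of class \code{MergeProposal} (list with \code{tileA},
#'   \code{tileB}, \code{key}), or \code{NULL} when no untried eligible pair
#'   remains (exhausted).
#' @export
proposeMerge <- function(system, phase = c("global", "chequerboard"),
                         parity = 0L, exclude = character(), seed = NULL) {
  phase <- match.arg(phase)
  pairs <- .eligiblePairs(system, phase, parity)
  if (!ncol(pairs)) return(NULL)
  keys <- apply(pairs, 2L, function(p) paste(sort(p), collapse = "|"))
  avail <- which(!(keys %in% exclude))
  if (!length(avail)) return(NULL)
  i <- withSeed(seed, avail[sample.int(length(avail), 1L)])
  structure(list(tileA = pairs[1L, i], tileB = pairs[2L, i],
                 key = keys[i]),
            class = "MergeProposal")
}

#' Apply a tile merge to a system
#'
#' Makes the two proposed tiles identical by unifying their glues side by
#' side (complements unified consistently through a signed union-find over
#' the domain labels) and propagating the relabelling to every place the
#' affected glues occur in the whole system. Tiles whose four-glue signature
#' becomes identical are canonicalised to a single tile type. The merge is
#' rejected (error of class \code{mfsaMergeError}) if the unification would
#' force a glue to equal its own complement, or if a layout would end up
#' containing the same tile twice.
#'
#' @param system a \linkS4class{TileSystem}.
#' @param proposal a \code{MergeProposal} (or list with tileA/tileB).
#' @return the modified \linkS4class{TileSystem}; all layouts still pass
#'   \code{\link{validateLayout}}.
#' @export
applyMerge <- function(system, proposal) {
  tl <- system@tiles
  ia <- match(proposal$tileA, tl$name)
  ib <- match(proposal$tileB, tl$name)
  if (is.na(ia) || is.na(ib)) stop("proposal references unknown tiles")
  uf <- .ufNew(system@glues)
  for (s in .SIDES) {
    ga <- tl[[s]][ia]; gb <- tl[[s]][ib]
    if ((ga == "") != (gb == ""))
      .mergeFail("null glues not on the same sides")
    if (ga == "") next
    uf2 <- .ufUnion(uf, glueBase(ga), .glueSign(ga), glueBase(gb), .glueSign(gb))
    if (is.null(uf2))
      .mergeFail("unification would force a glue to equal its own complement")
    uf <- uf2
  }
  ## relabel every glue by its class representative
  relabel <- function(lab) {
    out <- lab
    nz <- lab != ""
    if (!any(nz)) return(out)
    f <- vapply(glueBase(lab[nz]), function(b) {
      r <- .ufFind(uf, b); paste0(r$root, if (r$sign < 0) "*" else "")
    }, character(1))
    starred <- .glueSign(lab[nz]) < 0
    out[nz] <- ifelse(starred, glueComplement(f), f)
    out
  }
  for (s in .SIDES) tl[[s]] <- relabel(tl[[s]])
  ## canonicalise tiles by glue signature
  sig <- paste(tl$N, tl$E, tl$S, tl$W, sep = "\r")
  canon <- stats::setNames(tl$name[match(sig, sig)], tl$name)
  keep <- !duplicated(sig)
  tl2 <- tl[keep, , drop = FALSE]
  newLayouts <- lapply(system@layouts, function(ly) {
    g <- ly@grid
    occv <- !is.na(g)
    g[occv] <- canon[g[occv]]
    if (anyDuplicated(g[occv]))
      .mergeFail(sprintf("merge would repeat a tile within layout '%s'", ly@name))
    shapeLayout(ly@name, g)
  })
  glues2 <- sort(unique(glueBase(unlist(tl2[.SIDES]))))
  glues2 <- glues2[glues2 != ""]
  tileSystem(tl2, glues = glues2, layouts = newLayouts)
}

.mergeFail <- function(msg) {
  stop(structure(class = c("mfsaMergeError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## Internal: per-location neighbour glue constraints and wrong-tile match
## counts, shared by both proofreading checks.
## Returns, for every location of every layout, the 4-vector of required
## glue labels ("" = no constraint) and the match-count vector over tiles.
.locationConstraints <- function(system) {
  gm <- .glueMatrix(system)
  out <- list()
  for (ly in system@layouts) {
    li <- .layoutIndex(ly)
    cells <- li$cells
    req <- matrix("", li$n, 4L, dimnames = list(NULL, .SIDES))
    for (s in .SIDES) {
      nb <- li$nbr[, s]
      has <- !is.na(nb)
      if (any(has)) {
        presented <- gm[cbind(cells$tile[nb[has]], .OPPOSITE[[s]])]
        req[has, s] <- ifelse(presented == "", "", glueComplement(presented))
      }
    }
    out[[ly@name]] <- list(layout = ly, li = li, req = req)
  }
  out
}

## Internal: match counts of every tile against a 4-vector of required glues.
.matchCounts <- function(gm, req) {
  m <- integer(nrow(gm))
  for (s in .SIDES) if (req[[s]] != "") m <- m + (gm[, s] == req[[s]])
  m
}

#' Self-healing proofreading criterion
#'
#' For every location of every layout, considering the glue constraints
#' presented by all of that location's neighbours, only the correct tile may
#' match two or more of them: every other tile in the system must match at
#' most one. Matching at most one of all four constraints implies matching at
#' most one under any subset of neighbours, so the check covers every correct
#' subassembly. Trivially satisfied by fully unique designs.
#'
#' @param system a validated \linkS4class{TileSystem}.
#' @return list with \code{pass} (logical) and \code{witnesses}, a
#'   data.frame (shape, row, col, tile, matches) of violations.
#' @export
checkSelfHealing <- function(system) {
  gm <- .glueMatrix(system)
  cons <- .locationConstraints(system)
  wit <- list()
  for (cn in cons) {
    cells <- cn$li$cells
    for (i in seq_len(cn$li$n)) {
      m <- .matchCounts(gm, cn$req[i, ])
      m[match(cells$tile[i], rownames(gm))] <- 0L
      bad <- which(m >= 2L)
      if (length(bad))
        wit[[length(wit) + 1L]] <- data.frame(
          shape = cn$layout@name, row = cells$row[i], col = cells$col[i],
          tile = rownames(gm)[bad], matches = m[bad],
          stringsAsFactors = FALSE)
    }
  }
  wit <- if (length(wit)) do.call(rbind, wit)
         else data.frame(shape = character(), row = integer(), col = integer(),
                         tile = character(), matches = integer(),
                         stringsAsFactors = FALSE)
  list(pass = nrow(wit) == 0L, witnesses = wit)
}

#' Second-order sensitivity proofreading criterion
#'
#' For every location l and every wrong tile t that can erroneously attach
#' there by exactly one bond, t must not create a neighbourhood in which a
#' further incorrect tile t' can attach by two or more bonds (at least one of
#' them to t) at any neighbouring position l' that is empty in the
#' subassembly -- so a one-bond error is likely to fall off rather than be
#' locked in.
#'
#' @param system a validated \linkS4class{TileSystem}.
#' @return list with \code{pass} and \code{witnesses}, a data.frame
#'   (shape, row, col, tile, row2, col2, tile2, bonds) of error-extension
#'   chains.
#' @export
checkSecondOrder <- function(system) {
  gm <- .glueMatrix(system)
  cons <- .locationConstraints(system)
  wit <- list()
  for (cn in cons) {
    ly <- cn$layout
    g <- ly@grid
    cells <- cn$li$cells
    for (i in seq_len(cn$li$n)) {
      m <- .matchCounts(gm, cn$req[i, ])
      m[match(cells$tile[i], rownames(gm))] <- 0L
      err <- which(m == 1L)
      if (!length(err)) next
      for (d in .SIDES) {
        r2 <- cells$row[i] + .SIDE_DROW[[d]]
        c2 <- cells$col[i] + .SIDE_DCOL[[d]]
        if (r2 < 1L || r2 > nrow(g) || c2 < 1L || c2 > ncol(g)) next
        ## constraints at l' from correct neighbours other than l
        req2base <- rep("", 4L); names(req2base) <- .SIDES
        for (e in .SIDES) {
          r3 <- r2 + .SIDE_DROW[[e]]; c3 <- c2 + .SIDE_DCOL[[e]]
          if (r3 == cells$row[i] && c3 == cells$col[i]) next
          if (r3 < 1L || r3 > nrow(g) || c3 < 1L || c3 > ncol(g)) next
          if (is.na(g[r3, c3])) next
          presented <- gm[g[r3, c3], .OPPOSITE[[e]]]
          if (presented != "") req2base[[e]] <- glueComplement(presented)
        }
        correct2 <- if (!is.na(g[r2, c2])) g[r2, c2] else NA_character_
        sideToErr <- .OPPOSITE[[d]]
        for (t in err) {
          gt <- gm[t, d]            # glue t presents toward l'
          if (gt == "") next
          req2 <- req2base
          req2[[sideToErr]] <- glueComplement(gt)
          m2 <- .matchCounts(gm, req2)
          bondToErr <- gm[, sideToErr] == req2[[sideToErr]]
          bad <- which(m2 >= 2L & bondToErr)
          if (!is.na(correct2)) bad <- setdiff(bad, match(correct2, rownames(gm)))
          bad <- setdiff(bad, t)
          if (length(bad))
            wit[[length(wit) + 1L]] <- data.frame(
              shape = ly@name, row = cells$row[i], col = cells$col[i],
              tile = rownames(gm)[t], row2 = r2, col2 = c2,
              tile2 = rownames(gm)[bad], bonds = m2[bad],
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  wit <- if (length(wit)) do.call(rbind, wit)
         else data.frame(shape = character(), row = integer(), col = integer(),
                         tile = character(), row2 = integer(), col2 = integer(),
                         tile2 = character(), bonds = integer(),
                         stringsAsFactors = FALSE)
  list(pass = nrow(wit) == 0L, witnesses = wit)
}

#' Run the stochastic merging algorithm
#'
#' Converts a fully unique multi-shape design into a multifarious shared-tile
#' system by repeatedly proposing random tile merges and accepting those that
#' keep every layout valid and preserve both proofreading criteria
#' (\code{\link{checkSelfHealing}} and \code{\link{checkSecondOrder}}). The
#' algorithm first exhausts merges within the chequerboard sublattice, then
#' attempts merges among all tiles; it stops when every currently eligible
#' pair has been tried and rejected since the last accepted merge. Across
#' restarts the minimum-tile-count system is returned.
#'
#' @param system a \linkS4class{TileSystem} (typically a unique design).
#' @param restarts number of independent runs.
#' @param parity chequerboard parity ((row + col) %% 2).
#' @param seed optional integer seed controlling the proposal stream.
#' @param verbose print per-restart progress.
#' @return list with \code{system} (the best merged system), \code{log}
#'   (object of class \code{MergeLog}: data.frame of proposals with columns
#'   restart, phase, tileA, tileB, accepted, reason, tilesAfter), and
#'   \code{tileCounts} (per-restart final counts).
#' @export
runMerging <- function(system, restarts = 1, parity = 0L, seed = NULL,
                       verbose = FALSE) {
  withSeed(seed, {
    best <- system
    logs <- list()
    counts <- integer(restarts)
    for (rs in seq_len(restarts)) {
      cur <- system
      for (phase in c("chequerboard", "global")) {
        tried <- character()
        repeat {
          prop <- proposeMerge(cur, phase = phase, parity = parity,
                               exclude = tried)
          if (is.null(prop)) break
          res <- tryCatch(applyMerge(cur, prop),
                          mfsaMergeError = function(e) e)
          if (inherits(res, "error")) {
            tried <- c(tried, prop$key)
            logs[[length(logs) + 1L]] <- data.frame(
              restart = rs, phase = phase, tileA = prop$tileA,
              tileB = prop$tileB, accepted = FALSE,
              reason = conditionMessage(res), tilesAfter = nTiles(cur),
              stringsAsFactors = FALSE)
            next
          }
          sh <- checkSelfHealing(res)
          so <- if (sh$pass) checkSecondOrder(res) else list(pass = FALSE)
          if (sh$pass && so$pass) {
            cur <- res
            tried <- character()   # acceptability may have changed
            logs[[length(logs) + 1L]] <- data.frame(
              restart = rs, phase = phase, tileA = prop$tileA,
              tileB = prop$tileB, accepted = TRUE, reason = "",
              tilesAfter = nTiles(cur), stringsAsFactors = FALSE)
          } else {
            tried <- c(tried, prop$key)
            logs[[length(logs) + 1L]] <- data.frame(
              restart = rs, phase = phase, tileA = prop$tileA,
              tileB = prop$tileB, accepted = FALSE,
              reason = if (!sh$pass) "self-healing" else "second-order",
              tilesAfter = nTiles(cur), stringsAsFactors = FALSE)
          }
        }
      }
      counts[rs] <- nTiles(cur)
      if (verbose)
        message(sprintf("restart %d: %d tiles", rs, nTiles(cur)))
      if (nTiles(cur) < nTiles(best)) best <- cur
    }
    log <- do.call(rbind, logs)
    if (is.null(log))
      log <- data.frame(restart = integer(), phase = character(),
                        tileA = character(), tileB = character(),
                        accepted = logical(), reason = character(),
                        tilesAfter = integer(), stringsAsFactors = FALSE)
    class(log) <- c("MergeLog", class(log))
    list(system = best, log = log, tileCounts = counts)
  })
}
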