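## Independent oracles used across the suite. These deliberately avoid the
## package's sampling/vectorised code paths: barriers come from exhaustive
## minimax search over the subassembly lattice, sharing statistics from a
## direct set scan, and the proofreading checks from naive per-edge loops.

## Minimum achievable nucleation barrier of a layout: minimax over all
## single-tile-addition orders from every start monomer, by Dijkstra on the
## lattice of subsets (bitmasks). Feasible for layouts of <= ~12 tiles.
oracleMinBarrier <- function(layout, pattern, params, tempC = 53) {
  cells <- layoutCells(layout)
  n <- nrow(cells)
  stopifnot(n <= 14)
  gmc <- params@alpha - log(unname(pattern[cells$tile]) * 1e-9 / params@u0)
  Gse <- gseAt(params, tempC)
  ## adjacency between cells
  adj <- which(outer(cells$row, cells$row, function(a, b) abs(a - b)) +
               outer(cells$col, cells$col, function(a, b) abs(a - b)) == 1,
               arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  nSets <- bitwShiftL(1L, n)
  bonds <- integer(nSets)
  gsum <- numeric(nSets)
  for (s in seq_len(nSets - 1L)) {
    memb <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    gsum[s + 1L] <- sum(gmc[memb])
    if (nrow(adj))
      bonds[s + 1L] <- sum(adj[, 1] %in% memb & adj[, 2] %in% memb)
  }
  G <- gsum - bonds * Gse - params@alpha
  dist <- rep(Inf, nSets)
  for (i in seq_len(n)) {
    s <- bitwShiftL(1L, i - 1L)
    dist[s + 1L] <- G[s + 1L]
  }
  done <- logical(nSets)
  full <- nSets - 1L
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    if (u == full + 1L) return(dist[u])
    done[u] <- TRUE
    s <- u - 1L
    memb <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    out <- setdiff(seq_len(n), memb)
    for (j in out) {
      touches <- any((adj[, 1] == j & adj[, 2] %in% memb) |
                     (adj[, 2] == j & adj[, 1] %in% memb))
      if (!touches) next
      t2 <- s + bitwShiftL(1L, j - 1L)
      nd <- max(dist[u], G[t2 + 1L])
      if (nd < dist[t2 + 1L]) dist[t2 + 1L] <- nd
    }
  }
  dist[full + 1L]
}

## Direct set-scan sharing statistics from the layout grids alone.
oracleSharing <- function(system) {
  occ <- lapply(layouts(system), function(l) unique(layoutGrid(l)[!is.na(layoutGrid(l))]))
  counts <- table(unlist(occ))
  tabulate(counts, nbins = length(occ))
}

## Naive self-healing scan: for every location and every wrong tile, count
## matching sides one edge at a time with gluesMatch().
oracleSelfHealing <- function(system) {
  tl <- tiles(system)
  bad <- list()
  for (ly in layouts(system)) {
    g <- layoutGrid(ly)
    for (r in seq_len(nrow(g))) for (cc in seq_len(ncol(g))) {
      if (is.na(g[r, cc])) next
      for (tn in tl$name) {
        if (tn == g[r, cc]) next
        m <- 0L
        for (d in list(c("N", -1, 0, "S"), c("E", 0, 1, "W"),
                       c("S", 1, 0, "N"), c("W", 0, -1, "E"))) {
          r2 <- r + as.integer(d[2]); c2 <- cc + as.integer(d[3])
          if (r2 < 1 || r2 > nrow(g) || c2 < 1 || c2 > ncol(g)) next
          if (is.na(g[r2, c2])) next
          mine <- tl[[d[1]]][tl$name == tn]
          theirs <- tl[[d[4]]][tl$name == g[r2, c2]]
          if (gluesMatch(mine, theirs)) m <- m + 1L
        }
        if (m >= 2L)
          bad[[length(bad) + 1L]] <- c(layoutName(ly), r, cc, tn)
      }
    }
  }
  bad
}

## Naive two-step error-chain enumeration for the second-order criterion.
oracleSecondOrder <- function(system) {
  tl <- tiles(system)
  sideInfo <- list(N = c(-1, 0), E = c(0, 1), S = c(1, 0), W = c(0, -1))
  opp <- c(N = "S", E = "W", S = "N", W = "E")
  glueOf <- function(tn, s) tl[[s]][tl$name == tn]
  bad <- list()
  for (ly in layouts(system)) {
    g <- layoutGrid(ly)
    inGrid <- function(r, cc) r >= 1 && r <= nrow(g) && cc >= 1 && cc <= ncol(g)
    matchesAt <- function(tn, r, cc) {
      m <- 0L
      for (s in names(sideInfo)) {
        r2 <- r + sideInfo[[s]][1]; c2 <- cc + sideInfo[[s]][2]
        if (!inGrid(r2, c2) || is.na(g[r2, c2])) next
        if (gluesMatch(glueOf(tn, s), glueOf(g[r2, c2], opp[[s]]))) m <- m + 1L
      }
      m
    }
    for (r in seq_len(nrow(g))) for (cc in seq_len(ncol(g))) {
      if (is.na(g[r, cc])) next
      for (tn in tl$name) {
        if (tn == g[r, cc] || matchesAt(tn, r, cc) != 1L) next
        ## tn erroneously at (r, cc); can a further wrong tile attach by 2
        ## bonds, one of them to tn, at a neighbouring empty position?
        for (s in names(sideInfo)) {
          r2 <- r + sideInfo[[s]][1]; c2 <- cc + sideInfo[[s]][2]
          if (!inGrid(r2, c2)) next
          correct2 <- g[r2, c2]
          for (t2 in tl$name) {
            if (!is.na(correct2) && t2 == correct2) next
            if (t2 == tn) next
            bToErr <- gluesMatch(glueOf(t2, opp[[s]]), glueOf(tn, s))
            if (!bToErr) next
            m <- 1L
            for (e in names(sideInfo)) {
              if (e == opp[[s]]) next
              r3 <- r2 + sideInfo[[e]][1]; c3 <- c2 + sideInfo[[e]][2]
              if (r3 == r && c3 == cc) next
              if (!inGrid(r3, c3) || is.na(g[r3, c3])) next
              if (gluesMatch(glueOf(t2, e), glueOf(g[r3, c3], opp[[e]])))
                m <- m + 1L
            }
            if (m >= 2L)
              bad[[length(bad) + 1L]] <- c(layoutName(ly), r, cc, tn, r2, c2, t2)
          }
        }
      }
    }
  }
  bad
}

## All permutations of a small vector (for the toy training brute force).
allPerms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}
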