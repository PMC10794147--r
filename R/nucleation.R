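## Internal: precomputed sampling engine for one layout under one pattern.
.sgmEngine <- function(layout, pattern, params, tempC = 53) {
  li <- .layoutIndex(layout)
  conc <- pattern[li$cells$tile]
  if (anyNA(conc))
    stop("pattern is missing concentrations for tile(s): ",
         paste(unique(li$cells$tile[is.na(conc)]), collapse = ", "))
  if (any(conc <= 0)) stop("all concentrations must be > 0")
  list(li = li, n = li$n, nbrM = li$nbr,
       gmc = .gmc(unname(conc), params),
       logc = log(unname(conc) * 1e-9 / params@u0),
       Gse = gseAt(params, tempC), alpha = params@alpha,
       cells = li$cells, layout = layout)
}

## Internal: one stochastic greedy growth path from a start cell index.
## Favourable attachments (dG < 0) are exhausted one at a time, most
## favourable first (ties broken by row-major location order); when none is
## favourable one unfavourable attachment is chosen with probability
## proportional to exp(-dG) ("boltzmann") or to its relative closeness to the
## least unfavourable dG ("linear"). Growth stops at full tiling or once the
## running G has fallen `margin` RT below the running barrier.
.sgmPath <- function(eng, start, margin = 10, cap = Inf,
                     weighting = c("boltzmann", "linear")) {
  weighting <- match.arg(weighting)
  n <- eng$n; nbrM <- eng$nbrM; gmc <- eng$gmc; Gse <- eng$Gse
  occ <- logical(n)
  nb <- integer(n)
  ord <- integer(n)
  Gtraj <- numeric(n)
  occ[start] <- TRUE; ord[1L] <- start
  for (m in nbrM[start, ]) if (!is.na(m)) nb[m] <- nb[m] + 1L
  G <- gmc[start]; Gtraj[1L] <- G
  barrier <- G; bSize <- 1L
  k <- 1L
  while (k < n && k < cap) {
    cand <- which(nb > 0L & !occ)
    if (!length(cand)) break
    dg <- gmc[cand] - nb[cand] * Gse
    if (any(dg < 0)) {
      j <- which.min(dg)            # stable: first index on ties
    } else if (length(cand) == 1L) {
      j <- 1L
    } else {
      w <- if (weighting == "boltzmann") exp(-(dg - min(dg)))
           else (max(dg) - dg) + 1e-9
      j <- sample.int(length(cand), 1L, prob = w)
    }
    pick <- cand[j]
    k <- k + 1L
    occ[pick] <- TRUE; ord[k] <- pick
    G <- G + dg[j]; Gtraj[k] <- G
    for (m in nbrM[pick, ]) if (!is.na(m) && !occ[m]) nb[m] <- nb[m] + 1L
    if (G > barrier) { barrier <- G; bSize <- k }
    if (G <= barrier - margin) break
  }
  list(order = ord[seq_len(k)], G = Gtraj[seq_len(k)],
       barrier = barrier, barrierSize = bSize)
}

#' Sample one stochastic greedy nucleation pathway
#'
#' Grows an assembly from a single starting monomer by single-tile additions:
#' while any attachment is favourable (dG < 0) the most favourable one is
#' made deterministically (ties broken by fixed row-major location order);
#' when none is favourable, one unfavourable attachment is chosen with
#' probability weighted by the relative free-energy differences (Boltzmann
#' weights exp(-dG) by default). The barrier is the highest free energy
#' visited; growth stops at full tiling or once G has dropped \code{margin}
#' RT below the running barrier (commitment to downhill growth).
#'
#' @param layout a \linkS4class{ShapeLayout}.
#' @param pattern named numeric concentrations (nM) covering the layout.
#' @param params an \linkS4class{EnergyParams}.
#' @param start integer c(row, col), an occupied layout location.
#' @param margin stop once G <= barrier - margin (RT).
#' @param cap maximum number of tiles added (safety cap).
#' @param weighting "boltzmann" (exp(-dG)) or "linear" unfavourable-step
#'   weights.
#' @param tempC temperature for Gse in temperature mode.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return object of class \code{GreedyPath}: list with \code{cells} (the
#'   growth order as a data.frame row/col/tile), \code{G} (free energy after
#'   each step), \code{barrier} (max G), \code{barrierSize} (tiles in the
#'   barrier state), \code{barrierCells}, and \code{start}.
#' @export
sgmSamplePath <- function(layout, pattern, params, start, margin = 10,
                          cap = Inf, weighting = "boltzmann", tempC = 53,
                          seed = NULL) {
  eng <- .sgmEngine(layout, pattern, params, tempC)
  if (start[[1L]] < 1L || start[[1L]] > eng$li$dim[1L] ||
      start[[2L]] < 1L || start[[2L]] > eng$li$dim[2L] ||
      is.na(s <- eng$li$pos[start[[1L]], start[[2L]]]))
    stop("start location is not occupied in the layout")
  p <- withSeed(seed, .sgmPath(eng, s, margin = margin, cap = cap,
                               weighting = weighting))
  structure(list(
    shape = layout@name,
    cells = eng$cells[p$order, c("row", "col", "tile")],
    G = p$G, barrier = p$barrier, barrierSize = p$barrierSize,
    barrierCells = eng$cells[p$order[seq_len(p$barrierSize)],
                             c("row", "col", "tile")],
    start = c(row = start[[1L]], col = start[[2L]])),
    class = "GreedyPath")
}

#' @export
print.GreedyPath <- function(x, ...) {
  cat(sprintf(
    "GreedyPath (%s): %d steps from (%d,%d); barrier %.3f RT at size %d\n",
    x$shape, nrow(x$cells), x$start[["row"]], x$start[["col"]],
    x$barrier, x$barrierSize))
  invisible(x)
}

#' Estimate a shape's nucleation rate by stochastic greedy sampling
#'
#' Samples \code{nPaths} greedy pathways from every start site, records the
#' barrier state of each path, and applies the Arrhenius approximation:
#' assuming equilibrium occupation of each distinct barrier state A, its
#' contribution is \code{exp(-G(A))} times the sum over available forward
#' attachments of \code{c_tile / u0} (second-order attachment kinetics).
#' Identical barrier states sampled via different growth orders are counted
#' once; the shape rate is the sum over distinct barrier states.
#'
#' @inheritParams sgmSamplePath
#' @param nPaths number of sampled paths per start site.
#' @param starts optional data.frame/matrix of start locations (row, col);
#'   defaults to every occupied location.
#' @return object of class \code{NucleationEstimate}: list with \code{rate},
#'   \code{logRate}, \code{shape}, \code{barriers} (per-path), \code{K}
#'   (median barrier-state size), \code{participation} (canvas matrix: the
#'   contribution-weighted fraction of the estimated rate carried by barrier
#'   states containing each location, in [0,1]), \code{perStart}
#'   (data.frame of per-start-site minimum and median barriers),
#'   \code{nPaths}, \code{nDistinctBarriers}.
#' @export
sgmEstimateRate <- function(layout, pattern, params, nPaths = 50,
                            starts = NULL, margin = 10, cap = Inf,
                            weighting = "boltzmann", tempC = 53,
                            seed = NULL) {
  eng <- .sgmEngine(layout, pattern, params, tempC)
  if (is.null(starts)) sidx <- seq_len(eng$n)
  else {
    starts <- as.matrix(starts)
    sidx <- eng$li$pos[starts[, 1:2, drop = FALSE]]
    if (anyNA(sidx)) stop("a start location is not occupied in the layout")
  }
  withSeed(seed, {
    total <- length(sidx) * nPaths
    barriers <- numeric(total)
    bsizes <- integer(total)
    startcol <- integer(total)
    seen <- new.env(parent = emptyenv())
    i <- 0L
    for (s in sidx) for (rep in seq_len(nPaths)) {
      i <- i + 1L
      p <- .sgmPath(eng, s, margin = margin, cap = cap, weighting = weighting)
      barriers[i] <- p$barrier
      bsizes[i] <- p$barrierSize
      startcol[i] <- s
      bc <- p$order[seq_len(p$barrierSize)]
      key <- paste(sort(bc), collapse = ",")
      if (is.null(seen[[key]]))
        seen[[key]] <- list(G = p$barrier, cells = sort(bc))
    }
    ## sum contributions over distinct barrier states
    keys <- ls(seen)
    logContrib <- vapply(keys, function(k) {
      st <- seen[[k]]
      occ <- logical(eng$n); occ[st$cells] <- TRUE
      fwd <- unique(stats::na.omit(as.vector(eng$nbrM[st$cells, , drop = FALSE])))
      fwd <- fwd[!occ[fwd]]
      if (!length(fwd)) return(-Inf)
      -st$G + logSumExp(eng$logc[fwd])
    }, numeric(1))
    logRate <- logSumExp(logContrib)
    ## participation: fraction of the total rate carried by barrier states
    ## containing each location (contribution-weighted, in [0, 1])
    partCount <- numeric(eng$n)
    w <- exp(logContrib - max(logContrib[is.finite(logContrib)], -Inf))
    w[!is.finite(w)] <- 0
    for (j in seq_along(keys))
      partCount[seen[[keys[j]]]$cells] <- partCount[seen[[keys[j]]]$cells] + w[j]
    part <- matrix(0, eng$li$dim[1L], eng$li$dim[2L])
    if (sum(w) > 0)
      part[cbind(eng$cells$row, eng$cells$col)] <- partCount / sum(w)
    perStart <- do.call(rbind, lapply(split(seq_len(total), startcol), function(ii) {
      s <- startcol[ii[1L]]
      data.frame(row = eng$cells$row[s], col = eng$cells$col[s],
                 minBarrier = min(barriers[ii]),
                 medianBarrier = stats::median(barriers[ii]))
    }))
    structure(list(shape = layout@name, rate = exp(logRate),
                   logRate = logRate, barriers = barriers,
                   K = stats::median(bsizes), participation = part,
                   perStart = perStart, nPaths = total,
                   nDistinctBarriers = length(keys)),
              class = "NucleationEstimate")
  })
}

#' @export
print.NucleationEstimate <- function(x, ...) {
  cat(sprintf(
    "NucleationEstimate (%s): log rate %.3f (%d paths, %d distinct barrier states)\n",
    x$shape, x$logRate, x$nPaths, x$nDistinctBarriers))
  cat(sprintf("  min barrier %.3f RT; median barrier-state size K = %g\n",
              min(x$barriers), x$K))
  invisible(x)
}

#' Window Nucleation Model score
#'
#' A fast nucleation proxy: for every k x k window of locations fully inside
#' the shape, the window weight is the equilibrium Boltzmann weight of the
#' fully assembled window, \code{exp(sum_i log(c_i/u0) + Bw * Gse)} with
#' \code{Bw = 2 k (k-1)} internal bonds; the score sums the weights over all
#' windows and is monotone increasing in every concentration.
#'
#' @inheritParams sgmSamplePath
#' @param k window side length (>= 1).
#' @return numeric score, with attributes \code{logScore} (log of the score,
#'   computed stably) and \code{nWindows}.
#' @export
wnmScore <- function(layout, pattern, params, k = 2, tempC = 53) {
  stopifnot(k >= 1)
  g <- layout@grid
  occ <- !is.na(g)
  if (nrow(g) < k || ncol(g) < k)
    stop("no complete ", k, "x", k, " window fits the canvas")
  conc <- pattern[g[occ]]
  if (anyNA(conc))
    stop("pattern is missing concentrations for some layout tiles")
  logc <- matrix(NA_real_, nrow(g), ncol(g))
  logc[occ] <- log(unname(conc) * 1e-9 / params@u0)
  Bw <- 2 * k * (k - 1)
  Gse <- gseAt(params, tempC)
  ## summed-area tables give all k x k window sums at once
  sat <- function(m) {
    m <- apply(m, 2L, cumsum)
    m <- t(apply(m, 1L, cumsum))
    rbind(0, cbind(0, m))
  }
  z <- logc; z[!occ] <- 0
  So <- sat(occ + 0); Sl <- sat(z)
  nr <- nrow(g) - k + 1L; nc <- ncol(g) - k + 1L
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  wsum <- function(S)
    S[r0 + k, c0 + k, drop = FALSE] - S[r0, c0 + k, drop = FALSE] -
    S[r0 + k, c0, drop = FALSE] + S[r0, c0, drop = FALSE]
  full <- wsum(So) == k * k
  logw <- wsum(Sl)[full] + Bw * Gse
  if (!length(logw))
    stop("layout contains no fully occupied ", k, "x", k, " window")
  ls <- logSumExp(logw)
  structure(exp(ls), logScore = ls, nWindows = length(logw))
}

#' Free-energy profile over assembly size
#'
#' Aggregates sampled pathway states by assembly size n: reports the minimum
#' free energy among distinct sampled states of each size and the macrostate
#' free energy \code{-log sum exp(-G)} over those states. In
#' nucleation-limited regimes the profile has a maximum at the barrier.
#'
#' @param x a list of \code{GreedyPath} objects, or a
#'   \linkS4class{ShapeLayout} (paths are then sampled internally).
#' @inheritParams sgmEstimateRate
#' @return data.frame with columns \code{size, minG, macroG, nStates}.
#' @export
freeEnergyProfile <- function(x, pattern = NULL, params = NULL, nPaths = 50,
                              tempC = 53, seed = NULL, ...) {
  if (is(x, "ShapeLayout")) {
    eng <- .sgmEngine(x, pattern, params, tempC)
    paths <- withSeed(seed, {
      unlist(lapply(seq_len(eng$n), function(s)
        lapply(seq_len(nPaths), function(i) {
          p <- .sgmPath(eng, s, ...)
          list(order = p$order, G = p$G)
        })), recursive = FALSE)
    })
    getStates <- function(p) list(order = p$order, G = p$G)
  } else {
    stopifnot(is.list(x), length(x) >= 1L)
    paths <- lapply(x, function(p) {
      key <- paste(p$cells$row, p$cells$col, sep = "_")
      list(order = key, G = p$G)
    })
  }
  seen <- new.env(parent = emptyenv())
  for (p in paths) {
    for (n in seq_along(p$G)) {
      key <- paste(n, paste(sort(p$order[seq_len(n)]), collapse = ","), sep = ":")
      if (is.null(seen[[key]])) seen[[key]] <- c(n, p$G[n])
    }
  }
  states <- do.call(rbind, mget(ls(seen), envir = seen))
  df <- data.frame(size = states[, 1L], G = states[, 2L])
  out <- do.call(rbind, lapply(split(df, df$size), function(d)
    data.frame(size = d$size[1L], minG = min(d$G),
               macroG = -logSumExp(-d$G), nStates = nrow(d))))
  out[order(out$size), , drop = FALSE]
}

#' Classify a concentration pattern by competitive nucleation
#'
#' Computes per-shape nucleation rates (SGM) or window scores (WNM) for
#' every layout of the system and returns the shape with the highest
#' (log) rate together with the log-ratio margin over the runner-up. Exact
#' ties are reported explicitly rather than silently broken.
#'
#' @param pattern named numeric concentrations (nM) over the system tiles.
#' @param system a \linkS4class{TileSystem}.
#' @param params an \linkS4class{EnergyParams}.
#' @param method "sgm" or "wnm".
#' @param k WNM window size.
#' @param nPaths SGM paths per start site.
#' @param tieTol log-rate difference below which a tie is declared.
#' @param ... passed to \code{\link{sgmEstimateRate}}.
#' @inheritParams sgmSamplePath
#' @return object of class \code{PatternClassification}: list with
#'   \code{predicted} (shape name, or NA on a tie), \code{tie} (logical),
#'   \code{logRates} (named vector), \code{margin} (log-ratio of best over
#'   runner-up) and \code{method}.
#' @export
classifyPattern <- function(pattern, system, params,
                            method = c("sgm", "wnm"), k = 2, nPaths = 50,
                            tempC = 53, seed = NULL, tieTol = 1e-9, ...) {
  method <- match.arg(method)
  if (!length(system@layouts)) stop("system has no layouts")
  ## each layout gets the same RNG stream, so identical layouts under
  ## identical patterns receive exactly equal rate estimates
  lr <- vapply(system@layouts, function(ly) {
    if (method == "sgm")
      sgmEstimateRate(ly, pattern, params, nPaths = nPaths,
                      tempC = tempC, seed = seed, ...)$logRate
    else
      attr(wnmScore(ly, pattern, params, k = k, tempC = tempC), "logScore")
  }, numeric(1))
  ord <- order(lr, decreasing = TRUE)
  margin <- if (length(lr) > 1L) lr[ord[1L]] - lr[ord[2L]] else Inf
  tie <- is.na(margin) || margin <= tieTol
  structure(list(predicted = if (tie) NA_character_ else names(lr)[ord[1L]],
                 tie = tie, logRates = lr, margin = unname(margin),
                 method = method),
            class = "PatternClassification")
}

#' @export
print.PatternClassification <- function(x, ...) {
  if (x$tie)
    cat(sprintf("PatternClassification (%s): TIE among shapes\n", x$method))
  else
    cat(sprintf("PatternClassification (%s): %s (log-ratio margin %.3f)\n",
                x$method, x$predicted, x$margin))
  print(round(x$logRates, 3))
  invisible(x)
}
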