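#' Define a pixel-to-tile training problem
#'
#' Bundles the training images (one class per target shape), the tile
#' system, the energy/nucleation parameters and the loss hyperparameters.
#' All images must be standardised to the same level histogram (see
#' \code{\link{preprocessImage}}).
#'
#' @param images list of standardised grayscale matrices (equal dimensions).
#' @param labels character vector of shape names, one per image.
#' @param system a \linkS4class{TileSystem}.
#' @param params an \linkS4class{EnergyParams}.
#' @param method nucleation model for the loss: "wnm" (fast) or "sgm".
#' @param k WNM window size.
#' @param nPaths SGM paths per start site (method = "sgm").
#' @param base base concentration (nM) of the pixel map.
#' @param reserved reserved tile names (never assigned to pixels).
#' @param lambdaSite weight of the site-preference penalty; used with
#'   \code{siteWeights}.
#' @param siteWeights optional named list (by shape) of canvas matrices of
#'   location preference weights in [0, 1] (1 = preferred nucleation site);
#'   the penalty charges SGM barrier-state participation that falls on
#'   low-weight locations.
#' @param lambdaReserved weight of the reserved-tile violation penalty.
#' @param tempC temperature for Gse in temperature mode.
#' @param seed seed used for stochastic (SGM) loss evaluations.
#' @return object of class \code{TrainingProblem}.
#' @export
trainingProblem <- function(images, labels, system, params,
                            method = c("wnm", "sgm"), k = 2, nPaths = 10,
                            base = 16.67, reserved = character(),
                            lambdaSite = 0, siteWeights = NULL,
                            lambdaReserved = 1, tempC = 53, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(images) == length(labels), length(images) >= 1L)
  bad <- setdiff(unique(labels), names(layouts(system)))
  if (length(bad))
    stop("label(s) do not name a layout: ", paste(bad, collapse = ", "))
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1L) stop("all images must have identical dimensions")
  hists <- unique(lapply(images, function(im) sort(table(as.vector(im)))))
  if (length(hists) != 1L)
    stop("images do not share a common level histogram; standardise them first")
  prob <- list(images = images, labels = labels, system = system,
               params = params, method = method, k = k, nPaths = nPaths,
               base = base, reserved = reserved, lambdaSite = lambdaSite,
               siteWeights = siteWeights, lambdaReserved = lambdaReserved,
               tempC = tempC, seed = seed, dim = dims[[1L]])
  prob$wnmCache <- .wnmCache(system, params, k, tempC)
  structure(prob, class = "TrainingProblem")
}

## Internal: precomputed WNM evaluator. For each shape, an index matrix of
## the tiles in every fully occupied k x k window (into tileNames(system))
## plus the constant bond bonus, so a log score is a rowSums + logSumExp
## over a per-pattern log-concentration vector.
.wnmCache <- function(system, params, k, tempC) {
  nm <- tileNames(system)
  bonus <- 2 * k * (k - 1) * gseAt(params, tempC)
  shapes <- lapply(layouts(system), function(ly) {
    g <- ly@grid
    occ <- !is.na(g)
    wins <- list()
    if (nrow(g) >= k && ncol(g) >= k)
      for (r in seq_len(nrow(g) - k + 1L))
        for (cc in seq_len(ncol(g) - k + 1L)) {
          w <- g[r:(r + k - 1L), cc:(cc + k - 1L)]
          if (!anyNA(w)) wins[[length(wins) + 1L]] <- match(as.vector(w), nm)
        }
    if (!length(wins)) return(NULL)
    do.call(rbind, wins)
  })
  list(tiles = nm, bonus = bonus, u0 = params@u0, shapes = shapes)
}

## Internal: per-shape WNM log scores for a pattern, using the cache.
.cachedLogScores <- function(pattern, cache) {
  logc <- log(unname(pattern[cache$tiles]) * 1e-9 / cache$u0)
  vapply(cache$shapes, function(W) {
    if (is.null(W)) return(-Inf)
    logSumExp(rowSums(matrix(logc[W], nrow(W))) + cache$bonus)
  }, numeric(1))
}

## Internal: per-shape log rates/scores for one pattern under the problem's
## nucleation model.
.problemLogRates <- function(pattern, problem) {
  sys <- problem$system
  if (problem$method == "wnm" && !is.null(problem$wnmCache))
    return(.cachedLogScores(pattern, problem$wnmCache))
  vapply(layouts(sys), function(ly) {
    if (problem$method == "sgm")
      sgmEstimateRate(ly, pattern, problem$params, nPaths = problem$nPaths,
                      tempC = problem$tempC, seed = problem$seed)$logRate
    else
      attr(wnmScore(ly, pattern, problem$params, k = problem$k,
                    tempC = problem$tempC), "logScore")
  }, numeric(1))
}

#' Training loss of a pixel-to-tile map
#'
#' Sums, over training images, a softmax-margin term
#' \code{-(log r_on - log sum r_off)} on the per-shape nucleation rates of
#' the image's concentration pattern, plus a site-preference penalty (SGM
#' barrier participation on low-weight locations) and a reserved-tile
#' violation penalty. Lower is better; decreasing the on-target rate margin
#' of any image increases the loss.
#'
#' @param theta a \linkS4class{ThetaMap}.
#' @param problem a \code{TrainingProblem}.
#' @return scalar loss.
#' @export
trainingLoss <- function(theta, problem) {
  sys <- problem$system
  loss <- 0
  for (i in seq_along(problem$images)) {
    pat <- imageToConcentrations(problem$images[[i]], theta, sys,
                                 base = problem$base)
    lr <- .problemLogRates(pat, problem)
    on <- problem$labels[[i]]
    off <- setdiff(names(lr), on)
    margin <- if (length(off)) lr[[on]] - logSumExp(lr[off]) else lr[[on]]
    loss <- loss - margin
    if (problem$lambdaSite > 0 && !is.null(problem$siteWeights) &&
        problem$method == "sgm") {
      est <- sgmEstimateRate(layouts(sys)[[on]], pat, problem$params,
                             nPaths = problem$nPaths, tempC = problem$tempC,
                             seed = problem$seed)
      w <- problem$siteWeights[[on]]
      loss <- loss + problem$lambdaSite * sum(est$participation * (1 - w))
    }
  }
  loss + problem$lambdaReserved *
    length(intersect(as.vector(theta@assign), problem$reserved))
}

## Internal: one random theta move. Either swaps the tiles of two pixels or
## swaps an assigned tile with a random non-reserved unassigned tile.
.thetaMove <- function(theta) {
  a <- theta@assign
  pool <- setdiff(theta@unassigned, theta@reserved)
  swapOut <- length(pool) > 0L && stats::runif(1) < 0.3
  if (swapOut) {
    i <- sample.int(length(a), 1L)
    tnew <- pool[sample.int(length(pool), 1L)]
    told <- a[[i]]
    a[[i]] <- tnew
    un <- c(setdiff(theta@unassigned, tnew), told)
    thetaMap(a, unassigned = un, reserved = theta@reserved)
  } else {
    ij <- sample.int(length(a), 2L)
    a[ij] <- a[rev(ij)]
    thetaMap(a, unassigned = theta@unassigned, reserved = theta@reserved)
  }
}

#' Optimise a pixel-to-tile map by hill climbing
#'
#' Starting from \code{theta0}, attempts random modifications (swapping the
#' tiles of two pixels, or swapping an assigned tile with an unassigned
#' non-reserved one) and accepts a move only if it strictly decreases the
#' training loss, so the loss trajectory is monotone non-increasing.
#'
#' @param theta0 starting \linkS4class{ThetaMap}.
#' @param problem a \code{TrainingProblem}.
#' @param nSteps number of attempted moves.
#' @param seed optional integer seed.
#' @return object of class \code{TrainingResult}: list with \code{theta},
#'   \code{loss}, \code{trajectory} (loss after each attempted step),
#'   \code{accepted} (number of accepted moves), \code{model} (nucleation
#'   model used).
#' @export
hillClimb <- function(theta0, problem, nSteps = 200, seed = NULL) {
  withSeed(seed, {
    cur <- theta0
    curLoss <- trainingLoss(cur, problem)
    traj <- numeric(nSteps)
    acc <- 0L
    for (s in seq_len(nSteps)) {
      cand <- .thetaMove(cur)
      l <- trainingLoss(cand, problem)
      if (l < curLoss) {
        cur <- cand; curLoss <- l; acc <- acc + 1L
      }
      traj[s] <- curLoss
    }
    structure(list(theta = cur, loss = curLoss, trajectory = traj,
                   accepted = acc, model = problem$method),
              class = "TrainingResult")
  })
}

#' @export
print.TrainingResult <- function(x, ...) {
  cat(sprintf("TrainingResult (%s): loss %.4f after %d accepted moves\n",
              x$model, x$loss, x$accepted))
  invisible(x)
}

#' Train a pixel-to-tile map (WNM phase, then SGM refinement)
#'
#' Runs restarted hill climbs under the fast window model, keeps the best
#' map, then (optionally) refines it with the more detailed stochastic
#' greedy model for a further budget of steps.
#'
#' @param problem a \code{TrainingProblem} (its \code{method} is overridden
#'   per phase).
#' @param wnmSteps hill-climbing steps per restart in the WNM phase.
#' @param sgmSteps refinement steps under the SGM loss (0 = skip).
#' @param restarts number of random initial maps.
#' @param seed integer seed.
#' @return a \code{TrainingResult}; \code{$phases} records the per-phase
#'   losses.
#' @export
trainTheta <- function(problem, wnmSteps = 300, sgmSteps = 0, restarts = 3,
                       seed = 1) {
  withSeed(seed, {
    pw <- problem; pw$method <- "wnm"
    best <- NULL
    for (r in seq_len(restarts)) {
      t0 <- randomTheta(problem$system, size = problem$dim,
                        reserved = problem$reserved)
      res <- hillClimb(t0, pw, nSteps = wnmSteps)
      if (is.null(best) || res$loss < best$loss) best <- res
    }
    phases <- data.frame(phase = "wnm", loss = best$loss,
                         stringsAsFactors = FALSE)
    if (sgmSteps > 0) {
      ps <- problem; ps$method <- "sgm"
      res2 <- hillClimb(best$theta, ps, nSteps = sgmSteps)
      best <- res2
      phases <- rbind(phases, data.frame(phase = "sgm", loss = best$loss,
                                         stringsAsFactors = FALSE))
    }
    best$phases <- phases
    best
  })
}

#' Classification accuracy of a map on a training problem
#'
#' @param theta a \linkS4class{ThetaMap}.
#' @param problem a \code{TrainingProblem}.
#' @return fraction of images whose pattern is classified to its label
#'   (ties count as errors).
#' @export
trainingAccuracy <- function(theta, problem) {
  ok <- vapply(seq_along(problem$images), function(i) {
    pat <- imageToConcentrations(problem$images[[i]], theta, problem$system,
                                 base = problem$base)
    cl <- classifyPattern(pat, problem$system, problem$params,
                          method = problem$method, k = problem$k,
                          nPaths = problem$nPaths, tempC = problem$tempC,
                          seed = problem$seed)
    !cl$tie && identical(cl$predicted, problem$labels[[i]])
  }, logical(1))
  mean(ok)
}

#' Random standardised toy images
#'
#' Generates random grayscale images and standardises them, so they satisfy
#' the standard-histogram contract at the given size. Used by tests and
#' examples as stand-ins for photographic training images.
#'
#' @param n number of images.
#' @param size image dimensions c(rows, cols).
#' @param seed integer seed.
#' @return list of standardised matrices.
#' @export
makeRandomImages <- function(n, size = c(5, 5), seed = 1) {
  withSeed(seed, lapply(seq_len(n), function(i)
    preprocessImage(matrix(stats::runif(prod(size)), size[1L], size[2L]),
                    size = size)))
}
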