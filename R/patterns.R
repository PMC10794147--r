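## The ten grayscale levels are p = k/9, k = 0..9; level concentrations are
## geometric with ratio 3^(1/3), from the base (16.67 nM) to 27x the base
## (450 nM), matching both printed endpoints of the exponential map.
.N_LEVELS <- 10L

#' Exponential pixel-to-concentration map
#'
#' Converts grayscale values p in [0, 1] to tile concentrations
#' \code{c = base * exp(3 * p * ln 3)} nM: 16.67 nM at p = 0 rising to
#' 450 nM (nearest nM) at p = 1.
#'
#' @param p numeric grayscale values in [0, 1].
#' @param base base concentration in nM.
#' @return concentrations in nM.
#' @examples
#' pixelConcentration(c(0, 1/3, 1))
#' @export
pixelConcentration <- function(p, base = 16.67) {
  stopifnot(all(p >= 0 & p <= 1))
  base * exp(3 * p * log(3))
}

#' Level concentrations of the ten-level grayscale quantisation
#'
#' @param base base concentration in nM.
#' @return the ten concentrations \code{base * 3^(k/3)}, k = 0..9.
#' @export
levelConcentrations <- function(base = 16.67) {
  pixelConcentration((0:(.N_LEVELS - 1L)) / (.N_LEVELS - 1L), base)
}

#' The standard grayscale histogram
#'
#' The fixed per-level pixel counts to which every image is standardised.
#' The counts follow a geometric level profile (the unique ratio for which
#' the continuous profile has mean tile concentration exactly 60 nM),
#' rounded to integers by largest remainder and minimally adjusted so the
#' realised mean concentration still rounds to 60 nM. The 900-pixel
#' histogram is part of the package's contract and is frozen by tests.
#'
#' @param nPixels total number of pixels (900 for 30 x 30 images).
#' @param targetMean target mean tile concentration in nM.
#' @param base base concentration in nM.
#' @return integer vector of length 10 (levels 0..9) summing to
#'   \code{nPixels}.
#' @examples
#' h <- standardHistogram()
#' sum(h)  # 900
#' round(sum(h * levelConcentrations()) / sum(h))  # 60
#' @export
standardHistogram <- function(nPixels = 900, targetMean = 60, base = 16.67) {
  ck <- levelConcentrations(base)
  k <- 0:(.N_LEVELS - 1L)
  f <- function(r) sum(r^k * ck) / sum(r^k) - targetMean
  r <- stats::uniroot(f, c(1e-4, 1 - 1e-9), tol = 1e-12)$root
  w <- r^k / sum(r^k)
  exact <- nPixels * w
  n <- floor(exact)
  short <- nPixels - sum(n)
  if (short > 0) {
    up <- order(exact - n, decreasing = TRUE)[seq_len(short)]
    n[up] <- n[up] + 1
  }
  ## minimal deterministic moves until the realised mean rounds to target
  meanOf <- function(n) sum(n * ck) / sum(n)
  for (iter in seq_len(1000L)) {
    if (abs(meanOf(n) - targetMean) <= 0.5 - 1e-9) break
    best <- NULL; bestDev <- abs(meanOf(n) - targetMean)
    for (i in which(n > 0)) for (j in seq_len(.N_LEVELS)) {
      if (i == j) next
      n2 <- n; n2[i] <- n2[i] - 1; n2[j] <- n2[j] + 1
      d <- abs(meanOf(n2) - targetMean)
      if (d < bestDev - 1e-12) { best <- c(i, j); bestDev <- d }
    }
    if (is.null(best)) break
    n[best[1L]] <- n[best[1L]] - 1
    n[best[2L]] <- n[best[2L]] + 1
  }
  as.integer(n)
}

## Internal: area-average resampling weights (nOut x nIn, rows sum to 1).
.overlapWeights <- function(nIn, nOut) {
  m <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    lo <- (i - 1) * nIn / nOut
    hi <- i * nIn / nOut
    for (j in (floor(lo) + 1L):min(ceiling(hi), nIn)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) m[i, j] <- ov
    }
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

#' Standardise a grayscale image
#'
#' Rescales any 2-D grayscale image to the target size by deterministic
#' area-average downsampling, then discretises it to the ten grayscale
#' levels so that the number of pixels at each level equals the standard
#' histogram. Level assignment is by intensity rank (ties broken by
#' row-major scan order), so the discretisation is invariant under monotone
#' intensity transforms of the resampled image (and under affine transforms
#' of the raw input, which commute with area averaging); it is idempotent on
#' already-standardised images.
#'
#' @param img numeric matrix of intensities (any range; larger = brighter).
#' @param size target c(rows, cols); default 30 x 30.
#' @param histogram per-level counts; defaults to
#'   \code{standardHistogram(prod(size))}.
#' @return matrix of grayscale values p in \{0, 1/9, ..., 1\} with the
#'   standard level histogram.
#' @export
preprocessImage <- function(img, size = c(30, 30),
                            histogram = standardHistogram(prod(size))) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (sum(histogram) != prod(size))
    stop("histogram must sum to the number of pixels")
  rs <- if (all(dim(img) == size)) img
        else .overlapWeights(nrow(img), size[1L]) %*% img %*%
             t(.overlapWeights(ncol(img), size[2L]))
  v <- as.vector(t(rs))                       # row-major scan order
  ord <- order(v)                             # stable: ties by scan order
  lev <- integer(length(v))
  lev[ord] <- rep(0:(.N_LEVELS - 1L), times = histogram)
  matrix(lev / (.N_LEVELS - 1L), size[1L], size[2L], byrow = TRUE)
}

#' Read a grayscale image from PNG, PGM (P2) or CSV
#'
#' @param path file path; format chosen by extension (.png needs the png
#'   package; .pgm must be ASCII "P2"; anything else is read as a CSV grid
#'   of numbers).
#' @return numeric matrix of intensities.
#' @export
readImageGray <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L]), drop = FALSE],
                                         c(1L, 2L), mean)
    a
  } else if (ext == "pgm") {
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (toks[1L] != "P2") stop("only ASCII PGM (P2) is supported")
    nc <- as.integer(toks[2L]); nr <- as.integer(toks[3L])
    vals <- as.numeric(toks[-(1:4)])
    matrix(vals, nr, nc, byrow = TRUE)
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

#' Construct a pixel-to-tile map
#'
#' @param assign character matrix of tile names (image dimensions).
#' @param unassigned tiles not mapped by any pixel.
#' @param reserved subset of \code{unassigned} that must keep the lowest
#'   concentration (fluorophore/quencher label locations).
#' @return a \linkS4class{ThetaMap}.
#' @export
thetaMap <- function(assign, unassigned = character(), reserved = character()) {
  new("ThetaMap", assign = assign, unassigned = unassigned,
      reserved = reserved)
}

#' @describeIn thetaMap a uniformly random injective map from pixels to the
#'   non-reserved tiles; reserved tiles are drawn from the unassigned pool
#'   first.
#' @param tiles character vector of tile names, or a
#'   \linkS4class{TileSystem}.
#' @param size image dimensions c(rows, cols).
#' @param seed optional integer seed.
#' @export
randomTheta <- function(tiles, size = c(30, 30), reserved = character(),
                        seed = NULL) {
  if (is(tiles, "TileSystem")) tiles <- tileNames(tiles)
  npix <- prod(size)
  avail <- setdiff(tiles, reserved)
  if (length(avail) < npix)
    stop(sprintf("need %d assignable tiles for %d pixels but only %d available",
                 npix, npix, length(avail)))
  withSeed(seed, {
    asg <- sample(avail, npix)
    thetaMap(matrix(asg, size[1L], size[2L]),
             unassigned = setdiff(tiles, asg), reserved = reserved)
  })
}

#' @describeIn thetaMap accessor for the assignment matrix.
#' @param theta a ThetaMap.
#' @export
thetaAssign <- function(theta) theta@assign

#' @describeIn thetaMap accessor for the unassigned tiles.
#' @export
unassignedTiles <- function(theta) theta@unassigned

#' @describeIn thetaMap accessor for the reserved tiles.
#' @export
reservedTiles <- function(theta) theta@reserved

#' Convert a standardised image to a concentration pattern
#'
#' Applies \code{\link{pixelConcentration}} to each pixel and assigns the
#' result to the tile \code{theta(n)}; tiles not set by any pixel (including
#' all reserved tiles) are set to the base concentration.
#'
#' @param image standardised grayscale matrix (see
#'   \code{\link{preprocessImage}}).
#' @param theta a \linkS4class{ThetaMap} with the image's dimensions.
#' @param system a \linkS4class{TileSystem}; the returned pattern covers all
#'   of its tiles.
#' @param base base concentration in nM.
#' @return named numeric concentration vector (nM) over all system tiles.
#' @export
imageToConcentrations <- function(image, theta, system, base = 16.67) {
  a <- theta@assign
  if (!all(dim(image) == dim(a)))
    stop("image and theta dimensions differ")
  allTiles <- union(as.vector(a), theta@unassigned)
  missing <- setdiff(tileNames(system), allTiles)
  if (length(missing))
    stop("theta does not cover tile(s): ", paste(missing, collapse = ", "))
  if (length(intersect(as.vector(a), theta@reserved)))
    stop("a pixel is mapped to a reserved tile")
  pat <- stats::setNames(rep(base, nTiles(system)), tileNames(system))
  pat[as.vector(a)] <- pixelConcentration(as.vector(image), base)
  pat
}

#' Chequerboard parity of the shared-tile sublattice
#'
#' Reads the (row + col) parity on which tiles shared between layouts sit;
#' in the two-sublattice architecture shared tiles alternate with
#' shape-specific interaction tiles.
#'
#' @param system a \linkS4class{TileSystem}.
#' @return 0 or 1 (majority parity of shared-tile occurrences).
#' @export
sharedParity <- function(system) {
  st <- sharingStats(system)
  shared <- names(st$perTile)[st$perTile >= 2L]
  if (!length(shared)) stop("system has no shared tiles")
  occ <- .tileOccurrences(system)
  occ <- occ[occ$tile %in% shared, , drop = FALSE]
  par <- (occ$row + occ$col) %% 2L
  as.integer(round(mean(par)))
}

#' Build a flag concentration pattern
#'
#' A flag enhances the concentrations of the shared-sublattice
#' (chequerboard) tiles inside a window of one shape, leaving every other
#' tile at the base concentration. Tiles unique to a shape are never
#' enhanced, to avoid a thermodynamic bias towards one structure.
#'
#' @param system a \linkS4class{TileSystem} with shared tiles.
#' @param shape layout name carrying the flag.
#' @param center c(row, col) of the window centre.
#' @param base base concentration (nM) of unenhanced tiles.
#' @param enhanced concentration (nM) of enhanced tiles.
#' @param window odd window side length (published flags use 5).
#' @return object of class \code{FlagPattern}: list with \code{pattern}
#'   (named concentrations over all tiles), \code{enhancedTiles},
#'   \code{shape}, \code{center}, \code{window}.
#' @export
makeFlag <- function(system, shape, center, base = 50, enhanced = 880,
                     window = 5) {
  if (window %% 2 != 1) stop("window must be odd")
  ly <- system@layouts[[shape]]
  if (is.null(ly)) stop("no layout named '", shape, "'")
  h <- window %/% 2
  rr <- (center[[1L]] - h):(center[[1L]] + h)
  cc <- (center[[2L]] - h):(center[[2L]] + h)
  g <- ly@grid
  if (min(rr) < 1L || max(rr) > nrow(g) || min(cc) < 1L || max(cc) > ncol(g) ||
      anyNA(g[rr, cc]))
    stop("the flag window does not lie fully inside the shape")
  par <- sharedParity(system)
  st <- sharingStats(system)
  sharedNames <- names(st$perTile)[st$perTile >= 2L]
  wr <- rep(rr, times = window); wc <- rep(cc, each = window)
  onPar <- (wr + wc) %% 2L == par
  tilesWin <- g[cbind(wr, wc)]
  enh <- intersect(tilesWin[onPar], sharedNames)
  if (!length(enh))
    stop("the flag window contains no shared chequerboard tiles")
  pat <- stats::setNames(rep(base, nTiles(system)), tileNames(system))
  pat[enh] <- enhanced
  structure(list(pattern = pat, enhancedTiles = enh, shape = shape,
                 center = c(row = center[[1L]], col = center[[2L]]),
                 window = window, base = base, enhanced = enhanced),
            class = "FlagPattern")
}

#' @export
print.FlagPattern <- function(x, ...) {
  cat(sprintf(
    "FlagPattern: %dx%d window at (%d,%d) in '%s'; %d tiles at %g nM, rest %g nM\n",
    x$window, x$window, x$center[["row"]], x$center[["col"]], x$shape,
    length(x$enhancedTiles), x$enhanced, x$base))
  invisible(x)
}
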