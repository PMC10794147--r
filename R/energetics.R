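## Gas constant in kcal / (mol K)
.R_KCAL <- 0.0019872

#' Energy model parameters
#'
#' Constructs an \linkS4class{EnergyParams} object. Two modes are supported:
#' a fixed bond energy \code{Gse} (RT units, temperature-independent), or a
#' temperature-dependent mode where the per-bond standard enthalpy and
#' entropy give \code{Gse(T) = (-dH + T * dS) / (R * T)}. The defaults of the
#' temperature mode are tuned so that one binding domain contributes about
#' -9 kcal/mol at 53 degrees C, the design target for SST domain strengths.
#'
#' @param Gse fixed bond energy in RT (positive = stabilising), or NULL for
#'   temperature mode.
#' @param alpha reference offset, RT units. Defaults to 0: alpha cancels in
#'   all free-energy differences at fixed assembly size, so only relative
#'   rates depend on it.
#' @param u0 reference concentration in molar (default 1 M).
#' @param dH,dS per-bond standard enthalpy (kcal/mol) and entropy
#'   (kcal/mol/K), used when \code{Gse} is NULL.
#' @return an \linkS4class{EnergyParams}.
#' @examples
#' energyParams(Gse = 3)
#' gseAt(energyParams(), 53)  # about 13.9 RT
#' @export
energyParams <- function(Gse = NULL, alpha = 0, u0 = 1,
                         dH = -80, dS = (dH + 9) / (273.15 + 53)) {
  if (is.null(Gse))
    new("EnergyParams", Gse = NA_real_, alpha = alpha, u0 = u0,
        dH = dH, dS = dS)
  else
    new("EnergyParams", Gse = Gse, alpha = alpha, u0 = u0,
        dH = NA_real_, dS = NA_real_)
}

#' @describeIn energyParams bond energy (RT units) at temperature
#'   \code{tempC} (Celsius); in fixed mode the temperature is ignored.
#' @param params an EnergyParams object.
#' @param tempC temperature in degrees Celsius.
#' @export
gseAt <- function(params, tempC = 53) {
  if (!is.na(params@Gse)) return(rep(params@Gse, length(tempC)))
  tK <- tempC + 273.15
  (-params@dH + tK * params@dS) / (.R_KCAL * tK)
}

## Internal: Gmc values (RT) for a vector of concentrations in nM.
.gmc <- function(conc_nM, params) {
  if (any(conc_nM <= 0)) stop("all concentrations must be > 0")
  params@alpha - log(conc_nM * 1e-9 / params@u0)
}

#' Chemical potential of a tile
#'
#' The chemical potential (translational entropy) of a free tile at
#' concentration c is \code{Gmc = alpha - log(c / u0)} in RT units, with the
#' natural logarithm and c converted from nM to molar.
#'
#' @param tile tile name.
#' @param pattern named numeric vector of concentrations in nM.
#' @param params an \linkS4class{EnergyParams}.
#' @return Gmc in RT units.
#' @examples
#' p <- energyParams(Gse = 3)
#' chemicalPotential("t", c(t = 60), p)  # -log(6e-8), about 16.63
#' @export
chemicalPotential <- function(tile, pattern, params) {
  if (!tile %in% names(pattern))
    stop(sprintf("tile '%s' has no concentration in the pattern", tile))
  .gmc(unname(pattern[[tile]]), params)
}

#' Partial assemblies of a layout
#'
#' An assembly state is a non-empty, 4-connected subset of a layout's
#' occupied locations, each location carrying that location's layout tile.
#'
#' @param layout a \linkS4class{ShapeLayout}.
#' @param rows,cols integer vectors of the occupied locations.
#' @return an object of class \code{AssemblyState}: list with the layout,
#'   the location matrix, and the tiles at those locations.
#' @export
assemblyState <- function(layout, rows, cols) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1L)
  g <- layout@grid
  tl <- g[cbind(rows, cols)]
  if (anyNA(tl))
    stop("assembly state includes locations not occupied in the layout")
  st <- structure(list(layout = layout, rows = as.integer(rows),
                       cols = as.integer(cols), tiles = tl),
                  class = "AssemblyState")
  if (!.stateConnected(st)) stop("assembly state is not 4-connected")
  st
}

.stateConnected <- function(state) {
  n <- length(state$rows)
  if (n == 1L) return(TRUE)
  key <- paste(state$rows, state$cols)
  idx <- stats::setNames(seq_len(n), key)
  seen <- logical(n); seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (s in .SIDES) {
      k <- paste(state$rows[i] + .SIDE_DROW[[s]], state$cols[i] + .SIDE_DCOL[[s]])
      j <- idx[k]
      if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
    }
  }
  all(seen)
}

#' Number of bonds in an assembly state
#'
#' Counts adjacent occupied pairs within the state; each internal edge is
#' counted once.
#'
#' @param state an \code{AssemblyState}.
#' @return integer bond count B.
#' @examples
#' sys <- buildUniqueDesign(list(sq = matrix(TRUE, 2, 2)))
#' st <- assemblyState(layouts(sys)$sq, c(1, 1, 2, 2), c(1, 2, 1, 2))
#' bondCount(st)  # 4
#' @export
bondCount <- function(state) {
  key <- paste(state$rows, state$cols)
  has <- stats::setNames(rep(TRUE, length(key)), key)
  b <- 0L
  for (s in c("E", "S")) {
    k <- paste(state$rows + .SIDE_DROW[[s]], state$cols + .SIDE_DCOL[[s]])
    b <- b + sum(!is.na(has[k]))
  }
  b
}

#' Free energy of a partial assembly
#'
#' \code{G(A) = sum_i Gmc_i - B * Gse - alpha} in RT units, where the sum
#' runs over the tiles in the state and B is the bond count. For a single
#' tile this reduces to \code{-log(c / u0)} independent of alpha.
#'
#' @param state an \code{AssemblyState}.
#' @param pattern named numeric concentrations (nM) covering the state tiles.
#' @param params an \linkS4class{EnergyParams}; in temperature mode supply
#'   \code{tempC}.
#' @param tempC temperature (Celsius) for temperature-dependent Gse.
#' @return free energy G in RT units.
#' @export
assemblyFreeEnergy <- function(state, pattern, params, tempC = 53) {
  conc <- pattern[state$tiles]
  if (anyNA(conc))
    stop("missing concentration for tile(s): ",
         paste(state$tiles[is.na(conc)], collapse = ", "))
  sum(.gmc(unname(conc), params)) -
    bondCount(state) * gseAt(params, tempC) - params@alpha
}

#' Attachment free-energy change
#'
#' The change in G when the layout's tile for \code{location} attaches to the
#' state, forming b bonds: \code{dG = Gmc(tile) - b * Gse}. Attachment is
#' favourable iff dG < 0; at nucleation/growth temperatures attachment by two
#' or more bonds is favourable whereas one is insufficient.
#'
#' @param state an \code{AssemblyState}.
#' @param location integer c(row, col): an empty layout location adjacent to
#'   the state.
#' @inheritParams assemblyFreeEnergy
#' @return dG in RT units.
#' @export
attachmentDeltaG <- function(state, location, pattern, params, tempC = 53) {
  r <- location[[1L]]; cc <- location[[2L]]
  g <- state$layout@grid
  if (r < 1L || r > nrow(g) || cc < 1L || cc > ncol(g) || is.na(g[r, cc]))
    stop("location is not an occupied location of the layout")
  key <- paste(state$rows, state$cols)
  if (paste(r, cc) %in% key) stop("location is already occupied in the state")
  b <- sum(paste(r + .SIDE_DROW, cc + .SIDE_DCOL) %in% key)
  if (b == 0L) stop("location is not adjacent to the state")
  tile <- g[r, cc]
  chemicalPotential(tile, pattern, params) - b * gseAt(params, tempC)
}

#' Fill a concentration pattern over all tiles of a system
#'
#' Applies the explicit fill rule: tiles absent from \code{pattern} are set
#' to \code{fill} nM, so every layout tile has a concentration.
#'
#' @param system a \linkS4class{TileSystem}.
#' @param pattern named numeric vector (nM), possibly partial.
#' @param fill default concentration (nM) for missing tiles.
#' @return named numeric vector over all tiles of the system.
#' @export
fullPattern <- function(system, pattern = numeric(), fill = 60) {
  out <- stats::setNames(rep(fill, nTiles(system)), tileNames(system))
  common <- intersect(names(pattern), names(out))
  out[common] <- pattern[common]
  out
}

#' Uniform concentration pattern
#'
#' @param system a \linkS4class{TileSystem}.
#' @param conc concentration in nM for every tile (default 60 nM, the
#'   equimolar mix).
#' @return named numeric vector over all tiles.
#' @export
uniformPattern <- function(system, conc = 60) {
  stats::setNames(rep(conc, nTiles(system)), tileNames(system))
}

#' Total length of an SST strand from its domain lengths
#'
#' Single-stranded tiles have four binding domains with alternating lengths;
#' the standard motif of two 10-nt and two 11-nt domains gives a 42-nt
#' strand.
#'
#' @param domains integer vector of domain lengths in nt.
#' @return total strand length in nt.
#' @examples
#' sstStrandLength()  # 42
#' @export
sstStrandLength <- function(domains = c(10, 11, 10, 11)) {
  sum(domains)
}
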