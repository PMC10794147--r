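#' @import methods
NULL

#' ShapeLayout: a target shape on a bounded tile canvas
#'
#' A shape layout maps lattice locations of a rows x cols canvas to tile
#' names. The grid is a character matrix; \code{NA} marks unoccupied
#' locations. Each tile name may occur at most once per layout.
#'
#' @slot name single character, the shape's name.
#' @slot grid character matrix; entries are tile names or \code{NA}.
#' @export
setClass("ShapeLayout",
         representation(name = "character", grid = "matrix"))

setValidity("ShapeLayout", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  g <- object@grid
  if (!is.character(g) || length(dim(g)) != 2L)
    msgs <- c(msgs, "'grid' must be a character matrix")
  else {
    occ <- g[!is.na(g)]
    if (length(occ) == 0L)
      msgs <- c(msgs, "layout has no occupied locations")
    if (anyDuplicated(occ))
      msgs <- c(msgs, sprintf("tile name(s) repeated within layout: %s",
                              paste(unique(occ[duplicated(occ)]), collapse = ", ")))
    if (any(occ == "", na.rm = TRUE))
      msgs <- c(msgs, "empty-string tile names are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ShapeLayout
#'
#' @param name shape name.
#' @param grid character matrix of tile names, \code{NA} for empty locations.
#' @return a \linkS4class{ShapeLayout}.
#' @examples
#' shapeLayout("L", matrix(c("t1", "t2", NA, "t3"), 2, 2))
#' @export
shapeLayout <- function(name, grid) {
  new("ShapeLayout", name = as.character(name), grid = grid)
}

#' @describeIn shapeLayout shape name accessor.
#' @param x a ShapeLayout.
#' @export
layoutName <- function(x) x@name

#' @describeIn shapeLayout the canvas grid (character matrix).
#' @export
layoutGrid <- function(x) x@grid

#' @describeIn shapeLayout integer matrix of occupied (row, col) locations,
#'   row-major order, with the tile name at each location.
#' @export
layoutCells <- function(x) {
  idx <- which(!is.na(t(x@grid)))  # row-major order
  nc <- ncol(x@grid)
  row <- (idx - 1L) %/% nc + 1L
  col <- (idx - 1L) %% nc + 1L
  data.frame(row = row, col = col,
             tile = x@grid[cbind(row, col)],
             stringsAsFactors = FALSE)
}

#' @export
setMethod("show", "ShapeLayout", function(object) {
  cat(sprintf("ShapeLayout '%s': %d x %d canvas, %d occupied locations\n",
              object@name, nrow(object@grid), ncol(object@grid),
              sum(!is.na(object@grid))))
})

#' TileSystem: tiles, glue alphabet and target shape layouts
#'
#' A tile system holds a set of square tiles (each with four glue labels,
#' keyed N/E/S/W; the empty string is the null glue), the alphabet of
#' abstract binding domains (unstarred base labels), and the shape layouts
#' that reference the tiles.
#'
#' @slot tiles data.frame with columns \code{name, N, E, S, W}.
#' @slot glues character vector of base (unstarred) non-null domain labels.
#' @slot layouts named list of \linkS4class{ShapeLayout}.
#' @export
setClass("TileSystem",
         representation(tiles = "data.frame", glues = "character",
                        layouts = "list"))

setValidity("TileSystem", function(object) {
  msgs <- character()
  tl <- object@tiles
  need <- c("name", "N", "E", "S", "W")
  if (!all(need %in% names(tl)))
    return("tiles must have columns name, N, E, S, W")
  if (anyDuplicated(tl$name))
    msgs <- c(msgs, sprintf("duplicate tile names: %s",
                            paste(unique(tl$name[duplicated(tl$name)]), collapse = ", ")))
  used <- unique(glueBase(c(tl$N, tl$E, tl$S, tl$W)))
  used <- used[used != ""]
  undecl <- setdiff(used, object@glues)
  if (length(undecl))
    msgs <- c(msgs, sprintf("glue(s) used but not declared: %s",
                            paste(undecl, collapse = ", ")))
  for (ly in object@layouts) {
    if (!is(ly, "ShapeLayout")) {
      msgs <- c(msgs, "layouts must be ShapeLayout objects")
      next
    }
    miss <- setdiff(ly@grid[!is.na(ly@grid)], tl$name)
    if (length(miss))
      msgs <- c(msgs, sprintf("layout '%s' references unknown tile(s): %s",
                              ly@name, paste(miss, collapse = ", ")))
  }
  if (length(object@layouts) &&
      is.null(names(object@layouts)))
    msgs <- c(msgs, "layouts must be a named list")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TileSystem
#'
#' @param tiles data.frame with columns \code{name, N, E, S, W}; glue labels
#'   are strings, \code{""} for the null glue.
#' @param glues character vector of base domain labels; defaults to all base
#'   labels used by the tiles.
#' @param layouts list of \linkS4class{ShapeLayout} (named by shape).
#' @return a \linkS4class{TileSystem}.
#' @export
tileSystem <- function(tiles, glues = NULL, layouts = list()) {
  tiles <- as.data.frame(tiles, stringsAsFactors = FALSE)
  for (cc in c("name", "N", "E", "S", "W")) tiles[[cc]] <- as.character(tiles[[cc]])
  if (is.null(glues)) {
    glues <- unique(glueBase(c(tiles$N, tiles$E, tiles$S, tiles$W)))
    glues <- sort(glues[glues != ""])
  }
  if (length(layouts) && is.null(names(layouts)))
    names(layouts) <- vapply(layouts, function(l) l@name, character(1))
  new("TileSystem", tiles = tiles, glues = glues, layouts = layouts)
}

#' @describeIn tileSystem the tile table (data.frame name/N/E/S/W).
#' @param x a TileSystem.
#' @export
tiles <- function(x) x@tiles

#' @describeIn tileSystem tile names.
#' @export
tileNames <- function(x) x@tiles$name

#' @describeIn tileSystem the glue alphabet (base domain labels).
#' @export
glueAlphabet <- function(x) x@glues

#' @describeIn tileSystem named list of shape layouts.
#' @export
layouts <- function(x) x@layouts

#' @describeIn tileSystem number of tiles.
#' @export
nTiles <- function(x) nrow(x@tiles)

#' @describeIn tileSystem number of non-null binding domains (one per
#'   complementary glue pair).
#' @export
nGlues <- function(x) length(x@glues)

#' @export
setMethod("show", "TileSystem", function(object) {
  cat(sprintf("TileSystem: %d tiles, %d binding domains, %d layout(s)\n",
              nTiles(object), nGlues(object), length(object@layouts)))
  for (ly in object@layouts)
    cat(sprintf("  %s: %d x %d, %d tiles\n", ly@name,
                nrow(ly@grid), ncol(ly@grid), sum(!is.na(ly@grid))))
})

#' EnergyParams: free-energy model parameters
#'
#' Parameters of the tile-assembly free-energy model. \code{Gse} is the
#' stabilising free energy per matched glue bond in units of RT (positive =
#' stabilising); \code{alpha} is a dimensionless reference offset and
#' \code{u0} the reference concentration in molar. When per-bond standard
#' enthalpy/entropy are supplied, the bond energy becomes temperature
#' dependent: \code{Gse(T) = (-dH + T * dS) / (R * T)} with \code{dH} in
#' kcal/mol, \code{dS} in kcal/mol/K, and T the absolute temperature.
#'
#' @slot Gse numeric, fixed bond energy (RT); \code{NA} in temperature mode.
#' @slot alpha numeric reference offset (RT units).
#' @slot u0 numeric reference concentration (M).
#' @slot dH,dS numeric per-bond standard enthalpy/entropy (kcal/mol,
#'   kcal/mol/K); \code{NA} in fixed-Gse mode.
#' @export
setClass("EnergyParams",
         representation(Gse = "numeric", alpha = "numeric", u0 = "numeric",
                        dH = "numeric", dS = "numeric"))

setValidity("EnergyParams", function(object) {
  msgs <- character()
  if (object@u0 <= 0) msgs <- c(msgs, "u0 must be > 0")
  fixed <- !is.na(object@Gse)
  temp <- !is.na(object@dH) && !is.na(object@dS)
  if (!fixed && !temp)
    msgs <- c(msgs, "either Gse or both dH and dS must be set")
  if (fixed && object@Gse <= 0) msgs <- c(msgs, "Gse must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "EnergyParams", function(object) {
  if (!is.na(object@Gse))
    cat(sprintf("EnergyParams: fixed Gse = %.3f RT, alpha = %g, u0 = %g M\n",
                object@Gse, object@alpha, object@u0))
  else
    cat(sprintf(
      "EnergyParams: dH = %.1f kcal/mol, dS = %.4f kcal/mol/K (Gse(53C) = %.2f RT), alpha = %g, u0 = %g M\n",
      object@dH, object@dS, gseAt(object, 53), object@alpha, object@u0))
})

#' ThetaMap: the pixel-to-tile assignment
#'
#' An injective map from pixel positions of a grayscale image to tile names.
#' Tiles not assigned to any pixel are "unassigned" and receive the lowest
#' concentration; "reserved" tiles (e.g. fluorophore/quencher label
#' locations, which must not vary in concentration) are drawn from the
#' unassigned pool and are never assigned to pixels.
#'
#' @slot assign character matrix (image dimensions) of tile names.
#' @slot unassigned character vector of tiles not mapped by any pixel.
#' @slot reserved character vector, subset of \code{unassigned}.
#' @export
setClass("ThetaMap",
         representation(assign = "matrix", unassigned = "character",
                        reserved = "character"))

setValidity("ThetaMap", function(object) {
  msgs <- character()
  a <- object@assign
  if (!is.character(a) || anyNA(a))
    msgs <- c(msgs, "'assign' must be a complete character matrix")
  if (anyDuplicated(as.vector(a)))
    msgs <- c(msgs, "theta must be injective: a tile is assigned to two pixels")
  if (length(intersect(as.vector(a), object@unassigned)))
    msgs <- c(msgs, "a tile cannot be both assigned and unassigned")
  if (length(setdiff(object@reserved, object@unassigned)))
    msgs <- c(msgs, "reserved tiles must stay unassigned (lowest concentration)")
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "ThetaMap", function(object) {
  cat(sprintf("ThetaMap: %d x %d pixels -> tiles; %d unassigned (%d reserved)\n",
              nrow(object@assign), ncol(object@assign),
              length(object@unassigned), length(object@reserved)))
})
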