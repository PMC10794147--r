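## Internal: indexed view of a layout for fast neighbor lookups.
## Cells are numbered 1..n in row-major order of occupied locations.
.layoutIndex <- function(layout) {
  g <- layout@grid
  cells <- layoutCells(layout)
  n <- nrow(cells)
  pos <- matrix(NA_integer_, nrow(g), ncol(g))
  pos[cbind(cells$row, cells$col)] <- seq_len(n)
  nbr <- matrix(NA_integer_, n, 4L, dimnames = list(NULL, .SIDES))
  for (s in .SIDES) {
    rr <- cells$row + .SIDE_DROW[[s]]
    cc <- cells$col + .SIDE_DCOL[[s]]
    ok <- rr >= 1L & rr <= nrow(g) & cc >= 1L & cc <= ncol(g)
    nbr[ok, s] <- pos[cbind(rr[ok], cc[ok])]
  }
  list(cells = cells, nbr = nbr, pos = pos, dim = dim(g), n = n)
}

## Internal: tile glue lookup matrix (tiles x sides) for a system.
.glueMatrix <- function(system) {
  tl <- system@tiles
  m <- cbind(N = tl$N, E = tl$E, S = tl$S, W = tl$W)
  rownames(m) <- tl$name
  m
}

#' Validate a shape layout against its tile system
#'
#' Checks the two structural invariants of a layout: every internal edge
#' between two occupied locations must carry complementary glues, and every
#' boundary edge (a side of an occupied location whose neighbor is empty or
#' off-canvas) must carry the null glue.
#'
#' @param system a \linkS4class{TileSystem}.
#' @param layout a \linkS4class{ShapeLayout} whose tiles are in \code{system}.
#' @return data.frame of violations with columns \code{row, col, side, rule,
#'   detail}; zero rows when the layout is valid.
#' @examples
#' sys <- buildUniqueDesign(list(L = rbind(c(TRUE, TRUE), c(TRUE, FALSE))))
#' nrow(validateLayout(sys, layouts(sys)[[1]]))  # 0
#' @export
validateLayout <- function(system, layout) {
  gm <- .glueMatrix(system)
  miss <- setdiff(layout@grid[!is.na(layout@grid)], rownames(gm))
  if (length(miss))
    stop("layout references unknown tile(s): ", paste(miss, collapse = ", "))
  li <- .layoutIndex(layout)
  cells <- li$cells
  viol <- list()
  for (s in .SIDES) {
    mine <- gm[cbind(cells$tile, s)]
    nb <- li$nbr[, s]
    occ <- !is.na(nb)
    ## internal edges: complementary glues required (each edge checked once,
    ## from its N/W endpoint, so one broken edge yields one violation)
    if (s %in% c("E", "S") && any(occ)) {
      theirs <- gm[cbind(cells$tile[nb[occ]], .OPPOSITE[[s]])]
      bad <- !gluesMatch(mine[occ], theirs)
      if (any(bad)) {
        w <- which(occ)[bad]
        viol[[length(viol) + 1L]] <- data.frame(
          row = cells$row[w], col = cells$col[w], side = s,
          rule = "internal-edge-mismatch",
          detail = sprintf("glue '%s' vs neighbor '%s'",
                           mine[w], theirs[bad]),
          stringsAsFactors = FALSE)
      }
    }
    ## boundary edges: null glue required
    bnd <- !occ & mine != ""
    if (any(bnd)) {
      w <- which(bnd)
      viol[[length(viol) + 1L]] <- data.frame(
        row = cells$row[w], col = cells$col[w], side = s,
        rule = "boundary-not-null",
        detail = sprintf("glue '%s' on boundary edge", mine[w]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(row = integer(), col = integer(), side = character(),
                  rule = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

#' Validate every layout of a system
#'
#' @param system a \linkS4class{TileSystem}.
#' @return named list of violation data.frames (see
#'   \code{\link{validateLayout}}), one per layout.
#' @export
validateSystem <- function(system) {
  lapply(layouts(system), function(l) validateLayout(system, l))
}

#' Build a fully unique multi-shape design
#'
#' Each occupied location of each shape mask becomes a fresh tile; every
#' internal edge between two occupied locations gets a fresh binding domain
#' (the complementary pair placed on the two facing sides); every boundary
#' edge carries the null glue. This is the initial, maximally specific design
#' that a merging pass subsequently compresses into a shared-tile system.
#'
#' @param masks named list of logical occupancy matrices, one per shape.
#' @param prefix glue label prefix (labels are \code{"<prefix>1"}, ...).
#' @return a \linkS4class{TileSystem} whose layouts validate with zero
#'   violations; tile count equals total occupied locations and the domain
#'   count equals the total number of internal edges.
#' @examples
#' sys <- buildUniqueDesign(list(sq = matrix(TRUE, 2, 2)))
#' nTiles(sys)  # 4
#' nGlues(sys)  # 4 internal edges
#' @export
buildUniqueDesign <- function(masks, prefix = "g") {
  if (!length(masks)) stop("at least one shape mask is required")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    names(masks) <- paste0("S", seq_along(masks))
  tilerows <- list()
  layoutsL <- list()
  gcount <- 0L
  for (sname in names(masks)) {
    m <- masks[[sname]]
    if (!is.logical(m)) m <- m != 0
    if (!any(m)) stop(sprintf("mask '%s' is empty", sname))
    grid <- matrix(NA_character_, nrow(m), ncol(m))
    grid[m] <- sprintf("%s_%d_%d", sname, row(m)[m], col(m)[m])
    glN <- glE <- glS <- glW <- matrix("", nrow(m), ncol(m))
    ## vertical internal edges (cell and its S neighbor)
    for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
      if (!m[r, cc]) next
      if (r < nrow(m) && m[r + 1L, cc]) {
        gcount <- gcount + 1L
        lab <- paste0(prefix, gcount)
        glS[r, cc] <- lab
        glN[r + 1L, cc] <- paste0(lab, "*")
      }
      if (cc < ncol(m) && m[r, cc + 1L]) {
        gcount <- gcount + 1L
        lab <- paste0(prefix, gcount)
        glE[r, cc] <- lab
        glW[r, cc + 1L] <- paste0(lab, "*")
      }
    }
    tilerows[[sname]] <- data.frame(
      name = grid[m], N = glN[m], E = glE[m], S = glS[m], W = glW[m],
      stringsAsFactors = FALSE)
    layoutsL[[sname]] <- shapeLayout(sname, grid)
  }
  tileSystem(do.call(rbind, tilerows),
             glues = if (gcount) paste0(prefix, seq_len(gcount)) else character(),
             layouts = layoutsL)
}

#' Tile-sharing statistics of a multi-shape system
#'
#' Counts, for each tile, the number of distinct layouts in which it occurs,
#' and summarises how many tiles are unique to one shape, shared by exactly
#' two, shared by all, etc.
#'
#' @param system a \linkS4class{TileSystem} with at least one layout.
#' @return an object of class \code{SharingStats}: a list with
#'   \code{perTile} (named integer vector: layouts containing each tile),
#'   \code{counts} (integer vector: number of tiles occurring in exactly
#'   1, 2, ... layouts), \code{totalTiles}, \code{totalGlues},
#'   \code{sharedAtLeast2} (tiles in >= 2 layouts).
#' @examples
#' sys <- buildUniqueDesign(list(a = matrix(TRUE, 2, 2), b = matrix(TRUE, 2, 2)))
#' sharingStats(sys)$counts  # all tiles occur in exactly one layout
#' @export
sharingStats <- function(system) {
  if (!length(system@layouts)) stop("system has no layouts")
  per <- integer(nTiles(system))
  names(per) <- tileNames(system)
  for (ly in system@layouts) {
    occ <- unique(ly@grid[!is.na(ly@grid)])
    per[occ] <- per[occ] + 1L
  }
  nsh <- length(system@layouts)
  counts <- tabulate(per, nbins = nsh)
  names(counts) <- paste0("in", seq_len(nsh))
  structure(list(perTile = per, counts = counts,
                 totalTiles = nTiles(system), totalGlues = nGlues(system),
                 sharedAtLeast2 = sum(per >= 2L)),
            class = "SharingStats")
}

#' @export
print.SharingStats <- function(x, ...) {
  cat(sprintf("SharingStats: %d tiles, %d binding domains\n",
              x$totalTiles, x$totalGlues))
  for (k in seq_along(x$counts))
    cat(sprintf("  in exactly %d layout(s): %d\n", k, x$counts[[k]]))
  cat(sprintf("  shared by >= 2 layouts: %d\n", x$sharedAtLeast2))
  invisible(x)
}
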