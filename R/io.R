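#' Read and write tile systems as JSON
#'
#' The on-disk schema is a JSON object with fields \code{format}
#' ("mfsa-tilesystem"), \code{version} (1), \code{glues} (array of base
#' domain labels), \code{tiles} (array of objects with \code{name, N, E, S,
#' W}; \code{""} is the null glue) and \code{layouts} (array of objects with
#' \code{name, rows, cols, grid}, the grid a row-major array of tile names
#' with \code{"."} for empty locations). Read/write round trips are identity
#' on this canonical form.
#'
#' @param path file path (or connection for \code{readTileSystem}).
#' @param strict if TRUE, unknown top-level fields and undeclared glues are
#'   errors; if FALSE unknown fields are ignored and the glue alphabet is
#'   extended as needed.
#' @return \code{readTileSystem} returns a \linkS4class{TileSystem};
#'   \code{writeTileSystem} returns \code{path} invisibly.
#' @export
readTileSystem <- function(path, strict = TRUE) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  known <- c("format", "version", "glues", "tiles", "layouts")
  extra <- setdiff(names(doc), known)
  if (strict && length(extra))
    stop("unknown field(s) in tile-system document: ", paste(extra, collapse = ", "))
  if (!identical(doc$format, "mfsa-tilesystem"))
    stop("not an mfsa-tilesystem document")
  tl <- as.data.frame(doc$tiles, stringsAsFactors = FALSE)
  if (anyDuplicated(tl$name))
    stop("duplicate tile names in document")
  glues <- as.character(doc$glues %||% character())
  used <- unique(glueBase(c(tl$N, tl$E, tl$S, tl$W)))
  used <- used[used != ""]
  undecl <- setdiff(used, glues)
  if (strict && length(undecl))
    stop("glue(s) referenced but not declared: ", paste(undecl, collapse = ", "))
  glues <- union(glues, undecl)
  layoutsL <- list()
  if (!is.null(doc$layouts)) {
    lys <- doc$layouts
    ## jsonlite may simplify to a data.frame with a list column
    if (is.data.frame(lys)) lys <- split(lys, seq_len(nrow(lys)))
    for (ld in lys) {
      if (is.data.frame(ld)) ld <- as.list(ld)
      gridv <- unlist(ld$grid)
      if (length(gridv) != ld$rows * ld$cols)
        stop(sprintf("layout '%s': grid has %d entries for %d x %d canvas",
                     ld$name, length(gridv), ld$rows, ld$cols))
      gridv[gridv == "."] <- NA_character_
      g <- matrix(gridv, nrow = ld$rows, ncol = ld$cols, byrow = TRUE)
      layoutsL[[as.character(ld$name)]] <- shapeLayout(as.character(ld$name), g)
    }
  }
  tileSystem(tl, glues = sort(glues), layouts = layoutsL)
}

#' @rdname readTileSystem
#' @param system a \linkS4class{TileSystem} to serialise.
#' @export
writeTileSystem <- function(system, path) {
  doc <- list(
    format = jsonlite::unbox("mfsa-tilesystem"),
    version = jsonlite::unbox(1L),
    glues = sort(system@glues),
    tiles = system@tiles[order(system@tiles$name), , drop = FALSE],
    layouts = lapply(unname(system@layouts), function(ly) {
      g <- t(ly@grid)  # row-major
      v <- as.vector(g)
      v[is.na(v)] <- "."
      list(name = jsonlite::unbox(ly@name),
           rows = jsonlite::unbox(nrow(ly@grid)),
           cols = jsonlite::unbox(ncol(ly@grid)),
           grid = v)
    }))
  jsonlite::write_json(doc, path, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write shape layouts as text grids
#'
#' The layout text format is a whitespace-separated grid, one canvas row per
#' line; \code{"."} marks an empty location and any other token is a tile
#' name. Round trips are identity.
#'
#' @param path file path.
#' @param name shape name for the layout read from \code{path} (defaults to
#'   the file name without extension).
#' @return \code{readLayout} returns a \linkS4class{ShapeLayout}.
#' @export
readLayout <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty layout file")
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  w <- unique(lengths(toks))
  if (length(w) != 1L)
    stop("ragged rows in layout grid (widths: ", paste(w, collapse = ", "), ")")
  g <- do.call(rbind, toks)
  g[g == "."] <- NA_character_
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  shapeLayout(name, g)
}

#' @rdname readLayout
#' @param layout a \linkS4class{ShapeLayout} to serialise.
#' @export
writeLayout <- function(layout, path) {
  g <- layout@grid
  g[is.na(g)] <- "."
  writeLines(apply(g, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Read and write concentration patterns as CSV
#'
#' A concentration pattern is a named numeric vector mapping every tile of a
#' system to its free monomer concentration in nM. The CSV has columns
#' \code{tile, conc_nM}.
#'
#' @param path file path.
#' @return named numeric vector of concentrations (nM).
#' @export
readPattern <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tile", "conc_nM") %in% names(df)))
    stop("pattern CSV must have columns tile, conc_nM")
  stats::setNames(as.numeric(df$conc_nM), df$tile)
}

#' @rdname readPattern
#' @param pattern named numeric vector (nM).
#' @export
writePattern <- function(pattern, path) {
  utils::write.csv(data.frame(tile = names(pattern), conc_nM = unname(pattern)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write pixel-to-tile maps as CSV
#'
#' The CSV has columns \code{pixel_row, pixel_col, tile} for assigned pixels,
#' plus rows with \code{pixel_row = NA} for unassigned tiles (tile listed,
#' \code{reserved} column TRUE for reserved tiles).
#'
#' @param path file path.
#' @return \code{readTheta} returns a \linkS4class{ThetaMap}.
#' @export
readTheta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  asg <- df[!is.na(df$pixel_row), , drop = FALSE]
  un <- df[is.na(df$pixel_row), , drop = FALSE]
  nr <- max(asg$pixel_row); nc <- max(asg$pixel_col)
  m <- matrix(NA_character_, nr, nc)
  m[cbind(asg$pixel_row, asg$pixel_col)] <- asg$tile
  new("ThetaMap", assign = m, unassigned = un$tile,
      reserved = un$tile[as.logical(un$reserved)])
}

#' @rdname readTheta
#' @param theta a \linkS4class{ThetaMap}.
#' @export
writeTheta <- function(theta, path) {
  a <- theta@assign
  df <- data.frame(pixel_row = as.vector(row(a)), pixel_col = as.vector(col(a)),
                   tile = as.vector(a), reserved = FALSE,
                   stringsAsFactors = FALSE)
  if (length(theta@unassigned))
    df <- rbind(df, data.frame(pixel_row = NA_integer_, pixel_col = NA_integer_,
                               tile = theta@unassigned,
                               reserved = theta@unassigned %in% theta@reserved,
                               stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
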