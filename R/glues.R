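#' Glue label conventions
#'
#' Glues (abstract binding domains) are plain character labels. A glue binds
#' exactly one partner: the glue whose label is its complement, written with a
#' trailing \code{"*"} (so \code{"708"} pairs with \code{"708*"}, and the
#' complement of a complement is the original label). The empty string
#' \code{""} is the null glue, which binds nothing; shape edges carry null
#' glues.
#'
#' @param label character vector of glue labels (\code{""} = null glue).
#' @return \code{glueComplement} returns the complementary labels (null maps
#'   to null); \code{isNullGlue} a logical vector; \code{glueBase} the
#'   unstarred domain label; \code{gluesMatch} whether pairs of labels bind.
#' @examples
#' glueComplement(c("708", "708*", ""))
#' gluesMatch("9", "9*")
#' @export
glueComplement <- function(label) {
  stopifnot(is.character(label))
  out <- ifelse(endsWith(label, "*"),
                substr(label, 1L, nchar(label) - 1L),
                paste0(label, "*"))
  out[label == ""] <- ""
  out
}

#' @rdname glueComplement
#' @export
isNullGlue <- function(label) label == ""

#' @rdname glueComplement
#' @export
glueBase <- function(label) {
  out <- ifelse(endsWith(label, "*"), substr(label, 1L, nchar(label) - 1L), label)
  out[label == ""] <- ""
  out
}

#' @rdname glueComplement
#' @param a,b character vectors of glue labels compared elementwise.
#' @export
gluesMatch <- function(a, b) {
  a != "" & b != "" & a == glueComplement(b)
}

## Side conventions: four sides in fixed order; N binds S, E binds W.
.SIDES <- c("N", "E", "S", "W")
.SIDE_DROW <- c(N = -1L, E = 0L, S = 1L, W = 0L)
.SIDE_DCOL <- c(N = 0L, E = 1L, S = 0L, W = -1L)
.OPPOSITE <- c(N = "S", E = "W", S = "N", W = "E")
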