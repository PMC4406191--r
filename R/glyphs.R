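## Glyph scheme: BioPAX entity types mapped onto mEPN-derived 2D/3D shapes
## and colours. The table ships as a versioned TSV config so the palette can
## be replaced without code changes.

.glyphCache <- new.env(parent = emptyenv())

#' The glyph style table
#'
#' Loads the shipped BioPAX-to-mEPN style table (or a user-supplied one in
#' the same format: tab-separated columns type, shape2d, shape3d, colour;
#' `#` comments).
#'
#' @param path Optional path to an alternative style table.
#' @return data.frame with columns type, shape2d, shape3d, colour.
#' @export
glyphTable <- function(path = NULL) {
  cached <- is.null(path)
  if (cached) {
    if (!is.null(.glyphCache$default)) return(.glyphCache$default)
    path <- system.file("extdata", "glyph-styles.tsv", package = "biopaxnet",
                        mustWork = TRUE)
  }
  ## comment lines are stripped by hand: '#' also starts the colour values
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (cached) .glyphCache$default <- tab
  tab
}

#' Glyph style for a BioPAX type
#'
#' Returns the 2D shape, 3D shape and colour assigned to a supported BioPAX
#' type. Types without an explicit entry inherit the style of their nearest
#' listed ancestor (for example, `TransportWithBiochemicalReaction` renders
#' as `BiochemicalReaction`).
#'
#' @param type_name Supported BioPAX type name.
#' @param table Style table as returned by [glyphTable()].
#' @return Named list with entries `shape2d`, `shape3d`, `colour`.
#' @export
#' @examples
#' glyphForType("RnaRegion")$shape2d     # "dumbbell"
#' glyphForType("SmallMolecule")$shape2d # "ion-simple-molecule"
glyphForType <- function(type_name, table = glyphTable()) {
  .checkType(type_name)
  for (t in biopaxAncestors(type_name)) {
    i <- match(t, table$type)
    if (!is.na(i))
      return(list(shape2d = table$shape2d[i], shape3d = table$shape3d[i],
                  colour = table$colour[i]))
  }
  bpStop("unsupportedTypeError",
         sprintf("no glyph style found for type '%s' (style table lacks a root entry)",
                 type_name))
}
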