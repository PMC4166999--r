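# Minimal deterministic SVG emission. Elements are built as strings with
# fixed 2-decimal coordinate formatting, so identical inputs always produce
# byte-identical documents (no timestamps, no randomness).

fmt_px <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

svg_el <- function(tag, attrs = character(), children = NULL) {
  a <- ""
  if (length(attrs)) {
    a <- paste0(" ", paste0(names(attrs), "=\"", xml_escape(as.character(attrs)),
                            "\"", collapse = " "))
  }
  if (is.null(children)) {
    paste0("<", tag, a, "/>")
  } else {
    paste0("<", tag, a, ">", paste0(children, collapse = ""), "</", tag, ">")
  }
}

svg_text <- function(x, y, label, attrs = character()) {
  svg_el("text", c(x = fmt_px(x), y = fmt_px(y), attrs),
         children = xml_escape(label))
}

svg_document <- function(width, height, elements) {
  structure(list(width = width, height = height, elements = elements),
            class = "svg_document")
}

#' @export
as.character.svg_document <- function(x, ...) {
  paste0(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
           "width=\"", x$width, "\" height=\"", x$height, "\" ",
           "viewBox=\"0 0 ", x$width, " ", x$height, "\">"),
    x$elements,
    "</svg>"
  ), collapse = "\n")
}

#' @export
print.svg_document <- function(x, ...) {
  cat("<svg_document> ", x$width, "x", x$height, " px, ",
      length(x$elements), " top-level elements\n", sep = "")
  invisible(x)
}

#' Write an SVG document
#'
#' Emits standards-conformant SVG 1.1: well-formed XML with an explicit
#' width/height on the root element. Output is byte-deterministic for
#' identical inputs.
#'
#' @param doc an `svg_document` as returned by the render functions.
#' @param path output file path (or a connection).
#' @export
write_svg <- function(doc, path) {
  stopifnot(inherits(doc, "svg_document"))
  writeLines(as.character(doc), path)
  invisible(path)
}
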