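#' Read and write planar curves
#'
#' Two plain-text serialisations are supported and round-trip bit-stably:
#'
#' * CSV: one `x,y` row per vertex, with a header row `x,y,<closed|open>`
#'   carrying the topology flag. Coordinates are written with 17 significant
#'   digits so that `read_curve_csv(write_curve_csv(c))` reproduces the
#'   doubles exactly.
#' * JSON: an object `{"closed": bool, "x": [...], "y": [...], "meta": {...}}`
#'   with an optional free-form metadata block.
#'
#' @param curve a [planar_curve()].
#' @param path file path.
#' @param meta optional named list of metadata (JSON dialect only).
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [planar_curve()] (the JSON reader attaches any metadata as attribute
#'   `"meta"`).
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
write_curve_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("x,y,%s", if (curve$closed) "closed" else "open"), con)
  writeLines(sprintf("%.17g,%.17g",
                     curve$points[, 1L], curve$points[, 2L]), con)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L || hdr[1L] != "x" || hdr[2L] != "y") {
    stop("not a curve CSV: bad header")
  }
  closed <- identical(hdr[3L], "closed")
  body <- do.call(rbind, strsplit(lines[-1L], ",", fixed = TRUE))
  planar_curve(cbind(as.numeric(body[, 1L]), as.numeric(body[, 2L])),
               closed = closed)
}

#' @rdname curve_io
#' @export
write_curve_json <- function(curve, path, meta = list()) {
  obj <- list(closed = curve$closed,
              x = curve$points[, 1L],
              y = curve$points[, 2L],
              meta = meta)
  # I(17): 17 *significant* digits, enough to reproduce doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- planar_curve(cbind(obj$x, obj$y), closed = isTRUE(obj$closed))
  attr(out, "meta") <- obj$meta
  out
}
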