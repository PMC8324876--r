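#' Image tiles and labelled tile sets
#'
#' A tile is a single-channel 8-bit intensity patch with an optional class
#' label; a tile set is an ordered collection of tiles together with the
#' roster of class names, mirroring a class-per-folder tile dataset.
#'
#' @param pixels Numeric or integer matrix with values in 0..255.
#' @param label Optional class identifier (character scalar or `NA`).
#' @param id Unique tile identifier; autogenerated if missing.
#' @return `tile()` returns an object of class `tile`.
#' @export
tile <- function(pixels, label = NA_character_, id = NULL) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("tile must be at least 1x1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("tile intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  if (is.null(id)) id <- sprintf("tile_%08x", sample.int(.Machine$integer.max, 1L))
  structure(
    list(pixels = pixels, label = as.character(label), id = as.character(id)),
    class = "tile"
  )
}

#' @export
print.tile <- function(x, ...) {
  cat(sprintf(
    "<tile> %dx%d 8-bit, label=%s, id=%s\n",
    nrow(x$pixels), ncol(x$pixels), x$label, x$id
  ))
  invisible(x)
}

tile_pixels <- function(x) {
  if (inherits(x, "tile")) return(x$pixels)
  if (is.matrix(x)) return(x)
  stop("expected a tile or a matrix")
}

tile_id <- function(x) if (inherits(x, "tile")) x$id else NA_character_

#' @param tiles List of `tile` objects.
#' @param class_names Ordered character vector of class identifiers; defaults
#'   to the sorted unique tile labels.
#' @return `tile_set()` returns an object of class `tile_set`.
#' @rdname tile
#' @export
tile_set <- function(tiles, class_names = NULL) {
  stopifnot(is.list(tiles), length(tiles) > 0L)
  labs <- vapply(tiles, function(t) t$label, character(1))
  if (is.null(class_names)) class_names <- sort(unique(labs[!is.na(labs)]))
  if (!all(labs[!is.na(labs)] %in% class_names)) {
    stop("every tile label must appear in class_names")
  }
  ids <- vapply(tiles, function(t) t$id, character(1))
  if (anyDuplicated(ids)) stop("tile ids must be unique")
  structure(
    list(tiles = tiles, class_names = class_names),
    class = "tile_set"
  )
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf(
    "<tile_set> %d tiles, %d classes (%s)\n",
    length(x$tiles), length(x$class_names),
    paste(x$class_names, collapse = ", ")
  ))
  invisible(x)
}

#' @export
length.tile_set <- function(x) length(x$tiles)

#' Class label of every tile in a set
#' @param x A `tile_set`.
#' @return Character vector of labels, one per tile.
#' @export
tile_labels <- function(x) {
  stopifnot(inherits(x, "tile_set"))
  vapply(x$tiles, function(t) t$label, character(1))
}

#' Convert an RGB image to 8-bit grayscale luminance
#'
#' Uses ITU-R BT.601 luma weights, `round(0.299 R + 0.587 G + 0.114 B)`
#' with half-up rounding, clipped to 0..255.
#'
#' @param rgb A height x width x 3 array with channel values in 0..255.
#' @return Integer matrix of luminance values.
#' @examples
#' to_grayscale(array(c(100, 50, 200), c(1, 1, 3)))  # 82
#' @export
to_grayscale <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    stop("expected a height x width x 3 array")
  }
  y <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  y <- floor(y + 0.5)
  y[y < 0] <- 0
  y[y > 255] <- 255
  out <- as.integer(y)
  dim(out) <- dim(rgb)[1:2]
  out
}
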