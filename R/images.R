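#' Dense n-dimensional image
#'
#' A contiguous n-dimensional numeric grid with a shape (axis order: leading
#' axes slowest, last axis fastest; indices are 0-based in the data model,
#' 1-based through R's array accessors) and an element kind, `"uint8"`
#' (integral values in \[0, 255\]) or `"float64"`.  Images have reference
#' semantics -- a computer op writes into its container argument in place --
#' and carry a stable identifier used by the execution history.
#'
#' @param values numeric array (its `dim` is the shape) or a vector together
#'   with `shape`.
#' @param element_kind `"uint8"` or `"float64"`.
#' @param shape optional integer vector when `values` is a plain vector.
#' @return a `dense_image`.
#' @export
dense_image <- function(values, element_kind = "float64", shape = NULL) {
  element_kind <- match.arg(element_kind, c("float64", "uint8"))
  if (!is.null(shape)) dim(values) <- shape
  if (is.null(dim(values))) dim(values) <- length(values)
  img <- new.env(parent = emptyenv())
  img$element_kind <- element_kind
  img$id <- new_obj_id()
  class(img) <- c("dense_image", "ops_image")
  img_set_values(img, values)
  img
}

cast_kind <- function(values, kind) {
  if (kind == "uint8") {
    d <- dim(values)
    v <- pmin(255, pmax(0, floor(values + 0.5)))   # round half-up, clamp
    dim(v) <- d                                    # pmin drops attributes
    storage.mode(v) <- "double"
    v
  } else {
    storage.mode(values) <- "double"
    values
  }
}

#' @rdname dense_image
#' @param img an image.
#' @export
img_values <- function(img) img$values

#' Overwrite an image's values in place
#'
#' Values are cast to the image's element kind (uint8 rounds half-up and
#' clamps to \[0, 255\]); the shape must be preserved.
#' @param img a `dense_image`.
#' @param values numeric array of the same shape.
#' @return `img`, invisibly.
#' @export
img_set_values <- function(img, values) {
  if (!is.null(img$values) && !identical(dim(img$values), dim(values)))
    stop("dimension error: shapes ", paste(dim(img$values), collapse = "x"),
         " vs ", paste(dim(values), collapse = "x"))
  img$values <- cast_kind(values, img$element_kind)
  invisible(img)
}

#' @rdname dense_image
#' @export
img_shape <- function(img) dim(img$values)

#' @rdname dense_image
#' @export
img_kind <- function(img) img$element_kind

#' Deep copy of an image or sequence object
#' @param x a `dense_image`, `planar_image`, `byte_seq` or `real_seq`.
#' @return a fresh object with equal contents and a new identity.
#' @export
obj_clone <- function(x) {
  if (inherits(x, "dense_image")) dense_image(img_values(x), img_kind(x))
  else if (inherits(x, "planar_image")) planar_image(x$planes, x$element_kind)
  else if (inherits(x, "byte_seq")) byte_seq(x$values)
  else if (inherits(x, "real_seq")) real_seq(x$values)
  else x
}

#' @export
as.array.dense_image <- function(x, ...) x$values

#' Planar n-dimensional image
#'
#' A deliberately distinct image representation: an ordered list of 2-D
#' planes sharing one `(rows, cols)` shape.  Equivalent to a 3-D
#' [dense_image()] of shape `(n_planes, rows, cols)`; the two exist so that
#' parameter conversion between genuinely different data structures is
#' exercised for real.
#'
#' @param planes list of numeric matrices with equal dimensions.
#' @param element_kind `"uint8"` or `"float64"`.
#' @return a `planar_image`.
#' @export
planar_image <- function(planes, element_kind = "float64") {
  element_kind <- match.arg(element_kind, c("float64", "uint8"))
  stopifnot(length(planes) >= 1L)
  ps <- dim(planes[[1]])
  for (p in planes) if (!identical(dim(p), ps))
    stop("dimension error: planes must share one shape")
  img <- new.env(parent = emptyenv())
  img$plane_shape <- ps
  img$planes <- lapply(planes, function(p) cast_kind(p, element_kind))
  img$element_kind <- element_kind
  img$id <- new_obj_id()
  class(img) <- c("planar_image", "ops_image")
  img
}

#' Convert between dense and planar image representations
#'
#' `planar_from_dense` requires a 3-D dense image; plane `p`, row `r`,
#' column `c` corresponds to dense index `(p, r, c)`.  Values are preserved
#' exactly and the two functions compose to the identity.
#'
#' @param x a 3-D `dense_image` (forward) or a `planar_image` (inverse).
#' @return the converted image.
#' @export
planar_from_dense <- function(x) {
  v <- img_values(x)
  if (length(dim(v)) != 3L)
    stop("conversion inapplicable: dense image must have exactly 3 axes")
  planes <- lapply(seq_len(dim(v)[1]), function(p) v[p, , , drop = TRUE])
  planes <- lapply(planes, function(m) { dim(m) <- dim(v)[2:3]; m })
  planar_image(planes, img_kind(x))
}

#' @rdname planar_from_dense
#' @export
dense_from_planar <- function(x) {
  ps <- x$plane_shape
  n <- length(x$planes)
  arr <- array(0, dim = c(n, ps))
  for (p in seq_len(n)) arr[p, , ] <- x$planes[[p]]
  dense_image(arr, x$element_kind)
}

#' Mutable byte and real sequences
#'
#' Flat 1-D sequences with reference semantics; `byte_seq` holds unsigned
#' bytes (integral values in \[0, 255\]), `real_seq` doubles.  Used by the
#' engine-support conversion ops and the overhead micro-benchmark.
#'
#' @param values numeric vector.
#' @return a `byte_seq` / `real_seq`.
#' @export
byte_seq <- function(values) {
  if (any(values < 0 | values > 255 | values != floor(values)))
    stop("byte_seq values must be integers in [0, 255]")
  s <- new.env(parent = emptyenv())
  s$values <- as.double(values)
  s$id <- new_obj_id()
  class(s) <- c("byte_seq", "ops_seq")
  s
}

#' @rdname byte_seq
#' @export
real_seq <- function(values) {
  s <- new.env(parent = emptyenv())
  s$values <- as.double(values)
  s$id <- new_obj_id()
  class(s) <- c("real_seq", "ops_seq")
  s
}

#' @rdname byte_seq
#' @param x a sequence object.
#' @export
seq_values <- function(x) x$values

obj_id <- function(x) {
  if (is.environment(x) && !is.null(x$id)) x$id else NA_character_
}

#' Element-kind widening and narrowing
#'
#' Widening uint8 to float64 is exact; narrowing rounds half-up, then clamps
#' to \[0, 255\] (narrowing is total by design so that fuzzy matching through
#' conversion can never fail at run time).
#'
#' @param x a `dense_image`, `byte_seq` or `real_seq`.
#' @param to target kind, `"uint8"` or `"float64"`.
#' @return the converted object (a new object; `x` is untouched).
#' @export
convert_element_kind <- function(x, to) {
  to <- match.arg(to, c("float64", "uint8"))
  if (inherits(x, "dense_image")) return(dense_image(img_values(x), to))
  if (inherits(x, "byte_seq") && to == "float64") return(real_seq(x$values))
  if (inherits(x, "real_seq") && to == "uint8")
    return(byte_seq(pmin(255, pmax(0, floor(x$values + 0.5)))))
  if (inherits(x, "byte_seq") && to == "uint8") return(byte_seq(x$values))
  if (inherits(x, "real_seq") && to == "float64") return(real_seq(x$values))
  stop("unsupported element-kind conversion")
}
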