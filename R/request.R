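#' Construct an op request
#'
#' A declarative query against an op environment: op name, requested
#' functional shape, and optionally the argument/output type names.  When
#' `input_types` is `NULL` the request is a wildcard satisfied by any op of
#' that name and shape (used for dependency resolution by name).
#'
#' @param name requested op name.
#' @param shape requested functional shape.
#' @param input_types character vector of argument type names, in call
#'   order (for a computer request this includes the container position).
#' @param output_type requested output type, or `NULL` for "any".
#' @param container_pos for computer requests: which argument position is
#'   the pre-allocated container (default: last).
#' @param mutable_pos for inplace requests: which argument position is
#'   mutable (default: first).
#' @return an `op_request`.
#' @export
op_request <- function(name, shape, input_types = NULL, output_type = NULL,
                       container_pos = NULL, mutable_pos = NULL) {
  shape <- match.arg(shape, .shapes)
  if (!is.null(input_types)) {
    if (shape == "computer") {
      container_pos <- as.integer(container_pos %||% length(input_types))
      stopifnot(container_pos >= 1L, container_pos <= length(input_types))
    }
    if (shape == "inplace") {
      mutable_pos <- as.integer(mutable_pos %||% 1L)
      stopifnot(mutable_pos >= 1L, mutable_pos <= length(input_types))
    }
  }
  structure(list(name = name, shape = shape,
                 input_types = input_types, output_type = output_type,
                 container_pos = container_pos, mutable_pos = mutable_pos),
            class = "op_request")
}

#' Canonical cache key of a request
#'
#' Format `name|shape|in=t1,t2,...|out=t` (documented for debugging), with a
#' trailing `|c=<pos>` / `|m=<pos>` segment for computer/inplace requests.
#' Wildcard segments print as `*`.
#'
#' @param request an [op_request()].
#' @return character scalar.
#' @export
request_key <- function(request) {
  k <- sprintf("%s|%s|in=%s|out=%s", request$name, request$shape,
               if (is.null(request$input_types)) "*"
               else paste(request$input_types, collapse = ","),
               request$output_type %||% "*")
  if (!is.null(request$container_pos)) k <- sprintf("%s|c=%d", k, request$container_pos)
  if (!is.null(request$mutable_pos)) k <- sprintf("%s|m=%d", k, request$mutable_pos)
  k
}
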