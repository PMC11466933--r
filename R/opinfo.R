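.shapes <- c("function", "computer", "inplace")
.io_roles <- c("input", "container", "mutable", "output")

#' Declare one op parameter
#'
#' @param name parameter identifier.
#' @param type semantic type name (a key into the type registry).
#' @param io one of `"input"`, `"container"`, `"mutable"`, `"output"`.
#' @param optional may the parameter be omitted (only legal for inputs)?
#' @param default literal default injected when an optional parameter is
#'   dropped by signature reduction.
#' @param description free text shown by verbose help.
#' @return a `param_spec` list.
#' @export
param_spec <- function(name, type, io = "input", optional = FALSE,
                       default = NULL, description = "") {
  io <- match.arg(io, .io_roles)
  structure(list(name = name, type = type, io = io,
                 optional = isTRUE(optional), default = default,
                 description = description),
            class = "param_spec")
}

#' Declare an op dependency
#'
#' Dependencies are requests by name and functional shape; the engine
#' resolves them recursively at match time, never hard-linking a specific
#' implementation.  `input_types`/`output_type` optionally narrow the
#' request (omitted = wildcard).
#'
#' @param slot name under which the resolved executable is injected.
#' @param name requested op name.
#' @param shape requested functional shape.
#' @param input_types,output_type optional type constraints.
#' @return a `dep_spec` list.
#' @export
dep_spec <- function(slot, name, shape, input_types = NULL, output_type = NULL) {
  shape <- match.arg(shape, .shapes)
  structure(list(slot = slot, name = name, shape = shape,
                 input_types = input_types, output_type = output_type),
            class = "dep_spec")
}

#' Construct an op description (OpInfo)
#'
#' The registered description of one op: its names (first is canonical,
#' the rest aliases), functional shape, ordered parameters, priority,
#' implementation locator and dependencies.
#'
#' @param names non-empty character vector of dot-separated op names.
#' @param shape `"function"` (allocates a new output), `"computer"` (writes
#'   into a pre-allocated container) or `"inplace"` (overwrites one mutable
#'   argument).
#' @param parameters list of [param_spec()]s, in call order.
#' @param priority real; higher-priority ops win ties deterministically.
#' @param source text locator resolvable to a callable, e.g.
#'   `"opsmatch::.op_math_add"` or any key bound via [register_op()]'s
#'   `impl` argument.
#' @param description free text.
#' @param dependencies list of [dep_spec()]s.
#' @param adapter for engine adapter ops only: `list(from=, to=, kind=)`.
#' @param reduced_from internal; parent OpInfo of a reduced signature.
#' @param dropped internal; dropped trailing optional params of a reduced
#'   signature (with their defaults and original positions).
#' @return an `op_info` object.
#' @export
op_info <- function(names, shape, parameters = list(), priority = 0,
                    source, description = "", dependencies = list(),
                    adapter = NULL, reduced_from = NULL, dropped = NULL) {
  shape <- match.arg(shape, .shapes)
  info <- structure(list(names = as.character(names), shape = shape,
                         parameters = parameters, priority = as.numeric(priority),
                         source = source, description = description,
                         dependencies = dependencies, adapter = adapter,
                         reduced_from = reduced_from, dropped = dropped),
                    class = "op_info")
  validate_op_info(info)
  info
}

#' Validate OpInfo invariants
#'
#' Checks the structural invariants: a computer has exactly one container
#' parameter and no output; an inplace exactly one mutable; a function
#' exactly one output and neither container nor mutable; parameter names are
#' unique; optional is only legal on inputs.
#'
#' @param info an `op_info`.
#' @return `info`, invisibly; stops with the violated invariant otherwise.
#' @export
validate_op_info <- function(info) {
  if (!length(info$names)) stop("op_info invariant: names must be non-empty")
  ios <- vapply(info$parameters, function(p) p$io, character(1))
  nms <- vapply(info$parameters, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("op_info invariant: duplicate parameter names in ",
                               info$names[[1]])
  n_out <- sum(ios == "output"); n_con <- sum(ios == "container")
  n_mut <- sum(ios == "mutable")
  bad <- switch(info$shape,
    "function" = n_out != 1L || n_con > 0L || n_mut > 0L,
    "computer" = n_con != 1L || n_out > 0L || n_mut > 0L,
    "inplace"  = n_mut != 1L || n_out > 0L || n_con > 0L)
  if (bad) stop("op_info invariant: shape ", info$shape, " has wrong io roles in op ",
                info$names[[1]])
  for (p in info$parameters) {
    if (p$optional && p$io != "input")
      stop("op_info invariant: optional only allowed on inputs (", p$name, ")")
  }
  invisible(info)
}

op_param_names <- function(info) vapply(info$parameters, `[[`, character(1), "name")
op_param_types <- function(info) vapply(info$parameters, `[[`, character(1), "type")
op_param_ios <- function(info) vapply(info$parameters, `[[`, character(1), "io")

# Position of the single special parameter of a shape (container/mutable),
# or the output param of a function.
op_special_pos <- function(info) {
  ios <- op_param_ios(info)
  switch(info$shape,
    "function" = which(ios == "output"),
    "computer" = which(ios == "container"),
    "inplace"  = which(ios == "mutable"))
}

#' Expand optional parameters into reduced signatures
#'
#' Returns the op itself plus one reduced signature per right-to-left prefix
#' of the contiguous trailing block of optional input parameters (the
#' container parameter of a computer, conventionally declared last, is
#' ignored when determining "trailing").  Executing a reduced signature
#' injects the declared defaults.  An optional parameter followed by a
#' required one is legal but never droppable; a droppable optional parameter
#' with no default is an error.
#'
#' @param info an `op_info`.
#' @return list of `op_info`, length `1 + k` where `k` is the number of
#'   trailing droppable optionals; element 1 is `info` itself.
#' @export
reduce_optional <- function(info) {
  validate_op_info(info)
  params <- info$parameters
  ios <- op_param_ios(info)
  # indices considered for trailing reduction: inputs only, with a trailing
  # container/mutable/output param skipped over
  idx <- seq_along(params)
  work <- idx[ios == "input"]
  trailing <- integer()
  # walk the full parameter list from the right, skipping non-input params
  for (i in rev(idx)) {
    if (ios[[i]] != "input") next
    if (params[[i]]$optional) trailing <- c(i, trailing) else break
  }
  out <- list(info)
  if (!length(trailing)) return(out)
  for (i in trailing) {
    if (is.null(params[[i]]$default))
      stop("droppable optional parameter without default: ", params[[i]]$name,
           " in op ", info$names[[1]])
  }
  for (k in seq_along(trailing)) {
    drop_idx <- trailing[(length(trailing) - k + 1L):length(trailing)]
    dropped <- lapply(drop_idx, function(i)
      list(name = params[[i]]$name, position = i, default = params[[i]]$default))
    red <- info
    red$parameters <- params[-drop_idx]
    red$reduced_from <- info
    red$dropped <- dropped
    class(red) <- "op_info"
    out[[k + 1L]] <- red
  }
  out
}

#' @export
format.op_info <- function(x, ...) {
  ps <- vapply(x$parameters, function(p)
    sprintf("%s:%s%s", p$name, p$type,
            if (p$io == "input") if (p$optional) "?" else "" else paste0("[", p$io, "]")),
    character(1))
  sprintf("%s %s(%s) [priority=%g, source=%s]", x$shape, x$names[[1]],
          paste(ps, collapse = ", "), x$priority, x$source)
}

#' @export
print.op_info <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# Field-by-field structural equality ignoring reduction backrefs; used by
# round-trip checks.
op_info_equal <- function(a, b) {
  norm <- function(i) {
    i$reduced_from <- NULL; i$dropped <- NULL
    i$parameters <- lapply(i$parameters, function(p) { class(p) <- NULL; p })
    i$dependencies <- lapply(i$dependencies, function(d) { class(d) <- NULL; d })
    class(i) <- NULL
    i
  }
  isTRUE(all.equal(norm(a), norm(b)))
}
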