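#' Fluent op request builder
#'
#' Starts a declarative request for the named op.  Stage arguments with
#' [op_input()] (and a container with [op_output()]), then finish with a
#' terminal: [op_apply()] matches a function op and returns a new value,
#' [op_compute()] matches a computer op and overwrites the supplied
#' container, [op_mutate()] matches an inplace op and transforms the flagged
#' argument.  [op_function()], [op_computer()] and [op_inplace()] return the
#' matched executable without running it.
#'
#' Runtime argument types are resolved through the type registry's
#' recognizers (most specific recognizing type wins; an ambiguity is an
#' error, not a guess).
#'
#' @param env an [op_environment()].
#' @param name op name, e.g. `"filter.gauss"`.
#' @return an `op_builder`.
#' @examples
#' env <- default_ops_env()
#' op(env, "math.add") |> op_input(2, 3) |> op_apply()
#' @export
op <- function(env, name) {
  structure(list(env = env, name = name, args = list(), in_types = NULL,
                 out_type = NULL, container = NULL, container_pos = NULL,
                 mutable_pos = 1L),
            class = "op_builder")
}

#' @rdname op
#' @param builder an `op_builder`.
#' @param ... argument values, in the op's parameter order.
#' @export
op_input <- function(builder, ...) {
  builder$args <- c(builder$args, list(...))
  builder
}

#' @rdname op
#' @param container pre-allocated output container for [op_compute()].
#' @param pos position of the container among the call arguments
#'   (default: after all staged inputs).
#' @export
op_output <- function(builder, container, pos = NULL) {
  builder$container <- container
  builder$container_pos <- pos
  builder
}

#' @rdname op
#' @param types character type names, staged instead of values when matching
#'   an executable via [op_function()] and friends.
#' @export
op_in_types <- function(builder, types) {
  builder$in_types <- as.character(types)
  builder
}

#' @rdname op
#' @param type requested output type name (optional; wildcard when absent).
#' @export
op_ret_type <- function(builder, type) {
  builder$out_type <- type
  builder
}

staged_types <- function(builder) {
  builder$in_types %||% vapply(builder$args, function(a)
    resolve_type_name(builder$env$types, a), character(1))
}

#' @rdname op
#' @export
op_apply <- function(builder) {
  req <- op_request(builder$name, "function", input_types = staged_types(builder),
                    output_type = builder$out_type)
  run_request(builder$env, req, builder$args)$result
}

#' @rdname op
#' @export
op_compute <- function(builder) {
  if (is.null(builder$container)) stop("op_compute() needs op_output(<container>)")
  pos <- builder$container_pos %||% (length(builder$args) + 1L)
  args <- append(builder$args, list(builder$container), after = pos - 1L)
  types <- c(staged_types(builder), resolve_type_name(builder$env$types,
                                                      builder$container))
  types <- append(types[-length(types)], types[length(types)], after = pos - 1L)
  req <- op_request(builder$name, "computer", input_types = types,
                    container_pos = pos)
  run_request(builder$env, req, args)$result
}

#' @rdname op
#' @param pos which staged argument is mutable (default first).
#' @export
op_mutate <- function(builder, pos = 1L) {
  req <- op_request(builder$name, "inplace", input_types = staged_types(builder),
                    mutable_pos = pos)
  invisible(run_request(builder$env, req, builder$args)$result)
}

match_executable <- function(builder, shape, container_pos = NULL,
                             mutable_pos = NULL) {
  types <- staged_types(builder)
  req <- op_request(builder$name, shape,
                    input_types = if (length(types)) types,
                    output_type = builder$out_type,
                    container_pos = container_pos, mutable_pos = mutable_pos)
  tree <- op_match_cached(builder$env, req)
  tree_executable(builder$env, tree)
}

#' @rdname op
#' @export
op_function <- function(builder) match_executable(builder, "function")

#' @rdname op
#' @export
op_computer <- function(builder, pos = NULL) {
  match_executable(builder, "computer",
                   container_pos = pos %||%
                     length(builder$in_types %||% builder$args))
}

#' @rdname op
#' @export
op_inplace <- function(builder, pos = 1L) {
  match_executable(builder, "inplace", mutable_pos = pos)
}

# --- help and type descriptions -------------------------------------------

#' Describe a type through the environment's engine.describe ops
#'
#' Returns the simple name produced by the highest-priority
#' `engine.describe` op registered for exactly `type_name`; falls back to
#' the raw type name, so the lookup is total.
#'
#' @param env an [op_environment()].
#' @param type_name a type identifier.
#' @return character scalar.
#' @export
describe_type <- function(env, type_name) {
  cands <- Filter(function(o) {
    if (!is_engine_family(o, "engine.describe") || o$shape != "function") return(FALSE)
    ios <- op_param_ios(o)
    identical(o$parameters[[which(ios == "input")[1]]]$type, type_name)
  }, env$ops)
  best <- pick_best_op(cands)
  if (is.null(best)) return(type_name)
  impl <- resolve_impl(env, best$source)
  impl(type_name)
}

help_signature <- function(env, info) {
  parts <- vapply(info$parameters, function(p) {
    if (p$io == "output") return(NA_character_)
    sprintf("%s: %s%s", p$name, describe_type(env, p$type),
            if (p$io == "container") " [container]"
            else if (p$io == "mutable") " [mutable]" else "")
  }, character(1))
  ios <- op_param_ios(info)
  out <- if (any(ios == "output"))
    describe_type(env, info$parameters[[which(ios == "output")]]$type)
  else describe_type(env, info$parameters[[which(ios %in% c("container", "mutable"))[1]]]$type)
  sprintf("%s(%s) -> %s", info$names[[1]], paste(stats::na.omit(parts), collapse = ", "), out)
}

#' List and describe available ops
#'
#' A query matching a category prefix (e.g. `"math"`) lists all op names
#' under it, sorted; a query matching a full op name lists one signature
#' line per registered implementation (including reduced signatures derived
#' from optional parameters).  `verbose = TRUE` adds per-parameter
#' descriptions.  Type names are replaced by their `engine.describe` simple
#' names, so the text carries no package-specific terminology.
#'
#' @param env an [op_environment()].
#' @param query op name or category prefix; `""` lists everything.
#' @param verbose include parameter documentation?
#' @return character scalar (the help text); ops found as attribute `"n"`.
#' @export
op_help <- function(env, query = "", verbose = FALSE) {
  ops <- list_ops(env, prefix = if (nzchar(query)) query)
  if (!length(ops)) {
    all_names <- sort(unique(unlist(lapply(env$ops, `[[`, "names"))))
    near <- all_names[order(utils::adist(query, all_names))][seq_len(min(3, length(all_names)))]
    txt <- sprintf("no ops found for query '%s'; nearest names: %s", query,
                   paste(near, collapse = ", "))
    return(structure(txt, n = 0L))
  }
  exact <- any(vapply(ops, function(o) query %in% o$names, logical(1)))
  if (nzchar(query) && !exact) {
    nms <- sort(unique(unlist(lapply(ops, `[[`, "names"))))
    nms <- nms[nms == query | startsWith(nms, paste0(query, "."))]
    return(structure(paste(nms, collapse = "\n"), n = length(nms)))
  }
  prio <- vapply(ops, `[[`, numeric(1), "priority")
  src <- vapply(ops, `[[`, character(1), "source")
  nm <- vapply(ops, function(o) o$names[[1]], character(1))
  arity <- vapply(ops, function(o) length(o$parameters), integer(1))
  ord <- order(nm, -prio, src, -arity, method = "radix")
  lines <- vapply(ops[ord], function(o) {
    sig <- help_signature(env, o)
    if (!verbose) return(sig)
    det <- vapply(o$parameters, function(p) sprintf(
      "    %s (%s%s): %s", p$name, describe_type(env, p$type),
      if (p$optional) ", optional" else "",
      if (nzchar(p$description)) p$description else "no description"),
      character(1))
    paste(c(sig, det), collapse = "\n")
  }, character(1))
  structure(paste(lines, collapse = "\n"), n = length(lines))
}

# --- execution history -----------------------------------------------------

#' The execution history (OpHistory)
#'
#' Every terminal execution appends one record: timestamp, canonical request
#' key, InfoTree digest, and the identifier of the written/created output
#' (when the output is an identifiable mutable object).  The record of a
#' given output identifier reconstructs the tree that produced it (by
#' digest; the tree itself is recoverable by replaying the match).
#'
#' @param env an [op_environment()].
#' @return data.frame with columns `time`, `request`, `digest`, `output`.
#' @export
op_history <- function(env) {
  h <- env$history
  data.frame(
    time = if (length(h)) do.call(c, lapply(h, `[[`, "time")) else as.POSIXct(character()),
    request = vapply(h, `[[`, character(1), "request"),
    digest = vapply(h, `[[`, character(1), "digest"),
    output = vapply(h, `[[`, character(1), "output"),
    stringsAsFactors = FALSE)
}

#' @rdname op_history
#' @param output_id identifier of a written object (see `$id` on images and
#'   sequences).
#' @return for `history_for_output`: the digest(s) of the producing tree(s),
#'   most recent last.
#' @export
history_for_output <- function(env, output_id) {
  h <- op_history(env)
  h$digest[h$output == output_id]
}
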