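#' Create an op environment
#'
#' The op environment is the collection of all registered ops plus the
#' engine operating over them: a type registry, the op list, the resolved
#' implementation table, the match cache and the execution history.  It has
#' reference semantics: registration mutates it in place and invalidates the
#' cache.
#'
#' @param types a [type_registry()]; defaults to an empty one.
#' @param cache_enabled should [op_match_cached()] consult the cache?
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return an `op_environment`.
#' @seealso [default_ops_env()] for an environment pre-loaded with the
#'   engine-support and image op collections.
#' @export
op_environment <- function(types = type_registry(), cache_enabled = TRUE,
                           log_level = "warn") {
  env <- new.env(parent = emptyenv())
  env$types <- types
  env$ops <- list()
  env$impls <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$cache_enabled <- isTRUE(cache_enabled)
  env$generation <- 0L
  env$history <- list()
  env$log_level <- log_level
  class(env) <- "op_environment"
  env
}

# Any mutation of the op collection invalidates every cache entry.
bump_generation <- function(env) {
  env$generation <- env$generation + 1L
  rm(list = ls(env$cache), envir = env$cache)
  invisible(env)
}

#' Register an op in an environment
#'
#' Validates the [op_info()], materializes its reduced signatures (trailing
#' optional parameters dropped right-to-left, per [reduce_optional()]) and
#' adds all of them to the environment.  A non-trailing optional parameter
#' is legal but never droppable; it is logged at registration.
#'
#' @param env an [op_environment()].
#' @param info an `op_info`.
#' @param impl optional callable bound to `info$source`; when omitted the
#'   source locator must be resolvable as `"package::function"`.
#' @return `env`, invisibly.
#' @export
register_op <- function(env, info, impl = NULL) {
  validate_op_info(info)
  if (!is.null(impl)) assign(info$source, impl, envir = env$impls)
  ios <- op_param_ios(info)
  opts <- vapply(info$parameters, function(p) isTRUE(p$optional), logical(1))
  inputs <- which(ios == "input")
  if (length(inputs)) {
    trailing <- integer()
    for (i in rev(seq_along(info$parameters))) {
      if (ios[[i]] != "input") next
      if (opts[[i]]) trailing <- c(i, trailing) else break
    }
    stranded <- setdiff(which(opts), trailing)
    if (length(stranded))
      ops_log(env, "info", sprintf(
        "op %s: optional parameter(s) %s precede a required one; never droppable",
        info$names[[1]],
        paste(vapply(stranded, function(i) info$parameters[[i]]$name, character(1)),
              collapse = ", ")))
  }
  forms <- reduce_optional(info)
  env$ops <- c(env$ops, forms)
  bump_generation(env)
  invisible(env)
}

#' Register every op of a descriptor
#'
#' @param env an [op_environment()].
#' @param yaml_text descriptor document (see [parse_descriptor()]).
#' @param impls optional named list of callables keyed by source locator.
#' @return `env`, invisibly.
#' @export
register_descriptor <- function(env, yaml_text, impls = NULL) {
  for (info in parse_descriptor(yaml_text)) {
    register_op(env, info, impl = impls[[info$source]])
  }
  invisible(env)
}

#' Remove ops from an environment
#'
#' Removes every registered op (including reduced signatures) whose
#' canonical name or source locator matches `what`, and invalidates the
#' match cache.
#'
#' @param env an [op_environment()].
#' @param what op name or source locator.
#' @return number of removed entries, invisibly.
#' @export
unregister_op <- function(env, what) {
  keep <- vapply(env$ops, function(o)
    !(what %in% o$names || identical(o$source, what)), logical(1))
  n <- sum(!keep)
  env$ops <- env$ops[keep]
  bump_generation(env)
  invisible(n)
}

#' List registered ops
#'
#' @param env an [op_environment()].
#' @param prefix optional name filter: ops whose name equals `prefix` or
#'   starts with `prefix` followed by a dot.
#' @param include_reduced include materialized reduced signatures?
#' @return list of `op_info`.
#' @export
list_ops <- function(env, prefix = NULL, include_reduced = TRUE) {
  ops <- env$ops
  if (!include_reduced) ops <- Filter(function(o) is.null(o$reduced_from), ops)
  if (!is.null(prefix)) {
    ops <- Filter(function(o) any(o$names == prefix |
                                    startsWith(o$names, paste0(prefix, "."))), ops)
  }
  ops
}

resolve_impl <- function(env, source) {
  if (exists(source, envir = env$impls, inherits = FALSE))
    return(get(source, envir = env$impls))
  if (grepl("::", source, fixed = TRUE)) {
    parts <- strsplit(source, "::", fixed = TRUE)[[1]]
    return(get(parts[[2]], envir = asNamespace(parts[[1]])))
  }
  stop("cannot resolve implementation for source locator: ", source)
}

#' @export
print.op_environment <- function(x, ...) {
  cat(sprintf("<op_environment: %d ops (%d primary), %d types, generation %d>\n",
              length(x$ops), length(list_ops(x, include_reduced = FALSE)),
              length(x$types$types), x$generation))
  invisible(x)
}
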