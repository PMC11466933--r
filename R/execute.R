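# Turns a resolved InfoTree into an executable closure with the functional
# shape of the original request.  Wrapping order, innermost to outermost:
# implementation call (with injected defaults and dependency executables),
# shape adaptation / element-wise lifting, then parameter conversions with
# container copy-back.

#' Build an executable from a resolved match
#'
#' The returned closure takes the request's arguments positionally (for a
#' computer request this includes the container at its requested position)
#' and returns the output value: a fresh value for a function request, the
#' user's container for a computer request, the mutated argument
#' (invisibly) for an inplace request.
#'
#' @param env the [op_environment()] the tree was matched against.
#' @param tree an `info_tree` from [op_match()].
#' @return a function.
#' @export
tree_executable <- function(env, tree) {
  root <- tree$root
  impl <- resolve_impl(env, root$source)
  dep_execs <- lapply(tree$dependencies, function(d) tree_executable(env, d))
  aux_execs <- lapply(tree$adapter_aux, function(t) tree_executable(env, t))

  # call the implementation with args in the op's own parameter order,
  # injecting defaults of dropped optionals for reduced signatures
  base_call <- function(args) {
    if (!is.null(root$dropped)) {
      parent <- root$reduced_from
      # positions index the parent's full parameter list; the output param of
      # a function op is not a call argument
      call_idx <- which(op_param_ios(parent) != "output")
      full <- vector("list", length(call_idx))
      drop_at <- match(vapply(root$dropped, `[[`, integer(1), "position"), call_idx)
      for (k in seq_along(root$dropped))
        full[[drop_at[[k]]]] <- root$dropped[[k]]$default
      full[setdiff(seq_along(full), drop_at)] <- args
      args <- full
    }
    if (length(root$dependencies)) do.call(impl, c(args, list(.deps = dep_execs)))
    else do.call(impl, args)
  }

  view <- tree$view
  ad <- tree$adapter
  inner <- if (is.null(ad)) {
    switch(tree$request$shape,
      "function" = function(args) base_call(args),
      "computer" = function(args) { base_call(args); args[[view$container_pos]] },
      "inplace"  = function(args) { base_call(args); args[[view$mutable_pos]] })
  } else if (!is.null(tree$lift)) {
    function(args) {
      vals <- lapply(args, function(a) if (inherits(a, "dense_image"))
        img_values(a) else if (inherits(a, "planar_image"))
          img_values(dense_from_planar(a)) else a)
      out <- aux_execs$create(args[[1]])
      res <- if (length(vals) == 1L)
        mapply(function(x) base_call(list(x)), vals[[1]])
      else {
        if (!identical(dim(vals[[1]]), dim(vals[[2]])))
          stop("dimension error: lifted arguments must share one shape")
        mapply(function(x, y) base_call(list(x, y)), vals[[1]], vals[[2]])
      }
      if (inherits(out, "dense_image")) {
        img_set_values(out, array(res, dim = dim(vals[[1]])))
      } else if (inherits(out, "planar_image")) {
        .op_copy_planar(planar_from_dense(
          dense_image(array(res, dim = dim(vals[[1]])), out$element_kind)), out)
      } else stop("lifting supports image outputs only")
      out
    }
  } else {
    kind <- paste(ad$adapter$from, ad$adapter$to, sep = "->")
    switch(kind,
      "computer->function" = function(args) {
        container <- aux_execs$create(args[[.create_ref(env, view, args)]])
        full <- append(args, list(container), after = view$inner_container_pos - 1L)
        base_call(full)
        container
      },
      "inplace->function" = function(args) {
        mpos <- view$inner_mutable_pos
        clone <- aux_execs$create(args[[mpos]])
        aux_execs$copy(args[[mpos]], clone)
        full <- args; full[[mpos]] <- clone
        base_call(full)
        clone
      },
      "function->computer" = function(args) {
        n <- length(args)
        res <- base_call(args[-n])
        aux_execs$copy(res, args[[n]])
        args[[n]]
      },
      "inplace->computer" = function(args) {
        n <- length(args); mpos <- view$inner_mutable_pos
        container <- args[[n]]
        aux_execs$copy(args[[mpos]], container)
        full <- args[-n]; full[[mpos]] <- container
        base_call(full)
        container
      },
      "computer->inplace" = function(args) {
        tmp <- aux_execs$create(args[[view$mutable_pos]])
        full <- append(args, list(tmp), after = view$inner_container_pos - 1L)
        base_call(full)
        aux_execs$copy(tmp, args[[view$mutable_pos]])
        args[[view$mutable_pos]]
      },
      stop("unknown adapter transform: ", kind))
  }

  convs <- tree$conversions
  outc <- tree$output_conversion
  if (!length(convs) && is.null(outc)) return(function(...) inner(list(...)))

  conv_execs <- lapply(convs, function(cv) list(
    forward = tree_executable(env, cv$forward),
    backward = if (!is.null(cv$backward)) tree_executable(env, cv$backward),
    copy = if (!is.null(cv$copy)) tree_executable(env, cv$copy)))
  outc_exec <- if (!is.null(outc)) tree_executable(env, outc)

  function(...) {
    user_args <- list(...)
    args <- user_args
    for (p in names(conv_execs)) {
      i <- as.integer(p)
      args[[i]] <- conv_execs[[p]]$forward(user_args[[i]])
    }
    res <- inner(args)
    for (p in names(conv_execs)) {
      cv <- conv_execs[[p]]
      if (is.null(cv$copy)) next
      i <- as.integer(p)
      cv$copy(cv$backward(args[[i]]), user_args[[i]])
    }
    out <- switch(tree$request$shape,
      "function" = res,
      "computer" = user_args[[tree$request$container_pos %||% length(user_args)]],
      "inplace"  = user_args[[tree$request$mutable_pos %||% 1L]])
    if (!is.null(outc_exec)) out <- outc_exec(out)
    out
  }
}

# Reference argument for engine.create inside an adapter: the first call
# argument whose op-side parameter type matches the container type.
.create_ref <- function(env, view, args) {
  target <- view$aux$create
  for (i in seq_len(nrow(view$slots))) {
    if (assignable(env$types, view$slots$type[[i]], target)) return(i)
  }
  1L
}

# Shared execution path: match (cached), build, run, log provenance.
run_request <- function(env, request, args, use_cache = TRUE) {
  tree <- if (use_cache) op_match_cached(env, request) else op_match(env, request)
  exec <- tree_executable(env, tree)
  result <- tryCatch(do.call(exec, args), error = function(e)
    stop("op execution failed [InfoTree ", info_tree_digest(tree), "]: ",
         conditionMessage(e), call. = FALSE))
  out_id <- obj_id(result)
  env$history <- c(env$history, list(list(
    time = Sys.time(), request = request_key(request),
    digest = info_tree_digest(tree), output = out_id)))
  list(result = result, tree = tree)
}
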