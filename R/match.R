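# --- candidate views -------------------------------------------------------
#
# A "view" presents an op (possibly through an adapter) in the functional
# shape of a request: an ordered list of call slots (type + io role), the
# produced output type, and bookkeeping the executor needs to reassemble the
# underlying call.

direct_view <- function(op) {
  ios <- op_param_ios(op)
  types <- op_param_types(op)
  switch(op$shape,
    "function" = {
      idx <- which(ios == "input")
      list(slots = data.frame(type = types[idx], io = ios[idx],
                              stringsAsFactors = FALSE),
           out_type = types[[which(ios == "output")]],
           container_pos = NULL, mutable_pos = NULL, map = idx)
    },
    "computer" = {
      list(slots = data.frame(type = types, io = ios, stringsAsFactors = FALSE),
           out_type = types[[which(ios == "container")]],
           container_pos = which(ios == "container"), mutable_pos = NULL,
           map = seq_along(types))
    },
    "inplace" = {
      list(slots = data.frame(type = types,
                              io = ifelse(ios == "mutable", "mutable", "input"),
                              stringsAsFactors = FALSE),
           out_type = types[[which(ios == "mutable")]],
           container_pos = NULL, mutable_pos = which(ios == "mutable"),
           map = seq_along(types))
    })
}

# View of `op` as seen through a shape adapter; NULL when inapplicable.
# `aux_types` records the engine-op needs (create/copy) the adapter brings.
adapted_view <- function(op, adapter) {
  ad <- adapter$adapter
  if (is.null(ad) || !identical(ad$kind, "shape")) return(NULL)
  if (!identical(ad$from, op$shape)) return(NULL)
  ios <- op_param_ios(op)
  types <- op_param_types(op)
  from <- ad$from; to <- ad$to
  if (from == "computer" && to == "function") {
    cpos <- which(ios == "container")
    idx <- which(ios == "input")
    return(list(slots = data.frame(type = types[idx], io = ios[idx],
                                   stringsAsFactors = FALSE),
                out_type = types[[cpos]], container_pos = NULL, mutable_pos = NULL,
                map = idx, inner_container_pos = cpos,
                aux = list(create = types[[cpos]])))
  }
  if (from == "inplace" && to == "function") {
    mpos <- which(ios == "mutable")
    return(list(slots = data.frame(type = types, io = rep("input", length(types)),
                                   stringsAsFactors = FALSE),
                out_type = types[[mpos]], container_pos = NULL, mutable_pos = NULL,
                map = seq_along(types), inner_mutable_pos = mpos,
                aux = list(create = types[[mpos]], copy = types[[mpos]])))
  }
  if (from == "function" && to == "computer") {
    idx <- which(ios == "input")
    opos <- which(ios == "output")
    slots <- data.frame(type = c(types[idx], types[[opos]]),
                        io = c(ios[idx], "container"), stringsAsFactors = FALSE)
    return(list(slots = slots, out_type = types[[opos]],
                container_pos = nrow(slots), mutable_pos = NULL,
                map = c(idx, NA), aux = list(copy = types[[opos]])))
  }
  if (from == "inplace" && to == "computer") {
    mpos <- which(ios == "mutable")
    slots <- data.frame(type = c(types, types[[mpos]]),
                        io = c(rep("input", length(types)), "container"),
                        stringsAsFactors = FALSE)
    return(list(slots = slots, out_type = types[[mpos]],
                container_pos = nrow(slots), mutable_pos = NULL,
                map = c(seq_along(types), NA), inner_mutable_pos = mpos,
                aux = list(copy = types[[mpos]])))
  }
  if (from == "computer" && to == "inplace") {
    cpos <- which(ios == "container")
    idx <- which(ios == "input")
    merge <- idx[types[idx] == types[[cpos]]]
    if (!length(merge)) return(NULL)
    mpos_view <- match(merge[[1]], idx)
    io <- rep("input", length(idx)); io[mpos_view] <- "mutable"
    return(list(slots = data.frame(type = types[idx], io = io,
                                   stringsAsFactors = FALSE),
                out_type = types[[cpos]], container_pos = NULL,
                mutable_pos = mpos_view, map = idx, inner_container_pos = cpos,
                aux = list(create = types[[cpos]], copy = types[[cpos]])))
  }
  NULL
}

is_engine_family <- function(op, family) {
  any(op$names == family | startsWith(op$names, paste0(family, ".")))
}

converter_ops <- function(env) {
  Filter(function(o) is_engine_family(o, "engine.convert") &&
           o$shape == "function" && length(o$parameters) == 2L, env$ops)
}

copy_ops <- function(env) {
  Filter(function(o) is_engine_family(o, "engine.copy") &&
           o$shape == "computer" && length(o$parameters) == 2L, env$ops)
}

create_ops <- function(env) {
  Filter(function(o) is_engine_family(o, "engine.create") &&
           o$shape == "function" && length(o$parameters) == 2L, env$ops)
}

adapter_ops <- function(env) {
  Filter(function(o) !is.null(o$adapter), env$ops)
}

pick_best_op <- function(ops) {
  if (!length(ops)) return(NULL)
  prio <- vapply(ops, `[[`, numeric(1), "priority")
  src <- vapply(ops, `[[`, character(1), "source")
  ops[[order(-prio, src, method = "radix")[1]]]
}

# Best single-hop converter from `from_t` to `to_t`, or NULL.
find_converter <- function(env, from_t, to_t, loose_from = FALSE) {
  cands <- Filter(function(o) {
    ti <- op_param_types(o); io <- op_param_ios(o)
    cin <- ti[[which(io == "input")]]; cout <- ti[[which(io == "output")]]
    from_ok <- assignable(env$types, from_t, cin) ||
      (loose_from && assignable(env$types, cin, from_t))
    from_ok && assignable(env$types, cout, to_t)
  }, converter_ops(env))
  pick_best_op(cands)
}

find_copy <- function(env, type) {
  cands <- Filter(function(o) {
    ti <- op_param_types(o)
    assignable(env$types, type, ti[[1]]) && assignable(env$types, type, ti[[2]])
  }, copy_ops(env))
  pick_best_op(cands)
}

find_create <- function(env, type) {
  cands <- Filter(function(o) {
    ti <- op_param_types(o); io <- op_param_ios(o)
    cin <- ti[[which(io == "input")]]; cout <- ti[[which(io == "output")]]
    assignable(env$types, type, cin) && assignable(env$types, cout, type)
  }, create_ops(env))
  pick_best_op(cands)
}

# --- candidate generation --------------------------------------------------

# One scored candidate: the op, its (optional) adapter + lift details, the
# per-position conversions, and the ranking keys.
make_candidate <- function(op, view, adapter = NULL, lift = NULL,
                           conversions = list(), out_conv = NULL,
                           aux_resolved = list()) {
  n_conv <- length(conversions) + if (is.null(out_conv)) 0L else 1L
  wrappers <- n_conv + if (is.null(adapter)) 0L else 1L
  src_key <- paste(c(op$source,
                     if (!is.null(adapter)) adapter$source,
                     unlist(lapply(conversions, function(cv)
                       c(cv$forward$source,
                         if (!is.null(cv$backward)) cv$backward$source,
                         if (!is.null(cv$copy)) cv$copy$source))),
                     if (!is.null(out_conv)) out_conv$source),
                   collapse = "")
  list(op = op, view = view, adapter = adapter, lift = lift,
       conversions = conversions, out_conv = out_conv,
       aux_resolved = aux_resolved,
       priority = op$priority, wrappers = wrappers, source_key = src_key)
}

#' Deterministically rank scored match candidates
#'
#' Total order used inside each matching routine: higher op priority first,
#' then fewer total wrapper ops (adaptation plus conversions), then
#' lexicographic comparison of the canonical source locators of the op and
#' its wrappers.  The order is stable and independent of registration order.
#'
#' @param candidates list of candidates carrying `priority`, `wrappers` and
#'   `source_key` fields.
#' @return the candidates, ranked.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) <= 1L) return(candidates)
  prio <- vapply(candidates, `[[`, numeric(1), "priority")
  wrap <- vapply(candidates, `[[`, integer(1), "wrappers")
  key <- vapply(candidates, `[[`, character(1), "source_key")
  candidates[order(-prio, wrap, key, method = "radix")]
}

# Try to fit `view` of `op` to `req`; returns a candidate or a near-miss
# reason string.
fit_view <- function(env, req, op, view, adapter, allow_convert) {
  reason <- function(msg) structure(msg, class = "near_miss")
  # adapter engine-op needs (create/copy) must be satisfiable, else the
  # adapter is not a candidate at all
  aux_resolved <- list()
  if (!is.null(view$aux)) {
    for (role in names(view$aux)) {
      found <- switch(role, create = find_create(env, view$aux[[role]]),
                      copy = find_copy(env, view$aux[[role]]))
      if (is.null(found)) return(reason(sprintf(
        "adapter %s: no engine.%s op for type %s", adapter$names[[1]], role,
        view$aux[[role]])))
      aux_resolved[[role]] <- found
    }
  }
  if (is.null(req$input_types)) {
    # wildcard request: name and shape were already checked
    return(make_candidate(op, view, adapter = adapter,
                          aux_resolved = aux_resolved))
  }
  n <- length(req$input_types)
  if (nrow(view$slots) != n) return(reason("arity mismatch"))
  if (req$shape == "computer" && !identical(view$container_pos, req$container_pos))
    return(reason("container position mismatch"))
  if (req$shape == "inplace" && !identical(view$mutable_pos, req$mutable_pos))
    return(reason("mutable position mismatch"))
  conversions <- list()
  for (i in seq_len(n)) {
    t_req <- req$input_types[[i]]
    t_par <- view$slots$type[[i]]
    if (assignable(env$types, t_req, t_par)) next
    if (!allow_convert) return(reason(sprintf(
      "argument %d: %s not assignable to %s", i, t_req, t_par)))
    fwd <- find_converter(env, t_req, t_par)
    if (is.null(fwd)) return(reason(sprintf(
      "argument %d: no converter %s -> %s", i, t_req, t_par)))
    cv <- list(forward = fwd, backward = NULL, copy = NULL)
    if (view$slots$io[[i]] %in% c("container", "mutable")) {
      # results computed in the converted container must be copied back into
      # the user's container: impl-type -> user-type converter + a copy op
      # for the user's type
      back <- find_converter(env, t_par, t_req, loose_from = TRUE)
      cpy <- find_copy(env, t_req)
      if (is.null(back)) return(reason(sprintf(
        "argument %d: no back-converter %s -> %s for container copy-back",
        i, t_par, t_req)))
      if (is.null(cpy)) return(reason(sprintf(
        "argument %d: no engine.copy op for container type %s", i, t_req)))
      cv$backward <- back
      cv$copy <- cpy
    }
    conversions[[as.character(i)]] <- cv
  }
  out_conv <- NULL
  if (!is.null(req$output_type) && req$shape == "function") {
    if (!assignable(env$types, view$out_type, req$output_type)) {
      if (!allow_convert) return(reason(sprintf(
        "output: %s not assignable to %s", view$out_type, req$output_type)))
      out_conv <- find_converter(env, view$out_type, req$output_type)
      if (is.null(out_conv)) return(reason(sprintf(
        "output: no converter %s -> %s", view$out_type, req$output_type)))
    }
  }
  make_candidate(op, view, adapter = adapter, conversions = conversions,
                 out_conv = out_conv, aux_resolved = aux_resolved)
}

# Element-wise lifting: a scalar function op fitted to an image-typed
# function request through a lift adapter.
fit_lift <- function(env, req, op, adapter) {
  reason <- function(msg) structure(msg, class = "near_miss")
  if (req$shape != "function" || op$shape != "function") return(reason("lift: shapes"))
  if (is.null(req$input_types)) return(reason("lift: wildcard request"))
  ios <- op_param_ios(op)
  idx <- which(ios == "input")
  if (!(length(idx) %in% c(1L, 2L))) return(reason("lift: scalar arity must be 1 or 2"))
  if (length(req$input_types) != length(idx)) return(reason("lift: arity mismatch"))
  elems <- character(length(idx))
  for (i in seq_along(idx)) {
    t_req <- req$input_types[[i]]
    el <- env$types$element_type[[t_req]]
    if (is.null(el)) return(reason(sprintf(
      "lift: argument %d type %s has no element type", i, t_req)))
    t_par <- op$parameters[[idx[[i]]]]$type
    if (!assignable(env$types, el, t_par)) return(reason(sprintf(
      "lift: element type %s not assignable to %s", el, t_par)))
    elems[[i]] <- el
  }
  out_img <- req$input_types[[1]]
  if (!is.null(req$output_type) &&
      !assignable(env$types, out_img, req$output_type))
    return(reason("lift: output image type mismatch"))
  creator <- find_create(env, out_img)
  if (is.null(creator)) return(reason(sprintf(
    "lift: no engine.create op for image type %s", out_img)))
  view <- list(slots = data.frame(type = req$input_types,
                                  io = rep("input", length(idx)),
                                  stringsAsFactors = FALSE),
               out_type = out_img, container_pos = NULL, mutable_pos = NULL,
               map = idx)
  make_candidate(op, view, adapter = adapter, lift = list(arity = length(idx)),
                 aux_resolved = list(create = creator))
}

# All candidates for one routine (adapt/convert switches); also returns the
# near misses for error reporting.
routine_candidates <- function(env, req, allow_adapt, allow_convert) {
  cands <- list()
  near <- character()
  adapters <- if (allow_adapt) adapter_ops(env) else list()
  for (op in env$ops) {
    if (!(req$name %in% op$names)) next
    if (!is.null(op$adapter)) next          # adapters never match by themselves
    if (!allow_adapt) {
      if (op$shape != req$shape) { near <- c(near, sprintf(
        "%s [%s]: shape %s != requested %s", op$names[[1]], op$source,
        op$shape, req$shape)); next }
      res <- fit_view(env, req, op, direct_view(op), NULL, allow_convert)
      if (inherits(res, "near_miss")) near <- c(near, sprintf(
        "%s [%s]: %s", op$names[[1]], op$source, res))
      else cands[[length(cands) + 1L]] <- res
    } else {
      for (ad in adapters) {
        if (!identical(ad$adapter$to, req$shape)) next
        if (identical(ad$adapter$kind, "lift")) {
          res <- fit_lift(env, req, op, ad)
        } else {
          v <- adapted_view(op, ad)
          if (is.null(v)) next
          res <- fit_view(env, req, op, v, ad, allow_convert)
        }
        if (inherits(res, "near_miss")) near <- c(near, sprintf(
          "%s via %s: %s", op$names[[1]], ad$names[[1]], res))
        else cands[[length(cands) + 1L]] <- res
      }
    }
  }
  # routines are disjoint: conversion routines require >=1 conversion,
  # adaptation routines carry an adapter by construction
  if (allow_convert) cands <- Filter(function(cd)
    length(cd$conversions) > 0L || !is.null(cd$out_conv), cands)
  list(candidates = cands, near = sort(near))   # report order is canonical
}

# --- InfoTree --------------------------------------------------------------

new_info_tree <- function(request, cand, adapter_aux = list(),
                          conversions = list(), out_conv = NULL,
                          dependencies = list()) {
  structure(list(root = cand$op, request = request, view = cand$view,
                 adapter = cand$adapter, lift = cand$lift,
                 adapter_aux = adapter_aux, conversions = conversions,
                 output_conversion = out_conv, dependencies = dependencies),
            class = "info_tree")
}

#' Canonical text form of an InfoTree
#'
#' A deterministic serialization of the full resolution record: root op,
#' adaptation, per-parameter conversions (with copy-back ops) and recursively
#' the dependency subtrees.  Equal requests against an unchanged environment
#' yield equal canonical forms.
#'
#' @param tree an `info_tree` from [op_match()].
#' @return character scalar.
#' @export
info_tree_format <- function(tree) {
  leaf <- function(t) if (is.null(t)) "-" else info_tree_format(t)
  convs <- tree$conversions
  conv_txt <- if (!length(convs)) "-" else paste(vapply(
    sort(names(convs)), function(p) {
      cv <- convs[[p]]
      sprintf("%s:%s%s%s", p, leaf(cv$forward),
              if (is.null(cv$backward)) "" else paste0("/", leaf(cv$backward)),
              if (is.null(cv$copy)) "" else paste0("/", leaf(cv$copy)))
    }, character(1)), collapse = ",")
  aux <- tree$adapter_aux
  aux_txt <- if (!length(aux)) "-" else paste(vapply(
    sort(names(aux)), function(r) sprintf("%s:%s", r, leaf(aux[[r]])),
    character(1)), collapse = ",")
  deps <- tree$dependencies
  dep_txt <- if (!length(deps)) "-" else paste(vapply(
    sort(names(deps)), function(s) sprintf("%s:%s", s, info_tree_format(deps[[s]])),
    character(1)), collapse = ",")
  sprintf("{op=%s#%s#%d;adapt=%s;aux=%s;conv=%s;outconv=%s;deps=%s}",
          tree$root$source, tree$root$shape, length(tree$root$parameters),
          if (is.null(tree$adapter)) "-" else tree$adapter$source,
          aux_txt, conv_txt, leaf(tree$output_conversion), dep_txt)
}

#' Stable digest of an InfoTree
#'
#' A short hash of [info_tree_format()]; stored by the execution history so
#' provenance stays bounded in memory while remaining reconstructable by
#' replaying the match.
#'
#' @param tree an `info_tree`.
#' @return 8-hex-digit string.
#' @export
info_tree_digest <- function(tree) fnv1a32(info_tree_format(tree))

#' @export
print.info_tree <- function(x, ...) {
  cat("InfoTree", info_tree_digest(x), "\n ", info_tree_format(x), "\n")
  invisible(x)
}

# Count nodes in an InfoTree whose root op carries a given name.
info_tree_count <- function(tree, name) {
  n <- as.integer(name %in% tree$root$names)
  for (d in tree$dependencies) n <- n + info_tree_count(d, name)
  n
}

# --- matching --------------------------------------------------------------

.MAX_DEPTH <- 100L

# A chosen helper op (converter/copy/create) becomes a leaf tree; its own
# declared dependencies are resolved recursively.
make_helper_tree <- function(env, op, stack, depth) {
  cand <- make_candidate(op, direct_view(op))
  build_tree(env, op_request(op$names[[1]], op$shape), cand, stack, depth)
}

build_tree <- function(env, req, cand, stack, depth) {
  root <- cand$op
  key <- paste0(root$source, "|", req$shape)
  if (key %in% stack)
    stop("cycle error: dependency resolution revisits ", key,
         " along chain: ", paste(c(stack, key), collapse = " -> "))
  stack2 <- c(stack, key)
  deps <- list()
  for (d in root$dependencies) {
    dreq <- op_request(d$name, d$shape, input_types = d$input_types,
                       output_type = d$output_type)
    deps[[d$slot]] <- match_internal(env, dreq, stack2, depth + 1L)
  }
  aux <- lapply(cand$aux_resolved, function(op)
    make_helper_tree(env, op, stack2, depth + 1L))
  convs <- lapply(cand$conversions, function(cv) {
    list(forward = make_helper_tree(env, cv$forward, stack2, depth + 1L),
         backward = if (!is.null(cv$backward))
           make_helper_tree(env, cv$backward, stack2, depth + 1L),
         copy = if (!is.null(cv$copy))
           make_helper_tree(env, cv$copy, stack2, depth + 1L))
  })
  outc <- if (!is.null(cand$out_conv))
    make_helper_tree(env, cand$out_conv, stack2, depth + 1L)
  new_info_tree(req, cand, adapter_aux = aux, conversions = convs,
                out_conv = outc, dependencies = deps)
}

match_internal <- function(env, req, stack, depth) {
  if (depth > .MAX_DEPTH)
    stop("resolution error: dependency depth limit (", .MAX_DEPTH, ") exceeded")
  routines <- list(direct = c(FALSE, FALSE), adaptation = c(TRUE, FALSE),
                   conversion = c(FALSE, TRUE),
                   `adaptation+conversion` = c(TRUE, TRUE))
  near_all <- character()
  for (rn in names(routines)) {
    flags <- routines[[rn]]
    rc <- routine_candidates(env, req, flags[[1]], flags[[2]])
    near_all <- c(near_all, paste0("[", rn, "] ", rc$near))
    ranked <- rank_candidates(rc$candidates)
    errs <- character()
    for (cand in ranked) {
      tree <- tryCatch(build_tree(env, req, cand, stack, depth),
                       error = function(e) e)
      if (inherits(tree, "info_tree")) {
        ops_log(env, "debug", sprintf("matched %s via routine %s (op %s)",
                                      request_key(req), rn, cand$op$source))
        return(tree)
      }
      errs <- c(errs, sprintf("%s: %s", cand$op$source, conditionMessage(tree)))
    }
    near_all <- c(near_all, if (length(errs)) paste0("[", rn, "] ", sort(errs)))
  }
  cyc <- grep("cycle error", near_all, value = TRUE)
  if (length(cyc)) stop(sub("^\\[[^]]*\\] [^:]*: ", "", cyc[[1]]))
  stop("match failure for request ", request_key(req),
       if (length(near_all)) paste0("\nnear misses:\n  ",
                                    paste(near_all, collapse = "\n  ")))
}

#' Match a request against an op environment
#'
#' Attempts the four matching routines in fixed order -- direct, adaptation,
#' conversion, adaptation+conversion -- and returns the [info_tree] of the
#' winning candidate, with op dependencies resolved recursively.  The first
#' routine producing at least one fully resolvable candidate wins; within a
#' routine candidates are ordered by [rank_candidates()].  Matching is
#' deterministic: for a fixed environment it is a pure function of the
#' request, independent of registration order.
#'
#' @param env an [op_environment()].
#' @param request an [op_request()].
#' @return an `info_tree`.
#' @export
op_match <- function(env, request) {
  match_internal(env, request, character(), 0L)
}

#' Match with caching
#'
#' Equal to [op_match()] for every request; a second identical request
#' against an unmutated environment is served from the cache.  Any
#' registration or unregistration invalidates all entries.
#'
#' @inheritParams op_match
#' @return an `info_tree`.
#' @export
op_match_cached <- function(env, request) {
  if (!env$cache_enabled) return(op_match(env, request))
  key <- request_key(request)
  if (exists(key, envir = env$cache, inherits = FALSE))
    return(get(key, envir = env$cache))
  tree <- op_match(env, request)
  assign(key, tree, envir = env$cache)
  tree
}
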