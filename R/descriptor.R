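.descriptor_known_op_keys <- c("names", "type", "priority", "source",
                               "description", "parameters", "dependencies",
                               "adapter")
.descriptor_known_param_keys <- c("name", "type", "io", "optional", "default",
                                  "description")

#' Parse a YAML op descriptor
#'
#' Reads a descriptor document (schema below) into a list of [op_info()]s.
#' Missing `priority` defaults to 0, missing `optional` to `FALSE`; unknown
#' keys are ignored with a warning.
#'
#' ```yaml
#' version: "1"
#' ops:
#'   - names: [filter.gauss]
#'     type: computer            # function | computer | inplace
#'     priority: 0.0
#'     source: "pkg.module:callable"
#'     description: "..."
#'     parameters:
#'       - {name: input,  type: image, io: input,  optional: false}
#'       - {name: sigma,  type: real,  io: input,  optional: false}
#'       - {name: output, type: image, io: container}
#'     dependencies: []      # [{slot: gauss, name: filter.gauss, type: computer}]
#' ```
#'
#' Dependency entries may additionally carry `in:` (list of type names) and
#' `out:` to constrain the dependency request; adapter ops carry an
#' `adapter: {from, to, kind}` mapping.
#'
#' @param yaml_text descriptor document as a single string.
#' @return list of `op_info`.
#' @export
parse_descriptor <- function(yaml_text) {
  doc <- tryCatch(yaml::yaml.load(yaml_text),
                  error = function(e) stop("YAML parse error: ", conditionMessage(e)))
  if (is.null(doc)) return(list())
  entries <- doc$ops %||% list()
  lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    label <- if (!is.null(e$names)) paste(unlist(e$names), collapse = ",")
             else sprintf("entry %d", i)
    for (k in c("names", "type", "source", "parameters")) {
      if (is.null(e[[k]]))
        stop("descriptor schema error: missing mandatory key '", k, "' in ", label)
    }
    unknown <- setdiff(names(e), .descriptor_known_op_keys)
    if (length(unknown))
      warning("descriptor: ignoring unknown keys in ", label, ": ",
              paste(unknown, collapse = ", "))
    params <- lapply(e$parameters, function(p) {
      for (k in c("name", "type")) if (is.null(p[[k]]))
        stop("descriptor schema error: parameter missing '", k, "' in ", label)
      pun <- setdiff(names(p), .descriptor_known_param_keys)
      if (length(pun))
        warning("descriptor: ignoring unknown parameter keys in ", label, ": ",
                paste(pun, collapse = ", "))
      param_spec(p$name, p$type, io = p$io %||% "input",
                 optional = p$optional %||% FALSE,
                 default = p$default, description = p$description %||% "")
    })
    deps <- lapply(e$dependencies %||% list(), function(d)
      dep_spec(d$slot, d$name, d$type,
               input_types = if (!is.null(d[["in"]])) as.character(unlist(d[["in"]])),
               output_type = d[["out"]]))
    op_info(names = as.character(unlist(e$names)), shape = e$type,
            parameters = params, priority = e$priority %||% 0,
            source = e$source, description = e$description %||% "",
            dependencies = deps, adapter = e$adapter)
  })
}

#' Emit a YAML op descriptor
#'
#' Inverse of [parse_descriptor()]: serializes validated [op_info()]s with a
#' deterministic key ordering so that `parse_descriptor(emit_descriptor(x))`
#' reproduces `x` field-by-field.  Reduced signatures are a registration
#' artifact and are rejected here.
#'
#' @param infos list of `op_info`.
#' @return YAML text.
#' @export
emit_descriptor <- function(infos) {
  ops <- lapply(infos, function(info) {
    validate_op_info(info)
    if (!is.null(info$reduced_from))
      stop("validation error: reduced signatures are derived, not emitted (",
           info$names[[1]], ")")
    params <- lapply(info$parameters, function(p) {
      out <- list(name = p$name, type = p$type, io = p$io, optional = p$optional)
      if (!is.null(p$default)) out$default <- p$default
      if (nzchar(p$description)) out$description <- p$description
      out
    })
    deps <- lapply(info$dependencies, function(d) {
      out <- list(slot = d$slot, name = d$name, type = d$shape)
      if (!is.null(d$input_types)) out[["in"]] <- as.list(d$input_types)
      if (!is.null(d$output_type)) out[["out"]] <- d$output_type
      out
    })
    entry <- list(names = as.list(info$names), type = info$shape,
                  priority = info$priority, source = info$source,
                  description = info$description, parameters = params,
                  dependencies = deps)
    if (!is.null(info$adapter)) entry$adapter <- info$adapter
    entry
  })
  yaml::as.yaml(list(version = "1", ops = ops))
}
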