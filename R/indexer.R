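#' Index doc-comment op annotations into a YAML descriptor
#'
#' Scans R source text for roxygen-style doc comments carrying an
#' `@implNote` op tag and emits a YAML descriptor registering each annotated
#' callable as an op, with zero changes to the code itself.  The grammar is:
#'
#' ```
#' #' Adds two numbers.
#' #' @param a (real) first addend
#' #' @param b (real) second addend
#' #' @return (real) the sum
#' #' @implNote op names="math.add" type=function priority=1.0
#' add2 <- function(a, b) a + b
#' ```
#'
#' `@param name (type) text` declares an input, `@container name (type)` a
#' pre-allocated output container, `@mutable name (type)` the mutable
#' argument of an inplace op, and `@return (type) text` the output of a
#' function op.  Optional inputs are written `@param name (type, optional=v)`
#' where `v` is the default.  Callables without the tag are ignored.
#' Duplicate names across a scan are kept (priority breaks ties at match
#' time) with a warning.
#'
#' @param source_texts character vector (or list) of source file contents;
#'   names, when present, become the module part of each `module:callable`
#'   source locator.
#' @return YAML descriptor text (parseable by [parse_descriptor()]).
#' @export
index_annotations <- function(source_texts) {
  if (is.character(source_texts)) source_texts <- as.list(source_texts)
  mods <- names(source_texts) %||% rep("", length(source_texts))
  infos <- list()
  for (si in seq_along(source_texts)) {
    module <- if (nzchar(mods[[si]])) mods[[si]] else sprintf("src%d", si)
    lines <- strsplit(source_texts[[si]], "\n", fixed = TRUE)[[1]]
    is_doc <- grepl("^\\s*#'", lines)
    i <- 1L
    while (i <= length(lines)) {
      if (!is_doc[[i]]) { i <- i + 1L; next }
      j <- i
      while (j <= length(lines) && is_doc[[j]]) j <- j + 1L
      block <- sub("^\\s*#'\\s?", "", lines[i:(j - 1L)])
      # the annotated callable is the next assignment to a function
      callable <- NA_character_
      k <- j
      while (k <= length(lines)) {
        m <- regmatches(lines[[k]],
                        regexec("^\\s*([A-Za-z._][A-Za-z0-9._]*)\\s*(<-|=)\\s*function",
                                lines[[k]]))[[1]]
        if (length(m)) { callable <- m[[2]]; break }
        if (nzchar(trimws(lines[[k]])) && !grepl("^\\s*#", lines[[k]])) break
        k <- k + 1L
      }
      tag <- grep("^@implNote\\s+op\\b", block, value = TRUE)
      if (length(tag) && !is.na(callable)) {
        infos[[length(infos) + 1L]] <-
          .index_one(block, tag[[1]], module, callable)
      }
      i <- j
    }
  }
  nms <- unlist(lapply(infos, function(x) x$names))
  if (anyDuplicated(nms))
    warning("indexer: duplicate op names in scan (kept; priority breaks ties): ",
            paste(unique(nms[duplicated(nms)]), collapse = ", "))
  emit_descriptor(infos)
}

.index_one <- function(block, tag, module, callable) {
  err <- function(...) stop("indexing error for callable '", callable, "': ", ...)
  get_attr <- function(re) {
    m <- regmatches(tag, regexec(re, tag))[[1]]
    if (length(m)) m[[2]] else NULL
  }
  names_raw <- get_attr('names="([^"]*)"')
  type <- get_attr("type=([a-z]+)")
  prio <- get_attr("priority=([-0-9.eE+]+)")
  if (is.null(names_raw) || !nzchar(names_raw)) err("missing names=\"...\" in @implNote")
  if (is.null(type) || !(type %in% .shapes)) err("missing or invalid type= in @implNote")
  names <- trimws(strsplit(names_raw, ",", fixed = TRUE)[[1]])

  desc_lines <- block[!grepl("^@", block)]
  description <- trimws(paste(desc_lines[nzchar(trimws(desc_lines))], collapse = " "))

  params <- list()
  out_spec <- NULL
  for (ln in block) {
    m <- regmatches(ln, regexec(
      "^@(param|container|mutable)\\s+(\\S+)\\s+\\(([^)]*)\\)\\s*(.*)$", ln))[[1]]
    if (length(m)) {
      role <- switch(m[[2]], param = "input", container = "container",
                     mutable = "mutable")
      spec <- .parse_type_field(m[[4]])
      if (is.null(spec)) err("unparseable type annotation on @", m[[2]], " ", m[[3]])
      params[[length(params) + 1L]] <-
        param_spec(m[[3]], spec$type, io = role, optional = spec$optional,
                   default = spec$default, description = trimws(m[[5]]))
      next
    }
    mr <- regmatches(ln, regexec("^@return\\s+\\(([^)]*)\\)\\s*(.*)$", ln))[[1]]
    if (length(mr)) {
      spec <- .parse_type_field(mr[[2]])
      if (is.null(spec)) err("unparseable type annotation on @return")
      out_spec <- param_spec("output", spec$type, io = "output",
                             description = trimws(mr[[3]]))
    }
  }
  if (type == "function") {
    if (is.null(out_spec)) err("function op requires an @return (type) line")
    params[[length(params) + 1L]] <- out_spec
  }
  info <- tryCatch(
    op_info(names = names, shape = type, parameters = params,
            priority = as.numeric(prio %||% 0),
            source = paste0(module, ":", callable), description = description),
    error = function(e) err(conditionMessage(e)))
  info
}

# "(real)" or "(real, optional=0.5)" -> list(type, optional, default)
.parse_type_field <- function(txt) {
  parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  if (!length(parts) || !nzchar(parts[[1]])) return(NULL)
  out <- list(type = parts[[1]], optional = FALSE, default = NULL)
  for (p in parts[-1]) {
    m <- regmatches(p, regexec("^optional=(.*)$", p))[[1]]
    if (!length(m)) return(NULL)
    out$optional <- TRUE
    v <- m[[2]]
    out$default <- if (grepl("^(true|false)$", v, ignore.case = TRUE))
      tolower(v) == "true"
    else if (grepl("^[-0-9.eE+]+$", v)) as.numeric(v)
    else v
  }
  out
}
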