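#' Create an empty type registry
#'
#' A type registry holds the semantic type names the matching engine reasons
#' about, the subtype edges between them, a human-readable description per
#' type (used by help text), and optionally a recognizer predicate that maps
#' runtime values to type names, plus an element type for container-like
#' types (used by element-wise lifting).
#'
#' The subtype relation must stay a DAG; assignability is its reflexive
#' transitive closure.
#'
#' @return an object of class `type_registry`.
#' @export
type_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$types <- character()
  reg$parents <- list()
  reg$descriptions <- list()
  reg$recognizers <- list()
  reg$element_type <- list()
  class(reg) <- "type_registry"
  reg
}

#' Register a semantic type
#'
#' @param registry a [type_registry()].
#' @param name type identifier.
#' @param parent optional character vector of supertypes (must already be
#'   registered); adds subtype edges `name -> parent`.
#' @param description simple human-readable name (e.g. `"image"`).
#' @param recognizer optional predicate `function(x)` returning `TRUE` when a
#'   runtime value belongs to this type.
#' @param element_type optional identifier of the element type, for
#'   container-like types that element-wise lifting can traverse.
#' @return the registry, invisibly.
#' @export
register_type <- function(registry, name, parent = NULL, description = NULL,
                          recognizer = NULL, element_type = NULL) {
  stopifnot(inherits(registry, "type_registry"), is.character(name), length(name) == 1L)
  for (p in parent) {
    if (!(p %in% registry$types)) stop("unregistered parent type: ", p)
  }
  if (!(name %in% registry$types)) registry$types <- c(registry$types, name)
  registry$parents[[name]] <- unique(c(registry$parents[[name]], parent))
  if (!is.null(description)) registry$descriptions[[name]] <- description
  if (!is.null(recognizer)) registry$recognizers[[name]] <- recognizer
  if (!is.null(element_type)) registry$element_type[[name]] <- element_type
  # reject cycles eagerly: walking up from name must terminate without
  # revisiting name
  seen <- character()
  frontier <- registry$parents[[name]] %||% character()
  while (length(frontier)) {
    if (name %in% frontier) stop("subtype edge would create a cycle at type: ", name)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(lapply(frontier, function(t) registry$parents[[t]])))
    frontier <- setdiff(frontier, seen)
  }
  invisible(registry)
}

check_type_registered <- function(registry, name) {
  if (!(name %in% registry$types)) stop("unregistered type: ", name)
  invisible(TRUE)
}

#' Is one type assignable to another?
#'
#' `TRUE` iff `from_type == to_type` or the two are connected by subtype
#' edges, transitively (a child is assignable to any of its ancestors).
#'
#' @param registry a [type_registry()].
#' @param from_type,to_type registered type identifiers.
#' @return logical scalar.
#' @export
assignable <- function(registry, from_type, to_type) {
  check_type_registered(registry, from_type)
  check_type_registered(registry, to_type)
  if (from_type == to_type) return(TRUE)
  seen <- character()
  frontier <- registry$parents[[from_type]] %||% character()
  while (length(frontier)) {
    if (to_type %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(lapply(frontier, function(t) registry$parents[[t]])))
    frontier <- setdiff(frontier, seen)
  }
  FALSE
}

# Longest chain of subtype edges above a type; deeper = more specific.
type_depth <- function(registry, name) {
  ps <- registry$parents[[name]] %||% character()
  if (!length(ps)) return(0L)
  1L + max(vapply(ps, function(p) type_depth(registry, p), integer(1)))
}

#' Resolve the semantic type name of a runtime value
#'
#' Applies every registered recognizer; among the types that recognize the
#' value, the most specific (deepest in the subtype DAG) wins.  Two distinct
#' recognizing types at equal maximal depth are an error rather than a
#' guess.
#'
#' @param registry a [type_registry()].
#' @param value any R value.
#' @return a type identifier.
#' @export
resolve_type_name <- function(registry, value) {
  hits <- character()
  for (nm in names(registry$recognizers)) {
    ok <- tryCatch(isTRUE(registry$recognizers[[nm]](value)), error = function(e) FALSE)
    if (ok) hits <- c(hits, nm)
  }
  if (!length(hits)) stop("no registered type recognizes value of class: ",
                          paste(class(value), collapse = "/"))
  depths <- vapply(hits, function(h) type_depth(registry, h), integer(1))
  best <- hits[depths == max(depths)]
  if (length(best) > 1L)
    stop("ambiguous runtime type: ", paste(sort(best), collapse = ", "))
  best
}

#' Human-readable description of a type name
#'
#' Falls back to the raw identifier when the registry holds no description.
#' @param registry a [type_registry()].
#' @param name type identifier (need not be registered).
#' @return character scalar.
#' @export
type_description <- function(registry, name) {
  registry$descriptions[[name]] %||% name
}
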