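# In-memory typed document tree. Nodes are environments so that generated
# code and the interpreter share reference (mutation) semantics: assignment
# helpers mutate the target tree in place, as the generated programs expect.

#' Create an empty typed instance node
#'
#' @param models model set
#' @param type_name declared type of the node
#' @return an instance node (environment with reference semantics)
#' @export
new_instance_node <- function(models, type_name) {
  ti <- type_info(models, type_name)
  node <- new.env(parent = emptyenv())
  node$type <- type_name
  node$values <- list()  # element name -> list of (node | raw primitive)
  node$resource_kind <- if (ti$is_resource) type_name else NULL
  class(node) <- "fml_node"
  node
}

is_fml_node <- function(x) inherits(x, "fml_node")

node_set_raw <- function(node, element, values) {
  node$values[[element]] <- values
  invisible(node)
}

#' Raw stored values of an element on a node
#'
#' No unwrapping: returns stored child nodes / lexical primitives as-is
#' (see [dynamic_get()] for typed navigation).
#'
#' @param node instance node
#' @param element element name
#' @return list of stored values
#' @export
node_get <- function(node, element) {
  v <- node$values[[element]]
  if (is.null(v)) list() else v
}

node_append <- function(node, element, value) {
  node$values[[element]] <- c(node_get(node, element), list(value))
  invisible(node)
}

#' Deep-copy an instance node
#'
#' @param node instance node
#' @return an independent copy (nodes are mutable environments)
#' @export
node_deep_copy <- function(node) {
  if (!is_fml_node(node)) return(node)
  out <- new.env(parent = emptyenv())
  out$type <- node$type
  out$resource_kind <- node$resource_kind
  out$values <- lapply(node$values, function(items) lapply(items, node_deep_copy))
  class(out) <- "fml_node"
  out
}

#' Structural equality of instance nodes
#'
#' @param a,b instance nodes or primitive values
#' @return logical
#' @export
node_equal <- function(a, b) {
  if (is_fml_node(a) != is_fml_node(b)) return(FALSE)
  if (!is_fml_node(a)) return(identical(primitive_lexical(a), primitive_lexical(b)))
  if (!identical(a$type, b$type)) return(FALSE)
  an <- names(a$values)[vapply(a$values, length, integer(1)) > 0]
  bn <- names(b$values)[vapply(b$values, length, integer(1)) > 0]
  if (!identical(sort(an), sort(bn))) return(FALSE)
  for (nm in an) {
    av <- a$values[[nm]]; bv <- b$values[[nm]]
    if (length(av) != length(bv)) return(FALSE)
    for (i in seq_along(av)) if (!node_equal(av[[i]], bv[[i]])) return(FALSE)
  }
  TRUE
}

# Primitive values live in the tree as their lexical (string) form; typed
# views are produced on demand from the schema's primitive kind.
primitive_lexical <- function(x) {
  if (is.character(x)) {
    return(if (is.null(attributes(x))) x else as.vector(x))
  }
  if (is.logical(x)) return(if (x) "true" else "false")
  if (inherits(x, "fml_decimal")) return(attr(x, "lexical"))
  if (is.numeric(x)) return(canonical_decimal(x))
  fml_error("fmlc_value_error", paste0("not a primitive: ", class(x)[1]))
}

# Typed view of a lexical primitive according to a primitive kind
typed_primitive <- function(lexical, kind) {
  switch(kind,
    boolean = identical(lexical, "true"),
    integer = as.integer(lexical),
    decimal = fml_decimal(lexical),
    date = structure(lexical, class = c("fml_date", "character")),
    datetime = structure(lexical, class = c("fml_datetime", "character")),
    lexical
  )
}

#' Exact-lexical decimal value
#'
#' Carries the canonical lexical rendering alongside the numeric value so
#' serialization is byte-stable.
#'
#' @param lexical decimal text or number
#' @return classed decimal value
#' @export
fml_decimal <- function(lexical) {
  lex <- if (is.character(lexical) && grepl(CANONICAL_DECIMAL_RE, lexical)) {
    lexical
  } else {
    canonical_decimal(lexical)
  }
  structure(as.numeric(lexical), lexical = lex, class = "fml_decimal")
}
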