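# Semantics-preserving rewrites applied before emission. Fixed catalogue:
#   - constant folding of literal arithmetic / boolean / comparison operators
#   - X.exists().not()  ->  X.empty()
#   - X.where(true)     ->  X
#   - X.first()         ->  X  when the model proves X is a singleton path
# The pass is idempotent: simplify(simplify(x)) == simplify(x).

fp_is_literal <- function(ast) identical(ast$kind, "lit")

FOLDABLE_OPS <- c("+", "-", "*", "/", "div", "mod",
                  "and", "or", "xor", "implies",
                  "=", "!=", "<", "<=", ">", ">=", "&")

#' Simplify a FHIRPath AST
#'
#' @param ast FHIRPath AST
#' @param static_type optional focus type name; with `models`, enables the
#'   model-aware `first()`-on-singleton rule (skipped when unknown)
#' @param models optional model set
#' @return simplified AST
#' @export
fhirpath_simplify <- function(ast, static_type = NULL, models = NULL) {
  simp <- function(node) {
    # children first
    node <- switch(node$kind,
      nav = { node$base <- simp(node$base); node },
      index = { node$base <- simp(node$base); node$index <- simp(node$index); node },
      unary = { node$operand <- simp(node$operand); node },
      binop = { node$left <- simp(node$left); node$right <- simp(node$right); node },
      typeop = { node$operand <- simp(node$operand); node },
      call = {
        if (!is.null(node$base)) node$base <- simp(node$base)
        node$args <- lapply(node$args, simp)
        node
      },
      node
    )
    # constant folding of literal operands
    if (node$kind == "binop" && node$op %in% FOLDABLE_OPS &&
        fp_is_literal(node$left) && fp_is_literal(node$right)) {
      folded <- try_fold_binop(node)
      if (!is.null(folded)) return(folded)
    }
    if (node$kind == "unary" && node$op == "-" && fp_is_literal(node$operand) &&
        node$operand$type %in% c("integer", "decimal")) {
      lit <- node$operand
      if (lit$type == "integer") lit$value <- -lit$value
      else lit$value <- canonical_decimal(-as.numeric(lit$value))
      return(lit)
    }
    # X.exists().not() -> X.empty()
    if (node$kind == "call" && node$name == "not" && !is.null(node$base) &&
        node$base$kind == "call" && node$base$name == "exists" &&
        length(node$base$args) == 0) {
      return(list(kind = "call", name = "empty", base = node$base$base,
                  args = list()))
    }
    # X.where(true) -> X
    if (node$kind == "call" && node$name == "where" &&
        fp_is_literal(node$args[[1]]) &&
        identical(node$args[[1]]$type, "boolean") &&
        isTRUE(node$args[[1]]$value)) {
      return(if (is.null(node$base)) list(kind = "this") else node$base)
    }
    # X.first() -> X on a statically-known singleton path
    if (node$kind == "call" && node$name == "first" && !is.null(node$base) &&
        !is.null(static_type) && !is.null(models) &&
        fp_path_is_singleton(node$base, static_type, models)) {
      return(node$base)
    }
    node
  }
  simp(ast)
}

# Fold a binop with two literal operands by evaluating it with the shared
# runtime; refuse when the result is not a single literal (e.g. div by zero).
try_fold_binop <- function(node) {
  dummy_ctx <- list(models = NULL, shared_now = NA_character_)
  res <- tryCatch(eval_fp_binop(node, list(), list(), dummy_ctx),
                  error = function(e) NULL)
  if (is.null(res) || length(res) != 1) return(NULL)
  v <- res[[1]]
  switch(fp_item_class(v),
    integer = list(kind = "lit", type = "integer", value = v),
    decimal = list(kind = "lit", type = "decimal",
                   value = canonical_decimal(attr(v, "lexical") %||% v)),
    boolean = list(kind = "lit", type = "boolean", value = v),
    string = list(kind = "lit", type = "string", value = as.character(v)),
    NULL
  )
}

# TRUE when `ast` is a pure navigation chain from the focus whose final
# element has maxOccurs = 1 all the way down.
fp_path_is_singleton <- function(ast, static_type, models) {
  segs <- character(0)
  node <- ast
  while (node$kind == "nav") {
    segs <- c(node$name, segs)
    node <- node$base
  }
  if (node$kind == "path") segs <- c(node$name, segs)
  else if (node$kind != "this") return(FALSE)
  if (!length(segs)) return(FALSE)
  ty <- static_type
  for (s in segs) {
    e <- tryCatch(find_element(models, ty, s), error = function(e) NULL)
    if (is.null(e)) return(FALSE)
    if (is.infinite(e$max_occurs) || e$max_occurs > 1) return(FALSE)
    ty <- e$type_ref
    if (startsWith(ty, "xs:")) ty <- NULL
    if (is.null(ty)) {
      # ran out of model info before the end of the chain
      if (!identical(s, segs[length(segs)])) return(FALSE)
    }
  }
  TRUE
}
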