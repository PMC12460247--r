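# Execution runtime shipped with generated programs: cardinality-aware
# assignment, ConceptMap translation, execution-scoped timestamp, seeded UUID
# source and dynamic type dispatch. The reference interpreter uses these same
# helpers, so the two engines differ only in dispatch, never in semantics.

#' Create an execution context
#'
#' Captures a single timestamp for the whole mapping execution (every
#' `now()` reference sees the same instant) and initializes the UUID source.
#' With a `seed`, the UUID sequence is reproducible; by default it is drawn
#' from R's RNG.
#'
#' @param models model set for both source and target families
#' @param conceptmaps list of concept map definitions to register
#' @param seed optional integer seed for the UUID source
#' @param now optional fixed ISO-8601 timestamp (tests inject one so diffs
#'   between engines are clean)
#' @return execution context (environment)
#' @export
new_execution_context <- function(models, conceptmaps = list(), seed = NULL,
                                  now = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$models <- models
  ctx$shared_now <- if (is.null(now)) iso_now() else now
  ctx$uuid_state <- if (is.null(seed)) {
    as.integer(floor(runif(1) * 2147483646)) + 1L
  } else {
    s <- as.integer(seed) %% 2147483647L
    if (s <= 0L) s + 2147483646L else s
  }
  ctx$conceptmaps <- new.env(parent = emptyenv())
  for (cm in conceptmaps) register_conceptmap(ctx, cm)
  class(ctx) <- "fml_execution_context"
  ctx
}

#' Register a concept map definition on an execution context
#'
#' @param ctx execution context
#' @param cm concept map definition (from an FML `conceptmap` block or
#'   [read_conceptmap()])
#' @export
register_conceptmap <- function(ctx, cm) {
  assign(cm$url, cm, envir = ctx$conceptmaps)
  invisible(ctx)
}

#' Execution-scoped timestamp
#'
#' Constant within one execution context; ISO-8601 with timezone offset.
#'
#' @param ctx execution context
#' @return character timestamp
#' @export
shared_now <- function(ctx) ctx$shared_now

#' Draw a v4 UUID from the context's generator
#'
#' @param ctx execution context
#' @return RFC-4122 v4 formatted UUID string
#' @export
new_uuid <- function(ctx) uuid_v4(ctx)

#' Resolve an element on a node at run time
#'
#' Dynamic dispatch through the model set: unknown elements yield an empty
#' collection (FHIRPath navigation semantics); FHIR-style primitive nodes and
#' text-content types unwrap to typed primitive values.
#'
#' @param node instance node (non-nodes yield empty)
#' @param element element or attribute name
#' @param models model set
#' @return value collection (list)
#' @export
dynamic_get <- function(node, element, models) {
  if (!is_fml_node(node)) return(list())
  items <- node$values[[element]]
  if (is.null(items)) return(list())
  e <- find_element(models, node$type, element)
  kind <- element_primitive_kind(e, models)
  if (is.null(kind)) return(items)  # complex children, stored as nodes
  out <- vector("list", length(items))
  for (i in seq_along(items)) {
    v <- items[[i]]
    out[[i]] <- if (is_fml_node(v)) {
      unwrap_primitive_node(v, models)
    } else {
      typed_primitive(primitive_lexical(v), kind)
    }
  }
  out[!vapply(out, is.null, logical(1))]
}

# NULL for complex elements; the primitive kind for xs-typed and
# primitive-model elements (whose values are stored as raw lexicals)
element_primitive_kind <- function(e, models) {
  if (is.null(e)) return("string")
  te <- e$type_ref
  if (startsWith(te, "xs:")) return(XS_PRIMITIVE_KINDS[[te]] %||% "string")
  ti <- type_info(models, te)
  if (ti$is_primitive) ti$primitive_kind %||% "string" else NULL
}

unwrap_primitive_node <- function(v, models) {
  ti <- type_info(models, v$type)
  if (!ti$is_primitive) return(v)
  carrier <- if (identical(ti$value_carrier, "text")) ".text" else "value"
  pv <- v$values[[carrier]]
  if (!length(pv)) return(NULL)
  typed_primitive(primitive_lexical(pv[[1]]), ti$primitive_kind)
}

#' Cardinality-aware assignment into a target node
#'
#' `maxOccurs = 1` replaces, unbounded appends preserving order. Primitive
#' values are wrapped into primitive-model nodes when the element's declared
#' type is a FHIR-style primitive type; node values are stored by reference
#' (the returned value aliases the stored one, so `as <var>` bindings can be
#' populated afterwards).
#'
#' @param target instance node (mutated)
#' @param element element name on the target's type
#' @param value instance node or primitive value
#' @param ctx execution context
#' @return the stored value, invisibly
#' @export
fml_assign <- function(target, element, value, ctx) {
  models <- ctx$models
  if (!is_fml_node(target)) {
    fml_error("fmlc_runtime_error", "assignment target is not a node")
  }
  e <- find_element(models, target$type, element)
  if (is.null(e)) {
    fml_error("fmlc_runtime_error",
              paste0("unknown element '", element, "' on type '",
                     target$type, "'"))
  }
  if (is.null(value)) return(invisible(NULL))
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, paste0("assignment to ", element))
    if (is.null(value)) return(invisible(NULL))
  }
  stored <- coerce_for_element(value, e, models)
  if (is.finite(e$max_occurs) && e$max_occurs <= 1) {
    node_set_raw(target, element, list(stored))
  } else {
    node_append(target, element, stored)
  }
  invisible(stored)
}

# Primitive elements (xs-typed and primitive-model) store their raw lexical
# form; the XML/JSON writers re-project it (value attribute, text content or
# typed JSON scalar) from the schema.
coerce_for_element <- function(value, e, models) {
  te <- e$type_ref
  if (startsWith(te, "xs:") || type_info(models, te)$is_primitive) {
    if (is_fml_node(value)) {
      value <- primitive_node_lexical(value, models)
    }
    return(primitive_lexical(value))
  }
  if (!is_fml_node(value)) {
    fml_error("fmlc_runtime_error",
              paste0("cannot assign a primitive to complex element '",
                     e$name, "' of type ", te))
  }
  value
}

primitive_node_lexical <- function(node, models) {
  d <- type_info(models, node$type)
  if (!isTRUE(d$is_primitive)) {
    fml_error("fmlc_runtime_error",
              paste0("cannot take primitive value of complex type ", node$type))
  }
  carrier <- if (identical(d$value_carrier, "text")) ".text" else "value"
  pv <- node_get(node, carrier)
  if (!length(pv)) fml_error("fmlc_runtime_error",
                             paste0("empty primitive node of type ", node$type))
  primitive_lexical(pv[[1]])
}

#' Translate a code through a registered ConceptMap
#'
#' @param ctx execution context
#' @param code source code (primitive or collection)
#' @param source_system optional source system URI to disambiguate
#' @param map_url URL of the registered concept map
#' @param output `"code"` for the bare target code, `"Coding"` for a Coding
#'   node carrying the target system
#' @return target code string or Coding node
#' @export
translate_code <- function(ctx, code, source_system = NULL, map_url,
                           output = "code") {
  if (!exists(map_url, envir = ctx$conceptmaps, inherits = FALSE)) {
    fml_error("fmlc_runtime_error",
              paste0("concept map not registered: ", map_url))
  }
  cm <- get(map_url, envir = ctx$conceptmaps, inherits = FALSE)
  if (is.list(code) && !is_fml_node(code)) {
    code <- fp_singleton(code, "translate")
  }
  if (is_fml_node(code)) code <- primitive_node_lexical(code, ctx$models)
  code <- primitive_lexical(code)
  hits <- translate_hits(ctx, cm, code, source_system, map_url)
  if (!length(hits)) {
    fml_error("fmlc_translate_error",
              paste0("no mapping for code '", code, "' in ", map_url))
  }
  if (length(hits) > 1) {
    fml_error("fmlc_translate_error",
              paste0("ambiguous mapping for code '", code, "' in ", map_url))
  }
  hit <- hits[[1]]
  if (identical(output, "Coding")) {
    n <- fml_new_node("Coding")
    n$values <- list(system = list(hit$group$target_system),
                     code = list(hit$element$target_code))
    n
  } else {
    hit$element$target_code
  }
}

# per-context lookup table: map_url -> env(source_code -> hit list); built
# on first use of a map
translate_hits <- function(ctx, cm, code, source_system, map_url) {
  if (!is.null(source_system)) {
    hits <- list()
    for (g in cm$groups) {
      if (!identical(g$source_system, source_system)) next
      for (el in g$elements) {
        if (identical(el$source_code, code)) {
          hits[[length(hits) + 1L]] <- list(group = g, element = el)
        }
      }
    }
    return(hits)
  }
  if (is.null(ctx$translate_cache)) {
    ctx$translate_cache <- new.env(parent = emptyenv())
  }
  tab <- ctx$translate_cache[[map_url]]
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    for (g in cm$groups) {
      for (el in g$elements) {
        tab[[el$source_code]] <- c(tab[[el$source_code]] %||% list(),
                                   list(list(group = g, element = el)))
      }
    }
    ctx$translate_cache[[map_url]] <- tab
  }
  tab[[code]] %||% list()
}

# ---- transform helpers (one per FML transform) ------------------------------

#' Runtime counterparts of the FML transform operations
#'
#' Called from generated programs and from the reference interpreter.
#'
#' @param ctx execution context
#' @param type_name model type name
#' @param value,... primitive values, nodes or collections
#' @name fml_transforms
NULL

#' @rdname fml_transforms
#' @export
fml_create <- function(ctx, type_name) new_instance_node(ctx$models, type_name)

#' @rdname fml_transforms
#' @export
fml_copy <- function(value) {
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, "copy")
    if (is.null(value)) return(NULL)
  }
  if (is_fml_node(value)) node_deep_copy(value) else value
}

#' @rdname fml_transforms
#' @export
fml_append <- function(...) {
  parts <- lapply(list(...), function(p) {
    if (is.list(p) && !is_fml_node(p)) p <- fp_singleton(p, "append")
    if (is.null(p)) "" else fp_item_str(p)
  })
  paste(unlist(parts), collapse = "")
}

CAST_TABLE <- list(
  string = c("string", "integer", "decimal", "boolean", "date", "datetime",
             "uri"),
  integer = c("string", "integer"),
  decimal = c("string", "integer", "decimal"),
  boolean = c("string", "boolean"),
  dateTime = c("date", "datetime", "string")
)

#' @rdname fml_transforms
#' @export
fml_cast <- function(ctx, value, type_name) {
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, "cast")
    if (is.null(value)) return(NULL)
  }
  if (is_fml_node(value)) {
    value <- typed_primitive(primitive_node_lexical(value, ctx$models),
                             models_get(ctx$models, value$type)$primitive_kind %||% "string")
  }
  from <- fp_item_class(value)
  allowed <- CAST_TABLE[[type_name]]
  if (is.null(allowed)) {
    fml_error("fmlc_cast_error", paste0("unsupported cast target '", type_name, "'"))
  }
  if (!from %in% allowed) {
    fml_error("fmlc_cast_error",
              paste0("cannot cast ", from, " to ", type_name))
  }
  lex <- fp_item_str(value)
  switch(type_name,
    string = lex,
    integer = {
      if (!grepl("^[+-]?[0-9]+$", lex)) {
        fml_error("fmlc_cast_error", paste0("not an integer: '", lex, "'"))
      }
      as.integer(lex)
    },
    decimal = {
      if (is.na(suppressWarnings(as.numeric(lex)))) {
        fml_error("fmlc_cast_error", paste0("not a decimal: '", lex, "'"))
      }
      fml_decimal(lex)
    },
    boolean = {
      if (!lex %in% c("true", "false")) {
        fml_error("fmlc_cast_error", paste0("not a boolean: '", lex, "'"))
      }
      identical(lex, "true")
    },
    dateTime = structure(lex, class = c("fml_datetime", "character"))
  )
}

#' @rdname fml_transforms
#' @export
fml_truncate <- function(value, len) {
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, "truncate")
    if (is.null(value)) return(NULL)
  }
  s <- fp_item_str(value)
  substr(s, 1L, as.integer(len))
}

#' @rdname fml_transforms
#' @export
fml_cc <- function(ctx, a, b = NULL) {
  n <- fml_new_node("CodeableConcept")
  if (is.null(b)) {
    n$values <- list(text = list(as_lexical(a, ctx)))
  } else {
    n$values <- list(coding = list(fml_c(ctx, a, b)))
  }
  n
}

#' @rdname fml_transforms
#' @export
fml_c <- function(ctx, system, code, display = NULL) {
  n <- fml_new_node("Coding")
  vals <- list(system = list(as_lexical(system, ctx)),
               code = list(as_lexical(code, ctx)))
  if (!is.null(display)) vals$display <- list(as_lexical(display, ctx))
  n$values <- vals
  n
}

as_lexical <- function(value, ctx) {
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, "primitive parameter")
  }
  if (is_fml_node(value)) primitive_node_lexical(value, ctx$models)
  else primitive_lexical(value)
}

#' @rdname fml_transforms
#' @export
fml_translate <- function(ctx, value, map_url, output = "code") {
  translate_code(ctx, value, source_system = NULL, map_url = map_url,
                 output = output)
}

# ---- rule plumbing shared by both engines -----------------------------------

#' List-mode selection over a source collection
#'
#' @param items collection
#' @param mode one of first, not_first, last, not_last, only_one
#' @return selected collection; `only_one` raises a cardinality error unless
#'   exactly one item is present
#' @export
fml_listmode <- function(items, mode) {
  n <- length(items)
  switch(mode,
    first = if (n) items[1] else list(),
    not_first = if (n > 1) items[-1] else list(),
    last = if (n) items[n] else list(),
    not_last = if (n > 1) items[-n] else list(),
    only_one = {
      if (n != 1) {
        fml_error("fmlc_cardinality_error",
                  paste0("listMode only_one: expected exactly 1 item, got ", n))
      }
      items
    },
    fml_error("fmlc_runtime_error", paste0("unknown listMode '", mode, "'"))
  )
}

# ---- statically-specialized accessors ---------------------------------------
# Emitted by the compiler when element types are known at compile time; they
# skip the per-call model dispatch that dynamic_get / fml_assign perform.
# Semantics are identical to the dynamic helpers on the element shapes the
# compiler proved.

#' Statically-typed runtime accessors
#'
#' Fast paths emitted by the compiler for elements whose declared type is
#' known at compile time. `fml_children` reads complex or string-kind
#' children as stored; `fml_raw_typed` additionally types raw lexical values
#' (boolean/integer/decimal/date kinds); `fml_set1`/`fml_add1` write a
#' precomputed value; `fml_assign_lex`/`fml_assign_node` are the
#' cardinality-aware assignment specializations for primitive and complex
#' elements.
#'
#' @param node,target instance nodes
#' @param element element name
#' @param kind primitive kind
#' @param value value to store
#' @param replace TRUE for maxOccurs-1 elements (replace), FALSE to append
#' @name fml_fast
NULL

#' @rdname fml_fast
#' @param type type name for the node to create
#' @param resource_kind resource kind (precomputed by the compiler)
#' @export
fml_new_node <- function(type, resource_kind = NULL) {
  node <- new.env(hash = FALSE, parent = emptyenv())
  node$type <- type
  node$values <- list()
  node$resource_kind <- resource_kind
  class(node) <- "fml_node"
  node
}

#' @rdname fml_fast
#' @export
fml_children <- function(node, element) {
  v <- node$values[[element]]
  if (is.null(v)) list() else v
}

#' @rdname fml_fast
#' @export
fml_raw_typed <- function(node, element, kind) {
  v <- node$values[[element]]
  if (is.null(v)) return(list())
  out <- vector("list", length(v))
  for (i in seq_along(v)) out[[i]] <- typed_primitive(v[[i]], kind)
  out
}

#' @rdname fml_fast
#' @param type_name cast target type
#' @export
fml_cast_lex <- function(value, type_name) {
  # statically-dispatched cast: value is a scalar; result is the canonical
  # lexical form ready for storage
  if (is.null(value)) return(NULL)
  from <- fp_item_class(value)
  allowed <- CAST_TABLE[[type_name]]
  if (!from %in% allowed) {
    fml_error("fmlc_cast_error",
              paste0("cannot cast ", from, " to ", type_name))
  }
  lex <- fp_item_str(value)
  switch(type_name,
    string = lex,
    integer = {
      if (!grepl("^[+-]?[0-9]+$", lex)) {
        fml_error("fmlc_cast_error", paste0("not an integer: '", lex, "'"))
      }
      lex
    },
    decimal = {
      if (grepl(CANONICAL_DECIMAL_RE, lex)) lex else canonical_decimal(lex)
    },
    boolean = {
      if (!lex %in% c("true", "false")) {
        fml_error("fmlc_cast_error", paste0("not a boolean: '", lex, "'"))
      }
      lex
    },
    dateTime = lex
  )
}

#' @rdname fml_fast
#' @export
fml_set1 <- function(node, element, value) {
  if (is.null(value)) return(invisible(NULL))
  node$values[[element]] <- list(value)
  invisible(value)
}

#' @rdname fml_fast
#' @export
fml_add1 <- function(node, element, value) {
  if (is.null(value)) return(invisible(NULL))
  node$values[[element]] <- c(node$values[[element]], list(value))
  invisible(value)
}

#' @rdname fml_fast
#' @export
fml_assign_lex <- function(target, element, value, replace, ctx) {
  if (is.null(value)) return(invisible(NULL))
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, paste0("assignment to ", element))
    if (is.null(value)) return(invisible(NULL))
  }
  lex <- if (is_fml_node(value)) primitive_node_lexical(value, ctx$models)
         else primitive_lexical(value)
  if (replace) target$values[[element]] <- list(lex)
  else target$values[[element]] <- c(target$values[[element]], list(lex))
  invisible(lex)
}

#' @rdname fml_fast
#' @export
fml_assign_node <- function(target, element, value, replace, ctx) {
  if (is.null(value)) return(invisible(NULL))
  if (is.list(value) && !is_fml_node(value)) {
    value <- fp_singleton(value, paste0("assignment to ", element))
    if (is.null(value)) return(invisible(NULL))
  }
  if (!is_fml_node(value)) {
    fml_error("fmlc_runtime_error",
              paste0("cannot assign a primitive to complex element '",
                     element, "'"))
  }
  if (replace) target$values[[element]] <- list(value)
  else target$values[[element]] <- c(target$values[[element]], list(value))
  invisible(value)
}

#' Runtime assertion for an FML `check` clause
#'
#' @param result evaluated condition collection
#' @param expr_text original expression text (for the diagnostic)
#' @export
fml_check <- function(result, expr_text) {
  if (!fp_truthy(result)) {
    fml_error("fmlc_check_error", paste0("check failed: ", expr_text))
  }
  invisible(TRUE)
}
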