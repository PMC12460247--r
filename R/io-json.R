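# FHIR-style JSON projection of typed instances. Reading goes through
# jsonlite; writing is a deterministic text emitter following FHIR JSON
# conventions: resource roots carry `resourceType` first, repeating elements
# are arrays, primitives unwrap their `value` attribute, booleans/integers/
# decimals are JSON booleans/numbers, keys in schema order.

node_in_fhir_family <- function(models, node) {
  identical(models_get(models, node$type)$namespace, FHIR_NS)
}

#' Serialize a typed node tree to FHIR-style JSON text
#'
#' @param node instance node (FHIR-style model family)
#' @param models model set
#' @return JSON text (2-space indent, LF newlines; numbers in canonical
#'   minimal decimal form)
#' @export
write_fhir_json <- function(node, models) {
  if (!node_in_fhir_family(models, node)) {
    fml_error("fmlc_unsupported_model",
              paste0("type '", node$type, "' is not in the FHIR-style model ",
                     "family; JSON projection is undefined for it"))
  }
  paste0(paste(emit_json_value(node, models, 0L), collapse = "\n"), "\n")
}

render_json_primitive <- function(lexical, kind) {
  switch(kind,
    boolean = if (identical(lexical, "true")) "true" else "false",
    integer = lexical,
    decimal = canonical_decimal(lexical),
    json_escape(lexical)
  )
}

# Returns a character vector of lines; the first line carries no indentation
# of its own (the caller splices it after a key), subsequent lines are
# indented relative to `depth`.
emit_json_value <- function(value, models, depth) {
  if (!is_fml_node(value)) {
    return(json_escape(primitive_lexical(value)))
  }
  d <- type_info(models, value$type)
  if (isTRUE(d$is_primitive)) {
    carrier <- if (identical(d$value_carrier, "text")) ".text" else "value"
    v <- node_get(value, carrier)
    if (!length(v)) return("null")
    return(render_json_primitive(primitive_lexical(v[[1]]), d$primitive_kind))
  }
  if (is_resource_container(models, value$type)) {
    # unwrap to the contained resource object (FHIR JSON convention)
    for (e in effective_elements(models, value$type)) {
      items <- node_get(value, e$name)
      if (length(items)) return(emit_json_value(items[[1]], models, depth))
    }
    return("{}")
  }
  check_cardinality(value, models, value$type)

  pad <- strrep("  ", depth)
  ipad <- strrep("  ", depth + 1L)
  blocks <- list()
  if (!is.null(value$resource_kind)) {
    blocks[[length(blocks) + 1L]] <-
      paste0(ipad, "\"resourceType\": ", json_escape(value$resource_kind))
  }
  for (e in effective_elements(models, value$type)) {
    if (e$kind == "text") next
    key <- e$name
    items <- node_get(value, key)
    if (!length(items)) next
    kind <- element_primitive_kind(e, models)
    render_item <- function(it, d) {
      if (!is_fml_node(it) && !is.null(kind)) {
        render_json_primitive(primitive_lexical(it), kind)
      } else {
        emit_json_value(it, models, d)
      }
    }
    repeating <- is.infinite(e$max_occurs) || e$max_occurs > 1
    if (repeating) {
      item_blocks <- lapply(items, function(it) {
        lines <- render_item(it, depth + 2L)
        lines[1] <- paste0(strrep("  ", depth + 2L), lines[1])
        lines
      })
      arr <- join_json_blocks(item_blocks, ipad, paste0(ipad, json_escape(key), ": ["),
                              "]")
      blocks[[length(blocks) + 1L]] <- arr
    } else {
      lines <- render_item(items[[1]], depth + 1L)
      lines[1] <- paste0(ipad, json_escape(key), ": ", lines[1])
      blocks[[length(blocks) + 1L]] <- lines
    }
  }
  if (!length(blocks)) return("{}")
  join_json_blocks(blocks, pad, "{", "}")
}

#' Read FHIR-style JSON text into a typed node tree
#'
#' Inverse of [write_fhir_json()] on its image; unknown keys and shape
#' mismatches (scalar where an array is expected) are errors.
#'
#' @param json_text JSON text
#' @param models model set
#' @param root_type expected type of the root resource/object
#' @return instance node
#' @export
read_fhir_json <- function(json_text, models, root_type) {
  data <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) fml_error("fmlc_format_error",
                                  paste0("not valid JSON: ", conditionMessage(e))))
  build_node_from_json(data, models, root_type, "$")
}

build_node_from_json <- function(data, models, type_name, path) {
  d <- models_get(models, type_name)
  node <- new_instance_node(models, type_name)
  if (isTRUE(d$is_primitive)) {
    carrier <- if (identical(d$value_carrier, "text")) ".text" else "value"
    node_append(node, carrier, json_scalar_lexical(data, d$primitive_kind, path))
    return(node)
  }
  if (!is.list(data) || is.null(names(data))) {
    fml_error("fmlc_shape_error", paste0("expected object at ", path))
  }
  if (is_resource_container(models, type_name)) {
    rt <- data[["resourceType"]]
    if (is.null(rt)) {
      fml_error("fmlc_parse_error",
                paste0("contained resource without resourceType at ", path))
    }
    e <- find_element(models, type_name, rt)
    if (is.null(e)) {
      fml_error("fmlc_parse_error",
                paste0("resourceType '", rt, "' not allowed at ", path))
    }
    node_append(node, rt, build_node_from_json(data, models, e$type_ref, path))
    return(node)
  }
  for (key in names(data)) {
    if (identical(key, "resourceType")) {
      if (!identical(data[[key]], type_name)) {
        fml_error("fmlc_parse_error",
                  paste0("resourceType '", data[[key]], "' does not match ",
                         type_name, " at ", path))
      }
      next
    }
    e <- find_element(models, type_name, key)
    if (is.null(e) || e$kind == "text") {
      fml_error("fmlc_parse_error", paste0("unknown key '", key, "' at ", path))
    }
    repeating <- is.infinite(e$max_occurs) || e$max_occurs > 1
    v <- data[[key]]
    kpath <- paste0(path, ".", key)
    if (repeating) {
      if (!is.list(v) || !is.null(names(v))) {
        fml_error("fmlc_shape_error",
                  paste0("expected array for '", key, "' at ", kpath))
      }
      for (i in seq_along(v)) {
        node_append(node, key,
                    build_json_element(v[[i]], models, e, paste0(kpath, "[", i - 1, "]")))
      }
    } else {
      if (is.list(v) && is.null(names(v))) {
        fml_error("fmlc_shape_error",
                  paste0("unexpected array for singleton '", key, "' at ", kpath))
      }
      node_append(node, key, build_json_element(v, models, e, kpath))
    }
  }
  node
}

build_json_element <- function(v, models, e, path) {
  kind <- element_primitive_kind(e, models)
  if (!is.null(kind)) {
    return(json_scalar_lexical(v, kind, path))
  }
  build_node_from_json(v, models, e$type_ref, path)
}

json_scalar_lexical <- function(v, kind, path) {
  if (is.list(v)) {
    fml_error("fmlc_shape_error", paste0("expected scalar at ", path))
  }
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(canonical_decimal(v))
  as.character(v)
}

#' Canonicalize JSON text for comparison
#'
#' Re-emits parsed JSON deterministically (original key order, 2-space
#' indent, canonical number rendering). Used by the canonical diff.
#'
#' @param text JSON text
#' @return canonical JSON text
#' @export
canonicalize_json <- function(text) {
  data <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) fml_error("fmlc_format_error",
                                  paste0("not valid JSON: ", conditionMessage(e))))
  paste0(paste(canon_json_value(data, 0L), collapse = "\n"), "\n")
}

canon_json_value <- function(v, depth) {
  pad <- strrep("  ", depth)
  ipad <- strrep("  ", depth + 1L)
  if (is.null(v)) return("null")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) return(canonical_decimal(v))
  if (is.character(v)) return(json_escape(v))
  if (is.list(v) && !is.null(names(v))) {
    if (!length(v)) return("{}")
    blocks <- lapply(seq_along(v), function(i) {
      lines <- canon_json_value(v[[i]], depth + 1L)
      lines[1] <- paste0(ipad, json_escape(names(v)[i]), ": ", lines[1])
      lines
    })
    join_json_blocks(blocks, pad, "{", "}")
  } else if (is.list(v)) {
    if (!length(v)) return("[]")
    blocks <- lapply(v, function(it) {
      lines <- canon_json_value(it, depth + 1L)
      lines[1] <- paste0(ipad, lines[1])
      lines
    })
    join_json_blocks(blocks, pad, "[", "]")
  } else {
    json_escape(as.character(v))
  }
}

join_json_blocks <- function(blocks, pad, open, close) {
  n <- length(blocks)
  withcommas <- lapply(seq_len(n), function(i) {
    blk <- blocks[[i]]
    if (i < n) blk[length(blk)] <- paste0(blk[length(blk)], ",")
    blk
  })
  c(open, unlist(withcommas, use.names = FALSE), paste0(pad, close))
}
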