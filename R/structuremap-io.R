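# StructureMap / ConceptMap resource readers and writers (XML and JSON
# renderings of the supported element subset). Both formats parse to the same
# AST as the equivalent FML text; FHIRPath strings are raw in the resource
# and parsed here.

# ---- serialization ----------------------------------------------------------

#' Serialize a StructureMap AST to a FHIR resource rendering
#'
#' @param ast StructureMap AST
#' @param fmt `"xml"` or `"json"`
#' @return resource text; deterministic, and `parse_structuremap()` of the
#'   output reproduces the AST
#' @export
serialize_structuremap <- function(ast, fmt = c("json", "xml")) {
  fmt <- match.arg(fmt)
  data <- structuremap_to_plain(ast)
  if (fmt == "json") {
    paste0(paste(canon_json_value(data, 0L), collapse = "\n"), "\n")
  } else {
    paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
           paste(plain_to_fhir_xml(data, "StructureMap", 0L, root = TRUE),
                 collapse = "\n"), "\n")
  }
}

# plain representation: named lists mirror FHIR JSON; unnamed lists are arrays
structuremap_to_plain <- function(ast) {
  out <- list(resourceType = "StructureMap", url = ast$url, name = ast$name)
  if (length(ast$concept_maps)) {
    out$contained <- lapply(ast$concept_maps, conceptmap_to_plain)
  }
  if (length(ast$uses)) {
    out$structure <- lapply(ast$uses, function(u) {
      drop_null(list(url = u$url, alias = u$alias, mode = u$mode))
    })
  }
  if (length(ast$imports)) out$import <- as.list(ast$imports)
  out$group <- lapply(ast$groups, group_to_plain)
  out
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

conceptmap_to_plain <- function(cm) {
  list(resourceType = "ConceptMap", url = cm$url,
       group = lapply(cm$groups, function(g) {
         list(source = g$source_system, target = g$target_system,
              element = lapply(g$elements, function(el) {
                list(code = el$source_code,
                     target = list(list(code = el$target_code,
                                        relationship = el$relationship)))
              }))
       }))
}

group_to_plain <- function(g) {
  drop_null(list(
    name = g$name,
    extends = g$extends,
    typeMode = if (identical(g$type_mode, "none")) NULL else g$type_mode,
    input = lapply(g$inputs, function(i) {
      drop_null(list(name = i$name, type = i$type, mode = i$mode))
    }),
    rule = lapply(g$rules, rule_to_plain)
  ))
}

rule_to_plain <- function(r) {
  out <- drop_null(list(
    name = r$name,
    source = list(source_to_plain(r$source)),
    target = if (length(r$targets)) lapply(r$targets, target_to_plain) else NULL,
    rule = if (length(r$nested_rules)) lapply(r$nested_rules, rule_to_plain) else NULL,
    dependent = if (length(r$dependent_calls)) {
      lapply(r$dependent_calls, function(d) {
        list(name = d$group,
             parameter = lapply(d$args, function(a) list(valueId = a)))
      })
    } else NULL
  ))
  out
}

source_to_plain <- function(s) {
  out <- drop_null(list(
    context = s$context, element = s$element, type = s$declared_type,
    variable = s$variable, listMode = s$list_mode,
    condition = if (!is.null(s$condition)) s$condition$text else NULL,
    check = if (!is.null(s$check)) s$check$text else NULL
  ))
  if (!is.null(s$default_value)) {
    dv <- s$default_value
    key <- paste0("defaultValue",
                  toupper(substr(dv$type, 1, 1)), substr(dv$type, 2, nchar(dv$type)))
    out[[key]] <- literal_plain_value(dv)
  }
  out
}

literal_plain_value <- function(lit) {
  switch(lit$type,
    decimal = structure(as.numeric(lit$value), lexical = lit$value),
    lit$value
  )
}

target_to_plain <- function(t) {
  drop_null(list(
    context = t$context, element = t$element, variable = t$variable,
    transform = t$transform,
    parameter = if (length(t$params)) lapply(t$params, param_to_plain) else NULL
  ))
}

param_to_plain <- function(p) {
  if (identical(p$kind, "var")) return(list(valueId = p$name))
  if (identical(p$kind, "fhirpath")) return(list(valueString = p$text))
  switch(p$type,
    string = list(valueString = p$value),
    integer = list(valueInteger = p$value),
    decimal = list(valueDecimal = structure(as.numeric(p$value),
                                            lexical = p$value)),
    boolean = list(valueBoolean = p$value)
  )
}

# FHIR XML rendering of the plain form: scalar entries become
# `<name value="..."/>`, arrays repeat the element, `contained` resources
# nest their resource element.
plain_to_fhir_xml <- function(data, name, depth, root = FALSE) {
  pad <- strrep("  ", depth)
  open <- paste0(pad, "<", name,
                 if (root) paste0(" xmlns=\"", FHIR_NS, "\""), ">")
  lines <- character(0)
  for (key in names(data)) {
    if (identical(key, "resourceType")) next
    v <- data[[key]]
    if (identical(key, "contained")) {
      for (res in v) {
        inner <- plain_to_fhir_xml(res, res$resourceType, depth + 2L)
        lines <- c(lines, paste0(strrep("  ", depth + 1L), "<contained>"),
                   inner, paste0(strrep("  ", depth + 1L), "</contained>"))
      }
      next
    }
    items <- if (is.list(v) && is.null(names(v))) v else list(v)
    for (item in items) {
      if (is.list(item)) {
        lines <- c(lines, plain_to_fhir_xml(item, key, depth + 1L))
      } else {
        lex <- if (is.logical(item)) (if (item) "true" else "false")
               else if (is.numeric(item)) (attr(item, "lexical") %||% canonical_decimal(item))
               else as.character(item)
        lines <- c(lines, paste0(strrep("  ", depth + 1L), "<", key,
                                 " value=\"", xml_escape_attr(lex), "\"/>"))
      }
    }
  }
  c(open, lines, paste0(pad, "</", name, ">"))
}

# ---- parsing ----------------------------------------------------------------

#' Parse a StructureMap resource (XML or JSON) into the AST
#'
#' Produces the same AST as parsing the equivalent FML text; embedded raw
#' FHIRPath strings are parsed at this stage.
#'
#' @param doc_text resource text
#' @param fmt `"xml"` or `"json"`
#' @return StructureMap AST
#' @export
parse_structuremap <- function(doc_text, fmt = c("json", "xml")) {
  fmt <- match.arg(fmt)
  data <- if (fmt == "json") {
    jsonlite::fromJSON(doc_text, simplifyVector = FALSE)
  } else {
    fhir_xml_to_plain(xml2::xml_ns_strip(xml2::read_xml(doc_text)))
  }
  if (!identical(data$resourceType, "StructureMap")) {
    fml_error("fmlc_parse_error",
              paste0("expected a StructureMap resource, got ",
                     data$resourceType %||% "(none)"))
  }
  known <- c("resourceType", "url", "name", "contained", "structure",
             "import", "group")
  for (key in names(data)) {
    if (!key %in% known) {
      fml_error("fmlc_unsupported_feature",
                paste0("unsupported StructureMap element '", key, "'"))
    }
  }
  concept_maps <- lapply(as_plain_array(data$contained), plain_to_conceptmap)
  uses <- lapply(as_plain_array(data$structure), function(u) {
    list(url = u$url, alias = u$alias %||% NULL, mode = u$mode)
  })
  imports <- vapply(as_plain_array(data$import), as.character, character(1))
  groups_raw <- as_plain_array(data$group)
  groups <- list()
  for (i in seq_along(groups_raw)) {
    groups[[i]] <- plain_to_group(groups_raw[[i]], i)
  }
  ast <- structure(list(url = data$url, name = data$name, uses = uses,
                        imports = imports, concept_maps = concept_maps,
                        groups = groups),
                   class = "fml_structuremap")
  validate_structuremap_ast(ast)
  ast
}

# read a FHIR XML element tree into the plain (JSON-like) representation
fhir_xml_to_plain <- function(xnode) {
  out <- list(resourceType = xml2::xml_name(xnode))
  for (child in xml2::xml_children(xnode)) {
    nm <- xml2::xml_name(child)
    if (identical(nm, "contained")) {
      inner <- xml2::xml_children(child)
      if (length(inner) != 1) {
        fml_error("fmlc_parse_error", "contained must hold one resource")
      }
      out$contained <- c(out$contained %||% list(),
                         list(fhir_xml_to_plain(inner[[1]])))
      next
    }
    v <- xml2::xml_attr(child, "value")
    entry <- if (!is.na(v)) v else fhir_xml_to_plain_backbone(child)
    if (nm %in% names(out)) {
      if (is.list(out[[nm]]) && is.null(names(out[[nm]])) &&
          !is.null(attr(out[[nm]], "arr"))) {
        out[[nm]] <- structure(c(out[[nm]], list(entry)), arr = TRUE)
      } else {
        out[[nm]] <- structure(list(out[[nm]], entry), arr = TRUE)
      }
    } else {
      out[[nm]] <- entry
    }
  }
  out
}

fhir_xml_to_plain_backbone <- function(xnode) {
  out <- list()
  for (child in xml2::xml_children(xnode)) {
    nm <- xml2::xml_name(child)
    v <- xml2::xml_attr(child, "value")
    entry <- if (!is.na(v)) v else fhir_xml_to_plain_backbone(child)
    if (nm %in% names(out)) {
      if (!is.null(attr(out[[nm]], "arr"))) {
        out[[nm]] <- structure(c(out[[nm]], list(entry)), arr = TRUE)
      } else {
        out[[nm]] <- structure(list(out[[nm]], entry), arr = TRUE)
      }
    } else {
      out[[nm]] <- entry
    }
  }
  out
}

# normalize an entry that may be a single object or an array of objects
as_plain_array <- function(v) {
  if (is.null(v)) return(list())
  if (is.list(v) && is.null(names(v))) return(v)
  list(v)
}

plain_to_conceptmap <- function(data) {
  if (!identical(data$resourceType, "ConceptMap")) {
    fml_error("fmlc_unsupported_feature",
              paste0("unsupported contained resource ", data$resourceType))
  }
  cm <- list(
    url = data$url,
    groups = lapply(as_plain_array(data$group), function(g) {
      list(source_system = g$source, target_system = g$target,
           elements = lapply(as_plain_array(g$element), function(el) {
             tgt <- as_plain_array(el$target)[[1]]
             list(source_code = el$code,
                  relationship = tgt$relationship %||% "equivalent",
                  target_code = tgt$code)
           }))
    }))
  validate_conceptmap(cm)
  cm
}

plain_to_group <- function(g, index) {
  rules <- list()
  rl <- as_plain_array(g$rule)
  for (j in seq_along(rl)) {
    rules[[j]] <- plain_to_rule(rl[[j]], paste0("g", index, "_r", j))
  }
  structure(list(
    name = g$name,
    type_mode = if (is.null(g$typeMode)) "none" else g$typeMode,
    inputs = lapply(as_plain_array(g$input), function(i) {
      list(name = i$name, type = i$type %||% NULL, mode = i$mode)
    }),
    rules = rules,
    extends = g$extends %||% NULL
  ), class = "fml_map_group")
}

plain_to_rule <- function(r, rule_id) {
  srcs <- as_plain_array(r$source)
  if (length(srcs) != 1) {
    fml_error("fmlc_unsupported_feature",
              "exactly one source clause per rule is supported")
  }
  nested <- list()
  nl <- as_plain_array(r$rule)
  for (j in seq_along(nl)) {
    nested[[j]] <- plain_to_rule(nl[[j]], paste0(rule_id, "_r", j))
  }
  structure(list(
    name = r$name %||% NULL,
    rule_id = rule_id,
    source = plain_to_source(srcs[[1]]),
    targets = lapply(as_plain_array(r$target), plain_to_target),
    nested_rules = nested,
    dependent_calls = lapply(as_plain_array(r$dependent), function(d) {
      list(group = d$name,
           args = vapply(as_plain_array(d$parameter),
                         function(p) as.character(p$valueId), character(1)))
    })
  ), class = "fml_map_rule")
}

plain_to_source <- function(s) {
  dv <- NULL
  for (key in names(s)) {
    if (startsWith(key, "defaultValue")) {
      ty <- sub("^defaultValue", "", key)
      ty <- paste0(tolower(substr(ty, 1, 1)), substr(ty, 2, nchar(ty)))
      val <- s[[key]]
      dv <- switch(ty,
        string = list(kind = "literal", type = "string", value = as.character(val)),
        integer = list(kind = "literal", type = "integer", value = as.integer(val)),
        decimal = list(kind = "literal", type = "decimal",
                       value = attr(val, "lexical") %||% canonical_decimal(val)),
        boolean = list(kind = "literal", type = "boolean", value = isTRUE(val) ||
                         identical(val, "true")),
        fml_error("fmlc_unsupported_feature",
                  paste0("unsupported default value type ", ty)))
    }
  }
  structure(list(
    context = s$context, element = s$element %||% NULL,
    declared_type = s$type %||% NULL, variable = s$variable %||% NULL,
    condition = if (!is.null(s$condition))
      list(text = s$condition, ast = parse_fhirpath(s$condition)) else NULL,
    check = if (!is.null(s$check))
      list(text = s$check, ast = parse_fhirpath(s$check)) else NULL,
    list_mode = s$listMode %||% NULL,
    default_value = dv
  ), class = "fml_rule_source")
}

plain_to_target <- function(t) {
  transform <- t$transform %||% "create"
  if (transform %in% FML_REJECTED_TRANSFORMS || !transform %in% FML_TRANSFORMS) {
    fml_error("fmlc_unsupported_transform",
              paste0("unsupported transform '", transform, "'"))
  }
  raw_params <- as_plain_array(t$parameter)
  params <- list()
  for (i in seq_along(raw_params)) {
    p <- raw_params[[i]]
    key <- names(p)[1]
    val <- p[[1]]
    params[[i]] <- switch(key,
      valueId = list(kind = "var", name = as.character(val)),
      valueString = list(kind = "literal", type = "string",
                         value = as.character(val)),
      valueInteger = list(kind = "literal", type = "integer",
                          value = as.integer(val)),
      valueDecimal = list(kind = "literal", type = "decimal",
                          value = attr(val, "lexical") %||% canonical_decimal(val)),
      valueBoolean = list(kind = "literal", type = "boolean",
                          value = isTRUE(val) || identical(val, "true")),
      fml_error("fmlc_unsupported_feature",
                paste0("unsupported parameter key ", key)))
  }
  # evaluate carries its expression as a raw string parameter: re-parse it
  if (identical(transform, "evaluate") && length(params)) {
    last <- params[[length(params)]]
    if (identical(last$kind, "literal") && identical(last$type, "string")) {
      params[[length(params)]] <- list(kind = "fhirpath", text = last$value,
                                       ast = parse_fhirpath(last$value))
    }
  }
  check_transform_arity(transform, length(params))
  structure(list(context = t$context %||% NULL, element = t$element %||% NULL,
                 variable = t$variable %||% NULL, transform = transform,
                 params = params),
            class = "fml_rule_target")
}

# ---- ConceptMap files -------------------------------------------------------

#' Read a ConceptMap resource (XML or JSON)
#'
#' @param doc_text resource text
#' @param fmt `"xml"` or `"json"`; default sniffs the first character
#' @return concept map definition for [register_conceptmap()]
#' @export
read_conceptmap <- function(doc_text, fmt = NULL) {
  if (is.null(fmt)) {
    fmt <- if (startsWith(trimws(doc_text), "<")) "xml" else "json"
  }
  data <- if (fmt == "json") {
    jsonlite::fromJSON(doc_text, simplifyVector = FALSE)
  } else {
    fhir_xml_to_plain(xml2::xml_ns_strip(xml2::read_xml(doc_text)))
  }
  plain_to_conceptmap(data)
}

#' Serialize a concept map definition as a ConceptMap resource
#'
#' @param cm concept map definition
#' @param fmt `"xml"` or `"json"`
#' @return resource text
#' @export
serialize_conceptmap <- function(cm, fmt = c("json", "xml")) {
  fmt <- match.arg(fmt)
  data <- conceptmap_to_plain(cm)
  if (fmt == "json") {
    paste0(paste(canon_json_value(data, 0L), collapse = "\n"), "\n")
  } else {
    paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
           paste(plain_to_fhir_xml(data, "ConceptMap", 0L, root = TRUE),
                 collapse = "\n"), "\n")
  }
}

# ---- import resolution ------------------------------------------------------

#' Resolve a map's imports to a closed set of maps and concept maps
#'
#' @param ast StructureMap AST
#' @param resolver named list/character vector mapping import URIs to
#'   document text (FML, StructureMap or ConceptMap; format sniffed)
#' @return list with `maps` (named by url, including the root) and
#'   `conceptmaps` (named by url, embedded ones included)
#' @export
load_imports <- function(ast, resolver = list()) {
  maps <- list()
  conceptmaps <- list()
  visit <- function(a, stack) {
    if (a$url %in% stack) {
      fml_error("fmlc_import_cycle",
                paste0("import cycle: ", paste(c(stack, a$url), collapse = " -> ")))
    }
    if (!is.null(maps[[a$url]])) return(invisible(NULL))
    maps[[a$url]] <<- a
    for (cm in a$concept_maps) conceptmaps[[cm$url]] <<- cm
    for (uri in a$imports) {
      txt <- resolver[[uri]]
      if (is.null(txt)) {
        fml_error("fmlc_unresolved_import",
                  paste0("unresolved import: ", uri))
      }
      txt_t <- trimws(txt)
      if (startsWith(txt_t, "<")) {
        rn <- xml2::xml_name(xml2::read_xml(txt))
        if (identical(rn, "ConceptMap")) {
          cm <- read_conceptmap(txt, "xml")
          conceptmaps[[cm$url]] <<- cm
        } else {
          visit(parse_structuremap(txt, "xml"), c(stack, a$url))
        }
      } else if (startsWith(txt_t, "{")) {
        data <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
        if (identical(data$resourceType, "ConceptMap")) {
          cm <- plain_to_conceptmap(data)
          conceptmaps[[cm$url]] <<- cm
        } else {
          visit(parse_structuremap(txt, "json"), c(stack, a$url))
        }
      } else {
        visit(parse_fml(txt), c(stack, a$url))
      }
    }
  }
  visit(ast, character(0))
  list(maps = maps, conceptmaps = conceptmaps)
}
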