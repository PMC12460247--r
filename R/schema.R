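# Typed model descriptors derived from a restricted XML-Schema dialect.
#
# The descriptor set is the compiler's only type oracle: element types,
# cardinalities and choice groups all come from here, so no additional
# logical/meta model is needed at compile time or at run time.

XSD_NS <- "http://www.w3.org/2001/XMLSchema"
FHIR_NS <- "http://hl7.org/fhir"

XS_PRIMITIVE_KINDS <- c(
  "xs:string" = "string", "xs:token" = "string", "xs:ID" = "string",
  "xs:anyURI" = "uri", "xs:date" = "date", "xs:dateTime" = "datetime",
  "xs:boolean" = "boolean", "xs:integer" = "integer", "xs:int" = "integer",
  "xs:positiveInteger" = "integer", "xs:nonNegativeInteger" = "integer",
  "xs:decimal" = "decimal"
)

new_element_descriptor <- function(name, type_ref, min_occurs = 0L,
                                   max_occurs = 1, kind = "element",
                                   choice_group = NULL) {
  if (is.finite(max_occurs) && min_occurs > max_occurs) {
    fml_error("fmlc_schema_error",
              paste0("minOccurs > maxOccurs for element '", name, "'"))
  }
  structure(list(name = name, type_ref = type_ref,
                 min_occurs = as.integer(min_occurs), max_occurs = max_occurs,
                 kind = kind, choice_group = choice_group),
            class = "fml_element_descriptor")
}

new_model_descriptor <- function(type_name, namespace, base_type = NULL,
                                 is_primitive = FALSE, primitive_kind = NULL,
                                 value_carrier = NULL, elements = list(),
                                 root_element = NULL) {
  structure(list(type_name = type_name, namespace = namespace,
                 base_type = base_type, is_primitive = is_primitive,
                 primitive_kind = primitive_kind, value_carrier = value_carrier,
                 elements = elements, root_element = root_element),
            class = "fml_model_descriptor")
}

builtin_descriptors <- function() {
  lapply(names(XS_PRIMITIVE_KINDS), function(nm) {
    new_model_descriptor(nm, XSD_NS, is_primitive = TRUE,
                         primitive_kind = unname(XS_PRIMITIVE_KINDS[[nm]]),
                         value_carrier = "raw")
  })
}

new_model_set <- function() {
  ms <- new.env(parent = emptyenv())
  ms$types <- new.env(parent = emptyenv())
  ms$cache <- new.env(parent = emptyenv())  # lazily-built per-type info
  ms$order <- character(0)
  ms$roots <- list()  # root element name -> type name
  ms$prefixes <- character(0)  # prefix -> namespace URI
  for (d in builtin_descriptors()) {
    assign(d$type_name, d, envir = ms$types)
  }
  class(ms) <- "fml_model_set"
  ms
}

# Memoized per-type lookup structure: effective element list (base chain
# first), name-indexed descriptors, and derived flags. The descriptor set is
# immutable after parsing, so the cache is safe.
type_info <- function(models, type_name) {
  ti <- models$cache[[type_name]]
  if (!is.null(ti)) return(ti)
  d <- models_get(models, type_name)
  els <- effective_elements_uncached(models, type_name)
  by_name <- list()
  for (e in els) by_name[[e$name]] <- e
  # serialization plan: attribute descriptors, child-element rows with the
  # precomputed primitive projection style, plus cardinality facts
  attrs <- list(); elems <- list(); has_text <- FALSE
  required <- character(0)
  choice_map <- list()
  for (e in els) {
    if (e$min_occurs > 0) required <- c(required, e$name)
    if (!is.null(e$choice_group)) {
      choice_map[[e$choice_group]] <- c(choice_map[[e$choice_group]], e$name)
    }
    if (e$kind == "attribute") {
      attrs[[length(attrs) + 1L]] <- e
    } else if (e$kind == "text") {
      has_text <- TRUE
    } else {
      attr_style <- !startsWith(e$type_ref, "xs:") && {
        ed <- models_get(models, e$type_ref)
        isTRUE(ed$is_primitive) && identical(ed$value_carrier, "attribute")
      }
      elems[[length(elems) + 1L]] <-
        list(name = e$name, attr_style = attr_style,
             max_occurs = e$max_occurs)
    }
  }
  ti <- list(
    desc = d,
    elements = els,
    by_name = by_name,
    is_primitive = isTRUE(d$is_primitive),
    primitive_kind = d$primitive_kind,
    value_carrier = d$value_carrier,
    is_resource = derives_from(models, type_name, "Resource"),
    is_container = length(els) > 0 &&
      all(vapply(els, function(e) !is.null(e$choice_group) &&
                   derives_from(models, e$type_ref, "Resource"), logical(1))),
    xml_attrs = attrs,
    xml_elems = elems,
    has_text = has_text,
    required = required,
    choice_map = choice_map,
    known_names = names(by_name)
  )
  models$cache[[type_name]] <- ti
  ti
}

models_add <- function(models, desc) {
  if (desc$type_name %in% models$order) {
    fml_error("fmlc_schema_error",
              paste0("duplicate type name across schemas: ", desc$type_name))
  }
  assign(desc$type_name, desc, envir = models$types)
  models$order <- c(models$order, desc$type_name)
  invisible(models)
}

models_get <- function(models, type_name, where = "") {
  if (!exists(type_name, envir = models$types, inherits = FALSE)) {
    fml_error("fmlc_resolution_error",
              paste0("unresolved type reference '", type_name, "'",
                     if (nzchar(where)) paste0(" (", where, ")")))
  }
  get(type_name, envir = models$types, inherits = FALSE)
}

models_has <- function(models, type_name) {
  exists(type_name, envir = models$types, inherits = FALSE)
}

#' Type names declared in a model set
#'
#' @param models a model set from [parse_schema()] or [load_model_set()]
#' @return character vector of declared (non-builtin) type names in schema
#'   declaration order
#' @export
model_type_names <- function(models) models$order

#' Parse a restricted XML-Schema dialect into typed model descriptors
#'
#' Supports `complexType` with `sequence`, `choice`, `attribute`,
#' `complexContent`/`extension` and `simpleContent`/`extension`, named
#' `simpleType` restrictions of XSD builtins, and top-level `element`
#' declarations (used to bind document root names to types). Anything else
#' (substitution groups, `xs:any`, `redefine`, ...) is rejected with an error
#' naming the construct and its location.
#'
#' FHIR-style primitive types -- complex types in the FHIR namespace whose
#' only content is a single `value` attribute -- are flagged primitive so that
#' navigation and JSON serialization unwrap them; simple-content text types
#' (CDA-style `ST`) are likewise flagged with a text carrier.
#'
#' @param xsd_text XSD source text
#' @param models optionally, an existing model set to extend (schemas sharing
#'   one descriptor set, as with included/imported schemas)
#' @return a model set object; descriptors are retrieved internally by
#'   qualified name and listed by [model_type_names()]
#' @export
parse_schema <- function(xsd_text, models = new_model_set()) {
  doc <- xml2::read_xml(xsd_text)
  root <- xml2::xml_ns_strip(doc)  # we key on local names; namespace recorded below
  # re-read to keep the target namespace (ns_strip mutates in place)
  target_ns <- xml2::xml_attr(doc, "targetNamespace")
  if (is.na(target_ns)) target_ns <- ""
  register_prefixes(models, xsd_text)

  for (child in xml2::xml_children(doc)) {
    nm <- xml2::xml_name(child)
    if (nm == "annotation") next
    if (nm == "complexType") {
      models_add(models, parse_complex_type(child, target_ns))
    } else if (nm == "simpleType") {
      models_add(models, parse_simple_type(child, target_ns))
    } else if (nm == "element") {
      enm <- xml2::xml_attr(child, "name")
      ety <- xml2::xml_attr(child, "type")
      if (is.na(enm) || is.na(ety)) {
        fml_error("fmlc_schema_unsupported",
                  paste0("top-level element without name/type at ",
                         xml2::xml_path(child)))
      }
      models$roots[[enm]] <- ety
    } else {
      fml_error("fmlc_schema_unsupported",
                paste0("unsupported XSD construct <", nm, "> at ",
                       xml2::xml_path(child)))
    }
  }
  check_references(models)
  models
}

register_prefixes <- function(models, xsd_text) {
  # first-declaration-wins across schemas; conflicting redeclarations get a
  # deterministic generated alias ns1, ns2, ... in declaration order
  decls <- xml2::xml_ns(xml2::read_xml(xsd_text))
  for (i in seq_along(decls)) {
    p <- names(decls)[[i]]
    uri <- decls[[i]]
    if (p %in% names(models$prefixes)) {
      if (!identical(models$prefixes[[p]], uri)) {
        alias <- paste0("ns", length(models$prefixes) + 1L)
        models$prefixes[[alias]] <- uri
      }
    } else {
      models$prefixes[[p]] <- uri
    }
  }
  invisible(models)
}

#' Load and merge schema files into one model set
#'
#' @param paths character vector of XSD file paths
#' @return merged model set
#' @export
load_model_set <- function(paths) {
  models <- new_model_set()
  for (p in paths) {
    parse_schema(paste(readLines(p, warn = FALSE), collapse = "\n"), models)
  }
  models
}

first_child_named <- function(node, name) {
  for (ch in xml2::xml_children(node)) {
    if (identical(xml2::xml_name(ch), name)) return(ch)
  }
  NULL
}

parse_simple_type <- function(node, target_ns) {
  nm <- xml2::xml_attr(node, "name")
  restr <- first_child_named(node, "restriction")
  if (is.null(restr)) {
    fml_error("fmlc_schema_unsupported",
              paste0("simpleType without restriction at ", xml2::xml_path(node)))
  }
  base <- xml2::xml_attr(restr, "base")
  kind <- XS_PRIMITIVE_KINDS[[base]]
  if (is.null(kind)) {
    fml_error("fmlc_schema_unsupported",
              paste0("unsupported simpleType base '", base, "' at ",
                     xml2::xml_path(node)))
  }
  new_model_descriptor(nm, target_ns, base_type = base, is_primitive = TRUE,
                       primitive_kind = kind, value_carrier = "raw")
}

parse_occurs <- function(node) {
  mn <- xml2::xml_attr(node, "minOccurs")
  mx <- xml2::xml_attr(node, "maxOccurs")
  mn <- if (is.na(mn)) 1L else as.integer(mn)
  mx <- if (is.na(mx)) 1 else if (identical(mx, "unbounded")) Inf else as.numeric(mx)
  list(min = mn, max = mx)
}

parse_particles <- function(container, state, choice_group = NULL,
                            force_optional = FALSE) {
  for (p in xml2::xml_children(container)) {
    pn <- xml2::xml_name(p)
    if (pn == "annotation") next
    if (pn == "element") {
      enm <- xml2::xml_attr(p, "name")
      ety <- xml2::xml_attr(p, "type")
      if (is.na(enm) || is.na(ety)) {
        fml_error("fmlc_schema_unsupported",
                  paste0("element without name/type (inline types unsupported) at ",
                         xml2::xml_path(p)))
      }
      occ <- parse_occurs(p)
      mn <- if (force_optional || !is.null(choice_group)) 0L else occ$min
      state$elements[[length(state$elements) + 1L]] <-
        new_element_descriptor(enm, ety, mn, occ$max, "element", choice_group)
    } else if (pn == "choice") {
      state$n_choice <- state$n_choice + 1L
      parse_particles(p, state,
                      choice_group = paste0("choice", state$n_choice))
    } else if (pn == "sequence") {
      parse_particles(p, state, choice_group = choice_group)
    } else {
      fml_error("fmlc_schema_unsupported",
                paste0("unsupported XSD construct <", pn, "> at ",
                       xml2::xml_path(p)))
    }
  }
}

parse_attribute_decl <- function(p, state) {
  anm <- xml2::xml_attr(p, "name")
  aty <- xml2::xml_attr(p, "type")
  if (is.na(aty)) aty <- "xs:string"
  use <- xml2::xml_attr(p, "use")
  mn <- if (identical(use, "required")) 1L else 0L
  state$elements[[length(state$elements) + 1L]] <-
    new_element_descriptor(anm, aty, mn, 1, "attribute")
}

parse_complex_type <- function(node, target_ns) {
  nm <- xml2::xml_attr(node, "name")
  state <- new.env(parent = emptyenv())
  state$elements <- list()
  state$n_choice <- 0L
  base_type <- NULL
  value_carrier <- NULL

  kids <- xml2::xml_children(node)
  kids <- kids[xml2::xml_name(kids) != "annotation"]
  for (child in kids) {
    cn <- xml2::xml_name(child)
    if (cn %in% c("sequence", "choice")) {
      if (cn == "choice") {
        state$n_choice <- state$n_choice + 1L
        parse_particles(child, state,
                        choice_group = paste0("choice", state$n_choice))
      } else {
        parse_particles(child, state)
      }
    } else if (cn == "attribute") {
      parse_attribute_decl(child, state)
    } else if (cn == "complexContent") {
      ext <- first_child_named(child, "extension")
      if (is.null(ext)) {
        fml_error("fmlc_schema_unsupported",
                  paste0("complexContent without extension at ",
                         xml2::xml_path(child)))
      }
      base_type <- xml2::xml_attr(ext, "base")
      for (ec in xml2::xml_children(ext)) {
        ecn <- xml2::xml_name(ec)
        if (ecn == "annotation") next
        if (ecn %in% c("sequence")) parse_particles(ec, state)
        else if (ecn == "choice") {
          state$n_choice <- state$n_choice + 1L
          parse_particles(ec, state,
                          choice_group = paste0("choice", state$n_choice))
        } else if (ecn == "attribute") parse_attribute_decl(ec, state)
        else fml_error("fmlc_schema_unsupported",
                       paste0("unsupported XSD construct <", ecn, "> at ",
                              xml2::xml_path(ec)))
      }
    } else if (cn == "simpleContent") {
      ext <- first_child_named(child, "extension")
      if (is.null(ext)) {
        fml_error("fmlc_schema_unsupported",
                  paste0("simpleContent without extension at ",
                         xml2::xml_path(child)))
      }
      text_base <- xml2::xml_attr(ext, "base")
      state$elements[[length(state$elements) + 1L]] <-
        new_element_descriptor(".text", text_base, 0L, 1, "text")
      value_carrier <- "text"
      for (ec in xml2::xml_children(ext)) {
        if (xml2::xml_name(ec) == "attribute") parse_attribute_decl(ec, state)
      }
    } else {
      fml_error("fmlc_schema_unsupported",
                paste0("unsupported XSD construct <", cn, "> at ",
                       xml2::xml_path(child)))
    }
  }

  texts <- sum(vapply(state$elements, function(e) e$kind == "text", logical(1)))
  if (texts > 1) {
    fml_error("fmlc_schema_error",
              paste0("more than one text-content element on type ", nm))
  }

  desc <- new_model_descriptor(nm, target_ns, base_type = base_type,
                               elements = state$elements)
  # FHIR-style primitive: single `value` attribute, nothing else, FHIR family
  if (identical(target_ns, FHIR_NS) && length(state$elements) == 1L &&
      state$elements[[1]]$kind == "attribute" &&
      identical(state$elements[[1]]$name, "value")) {
    desc$is_primitive <- TRUE
    desc$value_carrier <- "attribute"
    desc$primitive_kind <- XS_PRIMITIVE_KINDS[[state$elements[[1]]$type_ref]]
  }
  # text-only simple content with no attributes: unwraps to its text
  if (identical(value_carrier, "text")) {
    attrs <- vapply(state$elements, function(e) e$kind == "attribute", logical(1))
    if (!any(attrs)) {
      desc$is_primitive <- TRUE
      desc$value_carrier <- "text"
      desc$primitive_kind <- XS_PRIMITIVE_KINDS[[state$elements[[1]]$type_ref]]
      if (is.null(desc$primitive_kind)) desc$primitive_kind <- "string"
    }
  }
  desc
}

check_references <- function(models) {
  for (tn in models$order) {
    d <- models_get(models, tn)
    if (!is.null(d$base_type) && !models_has(models, d$base_type)) {
      fml_error("fmlc_resolution_error",
                paste0("dangling base type '", d$base_type, "' on ", tn))
    }
    for (e in d$elements) {
      if (!models_has(models, e$type_ref)) {
        fml_error("fmlc_resolution_error",
                  paste0("dangling type reference '", e$type_ref,
                         "' on element ", tn, ".", e$name))
      }
    }
  }
  invisible(models)
}

# Effective element list: base-chain elements first (extension semantics),
# then the type's own, preserving declaration order.
effective_elements_uncached <- function(models, type_name) {
  d <- models_get(models, type_name)
  own <- d$elements
  if (!is.null(d$base_type) && models_has(models, d$base_type) &&
      !startsWith(d$base_type, "xs:")) {
    c(effective_elements_uncached(models, d$base_type), own)
  } else {
    own
  }
}

effective_elements <- function(models, type_name) {
  type_info(models, type_name)$elements
}

find_element <- function(models, type_name, element) {
  type_info(models, type_name)$by_name[[element]]
}

#' Resolve the declared type of an element on a context type
#'
#' Walks the base-type chain; choice members are addressable only by their
#' concrete member name (as with FHIR `value[x]` renderings such as
#' `valueQuantity`) -- the abstract choice-group name is not a path segment.
#'
#' @param models model set
#' @param context_type qualified type name to start from
#' @param element element or attribute name
#' @return the element's declared type name
#' @export
resolve_element_type <- function(models, context_type, element) {
  d <- models_get(models, context_type,
                  where = paste0("resolving element '", element, "'"))
  e <- find_element(models, context_type, element)
  if (is.null(e)) {
    cands <- vapply(effective_elements(models, context_type),
                    function(x) x$name, character(1))
    fml_error("fmlc_type_resolution_error",
              paste0("no element '", element, "' on type '", context_type,
                     "'; candidates: ", paste(cands, collapse = ", ")))
  }
  e$type_ref
}

# TRUE when the type derives (transitively) from the named base
derives_from <- function(models, type_name, base) {
  while (!is.null(type_name) && models_has(models, type_name)) {
    if (identical(type_name, base)) return(TRUE)
    type_name <- models_get(models, type_name)$base_type
  }
  FALSE
}

is_resource_type <- function(models, type_name) {
  models_has(models, type_name) && type_info(models, type_name)$is_resource
}

# A "resource container" holds exactly one choice whose members are all
# resources (FHIR Bundle.entry.resource pattern).
is_resource_container <- function(models, type_name) {
  type_info(models, type_name)$is_container
}
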