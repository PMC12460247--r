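# Exact XML reader/writer for typed instances. Reading goes through xml2;
# writing is a deterministic text emitter (canonical form: UTF-8, LF, 2-space
# indent, attributes in schema order, no insignificant whitespace).

root_name_for_type <- function(models, type_name) {
  for (nm in names(models$roots)) {
    if (identical(models$roots[[nm]], type_name)) return(nm)
  }
  type_name
}

#' Read an XML instance document into a typed node tree
#'
#' Inputs are assumed valid: unknown elements or attributes are errors with an
#' XPath-like location, not silently dropped.
#'
#' @param doc_text XML text
#' @param models model set
#' @param root_type expected type of the document root
#' @return an instance node
#' @export
read_xml_instance <- function(doc_text, models, root_type) {
  doc <- xml2::read_xml(doc_text)
  d <- models_get(models, root_type)
  ns <- xml2::xml_ns(doc)
  root_ns <- tryCatch(unname(ns[["d1"]]), error = function(e) NA_character_)
  if (!is.na(root_ns) && nzchar(d$namespace) && !identical(root_ns, d$namespace)) {
    fml_error("fmlc_namespace_error",
              paste0("root namespace '", root_ns, "' does not match '",
                     d$namespace, "' of type ", root_type))
  }
  xml2::xml_ns_strip(doc)
  expected <- root_name_for_type(models, root_type)
  if (!identical(xml2::xml_name(doc), expected)) {
    fml_error("fmlc_parse_error",
              paste0("root element <", xml2::xml_name(doc),
                     "> does not match expected <", expected, ">"))
  }
  build_node_from_xml(doc, models, root_type, paste0("/", expected))
}

build_node_from_xml <- function(xnode, models, type_name, path) {
  d <- models_get(models, type_name)
  node <- new_instance_node(models, type_name)

  attrs <- xml2::xml_attrs(xnode)
  attrs <- attrs[!grepl("^xmlns", names(attrs))]
  for (anm in names(attrs)) {
    e <- find_element(models, type_name, anm)
    if (is.null(e) || e$kind != "attribute") {
      fml_error("fmlc_parse_error",
                paste0("unknown attribute '", anm, "' at ", path))
    }
    node_append(node, anm, attrs[[anm]])
  }

  text_el <- NULL
  for (e in effective_elements(models, type_name)) {
    if (e$kind == "text") text_el <- e
  }

  counts <- new.env(parent = emptyenv())
  for (child in xml2::xml_children(xnode)) {
    cnm <- xml2::xml_name(child)
    cpath <- paste0(path, "/", cnm)
    e <- find_element(models, type_name, cnm)
    if (is.null(e) || e$kind != "element") {
      fml_error("fmlc_parse_error",
                paste0("unknown element <", cnm, "> at ", cpath))
    }
    k <- if (exists(cnm, envir = counts, inherits = FALSE))
      get(cnm, envir = counts) else 0L
    assign(cnm, k + 1L, envir = counts)
    if (is.finite(e$max_occurs) && k + 1L > e$max_occurs) {
      fml_error("fmlc_parse_error",
                paste0("element <", cnm, "> exceeds maxOccurs=", e$max_occurs,
                       " at ", cpath))
    }
    if (startsWith(e$type_ref, "xs:")) {
      node_append(node, cnm, xml2::xml_text(child))
    } else {
      ti_e <- type_info(models, e$type_ref)
      if (ti_e$is_primitive) {
        # primitive-model values are stored as raw lexicals
        lex <- if (identical(ti_e$value_carrier, "attribute")) {
          v <- xml2::xml_attr(child, "value")
          if (is.na(v)) fml_error("fmlc_parse_error",
                                  paste0("missing value attribute at ", cpath))
          v
        } else {
          xml2::xml_text(child)
        }
        node_append(node, cnm, lex)
      } else {
        node_append(node, cnm,
                    build_node_from_xml(child, models, e$type_ref, cpath))
      }
    }
  }

  if (length(xml2::xml_children(xnode)) == 0L) {
    txt <- xml2::xml_text(xnode)
    if (nzchar(trimws(txt))) {
      if (is.null(text_el)) {
        fml_error("fmlc_parse_error",
                  paste0("unexpected character data at ", path))
      }
      node_append(node, ".text", txt)
    }
  }
  node
}

#' Serialize a typed node tree to canonical XML text
#'
#' Deterministic byte output: schema-ordered attributes and children, 2-space
#' indentation, LF newlines. Cardinality violations raise a serialization
#' error naming the element.
#'
#' @param node instance node
#' @param models model set
#' @param root_name element name for the root (default: the name the schema
#'   declares for the node's type, or the type name)
#' @return XML text
#' @export
write_xml_instance <- function(node, models, root_name = NULL) {
  if (is.null(root_name)) root_name <- root_name_for_type(models, node$type)
  d <- models_get(models, node$type)
  xmlns <- if (nzchar(d$namespace)) d$namespace else NULL
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    emit_xml_tree(node, models, root_name, xmlns),
    "\n"
  )
}

XML_PADS <- strrep("  ", 0:30)

# Iterative serializer: one pass collects line descriptors into flat
# vectors (kept local so updates are in-place), a second pass renders all
# lines with vectorized escaping and paste0. Canonical form: 2-space
# indent, LF, schema-ordered attributes and children.
emit_xml_tree <- function(root, models, root_name, xmlns = NULL) {
  # line kinds
  OPEN <- 1L; CLOSE <- 2L; VAL <- 3L; TEXT <- 4L; SELF <- 5L; TEXTN <- 6L
  cap <- 256L
  l_kind <- integer(cap); l_depth <- integer(cap)
  l_name <- character(cap); l_val <- character(cap); l_attr <- character(cap)
  n <- 0L

  # frame stack: kind 0 = node to expand, otherwise a pre-rendered line
  scap <- 64L
  s_kind <- integer(scap); s_depth <- integer(scap)
  s_name <- character(scap); s_val <- character(scap)
  s_node <- vector("list", scap)
  m <- 1L
  s_kind[1] <- 0L; s_name[1] <- root_name; s_depth[1] <- 0L
  s_node[[1]] <- root
  first <- TRUE
  while (m > 0L) {
    kind <- s_kind[m]; name <- s_name[m]; depth <- s_depth[m]
    val <- s_val[m]; nd <- s_node[[m]]
    m <- m - 1L
    if (kind != 0L) {
      if (n + 1L > cap) {
        l_kind <- c(l_kind, integer(cap)); l_depth <- c(l_depth, integer(cap))
        l_name <- c(l_name, character(cap)); l_val <- c(l_val, character(cap))
        l_attr <- c(l_attr, character(cap)); cap <- 2L * cap
      }
      n <- n + 1L
      l_kind[n] <- kind; l_name[n] <- name; l_depth[n] <- depth
      l_val[n] <- val; l_attr[n] <- ""
      next
    }

    ti <- type_info(models, nd$type)
    check_cardinality(nd, models, name, ti)
    values <- nd$values

    attr_text <- ""
    if (first && !is.null(xmlns)) {
      attr_text <- paste0(" xmlns=\"", xml_escape_attr(xmlns), "\"")
      first <- FALSE
    }
    for (e in ti$xml_attrs) {
      for (v in values[[e$name]]) {
        attr_text <- paste0(attr_text, " ", e$name, "=\"",
                            xml_escape_attr(primitive_lexical(v)), "\"")
      }
    }

    # gather children in schema order
    kid_i <- 0L
    kid_kind <- integer(8L); kid_name <- character(8L)
    kid_val <- character(8L); kid_node <- vector("list", 8L)
    for (e in ti$xml_elems) {
      items <- values[[e$name]]
      if (is.null(items)) next
      for (v in items) {
        if (kid_i + 1L > length(kid_kind)) {
          kid_kind <- c(kid_kind, integer(length(kid_kind)))
          kid_name <- c(kid_name, character(length(kid_name)))
          kid_val <- c(kid_val, character(length(kid_val)))
          kid_node <- c(kid_node, vector("list", length(kid_node)))
        }
        kid_i <- kid_i + 1L
        kid_name[kid_i] <- e$name
        if (is_fml_node(v)) {
          kid_kind[kid_i] <- 0L
          kid_node[[kid_i]] <- v
        } else if (e$attr_style) {
          kid_kind[kid_i] <- VAL
          kid_val[kid_i] <- primitive_lexical(v)
        } else {
          kid_kind[kid_i] <- TEXT
          kid_val[kid_i] <- primitive_lexical(v)
        }
      }
    }

    if (kid_i > 0L) {
      if (n + 1L > cap) {
        l_kind <- c(l_kind, integer(cap)); l_depth <- c(l_depth, integer(cap))
        l_name <- c(l_name, character(cap)); l_val <- c(l_val, character(cap))
        l_attr <- c(l_attr, character(cap)); cap <- 2L * cap
      }
      n <- n + 1L
      l_kind[n] <- OPEN; l_name[n] <- name; l_depth[n] <- depth
      l_val[n] <- ""; l_attr[n] <- attr_text
      # close frame, then children in reverse so the first child pops first
      while (m + kid_i + 1L > scap) {
        s_kind <- c(s_kind, integer(scap)); s_depth <- c(s_depth, integer(scap))
        s_name <- c(s_name, character(scap)); s_val <- c(s_val, character(scap))
        s_node <- c(s_node, vector("list", scap)); scap <- 2L * scap
      }
      m <- m + 1L
      s_kind[m] <- CLOSE; s_name[m] <- name; s_depth[m] <- depth
      s_val[m] <- ""
      for (i in kid_i:1L) {
        m <- m + 1L
        s_kind[m] <- kid_kind[i]; s_name[m] <- kid_name[i]
        s_depth[m] <- depth + 1L; s_val[m] <- kid_val[i]
        s_node[m] <- kid_node[i]  # single-bracket: keeps NULL slots intact
      }
    } else {
      if (n + 1L > cap) {
        l_kind <- c(l_kind, integer(cap)); l_depth <- c(l_depth, integer(cap))
        l_name <- c(l_name, character(cap)); l_val <- c(l_val, character(cap))
        l_attr <- c(l_attr, character(cap)); cap <- 2L * cap
      }
      n <- n + 1L
      tv <- if (ti$has_text) values[[".text"]] else NULL
      l_name[n] <- name; l_depth[n] <- depth; l_attr[n] <- attr_text
      if (length(tv)) {
        l_kind[n] <- TEXTN; l_val[n] <- primitive_lexical(tv[[1]])
      } else {
        l_kind[n] <- SELF; l_val[n] <- ""
      }
    }
  }

  idx <- seq_len(n)
  kind <- l_kind[idx]; nm <- l_name[idx]; dp <- l_depth[idx]
  vl <- l_val[idx]; at <- l_attr[idx]
  esc_val <- vl
  need <- grepl("[&<>\"]", vl)
  if (any(need)) {
    ev <- vl[need]
    ev <- gsub("&", "&amp;", ev, fixed = TRUE)
    ev <- gsub("<", "&lt;", ev, fixed = TRUE)
    ev <- gsub(">", "&gt;", ev, fixed = TRUE)
    is_attr_val <- kind[need] == 3L
    ev[is_attr_val] <- gsub("\"", "&quot;", ev[is_attr_val], fixed = TRUE)
    esc_val[need] <- ev
  }
  body <- character(n)
  sel <- kind == 1L
  if (any(sel)) body[sel] <- paste0("<", nm[sel], at[sel], ">")
  sel <- kind == 2L
  if (any(sel)) body[sel] <- paste0("</", nm[sel], ">")
  sel <- kind == 3L
  if (any(sel)) body[sel] <- paste0("<", nm[sel], " value=\"", esc_val[sel], "\"/>")
  sel <- kind == 4L
  if (any(sel)) body[sel] <- paste0("<", nm[sel], ">", esc_val[sel], "</", nm[sel], ">")
  sel <- kind == 5L
  if (any(sel)) body[sel] <- paste0("<", nm[sel], at[sel], "/>")
  sel <- kind == 6L
  if (any(sel)) body[sel] <- paste0("<", nm[sel], at[sel], ">", esc_val[sel],
                                    "</", nm[sel], ">")
  paste(paste0(XML_PADS[dp + 1L], body), collapse = "\n")
}

check_cardinality <- function(node, models, where, ti = NULL) {
  if (is.null(ti)) ti <- type_info(models, node$type)
  values <- node$values
  lens <- lengths(values)
  if (!all(names(lens) %in% ti$known_names)) {
    bad <- setdiff(names(lens), ti$known_names)
    fml_error("fmlc_serialization_error",
              paste0("unknown element '", bad[1], "' at ", where))
  }
  for (nm in ti$required) {
    if (!length(values[[nm]])) {
      fml_error("fmlc_serialization_error",
                paste0("required element '", nm, "' missing at ", where))
    }
  }
  if (any(lens > 1L)) {
    for (nm in names(lens)[lens > 1L]) {
      e <- ti$by_name[[nm]]
      if (is.finite(e$max_occurs) && lens[[nm]] > e$max_occurs) {
        fml_error("fmlc_serialization_error",
                  paste0("element '", e$name, "' has ", lens[[nm]],
                         " values, maxOccurs=", e$max_occurs, " at ", where))
      }
    }
  }
  for (g in names(ti$choice_map)) {
    present <- ti$choice_map[[g]][vapply(ti$choice_map[[g]],
                                         function(nm) length(values[[nm]]) > 0,
                                         logical(1))]
    if (length(present) > 1) {
      fml_error("fmlc_serialization_error",
                paste0("choice members ", paste(present, collapse = ", "),
                       " are mutually exclusive at ", where))
    }
  }
}

#' Canonicalize XML text for comparison
#'
#' Re-serializes via a deterministic emitter: 2-space indent, LF, attributes
#' in document order, whitespace-only text dropped. Schema-independent (works
#' on any well-formed XML), used by the canonical diff.
#'
#' @param text XML text
#' @return canonical XML text
#' @export
canonicalize_xml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    fml_error("fmlc_format_error", paste0("not well-formed XML: ",
                                          conditionMessage(e)))
  })
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         paste(canon_xml_node(doc, 0L), collapse = "\n"), "\n")
}

canon_xml_node <- function(xnode, depth) {
  pad <- strrep("  ", depth)
  nm <- xml2::xml_name(xnode)
  attrs <- xml2::xml_attrs(xnode)
  # keep xmlns on the root (xml_attrs omits namespace declarations; recover)
  attr_parts <- character(0)
  if (depth == 0L) {
    ns <- tryCatch(xml2::xml_ns(xnode), error = function(e) NULL)
    if (!is.null(ns) && length(ns) && "d1" %in% names(ns)) {
      attr_parts <- paste0("xmlns=\"", xml_escape_attr(unname(ns[["d1"]])), "\"")
    }
  }
  for (anm in names(attrs)) {
    attr_parts <- c(attr_parts,
                    paste0(anm, "=\"", xml_escape_attr(attrs[[anm]]), "\""))
  }
  attr_text <- if (length(attr_parts)) paste0(" ", paste(attr_parts, collapse = " ")) else ""
  kids <- xml2::xml_children(xnode)
  if (length(kids)) {
    lines <- unlist(lapply(kids, canon_xml_node, depth = depth + 1L))
    c(paste0(pad, "<", nm, attr_text, ">"), lines, paste0(pad, "</", nm, ">"))
  } else {
    txt <- xml2::xml_text(xnode)
    if (nzchar(trimws(txt))) {
      paste0(pad, "<", nm, attr_text, ">", xml_escape_text(txt), "</", nm, ">")
    } else {
      paste0(pad, "<", nm, attr_text, "/>")
    }
  }
}
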