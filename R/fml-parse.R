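# FML text frontend: tokenizer and recursive-descent parser for the supported
# grammar subset (map header, uses, imports, conceptmap blocks, groups with
# rules). Embedded FHIRPath is parsed eagerly at first sight; the original
# expression text is retained for re-serialization.

FML_TRANSFORMS <- c("copy", "create", "translate", "append", "cast",
                    "truncate", "evaluate", "cc", "c", "uuid")

FML_REJECTED_TRANSFORMS <- c("pointer", "dateOp", "escape", "cp", "qty", "id",
                             "reference")

TRANSFORM_ARITY <- list(
  copy = c(1, 1), create = c(0, 1), translate = c(3, 3), append = c(1, Inf),
  cast = c(2, 2), truncate = c(2, 2), evaluate = c(1, 2), cc = c(1, 2),
  c = c(2, 3), uuid = c(0, 0)
)

LIST_MODES <- c("first", "not_first", "last", "not_last", "only_one")

fml_tokenize <- function(text) {
  tokens <- list()
  n <- nchar(text)
  i <- 1L
  line <- 1L
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos, line = line)
  }
  two <- function() substr(text, i, i + 1L)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (two() == "//") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    if (two() == "/*") {
      j <- i + 2L
      while (j <= n && substr(text, j, j + 1L) != "*/") {
        if (substr(text, j, j) == "\n") line <- line + 1L
        j <- j + 1L
      }
      if (j > n) fml_error("fmlc_fml_syntax_error",
                           paste0("unterminated comment at line ", line))
      i <- j + 2L
      next
    }
    start <- i
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      push("IDENT", substr(text, i, j - 1L), start)
      i <- j
    } else if (grepl("^[0-9]$", ch) ||
               (ch == "-" && grepl("^[0-9]$", substr(text, i + 1L, i + 1L)) &&
                length(tokens) && tokens[[length(tokens)]]$type %in%
                  c("EQ", "LPAREN", "COMMA"))) {
      j <- if (ch == "-") i + 1L else i
      while (j <= n && grepl("^[0-9]$", substr(text, j, j))) j <- j + 1L
      if (j <= n && substr(text, j, j) == "." &&
          grepl("^[0-9]$", substr(text, j + 1L, j + 1L))) {
        j <- j + 1L
        while (j <= n && grepl("^[0-9]$", substr(text, j, j))) j <- j + 1L
        push("DECIMAL", substr(text, i, j - 1L), start)
      } else {
        push("INTEGER", substr(text, i, j - 1L), start)
      }
      i <- j
    } else if (ch %in% c("'", "\"")) {
      quote_ch <- ch
      out <- character(0)
      j <- i + 1L
      closed <- FALSE
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          esc <- substr(text, j + 1L, j + 1L)
          out <- c(out, switch(esc, n = "\n", t = "\t", "\\" = "\\",
                               "'" = "'", "\"" = "\"",
                               fml_error("fmlc_fml_syntax_error",
                                         paste0("bad escape \\", esc,
                                                " at line ", line))))
          j <- j + 2L
        } else if (cj == quote_ch) { closed <- TRUE; j <- j + 1L; break }
        else {
          if (cj == "\n") line <- line + 1L
          out <- c(out, cj); j <- j + 1L
        }
      }
      if (!closed) fml_error("fmlc_fml_syntax_error",
                             paste0("unterminated string at line ", line))
      # single quotes: string literal; double quotes: quoted identifier/url
      push(if (quote_ch == "'") "STRING" else "QSTRING",
           paste(out, collapse = ""), start)
      i <- j
    } else if (two() == "->") { push("ARROW", "->", start); i <- i + 2L }
    else if (two() == "<<") { push("LTLT", "<<", start); i <- i + 2L }
    else if (two() == ">>") { push("GTGT", ">>", start); i <- i + 2L }
    else if (two() == "==") { push("RELEQ", "==", start); i <- i + 2L }
    else if (two() == "<=") { push("RELLE", "<=", start); i <- i + 2L }
    else if (two() == ">=") { push("RELGE", ">=", start); i <- i + 2L }
    else if (two() == "--") { push("RELREL", "--", start); i <- i + 2L }
    else if (ch == "(") { push("LPAREN", ch, start); i <- i + 1L }
    else if (ch == ")") { push("RPAREN", ch, start); i <- i + 1L }
    else if (ch == "{") { push("LBRACE", ch, start); i <- i + 1L }
    else if (ch == "}") { push("RBRACE", ch, start); i <- i + 1L }
    else if (ch == ";") { push("SEMI", ch, start); i <- i + 1L }
    else if (ch == ",") { push("COMMA", ch, start); i <- i + 1L }
    else if (ch == ".") { push("DOT", ch, start); i <- i + 1L }
    else if (ch == "=") { push("EQ", ch, start); i <- i + 1L }
    else if (ch == ":") { push("COLON", ch, start); i <- i + 1L }
    else if (ch == "+") { push("PLUS", ch, start); i <- i + 1L }
    else if (ch %in% c("&", "|", "[", "]", "%", "$", "@", "*", "!", "/",
                       "<", ">", "-")) {
      # FHIRPath-only characters: legal inside captured where/check/evaluate
      # expression spans, rejected by the grammar anywhere else
      push("OTHER", ch, start); i <- i + 1L
    }
    else {
      fml_error("fmlc_fml_syntax_error",
                paste0("unexpected character '", ch, "' at line ", line))
    }
  }
  push("EOF", "", n + 1L)
  list(tokens = tokens, text = text)
}

fml_state <- function(tokenized) {
  st <- new.env(parent = emptyenv())
  st$tokens <- tokenized$tokens
  st$text <- tokenized$text
  st$pos <- 1L
  st
}

m_peek <- function(st, k = 0L) st$tokens[[st$pos + k]]
m_next <- function(st) { t <- st$tokens[[st$pos]]; st$pos <- st$pos + 1L; t }
m_err <- function(st, msg) {
  t <- m_peek(st)
  fml_error("fmlc_fml_syntax_error",
            paste0(msg, " near '", t$value, "' at line ", t$line))
}
m_expect <- function(st, type, what = type) {
  t <- m_next(st)
  if (!identical(t$type, type)) {
    fml_error("fmlc_fml_syntax_error",
              paste0("expected ", what, " but found '", t$value,
                     "' at line ", t$line))
  }
  t
}
m_at_kw <- function(st, kw) {
  t <- m_peek(st)
  identical(t$type, "IDENT") && t$value %in% kw
}
m_kw <- function(st, kw) {
  t <- m_expect(st, "IDENT", paste0("keyword '", kw, "'"))
  if (!identical(t$value, kw)) {
    fml_error("fmlc_fml_syntax_error",
              paste0("expected '", kw, "' but found '", t$value,
                     "' at line ", t$line))
  }
  t
}
# identifier: plain or quoted (quoted identifiers are always literal names)
m_ident <- function(st, what = "identifier") {
  t <- m_next(st)
  if (!t$type %in% c("IDENT", "QSTRING")) {
    fml_error("fmlc_fml_syntax_error",
              paste0("expected ", what, " but found '", t$value,
                     "' at line ", t$line))
  }
  t$value
}

#' Parse FML mapping text into a StructureMap AST
#'
#' Embedded FHIRPath expressions (where/check conditions and `evaluate`
#' parameters) are parsed eagerly; the original expression text is kept
#' alongside the parsed tree for re-serialization.
#'
#' @param fml_text FML source text
#' @return a StructureMap AST (class `fml_structuremap`)
#' @export
parse_fml <- function(fml_text) {
  st <- fml_state(fml_tokenize(fml_text))
  m_kw(st, "map")
  url <- m_expect(st, "QSTRING", "map url string")$value
  m_expect(st, "EQ")
  t <- m_next(st)
  name <- if (t$type %in% c("QSTRING", "STRING", "IDENT")) t$value else
    fml_error("fmlc_fml_syntax_error",
              paste0("expected map name at line ", t$line))

  uses <- list(); imports <- character(0); concept_maps <- list(); groups <- list()
  repeat {
    t <- m_peek(st)
    if (identical(t$type, "EOF")) break
    if (m_at_kw(st, "uses")) {
      m_next(st)
      u_url <- m_expect(st, "QSTRING", "model url")$value
      alias <- NULL
      if (m_at_kw(st, "alias")) { m_next(st); alias <- m_ident(st, "alias") }
      m_kw(st, "as")
      mode <- m_ident(st, "mode")
      if (!mode %in% c("source", "target")) m_err(st, "uses mode must be source/target")
      uses[[length(uses) + 1L]] <- list(url = u_url, alias = alias, mode = mode)
    } else if (m_at_kw(st, "imports")) {
      m_next(st)
      imports <- c(imports, m_expect(st, "QSTRING", "import url")$value)
    } else if (m_at_kw(st, "conceptmap")) {
      concept_maps[[length(concept_maps) + 1L]] <- parse_fml_conceptmap(st)
    } else if (m_at_kw(st, "group")) {
      groups[[length(groups) + 1L]] <- parse_fml_group(st, length(groups) + 1L)
    } else {
      m_err(st, "expected uses/imports/conceptmap/group")
    }
  }
  ast <- structure(list(url = url, name = name, uses = uses, imports = imports,
                        concept_maps = concept_maps, groups = groups),
                   class = "fml_structuremap")
  validate_structuremap_ast(ast)
  ast
}

validate_structuremap_ast <- function(ast) {
  gnames <- vapply(ast$groups, function(g) g$name, character(1))
  if (anyDuplicated(gnames)) {
    fml_error("fmlc_fml_syntax_error",
              paste0("duplicate group name: ", gnames[duplicated(gnames)][1]))
  }
  for (g in ast$groups) {
    modes <- vapply(g$inputs, function(i) i$mode, character(1))
    if (!("source" %in% modes) || !("target" %in% modes)) {
      fml_error("fmlc_fml_syntax_error",
                paste0("group '", g$name,
                       "' needs at least one source and one target input"))
    }
  }
  invisible(ast)
}

parse_fml_conceptmap <- function(st) {
  m_kw(st, "conceptmap")
  url <- m_expect(st, "QSTRING", "conceptmap url")$value
  m_expect(st, "LBRACE")
  prefixes <- list()
  # group key: source_system|target_system -> elements
  group_env <- new.env(parent = emptyenv())
  group_order <- character(0)
  repeat {
    if (identical(m_peek(st)$type, "RBRACE")) { m_next(st); break }
    if (m_at_kw(st, "prefix")) {
      m_next(st)
      p <- m_ident(st, "prefix name")
      m_expect(st, "EQ")
      prefixes[[p]] <- m_expect(st, "QSTRING", "system url")$value
    } else {
      sp <- m_ident(st, "source prefix")
      m_expect(st, "COLON")
      sc <- m_code_token(st)
      rel_tok <- m_next(st)
      rel <- switch(rel_tok$type,
        RELEQ = "equivalent", RELLE = "wider", RELGE = "narrower",
        RELREL = "related",
        fml_error("fmlc_fml_syntax_error",
                  paste0("expected relationship operator at line ", rel_tok$line)))
      tp <- m_ident(st, "target prefix")
      m_expect(st, "COLON")
      tc <- m_code_token(st)
      if (is.null(prefixes[[sp]]) || is.null(prefixes[[tp]])) {
        fml_error("fmlc_fml_syntax_error",
                  paste0("undeclared conceptmap prefix at line ", rel_tok$line))
      }
      key <- paste0(prefixes[[sp]], "|", prefixes[[tp]])
      els <- if (exists(key, envir = group_env, inherits = FALSE))
        get(key, envir = group_env) else { group_order <- c(group_order, key); list() }
      els[[length(els) + 1L]] <- list(source_code = sc, relationship = rel,
                                      target_code = tc)
      assign(key, els, envir = group_env)
      if (!key %in% group_order) group_order <- c(group_order, key)
    }
  }
  groups <- lapply(group_order, function(key) {
    ss <- strsplit(key, "|", fixed = TRUE)[[1]]
    list(source_system = ss[1], target_system = ss[2],
         elements = get(key, envir = group_env))
  })
  cm <- list(url = url, groups = groups)
  validate_conceptmap(cm)
  cm
}

validate_conceptmap <- function(cm) {
  seen <- character(0)
  for (g in cm$groups) {
    for (el in g$elements) {
      key <- paste0(g$source_system, "|", el$source_code)
      if (key %in% seen) {
        fml_error("fmlc_fml_syntax_error",
                  paste0("duplicate source code '", el$source_code,
                         "' in conceptmap ", cm$url))
      }
      seen <- c(seen, key)
    }
  }
  invisible(cm)
}

m_code_token <- function(st) {
  t <- m_next(st)
  if (t$type %in% c("IDENT", "QSTRING", "STRING")) return(t$value)
  if (t$type %in% c("INTEGER", "DECIMAL")) {
    # codes like 718-7 tokenize as INTEGER '-'? handled below via IDENT; plain
    # numeric codes arrive here
    return(t$value)
  }
  fml_error("fmlc_fml_syntax_error",
            paste0("expected code at line ", t$line))
}

parse_fml_group <- function(st, index) {
  m_kw(st, "group")
  name <- m_ident(st, "group name")
  m_expect(st, "LPAREN")
  inputs <- list()
  repeat {
    mode <- m_ident(st, "input mode")
    if (!mode %in% c("source", "target")) m_err(st, "input mode must be source/target")
    inm <- m_ident(st, "input name")
    ity <- NULL
    if (identical(m_peek(st)$type, "COLON")) {
      m_next(st)
      ity <- m_ident(st, "input type")
    }
    inputs[[length(inputs) + 1L]] <- list(name = inm, type = ity, mode = mode)
    if (identical(m_peek(st)$type, "COMMA")) m_next(st) else break
  }
  m_expect(st, "RPAREN")
  extends <- NULL
  if (m_at_kw(st, "extends")) { m_next(st); extends <- m_ident(st, "parent group") }
  type_mode <- "none"
  if (identical(m_peek(st)$type, "LTLT")) {
    m_next(st)
    tm <- m_ident(st, "type mode")
    if (identical(tm, "types")) {
      type_mode <- "types"
    } else if (identical(tm, "type")) {
      m_expect(st, "PLUS", "'+' in <<type+>>")
      type_mode <- "type-and-types"
    } else m_err(st, "unknown type mode")
    m_expect(st, "GTGT")
  }
  m_expect(st, "LBRACE")
  rules <- parse_fml_rules(st, paste0("g", index))
  structure(list(name = name, type_mode = type_mode, inputs = inputs,
                 rules = rules, extends = extends), class = "fml_map_group")
}

parse_fml_rules <- function(st, id_prefix) {
  rules <- list()
  repeat {
    if (identical(m_peek(st)$type, "RBRACE")) { m_next(st); break }
    rules[[length(rules) + 1L]] <-
      parse_fml_rule(st, paste0(id_prefix, "_r", length(rules) + 1L))
  }
  rules
}

parse_fml_rule <- function(st, rule_id) {
  source <- parse_rule_source(st)
  targets <- list()
  nested <- list()
  dep_calls <- list()
  if (identical(m_peek(st)$type, "ARROW")) {
    m_next(st)
    repeat {
      targets[[length(targets) + 1L]] <- parse_rule_target(st)
      if (identical(m_peek(st)$type, "COMMA")) m_next(st) else break
    }
  }
  if (m_at_kw(st, "then")) {
    m_next(st)
    if (identical(m_peek(st)$type, "LBRACE")) {
      m_next(st)
      nested <- parse_fml_rules(st, rule_id)
    } else {
      repeat {
        gname <- m_ident(st, "dependent group name")
        m_expect(st, "LPAREN")
        args <- character(0)
        repeat {
          args <- c(args, m_ident(st, "argument variable"))
          if (identical(m_peek(st)$type, "COMMA")) m_next(st) else break
        }
        m_expect(st, "RPAREN")
        dep_calls[[length(dep_calls) + 1L]] <- list(group = gname, args = args)
        if (identical(m_peek(st)$type, "COMMA")) m_next(st) else break
      }
    }
  }
  name <- NULL
  t <- m_peek(st)
  if (t$type %in% c("STRING", "QSTRING")) { name <- t$value; m_next(st) }
  m_expect(st, "SEMI", "';'")
  structure(list(name = name, rule_id = rule_id, source = source,
                 targets = targets, nested_rules = nested,
                 dependent_calls = dep_calls), class = "fml_map_rule")
}

parse_rule_source <- function(st) {
  context <- m_ident(st, "source context variable")
  element <- NULL
  if (identical(m_peek(st)$type, "DOT")) {
    m_next(st)
    element <- m_ident(st, "source element")
  }
  declared_type <- NULL
  variable <- NULL
  condition <- NULL
  check <- NULL
  list_mode <- NULL
  default_value <- NULL
  if (identical(m_peek(st)$type, "COLON")) {
    m_next(st)
    declared_type <- m_ident(st, "declared type")
  }
  repeat {
    if (m_at_kw(st, "default")) {
      m_next(st)
      default_value <- parse_fml_literal(st)
    } else if (m_at_kw(st, LIST_MODES)) {
      list_mode <- m_next(st)$value
    } else if (m_at_kw(st, "as")) {
      m_next(st)
      variable <- m_ident(st, "source variable")
    } else if (m_at_kw(st, "where")) {
      m_next(st)
      condition <- parse_embedded_fhirpath(st)
    } else if (m_at_kw(st, "check")) {
      m_next(st)
      check <- parse_embedded_fhirpath(st)
    } else break
  }
  structure(list(context = context, element = element,
                 declared_type = declared_type, variable = variable,
                 condition = condition, check = check, list_mode = list_mode,
                 default_value = default_value), class = "fml_rule_source")
}

# where/check conditions are parenthesized; the raw text between the
# balancing parens is sliced from the source and handed to the FHIRPath
# parser, so re-serialization can reproduce it verbatim.
parse_embedded_fhirpath <- function(st) {
  open <- m_expect(st, "LPAREN", "'(' before condition")
  depth <- 1L
  start_tok <- m_peek(st)
  last_end <- start_tok$pos
  while (depth > 0L) {
    t <- m_next(st)
    if (identical(t$type, "EOF")) {
      fml_error("fmlc_fml_syntax_error", "unterminated condition")
    }
    if (identical(t$type, "LPAREN")) depth <- depth + 1L
    if (identical(t$type, "RPAREN")) {
      depth <- depth - 1L
      if (depth == 0L) { close_pos <- t$pos; break }
    }
  }
  text <- trimws(substr(st$text, open$pos + 1L, close_pos - 1L))
  list(text = text, ast = parse_fhirpath(text))
}

parse_fml_literal <- function(st) {
  t <- m_next(st)
  switch(t$type,
    STRING = list(kind = "literal", type = "string", value = t$value),
    INTEGER = list(kind = "literal", type = "integer",
                   value = as.integer(t$value)),
    DECIMAL = list(kind = "literal", type = "decimal", value = t$value),
    IDENT = {
      if (t$value %in% c("true", "false")) {
        list(kind = "literal", type = "boolean",
             value = identical(t$value, "true"))
      } else {
        list(kind = "var", name = t$value)
      }
    },
    fml_error("fmlc_fml_syntax_error",
              paste0("expected literal at line ", t$line))
  )
}

parse_rule_target <- function(st) {
  first <- m_ident(st, "target context")
  context <- first
  element <- NULL
  if (identical(m_peek(st)$type, "DOT")) {
    m_next(st)
    element <- m_ident(st, "target element")
  }
  transform <- NULL
  params <- list()
  if (identical(m_peek(st)$type, "EQ")) {
    m_next(st)
    t <- m_peek(st)
    if (identical(t$type, "IDENT") && identical(m_peek(st, 1L)$type, "LPAREN")) {
      fname <- t$value
      if (fname %in% FML_REJECTED_TRANSFORMS) {
        fml_error("fmlc_unsupported_transform",
                  paste0("unsupported transform '", fname, "' at line ", t$line))
      }
      if (!fname %in% FML_TRANSFORMS) {
        fml_error("fmlc_unsupported_transform",
                  paste0("unknown transform '", fname, "' at line ", t$line))
      }
      m_next(st)
      transform <- fname
      params <- parse_transform_params(st, fname)
    } else {
      transform <- "copy"
      params <- list(parse_fml_literal(st))
    }
  } else {
    # no '=': implicit element creation (type resolved from context element)
    transform <- "create"
  }
  variable <- NULL
  if (m_at_kw(st, "as")) {
    m_next(st)
    variable <- m_ident(st, "target variable")
  }
  check_transform_arity(transform, length(params))
  structure(list(context = context, element = element, variable = variable,
                 transform = transform, params = params),
            class = "fml_rule_target")
}

check_transform_arity <- function(transform, n) {
  rng <- TRANSFORM_ARITY[[transform]]
  if (n < rng[1] || (is.finite(rng[2]) && n > rng[2])) {
    fml_error("fmlc_fml_syntax_error",
              paste0("transform ", transform, " takes ", rng[1],
                     if (rng[2] > rng[1]) paste0("-", if (is.finite(rng[2])) rng[2] else "n"),
                     " parameter(s), got ", n))
  }
  invisible(TRUE)
}

parse_transform_params <- function(st, fname) {
  params <- list()
  if (identical(fname, "evaluate")) {
    # evaluate(var, <fhirpath>) or evaluate(<fhirpath>): the final parameter
    # is raw FHIRPath text up to the balancing paren
    st$pos <- st$pos  # LPAREN is next
    open <- m_expect(st, "LPAREN")
    # try: IDENT COMMA -> variable first
    if (identical(m_peek(st)$type, "IDENT") &&
        identical(m_peek(st, 1L)$type, "COMMA")) {
      v <- m_next(st)$value
      m_next(st)  # comma
      params[[1]] <- list(kind = "var", name = v)
      fp_open_pos <- m_peek(st)$pos
    } else {
      fp_open_pos <- m_peek(st)$pos
    }
    depth <- 1L
    repeat {
      t <- m_next(st)
      if (identical(t$type, "EOF")) {
        fml_error("fmlc_fml_syntax_error", "unterminated evaluate()")
      }
      if (identical(t$type, "LPAREN")) depth <- depth + 1L
      if (identical(t$type, "RPAREN")) {
        depth <- depth - 1L
        if (depth == 0L) { close_pos <- t$pos; break }
      }
    }
    text <- trimws(substr(st$text, fp_open_pos, close_pos - 1L))
    params[[length(params) + 1L]] <-
      list(kind = "fhirpath", text = text, ast = parse_fhirpath(text))
    return(params)
  }
  m_expect(st, "LPAREN")
  if (!identical(m_peek(st)$type, "RPAREN")) {
    repeat {
      t <- m_peek(st)
      params[[length(params) + 1L]] <- parse_fml_literal(st)
      if (identical(m_peek(st)$type, "COMMA")) m_next(st) else break
    }
  }
  m_expect(st, "RPAREN")
  params
}
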