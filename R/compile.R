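# StructureMap -> R compiler. One generated function per group, named after
# the FML group (sanitized only); parameter and variable identifiers are
# preserved for traceability; rule names are never emitted. Generated text
# depends only on the runtime helpers and the model schemas.

new_type_env <- function(parent = NULL) {
  list(vars = list(), parent = parent)
}

env_bind <- function(env, fml_name, r_name, type) {
  env$vars[[fml_name]] <- list(r_name = r_name, type = type)
  env
}

env_lookup <- function(env, fml_name) {
  while (!is.null(env)) {
    if (!is.null(env$vars[[fml_name]])) return(env$vars[[fml_name]])
    env <- env$parent
  }
  NULL
}

env_scope_vars <- function(env) {
  out <- character(0)
  while (!is.null(env)) {
    for (nm in names(env$vars)) {
      if (!nm %in% names(out)) out[nm] <- env$vars[[nm]]$r_name
    }
    env <- env$parent
  }
  out
}

compiler_state <- function(ast, models, conceptmaps, emit_fml_comments) {
  st <- new.env(parent = emptyenv())
  st$ast <- ast
  st$models <- models
  st$conceptmaps <- conceptmaps
  st$emit_fml_comments <- emit_fml_comments
  st$symbol_table <- character(0)
  st$tmp <- 0L
  st
}

st_symbol <- function(st, fml_name, r_name) {
  if (!fml_name %in% names(st$symbol_table)) {
    st$symbol_table[[fml_name]] <- r_name
  }
  invisible(st)
}

st_tmp <- function(st, prefix) {
  st$tmp <- st$tmp + 1L
  paste0(".", prefix, st$tmp)
}

#' Compile a StructureMap AST into a standalone R transformation program
#'
#' The generated program defines one function per FML group (same name after
#' identifier sanitization), an entry runner, and a command-line `main`
#' accepting `-s <source> -t <target>` with the format inferred from the file
#' extension. Executing it on any input is equivalent to
#' [interpret_map()] up to generated UUIDs.
#'
#' @param ast StructureMap AST
#' @param models model set covering source and target families
#' @param conceptmaps named list of concept map definitions available to
#'   `translate` (embedded ones are taken from the AST automatically)
#' @param schema_paths schema file paths recorded in the program so it can
#'   rebuild its model set when run standalone
#' @param conceptmap_files external ConceptMap file paths recorded likewise
#' @param emit_fml_comments embed reconstructed FML clauses as comments
#' @return a `fml_generated_program`: list with `source_text`,
#'   `symbol_table`, `entry_point`, `required_models`,
#'   `required_conceptmaps`
#' @export
compile_map <- function(ast, models, conceptmaps = list(),
                        schema_paths = character(0),
                        conceptmap_files = character(0),
                        emit_fml_comments = FALSE) {
  for (cm in ast$concept_maps) conceptmaps[[cm$url]] <- cm
  st <- compiler_state(ast, models, conceptmaps, emit_fml_comments)

  sanitized <- vapply(ast$groups, function(g) sanitize_identifier(g$name),
                      character(1))
  dup <- duplicated(sanitized)
  if (any(dup)) {
    orig <- vapply(ast$groups, function(g) g$name, character(1))
    clash <- orig[sanitized %in% sanitized[dup]]
    fml_error("fmlc_compile_error",
              paste0("group names collide after sanitization: ",
                     paste(clash, collapse = " vs ")))
  }

  st$group_types <- infer_group_input_types(st)
  fn_blocks <- lapply(ast$groups, function(g) compile_group(g, st))

  entry <- ast$groups[[1]]
  io_types <- entry_io_types(entry, st)

  header <- c(
    paste0("# Transformation program generated from map \"", ast$name, "\""),
    paste0("# ", io_types$source, " -> ", io_types$target),
    ""
  )
  meta <- c(
    "fml__metadata <- list(",
    paste0("  map_url = ", r_string(ast$url), ","),
    paste0("  entry = ", r_string(sanitize_identifier(entry$name)), ","),
    paste0("  source_type = ", r_string(io_types$source), ","),
    paste0("  target_type = ", r_string(io_types$target), ","),
    paste0("  schemas = ", r_char_vector(schema_paths), ","),
    paste0("  conceptmap_files = ", r_char_vector(conceptmap_files), ","),
    "  conceptmaps_json = c(",
    paste0("    ",
           paste(vapply(unname(st$conceptmaps),
                        function(cm) r_string(serialize_conceptmap(cm, "json")),
                        character(1)),
                 collapse = ",\n    ")),
    "  )",
    ")",
    ""
  )
  if (!length(st$conceptmaps)) {
    meta <- c(
      "fml__metadata <- list(",
      paste0("  map_url = ", r_string(ast$url), ","),
      paste0("  entry = ", r_string(sanitize_identifier(entry$name)), ","),
      paste0("  source_type = ", r_string(io_types$source), ","),
      paste0("  target_type = ", r_string(io_types$target), ","),
      paste0("  schemas = ", r_char_vector(schema_paths), ","),
      paste0("  conceptmap_files = ", r_char_vector(conceptmap_files), ","),
      "  conceptmaps_json = character(0)",
      ")",
      ""
    )
  }
  runner <- c(
    "fml__context <- function(seed = NULL, now = NULL) {",
    "  models <- fmlc::load_model_set(fml__metadata$schemas)",
    "  ctx <- fmlc::new_execution_context(models, seed = seed, now = now)",
    "  for (txt in fml__metadata$conceptmaps_json) {",
    "    fmlc::register_conceptmap(ctx, fmlc::read_conceptmap(txt, \"json\"))",
    "  }",
    "  for (f in fml__metadata$conceptmap_files) {",
    "    cm_text <- paste(readLines(f, warn = FALSE), collapse = \"\\n\")",
    "    fmlc::register_conceptmap(ctx, fmlc::read_conceptmap(cm_text))",
    "  }",
    "  ctx",
    "}",
    "",
    "fml__run <- function(source_node, ctx) {",
    paste0("  .target <- fml_create(ctx, ",
           r_string(io_types$target), ")"),
    paste0("  ", sanitize_identifier(entry$name), "(source_node, .target, ctx)"),
    "  .target",
    "}",
    "",
    "fml__main <- function(argv = commandArgs(trailingOnly = TRUE)) {",
    "  src <- NULL; tgt <- NULL; seed <- NULL",
    "  i <- 1L",
    "  while (i <= length(argv)) {",
    "    a <- argv[[i]]",
    "    if (a == \"-s\") { src <- argv[[i + 1L]]; i <- i + 2L }",
    "    else if (a == \"-t\") { tgt <- argv[[i + 1L]]; i <- i + 2L }",
    "    else if (a == \"--seed\") { seed <- as.integer(argv[[i + 1L]]); i <- i + 2L }",
    "    else stop(\"unknown argument: \", a)",
    "  }",
    "  if (is.null(src) || is.null(tgt)) stop(\"usage: -s <source> -t <target>\")",
    "  ctx <- fml__context(seed = seed)",
    "  src_text <- paste(readLines(src, warn = FALSE), collapse = \"\\n\")",
    "  source_node <- if (grepl(\"\\\\.json$\", src)) {",
    "    fmlc::read_fhir_json(src_text, ctx$models, fml__metadata$source_type)",
    "  } else {",
    "    fmlc::read_xml_instance(src_text, ctx$models, fml__metadata$source_type)",
    "  }",
    "  out_node <- fml__run(source_node, ctx)",
    "  out_text <- if (grepl(\"\\\\.json$\", tgt)) {",
    "    fmlc::write_fhir_json(out_node, ctx$models)",
    "  } else {",
    "    fmlc::write_xml_instance(out_node, ctx$models)",
    "  }",
    "  writeLines(out_text, tgt, sep = \"\")",
    "  invisible(0L)",
    "}",
    "",
    "if (sys.nframe() == 0L) {",
    "  suppressPackageStartupMessages(library(fmlc))",
    "  fml__main()",
    "}"
  )

  source_text <- paste(c(header, unlist(fn_blocks), meta, runner, ""),
                       collapse = "\n")
  structure(list(
    source_text = source_text,
    symbol_table = st$symbol_table,
    entry_point = sanitize_identifier(entry$name),
    required_models = schema_paths,
    required_conceptmaps = names(st$conceptmaps) %||% character(0)
  ), class = "fml_generated_program")
}

r_char_vector <- function(x) {
  if (!length(x)) return("character(0)")
  paste0("c(", paste(vapply(x, r_string, character(1)), collapse = ", "), ")")
}

# entry group input types resolved through the uses aliases
entry_io_types <- function(group, st) {
  src <- NULL; tgt <- NULL
  for (inp in group$inputs) {
    ty <- resolve_input_type(inp$type, st)
    if (identical(inp$mode, "source") && is.null(src)) src <- ty
    if (identical(inp$mode, "target") && is.null(tgt)) tgt <- ty
  }
  if (is.null(src) || is.null(tgt) || is.na(src) || is.na(tgt)) {
    fml_error("fmlc_compile_error",
              paste0("entry group '", group$name,
                     "' needs typed source and target inputs"))
  }
  list(source = src, target = tgt)
}

resolve_input_type <- function(type_text, st) {
  if (is.null(type_text)) return(NA_character_)
  if (models_has(st$models, type_text)) return(type_text)
  # an alias declared in `uses` naming a model type
  for (u in st$ast$uses) {
    if (identical(u$alias, type_text)) return(type_text)
  }
  NA_character_
}

# Propagate static types into untyped group inputs from their call sites
# (fixpoint over dependent calls): groups reached only through typed calls
# compile with full static dispatch instead of runtime type resolution.
infer_group_input_types <- function(st) {
  ast <- st$ast
  models <- st$models
  types <- list()
  for (g in ast$groups) {
    types[[g$name]] <- vapply(g$inputs, function(i)
      resolve_input_type(i$type, st), character(1))
  }
  resolve_elem <- function(ctx_type, element) {
    if (is.na(ctx_type %||% NA_character_)) return(NA_character_)
    tryCatch(resolve_element_type(models, ctx_type, element),
             error = function(e) NA_character_)
  }
  changed <- TRUE
  iter <- 0L
  while (changed && iter <= length(ast$groups) + 1L) {
    changed <- FALSE
    iter <- iter + 1L
    walk_rule <- function(rule, env) {
      s <- rule$source
      ct <- env[[s$context]] %||% NA_character_
      ftype <- if (!is.null(s$declared_type)) s$declared_type
               else if (is.null(s$element)) ct
               else resolve_elem(ct, s$element)
      if (!is.null(s$variable)) env[[s$variable]] <- ftype
      for (t in rule$targets) {
        et <- if (!is.null(t$element)) {
          resolve_elem(env[[t$context]] %||% NA_character_, t$element)
        } else NA_character_
        vt <- switch(t$transform,
          create = if (length(t$params) &&
                       identical(t$params[[1]]$kind, "literal"))
                     t$params[[1]]$value else et,
          copy = if (identical(t$params[[1]]$kind, "var"))
                   env[[t$params[[1]]$name]] %||% et else et,
          cc = "CodeableConcept",
          c = "Coding",
          et)
        if (!is.null(t$variable)) env[[t$variable]] <- vt %||% NA_character_
      }
      for (nested in rule$nested_rules) env <- walk_rule(nested, env)
      for (dep in rule$dependent_calls) {
        callee <- types[[dep$group]]
        if (is.null(callee)) next
        for (i in seq_along(dep$args)) {
          if (i > length(callee)) break
          at <- env[[dep$args[[i]]]] %||% NA_character_
          if (is.na(callee[[i]]) && !is.na(at)) {
            callee[[i]] <- at
            changed <<- TRUE
          }
        }
        types[[dep$group]] <<- callee
      }
      env
    }
    for (g in ast$groups) {
      env <- list()
      tv <- types[[g$name]]
      for (i in seq_along(g$inputs)) env[[g$inputs[[i]]$name]] <- tv[[i]]
      for (rule in g$rules) env <- walk_rule(rule, env)
    }
  }
  types
}

#' @rdname compile_map
#' @param group a map group from the AST
#' @param st internal compiler state (used by [compile_map()])
#' @export
compile_group <- function(group, st) {
  fn_name <- sanitize_identifier(group$name)
  st_symbol(st, group$name, fn_name)

  env <- new_type_env()
  params <- character(0)
  input_types <- st$group_types[[group$name]] %||%
    vapply(group$inputs, function(i) resolve_input_type(i$type, st),
           character(1))
  for (i in seq_along(group$inputs)) {
    inp <- group$inputs[[i]]
    r_name <- sanitize_identifier(inp$name)
    if (r_name %in% params) {
      fml_error("fmlc_compile_error",
                paste0("input names collide after sanitization in group '",
                       group$name, "': ", inp$name))
    }
    params <- c(params, r_name)
    env <- env_bind(env, inp$name, r_name, input_types[[i]])
    st_symbol(st, inp$name, r_name)
  }

  body <- character(0)
  if (!is.null(group$extends)) {
    parent <- NULL
    for (g in st$ast$groups) if (identical(g$name, group$extends)) parent <- g
    if (is.null(parent)) {
      fml_error("fmlc_compile_error",
                paste0("group '", group$name, "' extends unknown group '",
                       group$extends, "'"))
    }
    n <- length(parent$inputs)
    body <- c(body, paste0("  ", sanitize_identifier(parent$name), "(",
                           paste(c(params[seq_len(n)], "ctx"), collapse = ", "),
                           ")"))
  }
  for (rule in group$rules) {
    body <- c(body, compile_rule(rule, env, st, indent = 1L))
  }
  c(paste0(fn_name, " <- function(", paste(c(params, "ctx"), collapse = ", "),
           ") {"),
    body,
    "}",
    "")
}

pad_lines <- function(lines, indent) paste0(strrep("  ", indent), lines)

# Element read specialized on the statically-known context type; falls back
# to runtime dynamic dispatch (fp_get) when the type or element is unknown.
emit_element_read <- function(binding, element, st) {
  e <- if (!is.na(binding$type %||% NA_character_) &&
           models_has(st$models, binding$type)) {
    find_element(st$models, binding$type, element)
  } else NULL
  if (is.null(e)) {
    return(paste0("fp_get(", binding$r_name, ", ", r_string(element), ", ctx)"))
  }
  kind <- element_primitive_kind(e, st$models)
  if (is.null(kind) || kind %in% c("string", "uri")) {
    # complex children and string-kind lexicals are stored in typed form
    paste0("fml_children(", binding$r_name, ", ", r_string(element), ")")
  } else {
    paste0("fml_raw_typed(", binding$r_name, ", ", r_string(element), ", ",
           r_string(kind), ")")
  }
}

#' Compile one map rule to R statements
#'
#' @param rule map rule
#' @param env lexical type environment
#' @param st compiler state
#' @param indent indentation level
#' @return character vector of statement lines
#' @keywords internal
compile_rule <- function(rule, env, st, indent) {
  s <- rule$source
  binding <- env_lookup(env, s$context)
  if (is.null(binding)) {
    fml_error("fmlc_compile_error",
              paste0("variable '", s$context, "' not in scope (rule ",
                     rule$rule_id, ")"))
  }
  scope <- env_scope_vars(env)
  out <- character(0)
  if (st$emit_fml_comments) {
    out <- c(out, pad_lines(paste0("# ", fml_clause_comment(rule)), indent))
  }

  focus_type <- NA_character_
  if (!is.null(s$element)) {
    focus_type <- if (!is.null(s$declared_type)) s$declared_type else
      tryCatch(resolve_element_type(st$models, binding$type, s$element),
               error = function(e) NA_character_)
  } else {
    focus_type <- if (!is.null(s$declared_type)) s$declared_type else binding$type
  }

  simple <- is.null(s$element) && is.null(s$condition) && is.null(s$list_mode) &&
    is.null(s$default_value) && is.null(s$check)

  if (simple) {
    inner_env <- new_type_env(parent = env)
    focus_r <- binding$r_name
    if (!is.null(s$variable)) {
      vr <- sanitize_identifier(s$variable)
      out <- c(out, pad_lines(paste0(vr, " <- ", binding$r_name), indent))
      inner_env <- env_bind(inner_env, s$variable, vr, focus_type)
      st_symbol(st, s$variable, vr)
      focus_r <- vr
    }
    out <- c(out, compile_rule_body(rule, inner_env, st, indent,
                                    focus_r = focus_r,
                                    focus_type = focus_type))
    return(out)
  }

  items_var <- st_tmp(st, "items")
  src_expr <- if (!is.null(s$element)) {
    emit_element_read(binding, s$element, st)
  } else {
    # rule variables always bind single items
    paste0("list(", binding$r_name, ")")
  }
  out <- c(out, pad_lines(paste0(items_var, " <- ", src_expr), indent))
  if (!is.null(s$default_value)) {
    out <- c(out, pad_lines(paste0(
      "if (length(", items_var, ") == 0L) ", items_var, " <- list(",
      literal_r_value(s$default_value), ")"), indent))
  }
  if (!is.null(s$condition)) {
    pred <- emit_expression(s$condition$ast, focus_var = ".this",
                            scope_vars = scope,
                            static_type = if (is.na(focus_type)) NULL else focus_type,
                            models = st$models)
    out <- c(out, pad_lines(paste0(items_var, " <- fp_where(", items_var,
                                   ", function(.this) ", pred, ")"), indent))
  }
  if (!is.null(s$list_mode)) {
    out <- c(out, pad_lines(paste0(items_var, " <- fml_listmode(", items_var,
                                   ", ", r_string(s$list_mode), ")"), indent))
  }

  loop_var <- if (!is.null(s$variable)) sanitize_identifier(s$variable) else
    st_tmp(st, "it")
  if (!is.null(s$variable)) st_symbol(st, s$variable, loop_var)
  inner_env <- new_type_env(parent = env)
  if (!is.null(s$variable)) {
    inner_env <- env_bind(inner_env, s$variable, loop_var, focus_type)
  }
  out <- c(out, pad_lines(paste0("for (", loop_var, " in ", items_var, ") {"),
                          indent))
  if (!is.null(s$check)) {
    chk <- emit_expression(s$check$ast, focus_var = loop_var,
                           scope_vars = env_scope_vars(inner_env),
                           static_type = if (is.na(focus_type)) NULL else focus_type,
                           models = st$models)
    out <- c(out, pad_lines(paste0("fml_check(", chk, ", ",
                                   r_string(s$check$text), ")"), indent + 1L))
  }
  out <- c(out, compile_rule_body(rule, inner_env, st, indent + 1L,
                                  focus_r = loop_var, focus_type = focus_type))
  out <- c(out, pad_lines("}", indent))
  out
}

compile_rule_body <- function(rule, env, st, indent, focus_r, focus_type) {
  out <- character(0)
  created_types <- list()
  for (t in rule$targets) {
    res <- compile_transform(t, env, st, indent,
                             focus_r = focus_r, focus_type = focus_type,
                             rule = rule)
    out <- c(out, res$lines)
    env <- res$env
    if (!is.null(t$variable) && !is.null(res$var_type)) {
      created_types[[t$variable]] <- res$var_type
    }
  }
  for (nested in rule$nested_rules) {
    out <- c(out, compile_rule(nested, env, st, indent))
  }
  for (dep in rule$dependent_calls) {
    grp <- resolve_dependent_group(list(group = dep$group, args = dep$args),
                                   st$ast)
    args <- vapply(dep$args, function(a) {
      b <- env_lookup(env, a)
      if (is.null(b)) {
        fml_error("fmlc_compile_error",
                  paste0("variable '", a, "' not in scope (rule ",
                         rule$rule_id, ")"))
      }
      b$r_name
    }, character(1))
    out <- c(out, pad_lines(paste0(sanitize_identifier(grp$name), "(",
                                   paste(c(args, "ctx"), collapse = ", "), ")"),
                            indent))
  }
  # type-based dependent resolution: a rule that creates a typed target from
  # a typed source and has no explicit continuation may match a <<types>>
  # group
  if (!length(rule$nested_rules) && !length(rule$dependent_calls) &&
      !is.null(rule$source$variable)) {
    sb <- env_lookup(env, rule$source$variable)
    for (t in rule$targets) {
      if (is.null(t$variable) || !identical(t$transform, "create")) next
      tb <- env_lookup(env, t$variable)
      if (is.null(sb) || is.null(tb)) next
      if (is.na(sb$type %||% NA) || is.na(tb$type %||% NA)) next
      grp <- tryCatch(
        resolve_dependent_group(list(source_type = sb$type,
                                     target_type = tb$type), st$ast),
        fmlc_no_type_group = function(e) NULL)
      if (!is.null(grp)) {
        out <- c(out, pad_lines(paste0(sanitize_identifier(grp$name), "(",
                                       sb$r_name, ", ", tb$r_name, ", ctx)"),
                                indent))
      }
    }
  }
  out
}

literal_r_value <- function(lit) {
  switch(lit$type,
    string = r_string(lit$value),
    integer = paste0(lit$value, "L"),
    decimal = paste0("fml_decimal(", r_string(lit$value), ")"),
    boolean = if (lit$value) "TRUE" else "FALSE"
  )
}

param_r_expr <- function(p, env, rule_id) {
  if (identical(p$kind, "var")) {
    b <- env_lookup(env, p$name)
    if (is.null(b)) {
      fml_error("fmlc_compile_error",
                paste0("variable '", p$name, "' not in scope (rule ",
                       rule_id, ")"))
    }
    return(b$r_name)
  }
  if (identical(p$kind, "literal")) return(literal_r_value(p))
  fml_error("fmlc_compile_error", "unexpected parameter kind")
}

param_literal_string <- function(p, what) {
  if (!identical(p$kind, "literal") || !identical(p$type, "string")) {
    fml_error("fmlc_compile_error", paste0(what, " must be a string literal"))
  }
  p$value
}

#' Compile one rule target (transform application) to statements
#'
#' @param target rule target
#' @param env lexical type environment
#' @param st compiler state
#' @param indent indentation level
#' @param focus_r R name of the rule's focus binding
#' @param focus_type static type of the focus (NA when unknown)
#' @param rule enclosing rule (for diagnostics)
#' @return list with `lines`, updated `env`, `var_type`
#' @keywords internal
compile_transform <- function(target, env, st, indent, focus_r, focus_type,
                              rule) {
  t <- target
  var_type <- NULL
  ctx_binding <- NULL
  if (!is.null(t$element)) {
    ctx_binding <- env_lookup(env, t$context)
    if (is.null(ctx_binding)) {
      fml_error("fmlc_compile_error",
                paste0("variable '", t$context, "' not in scope (rule ",
                       rule$rule_id, ")"))
    }
  }

  elem_type <- NA_character_
  if (!is.null(t$element) && !is.null(ctx_binding) &&
      !is.na(ctx_binding$type %||% NA)) {
    elem_type <- tryCatch(
      resolve_element_type(st$models, ctx_binding$type, t$element),
      error = function(e) NA_character_)
  }

  # shape of the computed value, when the compiler can prove it:
  # "scalar" (typed primitive, never a collection), "node", or "unknown"
  val_class <- "unknown"
  value_expr <- switch(t$transform,
    copy = {
      p <- t$params[[1]]
      if (identical(p$kind, "literal")) {
        var_type <- NULL
        val_class <- "scalar"
        literal_r_value(p)  # literals embedded directly
      } else {
        b <- env_lookup(env, p$name)
        if (!is.null(b) && !is.na(b$type %||% NA_character_)) {
          if (startsWith(b$type, "xs:")) {
            val_class <- "scalar"
          } else if (models_has(st$models, b$type)) {
            val_class <- if (type_info(st$models, b$type)$is_primitive)
              "scalar" else "node"
          }
        }
        paste0("fml_copy(", param_r_expr(p, env, rule$rule_id), ")")
      }
    },
    create = {
      ty <- if (length(t$params)) {
        param_literal_string(t$params[[1]], "create type")
      } else if (!is.na(elem_type)) {
        elem_type
      } else NULL
      val_class <- "node"
      if (is.null(ty)) {
        if (is.null(t$element)) {
          fml_error("fmlc_compile_error",
                    paste0("create without type or element (rule ",
                           rule$rule_id, ")"))
        }
        # static type unknown: resolve the element's type at run time
        var_type <- NA_character_
        paste0("fml_create(ctx, resolve_element_type(ctx$models, ",
               ctx_binding$r_name, "$type, ", r_string(t$element), "))")
      } else {
        var_type <- ty
        rk <- if (is_resource_type(st$models, ty)) r_string(ty) else "NULL"
        paste0("fml_new_node(", r_string(ty), ", ", rk, ")")
      }
    },
    translate = {
      src <- param_r_expr(t$params[[1]], env, rule$rule_id)
      url <- param_literal_string(t$params[[2]], "translate map url")
      outp <- param_literal_string(t$params[[3]], "translate output mode")
      if (!outp %in% c("code", "Coding")) {
        fml_error("fmlc_compile_error",
                  paste0("translate output must be 'code' or 'Coding', got '",
                         outp, "'"))
      }
      if (!url %in% names(st$conceptmaps)) {
        fml_error("fmlc_compile_error",
                  paste0("translate references unregistered concept map ", url))
      }
      val_class <- if (identical(outp, "Coding")) "node" else "scalar"
      paste0("fml_translate(ctx, ", src, ", ", r_string(url), ", ",
             r_string(outp), ")")
    },
    append = {
      args <- vapply(t$params, param_r_expr, character(1), env = env,
                     rule_id = rule$rule_id)
      val_class <- "scalar"
      paste0("fml_append(", paste(args, collapse = ", "), ")")
    },
    cast = {
      src <- param_r_expr(t$params[[1]], env, rule$rule_id)
      ty <- param_literal_string(t$params[[2]], "cast type")
      if (is.null(CAST_TABLE[[ty]])) {
        fml_error("fmlc_compile_error",
                  paste0("unsupported cast target '", ty, "'"))
      }
      val_class <- "scalar"
      paste0("fml_cast_lex(", src, ", ", r_string(ty), ")")
    },
    truncate = {
      src <- param_r_expr(t$params[[1]], env, rule$rule_id)
      len <- t$params[[2]]
      if (!identical(len$kind, "literal") || !identical(len$type, "integer")) {
        fml_error("fmlc_compile_error", "truncate length must be an integer")
      }
      val_class <- "scalar"
      paste0("fml_truncate(", src, ", ", len$value, "L)")
    },
    evaluate = {
      fp <- t$params[[length(t$params)]]
      if (!identical(fp$kind, "fhirpath")) {
        fml_error("fmlc_compile_error", "evaluate needs a FHIRPath parameter")
      }
      focus <- focus_r
      ftype <- focus_type
      if (length(t$params) == 2L) {
        b <- env_lookup(env, t$params[[1]]$name)
        if (is.null(b)) {
          fml_error("fmlc_compile_error",
                    paste0("variable '", t$params[[1]]$name,
                           "' not in scope (rule ", rule$rule_id, ")"))
        }
        focus <- b$r_name
        ftype <- b$type
      }
      emit_expression(fp$ast, focus_var = focus,
                      scope_vars = env_scope_vars(env),
                      static_type = if (is.na(ftype %||% NA)) NULL else ftype,
                      models = st$models)
    },
    cc = {
      args <- vapply(t$params, param_r_expr, character(1), env = env,
                     rule_id = rule$rule_id)
      val_class <- "node"
      paste0("fml_cc(ctx, ", paste(args, collapse = ", "), ")")
    },
    c = {
      args <- vapply(t$params, param_r_expr, character(1), env = env,
                     rule_id = rule$rule_id)
      val_class <- "node"
      paste0("fml_c(ctx, ", paste(args, collapse = ", "), ")")
    },
    uuid = {
      val_class <- "scalar"
      "new_uuid(ctx)"
    },
    fml_error("fmlc_compile_error",
              paste0("unsupported transform '", t$transform, "'"))
  )

  lines <- character(0)
  if (!is.null(t$element)) {
    e_desc <- if (!is.na(ctx_binding$type %||% NA_character_) &&
                  models_has(st$models, ctx_binding$type)) {
      find_element(st$models, ctx_binding$type, t$element)
    } else NULL
    stmt <- if (is.null(e_desc)) {
      paste0("fml_assign(", ctx_binding$r_name, ", ",
             r_string(t$element), ", ", value_expr, ", ctx)")
    } else {
      replace <- is.finite(e_desc$max_occurs) && e_desc$max_occurs <= 1
      kind <- element_primitive_kind(e_desc, st$models)
      if (!is.null(kind)) {
        lit <- if (identical(t$transform, "copy") &&
                   identical(t$params[[1]]$kind, "literal")) t$params[[1]]
        if (!is.null(lit)) {
          # literals are embedded directly as their lexical form
          lex <- switch(lit$type,
            string = lit$value,
            integer = as.character(lit$value),
            decimal = canonical_decimal(lit$value),
            boolean = if (lit$value) "true" else "false")
          paste0(if (replace) "fml_set1(" else "fml_add1(",
                 ctx_binding$r_name, ", ", r_string(t$element), ", ",
                 r_string(lex), ")")
        } else if (identical(val_class, "scalar")) {
          # value proven to be a typed scalar: store it directly
          paste0(if (replace) "fml_set1(" else "fml_add1(",
                 ctx_binding$r_name, ", ", r_string(t$element), ", ",
                 value_expr, ")")
        } else {
          paste0("fml_assign_lex(", ctx_binding$r_name, ", ",
                 r_string(t$element), ", ", value_expr, ", ",
                 if (replace) "TRUE" else "FALSE", ", ctx)")
        }
      } else if (identical(val_class, "node")) {
        paste0(if (replace) "fml_set1(" else "fml_add1(",
               ctx_binding$r_name, ", ", r_string(t$element), ", ",
               value_expr, ")")
      } else {
        paste0("fml_assign_node(", ctx_binding$r_name, ", ",
               r_string(t$element), ", ", value_expr, ", ",
               if (replace) "TRUE" else "FALSE", ", ctx)")
      }
    }
    if (!is.null(t$variable)) {
      vr <- sanitize_identifier(t$variable)
      stmt <- paste0(vr, " <- ", stmt)
      bind_type <- if (!is.null(var_type)) var_type else elem_type
      env <- env_bind(env, t$variable, vr, bind_type)
      st_symbol(st, t$variable, vr)
    }
    lines <- pad_lines(stmt, indent)
  } else if (!is.null(t$variable)) {
    vr <- sanitize_identifier(t$variable)
    lines <- pad_lines(paste0(vr, " <- ", value_expr), indent)
    env <- env_bind(env, t$variable, vr, var_type %||% NA_character_)
    st_symbol(st, t$variable, vr)
  } else {
    fml_error("fmlc_compile_error",
              paste0("target without element or variable (rule ",
                     rule$rule_id, ")"))
  }
  # when create resolved its type only at run time the binding type is NA
  if (!is.null(t$variable) && is.null(var_type) && !is.na(elem_type)) {
    var_type <- elem_type
  }
  list(lines = lines, env = env, var_type = var_type)
}

fml_clause_comment <- function(rule) {
  s <- rule$source
  src <- paste0(s$context, if (!is.null(s$element)) paste0(".", s$element))
  tg <- vapply(rule$targets, function(t) {
    paste0(t$context, if (!is.null(t$element)) paste0(".", t$element),
           " = ", t$transform)
  }, character(1))
  paste0(src, if (length(tg)) paste0(" -> ", paste(tg, collapse = ", ")))
}

#' Resolve a dependent group by explicit name or by input types
#'
#' Explicit calls always win; type-based resolution selects the unique
#' `<<types>>` group whose first source/target input types match. Zero
#' matches and ambiguous matches are errors (no silent pick).
#'
#' @param call_or_types either `list(group=, args=)` or
#'   `list(source_type=, target_type=)`
#' @param ast StructureMap AST
#' @return the matching map group
#' @export
resolve_dependent_group <- function(call_or_types, ast) {
  if (!is.null(call_or_types$group)) {
    for (g in ast$groups) {
      if (identical(g$name, call_or_types$group)) return(g)
    }
    fml_error("fmlc_compile_error",
              paste0("dependent call to unknown group '",
                     call_or_types$group, "'"))
  }
  stype <- call_or_types$source_type
  ttype <- call_or_types$target_type
  matches <- list()
  for (g in ast$groups) {
    if (identical(g$type_mode, "none")) next
    src_in <- NULL; tgt_in <- NULL
    for (inp in g$inputs) {
      if (identical(inp$mode, "source") && is.null(src_in)) src_in <- inp
      if (identical(inp$mode, "target") && is.null(tgt_in)) tgt_in <- inp
    }
    if (identical(src_in$type, stype) && identical(tgt_in$type, ttype)) {
      matches[[length(matches) + 1L]] <- g
    }
  }
  if (!length(matches)) {
    stop(structure(
      class = c("fmlc_no_type_group", "fmlc_error", "error", "condition"),
      list(message = paste0("no type-mode group for (", stype, ", ", ttype, ")"),
           call = sys.call(-1))))
  }
  if (length(matches) > 1) {
    fml_error("fmlc_compile_error",
              paste0("ambiguous type-mode groups for (", stype, ", ", ttype,
                     "): ", paste(vapply(matches, function(g) g$name,
                                         character(1)), collapse = ", ")))
  }
  matches[[1]]
}
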