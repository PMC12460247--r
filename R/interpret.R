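# Reference interpreter: executes a StructureMap AST directly over instance
# nodes by AST walking. It shares the runtime helpers (assign, translate,
# now, uuid, FHIRPath evaluation) with compiled programs, so the two engines
# differ only in dispatch. This path is the conformance oracle; it is
# expected to be slower than compiled execution.

#' Interpret a StructureMap over a source document
#'
#' @param ast StructureMap AST
#' @param source source instance node
#' @param models model set
#' @param conceptmaps list of concept map definitions (embedded ones are
#'   registered automatically)
#' @param ctx optional execution context (created when omitted)
#' @return the target instance node
#' @export
interpret_map <- function(ast, source, models, conceptmaps = list(),
                          ctx = NULL) {
  if (is.null(ctx)) ctx <- new_execution_context(models)
  for (cm in ast$concept_maps) register_conceptmap(ctx, cm)
  for (cm in conceptmaps) register_conceptmap(ctx, cm)
  entry <- ast$groups[[1]]
  ttype <- NULL
  for (inp in entry$inputs) {
    if (identical(inp$mode, "target") && is.null(ttype)) ttype <- inp$type
  }
  if (is.null(ttype) || !models_has(models, ttype)) {
    fml_error("fmlc_runtime_error",
              paste0("entry group '", entry$name,
                     "' has no resolvable target type"))
  }
  target <- new_instance_node(models, ttype)
  exec_group(entry, list(source, target), ast, ctx)
  target
}

exec_group <- function(group, arg_values, ast, ctx) {
  if (length(arg_values) != length(group$inputs)) {
    fml_error("fmlc_runtime_error",
              paste0("group '", group$name, "' expects ",
                     length(group$inputs), " arguments, got ",
                     length(arg_values)))
  }
  vars <- list()
  for (i in seq_along(group$inputs)) {
    vars[[group$inputs[[i]]$name]] <- arg_values[[i]]
  }
  if (!is.null(group$extends)) {
    parent <- NULL
    for (g in ast$groups) if (identical(g$name, group$extends)) parent <- g
    if (is.null(parent)) {
      fml_error("fmlc_runtime_error",
                paste0("unknown parent group '", group$extends, "'"))
    }
    exec_group(parent, arg_values[seq_along(parent$inputs)], ast, ctx)
  }
  for (rule in group$rules) exec_rule(rule, vars, ast, ctx)
  invisible(NULL)
}

exec_rule <- function(rule, vars, ast, ctx) {
  s <- rule$source
  if (!s$context %in% names(vars)) {
    fml_error("fmlc_runtime_error",
              paste0("variable '", s$context, "' not in scope (rule ",
                     rule$rule_id, ")"))
  }
  ctxv <- vars[[s$context]]
  items <- if (!is.null(s$element)) fp_get(ctxv, s$element, ctx) else fp_coll(ctxv)
  if (!is.null(s$default_value) && length(items) == 0L) {
    items <- list(literal_value(s$default_value))
  }
  if (!is.null(s$condition)) {
    items <- fp_where(items, function(it) {
      fhirpath_evaluate(s$condition$ast, focus = it, variables = vars, ctx = ctx)
    })
  }
  if (!is.null(s$list_mode)) items <- fml_listmode(items, s$list_mode)

  for (item in items) {
    ivars <- vars
    if (!is.null(s$variable)) ivars[[s$variable]] <- item
    if (!is.null(s$check)) {
      fml_check(fhirpath_evaluate(s$check$ast, focus = list(item),
                                  variables = ivars, ctx = ctx),
                s$check$text)
    }
    exec_rule_body(rule, item, ivars, ast, ctx)
  }
  invisible(NULL)
}

exec_rule_body <- function(rule, focus, vars, ast, ctx) {
  created <- character(0)
  for (t in rule$targets) {
    res <- exec_transform(t, focus, vars, ast, ctx, rule)
    vars <- res$vars
    if (!is.null(t$variable) && identical(t$transform, "create")) {
      created <- c(created, t$variable)
    }
  }
  for (nested in rule$nested_rules) exec_rule(nested, vars, ast, ctx)
  for (dep in rule$dependent_calls) {
    grp <- resolve_dependent_group(list(group = dep$group, args = dep$args),
                                   ast)
    args <- lapply(dep$args, function(a) {
      if (!a %in% names(vars)) {
        fml_error("fmlc_runtime_error",
                  paste0("variable '", a, "' not in scope (rule ",
                         rule$rule_id, ")"))
      }
      vars[[a]]
    })
    exec_group(grp, args, ast, ctx)
  }
  if (!length(rule$nested_rules) && !length(rule$dependent_calls) &&
      !is.null(rule$source$variable)) {
    sv <- vars[[rule$source$variable]]
    for (tv in created) {
      tval <- vars[[tv]]
      if (!is_fml_node(sv) || !is_fml_node(tval)) next
      grp <- tryCatch(
        resolve_dependent_group(list(source_type = sv$type,
                                     target_type = tval$type), ast),
        fmlc_no_type_group = function(e) NULL)
      if (!is.null(grp)) exec_group(grp, list(sv, tval), ast, ctx)
    }
  }
  invisible(NULL)
}

literal_value <- function(lit) {
  switch(lit$type,
    string = lit$value,
    integer = lit$value,
    decimal = fml_decimal(lit$value),
    boolean = lit$value
  )
}

exec_transform <- function(t, focus, vars, ast, ctx, rule) {
  getvar <- function(name) {
    if (!name %in% names(vars)) {
      fml_error("fmlc_runtime_error",
                paste0("variable '", name, "' not in scope (rule ",
                       rule$rule_id, ")"))
    }
    vars[[name]]
  }
  pval <- function(p) {
    if (identical(p$kind, "var")) getvar(p$name) else literal_value(p)
  }
  value <- switch(t$transform,
    copy = {
      p <- t$params[[1]]
      if (identical(p$kind, "literal")) literal_value(p) else fml_copy(getvar(p$name))
    },
    create = {
      ty <- if (length(t$params)) {
        param_literal_string(t$params[[1]], "create type")
      } else {
        ctxv <- getvar(t$context)
        if (!is_fml_node(ctxv)) {
          fml_error("fmlc_runtime_error", "create context is not a node")
        }
        resolve_element_type(ctx$models, ctxv$type, t$element)
      }
      fml_create(ctx, ty)
    },
    translate = {
      fml_translate(ctx, pval(t$params[[1]]),
                    param_literal_string(t$params[[2]], "translate map url"),
                    param_literal_string(t$params[[3]], "translate output mode"))
    },
    append = do.call(fml_append, lapply(t$params, pval)),
    cast = fml_cast(ctx, pval(t$params[[1]]),
                    param_literal_string(t$params[[2]], "cast type")),
    truncate = fml_truncate(pval(t$params[[1]]), t$params[[2]]$value),
    evaluate = {
      fp <- t$params[[length(t$params)]]
      f <- if (length(t$params) == 2L) getvar(t$params[[1]]$name) else focus
      fhirpath_evaluate(fp$ast, focus = f, variables = vars, ctx = ctx)
    },
    cc = do.call(fml_cc, c(list(ctx), lapply(t$params, pval))),
    c = do.call(fml_c, c(list(ctx), lapply(t$params, pval))),
    uuid = new_uuid(ctx),
    fml_error("fmlc_runtime_error",
              paste0("unsupported transform '", t$transform, "'"))
  )
  if (!is.null(t$element)) {
    stored <- fml_assign(getvar(t$context), t$element, value, ctx)
    if (!is.null(t$variable)) vars[[t$variable]] <- stored
  } else if (!is.null(t$variable)) {
    vars[[t$variable]] <- value
  } else {
    fml_error("fmlc_runtime_error", "target without element or variable")
  }
  list(vars = vars)
}

# ---- canonical diff ---------------------------------------------------------

#' Canonical diff between two documents
#'
#' Canonicalizes both texts (schema-independent XML/JSON canonical form),
#' normalizes v4-UUID tokens -- the only permitted difference class besides
#' whitespace -- and compares line by line.
#'
#' @param a,b document texts
#' @param fmt `"xml"` or `"json"`
#' @return a `fml_diff_report`; empty (length-0 `differences`) iff equivalent
#' @export
diff_canonical <- function(a, b, fmt = c("xml", "json")) {
  fmt <- match.arg(fmt)
  canon <- if (fmt == "xml") canonicalize_xml else canonicalize_json
  ca <- gsub(UUID_V4_REGEX, "00000000-0000-4000-8000-000000000000", canon(a))
  cb <- gsub(UUID_V4_REGEX, "00000000-0000-4000-8000-000000000000", canon(b))
  la <- strsplit(ca, "\n", fixed = TRUE)[[1]]
  lb <- strsplit(cb, "\n", fixed = TRUE)[[1]]
  n <- max(length(la), length(lb))
  length(la) <- n; length(lb) <- n
  diff_idx <- which(is.na(la) | is.na(lb) | la != lb)
  differences <- vapply(diff_idx, function(i) {
    paste0("line ", i, ": ",
           if (is.na(la[i])) "<absent>" else la[i], " | ",
           if (is.na(lb[i])) "<absent>" else lb[i])
  }, character(1))
  structure(list(differences = differences, equivalent = length(differences) == 0L),
            class = "fml_diff_report")
}

#' @export
print.fml_diff_report <- function(x, ...) {
  if (x$equivalent) {
    cat("documents are canonically equivalent\n")
  } else {
    cat(length(x$differences), "difference(s):\n")
    for (d in utils::head(x$differences, 20)) cat(" ", d, "\n")
  }
  invisible(x)
}
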