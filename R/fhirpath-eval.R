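# FHIRPath collection semantics. Every result is a collection (an R list);
# empty propagates through operators; comparisons coerce singletons. These
# helpers are the single runtime shared by the tree-walking evaluator and by
# emitted code, so the two execution paths can only differ in dispatch.

#' @rdname fp_helpers
#' @param x a value or collection
#' @export
fp_coll <- function(x) if (is.list(x) && !is_fml_node(x)) x else list(x)

fp_singleton <- function(coll, what = "operand") {
  if (length(coll) > 1) {
    fml_error("fmlc_fp_eval_error",
              paste0("singleton required for ", what, ", got ", length(coll),
                     " items"))
  }
  if (length(coll) == 0) NULL else coll[[1]]
}

fp_item_class <- function(x) {
  if (is_fml_node(x)) return("node")
  if (inherits(x, "fml_decimal")) return("decimal")
  if (inherits(x, "fml_date")) return("date")
  if (inherits(x, "fml_datetime")) return("datetime")
  if (is.logical(x)) return("boolean")
  if (is.integer(x)) return("integer")
  if (is.numeric(x)) return("decimal")
  "string"
}

fp_item_num <- function(x) {
  cl <- fp_item_class(x)
  if (!cl %in% c("integer", "decimal")) {
    fml_error("fmlc_fp_eval_error", paste0("expected a number, got ", cl))
  }
  as.numeric(x)
}

fp_item_str <- function(x) {
  switch(fp_item_class(x),
    boolean = if (x) "true" else "false",
    integer = as.character(x),
    decimal = canonical_decimal(attr(x, "lexical") %||% x),
    node = fml_error("fmlc_fp_eval_error", "cannot stringify a complex node"),
    as.character(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- navigation -------------------------------------------------------------

#' @rdname fp_helpers
#' @export
fp_get <- function(input, name, ctx) {
  out <- list()
  for (item in fp_coll(input)) {
    if (is_fml_node(item)) {
      out <- c(out, dynamic_get(item, name, ctx$models))
    }
  }
  out
}

#' @rdname fp_helpers
#' @export
fp_index <- function(input, idx) {
  input <- fp_coll(input)
  i <- fp_singleton(fp_coll(idx), "indexer")
  if (is.null(i)) return(list())
  i <- as.integer(fp_item_num(i))
  if (i < 0 || i >= length(input)) list() else input[i + 1L]
}

# ---- existence / subsetting -------------------------------------------------

#' FHIRPath runtime helpers
#'
#' Collection-semantics building blocks referenced both by the reference
#' interpreter and by emitted R expressions. All take and return collections
#' (plain lists); `ctx` is the execution context carrying the model set and
#' the shared execution timestamp.
#'
#' @param input,a,b,idx,sub,prefix,start,len,cond collections (lists)
#' @param pred,then_fn,else_fn functions
#' @param ctx execution context
#' @param name,type_name character
#' @name fp_helpers
NULL

#' @rdname fp_helpers
#' @export
fp_exists <- function(input) list(length(fp_coll(input)) > 0)

#' @rdname fp_helpers
#' @export
fp_empty <- function(input) list(length(fp_coll(input)) == 0)

#' @rdname fp_helpers
#' @export
fp_first <- function(input) {
  input <- fp_coll(input)
  if (length(input)) input[1] else list()
}

#' @rdname fp_helpers
#' @export
fp_last <- function(input) {
  input <- fp_coll(input)
  if (length(input)) input[length(input)] else list()
}

#' @rdname fp_helpers
#' @export
fp_count <- function(input) list(length(fp_coll(input)))

#' @rdname fp_helpers
#' @export
fp_where <- function(input, pred) {
  input <- fp_coll(input)
  input[vapply(input, function(it) fp_truthy(pred(list(it))), logical(1))]
}

#' @rdname fp_helpers
#' @export
fp_select <- function(input, fn) {
  out <- list()
  for (it in fp_coll(input)) out <- c(out, fp_coll(fn(list(it))))
  out
}

#' @rdname fp_helpers
#' @export
fp_iif <- function(cond, then_fn, else_fn = function() list()) {
  if (fp_truthy(cond)) then_fn() else else_fn()
}

# Boolean view used by filters and conditionals: empty -> FALSE, a singleton
# boolean -> its value, any other non-empty collection -> TRUE.
#' @rdname fp_helpers
#' @export
fp_truthy <- function(input) {
  input <- fp_coll(input)
  if (!length(input)) return(FALSE)
  if (length(input) == 1 && is.logical(input[[1]])) return(isTRUE(input[[1]]))
  TRUE
}

# Three-valued boolean view: empty -> NA
fp_bool3 <- function(input) {
  input <- fp_coll(input)
  if (!length(input)) return(NA)
  v <- fp_singleton(input, "boolean operand")
  if (is.logical(v)) v else TRUE
}

fp_wrap3 <- function(v) if (is.na(v)) list() else list(v)

#' @rdname fp_helpers
#' @export
fp_not <- function(input) {
  v <- fp_bool3(input)
  fp_wrap3(if (is.na(v)) NA else !v)
}

#' @rdname fp_helpers
#' @export
fp_and <- function(a, b) {
  x <- fp_bool3(a); y <- fp_bool3(b)
  fp_wrap3(if (isFALSE(x) || isFALSE(y)) FALSE
           else if (is.na(x) || is.na(y)) NA else TRUE)
}

#' @rdname fp_helpers
#' @export
fp_or <- function(a, b) {
  x <- fp_bool3(a); y <- fp_bool3(b)
  fp_wrap3(if (isTRUE(x) || isTRUE(y)) TRUE
           else if (is.na(x) || is.na(y)) NA else FALSE)
}

#' @rdname fp_helpers
#' @export
fp_xor <- function(a, b) {
  x <- fp_bool3(a); y <- fp_bool3(b)
  fp_wrap3(if (is.na(x) || is.na(y)) NA else xor(x, y))
}

#' @rdname fp_helpers
#' @export
fp_implies <- function(a, b) {
  x <- fp_bool3(a); y <- fp_bool3(b)
  fp_wrap3(if (isFALSE(x)) TRUE
           else if (isTRUE(x)) y
           else if (isTRUE(y)) TRUE else NA)
}

# ---- equality / comparison --------------------------------------------------

fp_item_eq <- function(a, b) {
  ca <- fp_item_class(a); cb <- fp_item_class(b)
  if (ca == "node" || cb == "node") {
    if (ca != "node" || cb != "node") return(FALSE)
    return(node_equal(a, b))
  }
  num <- c("integer", "decimal")
  if (ca %in% num && cb %in% num) return(as.numeric(a) == as.numeric(b))
  if (ca == "boolean" || cb == "boolean") {
    return(ca == cb && identical(unclass(a), unclass(b)))
  }
  str <- c("string", "date", "datetime")
  if (ca %in% str && cb %in% str) return(identical(as.character(a), as.character(b)))
  FALSE
}

#' @rdname fp_helpers
#' @export
fp_eq <- function(a, b) {
  a <- fp_coll(a); b <- fp_coll(b)
  if (!length(a) || !length(b)) return(list())
  if (length(a) != length(b)) return(list(FALSE))
  for (i in seq_along(a)) {
    if (!fp_item_eq(a[[i]], b[[i]])) return(list(FALSE))
  }
  list(TRUE)
}

#' @rdname fp_helpers
#' @export
fp_ne <- function(a, b) {
  r <- fp_eq(a, b)
  if (!length(r)) list() else list(!r[[1]])
}

fp_compare <- function(a, b, op) {
  a <- fp_coll(a); b <- fp_coll(b)
  if (!length(a) || !length(b)) return(list())
  x <- fp_singleton(a, "comparison"); y <- fp_singleton(b, "comparison")
  cx <- fp_item_class(x); cy <- fp_item_class(y)
  num <- c("integer", "decimal"); str <- c("string", "date", "datetime")
  if (cx %in% num && cy %in% num) {
    xv <- as.numeric(x); yv <- as.numeric(y)
  } else if (cx %in% str && cy %in% str) {
    xv <- as.character(x); yv <- as.character(y)
  } else {
    fml_error("fmlc_fp_eval_error",
              paste0("cannot compare ", cx, " with ", cy))
  }
  list(switch(op, "<" = xv < yv, "<=" = xv <= yv, ">" = xv > yv, ">=" = xv >= yv))
}

#' @rdname fp_helpers
#' @export
fp_lt <- function(a, b) fp_compare(a, b, "<")
#' @rdname fp_helpers
#' @export
fp_le <- function(a, b) fp_compare(a, b, "<=")
#' @rdname fp_helpers
#' @export
fp_gt <- function(a, b) fp_compare(a, b, ">")
#' @rdname fp_helpers
#' @export
fp_ge <- function(a, b) fp_compare(a, b, ">=")

# ---- arithmetic -------------------------------------------------------------

fp_arith <- function(a, b, op) {
  a <- fp_coll(a); b <- fp_coll(b)
  if (!length(a) || !length(b)) return(list())
  x <- fp_singleton(a, "arithmetic"); y <- fp_singleton(b, "arithmetic")
  cx <- fp_item_class(x); cy <- fp_item_class(y)
  if (op == "+" && cx == "string" && cy == "string") {
    return(list(paste0(x, y)))
  }
  xv <- fp_item_num(x); yv <- fp_item_num(y)
  both_int <- cx == "integer" && cy == "integer"
  if (op == "/") {
    if (yv == 0) return(list())
    return(list(fml_decimal(canonical_decimal(xv / yv))))
  }
  if (op == "div") {
    if (yv == 0) return(list())
    return(list(as.integer(trunc(xv / yv))))
  }
  if (op == "mod") {
    if (yv == 0) return(list())
    r <- xv - trunc(xv / yv) * yv
    return(list(if (both_int) as.integer(r) else fml_decimal(canonical_decimal(r))))
  }
  r <- switch(op, "+" = xv + yv, "-" = xv - yv, "*" = xv * yv)
  list(if (both_int) as.integer(r) else fml_decimal(canonical_decimal(r)))
}

#' @rdname fp_helpers
#' @export
fp_add <- function(a, b) fp_arith(a, b, "+")
#' @rdname fp_helpers
#' @export
fp_sub <- function(a, b) fp_arith(a, b, "-")
#' @rdname fp_helpers
#' @export
fp_mul <- function(a, b) fp_arith(a, b, "*")
#' @rdname fp_helpers
#' @export
fp_div <- function(a, b) fp_arith(a, b, "/")
#' @rdname fp_helpers
#' @export
fp_intdiv <- function(a, b) fp_arith(a, b, "div")
#' @rdname fp_helpers
#' @export
fp_mod <- function(a, b) fp_arith(a, b, "mod")

#' @rdname fp_helpers
#' @export
fp_neg <- function(a) {
  a <- fp_coll(a)
  if (!length(a)) return(list())
  x <- fp_singleton(a, "unary minus")
  if (fp_item_class(x) == "integer") list(-x)
  else list(fml_decimal(canonical_decimal(-fp_item_num(x))))
}

# string concatenation operator &: empty operands become ""
#' @rdname fp_helpers
#' @export
fp_concat <- function(a, b) {
  sa <- fp_singleton(fp_coll(a), "&"); sb <- fp_singleton(fp_coll(b), "&")
  list(paste0(if (is.null(sa)) "" else fp_item_str(sa),
              if (is.null(sb)) "" else fp_item_str(sb)))
}

# union operator |: combined collection with exact duplicates removed
#' @rdname fp_helpers
#' @export
fp_union <- function(a, b) {
  out <- list()
  for (it in c(fp_coll(a), fp_coll(b))) {
    dup <- FALSE
    for (o in out) if (fp_item_eq(o, it)) { dup <- TRUE; break }
    if (!dup) out[[length(out) + 1L]] <- it
  }
  out
}

# ---- string functions -------------------------------------------------------

fp_str_input <- function(input, what) {
  s <- fp_singleton(fp_coll(input), what)
  if (is.null(s)) NULL else fp_item_str(s)
}

#' @rdname fp_helpers
#' @export
fp_contains <- function(input, sub) {
  s <- fp_str_input(input, "contains()")
  x <- fp_str_input(sub, "contains() argument")
  if (is.null(s) || is.null(x)) return(list())
  list(grepl(x, s, fixed = TRUE) || x == "")
}

#' @rdname fp_helpers
#' @export
fp_startswith <- function(input, prefix) {
  s <- fp_str_input(input, "startsWith()")
  x <- fp_str_input(prefix, "startsWith() argument")
  if (is.null(s) || is.null(x)) return(list())
  list(startsWith(s, x))
}

#' @rdname fp_helpers
#' @export
fp_substring <- function(input, start, len = NULL) {
  s <- fp_str_input(input, "substring()")
  st <- fp_singleton(fp_coll(start), "substring() start")
  if (is.null(s) || is.null(st)) return(list())
  st <- as.integer(fp_item_num(st))
  if (st < 0 || st >= nchar(s)) return(list())
  if (is.null(len)) return(list(substr(s, st + 1L, nchar(s))))
  l <- fp_singleton(fp_coll(len), "substring() length")
  if (is.null(l)) return(list(substr(s, st + 1L, nchar(s))))
  l <- as.integer(fp_item_num(l))
  if (l <= 0) return(list(""))
  list(substr(s, st + 1L, st + l))
}

#' @rdname fp_helpers
#' @export
fp_tostring <- function(input) {
  s <- fp_singleton(fp_coll(input), "toString()")
  if (is.null(s)) return(list())
  if (fp_item_class(s) == "node") return(list())
  list(fp_item_str(s))
}

#' @rdname fp_helpers
#' @export
fp_tointeger <- function(input) {
  s <- fp_singleton(fp_coll(input), "toInteger()")
  if (is.null(s)) return(list())
  cl <- fp_item_class(s)
  if (cl == "integer") return(list(s))
  if (cl == "boolean") return(list(if (s) 1L else 0L))
  if (cl == "string" && grepl("^[+-]?[0-9]+$", s)) return(list(as.integer(s)))
  list()
}

# ---- time / type ------------------------------------------------------------

#' @rdname fp_helpers
#' @export
fp_now <- function(ctx) {
  list(structure(ctx$shared_now, class = c("fml_datetime", "character")))
}

#' @rdname fp_helpers
#' @export
fp_today <- function(ctx) {
  list(structure(substr(ctx$shared_now, 1, 10),
                 class = c("fml_date", "character")))
}

#' @rdname fp_helpers
#' @export
fp_date <- function(lexical) {
  list(structure(lexical, class = c("fml_date", "character")))
}

#' @rdname fp_helpers
#' @export
fp_datetime <- function(lexical) {
  list(structure(lexical, class = c("fml_datetime", "character")))
}

fp_type_match <- function(item, type_name, ctx) {
  cl <- fp_item_class(item)
  if (cl == "node") {
    if (!models_has(ctx$models, type_name)) {
      fml_error("fmlc_fp_type_error",
                paste0("unknown type name '", type_name, "' in is/as"))
    }
    return(derives_from(ctx$models, item$type, type_name))
  }
  sys_map <- c(String = "string", Integer = "integer", Decimal = "decimal",
               Boolean = "boolean", Date = "date", DateTime = "datetime",
               string = "string", integer = "integer", decimal = "decimal",
               boolean = "boolean", date = "date", dateTime = "datetime")
  want <- sys_map[[type_name]]
  if (is.null(want)) {
    if (!models_has(ctx$models, type_name)) {
      fml_error("fmlc_fp_type_error",
                paste0("unknown type name '", type_name, "' in is/as"))
    }
    return(FALSE)
  }
  identical(cl, want)
}

#' @rdname fp_helpers
#' @export
fp_is <- function(input, type_name, ctx) {
  input <- fp_coll(input)
  if (!length(input)) return(list())
  item <- fp_singleton(input, "is")
  list(fp_type_match(item, type_name, ctx))
}

#' @rdname fp_helpers
#' @export
fp_as <- function(input, type_name, ctx) {
  input <- fp_coll(input)
  if (!length(input)) return(list())
  item <- fp_singleton(input, "as")
  if (fp_type_match(item, type_name, ctx)) list(item) else list()
}

# ---- tree-walking evaluator -------------------------------------------------

#' Evaluate a FHIRPath AST over a focus collection
#'
#' Reference semantics for the expression subset: the same helper runtime the
#' emitted code calls, driven by a direct AST walk.
#'
#' @param ast parsed FHIRPath AST from [parse_fhirpath()]
#' @param focus focus collection (list of nodes/primitives)
#' @param variables named list of variable collections (FML rule variables)
#' @param ctx execution context from [new_execution_context()]
#' @return result collection (list)
#' @export
fhirpath_evaluate <- function(ast, focus = list(), variables = list(), ctx) {
  eval_fp(ast, fp_coll(focus), variables, ctx)
}

eval_fp <- function(ast, focus, vars, ctx) {
  switch(ast$kind,
    lit = list(fp_literal_value(ast)),
    this = focus,
    path = {
      if (ast$name %in% names(vars)) fp_coll(vars[[ast$name]])
      else fp_get(focus, ast$name, ctx)
    },
    var = {
      if (!ast$name %in% names(vars)) {
        fml_error("fmlc_fp_eval_error",
                  paste0("undefined variable %", ast$name))
      }
      fp_coll(vars[[ast$name]])
    },
    nav = fp_get(eval_fp(ast$base, focus, vars, ctx), ast$name, ctx),
    index = fp_index(eval_fp(ast$base, focus, vars, ctx),
                     eval_fp(ast$index, focus, vars, ctx)),
    unary = {
      v <- eval_fp(ast$operand, focus, vars, ctx)
      if (ast$op == "-") fp_neg(v) else v
    },
    binop = eval_fp_binop(ast, focus, vars, ctx),
    typeop = {
      v <- eval_fp(ast$operand, focus, vars, ctx)
      if (ast$op == "is") fp_is(v, ast$type, ctx) else fp_as(v, ast$type, ctx)
    },
    call = eval_fp_call(ast, focus, vars, ctx),
    fml_error("fmlc_fp_eval_error", paste0("unknown AST kind ", ast$kind))
  )
}

fp_literal_value <- function(ast) {
  switch(ast$type,
    string = ast$value,
    integer = ast$value,
    decimal = fml_decimal(ast$value),
    boolean = ast$value,
    date = structure(ast$value, class = c("fml_date", "character")),
    datetime = structure(ast$value, class = c("fml_datetime", "character"))
  )
}

FP_BINOP_FN <- list(
  "=" = fp_eq, "!=" = fp_ne, "<" = fp_lt, "<=" = fp_le, ">" = fp_gt,
  ">=" = fp_ge, "and" = fp_and, "or" = fp_or, "xor" = fp_xor,
  "implies" = fp_implies, "+" = fp_add, "-" = fp_sub, "*" = fp_mul,
  "/" = fp_div, "div" = fp_intdiv, "mod" = fp_mod, "&" = fp_concat,
  "|" = fp_union
)

eval_fp_binop <- function(ast, focus, vars, ctx) {
  fn <- FP_BINOP_FN[[ast$op]]
  fn(eval_fp(ast$left, focus, vars, ctx), eval_fp(ast$right, focus, vars, ctx))
}

eval_fp_call <- function(ast, focus, vars, ctx) {
  input <- if (is.null(ast$base)) focus else eval_fp(ast$base, focus, vars, ctx)
  pred <- function(arg_ast) function(item) eval_fp(arg_ast, item, vars, ctx)
  switch(ast$name,
    where = fp_where(input, pred(ast$args[[1]])),
    select = fp_select(input, pred(ast$args[[1]])),
    exists = {
      if (length(ast$args)) fp_exists(fp_where(input, pred(ast$args[[1]])))
      else fp_exists(input)
    },
    empty = fp_empty(input),
    first = fp_first(input),
    last = fp_last(input),
    count = fp_count(input),
    iif = {
      cond <- eval_fp(ast$args[[1]], input, vars, ctx)
      fp_iif(cond,
             function() eval_fp(ast$args[[2]], input, vars, ctx),
             if (length(ast$args) == 3)
               function() eval_fp(ast$args[[3]], input, vars, ctx)
             else function() list())
    },
    not = fp_not(input),
    contains = fp_contains(input, eval_fp(ast$args[[1]], focus, vars, ctx)),
    startsWith = fp_startswith(input, eval_fp(ast$args[[1]], focus, vars, ctx)),
    substring = {
      st <- eval_fp(ast$args[[1]], focus, vars, ctx)
      if (length(ast$args) == 2)
        fp_substring(input, st, eval_fp(ast$args[[2]], focus, vars, ctx))
      else fp_substring(input, st)
    },
    toString = fp_tostring(input),
    toInteger = fp_tointeger(input),
    now = fp_now(ctx),
    today = fp_today(ctx),
    fml_error("fmlc_fp_eval_error",
              paste0("unsupported function ", ast$name))
  )
}
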