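# Single-pass emission of FHIRPath ASTs as concise R expression text. The
# emitted text references only the package's fp_* runtime helpers, local
# (FML-derived) variables and the execution context `ctx`; string literals
# are embedded verbatim, now()/today() read the execution-scoped shared
# timestamp instead of the clock.

FP_BINOP_EMIT <- c(
  "=" = "fp_eq", "!=" = "fp_ne", "<" = "fp_lt", "<=" = "fp_le",
  ">" = "fp_gt", ">=" = "fp_ge", "and" = "fp_and", "or" = "fp_or",
  "xor" = "fp_xor", "implies" = "fp_implies", "+" = "fp_add", "-" = "fp_sub",
  "*" = "fp_mul", "/" = "fp_div", "div" = "fp_intdiv", "mod" = "fp_mod",
  "&" = "fp_concat", "|" = "fp_union"
)

#' Emit a FHIRPath AST as host (R) expression text
#'
#' A single traversal produces an expression over the runtime helper
#' namespace; evaluating the text with the focus variable and `ctx` bound
#' yields the same collection as [fhirpath_evaluate()]. When the static type
#' of the focus is unknown the emitted navigation defers to runtime dynamic
#' dispatch (the helpers resolve elements against the model set at run time).
#'
#' @param ast FHIRPath AST
#' @param focus_var name of the R variable holding the focus collection
#'   (default `".focus"`)
#' @param scope_vars named character vector mapping FML variable names in
#'   scope to generated R identifiers
#' @param static_type optional qualified type name of the focus, when known
#'   at compile time (consumed by [fhirpath_simplify()] before emission)
#' @param models optional model set (with `static_type`, enables model-aware
#'   simplification)
#' @return single string of R expression text
#' @export
emit_expression <- function(ast, focus_var = ".focus",
                            scope_vars = character(0),
                            static_type = NULL, models = NULL) {
  ast <- fhirpath_simplify(ast, static_type = static_type, models = models)
  emit_fp(ast, focus_var, scope_vars)
}

emit_fp <- function(ast, focus, vars) {
  switch(ast$kind,
    lit = emit_fp_literal(ast),
    this = focus,
    path = {
      if (ast$name %in% names(vars)) {
        paste0("fp_coll(", vars[[ast$name]], ")")
      } else {
        paste0("fp_get(", focus, ", ", r_string(ast$name), ", ctx)")
      }
    },
    var = {
      if (!ast$name %in% names(vars)) {
        fml_error("fmlc_compile_error",
                  paste0("variable %", ast$name, " not in scope"))
      }
      paste0("fp_coll(", vars[[ast$name]], ")")
    },
    nav = paste0("fp_get(", emit_fp(ast$base, focus, vars), ", ",
                 r_string(ast$name), ", ctx)"),
    index = paste0("fp_index(", emit_fp(ast$base, focus, vars), ", ",
                   emit_fp(ast$index, focus, vars), ")"),
    unary = {
      inner <- emit_fp(ast$operand, focus, vars)
      if (ast$op == "-") paste0("fp_neg(", inner, ")") else inner
    },
    binop = paste0(FP_BINOP_EMIT[[ast$op]], "(",
                   emit_fp(ast$left, focus, vars), ", ",
                   emit_fp(ast$right, focus, vars), ")"),
    typeop = paste0(if (ast$op == "is") "fp_is(" else "fp_as(",
                    emit_fp(ast$operand, focus, vars), ", ",
                    r_string(ast$type), ", ctx)"),
    call = emit_fp_call(ast, focus, vars),
    fml_error("fmlc_compile_error", paste0("unknown AST kind ", ast$kind))
  )
}

emit_fp_literal <- function(ast) {
  switch(ast$type,
    string = paste0("list(", r_string(ast$value), ")"),
    integer = paste0("list(", ast$value, "L)"),
    decimal = paste0("list(fml_decimal(", r_string(ast$value), "))"),
    boolean = paste0("list(", if (ast$value) "TRUE" else "FALSE", ")"),
    date = paste0("fp_date(", r_string(ast$value), ")"),
    datetime = paste0("fp_datetime(", r_string(ast$value), ")")
  )
}

emit_fp_call <- function(ast, focus, vars) {
  base <- if (is.null(ast$base)) focus else emit_fp(ast$base, focus, vars)
  lam <- function(arg_ast) {
    paste0("function(.this) ", emit_fp(arg_ast, ".this", vars))
  }
  switch(ast$name,
    where = paste0("fp_where(", base, ", ", lam(ast$args[[1]]), ")"),
    select = paste0("fp_select(", base, ", ", lam(ast$args[[1]]), ")"),
    exists = {
      if (length(ast$args)) {
        paste0("fp_exists(fp_where(", base, ", ", lam(ast$args[[1]]), "))")
      } else paste0("fp_exists(", base, ")")
    },
    empty = paste0("fp_empty(", base, ")"),
    first = paste0("fp_first(", base, ")"),
    last = paste0("fp_last(", base, ")"),
    count = paste0("fp_count(", base, ")"),
    not = paste0("fp_not(", base, ")"),
    iif = {
      else_txt <- if (length(ast$args) == 3) {
        paste0(", function() ", emit_fp(ast$args[[3]], ".this", vars))
      } else ""
      # iif arguments see the invocation input as their focus
      paste0("(function(.this) fp_iif(",
             emit_fp(ast$args[[1]], ".this", vars),
             ", function() ", emit_fp(ast$args[[2]], ".this", vars),
             else_txt, "))(", base, ")")
    },
    contains = paste0("fp_contains(", base, ", ",
                      emit_fp(ast$args[[1]], focus, vars), ")"),
    startsWith = paste0("fp_startswith(", base, ", ",
                        emit_fp(ast$args[[1]], focus, vars), ")"),
    substring = {
      extra <- if (length(ast$args) == 2) {
        paste0(", ", emit_fp(ast$args[[2]], focus, vars))
      } else ""
      paste0("fp_substring(", base, ", ",
             emit_fp(ast$args[[1]], focus, vars), extra, ")")
    },
    toString = paste0("fp_tostring(", base, ")"),
    toInteger = paste0("fp_tointeger(", base, ")"),
    now = "fp_now(ctx)",
    today = "fp_today(ctx)",
    fml_error("fmlc_compile_error",
              paste0("unsupported function ", ast$name))
  )
}
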