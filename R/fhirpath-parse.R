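# FHIRPath frontend: tokenizer and layered recursive-descent parser for the
# supported subset. Unsupported functions and operators are rejected here, at
# parse time, never at evaluation time.

FP_FUNCTIONS <- c("where", "exists", "empty", "first", "last", "count",
                  "select", "iif", "not", "contains", "startsWith",
                  "substring", "toString", "toInteger", "now", "today")

FP_KEYWORD_OPS <- c("and", "or", "xor", "implies", "div", "mod", "is", "as")

fp_tokenize <- function(text) {
  tokens <- list()
  n <- nchar(text)
  i <- 1L
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    start <- i
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      word <- substr(text, i, j - 1L)
      if (word %in% c("true", "false")) push("BOOL", word, start)
      else if (word %in% FP_KEYWORD_OPS) push("OP", word, start)
      else push("IDENT", word, start)
      i <- j
    } else if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9]$", substr(text, j, j))) j <- j + 1L
      if (j <= n && substr(text, j, j) == "." &&
          j + 1L <= n && grepl("^[0-9]$", substr(text, j + 1L, j + 1L))) {
        j <- j + 1L
        while (j <= n && grepl("^[0-9]$", substr(text, j, j))) j <- j + 1L
        push("DECIMAL", substr(text, i, j - 1L), start)
      } else {
        push("INTEGER", substr(text, i, j - 1L), start)
      }
      i <- j
    } else if (ch == "'") {
      out <- character(0)
      j <- i + 1L
      closed <- FALSE
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          esc <- substr(text, j + 1L, j + 1L)
          out <- c(out, switch(esc, n = "\n", t = "\t", r = "\r",
                               "\\" = "\\", "'" = "'", "\"" = "\"",
                               fml_error("fmlc_fp_syntax_error",
                                         paste0("bad escape \\", esc,
                                                " at position ", j))))
          j <- j + 2L
        } else if (cj == "'") { closed <- TRUE; j <- j + 1L; break }
        else { out <- c(out, cj); j <- j + 1L }
      }
      if (!closed) fml_error("fmlc_fp_syntax_error",
                             paste0("unterminated string at position ", start))
      push("STRING", paste(out, collapse = ""), start)
      i <- j
    } else if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9T:.+Z-]$", substr(text, j, j))) j <- j + 1L
      lex <- substr(text, i + 1L, j - 1L)
      push(if (grepl("T", lex)) "DATETIME" else "DATE", lex, start)
      i <- j
    } else if (ch == "%") {
      j <- i + 1L
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      if (j == i + 1L) fml_error("fmlc_fp_syntax_error",
                                 paste0("empty variable name at position ", start))
      push("VAR", substr(text, i + 1L, j - 1L), start)
      i <- j
    } else if (ch == "$") {
      if (substr(text, i, i + 4L) == "$this") { push("THIS", "$this", start); i <- i + 5L }
      else fml_error("fmlc_fp_syntax_error",
                     paste0("unsupported special variable at position ", start))
    } else if (substr(text, i, i + 1L) %in% c("!=", "<=", ">=")) {
      push("OP", substr(text, i, i + 1L), start); i <- i + 2L
    } else if (ch %in% c("=", "<", ">", "+", "-", "*", "/", "&", "|")) {
      push("OP", ch, start); i <- i + 1L
    } else if (ch == "(") { push("LPAREN", ch, start); i <- i + 1L }
    else if (ch == ")") { push("RPAREN", ch, start); i <- i + 1L }
    else if (ch == "[") { push("LBRACKET", ch, start); i <- i + 1L }
    else if (ch == "]") { push("RBRACKET", ch, start); i <- i + 1L }
    else if (ch == ",") { push("COMMA", ch, start); i <- i + 1L }
    else if (ch == ".") { push("DOT", ch, start); i <- i + 1L }
    else {
      fml_error("fmlc_fp_syntax_error",
                paste0("unexpected character '", ch, "' at position ", i))
    }
  }
  push("EOF", "", n + 1L)
  tokens
}

fp_parser_state <- function(tokens) {
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$pos <- 1L
  st
}

fp_peek <- function(st) st$tokens[[st$pos]]
fp_next <- function(st) { t <- st$tokens[[st$pos]]; st$pos <- st$pos + 1L; t }
fp_expect <- function(st, type) {
  t <- fp_next(st)
  if (!identical(t$type, type)) {
    fml_error("fmlc_fp_syntax_error",
              paste0("expected ", type, " but found '", t$value,
                     "' at position ", t$pos))
  }
  t
}
fp_at_op <- function(st, ops) {
  t <- fp_peek(st)
  identical(t$type, "OP") && t$value %in% ops
}

#' Parse a FHIRPath expression into an AST
#'
#' Supports literals, path navigation, `[n]` indexing, the functions where,
#' exists, empty, first, last, count, select, iif, not, contains, startsWith,
#' substring, toString, toInteger, now, today, the standard operators, and
#' `is`/`as` type tests. Anything outside the subset is an error at parse
#' time.
#'
#' @param expr_text FHIRPath expression text
#' @return a FHIRPath AST (nested lists tagged by `kind`)
#' @export
parse_fhirpath <- function(expr_text) {
  st <- fp_parser_state(fp_tokenize(expr_text))
  ast <- fp_parse_implies(st)
  t <- fp_peek(st)
  if (!identical(t$type, "EOF")) {
    fml_error("fmlc_fp_syntax_error",
              paste0("unexpected '", t$value, "' at position ", t$pos))
  }
  ast
}

fp_binop_layer <- function(st, ops, next_layer) {
  left <- next_layer(st)
  while (fp_at_op(st, ops)) {
    op <- fp_next(st)$value
    right <- next_layer(st)
    left <- list(kind = "binop", op = op, left = left, right = right)
  }
  left
}

fp_parse_implies <- function(st) fp_binop_layer(st, "implies", fp_parse_or)
fp_parse_or <- function(st) fp_binop_layer(st, c("or", "xor"), fp_parse_and)
fp_parse_and <- function(st) fp_binop_layer(st, "and", fp_parse_equality)
fp_parse_equality <- function(st) fp_binop_layer(st, c("=", "!="), fp_parse_comparison)
fp_parse_comparison <- function(st) fp_binop_layer(st, c("<", "<=", ">", ">="),
                                                   fp_parse_union)
fp_parse_union <- function(st) fp_binop_layer(st, "|", fp_parse_typeop)

fp_parse_typeop <- function(st) {
  left <- fp_parse_additive(st)
  while (fp_at_op(st, c("is", "as"))) {
    op <- fp_next(st)$value
    tn <- fp_expect(st, "IDENT")$value
    left <- list(kind = "typeop", op = op, operand = left, type = tn)
  }
  left
}

fp_parse_additive <- function(st) fp_binop_layer(st, c("+", "-", "&"),
                                                 fp_parse_multiplicative)
fp_parse_multiplicative <- function(st) fp_binop_layer(st, c("*", "/", "div", "mod"),
                                                       fp_parse_unary)

fp_parse_unary <- function(st) {
  if (fp_at_op(st, c("-", "+"))) {
    op <- fp_next(st)$value
    list(kind = "unary", op = op, operand = fp_parse_unary(st))
  } else {
    fp_parse_postfix(st)
  }
}

fp_parse_postfix <- function(st) {
  node <- fp_parse_primary(st)
  repeat {
    t <- fp_peek(st)
    if (identical(t$type, "DOT")) {
      fp_next(st)
      nm <- fp_expect(st, "IDENT")$value
      if (identical(fp_peek(st)$type, "LPAREN")) {
        node <- fp_parse_call(st, nm, base = node)
      } else {
        node <- list(kind = "nav", base = node, name = nm)
      }
    } else if (identical(t$type, "LBRACKET")) {
      fp_next(st)
      idx <- fp_parse_implies(st)
      fp_expect(st, "RBRACKET")
      node <- list(kind = "index", base = node, index = idx)
    } else break
  }
  node
}

fp_parse_call <- function(st, name, base) {
  if (!(name %in% FP_FUNCTIONS)) {
    fml_error("fmlc_fp_unsupported_function",
              paste0("unsupported FHIRPath function '", name, "'"))
  }
  fp_expect(st, "LPAREN")
  args <- list()
  if (!identical(fp_peek(st)$type, "RPAREN")) {
    repeat {
      args[[length(args) + 1L]] <- fp_parse_implies(st)
      if (identical(fp_peek(st)$type, "COMMA")) fp_next(st) else break
    }
  }
  fp_expect(st, "RPAREN")
  fp_check_arity(name, length(args))
  list(kind = "call", name = name, base = base, args = args)
}

FP_ARITY <- list(
  where = c(1, 1), exists = c(0, 1), empty = c(0, 0), first = c(0, 0),
  last = c(0, 0), count = c(0, 0), select = c(1, 1), iif = c(2, 3),
  not = c(0, 0), contains = c(1, 1), startsWith = c(1, 1),
  substring = c(1, 2), toString = c(0, 0), toInteger = c(0, 0),
  now = c(0, 0), today = c(0, 0)
)

fp_check_arity <- function(name, n) {
  rng <- FP_ARITY[[name]]
  if (n < rng[1] || n > rng[2]) {
    fml_error("fmlc_fp_syntax_error",
              paste0("function ", name, "() takes ", rng[1],
                     if (rng[2] > rng[1]) paste0("-", rng[2]), " argument(s), got ", n))
  }
}

fp_parse_primary <- function(st) {
  t <- fp_peek(st)
  switch(t$type,
    STRING = { fp_next(st); list(kind = "lit", type = "string", value = t$value) },
    INTEGER = { fp_next(st); list(kind = "lit", type = "integer",
                                  value = as.integer(t$value)) },
    DECIMAL = { fp_next(st); list(kind = "lit", type = "decimal",
                                  value = t$value) },
    BOOL = { fp_next(st); list(kind = "lit", type = "boolean",
                               value = identical(t$value, "true")) },
    DATE = { fp_next(st); list(kind = "lit", type = "date", value = t$value) },
    DATETIME = { fp_next(st); list(kind = "lit", type = "datetime",
                                   value = t$value) },
    VAR = { fp_next(st); list(kind = "var", name = t$value) },
    THIS = { fp_next(st); list(kind = "this") },
    LPAREN = {
      fp_next(st)
      inner <- fp_parse_implies(st)
      fp_expect(st, "RPAREN")
      inner
    },
    IDENT = {
      fp_next(st)
      if (identical(fp_peek(st)$type, "LPAREN")) {
        fp_parse_call(st, t$value, base = NULL)
      } else {
        list(kind = "path", name = t$value)
      }
    },
    fml_error("fmlc_fp_syntax_error",
              paste0("unexpected '", t$value, "' at position ", t$pos))
  )
}
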