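#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd runif
#' @importFrom utils head tail
NULL

# Condition constructors ------------------------------------------------------

fml_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "fmlc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Identifier sanitization for generated code: characters outside [A-Za-z0-9_]
# become "_"; a leading digit gets a "_" prefix. Collisions are the caller's
# problem (compile error), never silently renamed.
sanitize_identifier <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", out), paste0("_", out), out)
}

# Deterministic R string literal (double quotes, escaped)
r_string <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\t", "\\\\t", x)
  x <- gsub("\r", "\\\\r", x)
  paste0("\"", x, "\"")
}

# XML escaping ----------------------------------------------------------------

xml_escape_text <- function(x) {
  if (!grepl("[&<>]", x)) return(x)
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  if (!grepl("[&<>\"]", x)) return(x)
  x <- xml_escape_text(x)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# JSON string escaping (canonical: only mandatory escapes + \n \t \r)
json_escape <- function(x) {
  if (!grepl("[\\\\\"\n\t\r]", x)) return(paste0("\"", x, "\""))
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

# Canonical decimal rendering: no exponent, no trailing fractional zeros,
# "0.5" not ".5". Used for JSON numbers and FHIRPath decimal results.
CANONICAL_DECIMAL_RE <- "^-?(0|[1-9][0-9]*)(\\.[0-9]*[1-9])?$"

canonical_decimal <- function(x) {
  if (is.character(x) && grepl(CANONICAL_DECIMAL_RE, x)) return(x)
  if (is.character(x)) {
    # normalize a lexical decimal
    s <- sub("^\\+", "", trimws(x))
    num <- suppressWarnings(as.numeric(s))
    if (is.na(num)) fml_error("fmlc_value_error", paste0("not a decimal: ", x))
    x <- num
  }
  if (x == floor(x) && abs(x) < 1e15) {
    s <- format(x, scientific = FALSE)
    # integers keep a plain integral rendering
    return(sub("\\.0*$", "", s))
  }
  s <- format(x, scientific = FALSE, digits = 15, trim = TRUE)
  if (grepl("\\.", s)) {
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
  }
  s
}

# v4 UUID from an internal xorshift-style generator so seeded runs are
# reproducible without touching R's global RNG stream.
uuid_v4 <- function(state) {
  # two inlined xorshift rounds per draw; fields reuse bit ranges of the two
  # words (a deterministic pseudo-random id source, not a cryptographic one)
  s <- state$uuid_state
  s <- bitwXor(s, bitwAnd(bitwShiftL(s, 13L), 0x7FFFFFFF))
  s <- bitwXor(s, bitwShiftR(s, 17L))
  s1 <- bitwXor(s, bitwAnd(bitwShiftL(s, 5L), 0x7FFFFFFF))
  s <- bitwXor(s1, bitwAnd(bitwShiftL(s1, 13L), 0x7FFFFFFF))
  s <- bitwXor(s, bitwShiftR(s, 17L))
  s2 <- bitwXor(s, bitwAnd(bitwShiftL(s, 5L), 0x7FFFFFFF))
  state$uuid_state <- s2
  # single formatting call; version nibble fixed to 4, variant to 8..b
  sprintf("%08x-%04x-4%03x-%x%03x-%04x%08x",
          s1,
          bitwAnd(bitwShiftR(s2, 15L), 0xFFFFL),
          bitwAnd(s2, 0xFFFL),
          8L + bitwAnd(bitwShiftR(s1, 14L), 3L),
          bitwAnd(bitwShiftR(s1, 9L), 0xFFFL),
          bitwAnd(bitwShiftR(s2, 7L), 0xFFFFL),
          bitwXor(s1, bitwShiftL(bitwAnd(s2, 7L), 28L)))
}

UUID_V4_REGEX <-
  "[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-4[0-9a-fA-F]{3}-[89abAB][0-9a-fA-F]{3}-[0-9a-fA-F]{12}"

# ISO-8601 timestamp with a colon-separated timezone offset, captured once per
# execution context.
iso_now <- function(time = Sys.time()) {
  base <- format(time, "%Y-%m-%dT%H:%M:%S")
  off <- format(time, "%z")
  if (off == "") off <- "+0000"
  paste0(base, substr(off, 1, 3), ":", substr(off, 4, 5))
}
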