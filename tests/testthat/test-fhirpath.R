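test_that("parser produces the expected shapes and rejects the unsupported", {
  now_ast <- parse_fhirpath("now()")
  expect_identical(now_ast$kind, "call")
  expect_identical(now_ast$name, "now")
  expect_length(now_ast$args, 0)

  lit <- parse_fhirpath("'routine'")
  expect_identical(lit, list(kind = "lit", type = "string", value = "routine"))

  chain <- parse_fhirpath("name.where(use = 'official').first()")
  expect_identical(chain$name, "first")
  expect_identical(chain$base$name, "where")
  expect_identical(chain$base$base, list(kind = "path", name = "name"))

  expect_error(parse_fhirpath("name.aggregate($this)"),
               class = "fmlc_fp_unsupported_function")
  err <- expect_error(parse_fhirpath("1 + + +"), class = "fmlc_fp_syntax_error")
  expect_match(conditionMessage(err), "position")
})

test_that("evaluation follows collection semantics", {
  ctx <- test_ctx()
  ev <- function(txt, focus = list(), vars = list()) {
    fhirpath_evaluate(parse_fhirpath(txt), focus = focus, variables = vars,
                      ctx = ctx)
  }
  expect_identical(ev("(1 + 2) * 3"), list(9L))
  expect_identical(ev("exists()"), list(FALSE))
  expect_identical(ev("empty()"), list(TRUE))
  # comparisons with empty propagate empty
  expect_identical(ev("unknown = 1", focus = list(fixture_patient())), list())
  # every result is a collection
  for (txt in c("1", "'a'", "true", "name", "name.count()")) {
    expect_true(is.list(ev(txt, focus = list(fixture_patient()))), info = txt)
  }
})

test_that("where filters items by per-item criteria truth", {
  models <- fixture_models()
  ctx <- test_ctx()
  items <- lapply(c("3", "7", "9"), function(v) {
    q <- new_instance_node(models, "Quantity")
    fml_assign(q, "value", fml_decimal(v), ctx)
    q
  })
  # oracle: brute-force filter over the three items
  expected <- Filter(function(q) as.numeric(node_get(q, "value")[[1]]) > 5,
                     items)
  got <- fhirpath_evaluate(parse_fhirpath("where(value > 5)"),
                           focus = items, ctx = ctx)
  expect_length(got, length(expected))
  for (i in seq_along(got)) expect_true(node_equal(got[[i]], expected[[i]]))
})

test_that("now() is constant within one execution context", {
  ctx <- test_ctx(now = NULL)  # live clock, captured once
  a <- fhirpath_evaluate(parse_fhirpath("now()"), ctx = ctx)
  Sys.sleep(0.01)
  b <- fhirpath_evaluate(parse_fhirpath("now()"), ctx = ctx)
  expect_identical(as.character(a[[1]]), as.character(b[[1]]))
  ctx2 <- test_ctx(now = "2020-01-01T00:00:00+00:00")
  c2 <- fhirpath_evaluate(parse_fhirpath("now()"), ctx = ctx2)
  expect_false(identical(as.character(a[[1]]), as.character(c2[[1]])))
  expect_match(as.character(a[[1]]),
               "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}[+-]\\d{2}:\\d{2}$")
})

test_that("decimal arithmetic renders canonically, not as binary float text", {
  ctx <- test_ctx()
  r <- fhirpath_evaluate(parse_fhirpath("0.1 + 0.2"), ctx = ctx)
  expect_identical(attr(r[[1]], "lexical"), "0.3")
  r2 <- fhirpath_evaluate(parse_fhirpath("10 / 4"), ctx = ctx)
  expect_identical(attr(r2[[1]], "lexical"), "2.5")
})

test_that("the committed case suite passes under both execution paths", {
  cases <- fhirpath_case_suite()
  expect_gte(length(cases), 50)
  models <- fixture_models()
  ctx <- test_ctx()
  for (cs in cases) {
    res <- run_fhirpath_case(cs, models, ctx)
    expect_true(res$pass, info = cs$name)
  }
})

test_that("emitted expressions agree with the evaluator on random expressions", {
  models <- fixture_models()
  ctx <- test_ctx()
  pat <- fixture_patient(models)
  env <- new.env(parent = asNamespace("fmlc"))
  assign("ctx", ctx, envir = env)
  for (expr in fhirpath_random_exprs(60, seed = 11)) {
    ast <- parse_fhirpath(expr)
    interp <- fhirpath_evaluate(ast, focus = list(pat), ctx = ctx)
    assign(".focus", list(pat), envir = env)
    emitted <- eval(parse(text = emit_expression(
      ast, ".focus", static_type = "Patient", models = models)), envir = env)
    expect_true(fp_collections_equal(interp, emitted), info = expr)
  }
})

test_that("simplification is sound, idempotent, and model-aware", {
  models <- fixture_models()
  ctx <- test_ctx()
  pat <- fixture_patient(models)

  expect_identical(fhirpath_simplify(parse_fhirpath("1 + 2")),
                   list(kind = "lit", type = "integer", value = 3L))
  expect_identical(fhirpath_simplify(parse_fhirpath("a.where(true)")),
                   list(kind = "path", name = "a"))
  simplified <- fhirpath_simplify(parse_fhirpath("name.exists().not()"))
  expect_identical(simplified$name, "empty")
  expect_identical(simplified$base, list(kind = "path", name = "name"))
  # first() on a model-proven singleton path collapses; unknown type keeps it
  with_model <- fhirpath_simplify(parse_fhirpath("birthDate.first()"),
                                  static_type = "Patient", models = models)
  expect_identical(with_model, list(kind = "path", name = "birthDate"))
  without <- fhirpath_simplify(parse_fhirpath("birthDate.first()"))
  expect_identical(without$kind, "call")

  for (expr in fhirpath_random_exprs(60, seed = 12)) {
    ast <- parse_fhirpath(expr)
    s <- fhirpath_simplify(ast, static_type = "Patient", models = models)
    expect_identical(s, fhirpath_simplify(s, static_type = "Patient",
                                          models = models), info = expr)
    expect_true(fp_collections_equal(
      fhirpath_evaluate(ast, focus = list(pat), ctx = ctx),
      fhirpath_evaluate(s, focus = list(pat), ctx = ctx)), info = expr)
  }
})

test_that("indexing is zero-based and out-of-range yields empty", {
  ctx <- test_ctx()
  pat <- fixture_patient()
  ev <- function(txt) fhirpath_evaluate(parse_fhirpath(txt),
                                        focus = list(pat), ctx = ctx)
  expect_identical(ev("name[0].family"), list("Muster"))
  expect_identical(ev("name[2]"), list())
  expect_identical(ev("name[-1]"), list())
})
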