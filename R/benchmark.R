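# Benchmark harness: warm-up plus test cycles for the compiled and
# interpreted engines over the synthetic laboratory report, with a zero-rule
# baseline mapping to estimate overhead (document parsing/serialization,
# context setup). Overhead-adjusted time = example mean - baseline mean.

#' Load a generated program into an environment
#'
#' @param program a `fml_generated_program` or program source text
#' @return environment holding the generated functions (`fml__run`,
#'   `fml__context`, one function per group)
#' @export
load_generated_program <- function(program) {
  text <- if (inherits(program, "fml_generated_program")) program$source_text
          else program
  env <- new.env(parent = asNamespace("fmlc"))
  eval(parse(text = text), envir = env)
  for (nm in ls(env)) {
    v <- get(nm, envir = env)
    if (is.function(v)) assign(nm, compiler::cmpfun(v), envir = env)
  }
  env
}

#' Execution context pre-wired for a map's concept maps
#'
#' @param ast StructureMap AST
#' @param models model set
#' @param conceptmaps extra concept map definitions
#' @param seed,now forwarded to [new_execution_context()]
#' @return execution context
#' @export
make_map_context <- function(ast, models, conceptmaps = list(), seed = NULL,
                             now = NULL) {
  ctx <- new_execution_context(models, seed = seed, now = now)
  for (cm in ast$concept_maps) register_conceptmap(ctx, cm)
  for (cm in conceptmaps) register_conceptmap(ctx, cm)
  ctx
}

time_once <- function(fn) {
  t0 <- proc.time()[["elapsed"]]
  fn()
  proc.time()[["elapsed"]] - t0
}

bench_stats <- function(times) {
  c(mean = mean(times), min = min(times), max = max(times),
    median = stats::median(times), std = stats::sd(times))
}

#' Run the scaled benchmark protocol
#'
#' Both engines (compiled, interpreted) are run over the synthetic
#' laboratory report with `n_observations` entries and over the zero-rule
#' baseline mapping on the same input, with `warmup` warm-up cycles followed
#' by `cycles` timed cycles each. Every cycle reads the source document,
#' executes the mapping and serializes the target.
#'
#' @param n_observations laboratory report size
#' @param warmup warm-up cycles (untimed)
#' @param cycles timed cycles
#' @param seed seed for the synthetic document and the UUID source
#' @param output_format `"xml"` or `"json"` target serialization
#' @return list with `report` (one row per engine x example with
#'   mean/min/max/median/std), `adjusted` (overhead-adjusted means per
#'   engine) and `speedup` (interpreted / compiled adjusted means)
#' @export
run_benchmark <- function(n_observations = 1000, warmup = 5, cycles = 50,
                          seed = 1, output_format = c("xml", "json")) {
  output_format <- match.arg(output_format)
  models <- load_fixture_models()
  input_text <- mini_cda_document(n_observations, seed = seed)
  asts <- list(lab = parse_fml(example_map("cda_lab_bundle")),
               noop = parse_fml(example_map("noop")))
  progs <- lapply(asts, function(a) load_generated_program(
    compile_map(a, models)))

  serialize <- function(node) {
    if (output_format == "xml") write_xml_instance(node, models)
    else write_fhir_json(node, models)
  }
  run_cycle <- function(engine, example) {
    ast <- asts[[example]]
    force(ast)
    if (engine == "compiled") {
      env <- progs[[example]]
      function() {
        ctx <- make_map_context(ast, models, seed = seed)
        src <- read_xml_instance(input_text, models, "ClinicalDocument")
        invisible(serialize(env$fml__run(src, ctx)))
      }
    } else {
      function() {
        ctx <- make_map_context(ast, models, seed = seed)
        src <- read_xml_instance(input_text, models, "ClinicalDocument")
        invisible(serialize(interpret_map(ast, src, models, ctx = ctx)))
      }
    }
  }

  rows <- list()
  timings <- list()
  for (engine in c("compiled", "interpreted")) {
    for (example in c("noop", "lab")) {
      cycle <- run_cycle(engine, example)
      gc(FALSE)  # start each block from a comparable allocator state
      for (i in seq_len(warmup)) cycle()
      times <- vapply(seq_len(cycles), function(i) time_once(cycle), numeric(1))
      stats <- bench_stats(times)
      timings[[paste(engine, example, sep = ".")]] <- times
      rows[[length(rows) + 1L]] <- data.frame(
        engine = engine, example = example, n = n_observations,
        mean = stats[["mean"]], min = stats[["min"]], max = stats[["max"]],
        median = stats[["median"]], std = stats[["std"]],
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  mean_of <- function(engine, example) {
    report$mean[report$engine == engine & report$example == example]
  }
  adjusted <- c(
    compiled = mean_of("compiled", "lab") - mean_of("compiled", "noop"),
    interpreted = mean_of("interpreted", "lab") - mean_of("interpreted", "noop")
  )
  list(report = report, adjusted = adjusted,
       speedup = unname(adjusted[["interpreted"]] / adjusted[["compiled"]]))
}
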