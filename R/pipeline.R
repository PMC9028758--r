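# Pipeline runner: generation -> extraction -> decision -> evaluation as one
# reproducible, manifest-carrying run over the documented file dialects.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Run seed; per-stage child seeds are derived from it by a
#'   fixed stage-name-keyed scheme, so stages re-run identically in
#'   isolation.
#' @param n_cases Cohort size (ignored when `input_corpus` is given).
#' @param noise A `ich_noise_model`.
#' @param plan_mix,split_ratio Passed to [cohort_spec()].
#' @param lexicon_path,logic_table_path,gold_table_path,templates_path
#'   Optional configuration file paths; `NULL` uses the packaged defaults.
#'   Referenced files must exist at load.
#' @param input_corpus,input_gold Optional paths to an existing eEMR corpus
#'   and gold-standard file; when given the generate stage is skipped.
#' @return A `ich_run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, n_cases = 100L,
                       noise = noise_model(), plan_mix = NULL,
                       split_ratio = split_preset_622(),
                       lexicon_path = NULL, logic_table_path = NULL,
                       gold_table_path = NULL, templates_path = NULL,
                       input_corpus = NULL, input_gold = NULL) {
  for (p in c(lexicon_path, logic_table_path, gold_table_path, templates_path,
    input_corpus, input_gold)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("configuration error: referenced file not found: ", p))
    }
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), n_cases = as.integer(n_cases),
      noise = noise, plan_mix = plan_mix, split_ratio = split_ratio,
      lexicon_path = lexicon_path, logic_table_path = logic_table_path,
      gold_table_path = gold_table_path, templates_path = templates_path,
      input_corpus = input_corpus, input_gold = input_gold
    ),
    class = "ich_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()] (noise given as a
#'   mapping of rate names).
#' @return A `ich_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("configuration error: config file not found: ", path))
  }
  raw <- yaml::yaml.load_file(path)
  noise <- if (is.null(raw$noise)) noise_model() else do.call(noise_model, raw$noise)
  run_config(
    out_dir = raw$out_dir %||% ".",
    seed = raw$seed %||% 1L,
    n_cases = raw$n_cases %||% 100L,
    noise = noise,
    plan_mix = if (!is.null(raw$plan_mix)) unlist(raw$plan_mix) else NULL,
    split_ratio = raw$split_ratio %||% split_preset_622(),
    lexicon_path = raw$lexicon_path, logic_table_path = raw$logic_table_path,
    gold_table_path = raw$gold_table_path, templates_path = raw$templates_path,
    input_corpus = raw$input_corpus, input_gold = raw$input_gold
  )
}

#' Run the full pipeline
#'
#' Generate (unless an input corpus is supplied), extract, decide, evaluate;
#' write every stage artifact plus a manifest (seed, configuration hash,
#' package version, per-stage record counts) into `out_dir`.
#'
#' @param config A `ich_run_config` or path to a YAML config.
#' @return The `ich_metrics` of the run, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ich_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  lexicon <- if (is.null(config$lexicon_path)) {
    default_lexicon()
  } else {
    read_lexicon(config$lexicon_path)
  }
  table <- if (is.null(config$logic_table_path)) {
    default_logic_table()
  } else {
    read_logic_table(config$logic_table_path)
  }
  gold_table <- if (is.null(config$gold_table_path)) {
    table
  } else {
    read_logic_table(config$gold_table_path)
  }
  templates <- if (is.null(config$templates_path)) {
    default_templates()
  } else {
    read_templates(config$templates_path)
  }

  # -- generate ---------------------------------------------------------------
  if (is.null(config$input_corpus)) {
    spec <- cohort_spec(
      n_cases = config$n_cases, seed = stage_seed(config$seed, "generate"),
      plan_mix = config$plan_mix, noise = config$noise,
      split_ratio = config$split_ratio
    )
    cohort <- generate_cohort(spec, gold_table, templates, lexicon)
    records <- cohort$records
    gold <- cohort$gold
    write_emr_corpus(records, file.path(config$out_dir, "corpus.jsonl"))
    write_gold_standard(gold, file.path(config$out_dir, "gold.jsonl"))
    utils::write.csv(cohort$split, file.path(config$out_dir, "split.csv"),
      row.names = FALSE
    )
  } else {
    records <- read_emr_corpus(config$input_corpus)
    if (is.null(config$input_gold)) {
      abort("configuration error: input_corpus requires input_gold")
    }
    gold <- read_gold_standard(config$input_gold)
  }

  # -- extract ----------------------------------------------------------------
  mentions <- extract_entities(records, lexicon)
  assembled <- assemble_case_facts(mentions, records)
  write_mentions(mentions, file.path(config$out_dir, "mentions.jsonl"))
  write_case_facts(assembled$facts, file.path(config$out_dir, "facts.jsonl"))
  if (nrow(assembled$conflicts) > 0) {
    utils::write.csv(assembled$conflicts,
      file.path(config$out_dir, "conflicts.csv"),
      row.names = FALSE
    )
  }

  # -- decide -----------------------------------------------------------------
  decisions <- suppressWarnings(classify_plan(assembled$facts, table))
  write_decisions(decisions, file.path(config$out_dir, "decisions.jsonl"))

  # -- evaluate ---------------------------------------------------------------
  metrics <- evaluate_run(decisions, gold)
  write_metrics_report(metrics, config$out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ichtriage")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_records = nrow(records),
    n_mentions = nrow(mentions),
    n_conflicts = nrow(assembled$conflicts),
    n_decisions = nrow(decisions),
    n_evaluated = metrics$n,
    n_insufficient_data = sum(decisions$insufficient_data, na.rm = TRUE)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(metrics)
}
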