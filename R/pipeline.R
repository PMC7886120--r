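#' Select antecedent pairs for the stratified second stage
#'
#' Chooses which pre-onset rule pairs define the strata in which
#' post-onset complications are mined. Three policies cover the designs
#' of interest: the top rules by support; the top rules by support among
#' rules free of a given code set (e.g. the strongest combination not
#' involving sleeping disorder); or an explicit list of pairs. Directed
#' duplicates of the same unordered pair collapse to one stratum.
#'
#' @param rules Sorted rule tibble from [mine_rules()].
#' @param policy One of `"top_n"`, `"top_n_excluding"`, `"explicit"`.
#' @param n Number of pairs for the top-n policies.
#' @param exclude Character vector of codes to avoid
#'   (`"top_n_excluding"`).
#' @param pairs List of length-2 character vectors (`"explicit"`).
#' @return A list of length-2 character vectors (x, y).
#' @export
select_antecedents <- function(rules,
                               policy = c("top_n", "top_n_excluding", "explicit"),
                               n = 1L, exclude = character(), pairs = NULL) {
  policy <- match.arg(policy)
  if (policy == "explicit") {
    stopifnot(is.list(pairs), all(vapply(pairs, length, integer(1)) == 2L))
    return(lapply(pairs, truncate_code))
  }
  if (policy == "top_n_excluding") {
    keep <- !(rules$x_code %in% exclude | rules$y_code %in% exclude)
    rules <- rules[keep, , drop = FALSE]
  }
  seen <- character(); out <- list()
  for (i in seq_len(nrow(rules))) {
    key <- paste(sort(c(rules$x_code[i], rules$y_code[i])), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- c(rules$x_code[i], rules$y_code[i])
    if (length(out) == n) break
  }
  if (length(out) == 0L) message("antecedent selection produced no pairs")
  out
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input` (path to a claims file) or `synthetic` (a
#' [synthetic_config()]) supplies the claims. Defaults follow the study
#' design: 730-day windows around the first F32 claim, pairs kept at
#' joint count >= 51 and confidence >= 0.5, top-10 rules reported, Mapper
#' with 5 intervals at 50% overlap, and no Mapper graph for strata
#' yielding fewer than `min_rules_for_mapper` rules.
#'
#' @param input Optional claims file path (see [read_claims()]).
#' @param input_cols Optional named list overriding `patient_col`,
#'   `code_col`, `date_col`.
#' @param synthetic Optional [synthetic_config()].
#' @param cohort A [cohort_spec()].
#' @param pre_filter,post_filter [rule_filter()]s for the two stages.
#' @param mapper A [mapper_config()].
#' @param antecedents Arguments for [select_antecedents()] as a list
#'   (`policy`, `n`, `exclude`, `pairs`).
#' @param min_rules_for_mapper Minimum rule count for a Mapper graph to
#'   be drawn for a table (default 10); smaller tables are skipped with a
#'   log line.
#' @param outdir Output directory (created if absent).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, input_cols = list(),
                            synthetic = NULL, cohort = cohort_spec(),
                            pre_filter = rule_filter(top_k = 10L),
                            post_filter = rule_filter(top_k = 10L),
                            mapper = mapper_config(),
                            antecedents = list(policy = "top_n", n = 1L),
                            min_rules_for_mapper = 10L, outdir) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of 'input' or 'synthetic' must be given", call. = FALSE)
  }
  if (min_rules_for_mapper < 2L) stop("min_rules_for_mapper must be >= 2", call. = FALSE)
  structure(list(input = input, input_cols = input_cols, synthetic = synthetic,
                 cohort = cohort, pre_filter = pre_filter,
                 post_filter = post_filter, mapper = mapper,
                 antecedents = antecedents,
                 min_rules_for_mapper = as.integer(min_rules_for_mapper),
                 outdir = outdir),
            class = "pipeline_config")
}

.maybe_mapper <- function(rules, config, stem, log) {
  if (nrow(rules) < config$min_rules_for_mapper) {
    log(sprintf("skipping Mapper for %s: %d rule(s) < min_rules_for_mapper = %d",
                basename(stem), nrow(rules), config$min_rules_for_mapper))
    return(NULL)
  }
  graph <- run_mapper(rule_index_matrix(rules), config$mapper)
  write_mapper_graphml(graph, paste0(stem, ".graphml"))
  write_mapper_dot(graph, paste0(stem, ".dot"))
  write_mapper_membership(graph, paste0(stem, "_membership.csv"))
  graph
}

#' Run the full two-stage study pipeline
#'
#' Executes cohort extraction, first-stage pre-onset rule mining with its
#' Mapper graph, antecedent selection, and per-stratum second-stage
#' post-onset rule mining with conditional Mapper graphs, writing every
#' artifact under `config$outdir`:
#'
#' * `cohort_summary.csv` — one row per cohort patient;
#' * `pre_rules.csv` — first-stage rule table;
#' * `pre_mapper.{graphml,dot}` + `pre_mapper_membership.csv` — first-stage
#'   Mapper graph (when the rule count reaches `min_rules_for_mapper`);
#' * `strata/<X>_<Y>/post_rules.csv` (+ Mapper files) per antecedent pair;
#' * `run.log` — log lines also echoed to the console;
#' * `manifest.json` — config echo, cohort size, per-stage rule counts and
#'   file inventory, written last.
#'
#' The run is deterministic: identical config (including the synthetic
#' seed) reproduces byte-identical tables and graphs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list mirroring `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg)
    writeLines(line, log_con); message(line)
  }
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, basename(path))

  claims <- if (!is.null(config$input)) {
    log(paste("reading claims from", config$input))
    do.call(read_claims, c(list(config$input), config$input_cols))
  } else {
    log(sprintf("generating synthetic claims (n = %d, seed = %d)",
                config$synthetic$n_patients, config$synthetic$seed))
    generate_claims(config$synthetic)
  }
  journeys <- extract_cohort(claims, config$cohort)
  t <- nrow(journeys)
  log(sprintf("cohort: t = %d patients with index code %s", t,
              config$cohort$index_code))
  emit(write_cohort_summary(journeys, file.path(config$outdir, "cohort_summary.csv")))

  pre_matrix <- binarize(journeys, "pre")
  pre_rules <- mine_rules(pre_matrix, config$pre_filter)
  log(sprintf("first stage: %d pre-onset rule(s) pass the filters", nrow(pre_rules)))
  emit(write_rule_table(pre_rules, file.path(config$outdir, "pre_rules.csv")))
  pre_graph <- .maybe_mapper(pre_rules, config,
                             file.path(config$outdir, "pre_mapper"), log)
  if (!is.null(pre_graph)) {
    emit(file.path(config$outdir, "pre_mapper.graphml"))
    emit(file.path(config$outdir, "pre_mapper.dot"))
    emit(file.path(config$outdir, "pre_mapper_membership.csv"))
  }

  ante <- do.call(select_antecedents, c(list(pre_rules), config$antecedents))
  strata <- list()
  for (pair in ante) {
    tag <- paste(pair, collapse = "_")
    stratum_dir <- file.path(config$outdir, "strata", tag)
    dir.create(stratum_dir, recursive = TRUE, showWarnings = FALSE)
    res <- stratified_rules(journeys, pair, config$post_filter)
    log(sprintf("stratum {%s}: subset size %d, %d post-onset rule(s)",
                paste(pair, collapse = ", "), res$subset_size, nrow(res$rules)))
    write_rule_table(res$rules, file.path(stratum_dir, "post_rules.csv"))
    outputs <- c(outputs, file.path("strata", tag, "post_rules.csv"))
    graph <- .maybe_mapper(res$rules, config,
                           file.path(stratum_dir, "post_mapper"), log)
    if (!is.null(graph)) {
      outputs <- c(outputs, file.path("strata", tag,
                                      c("post_mapper.graphml", "post_mapper.dot",
                                        "post_mapper_membership.csv")))
    }
    strata[[tag]] <- list(antecedent = pair, subset_size = res$subset_size,
                          n_rules = nrow(res$rules),
                          mapper_drawn = !is.null(graph))
  }

  manifest <- list(
    tool = paste("rulemapper", as.character(utils::packageVersion("rulemapper"))),
    config = .echo_config(config),
    cohort_size = t,
    n_pre_rules = nrow(pre_rules),
    pre_mapper_drawn = !is.null(pre_graph),
    strata = strata,
    outputs = sort(unique(outputs))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  log("manifest written; run complete")
  invisible(manifest)
}

# config echo for the manifest: plain lists, dates as strings
.echo_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, "Date")) return(as.character(x))
    if (inherits(x, "planted_rule") || inherits(x, "synthetic_config") ||
        inherits(x, "cohort_spec") || inherits(x, "rule_filter") ||
        inherits(x, "mapper_config") || inherits(x, "pipeline_config")) {
      return(lapply(unclass(x), strip))
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(config)
}
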