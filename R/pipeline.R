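# End-to-end pipeline driver: preprocess -> learn (full network and its
# Markov-blanket restriction) -> evaluate -> sensitivity -> what-if, each
# stage writing one artifact stamped with the config hash and seeds.

#' Read a pipeline configuration
#'
#' One YAML file with per-stage blocks:
#' \preformatted{
#' input: survey.csv            # or simulate: {fixture: survey11, rows: ...}
#' seed: 42
#' preprocess:
#'   missing_markers: ["", "NA", "-9"]
#'   smartphone:
#'     column: Smartphone_Time
#'     nonuser: never_used
#'     dontknow: dont_know
#'   merges: []                 # list of merge_spec fields
#' learn:
#'   score: bdeu
#'   equivalent_sample_size: 1.0
#'   max_parents: 3
#'   smoothing_alpha: 1.0
#' sensitivity:
#'   target: Obesity_Level
#' whatif:
#'   scenarios: scenarios.yaml
#' evaluate:
#'   models: [gbn, gbn-mb, nb]
#'   folds: 10
#' }
#' Stage blocks other than `learn` and `sensitivity` may be omitted, in which
#' case the stage is skipped.
#'
#' @param path YAML file path.
#' @return the parsed configuration list, with `config_hash` (md5 of the
#'   file) attached.
#' @export
read_pipeline_config <- function(path) {
  gbn_assert(file.exists(path), "config",
             paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  cfg$config_hash <- unname(tools::md5sum(path))
  cfg$config_dir <- dirname(normalizePath(path))
  cfg
}

resolve_path <- function(p, base) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) return(p)
  file.path(base, p)
}

validate_pipeline_config <- function(cfg) {
  gbn_assert(!is.null(cfg$input) || !is.null(cfg$simulate), "config",
             "config needs either an input CSV or a simulate block")
  if (!is.null(cfg$input)) {
    gbn_assert(file.exists(cfg$input), "config",
               paste0("input file not found: ", cfg$input))
  }
  gbn_assert(!is.null(cfg$sensitivity$target), "config",
             "config needs sensitivity: target")
  if (!is.null(cfg$whatif$scenarios)) {
    gbn_assert(file.exists(cfg$whatif$scenarios), "config",
               paste0("scenario file not found: ", cfg$whatif$scenarios))
  }
  invisible(TRUE)
}

pipeline_log <- function(verbose, ...) {
  message("[gbnwhatif] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load/simulate, preprocess, learn the full
#' network and the blanket-restricted classifier, cross-validated
#' evaluation, sensitivity-to-findings, what-if scenarios — and writes one
#' artifact per stage into `out_dir` (`cleaned.csv`, `network.json`,
#' `network_mb.json`, `evaluation.tsv`, `sensitivity.tsv`,
#' `scenario_<name>.json`, plus `run_info.json` with the config hash and
#' seeds). A stage failure aborts the run with the stage name attached and
#' removes partial outputs. Reruns with an identical config and seed are
#' byte-identical apart from the timestamp recorded in `run_info.json`.
#'
#' @param config a configuration list from [read_pipeline_config()] (or an
#'   equivalent list; paths must then be resolvable from the working
#'   directory).
#' @param out_dir output directory, created if needed.
#' @param verbose emit progress to stderr.
#' @return named list of artifact paths, invisibly; the in-memory stage
#'   results are attached as attributes (`net`, `mb`, `sensitivity`,
#'   `evaluation`, `reports`, `filter_report`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  seed <- as.integer(config$seed %||% 1L)
  stage <- "load"
  on_fail <- function(c_) {
    unlink(written)
    gbn_abort("pipeline",
              paste0("stage '", stage, "' failed: ", conditionMessage(c_)),
              stage = stage, parent = c_)
  }
  tryCatch({
    # ---- load or simulate
    if (!is.null(config$input)) {
      data <- utils::read.csv(config$input, stringsAsFactors = FALSE,
                              check.names = FALSE,
                              colClasses = "character")
    } else {
      sim <- config$simulate
      net0 <- build_fixture(sim[["fixture"]] %||% "survey11",
                            seed = derive_seed(seed, 1))
      cs <- corruption_spec(missing_rate = sim[["missing"]] %||% 0,
                            nonuser_rate = sim[["nonuser"]] %||% 0,
                            dontknow_rate = sim[["dontknow"]] %||% 0,
                            seed = derive_seed(seed, 2))
      # note: the row-count key is "rows" ("n" is a YAML 1.1 boolean literal)
      data <- generate_survey(net0, sim[["rows"]] %||% 1000, cs,
                              seed = derive_seed(seed, 3))$data
    }
    pipeline_log(verbose, "loaded ", nrow(data), " rows, ", ncol(data),
                 " columns")

    # ---- preprocess
    stage <- "preprocess"
    pp <- config$preprocess %||% list()
    fr <- filter_rows(data,
                      missing_markers = unlist(pp$missing_markers %||%
                                                 c("", "NA", "-9")),
                      smartphone_rules = pp$smartphone %||%
                        (if ("Smartphone_Time" %in% names(data))
                          list(column = "Smartphone_Time",
                               nonuser = "never_used", dontknow = "dont_know")))
    data <- fr$data
    rep_ <- fr$report
    pipeline_log(verbose, "filter: ", rep_$rows_in, " -> ", rep_$rows_out,
                 " rows (missing ", rep_$rows_dropped_missing,
                 ", non-user ", rep_$rows_dropped_nonuser,
                 ", don't-know ", rep_$rows_dropped_dontknow, ")")
    if (length(pp$merges) > 0) {
      specs <- lapply(pp$merges, function(m) do.call(merge_spec, m))
      data <- merge_attributes(data, specs)
    }
    cleaned_path <- file.path(out_dir, "cleaned.csv")
    utils::write.csv(data, cleaned_path, row.names = FALSE)
    written <- c(written, cleaned_path)

    # ---- learn
    stage <- "learn"
    lc <- config$learn %||% list()
    lc$seed <- lc$seed %||% derive_seed(seed, 4)
    lconf <- as_learner_config(lc)
    target <- config$sensitivity$target
    net <- learn_structure(data, lconf)
    mb <- gbn_mb_classifier(data, target, lconf)
    pipeline_log(verbose, "learned network with ",
                 nrow(net$structure$edges), " edges; blanket of ", target,
                 ": {", paste(mb$selection$blanket, collapse = ", "), "}",
                 "; discarded: {",
                 paste(mb$selection$discarded, collapse = ", "), "}")
    net_path <- file.path(out_dir, "network.json")
    mb_path <- file.path(out_dir, "network_mb.json")
    write_dbn_json(net, net_path)
    write_dbn_json(mb$net, mb_path)
    written <- c(written, net_path, mb_path)

    # ---- evaluate
    stage <- "evaluate"
    ev_paths <- character(0)
    evaluation <- NULL
    if (!is.null(config$evaluate)) {
      ec <- config$evaluate
      evaluation <- evaluate_models(data, target,
                                    models = unlist(ec$models %||%
                                                      c("gbn", "gbn-mb", "nb")),
                                    k = ec$folds %||% 10L,
                                    seed = derive_seed(seed, 5),
                                    config = lconf)
      eval_path <- file.path(out_dir, "evaluation.tsv")
      write_evaluation_tsv(evaluation, eval_path)
      written <- c(written, eval_path)
      ev_paths <- eval_path
    }

    # ---- sensitivity
    stage <- "sensitivity"
    sens <- sensitivity_to_findings(net, target)
    sens_path <- file.path(out_dir, "sensitivity.tsv")
    write_sensitivity_tsv(sens, sens_path)
    written <- c(written, sens_path)

    # ---- what-if
    stage <- "whatif"
    reports <- list()
    scn_paths <- character(0)
    if (!is.null(config$whatif$scenarios)) {
      for (scn in read_scenarios(config$whatif$scenarios)) {
        rep2 <- apply_scenario(net, scn)
        p <- file.path(out_dir,
                       paste0("scenario_", gsub("[^A-Za-z0-9]+", "_",
                                                scn$name), ".json"))
        write_scenario_json(rep2, p)
        written <- c(written, p)
        scn_paths <- c(scn_paths, p)
        reports[[scn$name]] <- rep2
      }
    }

    # ---- run stamp
    stage <- "stamp"
    info_path <- file.path(out_dir, "run_info.json")
    jsonlite::write_json(list(
      config_hash = config$config_hash %||% NA,
      seed = seed,
      filter_report = unclass(rep_),
      mb_blanket = mb$selection$blanket,
      mb_discarded = mb$selection$discarded,
      timestamp = format(Sys.time(), tz = "UTC")
    ), info_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, info_path)

    out <- list(cleaned = cleaned_path, network = net_path,
                network_mb = mb_path, evaluation = ev_paths,
                sensitivity = sens_path, scenarios = scn_paths,
                run_info = info_path)
    attr(out, "net") <- net
    attr(out, "mb") <- mb
    attr(out, "sensitivity") <- sens
    attr(out, "evaluation") <- evaluation
    attr(out, "reports") <- reports
    attr(out, "filter_report") <- rep_
    invisible(out)
  }, gbn_error = function(c_) {
    if (inherits(c_, "gbn_pipeline")) stop(c_)
    on_fail(c_)
  }, error = function(c_) {
    if (inherits(c_, "gbn_pipeline")) stop(c_)
    on_fail(c_)
  })
}
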