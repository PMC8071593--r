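#' @title End-to-end pipeline
#' @description One call runs the whole workflow: obtain group CLDs
#'   (synthetic ensemble or CSV files), merge them hierarchically into
#'   country maps and a master map, enumerate and classify the master's
#'   feedback loops, and write every artifact (maps as CSV + GraphML +
#'   DOT, merge reports, loop report, summary, manifest with checksums)
#'   under one output directory.
#' @name cli_reporting
NULL

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("input file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Load group CLDs from edge CSV files
#'
#' @param files named list: country id -> character vector of edge-CSV
#'   paths; a sibling `*_variables.csv` is picked up automatically when
#'   present.
#' @param lexicon theme lexicon for labels without a variables file.
#' @return named list: country -> list of `cld`.
#' @export
load_file_groups <- function(files, lexicon = default_theme_lexicon()) {
  stopifnot(is.list(files), !is.null(names(files)))
  out <- list()
  for (ctry in sort_c(names(files))) {
    paths <- files[[ctry]]
    out[[ctry]] <- lapply(paths, function(p) {
      if (!file.exists(p)) stop("input file not found: ", p)
      vp <- default_variables_path(p)
      read_cld_csv(p, if (file.exists(vp)) vp else NULL,
                   map_id = slugify(sub("\\.csv$", "", basename(p))),
                   level = "group", lexicon = lexicon)
    })
  }
  out
}

#' Run the full merge-and-loops pipeline
#'
#' The configuration is a list (or a path to a JSON/YAML file) with
#' fields:
#' \describe{
#'   \item{mode}{"synthetic" or "files" (exactly one input mode).}
#'   \item{synthetic}{for synthetic mode, arguments passed to
#'     `synthetic_study_config()` (e.g. `seed`).}
#'   \item{files}{for files mode, named list: country -> character
#'     vector of edge-CSV paths; a sibling `*_variables.csv` is picked
#'     up automatically when present.}
#'   \item{merge}{options: `prune_mode` ("fixpoint"/"single_pass"),
#'     `fuzzy_threshold`, `synonyms` (CSV path), `decisions` (CSV
#'     path).}
#'   \item{loops}{options: `max_length` (default 12), `max_cycles`
#'     (default 10000).}
#'   \item{out_dir}{output directory, created if needed.}
#' }
#'
#' @param config list or path to JSON/YAML config.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `master`, `country_maps`, `loops`,
#'   `reports` and `manifest` (data.frame of artifact paths and md5
#'   checksums, also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  mode <- config$mode %||% stop("config$mode must be 'synthetic' or 'files'")
  if (!mode %in% c("synthetic", "files")) {
    stop("config$mode must be 'synthetic' or 'files'")
  }
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  mcfg <- config$merge %||% list()
  if (is.character(mcfg$synonyms)) {
    mcfg$synonyms <- read_synonym_map(mcfg$synonyms)
  }
  if (is.character(mcfg$decisions)) {
    mcfg$decisions <- read_decision_file(mcfg$decisions)
  }
  synonyms <- mcfg$synonyms
  merge_cfg <- list(prune_mode = mcfg$prune_mode %||% "fixpoint",
                    fuzzy_threshold = mcfg$fuzzy_threshold,
                    decisions = mcfg$decisions)
  lcfg <- config$loops %||% list()
  max_length <- lcfg$max_length %||% 12
  max_cycles <- lcfg$max_cycles %||% 10000

  ground_truth <- NULL
  if (mode == "synthetic") {
    scfg <- do.call(synthetic_study_config, config$synthetic %||% list())
    say("generating synthetic study (seed ", scfg$seed, ")")
    study <- generate_study(scfg)
    groups <- lapply(study, function(entries) lapply(entries, `[[`, "cld"))
    ground_truth <- study_ground_truth(study)
  } else {
    if (is.null(config$files)) stop("config$files is required in files mode")
    groups <- load_file_groups(config$files)
  }

  say("merging ", sum(lengths(groups)), " group maps from ",
      length(groups), " countries")
  merged <- merge_hierarchical(groups, synonyms, merge_cfg)
  master <- merged$master

  say("enumerating feedback loops (max length ", max_length, ")")
  loops <- rank_loops(find_feedback_loops(master, max_length, max_cycles))

  paths <- character(0)
  emit <- function(p) { paths[length(paths) + 1] <<- p; p }
  for (ctry in names(merged$country_maps)) {
    write_cld(merged$country_maps[[ctry]],
              emit(file.path(out_dir, paste0("country_", ctry, ".csv"))),
              "csv",
              emit(file.path(out_dir,
                             paste0("country_", ctry, "_variables.csv"))))
  }
  write_cld(master, emit(file.path(out_dir, "master.csv")), "csv",
            emit(file.path(out_dir, "master_variables.csv")))
  write_cld(master, emit(file.path(out_dir, "master.graphml")), "graphml")
  write_cld(master, emit(file.path(out_dir, "master.dot")), "dot",
            highlight = if (length(loops)) loops[[1]])
  write_merge_reports(merged$reports,
                      emit(file.path(out_dir, "merge_reports.json")))
  write_loop_report(loops,
                    emit(file.path(out_dir, "loop_report.tsv")),
                    emit(file.path(out_dir, "loop_report.json")))
  if (!is.null(ground_truth)) {
    utils::write.csv(ground_truth,
                     emit(file.path(out_dir, "planted_loops.csv")),
                     row.names = FALSE)
  }
  writeLines(summarize_cld(master, loops),
             emit(file.path(out_dir, "summary.txt")))

  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote ", nrow(manifest) + 1, " artifacts to ", out_dir)
  invisible(list(master = master, country_maps = merged$country_maps,
                 loops = loops, reports = merged$reports,
                 manifest = manifest))
}

#' Deterministic text summary of a map and its loops
#'
#' @param master a `cld`.
#' @param loops list of `feedback_loop` (as from
#'   `find_feedback_loops()`).
#' @return character vector of summary lines.
#' @export
summarize_cld <- function(master, loops = list()) {
  npos <- sum(master$links$polarity == 1L)
  nneg <- sum(master$links$polarity == -1L)
  cls <- vapply(loops, `[[`, character(1), "classification")
  lines <- c(
    sprintf("map: %s (level %s)", master$map_id, master$level),
    sprintf("variables: %d", nrow(master$variables)),
    sprintf("links: %d (%d positive, %d negative)",
            nrow(master$links), npos, nneg),
    sprintf("feedback loops: %d (%d reinforcing, %d balancing)",
            length(loops), sum(cls == "reinforcing"),
            sum(cls == "balancing")))
  if (nrow(master$variables) > 0) {
    tab <- table(factor(master$variables$theme, levels = cld_themes()))
    tab <- tab[tab > 0]
    lines <- c(lines, "variables by theme:",
               sprintf("  %s: %d", names(tab), as.integer(tab)))
  }
  lines
}
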