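# Orchestration: a validated run configuration chains
# simulate -> segment -> stats -> triage and writes the result tables.

default_run_config <- function() {
  list(assay = "salt", condition = "stress", seed = 1,
       wild_type = "Col-0", replicates = NULL, out_dir = NULL,
       lines = list(list(id = "Col-0")),
       assay_overrides = list(), verbosity = "INFO")
}

# stable small checksum for result-file headers (order-independent
# serialisation via sorted YAML)
config_hash <- function(config) {
  txt <- yaml::as.yaml(config[order(names(config))])
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- (xor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Validate a pipeline run configuration
#'
#' Merges user settings over the defaults and type-checks them; every
#' assay threshold can be overridden through `assay_overrides` (checked
#' against [assay_config()] keys). Unknown keys are an error that names
#' the key, so typos never silently fall back to a default.
#'
#' @param config named list, or path to a YAML file.
#' @return A validated list of class `run_config` (with the
#'   [assay_config()] instantiated under `$assay_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config[setdiff(names(config), "lines")])
  if (!is.null(config$lines)) cfg$lines <- config$lines
  if (!cfg$assay %in% c("salt", "arsenic", "freezing", "phosphate"))
    stop("unknown assay: ", cfg$assay)
  if (!cfg$condition %in% c("stress", "standard"))
    stop("unknown condition: ", cfg$condition)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  ids <- vapply(cfg$lines, function(l) l$id %||% stop("every line needs an id"),
                character(1))
  if (anyDuplicated(ids)) stop("duplicated line ids in config")
  if (!cfg$wild_type %in% ids)
    stop("config lines must include the wild-type '", cfg$wild_type, "'")
  cfg$assay_config <- assay_config(cfg$assay, cfg$condition,
                                   overrides = cfg$assay_overrides)
  cfg$hash <- config_hash(config)
  class(cfg) <- "run_config"
  cfg
}

config_specs <- function(cfg) {
  specs <- lapply(cfg$lines, function(l) {
    args <- l[setdiff(names(l), "locus")]
    names(args)[names(args) == "id"] <- "line_id"
    do.call(line_effect_spec, args)
  })
  setNames(specs, vapply(specs, `[[`, character(1), "line_id"))
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$verbosity, "QUIET")) return(invisible())
  message(sprintf("[phenoplate] %s", sprintf(...)))
}

write_result_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phenoplate %s  config=%s",
                     as.character(utils::packageVersion("phenoplate")),
                     cfg$hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Segment a set of generated plates into seedling records
#'
#' @param plates list of [generate_plate()] results.
#' @param config an [assay_config()].
#' @return Combined records data frame.
#' @export
segment_plates <- function(plates, config) {
  recs <- lapply(plates, function(pl) {
    rep <- pl$replicate %||% NA_integer_
    switch(config$assay,
      salt = run_salt_plate(pl$vis, pl$fluo, pl$layout, config, rep),
      arsenic = run_arsenic_plate(pl$vis, pl$fluo, pl$layout, config, rep),
      freezing = run_freezing_plate(pl$vis, pl$layout, config, rep),
      phosphate = run_phosphate_plate(pl$vis, pl$layout, config, rep))
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(NULL)
  do.call(rbind, c(recs, make.row.names = FALSE))
}

#' Run the full pipeline on a simulated experiment
#'
#' Chains the stages end to end: synthetic-plate generation for the
#' configured lines, per-plate segmentation, state calling (two-group
#' colour clustering for salt/arsenic, the damage flag for freezing,
#' the root-length proxy for phosphate), line-versus-wild-type testing
#' with BH-FDR control, the multi-trait profile clustering, and the
#' per-gene summary. When `out_dir` is set, writes `records.csv`,
#' `results.csv`, `summary.csv` and `heatmap.csv` (each with a header
#' comment carrying the tool version and config hash).
#'
#' @param config a [validate_config()] result, a named list, or a YAML
#'   path.
#' @return List with `records`, `results`, `summary`, `multitrait` and
#'   `truth` (generator ground truth), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  specs <- config_specs(cfg)
  pipeline_log(cfg, "simulating %d line(s), assay %s, seed %d",
               length(specs), cfg$assay, cfg$seed)
  sim <- generate_experiment(cfg$assay, specs, replicates = cfg$replicates,
                             seed = cfg$seed, wild_type = cfg$wild_type)
  t0 <- proc.time()[3]
  records <- segment_plates(sim$plates, cfg$assay_config)
  if (is.null(records)) stop("segmentation produced no records")
  pipeline_log(cfg, "segmented %d seedling(s) from %d plate(s) in %.1fs",
               nrow(records), length(sim$plates), proc.time()[3] - t0)

  acfg <- cfg$assay_config
  if (cfg$assay %in% c("salt", "arsenic")) {
    records <- two_group_color_clustering(records,
                                          labels = acfg$group_labels,
                                          linkage = acfg$linkage)
    tab <- count_groups(records)
    results <- line_significance(tab, "fisher", cfg$wild_type,
                                 condition = cfg$assay)
  } else if (cfg$assay == "freezing") {
    tab <- count_groups(records)
    results <- line_significance(tab, "fisher", cfg$wild_type,
                                 condition = cfg$assay)
  } else {
    tab <- data.frame(line_id = records$line_id, value = records$major_axis)
    results <- line_significance(tab, "anova", cfg$wild_type,
                                 condition = cfg$assay)
  }
  loci <- vapply(cfg$lines, function(l) l$locus %||% l$id, character(1))
  names(loci) <- vapply(cfg$lines, `[[`, character(1), "id")
  res_tri <- results
  res_tri$locus <- loci[res_tri$line_id]
  res_tri$stress <- cfg$assay
  summary <- summarize_genes(res_tri)
  mt <- multitrait_profile_heatmap(records)
  records$multitrait_group <- mt$plant_groups

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(records, file.path(cfg$out_dir, "records.csv"), cfg)
    write_result_csv(results, file.path(cfg$out_dir, "results.csv"), cfg)
    write_result_csv(summary, file.path(cfg$out_dir, "summary.csv"), cfg)
    write_result_csv(as.data.frame(mt$density),
                     file.path(cfg$out_dir, "heatmap.csv"), cfg)
    pipeline_log(cfg, "results written to %s", cfg$out_dir)
  }
  invisible(list(records = records, results = results, summary = summary,
                 multitrait = mt, truth = sim$truth,
                 expected = sim$expected))
}
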