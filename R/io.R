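# Shared readers/writers, pipeline configuration, and the end-to-end
# workflow: simulate/ingest -> curate -> featurize -> cross-validate ->
# train -> screen.

#' Read a compound table
#'
#' Formats: `csv` (columns `compound_id`, `smiles`, `source`,
#' `activity_value`, optionally `label`), `smiles` (whitespace-separated
#' `SMILES id` lines), or `sdf` (identifiers from the molecule title;
#' `source`/`activity_value`/`label` from SD tags when present). Rows with
#' an empty or missing SMILES are collected into the `rejected` attribute,
#' never silently dropped.
#'
#' @param path input file.
#' @param format `"csv"`, `"smiles"` or `"sdf"` (default: by extension).
#' @return data.frame of records, with attribute `rejected` (data.frame of
#'   malformed rows and reasons).
#' @export
read_compounds <- function(path, format = NULL) {
  stopifnot(file.exists(path))
  format <- format %||% guess_format(path)
  rec <- switch(format,
    csv = read_compounds_csv(path),
    smiles = read_compounds_smiles(path),
    sdf = read_compounds_sdf(path),
    stop("unsupported format: ", format))
  rec
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = "csv", smi = "smiles", smiles = "smiles", sdf = "sdf",
         stop("cannot infer format from extension: ", ext))
}

read_compounds_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles", "source")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("CSV is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"activity_value" %in% names(df)) df$activity_value <- NA_real_
  bad <- is.na(df$smiles) | !nzchar(trimws(df$smiles))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(
    row = which(bad), reason = rep("empty-smiles", sum(bad)))
  out
}

read_compounds_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else sprintf("MOL-%05d", i)
  }, "")
  out <- data.frame(compound_id = ids, smiles = smiles, source = "library",
                    activity_value = NA_real_, stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(row = integer(0), reason = character(0))
  out
}

read_compounds_sdf <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sdf)
  n <- length(sdf)
  ids <- character(n); smiles <- character(n)
  source <- character(n); value <- rep(NA_real_, n); label <- character(n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    one <- sdf[[i]]
    ids[i] <- ChemmineR::sdfid(sdf[i])
    db <- ChemmineR::datablock(one)
    source[i] <- if ("source" %in% names(db)) db[["source"]] else "library"
    if ("activity_value" %in% names(db)) {
      value[i] <- suppressWarnings(as.numeric(db[["activity_value"]]))
    }
    label[i] <- if ("label" %in% names(db)) db[["label"]] else ""
    smi <- tryCatch(sdf_to_smiles_one(one), error = function(e) NA_character_)
    smiles[i] <- smi %||% NA_character_
  }
  ok <- valid & !is.na(smiles) & nzchar(smiles)
  out <- data.frame(compound_id = ids[ok], smiles = smiles[ok],
                    source = source[ok], activity_value = value[ok],
                    stringsAsFactors = FALSE)
  if (any(nzchar(label[ok]))) out$label <- label[ok]
  attr(out, "rejected") <- data.frame(
    row = which(!ok), reason = rep("invalid-sdf-record", sum(!ok)))
  out
}

sdf_to_smiles_one <- function(sdf_one) {
  sdfstr <- ChemmineR::sdf2str(sdf_one)
  txt <- paste(sdfstr, collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  sub("[ \t\n].*$", "", out)
}

#' Write a compound table
#'
#' @param records data.frame with at least `compound_id` and a SMILES
#'   column (`smiles` or `smiles_std`).
#' @param path output file.
#' @param format `"csv"`, `"smiles"` or `"sdf"` (default: by extension).
#' @export
write_compounds <- function(records, path, format = NULL) {
  format <- format %||% guess_format(path)
  smiles <- records$smiles_std %||% records$smiles
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else if (format == "smiles") {
    writeLines(paste(smiles, records$compound_id), path)
  } else if (format == "sdf") {
    write_compounds_sdf(records, smiles, path)
  } else {
    stop("unsupported format: ", format)
  }
  invisible(path)
}

write_compounds_sdf <- function(records, smiles, path) {
  blocks <- character(nrow(records))
  tags <- intersect(c("source", "activity_value", "label"), names(records))
  for (i in seq_len(nrow(records))) {
    sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                         paste0(smiles[i], "\t",
                                                records$compound_id[i]))
    sdf_txt <- sub("\\$\\$\\$\\$\n?$", "", sdf_txt)
    tag_txt <- ""
    for (tg in tags) {
      tag_txt <- paste0(tag_txt, "> <", tg, ">\n", records[[tg]][i], "\n\n")
    }
    blocks[i] <- paste0(sdf_txt, tag_txt, "$$$$\n")
  }
  writeLines(paste(blocks, collapse = ""), sep = "", con = path)
  invisible(path)
}

# ---- pipeline configuration -------------------------------------------------

#' Assemble a validated pipeline configuration
#'
#' Nested sections with documented defaults; unknown keys are rejected.
#' The configuration round-trips losslessly through JSON.
#'
#' @param simulation named list overriding [synthetic_config()] arguments.
#' @param curation named list: `mw_min`, `mw_max`.
#' @param modeling named list: `grid`, `k`, `alpha`, `seed`, `n_trees`,
#'   `similarity_floor`, `test_fraction`, `oversample_mode`.
#' @param funnel named list overriding [funnel_config()] arguments.
#' @param screening named list: `n_decoys`, `n_planted`,
#'   `liability_fraction`, `ro5_break_fraction`.
#' @param output_dir artifact directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = list(), curation = list(),
                            modeling = list(), funnel = list(),
                            screening = list(), output_dir = tempfile("lbvs")) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0) {
      stop("unknown ", where, " config keys: ", paste(bad, collapse = ", "))
    }
  }
  check_keys(simulation, names(formals(synthetic_config)), "simulation")
  check_keys(curation, c("mw_min", "mw_max"), "curation")
  check_keys(modeling, c("grid", "k", "alpha", "seed", "n_trees",
                         "similarity_floor", "test_fraction",
                         "oversample_mode"), "modeling")
  check_keys(funnel, names(formals(funnel_config)), "funnel")
  check_keys(screening, c("n_decoys", "n_planted", "liability_fraction",
                          "ro5_break_fraction"), "screening")
  defaults_modeling <- list(grid = list("all", "sqrt", 0.2, 0.4, 0.8),
                            k = 5, alpha = 20.0, seed = 42, n_trees = 1000,
                            similarity_floor = 0.3, test_fraction = 0.2,
                            oversample_mode = "continuous")
  defaults_screening <- list(n_decoys = 1000, n_planted = 25,
                             liability_fraction = 0.15,
                             ro5_break_fraction = 0.08)
  cfg <- list(
    simulation = simulation,
    curation = utils::modifyList(list(mw_min = 250, mw_max = 900), curation),
    modeling = utils::modifyList(defaults_modeling, modeling),
    funnel = funnel,
    screening = utils::modifyList(defaults_screening, screening),
    output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates the two bioactivity sources, curates them, featurizes with
#' both panels, selects hyperparameters by similarity-constrained CV on
#' the potency source, trains the four final models (two sources x two
#' panels), generates and screens a synthetic library through the triage
#' funnel, and writes all artifacts (curated CSVs, curation reports, CV
#' tables, model manifests, funnel report, shortlist, run manifest) to
#' `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return (invisibly) a list with the in-memory artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list(config = config)
  mcfg <- config$modeling

  # simulate the two sources
  sim_args <- config$simulation
  cfg_pot <- do.call(synthetic_config,
                     utils::modifyList(list(source_profile = "balanced_potency"),
                                       sim_args))
  sim_args_sco <- utils::modifyList(sim_args,
                                    list(source_profile = "imbalanced_score"))
  sim_args_sco$seed <- (sim_args$seed %||% 1) + 1000L
  cfg_sco <- do.call(synthetic_config, sim_args_sco)
  raw_pot <- generate_labeled_dataset(cfg_pot)
  raw_sco <- generate_labeled_dataset(cfg_sco)
  say("simulated %d potency-source and %d score-source records",
      nrow(raw_pot), nrow(raw_sco))

  # curate
  cur_pot <- curate_compounds(raw_pot, config$curation$mw_min, config$curation$mw_max)
  cur_sco <- curate_compounds(raw_sco, config$curation$mw_min, config$curation$mw_max)
  say("curated: potency %d -> %d, score %d -> %d",
      nrow(raw_pot), nrow(cur_pot$data), nrow(raw_sco), nrow(cur_sco$data))
  write_compounds(cur_pot$data, file.path(config$output_dir, "curated_potency.csv"))
  write_compounds(cur_sco$data, file.path(config$output_dir, "curated_score.csv"))
  write_json_file(list(potency = as.list(cur_pot$report),
                       score = as.list(cur_sco$report)),
                  file.path(config$output_dir, "curation_report.json"))

  # featurize
  datasets <- list(potency = cur_pot$data, score = cur_sco$data)
  features <- list()
  for (src in names(datasets)) {
    smiles <- datasets[[src]]$smiles_std
    features[[src]] <- list(ecfp4_2048 = ecfp4(smiles),
                            physchem_2d = physchem_panel(smiles))
  }

  # cross-validated hyperparameter selection on the potency source
  cv <- list()
  for (panel in c("ecfp4_2048", "physchem_2d")) {
    cv[[panel]] <- cv_select(
      features$potency[[panel]], datasets$potency$label,
      fingerprints = features$potency$ecfp4_2048,
      grid = mcfg$grid, k = mcfg$k, alpha = mcfg$alpha,
      seed = mcfg$seed, similarity_floor = mcfg$similarity_floor,
      oversample_mode = mcfg$oversample_mode, n_trees = mcfg$n_trees)
    say("CV [%s]: best max_features=%s mean BEDROC %.3f", panel,
        format(cv[[panel]]$best_max_features), cv[[panel]]$best_mean_bedroc)
    utils::write.csv(cv[[panel]]$table,
                     file.path(config$output_dir,
                               paste0("cv_", panel, ".csv")),
                     row.names = FALSE)
  }
  out$cv <- cv

  # four final bundles: two sources x two panels
  bundles <- list()
  for (src in names(datasets)) {
    for (panel in c("ecfp4_2048", "physchem_2d")) {
      key <- paste(src, panel, sep = "_")
      bundles[[key]] <- train_final(
        features[[src]][[panel]], datasets[[src]]$label,
        max_features = cv[[panel]]$best_max_features,
        panel = panel, n_trees = mcfg$n_trees, seed = mcfg$seed,
        oversample_mode = mcfg$oversample_mode)
      say("trained bundle %s", key)
    }
  }
  out$bundles <- bundles
  write_json_file(lapply(bundles, function(b) b$manifest),
                  file.path(config$output_dir, "model_manifests.json"))

  # synthetic screening library and the funnel
  scr <- config$screening
  library_raw <- generate_screening_library(
    scr$n_decoys, scr$n_planted, cfg_pot,
    liability_fraction = scr$liability_fraction,
    ro5_break_fraction = scr$ro5_break_fraction)
  lib_cur <- curate_compounds(library_raw,
                              config$curation$mw_min, config$curation$mw_max)
  fcfg <- do.call(funnel_config, config$funnel)
  known_actives <- datasets$potency$smiles_std[datasets$potency$label == "active"]
  report <- run_funnel(lib_cur$data, bundles,
                       known_active_smiles = known_actives, config = fcfg)
  out$funnel <- report
  out$library <- lib_cur$data
  if (verbose) print(report)
  write_json_file(list(stages = report$stages,
                       first_failure = as.list(report$first_failure)),
                  file.path(config$output_dir, "funnel_report.json"))
  utils::write.csv(report$shortlist,
                   file.path(config$output_dir, "shortlist.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lbvscreen")),
    seeds = list(simulation = cfg_pot$seed, modeling = mcfg$seed),
    sizes = list(potency = nrow(datasets$potency),
                 score = nrow(datasets$score),
                 library = nrow(lib_cur$data)),
    funnel_counts = stats::setNames(report$stages$n_out, report$stages$stage))
  write_json_file(manifest, file.path(config$output_dir, "run_manifest.json"))
  invisible(out)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
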