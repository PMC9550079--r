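## pipeline: end-to-end orchestration with a run directory, fixed output
## filenames, a manifest, and stage logging to stderr plus a run log.

#' Build a pipeline run configuration
#'
#' @param alignment_path aligned FASTA (study + external sequences).
#' @param metadata_path metadata TSV.
#' @param tree_path optional rooted ultrametric Newick tree (required when
#'   the GMYC method is enabled).
#' @param imported_partitions named character vector of partition TSV
#'   paths to import as additional methods (e.g. an externally computed
#'   Poisson-tree-processes partition).
#' @param out_dir output directory (created if missing).
#' @param methods character subset of `c("abgd", "linkage", "gmyc")`; at
#'   least one method (or one imported partition) must be enabled.
#' @param min_common common-overlap trimming floor (default 150).
#' @param min_overlap pairwise-deletion overlap floor (default 100).
#' @param abgd_P,abgd_X barcode-gap prior and relative gap width used for
#'   the reported partition (defaults 0.01 and 1).
#' @param linkage_threshold single-linkage distance (default 0.022).
#' @param novelty_threshold divergence-novelty threshold (default 0.05).
#' @param min_similarity best-match similarity floor (default 0.80).
#' @param seed integer seed for any stochastic step.
#' @param strict fail on cross-validation inconsistencies.
#' @return An object of class `run_config`.
#' @export
run_config <- function(alignment_path, metadata_path, tree_path = NULL,
                       imported_partitions = character(0),
                       out_dir = "barcodeconcord_run",
                       methods = c("abgd", "linkage"),
                       min_common = 150L, min_overlap = 100L,
                       abgd_P = 0.01, abgd_X = 1.0,
                       linkage_threshold = 0.022,
                       novelty_threshold = 0.05,
                       min_similarity = 0.80,
                       seed = 1L, strict = FALSE) {
  if (length(methods) == 0L && length(imported_partitions) == 0L)
    bc_stop("at least one delimitation method must be enabled")
  if (length(methods))
    methods <- match.arg(methods, c("abgd", "linkage", "gmyc"),
                         several.ok = TRUE)
  if ("gmyc" %in% methods && is.null(tree_path))
    bc_stop("the GMYC method requires a tree_path")
  structure(list(alignment_path = alignment_path,
                 metadata_path = metadata_path, tree_path = tree_path,
                 imported_partitions = imported_partitions,
                 out_dir = out_dir, methods = methods,
                 min_common = min_common, min_overlap = min_overlap,
                 abgd_P = abgd_P, abgd_X = abgd_X,
                 linkage_threshold = linkage_threshold,
                 novelty_threshold = novelty_threshold,
                 min_similarity = min_similarity,
                 seed = as.integer(seed), strict = strict),
            class = "run_config")
}

.log_stage <- function(logfile, stage, msg) {
  line <- sprintf("[%s] [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full concordance pipeline
#'
#' Executes trim, distances, delimitation (enabled methods), reference
#' matching, concordance classification and summaries, writing each stage
#' to a fixed filename inside the run directory plus a manifest with input
#' and output checksums. Reruns with identical inputs and seed produce
#' identical outputs and manifest checksums.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `status` (`"ok"` or the failed stage name).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("barcodeconcord")),
                   inputs = list(), outputs = list(), status = "ok")
  stage <- "init"
  result <- list()
  finish <- function() {
    for (f in list.files(config$out_dir, full.names = TRUE)) {
      bn <- basename(f)
      if (bn %in% c("manifest.json", "run.log")) next
      manifest$outputs[[bn]] <<- unname(tools::md5sum(f))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  tryCatch({
    stage <- "load"
    for (p in c(config$alignment_path, config$metadata_path, config$tree_path,
                unname(config$imported_partitions)))
      manifest$inputs[[basename(p)]] <- unname(tools::md5sum(p))
    sequences <- read_alignment(config$alignment_path)
    records <- read_metadata(config$metadata_path)
    tree <- if (!is.null(config$tree_path)) ape::read.tree(config$tree_path)
    imported <- lapply(names0 <- names(config$imported_partitions), function(nm)
      read_partition(config$imported_partitions[[nm]], nm))
    names(imported) <- names0
    rep <- cross_validate(sequences, records, trees = if (!is.null(tree)) list(tree),
                          partitions = imported, strict = config$strict)
    .log_stage(logfile, stage, sprintf("%d sequences, %d records, %d validation notes",
                                       length(sequences), nrow(records), nrow(rep)))

    stage <- "trim"
    tr <- trim_to_common_overlap(sequences, config$min_common)
    sequences <- tr$kept
    records <- records[records$specimen_id %in% names(sequences), ]
    .log_stage(logfile, stage, sprintf("kept %d, removed %d", length(sequences),
                                       length(tr$removed)))

    stage <- "distances"
    dm <- p_distance_matrix(sequences, config$min_overlap)
    write_distances(dm, file.path(config$out_dir, "distances.tsv"))
    .log_stage(logfile, stage, sprintf("%d x %d matrix", length(dm$ids), length(dm$ids)))

    stage <- "delimit"
    study_ids <- intersect(records$specimen_id[records$provenance == "STUDY"],
                           dm$ids)
    parts_all <- imported
    parts_study <- lapply(imported, function(p)
      partition(p$assignment[intersect(partition_scope(p), study_ids)], p$method))
    dm_study <- subset_pdist(dm, study_ids)
    if ("abgd" %in% config$methods) {
      parts_all$abgd <- abgd_partition(dm, config$abgd_P, config$abgd_X)
      parts_study$abgd <- abgd_partition(dm_study, config$abgd_P, config$abgd_X)
    }
    if ("linkage" %in% config$methods) {
      parts_all$linkage <- single_linkage_partition(dm, config$linkage_threshold)
      parts_study$linkage <- single_linkage_partition(dm_study,
                                                      config$linkage_threshold)
    }
    gfit <- NULL
    if ("gmyc" %in% config$methods) {
      gfit <- gmyc_single_threshold(tree)
      parts_all$gmyc <- gfit$partition
      keep <- intersect(partition_scope(gfit$partition), study_ids)
      parts_study$gmyc <- partition(gfit$partition$assignment[keep], "gmyc")
      write_gmyc_json(gfit, file.path(config$out_dir, "gmyc.json"))
    }
    for (nm in names(parts_all))
      write_partition(parts_all[[nm]],
                      file.path(config$out_dir, sprintf("partition_%s.tsv", nm)))
    .log_stage(logfile, stage, sprintf("methods: %s",
                                       paste(names(parts_all), collapse = ", ")))

    stage <- "match"
    matches <- match_table(sequences, records,
                           min_similarity = config$min_similarity,
                           min_overlap = config$min_overlap)
    write_matches(matches, file.path(config$out_dir, "matches.tsv"))
    novel <- flag_novelty(matches, records, config$novelty_threshold)
    firstbc <- flag_first_barcode(records)
    jsonlite::write_json(list(divergent_novel = novel, first_barcode = firstbc),
                         file.path(config$out_dir, "novelty.json"),
                         auto_unbox = FALSE, digits = NA)
    .log_stage(logfile, stage, sprintf("%d matches, %d divergent, %d first-barcode",
                                       if (is.null(matches)) 0L else nrow(matches),
                                       length(novel), length(firstbc)))

    stage <- "concord"
    disc <- classify_discordances(records, parts_study, parts_all)
    write_discordances(disc, file.path(config$out_dir, "discordances.tsv"))
    prov <- resolve_all_provisional(parts_all, records, matches,
                                    config$novelty_threshold)
    utils::write.table(prov, file.path(config$out_dir, "provisional.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_concordance(records, parts_all, disc)
    utils::write.table(summ$by_class, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(summary = summ$by_class,
                              discordance_tally = summ$discordance_tally,
                              discordances = disc, provisional = prov,
                              divergent_novel = novel,
                              first_barcode = firstbc,
                              validation = rep),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = FALSE, digits = NA, force = TRUE)
    .log_stage(logfile, stage,
               sprintf("%d discordance records", sum(disc$category != "CONCORDANT")))
    result <- list(sequences = sequences, records = records, distances = dm,
                   partitions_all = parts_all, partitions_study = parts_study,
                   gmyc = gfit, matches = matches, novel = novel,
                   first_barcode = firstbc, discordances = disc,
                   provisional = prov, summary = summ, validation = rep,
                   status = "ok")
  }, error = function(e) {
    manifest$status <<- sprintf("failed at stage '%s': %s", stage,
                                conditionMessage(e))
    .log_stage(logfile, stage, manifest$status)
    finish()
    stop(e)
  })
  finish()
  invisible(result)
}
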