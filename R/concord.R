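## concordance: classify morphospecies-vs-partition discordances.
##
## A morphospecies has a splitting issue (S) when its specimens occupy two
## or more putative species, and a lumping issue (L) when a putative
## species mixes two or more morphospecies. The resolution flag (R) marks
## issues the delimitation methods disagree about (some but not all
## evaluable methods exhibit them); "_" marks unanimous issues. The
## context records whether the issue is already visible within the study's
## own data (H) or only after merging with external reference data (A);
## H takes precedence.

#' Per-method splitting status of a morphospecies
#'
#' @param morphospecies label.
#' @param partitions named list of `partition` objects (one per method).
#' @param records metadata data.frame.
#' @param restrict optional provenance filter applied to the specimens
#'   considered (`"STUDY"`, `"EXTERNAL"`, or `NULL` for all).
#' @return Named logical vector (one per method): `TRUE` when the
#'   morphospecies' specimens occupy at least two groups, `NA` when the
#'   morphospecies is absent from that method's scope.
#' @export
split_status <- function(morphospecies, partitions, records, restrict = NULL) {
  lab <- normalize_name(morphospecies)
  sel <- records$morphospecies == lab
  if (!is.null(restrict)) sel <- sel & records$provenance %in% restrict
  ids <- records$specimen_id[sel]
  vapply(partitions, function(p) {
    inscope <- intersect(ids, partition_scope(p))
    if (!length(inscope)) return(NA)
    length(unique(p$assignment[inscope])) >= 2L
  }, logical(1))
}

#' Per-method lumping partners of a morphospecies
#'
#' @inheritParams split_status
#' @return Named list (one per method) of character vectors: the other
#'   morphospecies labels co-occurring in any group containing this
#'   morphospecies; `NULL` entries mark methods where the label is out of
#'   scope.
#' @export
lump_partners <- function(morphospecies, partitions, records, restrict = NULL) {
  lab <- normalize_name(morphospecies)
  recs <- records
  if (!is.null(restrict)) recs <- recs[recs$provenance %in% restrict, ]
  lapply(partitions, function(p) {
    scope <- partition_scope(p)
    inscope <- recs[recs$specimen_id %in% scope, ]
    ids <- inscope$specimen_id[inscope$morphospecies == lab]
    if (!length(ids)) return(NULL)
    mygroups <- unique(p$assignment[ids])
    members <- inscope$specimen_id[p$assignment[inscope$specimen_id] %in% mygroups]
    sort(setdiff(unique(inscope$morphospecies[match(members, inscope$specimen_id)]),
                 lab))
  })
}

## Evaluable = not NA. Flag is "_" (FALSE) only when every evaluable
## method exhibits the issue; otherwise "R" (TRUE).
.resolution_flag <- function(status) {
  ev <- status[!is.na(status)]
  !(length(ev) > 0L && all(ev))
}

#' Classify discordances between morphospecies and putative species
#'
#' For every morphospecies observed among study specimens, emits `SPLIT`
#' and/or `LUMP` records (a morphospecies may carry both), or a single
#' `CONCORDANT` record. Lump records are emitted once per connected set of
#' co-lumped morphospecies, not per pair. Context is `H` when the issue
#' already holds on the study-restricted partitions and `A` when it
#' appears only after merging with external data.
#'
#' @param records metadata data.frame (study + external specimens).
#' @param partitions_study named list of `partition`s computed on study
#'   specimens only.
#' @param partitions_all named list of `partition`s computed on the merged
#'   (study + external) dataset; must have the same method names.
#' @return data.frame with columns `morphospecies` (comma-joined label set
#'   for lumps), `category` (`CONCORDANT`/`SPLIT`/`LUMP`),
#'   `resolution_flag` (logical; printed `R`/`_`), `context` (`H`/`A` or
#'   `""`), `methods` (comma-joined set exhibiting the issue), `detail`.
#' @export
classify_discordances <- function(records, partitions_study, partitions_all) {
  if (!setequal(names(partitions_study), names(partitions_all)))
    bc_stop("method sets differ between study and merged partitions: %s vs %s",
            paste(sort(names(partitions_study)), collapse = ","),
            paste(sort(names(partitions_all)), collapse = ","))
  methods <- sort(names(partitions_all))
  partitions_study <- partitions_study[methods]
  partitions_all <- partitions_all[methods]
  study_labels <- sort(unique(records$morphospecies[records$provenance == "STUDY"]))
  rows <- list()
  addrow <- function(...) rows[[length(rows) + 1L]] <<-
    data.frame(..., stringsAsFactors = FALSE)

  ## ---- splits -------------------------------------------------------
  split_of <- function(parts, restrict) {
    do.call(rbind, lapply(study_labels, split_status,
                          partitions = parts, records = records,
                          restrict = restrict))
  }
  sp_all <- split_of(partitions_all, NULL)
  sp_h <- split_of(partitions_study, "STUDY")
  rownames(sp_all) <- rownames(sp_h) <- study_labels
  has_split <- logical(length(study_labels))
  names(has_split) <- study_labels
  for (m in study_labels) {
    merged <- sp_all[m, ]
    studyv <- sp_h[m, ]
    any_merged <- isTRUE(any(merged, na.rm = TRUE))
    any_study <- isTRUE(any(studyv, na.rm = TRUE))
    if (!any_merged && !any_study) next
    has_split[m] <- TRUE
    status <- if (any_merged) merged else studyv
    splitters <- methods[which(status)]
    addrow(morphospecies = m, category = "SPLIT",
           resolution_flag = .resolution_flag(status),
           context = if (any_study) "H" else "A",
           methods = paste(splitters, collapse = ","),
           detail = sprintf("split by %s", paste(splitters, collapse = ", ")))
  }

  ## ---- lumps --------------------------------------------------------
  lp_all <- lapply(study_labels, lump_partners, partitions = partitions_all,
                   records = records)
  names(lp_all) <- study_labels
  edges <- list()
  for (m in study_labels) for (meth in methods) {
    ps <- lp_all[[m]][[meth]]
    if (length(ps))
      edges[[length(edges) + 1L]] <- data.frame(a = m, b = ps,
                                                stringsAsFactors = FALSE)
  }
  in_lump <- character(0)
  if (length(edges)) {
    ed <- unique(do.call(rbind, edges))
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
    comp <- igraph::components(g)$membership
    for (k in sort(unique(comp))) {
      labs <- sort(names(comp)[comp == k])
      ## method exhibits the lump iff it co-groups >= 2 of these labels
      lumped_by <- function(parts, restrict) {
        vapply(methods, function(meth) {
          stat <- lapply(intersect(labs, study_labels), function(l)
            lump_partners(l, parts[meth], records, restrict)[[meth]])
          known <- !vapply(stat, is.null, logical(1))
          if (!any(known)) return(NA)
          any(vapply(stat[known], function(ps) any(ps %in% labs), logical(1)))
        }, logical(1))
      }
      st_all <- lumped_by(partitions_all, NULL)
      st_h <- lumped_by(partitions_study, "STUDY")
      any_study <- isTRUE(any(st_h, na.rm = TRUE))
      lumpers <- methods[which(st_all)]
      if (!length(lumpers)) { lumpers <- methods[which(st_h)]; st_all <- st_h }
      in_lump <- c(in_lump, intersect(labs, study_labels))
      addrow(morphospecies = paste(labs, collapse = ", "),
             category = "LUMP",
             resolution_flag = .resolution_flag(st_all),
             context = if (any_study) "H" else "A",
             methods = paste(lumpers, collapse = ","),
             detail = sprintf("lumped by %s", paste(lumpers, collapse = ", ")))
    }
  }

  ## ---- concordant ---------------------------------------------------
  for (m in study_labels) {
    if (!has_split[m] && !(m %in% in_lump))
      addrow(morphospecies = m, category = "CONCORDANT",
             resolution_flag = FALSE, context = "", methods = "",
             detail = "")
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$category, c("SPLIT", "LUMP", "CONCORDANT")),
                   out$morphospecies), ]
  rownames(out) <- NULL
  out
}

#' Resolve a provisionally named morphospecies
#'
#' Decides whether a provisional morphospecies stands alone
#' (`SEPARATE`), groups with one described species under every evaluable
#' method (`GROUPED_WITH`), or behaves differently across methods
#' (`MIXED`), and reports the nearest reference within the distance
#' threshold (`NO_MATCH` when none).
#'
#' @param morphospecies provisional label.
#' @param partitions_all named list of merged-scope `partition`s.
#' @param records metadata data.frame.
#' @param matches a [match_table()] result (may be `NULL`).
#' @param threshold nearest-reference dissimilarity ceiling (default 0.05).
#' @return List with `morphospecies`, `verdict` (`SEPARATE` /
#'   `GROUPED_WITH` / `MIXED`), `grouped_with` (described names, if any),
#'   `per_method` (named character vector of per-method outcomes),
#'   `nearest_name`, `nearest_distance` (`NA` + `NO_MATCH` semantics when
#'   beyond threshold).
#' @export
resolve_provisional <- function(morphospecies, partitions_all, records,
                                matches = NULL, threshold = 0.05) {
  lab <- normalize_name(morphospecies)
  prow <- records[records$morphospecies == lab, ]
  if (!nrow(prow)) bc_stop("unknown morphospecies '%s'", lab)
  if (!any(prow$provisional))
    bc_stop("'%s' is not flagged provisional", lab)
  described <- records[!records$provisional, ]
  per_method <- vapply(names(partitions_all), function(meth) {
    p <- partitions_all[[meth]]
    ids <- intersect(prow$specimen_id, partition_scope(p))
    if (!length(ids)) return(NA_character_)
    gids <- unique(p$assignment[ids])
    mem <- described[described$specimen_id %in% partition_scope(p) &
                       p$assignment[described$specimen_id] %in% gids, ]
    partners <- sort(unique(mem$morphospecies))
    if (!length(partners)) "SEPARATE" else paste(partners, collapse = ", ")
  }, character(1))
  ev <- per_method[!is.na(per_method)]
  verdict <- if (!length(ev)) "MIXED"
  else if (all(ev == "SEPARATE")) "SEPARATE"
  else if (length(unique(ev)) == 1L && unique(ev) != "SEPARATE") "GROUPED_WITH"
  else "MIXED"
  grouped_with <- if (verdict == "GROUPED_WITH") unique(ev) else
    paste(sort(unique(ev[ev != "SEPARATE"])), collapse = "; ")
  nearest_name <- NA_character_
  nearest_distance <- NA_real_
  if (!is.null(matches) && nrow(matches)) {
    sub <- matches[matches$query_id %in% prow$specimen_id, ]
    if (nrow(sub)) {
      i <- which.min(sub$p_distance)
      if (sub$p_distance[i] < threshold) {
        nearest_name <- sub$reference_name[i]
        nearest_distance <- sub$p_distance[i]
      }
    }
  }
  list(morphospecies = lab, verdict = verdict,
       grouped_with = if (nzchar(grouped_with)) grouped_with else NA_character_,
       per_method = per_method,
       nearest_name = nearest_name, nearest_distance = nearest_distance,
       nearest = if (is.na(nearest_name)) "NO_MATCH" else
         sprintf("%s (%.4f)", nearest_name, nearest_distance))
}

#' Resolve every provisional morphospecies
#'
#' @inheritParams resolve_provisional
#' @return data.frame with one row per provisional morphospecies:
#'   `morphospecies`, `verdict`, `grouped_with`, `nearest`.
#' @export
resolve_all_provisional <- function(partitions_all, records, matches = NULL,
                                    threshold = 0.05) {
  labs <- sort(unique(records$morphospecies[records$provisional &
                                              records$provenance == "STUDY"]))
  rows <- lapply(labs, function(l) {
    r <- resolve_provisional(l, partitions_all, records, matches, threshold)
    data.frame(morphospecies = r$morphospecies, verdict = r$verdict,
               grouped_with = ifelse(is.na(r$grouped_with), "", r$grouped_with),
               nearest = r$nearest, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(morphospecies = character(0), verdict = character(0),
                      grouped_with = character(0), nearest = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summary tables of specimens, morphospecies and putative species
#'
#' Per taxon class (when the metadata has a `taxon_class` column) and
#' overall: study specimen count, morphospecies count, provisional count,
#' and per-method putative-species count (groups containing at least one
#' study specimen). Optionally tallies discordances by category, flag and
#' context.
#'
#' @param records metadata data.frame.
#' @param partitions named list of `partition`s (merged scope).
#' @param discordances optional [classify_discordances()] result.
#' @return List with `by_class` (data.frame) and `discordance_tally`
#'   (data.frame or `NULL`).
#' @export
summarize_concordance <- function(records, partitions, discordances = NULL) {
  study <- records[records$provenance == "STUDY", ]
  classes <- if ("taxon_class" %in% names(study))
    sort(unique(study$taxon_class)) else character(0)
  count_row <- function(sub) {
    counts <- vapply(partitions, function(p) {
      ids <- intersect(sub$specimen_id, partition_scope(p))
      length(unique(p$assignment[ids]))
    }, integer(1))
    c(n_specimens = nrow(sub),
      n_morphospecies = length(unique(sub$morphospecies)),
      n_provisional = length(unique(sub$morphospecies[sub$provisional])),
      counts)
  }
  rows <- lapply(classes, function(cl)
    count_row(study[study$taxon_class == cl, ]))
  tab <- as.data.frame(do.call(rbind, c(rows, list(count_row(study)))))
  tab <- cbind(taxon_class = c(classes, "ALL"), tab)
  rownames(tab) <- NULL
  tally <- NULL
  if (!is.null(discordances) && nrow(discordances)) {
    disc <- discordances[discordances$category != "CONCORDANT", ]
    if (nrow(disc)) {
      tally <- as.data.frame(table(category = disc$category,
                                   flag = ifelse(disc$resolution_flag, "R", "_"),
                                   context = disc$context),
                             stringsAsFactors = FALSE)
      tally <- tally[tally$Freq > 0, ]
      names(tally)[names(tally) == "Freq"] <- "n"
      rownames(tally) <- NULL
    }
  }
  list(by_class = tab, discordance_tally = tally)
}

#' Write a discordance report as TSV
#'
#' Columns mirror the morphospecies / description / category-flag-context
#' layout, with the flag printed `R` or `_`.
#'
#' @param discordances a [classify_discordances()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_discordances <- function(discordances, path) {
  d <- discordances
  d$code <- ifelse(d$category == "CONCORDANT", "",
                   paste(substr(d$category, 1, 1),
                         ifelse(d$resolution_flag, "R", "_"),
                         d$context, sep = "-"))
  utils::write.table(d[, c("morphospecies", "detail", "category", "code")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
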