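## reference_match: best-match lists of study sequences against a local
## reference library, name-agreement classification, divergence-novelty
## and first-barcode flags.

## Pairwise p-distance and overlap between one query string and a set of
## reference strings (pairwise deletion, unambiguous bases only).
.query_distances <- function(query, refs) {
  qs <- strsplit(query, "", fixed = TRUE)[[1L]]
  qok <- qs %in% .BASES
  vapply(refs, function(r) {
    rs <- strsplit(r, "", fixed = TRUE)[[1L]]
    both <- qok & rs %in% .BASES
    nb <- sum(both)
    c(d = if (nb) sum(qs[both] != rs[both]) / nb else NA_real_, overlap = nb)
  }, numeric(2))
}

#' Best matches of a query against a reference library
#'
#' Returns up to `max_matches` references within the similarity floor,
#' sorted by p-distance then reference id. References flagged provisional
#' are excluded by default. Each match is classified `NAME_MATCH` /
#' `NAME_MISMATCH` on normalized exact names, or `PROVISIONAL_INVOLVED`
#' when either side carries a provisional name.
#'
#' @param query_id id of the query specimen.
#' @param sequences named character vector holding the query and reference
#'   residue strings (one aligned length).
#' @param records metadata data.frame covering query and references.
#' @param reference_ids ids to search (default: all `EXTERNAL` records).
#' @param max_matches maximum list length (default 100).
#' @param min_similarity similarity floor (default 0.80).
#' @param exclude_provisional_refs drop provisionally named references
#'   (default `TRUE`).
#' @param min_overlap minimum compared sites for a defined distance
#'   (default 100).
#' @return data.frame (possibly zero rows) with columns `query_id`,
#'   `rank`, `reference_id`, `reference_name`, `p_distance`,
#'   `classification`.
#' @export
best_matches <- function(query_id, sequences, records,
                         reference_ids = NULL,
                         max_matches = 100L, min_similarity = 0.80,
                         exclude_provisional_refs = TRUE,
                         min_overlap = 100L) {
  if (!query_id %in% names(sequences))
    bc_stop("query '%s' has no sequence", query_id)
  if (is.null(reference_ids))
    reference_ids <- records$specimen_id[records$provenance == "EXTERNAL"]
  reference_ids <- setdiff(intersect(reference_ids, names(sequences)), query_id)
  recs <- records[match(reference_ids, records$specimen_id), ]
  if (exclude_provisional_refs) {
    keep <- !recs$provisional
    reference_ids <- reference_ids[keep]
    recs <- recs[keep, ]
  }
  empty <- data.frame(query_id = character(0), rank = integer(0),
                      reference_id = character(0),
                      reference_name = character(0),
                      p_distance = numeric(0),
                      classification = character(0),
                      stringsAsFactors = FALSE)
  if (!length(reference_ids)) return(empty)
  dv <- .query_distances(sequences[[query_id]], sequences[reference_ids])
  d <- dv["d", ]
  ok <- !is.na(d) & dv["overlap", ] >= min_overlap & (1 - d) >= min_similarity
  if (!any(ok)) return(empty)
  d <- d[ok]
  ids <- reference_ids[ok]
  recs <- recs[ok, ]
  ord <- order(d, ids)
  take <- ord[seq_len(min(max_matches, length(ord)))]
  qrec <- records[match(query_id, records$specimen_id), ]
  qname <- normalize_name(qrec$morphospecies)
  cls <- ifelse(isTRUE(qrec$provisional) | recs$provisional[take],
                "PROVISIONAL_INVOLVED",
                ifelse(normalize_name(recs$morphospecies[take]) == qname,
                       "NAME_MATCH", "NAME_MISMATCH"))
  data.frame(query_id = query_id, rank = seq_along(take),
             reference_id = ids[take],
             reference_name = recs$morphospecies[take],
             p_distance = unname(d[take]),
             classification = cls, stringsAsFactors = FALSE)
}

#' Best-match table for every study sequence
#'
#' @inheritParams best_matches
#' @param query_ids ids to query (default: all `STUDY` records with a
#'   sequence).
#' @return Row-bound data.frame of [best_matches()] results; queries whose
#'   lists are empty contribute no rows.
#' @export
match_table <- function(sequences, records, query_ids = NULL,
                        reference_ids = NULL, max_matches = 100L,
                        min_similarity = 0.80,
                        exclude_provisional_refs = TRUE,
                        min_overlap = 100L) {
  if (is.null(query_ids))
    query_ids <- intersect(records$specimen_id[records$provenance == "STUDY"],
                           names(sequences))
  out <- lapply(query_ids, best_matches, sequences = sequences,
                records = records, reference_ids = reference_ids,
                max_matches = max_matches, min_similarity = min_similarity,
                exclude_provisional_refs = exclude_provisional_refs,
                min_overlap = min_overlap)
  res <- do.call(rbind, out)
  attr(res, "query_ids") <- query_ids
  res
}

#' Flag morphospecies divergent from the reference library
#'
#' A morphospecies is divergent-novel when the minimum best-match distance
#' over all its study sequences exceeds the threshold; study sequences with
#' an empty match list count as exceeding.
#'
#' @param matches a [match_table()] result (its `query_ids` attribute, or
#'   `query_ids`, defines which sequences were searched).
#' @param records metadata data.frame.
#' @param threshold divergence threshold on p-distance (default 0.05).
#' @param query_ids ids searched, if `matches` lacks the attribute.
#' @return Sorted character vector of divergent-novel morphospecies.
#' @export
flag_novelty <- function(matches, records, threshold = 0.05,
                         query_ids = NULL) {
  if (is.null(query_ids)) query_ids <- attr(matches, "query_ids")
  if (is.null(query_ids)) query_ids <- unique(matches$query_id)
  best <- stats::setNames(rep(Inf, length(query_ids)), query_ids)
  if (!is.null(matches) && nrow(matches)) {
    agg <- tapply(matches$p_distance, matches$query_id, min)
    best[names(agg)] <- agg
  }
  lab <- records$morphospecies[match(query_ids, records$specimen_id)]
  permorph <- tapply(best, lab, min)
  sort(names(permorph)[permorph > threshold])
}

#' Flag morphospecies absent from the reference name list
#'
#' Described (non-provisional) study morphospecies whose name matches no
#' reference name after whitespace normalization — candidates for a first
#' published barcode. Provisional morphospecies are handled by
#' [resolve_provisional()], never here.
#'
#' @param records metadata data.frame.
#' @param reference_names character vector of reference taxon names
#'   (default: names of `EXTERNAL` records).
#' @return Sorted character vector of flagged morphospecies.
#' @export
flag_first_barcode <- function(records, reference_names = NULL) {
  if (is.null(reference_names))
    reference_names <- records$morphospecies[records$provenance == "EXTERNAL"]
  refset <- unique(normalize_name(reference_names))
  study <- records[records$provenance == "STUDY" & !records$provisional, ]
  cand <- unique(normalize_name(study$morphospecies))
  sort(setdiff(cand, refset))
}

#' Write a match table as TSV
#' @param matches a [match_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  cols <- c("query_id", "rank", "reference_id", "reference_name",
            "p_distance", "classification")
  df <- if (is.null(matches) || !nrow(matches))
    stats::setNames(as.data.frame(replicate(6, character(0),
                                            simplify = FALSE)), cols)
  else matches[, cols]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
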