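## core_io: readers/writers for the artifact file formats and joint
## validation of sequences, metadata, trees and partitions.

#' Read an aligned FASTA file
#'
#' Reads an aligned nucleotide FASTA (gap characters allowed) into a named
#' character vector of uppercase residue strings. All sequences must share
#' the same aligned length and ids must be unique; violations raise errors
#' naming the offending line or ids.
#'
#' @param path path to a FASTA file. Lines starting with `;` or empty lines
#'   are ignored; the id is the header token up to the first whitespace.
#' @return Named character vector of residue strings (names are sequence
#'   ids), with attribute `aligned_length`. Order follows the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' read_alignment(f)
read_alignment <- function(path) {
  if (!file.exists(path)) bc_stop("alignment file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^;", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) bc_stop("empty FASTA file: %s", path)
  first <- idx[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    bc_stop("malformed FASTA at line %d: expected '>' header, got '%s'",
            first, substr(lines[first], 1, 30))
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  buf <- character(0)
  for (i in idx) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) {
        seqs[length(seqs) + 1L] <- paste0(buf, collapse = "")
        ids[length(ids) + 1L] <- cur
      }
      cur <- strsplit(sub("^>", "", ln), "[[:space:]]+")[[1L]][1L]
      if (is.na(cur) || !nzchar(cur))
        bc_stop("malformed FASTA at line %d: empty sequence id", i)
      buf <- character(0)
    } else {
      if (grepl("[^-ACGTUNRYSWKMBDHV?.acgtunryswkmbdhv]", ln))
        bc_stop("malformed FASTA at line %d: unexpected characters in %s",
                i, if (is.null(cur)) "file" else cur)
      buf[length(buf) + 1L] <- ln
    }
  }
  seqs[length(seqs) + 1L] <- paste0(buf, collapse = "")
  ids[length(ids) + 1L] <- cur
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    bc_stop("duplicate sequence id(s) in %s: %s", path,
            paste(dup, collapse = ", "))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) bc_stop("sequence with no residues: %s",
                                  paste(ids[!nzchar(seqs)], collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != stats::median(lens)]
    bc_stop("ragged alignment (unequal lengths) in %s: %s", path,
            paste(off, collapse = ", "))
  }
  only_gap <- !grepl("[ACGTNRYSWKMBDHV]", seqs)
  if (any(only_gap))
    bc_stop("sequence(s) with no non-gap residue: %s",
            paste(ids[only_gap], collapse = ", "))
  names(seqs) <- ids
  attr(seqs, "aligned_length") <- lens[1L]
  seqs
}

#' Write an aligned FASTA file
#'
#' @param sequences named character vector as returned by [read_alignment()].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(sequences, path, width = 70L) {
  out <- unlist(lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Reads a tab-separated metadata table with required columns
#' `specimen_id`, `morphospecies`, `provisional` and `provenance`
#' (`STUDY` or `EXTERNAL`). `#`-prefixed lines are comments. Extra columns
#' are preserved untouched.
#'
#' The provisional flag must be a literal boolean (`true`/`false`,
#' case-insensitive); open-nomenclature markers in the label (e.g. "sp.",
#' "cf.") are never interpreted automatically — see
#' [suggest_provisional()].
#'
#' @param path path to a TSV file.
#' @return A data.frame of specimen records, one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) bc_stop("metadata file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  required <- c("specimen_id", "morphospecies", "provisional", "provenance")
  miss <- setdiff(required, names(df))
  if (length(miss))
    bc_stop("metadata schema error: missing column(s) %s",
            paste(miss, collapse = ", "))
  if (any(!nzchar(trimws(df$specimen_id))))
    bc_stop("metadata validation error: empty specimen_id")
  dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
  if (length(dup))
    bc_stop("metadata validation error: duplicate specimen_id(s): %s",
            paste(dup, collapse = ", "))
  if (any(!nzchar(trimws(df$morphospecies))))
    bc_stop("metadata validation error: empty morphospecies for %s",
            paste(df$specimen_id[!nzchar(trimws(df$morphospecies))],
                  collapse = ", "))
  prov <- tolower(trimws(df$provisional))
  bad <- !prov %in% c("true", "false")
  if (any(bad))
    bc_stop("metadata validation error: provisional must be true/false, got %s (specimen %s)",
            paste(unique(df$provisional[bad]), collapse = ", "),
            paste(df$specimen_id[bad], collapse = ", "))
  df$provisional <- prov == "true"
  pv <- toupper(trimws(df$provenance))
  badp <- !pv %in% c("STUDY", "EXTERNAL")
  if (any(badp))
    bc_stop("metadata validation error: provenance must be one of STUDY, EXTERNAL; got %s",
            paste(unique(df$provenance[badp]), collapse = ", "))
  df$provenance <- pv
  df$morphospecies <- normalize_name(df$morphospecies)
  rownames(df) <- NULL
  df
}

#' Write a specimen metadata table
#'
#' @param records data.frame as returned by [read_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  out <- records
  out$provisional <- ifelse(records$provisional, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Suggest a provisional flag from label patterns
#'
#' Flags labels that look like open nomenclature ("sp.", "cf.", "aff.",
#' trailing "sp" plus number). This is a suggestion helper only; the
#' authoritative flag is the metadata column.
#'
#' @param morphospecies character vector of labels.
#' @return Logical vector, `TRUE` where the label looks provisional.
#' @export
suggest_provisional <- function(morphospecies) {
  grepl("(^|\\s)(sp|cf|aff|nr)\\.(\\s|$)|\\bsp\\.?\\s*[0-9]+$",
        morphospecies, ignore.case = TRUE)
}

#' Construct a putative-species partition
#'
#' A partition is one delimitation method's assignment of specimens to
#' putative-species groups. Group ids are opaque labels.
#'
#' @param assignment named character vector: names are specimen ids, values
#'   group ids.
#' @param method_name method label (e.g. "abgd", "linkage", "gmyc").
#' @return An object of class `partition`.
#' @export
partition <- function(assignment, method_name = "unknown") {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    bc_stop("partition assignment must be named by specimen id")
  dup <- unique(names(assignment)[duplicated(names(assignment))])
  if (length(dup))
    bc_stop("specimen(s) assigned more than once: %s", paste(dup, collapse = ", "))
  if (any(is.na(assignment) | !nzchar(assignment)))
    bc_stop("empty group id in partition")
  structure(list(method = method_name,
                 assignment = stats::setNames(as.character(assignment),
                                              names(assignment))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition '%s': %d specimens in %d groups\n",
              x$method, length(x$assignment),
              length(unique(x$assignment))))
  invisible(x)
}

#' Number of groups in a partition
#' @param x a `partition`.
#' @return integer group count.
#' @export
n_groups <- function(x) length(unique(x$assignment))

#' Specimen ids covered by a partition
#' @param x a `partition`.
#' @return character vector of specimen ids.
#' @export
partition_scope <- function(x) names(x$assignment)

#' Read a partition file
#'
#' Two-column TSV (`specimen_id`, `group_id`); duplicate identical rows are
#' deduplicated, conflicting assignments are an error.
#'
#' @param path path to a TSV file.
#' @param method_name method label recorded on the partition; if `NULL`, a
#'   `# method: <name>` comment line in the file is used when present.
#' @return A `partition`.
#' @export
read_partition <- function(path, method_name = NULL) {
  if (!file.exists(path)) bc_stop("partition file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(method_name)) {
    m <- grep("^#\\s*method:", lines, value = TRUE)
    method_name <- if (length(m)) trimws(sub("^#\\s*method:", "", m[1L])) else "imported"
  }
  df <- utils::read.delim(text = lines, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("specimen_id", "group_id") %in% names(df)))
    bc_stop("partition file %s must have columns specimen_id, group_id", path)
  df <- unique(df[, c("specimen_id", "group_id")])
  dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
  if (length(dup))
    bc_stop("conflicting group assignment for specimen(s): %s",
            paste(dup, collapse = ", "))
  partition(stats::setNames(df$group_id, df$specimen_id), method_name)
}

#' Write a partition file
#'
#' @param x a `partition`.
#' @param path output path. The method name is embedded as a
#'   `# method:` comment header.
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method: %s", x$method), con)
  writeLines("specimen_id\tgroup_id", con)
  ids <- names(x$assignment)
  writeLines(paste(ids, x$assignment[ids], sep = "\t"), con)
  invisible(path)
}

#' Cross-validate sequences, metadata, trees and partitions
#'
#' Reports ids present in one input but absent from another. By default the
#' report is advisory; with `strict = TRUE` any entry is an error.
#'
#' @param sequences named character vector from [read_alignment()], or NULL.
#' @param records metadata data.frame, or NULL.
#' @param trees list of `phylo` trees (optional).
#' @param partitions list of `partition` objects (optional).
#' @param strict fail on any inconsistency.
#' @return data.frame with columns `check`, `id`, `detail` (zero rows when
#'   fully consistent).
#' @export
cross_validate <- function(sequences = NULL, records = NULL, trees = NULL,
                           partitions = NULL, strict = FALSE) {
  entries <- list()
  add <- function(check, ids, detail) {
    if (length(ids))
      entries[[length(entries) + 1L]] <<-
        data.frame(check = check, id = ids, detail = detail,
                   stringsAsFactors = FALSE)
  }
  seq_ids <- names(sequences)
  rec_ids <- records$specimen_id
  if (!is.null(sequences) && !is.null(records)) {
    add("sequence_without_metadata", setdiff(seq_ids, rec_ids),
        "sequence id absent from metadata")
    add("metadata_without_sequence", setdiff(rec_ids, seq_ids),
        "specimen has no sequence")
  }
  for (ti in seq_along(trees)) {
    tips <- trees[[ti]]$tip.label
    if (!is.null(sequences))
      add(sprintf("tree%d_tip_without_sequence", ti), setdiff(tips, seq_ids),
          "tree tip absent from sequences")
  }
  for (pi in seq_along(partitions)) {
    sc <- partition_scope(partitions[[pi]])
    ref <- if (!is.null(rec_ids)) rec_ids else seq_ids
    if (!is.null(ref))
      add(sprintf("partition_%s_unknown_specimen", partitions[[pi]]$method),
          setdiff(sc, ref), "partition specimen absent from dataset")
  }
  rep <- if (length(entries)) do.call(rbind, entries) else
    data.frame(check = character(0), id = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  if (strict && nrow(rep))
    bc_stop("cross-validation failed: %d inconsistencies (first: %s %s)",
            nrow(rep), rep$check[1L], rep$id[1L])
  rep
}
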