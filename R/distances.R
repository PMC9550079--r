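## distances: common-overlap trimming and uncorrected p-distance matrices
## with pairwise deletion. Compared sites are positions where BOTH
## sequences carry an unambiguous base (A, C, G, T); gaps, N and other
## IUPAC ambiguity codes are excluded. p-distance is NOT a metric: nothing
## downstream may rely on the triangle inequality.

## 0/1 indicator matrices (n x L) per base, from residue strings.
.base_indicators <- function(sequences) {
  n <- length(sequences)
  L <- nchar(sequences[[1L]])
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  lapply(.BASES, function(b) (chars == b) * 1L)
}

#' Trim an alignment to a guaranteed common overlap
#'
#' Greedily removes sequences until the set of columns at which every kept
#' sequence carries an unambiguous base (A/C/G/T) has at least `min_common`
#' sites. At each step the sequence whose removal most increases the common
#' overlap is dropped (ties: fewest unambiguous sites, then lexicographic
#' id).
#'
#' @param sequences named character vector of aligned residue strings.
#' @param min_common minimum number of sites shared by all kept sequences
#'   (default 150).
#' @return List with `kept` (trimmed-input subset, same representation) and
#'   `removed` (character vector of removed ids, in removal order).
#' @export
trim_to_common_overlap <- function(sequences, min_common = 150L) {
  if (length(sequences) == 0L) bc_stop("empty alignment")
  cov <- Reduce(`+`, .base_indicators(sequences)) > 0
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = 1L)
  rownames(cov) <- names(sequences)
  removed <- character(0)
  repeat {
    n <- nrow(cov)
    cnt <- colSums(cov)
    common <- sum(cnt == n)
    if (common >= min_common) break
    if (n <= 2L)
      bc_stop("cannot reach %d common sites even with %d sequences (best: %d)",
              min_common, n, common)
    ## overlap after removing sequence i: columns covered by all others
    gains <- vapply(seq_len(n), function(i) {
      sum(cnt - cov[i, ] == n - 1L)
    }, numeric(1))
    nonamb <- rowSums(cov)
    ord <- order(-gains, nonamb, rownames(cov))
    drop <- ord[1L]
    removed <- c(removed, rownames(cov)[drop])
    cov <- cov[-drop, , drop = FALSE]
  }
  kept <- sequences[rownames(cov)]
  attr(kept, "aligned_length") <- attr(sequences, "aligned_length")
  list(kept = kept, removed = removed)
}

#' Uncorrected p-distance matrix with pairwise deletion
#'
#' For each pair, compared sites are the positions where both sequences
#' carry an unambiguous base; the distance is the proportion of compared
#' sites that differ. Pairs with fewer than `min_overlap` compared sites
#' are flagged undefined (`NA`). The diagonal is always 0.
#'
#' @param sequences named character vector of aligned residue strings
#'   sharing one aligned length.
#' @param min_overlap minimum compared-site count for a defined distance
#'   (default 100).
#' @return An object of class `pdist` with elements `ids`, `d` (distance
#'   matrix, `NA` = undefined), `overlap` (compared-site counts) and
#'   `min_overlap`.
#' @export
#' @examples
#' p_distance_matrix(c(a = "ACGT", b = "ACGA"), min_overlap = 1)$d
p_distance_matrix <- function(sequences, min_overlap = 100L) {
  if (length(sequences) == 0L) bc_stop("empty alignment")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    bc_stop("sequences do not share one aligned length")
  ind <- .base_indicators(sequences)
  Y <- Reduce(`+`, ind)                       # 1 where unambiguous base
  valid <- Y %*% t(Y)                         # compared sites per pair
  match <- Reduce(`+`, lapply(ind, function(X) X %*% t(X)))
  mism <- valid - match
  d <- ifelse(valid > 0, mism / pmax(valid, 1L), NA_real_)
  d[valid < min_overlap] <- NA_real_
  diag(d) <- 0
  storage.mode(valid) <- "integer"
  ids <- names(sequences)
  dimnames(d) <- dimnames(valid) <- list(ids, ids)
  structure(list(ids = ids, d = d, overlap = valid,
                 min_overlap = as.integer(min_overlap)),
            class = "pdist")
}

#' @export
print.pdist <- function(x, ...) {
  nd <- sum(is.na(x$d[upper.tri(x$d)]))
  cat(sprintf("p-distance matrix: %d sequences, %d undefined pairs (overlap < %d)\n",
              length(x$ids), nd, x$min_overlap))
  invisible(x)
}

#' @export
as.matrix.pdist <- function(x, ...) x$d

## Submatrix restricted to ids (keeps class and overlap bookkeeping).
subset_pdist <- function(dm, ids) {
  miss <- setdiff(ids, dm$ids)
  if (length(miss))
    bc_stop("ids absent from distance matrix: %s", paste(miss, collapse = ", "))
  structure(list(ids = ids, d = dm$d[ids, ids, drop = FALSE],
                 overlap = dm$overlap[ids, ids, drop = FALSE],
                 min_overlap = dm$min_overlap),
            class = "pdist")
}

#' Maximum within-morphospecies p-distance
#'
#' Maximum defined pairwise distance among specimens carrying one
#' morphospecies label, optionally restricted by provenance.
#'
#' @param dm a `pdist` matrix.
#' @param records metadata data.frame.
#' @param morphospecies label to examine.
#' @param restrict optional provenance filter (`"STUDY"`, `"EXTERNAL"` or
#'   `NULL` for both).
#' @return Maximum p-distance, or `NA` if fewer than two specimens qualify
#'   or no pair has a defined distance.
#' @export
max_within <- function(dm, records, morphospecies, restrict = NULL) {
  sel <- records$morphospecies == normalize_name(morphospecies)
  if (!is.null(restrict)) sel <- sel & records$provenance %in% restrict
  ids <- intersect(records$specimen_id[sel], dm$ids)
  if (length(ids) < 2L) return(NA_real_)
  sub <- dm$d[ids, ids]
  vals <- sub[upper.tri(sub)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  max(vals)
}

#' Write a p-distance matrix as square TSV
#'
#' Undefined pairs are serialized as `NA`.
#'
#' @param dm a `pdist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path) {
  df <- as.data.frame(dm$d)
  df <- cbind(specimen_id = dm$ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a p-distance matrix written by [write_distances()]
#'
#' Overlap counts are not serialized; the reader marks defined pairs with
#' overlap `min_overlap` and undefined pairs 0.
#'
#' @param path input path.
#' @param min_overlap threshold recorded on the object.
#' @return A `pdist`.
#' @export
read_distances <- function(path, min_overlap = 100L) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df$specimen_id)
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  dimnames(d) <- list(ids, ids)
  ov <- matrix(ifelse(is.na(d), 0L, as.integer(min_overlap)),
               nrow = nrow(d), dimnames = dimnames(d))
  diag(d) <- 0
  structure(list(ids = ids, d = d, overlap = ov,
                 min_overlap = as.integer(min_overlap)),
            class = "pdist")
}
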