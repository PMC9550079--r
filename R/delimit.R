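## delimitation: distance-based putative-species partitions.
##
## The barcode-gap method treats the prior P as an upper bound on
## intraspecific divergence: scanning the sorted pairwise distances, the
## first gap whose upper edge exceeds P and whose width exceeds X times the
## local spacing (mean spacing over a trailing window of W values) sets the
## clustering threshold at the gap midpoint; clusters are connected
## components of the d <= threshold graph, and the search recurses within
## each multi-member cluster. Numerical fidelity to the original web tool
## is out of scope; the correctness contract is that any clean gap
## (max intra < min inter) is found for every prior below the gap's upper
## edge.

## Connected components of the graph linking pairs with d <= tau.
## Undefined (NA) distances contribute no edge.
.threshold_components <- function(d, tau) {
  adj <- !is.na(d) & d <= tau
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), rownames(d))
}

## First significant gap in sorted distances above prior P, or NULL.
## Window W = max(3, ceil(0.1 * #distances)); ties resolved by smallest
## index because the scan is ascending.
.find_gap <- function(dsort, P, X) {
  m <- length(dsort)
  if (m < 2L) return(NULL)
  W <- max(3L, ceiling(0.1 * m))
  for (i in seq_len(m - 1L)) {
    if (dsort[i + 1L] <= P) next
    jump <- dsort[i + 1L] - dsort[i]
    if (jump <= 0) next
    lo <- max(1L, i - W + 1L)
    win <- dsort[lo:i]
    s <- if (length(win) >= 2L) mean(diff(win)) else 0
    if (jump > X * s) return((dsort[i] + dsort[i + 1L]) / 2)
  }
  NULL
}

#' Barcode-gap partition (recursive automatic gap discovery)
#'
#' Delimits putative species by detecting the first significant gap in the
#' sorted pairwise p-distance distribution above the prior intraspecific
#' divergence `P`, clustering below the gap, and recursing within each
#' multi-member group until no further gap is found.
#'
#' @param dm a `pdist` distance matrix; all pairwise distances in scope
#'   must be defined.
#' @param P prior maximal intraspecific p-distance.
#' @param X relative gap width (default 1).
#' @param method_name label recorded on the partition.
#' @return A `partition` covering `dm$ids`.
#' @export
abgd_partition <- function(dm, P, X = 1.0, method_name = "abgd") {
  d <- dm$d
  if (any(is.na(d[upper.tri(d)])))
    bc_stop(paste("undefined pairwise distances in scope; trim the alignment",
                  "more strictly (raise min_common) or drop short sequences"))
  groups <- stats::setNames(rep(NA_integer_, length(dm$ids)), dm$ids)
  nextg <- 1L
  recurse <- function(ids) {
    if (length(ids) == 1L) {
      groups[ids] <<- nextg; nextg <<- nextg + 1L
      return(invisible())
    }
    sub <- d[ids, ids, drop = FALSE]
    dsort <- sort(sub[upper.tri(sub)])
    tau <- .find_gap(dsort, P, X)
    if (is.null(tau)) {
      groups[ids] <<- nextg; nextg <<- nextg + 1L
      return(invisible())
    }
    comp <- .threshold_components(sub, tau)
    if (length(unique(comp)) == 1L) {
      ## gap detected but graph stays connected (chaining): terminal group
      groups[ids] <<- nextg; nextg <<- nextg + 1L
      return(invisible())
    }
    for (k in sort(unique(comp))) recurse(ids[comp == k])
  }
  recurse(dm$ids)
  partition(stats::setNames(sprintf("G%03d", groups), names(groups)),
            method_name)
}

#' Scan barcode-gap partitions over a range of priors
#'
#' Runs [abgd_partition()] at `steps` log-spaced priors between `P_min`
#' and `P_max` and reports the group count per prior. Recursion can break
#' monotonicity of the count in the prior; the counts are reported as-is.
#'
#' @param dm a `pdist`.
#' @param P_min,P_max prior range (defaults 0.0001 and 0.1).
#' @param steps number of log-spaced priors (default 20).
#' @param X relative gap width (default 1).
#' @return data.frame with columns `prior` and `n_groups`, plus attribute
#'   `partitions` (list of `partition` objects, one per prior).
#' @export
abgd_scan <- function(dm, P_min = 1e-4, P_max = 0.1, steps = 20L, X = 1.0) {
  if (!(P_min > 0 && P_min <= P_max && P_max < 1))
    bc_stop("need 0 < P_min <= P_max < 1")
  if (X <= 0 || steps < 1L) bc_stop("need X > 0 and steps >= 1")
  priors <- if (steps == 1L) P_min else
    exp(seq(log(P_min), log(P_max), length.out = steps))
  parts <- lapply(priors, function(p) abgd_partition(dm, p, X))
  out <- data.frame(prior = priors,
                    n_groups = vapply(parts, n_groups, integer(1)))
  attr(out, "partitions") <- parts
  out
}

#' Modal group count of a barcode-gap prior scan
#'
#' @param scan result of [abgd_scan()].
#' @return Most frequent group count across priors (smallest on ties).
#' @export
abgd_modal_groups <- function(scan) {
  tab <- table(scan$n_groups)
  as.integer(names(tab)[which.max(tab)])
}

#' Single-linkage partition at a fixed distance threshold
#'
#' Connected components of the graph linking pairs at p-distance at or
#' below the threshold: a proxy for Barcode Index Number (BIN) clustering
#' (the refinement stage of the production BIN pipeline is not modelled).
#'
#' @param dm a `pdist`.
#' @param threshold linking p-distance (default 0.022).
#' @param method_name label recorded on the partition.
#' @return A `partition` covering `dm$ids`.
#' @export
single_linkage_partition <- function(dm, threshold = 0.022,
                                     method_name = "linkage") {
  comp <- .threshold_components(dm$d, threshold)
  partition(stats::setNames(sprintf("G%03d", comp), names(comp)), method_name)
}

#' Assign a query to a group via its best match
#'
#' Fallback rule for sequences whose overlap with the clustered set is too
#' short for direct membership: the query inherits the group of its best
#' match provided the overlap is at least `min_overlap` sites and the
#' similarity (1 - p-distance) is at least `min_similarity`. Ties across
#' distinct groups leave the query unassigned (never an arbitrary pick).
#'
#' @param query_id id of the query; must have rows in `dm` but be outside
#'   the partition's scope.
#' @param dm a `pdist` containing the query and the partition scope.
#' @param part a `partition`.
#' @param min_overlap minimum compared sites (default 300).
#' @param min_similarity minimum similarity (default 0.99).
#' @return List with `group` (group id or `NA`) and `reason` (one of
#'   `"assigned"`, `"no_defined_pair"`, `"below_similarity"`, `"tie"`).
#' @export
assign_group_by_best_match <- function(query_id, dm, part,
                                       min_overlap = 300L,
                                       min_similarity = 0.99) {
  scope <- intersect(partition_scope(part), dm$ids)
  if (query_id %in% partition_scope(part))
    bc_stop("query '%s' is already in the partition scope", query_id)
  ok <- scope[dm$overlap[query_id, scope] >= min_overlap &
                !is.na(dm$d[query_id, scope])]
  if (!length(ok))
    return(list(group = NA_character_, reason = "no_defined_pair"))
  dd <- dm$d[query_id, ok]
  best <- min(dd)
  if (1 - best < min_similarity)
    return(list(group = NA_character_, reason = "below_similarity"))
  gids <- unique(part$assignment[ok[dd == best]])
  if (length(gids) > 1L)
    return(list(group = NA_character_, reason = "tie"))
  list(group = unname(gids), reason = "assigned")
}

#' Select representative sequences per oversplit group
#'
#' Partitions the dataset at a deliberately oversplitting prior, samples up
#' to `k` members per group (all members for groups of one or two), and
#' collapses exact duplicate residue strings to unique haplotypes. Fully
#' deterministic for a given seed.
#'
#' @param sequences named character vector of aligned residue strings.
#' @param dm a `pdist` over the same ids.
#' @param k maximum sampled members per group (default 3).
#' @param seed integer seed (required).
#' @param P oversplitting prior (default 0.0001).
#' @param X relative gap width (default 1).
#' @return Character vector of representative sequences (named by id),
#'   with attribute `sampled` (ids drawn before haplotype collapsing).
#' @export
select_representatives <- function(sequences, dm, k = 3L, seed,
                                   P = 1e-4, X = 1.0) {
  part <- abgd_partition(dm, P, X)
  byg <- split(names(part$assignment), part$assignment)
  byg <- byg[order(vapply(byg, function(g) sort(g)[1L], character(1)))]
  sampled <- with_seed(seed, {
    unlist(lapply(byg, function(g) {
      g <- sort(g)
      if (length(g) <= k) g else sample(g, k)
    }), use.names = FALSE)
  })
  keep <- sampled[!duplicated(sequences[sampled])]
  out <- sequences[keep]
  attr(out, "sampled") <- sampled
  out
}
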