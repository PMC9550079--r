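## Shared fixtures and independent oracles for the test suite.

## Quick alignment fixture from residue strings.
make_seqs <- function(...) {
  x <- toupper(c(...))
  if (is.null(names(x))) names(x) <- paste0("s", seq_along(x))
  attr(x, "aligned_length") <- nchar(x[[1L]])
  x
}

make_records <- function(ids, morpho, provisional = FALSE,
                         provenance = "STUDY", taxon_class = "TestClass") {
  data.frame(specimen_id = ids, morphospecies = morpho,
             provisional = rep_len(provisional, length(ids)),
             provenance = rep_len(provenance, length(ids)),
             taxon_class = rep_len(taxon_class, length(ids)),
             stringsAsFactors = FALSE)
}

## Independent p-distance oracle: naive per-site double loop.
naive_pdist <- function(seqs, min_overlap = 100L) {
  n <- length(seqs)
  d <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  ov <- matrix(0L, n, n, dimnames = dimnames(d))
  bases <- c("A", "C", "G", "T")
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- chars[[i]]; b <- chars[[j]]
    mism <- 0L; comp <- 0L
    for (k in seq_along(a)) {
      if (a[k] %in% bases && b[k] %in% bases) {
        comp <- comp + 1L
        if (a[k] != b[k]) mism <- mism + 1L
      }
    }
    ov[i, j] <- comp
    d[i, j] <- if (comp >= min_overlap) mism / comp else NA_real_
  }
  diag(d) <- 0
  list(d = d, overlap = ov)
}

## Independent connected-components oracle: plain union-find.
union_find_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(d[i, j]) && d[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), rownames(d))
}

## Random aligned sequences (uniform bases, optional gap fraction).
random_alignment <- function(n, L, gap_frac = 0, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (gap_frac > 0) {
      g <- runif(L) < gap_frac
      s[g] <- "-"
    }
    paste0(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("q%02d", seq_len(n))
  attr(seqs, "aligned_length") <- L
  seqs
}

## Two-cluster toy distance matrix: intra <= a, inter >= b.
toy_two_cluster_dm <- function(n1 = 3, n2 = 3, a = 0.01, b = 0.10, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  ids <- sprintf("t%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  grp <- c(rep(1, n1), rep(2, n2))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- if (grp[i] == grp[j]) runif(1, 0, a) else runif(1, b, b + 0.05)
  }
  structure(list(ids = ids, d = d,
                 overlap = matrix(500L, n, n, dimnames = list(ids, ids)),
                 min_overlap = 100L),
            class = "pdist")
}

## Same truth grouping attached.
toy_two_cluster_truth <- function(n1 = 3, n2 = 3) {
  c(rep("A", n1), rep("B", n2))
}

## Independent GMYC interval log-likelihood recomputation at fixed
## parameters: walks the tree from root to present, recomputing lineage
## counts per interval from scratch.
naive_gmyc_loglik <- function(tree, Tt, lam1, lam2, p1 = 1, p2 = 1) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(n)]) - depth
  h[seq_len(n)] <- 0
  ev <- sort(h[(n + 1):(n + tree$Nnode)], decreasing = TRUE)
  bounds <- c(ev, 0)
  parent_h <- h[tree$edge[, 1]]
  child_h <- h[tree$edge[, 2]]
  ## cluster membership of every edge at threshold: which crossing edge is
  ## the lineage's ancestor at the threshold?
  cross <- which(parent_h > Tt & child_h <= Tt)
  tips_under <- function(node) {
    if (node <= n) return(node)
    out <- integer(0)
    for (ch in tree$edge[tree$edge[, 1] == node, 2])
      out <- c(out, tips_under(ch))
    out
  }
  cluster_tips <- lapply(cross, function(e) tips_under(tree$edge[e, 2]))
  logL <- 0
  for (k in seq_len(length(bounds) - 1)) {
    top <- bounds[k]; bot <- bounds[k + 1]
    x <- top - bot
    tmid <- (top + bot) / 2
    crossing <- which(parent_h > tmid & child_h <= tmid)
    if (tmid > Tt) {
      bk <- lam1 * length(crossing)^p1
    } else {
      C <- length(cluster_tips)
      nj <- vapply(cluster_tips, function(tp) {
        sum(vapply(crossing, function(e) {
          tt <- tips_under(tree$edge[e, 2])
          all(tt %in% tp)
        }, logical(1)))
      }, numeric(1))
      bk <- lam1 * C^p1 + lam2 * sum(nj * pmax(nj - 1, 0)^p2)
    }
    logL <- logL + (if (k < length(bounds) - 1) log(bk) else 0) - bk * x
  }
  logL
}

## Two shallow clades joined deep, terminal branches snapped so the tree
## is exactly ultrametric.
mk_two_clade_tree <- function(seed = 1, d1 = 0.01, d2 = 0.008, join = 1.0) {
  set.seed(seed)
  mk <- function(n, depth, labels) {
    st <- ape::rcoal(n, tip.label = labels)
    st$edge.length <- st$edge.length * depth / max(ape::node.depth.edgelength(st))
    st
  }
  a <- mk(5, d1, paste0("a", 1:5))
  b <- mk(5, d2, paste0("b", 1:5))
  txt <- sprintf("(%s:%.6f,%s:%.6f);",
                 sub(";$", "", ape::write.tree(a)), join - d1,
                 sub(";$", "", ape::write.tree(b)), join - d2)
  tr <- ape::read.tree(text = txt)
  dd <- ape::node.depth.edgelength(tr)
  nt <- length(tr$tip.label)
  term <- match(seq_len(nt), tr$edge[, 2])
  tr$edge.length[term] <- tr$edge.length[term] + max(dd[seq_len(nt)]) - dd[seq_len(nt)]
  tr
}
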